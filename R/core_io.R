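# Readers and writers for the external formats the pipeline touches, plus
# the shared coordinate and allele conventions.
#
# File conventions: FASTA for genomes and IS references, GFF3 for gene
# features, a TSV variant dialect (1-based positions in files), a minimal
# VCF 4.2 subset, and a two-column TSV of protein melting temperatures.

#' Construct a genome record
#'
#' A genome record is the substrate of every scan: one sequence with an
#' identifier, a circularity flag and a free-text description.
#'
#' @param id sequence identifier (unique within a set).
#' @param sequence DNA string over A,C,G,T,N (uppercased).
#' @param circular logical; circular genomes are scanned with wrap-around.
#' @param description free text.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, circular = FALSE, description = "") {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("genome record '", id, "' has empty sequence")
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L)
    stop("genome record '", id, "' has non-ACGTN character '",
         substr(sequence, bad, bad), "' at position ", bad)
  structure(list(id = as.character(id), sequence = sequence,
                 circular = isTRUE(circular),
                 description = as.character(description)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %s%s\n", x$id,
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear",
              if (nzchar(x$description)) paste0(" | ", x$description) else ""))
  invisible(x)
}

#' Read genomes from FASTA
#'
#' Sequences are uppercased and validated against the A,C,G,T,N alphabet.
#' The circular flag comes from `expect_circular` when given, otherwise
#' from a `circular=true` token in the FASTA header description.
#'
#' @param path FASTA file.
#' @param expect_circular logical or NULL.
#' @return A named list of [genome_record] objects.
#' @export
read_genome <- function(path, expect_circular = NULL) {
  if (!file.exists(path)) stop("no such FASTA file: ", path)
  # read without an alphabet first: DNA parsing would silently drop
  # invalid letters, and the contract is to reject them with a position
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  out <- vector("list", length(ss))
  for (i in seq_along(ss)) {
    header <- names(ss)[i]
    id <- sub("\\s.*$", "", header)
    desc <- sub("^\\S+\\s*", "", header)
    circ <- if (!is.null(expect_circular)) isTRUE(expect_circular)
            else grepl("circular=true", desc, ignore.case = TRUE)
    seq <- toupper(as.character(ss[[i]]))
    bad <- regexpr("[^ACGTN]", seq)
    if (bad > 0L)
      stop("FASTA record '", id, "' has non-ACGTN character '",
           substr(seq, bad, bad), "' at position ", bad)
    out[[i]] <- genome_record(id, seq, circ, desc)
  }
  ids <- vapply(out, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate record id in ", path, ": ", ids[duplicated(ids)][1])
  names(out) <- ids
  out
}

#' Write genomes to FASTA
#'
#' Circularity is preserved as a `circular=true` token in the header so
#' that `read_genome()` round-trips.
#'
#' @param genomes a `genome_record` or list of them.
#' @param path output file.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(seqs) <- vapply(genomes, function(g) {
    desc <- g$description
    if (g$circular && !grepl("circular=true", desc, ignore.case = TRUE))
      desc <- trimws(paste(desc, "circular=true"))
    trimws(paste(g$id, desc))
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

# ---- gene features ---------------------------------------------------------

FEATURE_KINDS <- c("CDS", "mobile_element", "prophage", "other")

#' Construct a gene feature table
#'
#' Internal coordinates are 0-based half-open; [read_features()] and
#' [write_features()] convert from/to the 1-based inclusive GFF3 file
#' convention.
#'
#' @param seq_id,gene,locus_tag,start,end,strand,kind,product,
#'   interrupted_in_reference vectors, recycled to common length.
#' @return data.frame of class `gene_features`.
#' @export
gene_features <- function(seq_id = character(), gene = character(),
                          locus_tag = character(), start = integer(),
                          end = integer(), strand = character(),
                          kind = character(), product = character(),
                          interrupted_in_reference = logical()) {
  df <- data.frame(seq_id = as.character(seq_id), gene = as.character(gene),
                   locus_tag = as.character(locus_tag),
                   start = as.integer(start), end = as.integer(end),
                   strand = as.character(strand), kind = as.character(kind),
                   product = as.character(product),
                   interrupted_in_reference =
                     as.logical(interrupted_in_reference),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$end < df$start))
      stop("feature with end < start: ",
           df$locus_tag[df$end < df$start][1])
    if (!all(df$kind %in% FEATURE_KINDS))
      stop("unknown feature kind: ",
           setdiff(unique(df$kind), FEATURE_KINDS)[1])
    if (any(df$kind == "CDS" & !df$strand %in% c("+", "-")))
      stop("CDS feature without a defined strand")
  }
  class(df) <- c("gene_features", "data.frame")
  df
}

# GFF3 type -> internal kind
.gff_kind <- function(type) {
  ifelse(type == "CDS", "CDS",
    ifelse(type %in% c("mobile_genetic_element", "mobile_element",
                       "insertion_sequence"), "mobile_element",
      ifelse(type %in% c("prophage", "sequence_feature"), "prophage",
             "other")))
}

#' Read gene features from GFF3
#'
#' Retains CDS, mobile-element and prophage features; maps the `gene`,
#' `locus_tag` and `product` attributes; ignores everything else.
#' An `interrupted=true` attribute marks genes already interrupted in the
#' reference ("#"-style flags).  Coordinates are converted to the internal
#' 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @param genome optional matching [genome_record] (or list); features
#'   beyond the sequence length are rejected.
#' @return A `gene_features` data.frame.
#' @export
read_features <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such GFF3 file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  kind <- .gff_kind(as.character(gr$type))
  keep <- kind %in% c("CDS", "mobile_element", "prophage")
  gr <- gr[keep]
  kind <- kind[keep]
  if (length(gr) == 0L) return(gene_features())
  col <- function(name) {
    v <- S4Vectors::mcols(gr)[[name]]
    if (is.null(v)) rep("", length(gr)) else {
      v <- as.character(v)
      ifelse(is.na(v), "", v)
    }
  }
  start1 <- GenomicRanges::start(gr)
  end1 <- GenomicRanges::end(gr)
  if (!is.null(genome)) {
    if (inherits(genome, "genome_record")) genome <- list(genome)
    lens <- setNames(vapply(genome, function(g) nchar(g$sequence), 0L),
                     vapply(genome, `[[`, "", "id"))
    seqid <- as.character(GenomicRanges::seqnames(gr))
    over <- seqid %in% names(lens) & end1 > lens[seqid]
    if (any(over))
      stop("feature beyond sequence length on ", seqid[over][1],
           " (end ", end1[over][1], ")")
  }
  gene_features(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    gene = col("gene"),
    locus_tag = col("locus_tag"),
    start = start1 - 1L, end = end1,
    strand = ifelse(as.character(BiocGenerics::strand(gr)) %in%
                      c("+", "-"),
                    as.character(BiocGenerics::strand(gr)), "."),
    kind = kind,
    product = col("product"),
    interrupted_in_reference = tolower(col("interrupted")) == "true")
}

#' Write gene features to GFF3
#'
#' @param features `gene_features` data.frame (internal coordinates).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  type <- c(CDS = "CDS", mobile_element = "mobile_genetic_element",
            prophage = "prophage", other = "region")[features$kind]
  gr <- GenomicRanges::GRanges(
    seqnames = features$seq_id,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = ifelse(features$strand %in% c("+", "-"),
                    features$strand, "*"))
  gr$type <- type
  gr$source <- "evotrace"
  gr$ID <- ifelse(nzchar(features$locus_tag), features$locus_tag,
                  paste0("feat", seq_len(nrow(features))))
  gr$gene <- features$gene
  gr$locus_tag <- features$locus_tag
  gr$product <- features$product
  gr$interrupted <- ifelse(features$interrupted_in_reference, "true", NA)
  gr$phase <- ifelse(features$kind == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# ---- variants --------------------------------------------------------------

VARIANT_CLASSES <- c("snp", "insertion", "deletion", "substitution",
                     "is_insertion", "large_deletion")

#' Construct a variant table
#'
#' One row per normalized change against a named reference.  `pos` is the
#' internal 0-based position of the first affected reference base; an
#' insertion at `pos` p inserts before reference base p.  `ref` is empty
#' for pure insertions, `alt` empty for pure deletions.
#'
#' @param strain,seq_id,pos,ref,alt,class,length,frequency,note vectors.
#' @return data.frame of class `variant_table`.
#' @export
variant_table <- function(strain = character(), seq_id = character(),
                          pos = integer(), ref = character(),
                          alt = character(), class = character(),
                          length = integer(), frequency = numeric(),
                          note = character()) {
  n <- max(length(strain), length(seq_id), length(pos), length(ref),
           length(alt), length(class))
  if (n > 0L) {
    if (missing(length) || !base::length(length))
      length <- pmax(nchar(as.character(ref)), nchar(as.character(alt)))
    if (!base::length(frequency)) frequency <- 1.0
    if (!base::length(note)) note <- ""
  }
  df <- data.frame(strain = as.character(strain),
                   seq_id = as.character(seq_id), pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   class = as.character(class), length = as.integer(length),
                   frequency = as.numeric(frequency),
                   note = as.character(note), stringsAsFactors = FALSE)
  if (nrow(df)) {
    bad <- setdiff(unique(df$class), VARIANT_CLASSES)
    if (base::length(bad)) stop("unknown event class: ", bad[1])
    if (any(!is.finite(df$frequency) | df$frequency <= 0 | df$frequency > 1))
      stop("frequency outside (0,1]")
    if (any(df$class == "snp" & (nchar(df$ref) != 1L | nchar(df$alt) != 1L)))
      stop("snp rows must have |ref| = |alt| = 1")
    if (any(!nzchar(df$ref) & !nzchar(df$alt)))
      stop("variant with both alleles empty")
  }
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Read variants from the TSV dialect or a minimal VCF
#'
#' TSV columns: strain, seq_id, pos (1-based), ref, alt, class, length,
#' frequency, note.  VCF 4.2 input is restricted to SNP/indel records;
#' shared anchor bases are stripped so indels follow the pure-allele
#' convention (empty ref for insertions, empty alt for deletions), and
#' positions are converted to the internal 0-based convention.
#'
#' @param path TSV or VCF file (detected by `##fileformat=VCF` / `.vcf`).
#' @return A `variant_table`.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("no such variant file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^##fileformat=VCF", first) ||
      grepl("\\.vcf$", path, ignore.case = TRUE))
    return(.read_vcf(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("strain", "seq_id", "pos", "ref", "alt", "class", "length",
            "frequency", "note")
  if (!all(need %in% names(df)))
    stop("variant TSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df$ref[is.na(df$ref)] <- ""; df$alt[is.na(df$alt)] <- ""
  df$note[is.na(df$note)] <- ""
  variant_table(df$strain, df$seq_id, as.integer(df$pos) - 1L, df$ref,
                df$alt, df$class, as.integer(df$length),
                as.numeric(df$frequency), df$note)
}

.read_vcf <- function(path) {
  fix <- vcfR::getFIX(suppressWarnings(
    vcfR::read.vcfR(path, verbose = FALSE)))
  if (is.null(fix) || nrow(fix) == 0L) return(variant_table())
  chrom <- fix[, "CHROM"]; pos1 <- as.integer(fix[, "POS"])
  ref <- toupper(fix[, "REF"]); alt <- toupper(fix[, "ALT"])
  if (any(grepl(",", alt)))
    stop("multi-allelic VCF records are not supported")
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    r <- ref[i]; a <- alt[i]; p0 <- pos1[i] - 1L
    # strip shared leading anchor base(s)
    while (nchar(r) > 0L && nchar(a) > 0L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L) &&
           (nchar(r) > 1L || nchar(a) > 1L)) {
      r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a))
      p0 <- p0 + 1L
    }
    cls <- if (nchar(r) == 1L && nchar(a) == 1L) "snp"
           else if (nchar(r) == 0L) "insertion"
           else if (nchar(a) == 0L) "deletion"
           else "substitution"
    out[[i]] <- data.frame(strain = "", seq_id = chrom[i], pos = p0,
                           ref = r, alt = a, class = cls,
                           length = max(nchar(r), nchar(a)),
                           frequency = 1.0, note = "",
                           stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  variant_table(df$strain, df$seq_id, df$pos, df$ref, df$alt, df$class,
                df$length, df$frequency, df$note)
}

#' Write variants to the TSV dialect
#'
#' Positions are written 1-based per the file convention.
#'
#' @param variants a `variant_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  out <- as.data.frame(variants)
  out$pos <- out$pos + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write variants as a minimal VCF 4.2
#'
#' Indels are re-anchored on the preceding reference base as VCF requires,
#' which needs the reference genome.
#'
#' @param variants a `variant_table` (snp/insertion/deletion/substitution
#'   rows; IS insertions and large deletions are written as their allele
#'   representation).
#' @param genome the reference [genome_record].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", genome$id, ",length=",
                  nchar(genome$sequence), ">"),
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"))
  rows <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (nzchar(v$ref) && nzchar(v$alt)) {
      pos1 <- v$pos + 1L; r <- v$ref; a <- v$alt
    } else {
      # anchor on the preceding base
      anchor <- substr(genome$sequence, v$pos, v$pos)
      pos1 <- v$pos; r <- paste0(anchor, v$ref); a <- paste0(anchor, v$alt)
    }
    rows[i] <- paste(v$seq_id, pos1, ".", r, a, ".", "PASS",
                     paste0("CLASS=", v$class), sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# ---- melting temperatures --------------------------------------------------

#' Read a protein melting-temperature table
#'
#' Two-column TSV (`locus_tag`, `tm` in degrees Celsius), one row per
#' locus tag; duplicates and non-numeric temperatures are rejected.
#'
#' @param path TSV file.
#' @return data.frame with columns `locus_tag`, `tm`.
#' @export
read_tm_table <- function(path) {
  if (!file.exists(path)) stop("no such Tm table: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("locus_tag", "tm") %in% names(df)))
    stop("Tm table must have columns locus_tag, tm")
  if (anyDuplicated(df$locus_tag))
    stop("duplicate locus_tag in Tm table: ",
         df$locus_tag[duplicated(df$locus_tag)][1])
  tm <- suppressWarnings(as.numeric(df$tm))
  if (any(is.na(tm) | !is.finite(tm)))
    stop("non-numeric melting temperature for ",
         df$locus_tag[is.na(tm) | !is.finite(tm)][1])
  data.frame(locus_tag = df$locus_tag, tm = tm, stringsAsFactors = FALSE)
}
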