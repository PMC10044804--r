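# Insertion-sequence detection, composite-transposon flagging, target-site
# duplication extraction, degenerate target consensus, and hybrid-element
# classification against two reference alleles.

# IUPAC degenerate letter for a set of bases
.iupac_for <- function(bases) {
  bases <- sort(unique(bases))
  map <- Biostrings::IUPAC_CODE_MAP
  hit <- names(map)[vapply(map, function(s)
    identical(sort(strsplit(s, "")[[1L]]), bases), TRUE)]
  if (length(hit) == 0L) "N" else hit[1L]
}

#' Find copies of an insertion-sequence element in a genome
#'
#' Seeds with `k`-mers of the reference element on both strands, merges
#' seed hits into candidate intervals, extends each candidate to the
#' reference length, and scores it by alignment.  Overlapping candidates
#' are deduplicated keeping the highest identity; circular genomes are
#' scanned across the origin.
#'
#' @param genome [genome_record].
#' @param is_reference element sequence (character, [genome_record] or a
#'   single-record list from [read_genome()]).
#' @param family element family name recorded in the output.
#' @param min_identity minimum identity over the aligned span.
#' @param min_coverage minimum fraction of the reference length matched.
#' @param k seed length.
#' @return data.frame of class `is_copies`: family, seq_id, start, end
#'   (0-based half-open; may exceed the genome length when a copy spans
#'   the origin of a circular genome), strand, identity, coverage,
#'   in_composite.
#' @export
find_is_copies <- function(genome, is_reference, family = "IS",
                           min_identity = 0.95, min_coverage = 0.90,
                           k = 15L) {
  ref <- if (inherits(is_reference, "genome_record")) is_reference$sequence
         else if (is.list(is_reference)) is_reference[[1L]]$sequence
         else toupper(is_reference)
  if (nchar(ref) < 2L * k)
    stop("IS reference must be at least 2k bp (", 2L * k, ")")
  L <- nchar(genome$sequence)
  refL <- nchar(ref)
  # circular wraparound: append the leading refL bases
  subject <- if (genome$circular)
    paste0(genome$sequence, substr(genome$sequence, 1L, refL)) else
    genome$sequence
  subj <- Biostrings::DNAString(subject)

  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                      mismatch = -2)
  rows <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") ref else revcomp(ref)
    starts <- seq(1L, nchar(q) - k + 1L, by = k)  # non-overlapping seeds
    seeds <- unique(substring(q, starts, starts + k - 1L))
    seeds <- seeds[!grepl("N", seeds)]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
    mt <- Biostrings::matchPDict(pd, subj)
    pos <- sort(unique(unlist(lapply(mt, IRanges::start))))
    if (length(pos) == 0L) next
    # coarse clusters; a cluster may hold several adjacent copies, which
    # are resolved below by iterative align-and-mask
    grp <- cumsum(c(TRUE, diff(pos) > refL))
    qd <- Biostrings::DNAString(q)
    for (g in split(pos, grp)) {
      pad <- refL + 30L
      cs <- max(0L, min(g) - 1L - pad)
      ce <- min(nchar(subject), max(g) - 1L + k + pad)
      win <- substr(subject, cs + 1L, ce)
      for (iter in seq_len(20L)) {
        aln <- Biostrings::pairwiseAlignment(
          qd, Biostrings::DNAString(win), type = "overlap",
          substitutionMatrix = sub_mat, gapOpening = 4, gapExtension = 1)
        prng <- as.data.frame(Biostrings::pattern(aln)@range)
        srng <- as.data.frame(Biostrings::subject(aln)@range)
        span <- srng$end - srng$start + 1L
        if (span < k) break
        identity <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
        coverage <- prng$width / refL
        if (identity < min_identity || coverage < min_coverage) break
        # extend an ends-free-trimmed span to the full element length
        aln_start <- cs + srng$start - 1L - (prng$start - 1L)
        aln_end <- cs + srng$end + (refL - prng$end)
        rows[[length(rows) + 1L]] <- data.frame(
          family = family, seq_id = genome$id,
          start = max(0L, aln_start),
          end = min(nchar(subject), aln_end), strand = strand,
          identity = identity, coverage = coverage, in_composite = FALSE,
          stringsAsFactors = FALSE)
        # mask the matched span and look for another copy in the cluster
        win <- paste0(substr(win, 1L, srng$start - 1L),
                      strrep("N", span),
                      substr(win, srng$end + 1L, nchar(win)))
      }
    }
  }
  if (length(rows) == 0L) return(.empty_is_copies())
  out <- do.call(rbind, rows)
  # map wraparound copies back into [0, L) and drop duplicated images
  wrap <- out$start >= L
  out$start[wrap] <- out$start[wrap] - L
  out$end[wrap] <- out$end[wrap] - L
  out <- out[order(out$start, -out$identity), ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1L]) {
    prior <- which(keep[seq_len(i - 1L)])
    ovlen <- pmin(out$end[i], out$end[prior]) -
      pmax(out$start[i], out$start[prior])
    minlen <- pmin(out$end[i] - out$start[i],
                   out$end[prior] - out$start[prior])
    if (any(ovlen > 0.5 * minlen)) keep[i] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("is_copies", "data.frame")
  out
}

.empty_is_copies <- function() {
  out <- data.frame(family = character(), seq_id = character(),
                    start = integer(), end = integer(),
                    strand = character(), identity = numeric(),
                    coverage = numeric(), in_composite = logical(),
                    stringsAsFactors = FALSE)
  class(out) <- c("is_copies", "data.frame")
  out
}

#' Flag composite-transposon ends among IS copies
#'
#' Same-family copy pairs whose inner cargo gap is at most `max_cargo` bp
#' and contains at least one annotated CDS are flagged as composite ends;
#' requiring a cargo CDS keeps two adjacent independent insertions from
#' being merged into a spurious transposon.
#'
#' The cargo test uses CDS annotation when `features` is given in the same
#' coordinate frame as the copies; otherwise (e.g. when the scanned genome
#' is annotated only through a diverged reference) supply `genome` and the
#' cargo is required to contain an open reading frame of at least
#' `min_cargo_orf` bp.
#'
#' @param copies `is_copies` table from one genome.
#' @param features `gene_features` in the same frame as `copies`, or NULL.
#' @param max_cargo maximum cargo span, bp.
#' @param genome the scanned [genome_record], for the ORF-based cargo test.
#' @param min_cargo_orf minimum cargo ORF length, bp; random sequence of
#'   cargo size routinely contains chance ORFs up to ~200 codons, so the
#'   default asks for a gene-sized one.
#' @return the `is_copies` table with `in_composite` set.
#' @export
flag_composite <- function(copies, features = NULL, max_cargo = 15000L,
                           genome = NULL, min_cargo_orf = 600L) {
  if (nrow(copies) < 2L) return(copies)
  if (is.null(features) && is.null(genome))
    stop("flag_composite needs features or a genome for the cargo test")
  cds <- if (!is.null(features))
    features[features$kind == "CDS", , drop = FALSE] else NULL
  ord <- order(copies$start)
  for (a in seq_along(ord)[-length(ord)]) {
    i <- ord[a]; j <- ord[a + 1L]
    if (copies$family[i] != copies$family[j]) next
    gap_s <- copies$end[i]; gap_e <- copies$start[j]
    if (gap_e - gap_s <= 0L || gap_e - gap_s > max_cargo) next
    has_cargo <- if (!is.null(cds)) {
      any(cds$start >= gap_s & cds$end <= gap_e)
    } else {
      gap_seq <- substr(genome$sequence, gap_s + 1L, gap_e)
      orf_f <- .longest_orf(gap_seq)
      orf_r <- .longest_orf(revcomp(gap_seq))
      longest <- max(if (is.null(orf_f)) 0L else orf_f[2L] - orf_f[1L] + 1L,
                     if (is.null(orf_r)) 0L else orf_r[2L] - orf_r[1L] + 1L)
      longest >= min_cargo_orf
    }
    if (has_cargo) copies$in_composite[c(i, j)] <- TRUE
  }
  copies
}

#' Extract target-site duplications flanking an IS copy
#'
#' @param genome [genome_record].
#' @param copy one row of an `is_copies` table (or a list with
#'   `start`/`end`).
#' @param tsd_length duplication length, bp (9 for IS10-type elements).
#' @return list with `tsd_left`, `tsd_right`, `tsd_match` and
#'   `target_site` (the duplicated word when matched, else `NA`).
#' @export
extract_tsd <- function(genome, copy, tsd_length = 9L) {
  L <- nchar(genome$sequence)
  s <- copy$start; e <- copy$end
  if (!genome$circular && (s - tsd_length < 0L || e + tsd_length > L))
    return(list(tsd_left = NA_character_, tsd_right = NA_character_,
                tsd_match = FALSE, target_site = NA_character_))
  left <- subseq0(genome$sequence, s - tsd_length, s, genome$circular)
  right <- subseq0(genome$sequence, e, e + tsd_length, genome$circular)
  match <- identical(left, right)
  list(tsd_left = left, tsd_right = right, tsd_match = match,
       target_site = if (match) left else NA_character_)
}

#' Annotate an IS copy table with target-site duplications
#'
#' Convenience wrapper applying [extract_tsd()] to every copy.
#'
#' @param genome [genome_record].
#' @param copies `is_copies` table.
#' @param tsd_length duplication length, bp.
#' @return the table with columns `tsd_left`, `tsd_right`, `tsd_match`,
#'   `target_site` added.
#' @export
add_tsds <- function(genome, copies, tsd_length = 9L) {
  tl <- character(nrow(copies)); tr <- character(nrow(copies))
  tm <- logical(nrow(copies)); ts <- character(nrow(copies))
  for (i in seq_len(nrow(copies))) {
    t <- extract_tsd(genome, copies[i, ], tsd_length)
    tl[i] <- t$tsd_left; tr[i] <- t$tsd_right
    tm[i] <- t$tsd_match; ts[i] <- t$target_site
  }
  copies$tsd_left <- tl; copies$tsd_right <- tr
  copies$tsd_match <- tm; copies$target_site <- ts
  copies
}

#' Build a degenerate consensus motif from target sites
#'
#' Per position, the included base set is every base observed in at least
#' `freq_threshold` of the sites (ties at the threshold included); the
#' reported letter is the minimal IUPAC code covering exactly that set.
#'
#' @param target_sites character vector of equal-width sites.
#' @param freq_threshold inclusion frequency (default 0.25).
#' @return list of class `consensus_motif` with `width`, `counts`
#'   (4 x width matrix), `iupac` and `n_sites`.
#' @export
build_consensus <- function(target_sites, freq_threshold = 0.25) {
  target_sites <- toupper(target_sites[!is.na(target_sites)])
  if (length(target_sites) == 0L) stop("no target sites supplied")
  w <- unique(nchar(target_sites))
  if (length(w) != 1L)
    stop("target sites have mixed widths: ", paste(w, collapse = ", "))
  mat <- do.call(rbind, strsplit(target_sites, ""))
  counts <- vapply(seq_len(w), function(j)
    vapply(DNA_BASES, function(b) sum(mat[, j] == b), 0L),
    integer(4))
  rownames(counts) <- DNA_BASES
  n <- length(target_sites)
  iupac <- paste(vapply(seq_len(w), function(j) {
    inc <- DNA_BASES[counts[, j] / n >= freq_threshold]
    if (length(inc) == 0L) inc <- DNA_BASES[which.max(counts[, j])]
    .iupac_for(inc)
  }, ""), collapse = "")
  structure(list(width = w, counts = counts, iupac = iupac, n_sites = n),
            class = "consensus_motif")
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat(sprintf("<consensus_motif> %s (width %d, %d sites)\n",
              x$iupac, x$width, x$n_sites))
  invisible(x)
}

#' Classify an element copy against two reference alleles
#'
#' Diagnostic positions are the loci where the two alleles differ; the
#' copy is called A, B or neither at each.  Coding changes are reported by
#' translating the element's transposase ORF against the better-matching
#' allele.
#'
#' @param copy_sequence the element copy (character).
#' @param alleleA,alleleB reference alleles, equal length.
#' @param nameA,nameB allele labels.
#' @return list with `positions` (data.frame offset/alleleA/alleleB/
#'   observed/call), `calls` summary counts, `better_allele` and
#'   `coding_changes` (character vector like "V301I").
#' @export
classify_against_alleles <- function(copy_sequence, alleleA, alleleB,
                                     nameA = "A", nameB = "B") {
  a <- toupper(alleleA); b <- toupper(alleleB)
  s <- toupper(copy_sequence)
  if (nchar(a) != nchar(b))
    stop("alleles must have equal length after alignment")
  if (nchar(s) < 0.9 * nchar(a))
    stop("copy covers less than 90% of the allele length")
  if (nchar(s) != nchar(a)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(s), Biostrings::DNAString(a), type = "global")
    s <- gsub("-", "N", as.character(Biostrings::alignedPattern(aln)))
    if (nchar(s) != nchar(a))
      stop("copy cannot be aligned collinearly to the alleles")
  }
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  sv <- strsplit(s, "")[[1L]]
  d <- which(av != bv)
  call <- ifelse(sv[d] == av[d], nameA,
                 ifelse(sv[d] == bv[d], nameB, "neither"))
  positions <- data.frame(offset = d - 1L, alleleA = av[d], alleleB = bv[d],
                          observed = sv[d], call = call,
                          stringsAsFactors = FALSE)
  tab <- table(factor(call, levels = c(nameA, nameB, "neither")))
  better <- if (tab[[nameA]] >= tab[[nameB]]) a else b
  better_name <- if (tab[[nameA]] >= tab[[nameB]]) nameA else nameB
  # transposase ORF = longest ORF of the better-matching allele
  orf <- .longest_orf(better)
  coding <- character()
  if (!is.null(orf)) {
    ref_aa <- translate_dna(substr(better, orf[1L], orf[2L]))
    obs_aa <- translate_dna(substr(s, orf[1L], orf[2L]))
    n <- min(nchar(ref_aa), nchar(obs_aa))
    rv <- strsplit(substr(ref_aa, 1L, n), "")[[1L]]
    ov <- strsplit(substr(obs_aa, 1L, n), "")[[1L]]
    diffs <- which(rv != ov & ov != "X")
    coding <- sprintf("%s%d%s", rv[diffs], diffs, ov[diffs])
  }
  list(positions = positions, calls = as.list(tab),
       better_allele = better_name, coding_changes = coding)
}

# 1-based (start, end) of the longest forward-frame ORF (ATG..stop)
.longest_orf <- function(seq) {
  best <- NULL
  n <- nchar(seq)
  for (frame in 0:2) {
    i <- frame + 1L
    start <- NA_integer_
    while (i + 2L <= n) {
      codon <- substr(seq, i, i + 2L)
      if (is.na(start) && codon == "ATG") start <- i
      if (!is.na(start) && codon %in% c("TAA", "TAG", "TGA")) {
        if (is.null(best) || (i + 2L - start) > (best[2L] - best[1L]))
          best <- c(start, i + 2L)
        start <- NA_integer_
      }
      i <- i + 3L
    }
  }
  best
}
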