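# Variant consequence annotation, the knockout rule, and gene-list
# cross-referencing.
#
# The knockout rule follows the convention used for evolved-strain
# reporting: a frameshift, truncation or IS insertion removing more than
# `loss_threshold` (default 10%) of a protein's residues, or complete
# deletion of the gene.

# transcript-orientation CDS sequence of a feature
.cds_seq <- function(reference, f) {
  s <- substr(reference$sequence, f$start + 1L, f$end)
  if (f$strand == "-") revcomp(s) else s
}

# transcript offset (0-based) of the first affected base of a variant
# footprint [p, p + w) in feature f (w = 0 for insertions)
.toff <- function(f, p, w) {
  if (f$strand == "+") p - f$start else f$end - p - max(w, 0L)
}

.call_row <- function(variant_idx, strain, gene, effect,
                      codon = NA_integer_, total = NA_integer_,
                      fraction_lost = NA_real_, knockout = FALSE,
                      substitution = "", flank5 = "", flank3 = "",
                      upstream_of = "") {
  data.frame(variant_idx = variant_idx, strain = strain, gene = gene,
             effect = effect, codon_affected = codon,
             total_codons = total, fraction_lost = fraction_lost,
             knockout = knockout, substitution = substitution,
             flank5 = flank5, flank3 = flank3, upstream_of = upstream_of,
             stringsAsFactors = FALSE)
}

#' Annotate variant consequences on gene features
#'
#' For each variant, every affected CDS yields one consequence call:
#' `silent`/`missense`/`nonsense_truncation` for SNPs (by strand-aware
#' codon translation), `frameshift` for length-changing indels not a
#' multiple of 3, `start_codon_change` for changes to the annotated start
#' codon, `is_insertion_in_gene` for IS insertions inside a CDS,
#' `gene_deleted` for genes wholly inside a large deletion, truncation for
#' genes cut by a deletion breakpoint.  Intergenic variants report the
#' flanking genes and are `intergenic_upstream` when within
#' `upstream_window` bp 5' of a start codon.
#'
#' `codon_affected` is the first codon whose encoded residue changes (for
#' frameshifts, the codon containing the first shifted base);
#' `total_codons` is the protein length excluding the stop codon;
#' `fraction_lost = (total - affected + 1) / total` for truncating
#' classes.  `knockout` marks truncating calls losing more than
#' `loss_threshold` of the residues, and whole-gene deletions.
#'
#' @param variants normalized `variant_table`.
#' @param features `gene_features`.
#' @param reference [genome_record].
#' @param upstream_window bp 5' of a start codon regarded as promoter/RBS
#'   territory (default 50).
#' @param loss_threshold residue-loss fraction above which a truncating
#'   call is a knockout (default 0.10).
#' @return data.frame of consequence calls.
#' @export
annotate <- function(variants, features, reference, upstream_window = 50L,
                     loss_threshold = 0.10) {
  cds <- features[features$kind == "CDS", , drop = FALSE]
  out <- list()
  add <- function(row) out[[length(out) + 1L]] <<- row
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    w <- nchar(v$ref)
    vs <- v$pos; ve <- v$pos + w      # reference footprint [vs, ve)
    if (w == 0L) {
      inside <- cds$start < vs & cds$end > vs
    } else {
      inside <- cds$start < ve & cds$end > vs
    }
    hits <- cds[inside, , drop = FALSE]
    if (nrow(hits) == 0L) {
      add(.intergenic_call(i, v, cds, upstream_window))
      next
    }
    for (h in seq_len(nrow(hits))) {
      f <- hits[h, ]
      total <- (f$end - f$start) %/% 3L - 1L
      if (w > 0L && vs <= f$start && ve >= f$end) {
        add(.call_row(i, v$strain, f$locus_tag, "gene_deleted",
                      codon = 1L, total = total, fraction_lost = 1,
                      knockout = TRUE))
        next
      }
      if (v$class %in% c("large_deletion", "deletion") &&
          (vs <= f$start || ve >= f$end)) {
        # breakpoint cuts the gene: truncation from the breakpoint codon
        toff <- if (f$strand == "+") {
          if (vs > f$start) vs - f$start else 0L
        } else {
          if (ve < f$end) f$end - ve else 0L
        }
        codon <- toff %/% 3L + 1L
        fl <- (total - codon + 1L) / total
        add(.call_row(i, v$strain, f$locus_tag, "nonsense_truncation",
                      codon = codon, total = total, fraction_lost = fl,
                      knockout = fl > loss_threshold))
        next
      }
      if (v$class == "is_insertion") {
        toff <- .toff(f, vs, 0L)
        codon <- max(1L, toff %/% 3L + 1L)
        fl <- (total - codon + 1L) / total
        add(.call_row(i, v$strain, f$locus_tag, "is_insertion_in_gene",
                      codon = codon, total = total, fraction_lost = fl,
                      knockout = fl > loss_threshold))
        next
      }
      add(.coding_call(i, v, f, reference, total, loss_threshold))
    }
  }
  do.call(rbind, out)
}

.intergenic_call <- function(i, v, cds, w) {
  up <- cds[cds$end <= v$pos, , drop = FALSE]
  dn <- cds[cds$start >= v$pos + max(nchar(v$ref), 0L), , drop = FALSE]
  flank5 <- if (nrow(up)) up$locus_tag[which.max(up$end)] else ""
  flank3 <- if (nrow(dn)) dn$locus_tag[which.min(dn$start)] else ""
  upstream_of <- ""
  # within w bp 5' of a start codon, strand-aware
  if (nrow(dn)) {
    g <- dn[which.min(dn$start), ]
    if (g$strand == "+" && g$start - v$pos <= w) upstream_of <- g$locus_tag
  }
  if (upstream_of == "" && nrow(up)) {
    g <- up[which.max(up$end), ]
    if (g$strand == "-" && v$pos - g$end <= w) upstream_of <- g$locus_tag
  }
  .call_row(i, v$strain, "", ifelse(nzchar(upstream_of),
                                    "intergenic_upstream",
                                    "intergenic_other"),
            flank5 = flank5, flank3 = flank3, upstream_of = upstream_of)
}

.coding_call <- function(i, v, f, reference, total, loss_threshold) {
  tseq <- .cds_seq(reference, f)
  w <- nchar(v$ref)
  toff <- .toff(f, v$pos, w)
  # start-codon change
  alt_t <- if (f$strand == "-") revcomp(v$alt) else v$alt
  ref_t <- if (f$strand == "-") revcomp(v$ref) else v$ref
  if (w > 0L && w == nchar(v$alt) && toff < 3L) {
    return(.call_row(i, v$strain, f$locus_tag, "start_codon_change",
                     codon = 1L, total = total,
                     substitution = sprintf("%s>%s",
                                            substr(tseq, 1L, 3L),
                                            .mutate_start(tseq, toff,
                                                          alt_t))))
  }
  if (w == nchar(v$alt)) {                  # SNP or equal-length MNP
    mut <- paste0(substr(tseq, 1L, toff),
                  alt_t,
                  substr(tseq, toff + w + 1L, nchar(tseq)))
    return(.compare_translation(i, v, f, tseq, mut, total,
                                loss_threshold))
  }
  # indel
  frameshift <- (nchar(v$alt) - w) %% 3L != 0L
  mut <- paste0(substr(tseq, 1L, toff), alt_t,
                substr(tseq, toff + w + 1L, nchar(tseq)))
  if (frameshift) {
    codon <- toff %/% 3L + 1L
    fl <- (total - codon + 1L) / total
    return(.call_row(i, v$strain, f$locus_tag, "frameshift",
                     codon = codon, total = total, fraction_lost = fl,
                     knockout = fl > loss_threshold))
  }
  .compare_translation(i, v, f, tseq, mut, total, loss_threshold)
}

.mutate_start <- function(tseq, toff, alt_t) {
  s <- substr(tseq, 1L, 3L)
  substr(s, toff + 1L, toff + nchar(alt_t)) <- alt_t
  s
}

.compare_translation <- function(i, v, f, tseq, mut, total,
                                 loss_threshold) {
  ref_aa <- translate_dna(tseq)
  mut_aa <- translate_dna(mut)
  if (identical(ref_aa, mut_aa))
    return(.call_row(i, v$strain, f$locus_tag, "silent",
                     codon = .toff(f, v$pos, nchar(v$ref)) %/% 3L + 1L,
                     total = total))
  # premature = a stop strictly before the mutated CDS's own final codon
  stop_mut <- as.integer(regexpr("*", mut_aa, fixed = TRUE))
  if (stop_mut > 0L && stop_mut < nchar(mut_aa)) {
    fl <- (total - stop_mut + 1L) / total
    return(.call_row(i, v$strain, f$locus_tag, "nonsense_truncation",
                     codon = stop_mut, total = total,
                     fraction_lost = fl,
                     knockout = fl > loss_threshold))
  }
  n <- min(nchar(ref_aa), nchar(mut_aa))
  rv <- strsplit(substr(ref_aa, 1L, n), "")[[1L]]
  mv <- strsplit(substr(mut_aa, 1L, n), "")[[1L]]
  d <- which(rv != mv)
  first <- if (length(d)) d[1L] else n + 1L
  subst <- if (length(d) == 1L)
    sprintf("%s%d%s", rv[d], d, mv[d]) else ""
  .call_row(i, v$strain, f$locus_tag, "missense", codon = first,
            total = total, substitution = subst)
}

#' Apply the knockout rule across a call set
#'
#' The knocked-out set is the union of genes wholly inside large
#' deletions and genes with truncating calls (frameshift, nonsense
#' truncation, IS insertion) losing more than `loss_threshold` of their
#' residues.  Genes flagged as already interrupted in the reference are
#' reported separately, not counted.
#'
#' @param calls output of [annotate()].
#' @param features `gene_features`.
#' @param loss_threshold residue-loss fraction (default 0.10).
#' @return list with `knocked_out` and `preexisting_interruptions`
#'   (character vectors of locus tags).
#' @export
call_knockouts <- function(calls, features, loss_threshold = 0.10) {
  if (is.null(calls) || nrow(calls) == 0L)
    return(list(knocked_out = character(),
                preexisting_interruptions = character()))
  trunc_ok <- calls$effect %in% c("frameshift", "nonsense_truncation",
                                  "is_insertion_in_gene") &
    !is.na(calls$fraction_lost) & calls$fraction_lost > loss_threshold
  ko <- unique(calls$gene[trunc_ok | calls$effect == "gene_deleted"])
  ko <- ko[nzchar(ko)]
  pre <- features$locus_tag[features$interrupted_in_reference]
  list(knocked_out = sort(setdiff(ko, pre)),
       preexisting_interruptions = sort(intersect(ko, pre)))
}

#' Cross-reference consequence calls against named gene lists
#'
#' @param calls output of [annotate()].
#' @param gene_lists named list of locus-tag vectors (e.g. essential,
#'   heat-shock, low-Tm genes).  Unknown locus tags produce a warning.
#' @param features optional `gene_features` used to check list membership.
#' @return list with `summary` (per list: intragenic and
#'   intergenic-adjacent hit counts) and `per_gene` (the calls touching
#'   each listed gene).
#' @export
crossref_gene_sets <- function(calls, gene_lists, features = NULL) {
  if (is.null(calls)) calls <- .call_row(integer(), character(),
                                         character(), character())[0L, ]
  summaries <- list()
  per_gene <- list()
  for (nm in names(gene_lists)) {
    tags <- unique(gene_lists[[nm]])
    if (!is.null(features)) {
      unknown <- setdiff(tags, features$locus_tag)
      if (length(unknown))
        warning("gene list '", nm, "' has unknown locus tags: ",
                paste(head(unknown, 3L), collapse = ", "),
                if (length(unknown) > 3L) ", ..." else "")
    }
    intra <- calls[calls$gene %in% tags, , drop = FALSE]
    inter <- calls[startsWith(calls$effect, "intergenic") &
                     (calls$flank5 %in% tags | calls$flank3 %in% tags), ,
                   drop = FALSE]
    summaries[[nm]] <- data.frame(
      list = nm, n_genes = length(tags),
      n_intragenic_hits = nrow(intra),
      n_genes_hit = length(unique(intra$gene)),
      n_intergenic_adjacent = nrow(inter), stringsAsFactors = FALSE)
    if (nrow(intra)) {
      intra$list <- nm
      per_gene[[nm]] <- intra
    }
  }
  list(summary = do.call(rbind, summaries),
       per_gene = if (length(per_gene)) do.call(rbind, per_gene) else NULL)
}
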