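# Characterization of large deletions and scaffold ends: junction
# microhomology, in-frame gene fusions, precise element excision,
# IS-flanked recombination, and terminal-repeat circularization.

#' Junction microhomology of a deletion
#'
#' For a deletion of the 0-based half-open interval `[del_start, del_end)`
#' the microhomology is the longest common suffix of the two prefixes
#' ending at the breakpoints plus the longest common prefix of the two
#' suffixes starting there.  This definition is placement-invariant: the
#' junction may sit anywhere inside the homologous tract, and every
#' breakpoint placement inside `placement_range` yields the identical
#' post-deletion sequence.  The canonical breakpoint is the leftmost.
#'
#' @param reference [genome_record] (or plain DNA string).
#' @param del_start,del_end 0-based half-open deleted interval.
#' @param max_m cap on the scanned homology length.
#' @return list with `mh_length`, `mh_sequence`, `placement_range`
#'   (0-based start positions of equivalent deletions) and `category`
#'   (`"microhomology"` when `mh_length` > 0, else `"blunt"`).
#' @export
microhomology <- function(reference, del_start, del_end, max_m = 5000L) {
  seq <- if (inherits(reference, "genome_record")) reference$sequence
         else reference
  L <- nchar(seq)
  if (!(del_start >= 0L && del_start < del_end && del_end <= L))
    stop("invalid deletion interval [", del_start, ", ", del_end, ")")
  cap <- max_m
  # suffixes of prefixes ending at the two breakpoints
  suf <- 0L
  while (suf < cap && del_start - suf >= 1L &&
         substr(seq, del_start - suf, del_start - suf) ==
         substr(seq, del_end - suf, del_end - suf))
    suf <- suf + 1L
  # prefixes of suffixes starting at the two breakpoints
  pre <- 0L
  while (pre < cap - suf && del_end + 1L + pre <= L &&
         substr(seq, del_start + 1L + pre, del_start + 1L + pre) ==
         substr(seq, del_end + 1L + pre, del_end + 1L + pre))
    pre <- pre + 1L
  m <- suf + pre
  mh_seq <- if (m > 0L)
    substr(seq, del_start - suf + 1L, del_start + pre) else ""
  list(mh_length = m, mh_sequence = mh_seq,
       placement_range = c(del_start - suf, del_start + pre),
       category = if (m > 0L) "microhomology" else "blunt")
}

#' Detect a gene fusion created by a deletion
#'
#' Fires when both breakpoints fall inside CDS features on the same
#' strand.  The fusion is in frame iff the breakpoint offsets agree
#' modulo 3 (strand-adjusted).  Retained residue ranges are reported
#' maximally: the 5' range under the rightmost equivalent breakpoint
#' placement and the 3' range under the leftmost, so a junction inside a
#' homologous tract credits the shared residues to both partners, the
#' way fusion proteins are conventionally described.
#'
#' @param features `gene_features` of the reference.
#' @param del_start,del_end 0-based half-open deleted interval.
#' @param reference [genome_record].
#' @return `NULL` when no fusion, else list with `gene5`, `gene3`
#'   (feature rows), `retained5`, `retained3` (residue ranges, 1-based),
#'   `in_frame`, `fusion_length` (residues) and `fusion_protein`.
#' @export
detect_fusion <- function(features, del_start, del_end, reference) {
  cds <- features[features$kind == "CDS", , drop = FALSE]
  hit5 <- cds[cds$start < del_start & cds$end > del_start, , drop = FALSE]
  hit3 <- cds[cds$start < del_end & cds$end > del_end, , drop = FALSE]
  if (nrow(hit5) == 0L || nrow(hit3) == 0L) return(NULL)
  g5 <- hit5[1L, ]; g3 <- hit3[1L, ]
  if (g5$strand != g3$strand) return(NULL)
  if (identical(g5$locus_tag, g3$locus_tag) &&
      g5$start == g3$start) return(NULL)
  mh <- microhomology(reference, del_start, del_end)
  left <- mh$placement_range[1L]   # leftmost equivalent del_start
  right <- mh$placement_range[2L]  # rightmost equivalent del_start
  shift <- del_end - del_start
  if (g5$strand == "+") {
    off5 <- del_start - g5$start
    off3 <- del_end - g3$start
    in_frame <- (off5 %% 3L) == (off3 %% 3L)
    retained5 <- c(1L, (right - g5$start) %/% 3L)
    retained3 <- c((left + shift - g3$start) %/% 3L + 1L,
                   (g3$end - g3$start) %/% 3L - 1L)
    fused_nt <- paste0(
      substr(reference$sequence, g5$start + 1L, del_start),
      substr(reference$sequence, del_end + 1L, g3$end))
  } else {
    # minus strand: 5' partner is the gene containing the RIGHT breakpoint
    tmp <- g5; g5 <- g3; g3 <- tmp
    off5 <- g5$end - del_end
    off3 <- g3$end - del_start
    in_frame <- (off5 %% 3L) == (off3 %% 3L)
    retained5 <- c(1L, (g5$end - left - shift) %/% 3L)
    retained3 <- c((g3$end - right) %/% 3L + 1L,
                   (g3$end - g3$start) %/% 3L - 1L)
    fused_nt <- revcomp(paste0(
      substr(reference$sequence, g3$start + 1L, del_start),
      substr(reference$sequence, del_end + 1L, g5$end)))
  }
  prot <- translate_dna(fused_nt)
  stop_at <- regexpr("*", prot, fixed = TRUE)
  if (in_frame && stop_at > 0L && stop_at < nchar(prot))
    in_frame <- FALSE  # premature stop before the 3' partner's stop
  fusion_len <- if (stop_at > 0L) stop_at - 1L else nchar(prot)
  list(gene5 = g5, gene3 = g3, retained5 = retained5,
       retained3 = retained3, in_frame = in_frame,
       fusion_length = as.integer(fusion_len),
       fusion_protein = sub("\\*.*$", "", prot))
}

#' Classify a large deletion
#'
#' Categories, in precedence order: `precise_element_excision` when the
#' breakpoints coincide with an annotated mobile-element/prophage feature's
#' boundaries within tolerance `t`; `is_flank_recombination` when a
#' breakpoint abuts a detected IS copy boundary within `is_tol`;
#' `microhomology` when the junction shares at least `min_mh` bp; else
#' `blunt`.
#'
#' @param reference [genome_record].
#' @param del_start,del_end 0-based half-open deleted interval.
#' @param features `gene_features` (elements: kind `mobile_element` or
#'   `prophage`).
#' @param is_copies optional IS copy table from [find_is_copies()].
#' @param t boundary tolerance for precise excision (bp, default 0).
#' @param is_tol tolerance for IS-flank matching (bp, default 3).
#' @param min_mh minimum microhomology length (default 5).
#' @return list with `category` and the [microhomology()] fields.
#' @export
classify_deletion <- function(reference, del_start, del_end, features,
                              is_copies = NULL, t = 0L, is_tol = 3L,
                              min_mh = 5L) {
  mh <- microhomology(reference, del_start, del_end)
  elements <- features[features$kind %in% c("mobile_element", "prophage"), ,
                       drop = FALSE]
  category <- NULL
  if (nrow(elements)) {
    # any equivalent placement of the breakpoints may match the element
    lo <- mh$placement_range[1L]; hi <- mh$placement_range[2L]
    shift <- del_end - del_start
    for (i in seq_len(nrow(elements))) {
      e <- elements[i, ]
      if (any(abs(lo:hi - e$start) <= t &
              abs(lo:hi + shift - e$end) <= t)) {
        category <- "precise_element_excision"
        break
      }
    }
  }
  if (is.null(category) && !is.null(is_copies) && nrow(is_copies)) {
    bounds <- c(is_copies$start, is_copies$end)
    if (any(abs(bounds - del_start) <= is_tol) ||
        any(abs(bounds - del_end) <= is_tol))
      category <- "is_flank_recombination"
  }
  if (is.null(category))
    category <- if (mh$mh_length >= min_mh) "microhomology" else "blunt"
  mh$category <- category
  mh
}

#' Circularize a linear assembly scaffold by its terminal repeat
#'
#' Finds the longest exact match between a prefix and a suffix of the
#' scaffold; if it reaches `min_repeat` the right-hand copy is removed and
#' the record is flagged circular, the way a terminally redundant de novo
#' assembly is closed into one circle.
#'
#' @param scaffold linear [genome_record].
#' @param min_repeat minimum terminal identity to accept (bp).
#' @return list with `genome` (circularized or unchanged record) and
#'   `repeat_length`.
#' @export
circularize <- function(scaffold, min_repeat = 100L) {
  seq <- scaffold$sequence
  L <- nchar(seq)
  if (L < 2L * min_repeat)
    return(list(genome = scaffold, repeat_length = 0L))
  # longest proper border no longer than L/2 (KMP failure function)
  x <- utf8ToInt(seq)
  fail <- integer(L)
  k <- 0L
  for (i in 2:L) {
    while (k > 0L && x[k + 1L] != x[i]) k <- fail[k]
    if (x[k + 1L] == x[i]) k <- k + 1L
    fail[i] <- k
  }
  b <- fail[L]
  while (b > L %/% 2L) b <- fail[b]
  if (b < min_repeat)
    return(list(genome = scaffold, repeat_length = as.integer(b)))
  circ <- genome_record(scaffold$id, substr(seq, 1L, L - b),
                        circular = TRUE,
                        description = trimws(paste(
                          scaffold$description,
                          sprintf("circularized terminal_repeat=%d", b))))
  list(genome = circ, repeat_length = as.integer(b))
}
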