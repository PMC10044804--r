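# Variant recovery between two near-identical genomes by unique-k-mer
# anchoring, plus variant normalization and set comparison.
#
# Anchors are k-mers that occur exactly once in each genome and are shared;
# they are chained by longest collinear subsequence, and each inter-anchor
# gap is resolved into SNP / insertion / deletion / substitution events by
# end-anchored alignment.  Requiring uniqueness in BOTH genomes suppresses
# mis-anchoring across repeated elements (IS expansions are the main
# failure mode in evolved bacterial genomes).

# positions (0-based) and strings of k-mers occurring exactly once
.unique_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(data.frame(pos = integer(), kmer = character()))
  starts <- seq_len(L - k + 1L)
  km <- substring(seq, starts, starts + k - 1L)
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  keep <- !dup & !grepl("N", km, fixed = TRUE)
  data.frame(pos = starts[keep] - 1L, kmer = km[keep],
             stringsAsFactors = FALSE)
}

# longest strictly-increasing subsequence (patience); returns indices.
# Ties during reconstruction resolve to the earlier (smaller) element.
.lis <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer())
  tails <- integer(n)    # indices of smallest tail per length
  prev <- integer(n)
  len <- 0L
  tail_vals <- numeric(n)
  for (i in seq_len(n)) {
    lo <- 1L; hi <- len
    while (lo <= hi) {           # first tail >= x[i]
      mid <- (lo + hi) %/% 2L
      if (tail_vals[mid] < x[i]) lo <- mid + 1L else hi <- mid - 1L
    }
    prev[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
    tail_vals[lo] <- x[i]
    if (lo > len) len <- lo
  }
  out <- integer(len)
  j <- tails[len]
  for (pos in rev(seq_len(len))) {
    out[pos] <- j
    j <- prev[j]
  }
  out
}

# classify aligned gap strings into events; rs/qs are 0-based starts of the
# gap in reference/query
.gap_events <- function(rgap, qgap, rs, large_threshold, aligner_max) {
  ev <- list()
  emit <- function(pos, ref, alt) {
    cls <- if (nchar(ref) == 1L && nchar(alt) == 1L) "snp"
      else if (nchar(alt) == 0L)
        if (nchar(ref) >= large_threshold) "large_deletion" else "deletion"
      else if (nchar(ref) == 0L) "insertion"
      else "substitution"
    ev[[length(ev) + 1L]] <<- data.frame(
      pos = pos, ref = ref, alt = alt, class = cls,
      stringsAsFactors = FALSE)
  }
  # trim shared prefix then shared suffix
  pre <- lcp_len(rgap, qgap)
  rgap2 <- substr(rgap, pre + 1L, nchar(rgap))
  qgap2 <- substr(qgap, pre + 1L, nchar(qgap))
  rev1 <- function(s) paste(rev(strsplit(s, "")[[1L]]), collapse = "")
  suf <- lcp_len(rev1(rgap2), rev1(qgap2))
  rgap2 <- substr(rgap2, 1L, nchar(rgap2) - suf)
  qgap2 <- substr(qgap2, 1L, nchar(qgap2) - suf)
  base <- rs + pre
  if (nchar(rgap2) == 0L && nchar(qgap2) == 0L) {
    # identical
  } else if (nchar(rgap2) == 0L || nchar(qgap2) == 0L ||
             (nchar(rgap2) == 1L && nchar(qgap2) == 1L)) {
    emit(base, rgap2, qgap2)
  } else if (nchar(rgap2) <= aligner_max && nchar(qgap2) <= aligner_max) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(qgap2), Biostrings::DNAString(rgap2),
      type = "global", substitutionMatrix =
        Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2),
      gapOpening = 4, gapExtension = 1)
    qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
    ra <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
    state <- ifelse(ra == "-", "ins", ifelse(qa == "-", "del",
              ifelse(ra == qa, "match", "mis")))
    r <- rle(state)
    rpos <- base
    idx <- 1L
    for (j in seq_along(r$lengths)) {
      n <- r$lengths[j]; st <- r$values[j]
      cols <- idx:(idx + n - 1L)
      if (st == "mis") emit(rpos, paste(ra[cols], collapse = ""),
                            paste(qa[cols], collapse = ""))
      else if (st == "del") emit(rpos, paste(ra[cols], collapse = ""), "")
      else if (st == "ins") emit(rpos, "", paste(qa[cols], collapse = ""))
      if (st != "ins") rpos <- rpos + n
      idx <- idx + n
    }
  } else {
    return(list(events = NULL,
                unresolved = data.frame(start = base,
                                        end = base + nchar(rgap2))))
  }
  list(events = if (length(ev)) do.call(rbind, ev) else NULL,
       unresolved = NULL)
}

#' Call variants between a reference and a near-identical query genome
#'
#' Anchors the two genomes on shared unique k-mers, chains the anchors by
#' longest collinear subsequence (for circular genomes the query is first
#' rotated to the chain start), and resolves every inter-anchor gap into
#' left-normalized events.  Gaps whose diverged cores exceed `max_gap` on
#' both sides are reported as unresolved regions (attribute
#' `"unresolved"`), never silently dropped.
#'
#' @param reference,query [genome_record] objects.
#' @param k anchor length (default 21).
#' @param max_gap largest diverged gap resolved by alignment.
#' @param large_threshold event length at/above which a deletion is
#'   classed `large_deletion` (structural threshold; default 50).
#' @param strain strain label written into the output.
#' @return A `variant_table` (with attribute `unresolved`, a data.frame of
#'   0-based half-open reference intervals).
#' @export
diff_genomes <- function(reference, query, k = 21L, max_gap = 5000L,
                         large_threshold = 50L, strain = query$id) {
  R <- reference$sequence
  Q <- query$sequence
  if (identical(R, Q)) {
    out <- variant_table()
    attr(out, "unresolved") <- data.frame(start = integer(),
                                          end = integer())
    return(out)
  }
  ur <- .unique_kmers(R, k)
  uq <- .unique_kmers(Q, k)
  m <- match(ur$kmer, uq$kmer)
  shared <- !is.na(m)
  if (sum(shared) < 0.9 * min(nrow(ur), nrow(uq)))
    stop("genomes share fewer than 90% of their unique ", k,
         "-mers; use whole-genome alignment tooling for diverged pairs")
  anchors <- data.frame(rpos = ur$pos[shared], qpos = uq$pos[m[shared]])
  anchors <- anchors[order(anchors$rpos), ]
  if (nrow(anchors) == 0L) stop("no anchors; genomes too diverged")
  # adjacent anchors are redundant: keep about one per k/3 bp, which
  # leaves every inter-anchor gap shorter than one anchor length
  anchors <- anchors[!duplicated(anchors$rpos %/% max(1L, k %/% 3L)), ]

  # circular query: align the seams by rotating the query so the anchor
  # nearest the reference origin gets offset zero.  For a query that was
  # never rotated this offset is already zero and nothing happens.
  if (reference$circular && query$circular) {
    a1 <- anchors[which.min(anchors$rpos), ]
    rot <- (a1$qpos - a1$rpos) %% nchar(Q)
    if (rot != 0L) {
      Q <- paste0(substr(Q, rot + 1L, nchar(Q)), substr(Q, 1L, rot))
      uq <- .unique_kmers(Q, k)
      m <- match(ur$kmer, uq$kmer)
      shared <- !is.na(m)
      anchors <- data.frame(rpos = ur$pos[shared], qpos = uq$pos[m[shared]])
      anchors <- anchors[order(anchors$rpos), ]
    }
  }

  chain <- anchors[.lis(anchors$qpos), ]
  if (nrow(chain) == 0L) stop("no collinear anchor chain found")
  # greedy non-overlapping subset (>= k from the last kept anchor on both
  # sides) so inter-anchor gaps are well defined
  keep <- logical(nrow(chain))
  keep[1L] <- TRUE
  last <- 1L
  for (i in seq_len(nrow(chain))[-1L]) {
    if (chain$rpos[i] - chain$rpos[last] >= k &&
        chain$qpos[i] - chain$qpos[last] >= k) {
      keep[i] <- TRUE
      last <- i
    }
  }
  chain <- chain[keep, ]

  gaps <- data.frame(
    rs = c(0L, chain$rpos + k), re = c(chain$rpos, nchar(R)),
    qs = c(0L, chain$qpos + k), qe = c(chain$qpos, nchar(Q)))
  events <- list()
  unresolved <- list()
  for (i in seq_len(nrow(gaps))) {
    g <- gaps[i, ]
    if (g$re <= g$rs && g$qe <= g$qs) next
    res <- .gap_events(substr(R, g$rs + 1L, g$re),
                       substr(Q, g$qs + 1L, g$qe),
                       g$rs, large_threshold, aligner_max = max_gap)
    if (!is.null(res$events)) events[[length(events) + 1L]] <- res$events
    if (!is.null(res$unresolved))
      unresolved[[length(unresolved) + 1L]] <- res$unresolved
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(pos = integer(), ref = character(), alt = character(),
               class = character())
  out <- variant_table(strain = if (nrow(ev)) strain else character(),
                       seq_id = if (nrow(ev)) reference$id else character(),
                       pos = ev$pos, ref = ev$ref, alt = ev$alt,
                       class = ev$class,
                       length = pmax(nchar(ev$ref), nchar(ev$alt)),
                       frequency = if (nrow(ev)) 1.0 else numeric(),
                       note = if (nrow(ev)) "" else character())
  out <- normalize_variants(out, reference)
  attr(out, "unresolved") <- if (length(unresolved))
    do.call(rbind, unresolved) else
    data.frame(start = integer(), end = integer())
  out
}

#' Left-normalize one variant against its reference
#'
#' Indels are shifted to their leftmost equivalent placement; pure
#' homopolymer-run changes are annotated `run_before`/`run_after` in the
#' note (e.g. `A8>A7` for a one-base contraction of an A8 run).
#'
#' @param variant one-row `variant_table`.
#' @param reference the reference [genome_record].
#' @return the normalized one-row `variant_table`.
#' @export
normalize_variant <- function(variant, reference) {
  normalize_variants(variant, reference)
}

#' Left-normalize a variant table against its reference
#'
#' @param variants `variant_table`.
#' @param reference the reference [genome_record].
#' @return normalized `variant_table` (row order preserved).
#' @export
normalize_variants <- function(variants, reference) {
  if (nrow(variants) == 0L) return(variants)
  R <- reference$sequence
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (nzchar(v$ref)) {
      have <- substr(R, v$pos + 1L, v$pos + nchar(v$ref))
      if (have != v$ref)
        stop("ref allele mismatch at pos ", v$pos, ": variant says '",
             v$ref, "', reference has '", have, "'")
    }
    indel <- xor(nzchar(v$ref), nzchar(v$alt))
    if (!indel) next
    allele <- if (nzchar(v$ref)) v$ref else v$alt
    pos <- v$pos
    # shift left while the base preceding the site equals the allele end
    repeat {
      if (pos <= 0L) break
      prevb <- substr(R, pos, pos)
      lastb <- substr(allele, nchar(allele), nchar(allele))
      if (prevb != lastb) break
      allele <- paste0(lastb, substr(allele, 1L, nchar(allele) - 1L))
      pos <- pos - 1L
    }
    variants$pos[i] <- pos
    if (nzchar(v$ref)) variants$ref[i] <- allele
    else variants$alt[i] <- allele
    # homopolymer-run annotation
    b <- substr(allele, 1L, 1L)
    if (allele == strrep(b, nchar(allele))) {
      run <- 0L
      j <- pos + 1L
      while (j <= nchar(R) && substr(R, j, j) == b) {
        run <- run + 1L; j <- j + 1L
      }
      if (run >= nchar(allele) ||
          (!nzchar(v$ref) && run >= 1L)) {
        after <- if (nzchar(v$ref)) run - nchar(allele)
                 else run + nchar(allele)
        if (run >= 2L || after >= 2L)
          variants$note[i] <- sprintf("%s%d>%s%d", b, run, b, after)
      }
    }
  }
  variants
}

#' Apply a variant table to its reference
#'
#' Reconstructs the query sequence from a reference and a set of disjoint
#' normalized variants; the round-trip identity with [diff_genomes()] is
#' part of the module contract.
#'
#' @param reference [genome_record].
#' @param variants `variant_table` against that reference.
#' @return character DNA string.
#' @export
apply_variants <- function(reference, variants) {
  if (nrow(variants) == 0L) return(reference$sequence)
  v <- variants[order(variants$pos, nchar(variants$ref)), ]
  seq <- reference$sequence
  pieces <- character(2L * nrow(v) + 1L)
  cursor <- 0L
  for (i in seq_len(nrow(v))) {
    if (v$pos[i] < cursor) stop("overlapping variants at pos ", v$pos[i])
    pieces[2L * i - 1L] <- substr(seq, cursor + 1L, v$pos[i])
    pieces[2L * i] <- v$alt[i]
    cursor <- v$pos[i] + nchar(v$ref[i])
  }
  pieces[2L * nrow(v) + 1L] <- substr(seq, cursor + 1L, nchar(seq))
  paste(pieces, collapse = "")
}

#' Compare two variant sets called against the same reference
#'
#' The match key is (seq_id, pos, ref, alt, class); everything matching is
#' shared, the rest is strain-specific.
#'
#' @param a,b normalized `variant_table`s against the same reference.
#' @return list with `shared`, `a_only`, `b_only` (each a `variant_table`).
#' @export
compare_variant_sets <- function(a, b) {
  if (nrow(a) && nrow(b) &&
      length(union(unique(a$seq_id), unique(b$seq_id))) > 1L)
    stop("variant sets are against different references: ",
         paste(union(unique(a$seq_id), unique(b$seq_id)), collapse = ", "))
  key <- function(v) paste(v$seq_id, v$pos, v$ref, v$alt, v$class,
                           sep = "\r")
  ka <- key(a); kb <- key(b)
  list(shared = a[ka %in% kb, , drop = FALSE],
       a_only = a[!ka %in% kb, , drop = FALSE],
       b_only = b[!kb %in% ka, , drop = FALSE])
}

#' Count changes
#'
#' One count per event regardless of its length: an IS insertion, a 123-kb
#' deletion and a SNP each count 1.
#'
#' @param variants `variant_table`.
#' @return integer.
#' @export
count_changes <- function(variants) {
  nrow(variants)
}

#' Size display class of an event
#'
#' Reporting convention: events of 6 bp or smaller are "small", larger
#' ones "large".  This display threshold is distinct from the structural
#' `large_threshold` used for junction analysis.
#'
#' @param variants `variant_table`.
#' @return character vector `"small"`/`"large"`.
#' @export
size_class <- function(variants) {
  ifelse(variants$length <= 6L, "small", "large")
}
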