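# Low-level sequence and coordinate helpers shared by all modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so simulator calls do not perturb the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed from (seed, index), kept below 2^31.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

#' Reverse complement of a DNA string
#' @param x character scalar over A,C,G,T,N.
#' @return character scalar.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Translate a DNA string with the bacterial code (table 11: standard
# codon assignments; GTG/TTG accepted as starts and rendered as M when
# `as_start` covers the first codon).
translate_dna <- function(x, as_start = TRUE) {
  if (nchar(x) < 3L) return("")
  n <- nchar(x) - nchar(x) %% 3L
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(x, 1L, n)),
    if.fuzzy.codon = "X"))
  if (as_start && nchar(aa) > 0L &&
      substr(x, 1L, 3L) %in% c("ATG", "GTG", "TTG"))
    substr(aa, 1L, 1L) <- "M"
  aa
}

# Random DNA of length n with a given GC fraction.
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Longest common prefix length of two strings (bounded).
lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- charToRaw(substr(a, 1L, n))
  bv <- charToRaw(substr(b, 1L, n))
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1L] - 1L
}

# 1-based inclusive <-> 0-based half-open interval conversion.
to_file_interval <- function(start0, end0) {
  list(start = start0 + 1L, end = end0)
}
from_file_interval <- function(start1, end1) {
  list(start = start1 - 1L, end = end1)
}

# Splice `replacement` over [start, end) (0-based half-open) of `seq`.
splice <- function(seq, start, end, replacement = "") {
  paste0(substr(seq, 1L, start), replacement,
         substr(seq, end + 1L, nchar(seq)))
}

# Substring by 0-based half-open interval, with optional circular wrap.
subseq0 <- function(seq, start, end, circular = FALSE) {
  L <- nchar(seq)
  if (!circular) {
    stopifnot(start >= 0L, end <= L, start <= end)
    return(substr(seq, start + 1L, end))
  }
  span <- end - start
  if (span < 0L) stop("negative circular interval")
  start <- ((start %% L) + L) %% L
  if (start + span <= L) return(substr(seq, start + 1L, start + span))
  paste0(substr(seq, start + 1L, L), substr(seq, 1L, start + span - L))
}
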