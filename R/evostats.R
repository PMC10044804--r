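# Numerical evolution statistics: mutational spectra, per-day rates with
# exact Poisson uncertainty, expected spontaneous load under serial
# dilution, hyper-mutagenesis factor, sibling divergence dating, and
# melting-temperature enrichment among knockouts.

#' Pyrimidine-collapsed mutational spectrum
#'
#' Maps each SNP to one of the six strand-symmetric classes keyed to the
#' pyrimidine of the reference pair: a G-to-A change is counted as C-to-T
#' on the complementary strand, and so on.
#'
#' @param snps `variant_table` of SNP rows.
#' @param reference unused; accepted for interface symmetry.
#' @return list of class `spectrum_result` with `counts`, `fractions`
#'   (both named by the six classes) and `n_snps`.
#' @export
spectrum <- function(snps, reference = NULL) {
  if (nrow(snps) && any(snps$class != "snp"))
    stop("spectrum() expects SNP variants only; got class '",
         snps$class[snps$class != "snp"][1], "'")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cls <- character(nrow(snps))
  for (i in seq_len(nrow(snps))) {
    r <- snps$ref[i]; a <- snps$alt[i]
    if (r %in% c("G", "A")) { r <- comp[[r]]; a <- comp[[a]] }
    cls[i] <- paste0(r, ":", comp[[r]], ">", a, ":", comp[[a]])
  }
  counts <- vapply(SNP_CLASSES, function(k) sum(cls == k), 0L)
  n <- nrow(snps)
  structure(list(counts = counts,
                 fractions = if (n > 0L) counts / n else counts * NA_real_,
                 n_snps = n),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat("<spectrum_result>", x$n_snps, "SNPs\n")
  for (k in names(x$counts))
    cat(sprintf("  %s  %4d  (%.1f%%)\n", k, x$counts[[k]],
                100 * x$fractions[[k]]))
  invisible(x)
}

# exact (Garwood) Poisson confidence limits on a count
.poisson_ci <- function(n, conf = 0.95) {
  a <- (1 - conf) / 2
  lower <- if (n == 0L) 0 else stats::qgamma(a, n)
  upper <- stats::qgamma(1 - a, n + 1)
  c(lower, upper)
}

#' Per-day change rate with exact Poisson uncertainty
#'
#' @param n_changes observed number of changes.
#' @param days duration in days.
#' @param conf confidence level.
#' @return list of class `rate_estimate`: `n_changes`, `days`, `rate`,
#'   `ci95`.
#' @export
rate_per_day <- function(n_changes, days, conf = 0.95) {
  if (days <= 0) stop("days must be positive")
  if (n_changes < 0) stop("n_changes must be non-negative")
  ci <- .poisson_ci(n_changes, conf) / days
  structure(list(n_changes = n_changes, days = days,
                 rate = n_changes / days, ci95 = ci),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %.4g changes/day (%d in %g days; 95%% CI %.4g-%.4g)\n",
              x$rate, x$n_changes, x$days, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Doublings per day implied by a serial-dilution regime
#'
#' A culture diluted `dilution_factor`-fold must double
#' log2(`dilution_factor`) times per transfer to regrow.
#'
#' @param dilution_factor fold dilution per transfer (>= 1).
#' @param interval_days days between transfers.
#' @return doublings per day.
#' @export
doublings_from_dilution <- function(dilution_factor, interval_days) {
  if (dilution_factor < 1) stop("dilution factor must be >= 1")
  if (interval_days <= 0) stop("transfer interval must be positive")
  log2(dilution_factor) / interval_days
}

#' Expected spontaneous mutational load per day
#'
#' @param doublings_per_day generations per day.
#' @param mu_per_bp_per_generation spontaneous rate, changes/bp/generation.
#' @param genome_length bp.
#' @return list of class `load_expectation`: inputs,
#'   `per_genome_per_generation` (mu x L) and `expected_per_day`.
#' @export
expected_load <- function(doublings_per_day, mu_per_bp_per_generation,
                          genome_length) {
  if (any(c(doublings_per_day, mu_per_bp_per_generation,
            genome_length) < 0))
    stop("all inputs must be non-negative")
  per_gen <- mu_per_bp_per_generation * genome_length
  structure(list(doublings_per_day = doublings_per_day,
                 mu_per_bp_per_generation = mu_per_bp_per_generation,
                 genome_length = genome_length,
                 per_genome_per_generation = per_gen,
                 expected_per_day = per_gen * doublings_per_day),
            class = "load_expectation")
}

#' Hyper-mutagenesis factor
#'
#' Ratio of the observed per-day change rate to the spontaneous
#' expectation.
#'
#' @param observed_rate changes/day observed.
#' @param expected_rate changes/day expected from the spontaneous rate.
#' @return fold factor.
#' @export
hyper_factor <- function(observed_rate, expected_rate) {
  if (expected_rate <= 0) stop("expected rate must be positive")
  observed_rate / expected_rate
}

#' Sibling divergence duration from strain-specific change counts
#'
#' `days = n_specific / rate`, using the unrounded rate; the exact
#' Poisson interval on the strain-specific count is propagated.
#'
#' @param n_specific strain-specific change count.
#' @param rate a `rate_estimate` (or plain changes/day).
#' @param strain label.
#' @return list of class `divergence_estimate`: `strain`, `n_specific`,
#'   `rate`, `days` (unrounded), `days_rounded`, `ci95` (days).
#' @export
divergence_days <- function(n_specific, rate, strain = "") {
  r <- if (inherits(rate, "rate_estimate")) rate$rate else rate
  if (r <= 0) stop("rate must be positive")
  if (n_specific < 0) stop("n_specific must be non-negative")
  ci <- .poisson_ci(n_specific) / r
  days <- n_specific / r
  structure(list(strain = strain, n_specific = n_specific, rate = r,
                 days = days, days_rounded = round(days), ci95 = ci),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("<divergence_estimate>%s %d specific changes / %.4g per day = %d days (95%% CI %.0f-%.0f)\n",
              if (nzchar(x$strain)) paste0(" ", x$strain) else "",
              x$n_specific, x$rate, x$days_rounded, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Melting-temperature enrichment among knocked-out genes
#'
#' Restricts the knockout set to genes present in the melting-temperature
#' table, computes the proportion with Tm at most `t_max + delta`, and
#' tests it against a background proportion with an exact two-sided
#' binomial test.
#'
#' @param knockout_locus_tags character vector.
#' @param tm_table data.frame from [read_tm_table()].
#' @param t_max maximum growth temperature of the strain, degrees C.
#' @param delta margin above `t_max` (default 5).
#' @param background_proportion genome-wide proportion of detected
#'   proteins below the same threshold.
#' @return list of class `tm_enrichment`: `threshold`, `n_low`,
#'   `n_detected`, `proportion`, `background_proportion`, `p_value`,
#'   `undefined` (TRUE when no knockout is in the table).
#' @export
tm_enrichment <- function(knockout_locus_tags, tm_table, t_max, delta = 5,
                          background_proportion) {
  if (nrow(tm_table) == 0L) stop("empty Tm table")
  if (background_proportion < 0 || background_proportion > 1)
    stop("background proportion must be in [0, 1]")
  thr <- t_max + delta
  hit <- tm_table[tm_table$locus_tag %in% knockout_locus_tags, ,
                  drop = FALSE]
  n_det <- nrow(hit)
  if (n_det == 0L)
    return(structure(list(threshold = thr, n_low = 0L, n_detected = 0L,
                          proportion = NA_real_,
                          background_proportion = background_proportion,
                          p_value = NA_real_, undefined = TRUE),
                     class = "tm_enrichment"))
  n_low <- sum(hit$tm <= thr)
  p <- stats::binom.test(n_low, n_det, background_proportion)$p.value
  structure(list(threshold = thr, n_low = n_low, n_detected = n_det,
                 proportion = n_low / n_det,
                 background_proportion = background_proportion,
                 p_value = p, undefined = FALSE),
            class = "tm_enrichment")
}

#' @export
print.tm_enrichment <- function(x, ...) {
  if (x$undefined) {
    cat("<tm_enrichment> undefined (no knockout in the Tm table)\n")
  } else {
    cat(sprintf(
      "<tm_enrichment> %d of %d (%.1f%%) at Tm <= %.1f C; background %.1f%%; exact binomial p = %.3g\n",
      x$n_low, x$n_detected, 100 * x$proportion, x$threshold,
      100 * x$background_proportion, x$p_value))
  }
  invisible(x)
}
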