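# Synthetic serial-passage evolution with a complete ground-truth ledger.
#
# The generator emulates the statistical structure of a heat-evolution
# experiment: a gene-dense circular ancestor carrying an annotated
# prophage-like element and one composite transposon; descendant lineages
# accumulate Poisson-distributed events (SNPs under a pyrimidine-collapsed
# spectrum, small indels, IS cut-and-paste insertions with 9-bp target-site
# duplications drawn from a position-weight target model, large deletions
# at microhomologous tracts, precise element excision); sibling lineages
# share a common phase and then diverge.
#
# All events are recorded in the ancestor coordinate frame and are pairwise
# disjoint there (an event landing on a previously affected interval is
# resampled), so replaying the ledger left-to-right reproduces the evolved
# genome byte-for-byte.

SNP_CLASSES <- c("C:G>T:A", "C:G>A:T", "C:G>G:C",
                 "T:A>C:G", "T:A>A:T", "T:A>G:C")

EVENT_CLASSES <- c("snp", "small_indel", "is_insertion", "large_deletion",
                   "element_excision")

#' Default insertion-sequence target position-weight matrix
#'
#' A 4 x width matrix of per-position base probabilities describing the
#' degenerate target preference of the simulated element: pyrimidine,
#' purine, C, T, then unconstrained/purine positions (a YRCTNNRNN-style
#' preference for the default width of 9).
#'
#' @param width motif width in bp.
#' @return numeric matrix with rownames A,C,G,T, columns summing to 1.
#' @export
default_target_pwm <- function(width = 9L) {
  cols <- list(
    Y = c(A = .05, C = .45, G = .05, T = .45),
    R = c(A = .45, C = .05, G = .45, T = .05),
    C = c(A = .04, C = .88, G = .04, T = .04),
    T = c(A = .04, C = .04, G = .04, T = .88),
    N = c(A = .25, C = .25, G = .25, T = .25))
  pattern <- c("Y", "R", "C", "T", "N", "N", "R", "N", "N")
  pattern <- rep_len(pattern, width)
  m <- vapply(pattern, function(p) cols[[p]], numeric(4))
  rownames(m) <- DNA_BASES
  m
}

#' Deterministic synthetic insertion-sequence element
#'
#' A fixed IS10-scale element: 22-bp terminal inverted repeats flanking a
#' single transposase-style ORF.  The sequence is a deterministic function
#' of `seed` so fixtures are reproducible; it is synthetic, not a natural
#' IS allele.
#'
#' @param length approximate element length in bp.
#' @param seed integer seed fixing the content.
#' @return character DNA string.
#' @export
synthetic_is_element <- function(length = 1329L, seed = 7L) {
  with_seed(seed, {
    irl <- random_dna(22L)
    n_codons <- max(10L, (length - 44L - 6L) %/% 3L)
    codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L,
                    paste, collapse = "")
    codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
    orf <- paste0("ATG",
                  paste(sample(codons, n_codons - 2L, replace = TRUE),
                        collapse = ""),
                  "TAA")
    paste0(irl, orf, revcomp(irl))
  })
}

#' Simulation parameters for serial-passage evolution
#'
#' Defaults describe the emulated regime: 0.092 events/day over 2,512 days
#' of 48-h transfers at 1:8 dilution, sibling divergence for the final 400
#' days, a 0.65 spectrum weight on C:G to T:A transitions, and 9-bp
#' target-site duplications.  The genome itself is scaled down (200 kb)
#' so that scans stay desk-sized; event sizes scale with it.
#'
#' @param genome_length ancestor length, bp.
#' @param gc_fraction GC content of random sequence.
#' @param n_genes number of non-overlapping CDSs.
#' @param gene_length_mean mean CDS length, bp.
#' @param change_rate events per day.
#' @param days_total experiment duration, days.
#' @param divergence_day day at which sibling lineages split.
#' @param dilution_factor fold dilution per transfer.
#' @param transfer_interval days between transfers.
#' @param spectrum_weights named weights over the six collapsed SNP classes.
#' @param p_event_class named weights over the five event classes.
#' @param indel_length_geometric_p geometric parameter for indel lengths.
#' @param is_sequence the mobile element DNA (default:
#'   [synthetic_is_element()]).
#' @param tsd_length target-site duplication length, bp.
#' @param target_pwm 4 x `tsd_length` base-probability matrix.
#' @param deletion_size_log_mean,deletion_size_log_sd lognormal deletion
#'   size (bp scale).
#' @param microhomology_length_weights named weights over planted
#'   microhomology lengths (names are lengths in bp).
#' @param n_homology_tracts homologous tract pairs planted in the ancestor
#'   as future deletion junctions.
#' @param n_candidate_sites candidate positions scored per IS insertion
#'   when sampling from the target model.
#' @param seed integer seed.
#' @return list of class `evolution_params`.
#' @export
evolution_params <- function(genome_length = 200000L,
                             gc_fraction = 0.5,
                             n_genes = 120L,
                             gene_length_mean = 900L,
                             change_rate = 0.092,
                             days_total = 2512,
                             divergence_day = 2112,
                             dilution_factor = 8,
                             transfer_interval = 2,
                             spectrum_weights = c(
                               "C:G>T:A" = 0.65, "C:G>A:T" = 0.10,
                               "C:G>G:C" = 0.05, "T:A>C:G" = 0.10,
                               "T:A>A:T" = 0.05, "T:A>G:C" = 0.05),
                             p_event_class = c(
                               snp = 0.65, small_indel = 0.25,
                               is_insertion = 0.08, large_deletion = 0.015,
                               element_excision = 0.005),
                             indel_length_geometric_p = 0.5,
                             is_sequence = NULL,
                             tsd_length = 9L,
                             target_pwm = NULL,
                             deletion_size_log_mean = log(2000),
                             deletion_size_log_sd = 0.8,
                             microhomology_length_weights = c(
                               "0" = 0.10, "1" = 0.10, "2" = 0.12,
                               "3" = 0.12, "4" = 0.10, "5" = 0.10,
                               "6" = 0.08, "7" = 0.07, "8" = 0.06,
                               "9" = 0.05, "10" = 0.04, "11" = 0.03,
                               "12" = 0.03),
                             n_homology_tracts = 4L,
                             n_candidate_sites = 400L,
                             seed = 1L) {
  if (is.null(is_sequence)) is_sequence <- synthetic_is_element()
  if (is.null(target_pwm)) target_pwm <- default_target_pwm(tsd_length)
  p <- list(genome_length = as.integer(genome_length),
            gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
            gene_length_mean = as.integer(gene_length_mean),
            change_rate = change_rate, days_total = days_total,
            divergence_day = divergence_day,
            dilution_factor = dilution_factor,
            transfer_interval = transfer_interval,
            spectrum_weights = spectrum_weights,
            p_event_class = p_event_class,
            indel_length_geometric_p = indel_length_geometric_p,
            is_sequence = toupper(is_sequence),
            tsd_length = as.integer(tsd_length), target_pwm = target_pwm,
            deletion_size_log_mean = deletion_size_log_mean,
            deletion_size_log_sd = deletion_size_log_sd,
            microhomology_length_weights = microhomology_length_weights,
            n_homology_tracts = as.integer(n_homology_tracts),
            n_candidate_sites = as.integer(n_candidate_sites),
            seed = as.integer(seed))
  class(p) <- "evolution_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  chk1 <- function(w, what) {
    if (abs(sum(w) - 1) > 1e-9)
      stop(what, " must sum to 1 (got ", sum(w), ")")
  }
  chk1(p$spectrum_weights, "spectrum_weights")
  chk1(p$p_event_class, "p_event_class")
  chk1(p$microhomology_length_weights, "microhomology_length_weights")
  if (!identical(sort(names(p$spectrum_weights)), sort(SNP_CLASSES)))
    stop("spectrum_weights must be named by the six collapsed SNP classes")
  if (!identical(sort(names(p$p_event_class)), sort(EVENT_CLASSES)))
    stop("p_event_class must be named by the five event classes")
  if (p$genome_length < 10L * p$gene_length_mean)
    stop("genome_length must be at least 10 x gene_length_mean")
  if (p$divergence_day > p$days_total)
    stop("divergence_day must not exceed days_total")
  if (!all(dim(p$target_pwm) == c(4L, p$tsd_length)))
    stop("target_pwm must be 4 x tsd_length")
  if (any(abs(colSums(p$target_pwm) - 1) > 1e-9))
    stop("target_pwm columns must sum to 1")
  invisible(p)
}

# ---- ancestor --------------------------------------------------------------

# Sample a CDS body: ATG start, no internal stop, TAA end.
.random_cds <- function(len_codons) {
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1L,
                  paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(codons, len_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

# Non-overlapping placement bookkeeping on [0, L).
.place <- function(occupied, L, width, margin = 2L, tries = 2000L) {
  for (i in seq_len(tries)) {
    s <- sample.int(L - width - margin, 1L) + margin
    if (!any(occupied$start < s + width + margin &
             occupied$end > s - margin))
      return(s)
  }
  NA_integer_
}

#' Generate an annotated circular ancestor genome
#'
#' Places `n_genes` non-overlapping CDSs (ATG start, in-frame stop only at
#' the end) on random strands, one annotated prophage-like element, one
#' composite transposon (two identical IS copies flanking a cargo CDS),
#' and `n_homology_tracts` pairs of identical short tracts that serve as
#' microhomologous junction sites for later deletions.
#'
#' @param params an [evolution_params()] object.
#' @return list with `genome` (a [genome_record]), `features` (a
#'   `gene_features` table) and `mh_tracts` (data.frame of planted tract
#'   pairs: left/right tract end positions and tract length).
#' @export
generate_ancestor <- function(params) {
  validate_params(params)
  with_seed(params$seed, {
    L <- params$genome_length
    seq <- random_dna(L, params$gc_fraction)
    occupied <- data.frame(start = integer(), end = integer())
    feats <- list()
    occupy <- function(s, e) {
      occupied[nrow(occupied) + 1L, ] <<- list(s, e)
    }

    # composite transposon: IS + cargo CDS + IS
    is_seq <- params$is_sequence
    cargo_codons <- max(600L, params$gene_length_mean %/% 3L)
    cargo <- .random_cds(cargo_codons)
    spacer1 <- random_dna(40L, params$gc_fraction)
    spacer2 <- random_dna(40L, params$gc_fraction)
    tn <- paste0(is_seq, spacer1, cargo, spacer2, is_seq)
    tn_start <- .place(occupied, L, nchar(tn))
    if (is.na(tn_start)) stop("cannot place composite transposon")
    seq <- splice(seq, tn_start, tn_start + nchar(tn), tn)
    occupy(tn_start, tn_start + nchar(tn))
    isL <- nchar(is_seq)
    feats[[length(feats) + 1L]] <- data.frame(
      seq_id = "anc", gene = c("isL", "cargoA", "isR"),
      locus_tag = c("sim0001", "sim0002", "sim0003"),
      start = c(tn_start, tn_start + isL + 40L + 0L,
                tn_start + nchar(tn) - isL),
      end = c(tn_start + isL,
              tn_start + isL + 40L + nchar(cargo),
              tn_start + nchar(tn)),
      strand = c("+", "+", "+"),
      kind = c("mobile_element", "CDS", "mobile_element"),
      product = c("transposase", "cargo protein", "transposase"),
      interrupted_in_reference = FALSE, stringsAsFactors = FALSE)

    # prophage-like element with exact boundaries
    ph_len <- max(2000L, min(6000L, L %/% 30L))
    ph_start <- .place(occupied, L, ph_len)
    if (is.na(ph_start)) stop("cannot place prophage element")
    occupy(ph_start, ph_start + ph_len)
    feats[[length(feats) + 1L]] <- data.frame(
      seq_id = "anc", gene = "phageE", locus_tag = "sim0004",
      start = ph_start, end = ph_start + ph_len, strand = "+",
      kind = "prophage", product = "cryptic prophage element",
      interrupted_in_reference = FALSE, stringsAsFactors = FALSE)

    # protein-coding genes
    n_placed <- 0L
    gnum <- 4L
    for (i in seq_len(params$n_genes)) {
      len_codons <- max(50L, round(stats::rgamma(
        1L, shape = 9, scale = params$gene_length_mean / 27)))
      body <- .random_cds(len_codons)
      w <- nchar(body)
      s <- .place(occupied, L, w)
      if (is.na(s))
        stop("cannot place ", params$n_genes, " genes without overlap; ",
             "placed ", n_placed)
      strand <- sample(c("+", "-"), 1L)
      seq <- splice(seq, s, s + w, if (strand == "+") body else revcomp(body))
      occupy(s, s + w)
      gnum <- gnum + 1L
      feats[[length(feats) + 1L]] <- data.frame(
        seq_id = "anc", gene = sprintf("gene%03d", i),
        locus_tag = sprintf("sim%04d", gnum), start = s, end = s + w,
        strand = strand, kind = "CDS",
        product = sprintf("hypothetical protein %d", i),
        interrupted_in_reference = FALSE, stringsAsFactors = FALSE)
      n_placed <- n_placed + 1L
    }

    # homologous tract pairs: identical m-bp seeds ending at both future
    # breakpoints, the substrate for microhomology-mediated deletions
    mh_w <- params$microhomology_length_weights
    tracts <- data.frame(left = integer(), right = integer(),
                         m = integer())
    for (i in seq_len(params$n_homology_tracts)) {
      m <- as.integer(sample(names(mh_w), 1L, prob = mh_w))
      size <- round(stats::rlnorm(1L, params$deletion_size_log_mean,
                                  params$deletion_size_log_sd))
      size <- max(200L, min(size, L %/% 8L))
      placed <- FALSE
      for (try in seq_len(500L)) {
        p <- sample.int(L - size - 2L * m - 10L, 1L) + m + 5L
        q <- p + size
        # both m-bp tracts must fall in unoccupied sequence
        if (m > 0L &&
            (any(occupied$start < p & occupied$end > p - m - 1L) ||
             any(occupied$start < q & occupied$end > q - m - 1L)))
          next
        if (m > 0L) {
          tract <- substr(seq, p - m + 1L, p)
          seq <- splice(seq, q - m, q, tract)
          occupy(q - m, q)
          occupy(p - m, p)
        }
        tracts[nrow(tracts) + 1L, ] <- list(p, q, m)
        placed <- TRUE
        break
      }
      if (!placed) next
    }

    fdf <- do.call(rbind, feats)
    features <- gene_features(fdf$seq_id, fdf$gene, fdf$locus_tag,
                              fdf$start, fdf$end, fdf$strand, fdf$kind,
                              fdf$product, fdf$interrupted_in_reference)
    list(genome = genome_record("anc", seq, circular = TRUE,
                                description = "simulated ancestor"),
         features = features, mh_tracts = tracts)
  })
}

# ---- lineage evolution -----------------------------------------------------

.empty_ledger <- function() {
  data.frame(strain = character(), event_id = integer(),
             event_class = character(), day = numeric(),
             anc_start = integer(), anc_end = integer(),
             ref = character(), alt = character(),
             planted_mh = integer(), planted_tsd = character(),
             shared = logical(), evo_start = integer(),
             evo_end = integer(), stringsAsFactors = FALSE)
}

# measured microhomology at (a, b) by direct string comparison; used only
# to record ground truth at planting time
.mh_measure <- function(seq, a, b, cap = 200L) {
  suf <- 0L
  while (suf < cap && a - suf > 0L && b - suf > 0L &&
         substr(seq, a - suf, a - suf) == substr(seq, b - suf, b - suf))
    suf <- suf + 1L
  pre <- 0L
  L <- nchar(seq)
  while (pre < cap && a + 1L + pre <= L && b + 1L + pre <= L &&
         substr(seq, a + 1L + pre, a + 1L + pre) ==
         substr(seq, b + 1L + pre, b + 1L + pre))
    pre <- pre + 1L
  suf + pre
}

# Draw `days`-worth of events in the ancestor frame, avoiding `blocked`
# intervals (data.frame start/end, 0-based half-open).  Returns a ledger
# without evolved-frame coordinates.
.draw_events <- function(anc_seq, features, mh_tracts, params, days,
                         seed, day_offset = 0, blocked = NULL,
                         used_tracts = integer()) {
  L <- nchar(anc_seq)
  if (is.null(blocked))
    blocked <- data.frame(start = integer(), end = integer())
  led <- .empty_ledger()
  if (days <= 0 || params$change_rate <= 0) return(led)
  with_seed(seed, {
    n <- stats::rpois(1L, params$change_rate * days)
    times <- if (n > 0L) sort(stats::runif(n, 0, days)) + day_offset
             else numeric()
    prophage <- features[features$kind == "prophage", , drop = FALSE]
    # IS insertions never land inside an existing mobile element (or the
    # composite transposon it bounds), so the planted copy census and the
    # composite pairing stay unambiguous
    mobile <- features[features$kind == "mobile_element", , drop = FALSE]
    if (nrow(mobile) >= 2L)
      mobile <- rbind(mobile, data.frame(
        seq_id = mobile$seq_id[1L], gene = "tn", locus_tag = "tn",
        start = min(mobile$start), end = max(mobile$end),
        strand = "+", kind = "mobile_element", product = "",
        interrupted_in_reference = FALSE))
    clash <- function(s, e) {
      any(blocked$start < e & blocked$end > s) ||
        any(led$anc_start < e & led$anc_end > s)
    }
    free_tracts <- setdiff(seq_len(nrow(mh_tracts)), used_tracts)
    pwm_log <- log(pmax(params$target_pwm, 1e-12))
    tsdL <- params$tsd_length
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    # 1-based positions of each base; sampling sites conditionally on the
    # base keeps the realized class fractions exactly at spectrum_weights
    pos_by_base <- split(seq_len(L), strsplit(anc_seq, "")[[1L]])

    for (i in seq_len(n)) {
      cls <- sample(names(params$p_event_class), 1L,
                    prob = params$p_event_class)
      done <- FALSE
      snp_base <- NULL
      for (try in seq_len(200L)) {
        if (cls == "snp") {
          if (is.null(snp_base)) {
            sc <- sample(SNP_CLASSES, 1L, prob = params$spectrum_weights)
            pyr <- substr(sc, 1L, 1L)        # C or T
            to_pyr <- substr(sc, 5L, 5L)     # target base, pyrimidine strand
            if (stats::runif(1L) < 0.5) {    # strand expansion
              snp_base <- pyr; snp_alt <- to_pyr
            } else {
              snp_base <- comp[[pyr]]; snp_alt <- comp[[to_pyr]]
            }
          }
          cand <- pos_by_base[[snp_base]]
          if (is.null(cand) || !length(cand)) break
          p <- cand[sample.int(length(cand), 1L)]
          if (clash(p - 1L, p)) next
          led[nrow(led) + 1L, ] <- list("", i, "snp", times[i], p - 1L, p,
                                        snp_base, snp_alt, NA_integer_,
                                        "", FALSE, NA_integer_, NA_integer_)
          done <- TRUE
        } else if (cls == "small_indel") {
          len <- 1L + stats::rgeom(1L, params$indel_length_geometric_p)
          len <- min(len, 50L)
          if (stats::runif(1L) < 0.5) {      # insertion before base p
            p <- sample.int(L - 1L, 1L)
            if (clash(p, p)) next
            alt <- random_dna(len, params$gc_fraction)
            led[nrow(led) + 1L, ] <- list("", i, "small_indel", times[i],
                                          p, p, "", alt, NA_integer_, "",
                                          FALSE, NA_integer_, NA_integer_)
          } else {                            # deletion of [p, p+len)
            p <- sample.int(L - len - 1L, 1L)
            if (clash(p, p + len)) next
            ref <- substr(anc_seq, p + 1L, p + len)
            if (grepl("N", ref)) next
            led[nrow(led) + 1L, ] <- list("", i, "small_indel", times[i],
                                          p, p + len, ref, "", NA_integer_,
                                          "", FALSE, NA_integer_,
                                          NA_integer_)
          }
          done <- TRUE
        } else if (cls == "is_insertion") {
          cand <- sample.int(L - tsdL, params$n_candidate_sites,
                             replace = TRUE)
          words <- substring(anc_seq, cand, cand + tsdL - 1L)
          ok <- !grepl("N", words)
          cand <- cand[ok]; words <- words[ok]
          if (!length(cand)) next
          wm <- matrix(match(unlist(strsplit(words, "")), DNA_BASES),
                       nrow = length(words), byrow = TRUE)
          sc <- exp(rowSums(matrix(
            pwm_log[cbind(as.vector(wm),
                          rep(seq_len(tsdL), each = length(words)))],
            nrow = length(words))))
          j <- sample.int(length(cand), 1L, prob = sc)
          s0 <- cand[j] - 1L                 # site interval [s0, s0+tsdL)
          if (clash(s0, s0 + tsdL)) next
          if (any(mobile$start < s0 + tsdL & mobile$end > s0)) next
          target <- words[j]
          strand <- sample(c("+", "-"), 1L)
          body <- if (strand == "+") params$is_sequence
                  else revcomp(params$is_sequence)
          # evolved locus: target, element, duplicated target
          led[nrow(led) + 1L, ] <- list("", i, "is_insertion", times[i],
                                        s0, s0 + tsdL, target,
                                        paste0(target, body, target),
                                        NA_integer_, target, FALSE,
                                        NA_integer_, NA_integer_)
          done <- TRUE
        } else if (cls == "large_deletion") {
          if (length(free_tracts)) {
            ti <- free_tracts[1L]
            a <- mh_tracts$left[ti]; b <- mh_tracts$right[ti]
            if (clash(a, b)) { free_tracts <- free_tracts[-1L]; next }
            free_tracts <- free_tracts[-1L]
          } else {
            size <- round(stats::rlnorm(1L, params$deletion_size_log_mean,
                                        params$deletion_size_log_sd))
            size <- max(100L, min(size, L %/% 8L))
            a <- sample.int(L - size - 2L, 1L)
            b <- a + size
            if (clash(a, b)) next
          }
          ref <- substr(anc_seq, a + 1L, b)
          if (grepl("N", ref)) next
          mh <- .mh_measure(anc_seq, a, b)
          led[nrow(led) + 1L, ] <- list("", i, "large_deletion", times[i],
                                        a, b, ref, "", mh, "", FALSE,
                                        NA_integer_, NA_integer_)
          done <- TRUE
        } else { # element_excision
          if (nrow(prophage) == 0L) { cls <- "snp"; next }
          a <- prophage$start[1L]; b <- prophage$end[1L]
          if (clash(a, b)) { cls <- "snp"; next }
          led[nrow(led) + 1L, ] <- list("", i, "element_excision",
                                        times[i], a, b,
                                        substr(anc_seq, a + 1L, b), "",
                                        NA_integer_, "", FALSE,
                                        NA_integer_, NA_integer_)
          done <- TRUE
        }
        if (done) break
      }
      if (!done && !cls %in% c("large_deletion", "element_excision"))
        stop("event placement failed after bounded retries ",
             "(class ", cls, ")")
    }
    if (nrow(led)) led$event_id <- seq_len(nrow(led))
    led[order(led$anc_start, led$anc_end), ]
  })
}

# Fill evolved-frame coordinates for a position-sorted ledger.
.fill_evolved_frame <- function(led) {
  if (nrow(led) == 0L) return(led)
  led <- led[order(led$anc_start, led$anc_end), ]
  shift <- 0L
  for (i in seq_len(nrow(led))) {
    led$evo_start[i] <- led$anc_start[i] + shift
    led$evo_end[i] <- led$evo_start[i] + nchar(led$alt[i])
    shift <- shift + nchar(led$alt[i]) -
      (led$anc_end[i] - led$anc_start[i])
  }
  led
}

#' Replay a ground-truth ledger against the ancestor
#'
#' Applies every event (sorted by ancestor position; events are disjoint
#' in that frame) and returns the evolved sequence.  This is the oracle
#' identity: `replay_ledger(ancestor, truth)` must equal the evolved
#' genome byte-for-byte.
#'
#' @param ancestor the ancestor [genome_record] (or plain sequence).
#' @param ledger a ground-truth ledger.
#' @return character DNA string.
#' @export
replay_ledger <- function(ancestor, ledger) {
  seq <- if (inherits(ancestor, "genome_record")) ancestor$sequence
         else ancestor
  if (nrow(ledger) == 0L) return(seq)
  led <- ledger[order(ledger$anc_start, ledger$anc_end), ]
  pieces <- character(2L * nrow(led) + 1L)
  cursor <- 0L
  for (i in seq_len(nrow(led))) {
    pieces[2L * i - 1L] <- substr(seq, cursor + 1L, led$anc_start[i])
    pieces[2L * i] <- led$alt[i]
    cursor <- led$anc_end[i]
  }
  pieces[2L * nrow(led) + 1L] <- substr(seq, cursor + 1L, nchar(seq))
  paste(pieces, collapse = "")
}

#' Evolve one descendant lineage
#'
#' Draws a Poisson(`change_rate` x `days`) number of events, timestamps
#' them uniformly, places them disjointly in the ancestor frame and
#' assembles the evolved genome.
#'
#' @param ancestor ancestor [genome_record].
#' @param features ancestor `gene_features`.
#' @param params [evolution_params()].
#' @param days duration simulated.
#' @param seed integer seed (default from `params`).
#' @param mh_tracts planted homologous tract pairs from
#'   [generate_ancestor()]; optional.
#' @param strain name recorded in the ledger.
#' @return list with `genome` (evolved [genome_record]) and `ledger`
#'   (the ground truth; columns include both ancestor-frame and
#'   evolved-frame intervals).
#' @export
evolve_lineage <- function(ancestor, features, params,
                           days = params$days_total, seed = params$seed,
                           mh_tracts = NULL, strain = "evolved") {
  if (days < 0) stop("days must be >= 0")
  if (is.null(mh_tracts))
    mh_tracts <- data.frame(left = integer(), right = integer(),
                            m = integer())
  led <- .draw_events(ancestor$sequence, features, mh_tracts, params,
                      days, seed)
  led$strain <- rep_len(strain, nrow(led))
  led <- .fill_evolved_frame(led)
  evolved <- replay_ledger(ancestor, led)
  list(genome = genome_record(strain, evolved, circular = ancestor$circular,
                              description = sprintf(
                                "evolved %s days from %s", format(days),
                                ancestor$id)),
       ledger = led)
}

#' Simulate a sibling pair sharing a common phase
#'
#' One lineage evolves to `divergence_day`; two continuations then evolve
#' independently to `days_total`.  Shared events carry `shared = TRUE` in
#' both ledgers.
#'
#' @param params [evolution_params()].
#' @param ancestry optional precomputed [generate_ancestor()] output
#'   (so several replicates can reuse one ancestor).
#' @return list with `ancestor`, `features`, `genome_a`, `genome_b`,
#'   `ledger_a`, `ledger_b`.
#' @export
simulate_sibling_pair <- function(params, ancestry = NULL) {
  if (is.null(ancestry)) ancestry <- generate_ancestor(params)
  anc <- ancestry$genome
  feats <- ancestry$features
  tracts <- ancestry$mh_tracts
  shared <- .draw_events(anc$sequence, feats, tracts, params,
                         params$divergence_day, child_seed(params$seed, 1L))
  shared$shared <- rep_len(TRUE, nrow(shared))
  tail_days <- params$days_total - params$divergence_day
  blocked <- data.frame(start = shared$anc_start, end = shared$anc_end)
  used <- which(tracts$right %in% shared$anc_end &
                  tracts$left %in% shared$anc_start)
  contA <- .draw_events(anc$sequence, feats, tracts, params, tail_days,
                        child_seed(params$seed, 2L),
                        day_offset = params$divergence_day,
                        blocked = blocked, used_tracts = used)
  contB <- .draw_events(anc$sequence, feats, tracts, params, tail_days,
                        child_seed(params$seed, 3L),
                        day_offset = params$divergence_day,
                        blocked = blocked, used_tracts = used)
  mk <- function(cont, strain) {
    led <- rbind(shared, cont)
    led$strain <- rep_len(strain, nrow(led))
    led$event_id <- seq_len(nrow(led))
    led <- .fill_evolved_frame(led)
    led
  }
  ledA <- mk(contA, "lineageA")
  ledB <- mk(contB, "lineageB")
  gA <- genome_record("lineageA", replay_ledger(anc, ledA),
                      circular = anc$circular)
  gB <- genome_record("lineageB", replay_ledger(anc, ledB),
                      circular = anc$circular)
  list(ancestor = anc, features = feats, mh_tracts = tracts,
       genome_a = gA, genome_b = gB, ledger_a = ledA, ledger_b = ledB)
}

#' Project a ground-truth ledger into variant form
#'
#' Each event becomes one row of the core variant dialect against the
#' ancestor, left-normalized so it is directly comparable with
#' [diff_genomes()] output.
#'
#' @param ledger a ground-truth ledger.
#' @param ancestor the ancestor [genome_record].
#' @param normalize left-normalize indel rows (default TRUE).
#' @return A `variant_table` with the `shared` flag carried in `note`.
#' @export
truth_to_variants <- function(ledger, ancestor, normalize = TRUE) {
  if (nrow(ledger) == 0L) return(variant_table())
  cls <- vapply(seq_len(nrow(ledger)), function(i) {
    ev <- ledger$event_class[i]
    if (ev == "snp") "snp"
    else if (ev == "is_insertion") "is_insertion"
    else if (ev %in% c("large_deletion", "element_excision"))
      "large_deletion"
    else if (nchar(ledger$ref[i]) == 0L) "insertion" else "deletion"
  }, "")
  pos <- ledger$anc_start
  ref <- ledger$ref
  alt <- ledger$alt
  # IS insertions are recorded with their target site; express them as a
  # pure insertion of (element + duplicated target) after the site
  isv <- ledger$event_class == "is_insertion"
  if (any(isv)) {
    pos[isv] <- ledger$anc_end[isv]
    alt[isv] <- vapply(which(isv), function(i)
      substr(ledger$alt[i], nchar(ledger$ref[i]) + 1L,
             nchar(ledger$alt[i])), "")
    ref[isv] <- ""
  }
  vt <- variant_table(strain = ledger$strain, seq_id = ancestor$id,
                      pos = pos, ref = ref, alt = alt, class = cls,
                      length = pmax(nchar(ref), nchar(alt)),
                      frequency = 1.0,
                      note = ifelse(ledger$shared, "shared", ""))
  if (normalize) vt <- normalize_variants(vt, ancestor)
  vt
}
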