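# End-to-end orchestration: configuration, staged execution with
# deterministic seeding, per-stage TSV outputs and a consolidated summary.

#' Read a run configuration
#'
#' Flat INI-style file: `[section]` headers with `key = value` lines.
#' Unknown sections or keys are errors, not warnings — silent
#' misconfiguration is the main reproducibility hazard in a pipeline.
#'
#' @param path configuration file.
#' @return nested named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  known <- list(
    run = c("seed", "out_dir", "strain"),
    paths = c("reference", "query", "features", "is_reference",
              "tm_table", "gene_lists"),
    diff = c("k", "max_gap", "large_threshold"),
    junctions = c("min_mh", "excision_tolerance", "is_tolerance"),
    is_scan = c("family", "min_identity", "min_coverage", "seed_k",
                "tsd_length", "max_cargo", "consensus_threshold"),
    annotate = c("upstream_window", "loss_threshold"),
    stats = c("days", "dilution", "interval_days", "mu"),
    tm = c("t_max", "delta", "background"))
  cfg <- lapply(known, function(x) list())
  section <- NULL
  for (raw in readLines(path, warn = FALSE)) {
    line <- sub("[#;].*$", "", raw)
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[.*\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      if (!section %in% names(known))
        stop("unknown config section [", section, "]")
      next
    }
    if (is.null(section)) stop("config line before any [section]: ", raw)
    kv <- regmatches(line, regexec("^([^=]+)=(.*)$", line))[[1L]]
    if (length(kv) != 3L) stop("malformed config line: ", raw)
    key <- trimws(kv[2L]); val <- trimws(kv[3L])
    if (!key %in% known[[section]])
      stop("unknown key '", key, "' in section [", section, "]")
    num <- suppressWarnings(as.numeric(val))
    cfg[[section]][[key]] <- if (!is.na(num)) num else val
  }
  class(cfg) <- "run_config"
  cfg
}

.cfg_get <- function(cfg, section, key, default = NULL, required = FALSE) {
  v <- cfg[[section]][[key]]
  if (is.null(v)) {
    if (required) stop("config is missing [", section, "] ", key)
    return(default)
  }
  v
}

#' Run the full comparison pipeline from a configuration
#'
#' Stages, in order: variant calling (diff), junction characterization,
#' IS scan, consequence annotation, evolution statistics, Tm enrichment.
#' Every stage writes a TSV under the output directory; a `summary.txt`
#' records every parameter, the seed, and per-stage record counts.  Paths
#' and parameter domains are validated before any stage runs.
#'
#' @param config path to a config file or a `run_config` list.
#' @return invisibly, a list of the per-stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config
         else read_run_config(config)
  # ---- validation before any computation ----
  need <- c("reference", "query", "features")
  for (p in need)
    if (is.null(cfg$paths[[p]]))
      stop("config is missing [paths] ", p)
  for (p in names(cfg$paths)) {
    if (p == "gene_lists") next
    if (!file.exists(cfg$paths[[p]]))
      stop("configured path does not exist: ", p, " = ", cfg$paths[[p]])
  }
  out_dir <- .cfg_get(cfg, "run", "out_dir", required = TRUE)
  seed <- as.integer(.cfg_get(cfg, "run", "seed", 1))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- c(sprintf("evotrace run | seed=%d | %s", seed,
                   format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           sprintf("config: %s", paste(deparse(unclass(cfg)[lengths(cfg) > 0]),
                                       collapse = " ")))
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- inputs ----
  reference <- stage("input", read_genome(cfg$paths$reference)[[1L]])
  query <- stage("input", read_genome(cfg$paths$query)[[1L]])
  features <- stage("input", read_features(cfg$paths$features))

  # ---- diff ----
  k <- as.integer(.cfg_get(cfg, "diff", "k", 21))
  large_thr <- as.integer(.cfg_get(cfg, "diff", "large_threshold", 50))
  variants <- stage("diff", diff_genomes(
    reference, query, k = k,
    max_gap = as.integer(.cfg_get(cfg, "diff", "max_gap", 5000)),
    large_threshold = large_thr,
    strain = .cfg_get(cfg, "run", "strain", query$id)))
  write_variants(variants, file.path(out_dir, "variants.tsv"))
  unres <- attr(variants, "unresolved")
  write_bed(unres, reference$id, file.path(out_dir, "unresolved.bed"))
  log <- c(log, sprintf("diff: %d variants, %d unresolved regions",
                        nrow(variants), nrow(unres)))
  results$variants <- variants

  # ---- IS scan (before junction classification, which uses the copies) --
  copies <- NULL
  consensus <- NULL
  if (!is.null(cfg$paths$is_reference)) {
    isref <- read_genome(cfg$paths$is_reference)[[1L]]
    tsd_len <- as.integer(.cfg_get(cfg, "is_scan", "tsd_length", 9))
    copies <- stage("is-scan", find_is_copies(
      query, isref,
      family = .cfg_get(cfg, "is_scan", "family", isref$id),
      min_identity = .cfg_get(cfg, "is_scan", "min_identity", 0.95),
      min_coverage = .cfg_get(cfg, "is_scan", "min_coverage", 0.90),
      k = as.integer(.cfg_get(cfg, "is_scan", "seed_k", 15))))
    copies <- stage("is-scan", flag_composite(
      copies, genome = query,
      max_cargo = as.integer(.cfg_get(cfg, "is_scan", "max_cargo",
                                      15000))))
    copies <- stage("is-scan", add_tsds(query, copies, tsd_len))
    utils::write.table(as.data.frame(copies),
                       file.path(out_dir, "iscopies.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sites <- copies$target_site[!copies$in_composite &
                                  !is.na(copies$target_site)]
    if (length(sites)) {
      consensus <- build_consensus(
        sites, .cfg_get(cfg, "is_scan", "consensus_threshold", 0.25))
      writeLines(c(consensus$iupac,
                   apply(consensus$counts, 1, paste, collapse = "\t")),
                 file.path(out_dir, "consensus.txt"))
    }
    log <- c(log, sprintf(
      "is-scan: %d copies (%d composite, %d isolated)%s", nrow(copies),
      sum(copies$in_composite), sum(!copies$in_composite),
      if (!is.null(consensus)) paste0("; target consensus ",
                                      consensus$iupac) else ""))
    results$is_copies <- copies
    results$consensus <- consensus
  }

  # ---- junctions ----
  dels <- variants[variants$class == "large_deletion", , drop = FALSE]
  jrows <- list()
  for (i in seq_len(nrow(dels))) {
    d <- dels[i, ]
    cls <- stage("junctions", classify_deletion(
      reference, d$pos, d$pos + nchar(d$ref), features,
      is_copies = copies,
      t = as.integer(.cfg_get(cfg, "junctions", "excision_tolerance", 0)),
      is_tol = as.integer(.cfg_get(cfg, "junctions", "is_tolerance", 3)),
      min_mh = as.integer(.cfg_get(cfg, "junctions", "min_mh", 5))))
    fus <- stage("junctions", detect_fusion(
      features, d$pos, d$pos + nchar(d$ref), reference))
    jrows[[i]] <- data.frame(
      seq_id = d$seq_id, del_start = d$pos + 1L,
      del_end = d$pos + nchar(d$ref), mh_length = cls$mh_length,
      mh_sequence = cls$mh_sequence, category = cls$category,
      fusion = if (is.null(fus)) "" else sprintf(
        "%s(1-%d)::%s(%d-%d)%s", fus$gene5$gene, fus$retained5[2L],
        fus$gene3$gene, fus$retained3[1L], fus$retained3[2L],
        if (fus$in_frame) " in-frame" else " out-of-frame"),
      stringsAsFactors = FALSE)
  }
  junctions_tbl <- if (length(jrows)) do.call(rbind, jrows) else NULL
  if (!is.null(junctions_tbl))
    utils::write.table(junctions_tbl, file.path(out_dir, "junctions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  log <- c(log, sprintf("junctions: %d large deletions characterized",
                        nrow(dels)))
  results$junctions <- junctions_tbl

  # ---- annotate ----
  loss_thr <- .cfg_get(cfg, "annotate", "loss_threshold", 0.10)
  calls <- stage("annotate", annotate(
    variants, features, reference,
    upstream_window = as.integer(.cfg_get(cfg, "annotate",
                                          "upstream_window", 50)),
    loss_threshold = loss_thr))
  if (!is.null(calls))
    utils::write.table(calls, file.path(out_dir, "calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  kos <- call_knockouts(calls, features, loss_thr)
  writeLines(kos$knocked_out, file.path(out_dir, "knockouts.txt"))
  log <- c(log, sprintf("annotate: %d calls, %d knockouts (+%d pre-interrupted)",
                        if (is.null(calls)) 0L else nrow(calls),
                        length(kos$knocked_out),
                        length(kos$preexisting_interruptions)))
  results$calls <- calls
  results$knockouts <- kos

  # ---- stats ----
  days <- .cfg_get(cfg, "stats", "days", required = TRUE)
  rate <- rate_per_day(count_changes(variants), days)
  sp <- spectrum(variants[variants$class == "snp", , drop = FALSE])
  dil <- .cfg_get(cfg, "stats", "dilution", 8)
  interval <- .cfg_get(cfg, "stats", "interval_days", 2)
  mu <- .cfg_get(cfg, "stats", "mu", 1e-9)
  dbl <- doublings_from_dilution(dil, interval)
  load <- expected_load(dbl, mu, nchar(reference$sequence))
  hf <- hyper_factor(rate$rate, load$expected_per_day)
  stats_tbl <- data.frame(
    metric = c("n_changes", "days", "rate_per_day", "rate_ci_low",
               "rate_ci_high", "doublings_per_day",
               "per_genome_per_generation", "expected_per_day",
               "hyper_factor",
               paste0("spectrum_", gsub("[:>]", "_", SNP_CLASSES))),
    value = c(rate$n_changes, rate$days, rate$rate, rate$ci95,
              dbl, load$per_genome_per_generation, load$expected_per_day,
              hf, as.numeric(sp$fractions)),
    stringsAsFactors = FALSE)
  utils::write.table(stats_tbl, file.path(out_dir, "stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- c(log, sprintf(
    "stats: %.4f changes/day over %g days; %.1fx the spontaneous expectation",
    rate$rate, days, hf))
  results$rate <- rate
  results$spectrum <- sp
  results$load <- load
  results$hyper_factor <- hf

  # ---- tm ----
  if (!is.null(cfg$paths$tm_table) && !is.null(cfg$tm$t_max)) {
    tmt <- read_tm_table(cfg$paths$tm_table)
    enr <- stage("tm", tm_enrichment(
      kos$knocked_out, tmt, cfg$tm$t_max,
      delta = .cfg_get(cfg, "tm", "delta", 5),
      background_proportion = .cfg_get(cfg, "tm", "background", 0.219)))
    log <- c(log, if (enr$undefined)
      "tm: undefined (no knockout detected in the Tm study)" else
      sprintf("tm: %d/%d knockouts (%.1f%%) at Tm <= %.1f C (background %.1f%%, p=%.3g)",
              enr$n_low, enr$n_detected, 100 * enr$proportion,
              enr$threshold, 100 * enr$background_proportion,
              enr$p_value))
    results$tm <- enr
  }

  writeLines(log, file.path(out_dir, "summary.txt"))
  invisible(results)
}

#' Write intervals as BED
#'
#' @param intervals data.frame with 0-based half-open `start`/`end`.
#' @param seq_id chromosome name.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, seq_id, path) {
  lines <- if (nrow(intervals))
    paste(seq_id, intervals$start, intervals$end, sep = "\t") else
    character()
  writeLines(lines, path)
  invisible(path)
}

# ---- fixtures --------------------------------------------------------------

#' Scale presets for the fixture generator
#'
#' `tiny` is a smoke-test scale (30 kb, ~28 events) on which every stage
#' runs in seconds; `paper-like` keeps the emulated experiment's regime
#' (0.092 events/day, 2,512 days, divergence at day 2,112, 0.65 spectrum
#' weight on C:G to T:A, 9-bp TSDs) on a 150-kb genome.
#'
#' @param scale `"tiny"` or `"paper-like"`.
#' @param seed integer seed.
#' @return an [evolution_params()] object.
#' @export
scale_params <- function(scale = c("tiny", "paper-like"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "tiny")
    evolution_params(genome_length = 40000L, n_genes = 16L,
                     gene_length_mean = 700L, change_rate = 0.092,
                     days_total = 300, divergence_day = 200,
                     deletion_size_log_mean = log(900),
                     deletion_size_log_sd = 0.5,
                     n_homology_tracts = 2L, seed = seed)
  else
    evolution_params(genome_length = 150000L, n_genes = 90L,
                     gene_length_mean = 900L, change_rate = 0.092,
                     days_total = 2512, divergence_day = 2112,
                     deletion_size_log_mean = log(2000),
                     deletion_size_log_sd = 0.8,
                     n_homology_tracts = 4L, seed = seed)
}

#' Write a self-contained simulated fixture bundle
#'
#' Simulates a sibling pair and writes: ancestor and evolved genomes
#' (FASTA), features (GFF3), ground-truth ledgers and their variant
#' projections (TSV), the IS reference element (FASTA), a Tm table with a
#' known low-Tm fraction, and a ready-to-run pipeline config.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @param scale `"tiny"` or `"paper-like"`.
#' @return invisibly, the simulation object with a `files` element.
#' @export
make_fixtures <- function(dir, seed = 1L, scale = "tiny") {
  params <- scale_params(scale, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sib <- simulate_sibling_pair(params)
  f <- list(
    ancestor = file.path(dir, "ancestor.fa"),
    features = file.path(dir, "ancestor.gff3"),
    genome_a = file.path(dir, "lineageA.fa"),
    genome_b = file.path(dir, "lineageB.fa"),
    ledger_a = file.path(dir, "ledgerA.tsv"),
    ledger_b = file.path(dir, "ledgerB.tsv"),
    truth_a = file.path(dir, "truthA.variants.tsv"),
    truth_b = file.path(dir, "truthB.variants.tsv"),
    is_reference = file.path(dir, "is_element.fa"),
    tm_table = file.path(dir, "tm_table.tsv"),
    config = file.path(dir, "run.cfg"))
  write_genome(sib$ancestor, f$ancestor)
  write_features(sib$features, f$features)
  write_genome(sib$genome_a, f$genome_a)
  write_genome(sib$genome_b, f$genome_b)
  write_ledger(sib$ledger_a, f$ledger_a)
  write_ledger(sib$ledger_b, f$ledger_b)
  write_variants(truth_to_variants(sib$ledger_a, sib$ancestor), f$truth_a)
  write_variants(truth_to_variants(sib$ledger_b, sib$ancestor), f$truth_b)
  write_genome(genome_record("is_element", params$is_sequence),
               f$is_reference)
  # Tm table covering every gene; a fixed 25% of locus tags fall below
  # 53.5 C so enrichment arithmetic has a known expectation
  tags <- sib$features$locus_tag[sib$features$kind == "CDS"]
  tm <- with_seed(child_seed(seed, 9L), {
    low <- seq_along(tags) %% 4L == 0L
    round(ifelse(low, stats::runif(length(tags), 45, 53.5),
                 stats::runif(length(tags), 54, 75)), 1)
  })
  utils::write.table(data.frame(locus_tag = tags, tm = tm),
                     f$tm_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c(
    "[run]",
    sprintf("seed = %d", seed),
    sprintf("out_dir = %s", file.path(dir, "out")),
    "strain = lineageA",
    "[paths]",
    sprintf("reference = %s", f$ancestor),
    sprintf("query = %s", f$genome_a),
    sprintf("features = %s", f$features),
    sprintf("is_reference = %s", f$is_reference),
    sprintf("tm_table = %s", f$tm_table),
    "[is_scan]",
    "tsd_length = 9",
    sprintf("max_cargo = %d",
            if (scale == "tiny") 2500L else 15000L),
    "[stats]",
    sprintf("days = %g", params$days_total),
    sprintf("dilution = %g", params$dilution_factor),
    sprintf("interval_days = %g", params$transfer_interval),
    "mu = 1e-9",
    "[tm]",
    "t_max = 48.5",
    "delta = 5",
    "background = 0.25"), f$config)
  sib$files <- f
  sib$params <- params
  invisible(sib)
}

#' Write / read a ground-truth ledger
#'
#' @param ledger ledger data.frame.
#' @param path TSV file.
#' @return `path` (write) or the ledger (read).
#' @export
write_ledger <- function(ledger, path) {
  utils::write.table(ledger, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("ref", "alt", "planted_tsd", "strain"))
    df[[col]][is.na(df[[col]])] <- ""
  df
}
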