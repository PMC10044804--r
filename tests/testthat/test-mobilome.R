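is_el <- function() synthetic_is_element()

test_that("genomes without the element give an empty copy list", {
  set.seed(41)
  g <- genome_record("g", h_dna(20000))
  expect_identical(nrow(find_is_copies(g, is_el())), 0L)
})

test_that("planted copies are located with correct strand, including mutated ones", {
  set.seed(42)
  el <- is_el()
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(el)))
  # 2% point mutations in one copy
  mut <- strsplit(el, "")[[1]]
  idx <- sample(seq_along(mut), round(0.02 * length(mut)))
  mut[idx] <- vapply(mut[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  mutated <- paste(mut, collapse = "")
  blocks <- c(h_dna(3000), el, h_dna(3000), rc, h_dna(3000), el,
              h_dna(3000), rc, h_dna(3000), mutated, h_dna(3000))
  g <- genome_record("g", paste(blocks, collapse = ""))
  copies <- find_is_copies(g, el)
  expect_identical(nrow(copies), 5L)
  expect_identical(copies$strand, c("+", "-", "+", "-", "+"))
  starts <- cumsum(c(3000, nchar(el) + 3000, nchar(rc) + 3000,
                     nchar(el) + 3000, nchar(rc) + 3000))
  expect_identical(copies$start, as.integer(starts))
  expect_true(all(copies$end - copies$start == nchar(el)))
  expect_lt(copies$identity[5], 1)
  expect_gte(copies$identity[5], 0.95)
})

test_that("the scan is strand-symmetric under reverse complement", {
  set.seed(43)
  el <- is_el()
  s <- paste0(h_dna(2500), el, h_dna(4000),
              as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(el))), h_dna(2500))
  g <- genome_record("g", s)
  gr <- genome_record("g", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s))))
  a <- find_is_copies(g, el)
  b <- find_is_copies(gr, el)
  expect_identical(nrow(a), nrow(b))
  L <- nchar(s)
  mirrored <- data.frame(start = L - rev(a$end), end = L - rev(a$start),
                         strand = rev(ifelse(a$strand == "+", "-", "+")))
  expect_identical(b$start, mirrored$start)
  expect_identical(b$end, mirrored$end)
  expect_identical(b$strand, mirrored$strand)
})

test_that("copies spanning the origin of a circular genome are found once", {
  set.seed(44)
  el <- is_el()
  body <- paste0(h_dna(6000), el, h_dna(6000))
  # rotate so the element straddles the origin
  rot <- 6000 + 600
  s <- paste0(substr(body, rot + 1, nchar(body)), substr(body, 1, rot))
  g <- genome_record("g", s, circular = TRUE)
  copies <- find_is_copies(g, el)
  expect_identical(nrow(copies), 1L)
  tsd <- extract_tsd(g, copies[1, ], 9L)
  expect_identical(nchar(tsd$tsd_left), 9L)
})

test_that("composite flagging pairs copies around a cargo CDS only", {
  el <- is_el()
  mk <- function(gap_len, with_cds) {
    set.seed(45)
    cds <- if (with_cds)
      paste0("ATG", strrep("GCT", 250), "TAA") else ""
    cargo <- paste0(h_dna((gap_len - nchar(cds)) %/% 2), cds,
                    h_dna((gap_len - nchar(cds) + 1) %/% 2))
    s <- paste0(h_dna(2000), el, cargo, el, h_dna(2000))
    genome_record("g", s)
  }
  g1 <- mk(9000, TRUE)
  c1 <- flag_composite(find_is_copies(g1, el), genome = g1)
  expect_identical(nrow(c1), 2L)
  expect_true(all(c1$in_composite))

  # same geometry but no cargo ORF: two independent insertions
  g2 <- mk(9000, FALSE)
  c2 <- flag_composite(find_is_copies(g2, el), genome = g2)
  expect_false(any(c2$in_composite))

  # a single copy stays isolated
  set.seed(46)
  g3 <- genome_record("g", paste0(h_dna(3000), el, h_dna(3000)))
  c3 <- flag_composite(find_is_copies(g3, el), genome = g3)
  expect_false(any(c3$in_composite))

  # cargo beyond max_cargo is not a transposon
  g4 <- mk(9000, TRUE)
  c4 <- flag_composite(find_is_copies(g4, el), genome = g4,
                       max_cargo = 5000)
  expect_false(any(c4$in_composite))
})

test_that("target-site duplications are extracted and mismatches flagged", {
  set.seed(47)
  el <- is_el()
  target <- "GCTTAGCAT"
  s <- paste0(h_dna(2000), target, el, target, h_dna(2000))
  g <- genome_record("g", s)
  copies <- find_is_copies(g, el)
  expect_identical(nrow(copies), 1L)
  tsd <- extract_tsd(g, copies[1, ], 9L)
  expect_identical(tsd$tsd_left, target)
  expect_identical(tsd$tsd_right, target)
  expect_true(tsd$tsd_match)
  expect_identical(tsd$target_site, target)

  # mutate the right flank: no longer a duplication
  s2 <- s
  p <- 2000 + 9 + nchar(el) + 1
  base <- substr(s2, p, p)
  substr(s2, p, p) <- setdiff(c("A", "C", "G", "T"), base)[1]
  g2 <- genome_record("g", s2)
  tsd2 <- extract_tsd(g2, copies[1, ], 9L)
  expect_false(tsd2$tsd_match)
  expect_true(is.na(tsd2$target_site))

  # shorter duplications (IS5-style 4 bp) pass through the parameter
  tsd4 <- extract_tsd(g, copies[1, ], 4L)
  expect_identical(nchar(tsd4$tsd_left), 4L)
  expect_identical(tsd4$tsd_left, substr(target, 6, 9))
})

test_that("simulator-planted insertions have fully recoverable target sites", {
  anc <- tiny_ancestry(3)
  p <- scale_params("tiny", seed = 3)
  p$p_event_class <- c(snp = 0.3, small_indel = 0, is_insertion = 0.7,
                       large_deletion = 0, element_excision = 0)
  ev <- evolve_lineage(anc$genome, anc$features, p, days = 400,
                       seed = 55, mh_tracts = anc$mh_tracts)
  planted <- ev$ledger[ev$ledger$event_class == "is_insertion", ]
  copies <- add_tsds(ev$genome, find_is_copies(ev$genome, p$is_sequence))
  found <- copies$target_site[!is.na(copies$target_site)]
  expect_true(all(planted$planted_tsd %in% found))
})

test_that("consensus building follows the inclusion-threshold IUPAC rule", {
  expect_identical(build_consensus(rep("GCTTAGCAT", 8))$iupac,
                   "GCTTAGCAT")
  expect_identical(build_consensus(c("ACT", "GCT"))$iupac, "RCT")

  m <- build_consensus(c("ACT", "GCT", "GCT", "TCT"),
                       freq_threshold = 0.25)
  expect_identical(m$iupac, "DCT")     # A, G, T at position 1
  expect_identical(unname(m$counts[, 1]),
                   c(1L, 0L, 2L, 1L))
  expect_identical(m$n_sites, 4L)
  expect_error(build_consensus(c("ACT", "ACTG")), "mixed widths")

  # threshold 0 (any observed base) vs threshold 1 (unanimity or majority)
  sites <- c("AAAA", "AAAC", "AACC", "ACCC")
  lo <- build_consensus(sites, freq_threshold = 1e-9)
  hi <- build_consensus(sites, freq_threshold = 1)
  expect_identical(lo$iupac, "AMMM")
  expect_identical(hi$iupac, "AAAC")   # strict majority per position

  # monotone: raising the threshold never enlarges a position's base set
  grid <- seq(0.05, 0.95, by = 0.15)
  widths <- vapply(grid, function(th) {
    con <- build_consensus(sites, freq_threshold = th)
    sum(vapply(strsplit(con$iupac, "")[[1]], function(l)
      nchar(Biostrings::IUPAC_CODE_MAP[[l]]), 0L))
  }, 0L)
  expect_true(all(diff(widths) <= 0L))
})

test_that("hybrid elements are profiled against two alleles", {
  set.seed(48)
  el <- is_el()
  # allele B: 19 point differences from allele A
  av <- strsplit(el, "")[[1]]
  bv <- av
  # avoid the first/last 25 bp (inverted repeats) and keep the ORF frame
  idx <- sort(sample(seq(30, length(bv) - 30), 19))
  bv[idx] <- vapply(bv[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  alleleA <- el
  alleleB <- paste(bv, collapse = "")

  profA <- classify_against_alleles(alleleA, alleleA, alleleB)
  expect_identical(nrow(profA$positions), 19L)
  expect_true(all(profA$positions$call == "A"))
  expect_identical(length(profA$coding_changes), 0L)

  # mosaic: first third from A, rest from B
  cut <- length(av) %/% 3
  mosaic <- paste0(substr(alleleA, 1, cut),
                   substr(alleleB, cut + 1, nchar(alleleB)))
  prof <- classify_against_alleles(mosaic, alleleA, alleleB)
  expect_true(all(prof$positions$call[prof$positions$offset < cut] ==
                    "A"))
  expect_true(all(prof$positions$call[prof$positions$offset >= cut] ==
                    "B"))
  expect_error(classify_against_alleles(substr(el, 1, 400), alleleA,
                                        alleleB), "90%")
})
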