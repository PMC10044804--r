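test_that("junctions without shared flanks are blunt", {
  set.seed(31)
  # alternating composition guarantees no accidental flank identity
  s <- paste0(strrep("AC", 50), strrep("GT", 50), strrep("TA", 50))
  mh <- microhomology(s, 100L, 200L)
  expect_identical(mh$mh_length, 0L)
  expect_identical(mh$category, "blunt")
  expect_identical(mh$placement_range, c(100L, 100L))
  expect_error(microhomology(s, 200L, 100L), "invalid")
})

test_that("planted microhomology is measured exactly and placements are equivalent", {
  set.seed(32)
  for (m in c(3L, 7L, 12L)) {
    left <- h_dna(300); mid <- h_dna(500); right <- h_dna(300)
    tract <- h_dna(m)
    # tract ends at both breakpoints: ...[left tract] | mid [tract] | right...
    s <- paste0(left, tract, mid, tract, right)
    a <- nchar(left) + m                 # del_start after left tract
    b <- nchar(left) + m + nchar(mid) + m  # del_end after right tract
    mh <- microhomology(s, a, b)
    expect_gte(mh$mh_length, m)          # chance can extend it
    # the homologous word sits at both junction flanks in the reference
    expect_identical(substr(s, a - m + 1, a), tract)
    expect_identical(substr(s, b - m + 1, b), tract)
    # every placement yields the same post-deletion sequence
    size <- b - a
    target <- h_del(s, a, b)
    for (a2 in mh$placement_range[1]:mh$placement_range[2])
      expect_identical(h_del(s, a2, a2 + size), target)
  }
})

test_that("microhomology agrees with the brute-force placement oracle", {
  set.seed(33)
  for (i in 1:300) {
    s <- h_dna(sample(150:260, 1))
    a <- sample(20:60, 1)
    b <- a + sample(10:80, 1)
    mh <- microhomology(s, a, b)
    oracle <- mh_oracle(s, a, b)
    expect_identical(mh$mh_length, oracle$m)
    expect_identical(mh$placement_range, as.integer(oracle$range))
  }
})

test_that("a deletion joining two same-strand CDSs yields an in-frame fusion call", {
  set.seed(34)
  # two plus-strand genes; deletion from inside gene A (after codon 152)
  # to the equivalent frame position inside gene B (before codon 80),
  # with a 12-bp homologous tract (4 codons) shared at the junction
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste,
                  collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  tract <- "GCTAAAATTGCG"                 # 4 codons: A K I A
  # pinned codons around both tract copies stop chance extension of the
  # homology, so the junction arithmetic is exact
  geneA <- paste0("ATG", paste(sample(codons, 146, replace = TRUE),
                               collapse = ""), "AAA", tract, "GGG",
                  paste(sample(codons, 199, replace = TRUE),
                        collapse = ""), "TAA")   # tract = codons 149-152
  geneB <- paste0("ATG", paste(sample(codons, 74, replace = TRUE),
                               collapse = ""), "CCC", tract, "TTT",
                  paste(sample(codons, 253, replace = TRUE),
                        collapse = ""), "TAA")   # tract = codons 77-80
  gapAB <- h_dna(2000)
  s <- paste0(h_dna(500), geneA, gapAB, geneB, h_dna(500))
  startA <- 500L
  startB <- 500L + nchar(geneA) + nchar(gapAB)
  feats <- gene_features(rep("r", 2), c("dinX", "mhpY"),
                         c("g1", "g2"),
                         c(startA, startB),
                         c(startA + nchar(geneA), startB + nchar(geneB)),
                         c("+", "+"), c("CDS", "CDS"), c("", ""),
                         c(FALSE, FALSE))
  g <- genome_record("r", s)
  # delete from the end of geneA's tract to the end of geneB's tract
  del_start <- startA + 3L * 152L        # after codon 152 (tract end)
  del_end <- startB + 3L * 80L           # after geneB's tract (codon 80)
  mh <- microhomology(g, del_start, del_end)
  expect_identical(mh$mh_length, 12L)
  expect_identical(mh$mh_sequence, tract)
  fus <- detect_fusion(feats, del_start, del_end, g)
  expect_false(is.null(fus))
  expect_true(fus$in_frame)
  # maximal ranges credit the shared AKIA-style residues to both partners
  expect_identical(fus$retained5, c(1L, 152L))
  expect_identical(fus$retained3, c(77L, 334L))
  expect_identical(substr(fus$fusion_protein, 1, 1), "M")
  expect_identical(fus$fusion_length, 152L + 254L)

  # wholly intergenic deletion: no fusion
  expect_null(detect_fusion(feats, startA + nchar(geneA) + 10L,
                            startA + nchar(geneA) + 500L, g))
})

test_that("frame-incompatible junctions are called out of frame", {
  set.seed(35)
  codons <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T")), 1, paste,
                          collapse = ""), c("TAA", "TAG", "TGA"))
  geneA <- paste0("ATG", paste(sample(codons, 100, replace = TRUE),
                               collapse = ""), "TAA")
  geneB <- paste0("ATG", paste(sample(codons, 100, replace = TRUE),
                               collapse = ""), "TAA")
  s <- paste0(h_dna(200), geneA, h_dna(1000), geneB, h_dna(200))
  feats <- gene_features(rep("r", 2), c("a", "b"), c("g1", "g2"),
                         c(200L, 200L + nchar(geneA) + 1000L),
                         c(200L + nchar(geneA),
                           200L + nchar(geneA) + 1000L + nchar(geneB)),
                         c("+", "+"), c("CDS", "CDS"), c("", ""),
                         c(FALSE, FALSE))
  g <- genome_record("r", s)
  d1 <- 200L + 60L         # codon boundary in gene A
  d2 <- 200L + nchar(geneA) + 1000L + 61L  # off-frame in gene B
  fus <- detect_fusion(feats, d1, d2, g)
  expect_false(is.null(fus))
  expect_false(fus$in_frame)
})

test_that("deletions classify as precise excision, IS-flank, microhomology or blunt", {
  anc <- tiny_ancestry(1)
  g <- anc$genome; feats <- anc$features
  ph <- feats[feats$kind == "prophage", ]
  cls <- classify_deletion(g, ph$start, ph$end, feats)
  expect_identical(cls$category, "precise_element_excision")

  # deletion with one breakpoint at an IS copy boundary
  mob <- feats[feats$kind == "mobile_element", ][1, ]
  copies <- find_is_copies(g, scale_params("tiny", 1)$is_sequence)
  cls2 <- classify_deletion(g, mob$end + 1L, mob$end + 2001L, feats,
                            is_copies = copies)
  expect_identical(cls2$category, "is_flank_recombination")

  # planted microhomology tract from the simulator
  tr <- anc$mh_tracts[anc$mh_tracts$m >= 5, ]
  if (nrow(tr)) {
    cls3 <- classify_deletion(g, tr$left[1], tr$right[1], feats)
    expect_identical(cls3$category, "microhomology")
    expect_gte(cls3$mh_length, tr$m[1])
  }

  # random breakpoints in unique sequence: blunt
  set.seed(36)
  s2 <- h_dna(4000)
  f0 <- gene_features()
  cls4 <- classify_deletion(genome_record("p", s2), 1000L, 2000L, f0)
  expect_identical(cls4$category, "blunt")
})

test_that("terminal repeats circularize scaffolds and rotations are content-stable", {
  set.seed(37)
  core <- h_dna(5000)
  # no terminal identity: unchanged
  plain <- genome_record("s", paste0("AC", core, "GT"))
  r0 <- circularize(plain)
  expect_identical(r0$repeat_length, 0L)
  expect_false(r0$genome$circular)

  # 613-bp terminal repeat: closed with one copy retained
  rep613 <- h_dna(613)
  sc <- genome_record("s", paste0(rep613, core, rep613))
  r1 <- circularize(sc)
  expect_identical(r1$repeat_length, 613L)
  expect_true(r1$genome$circular)
  expect_identical(nchar(r1$genome$sequence), 5000L + 613L)
  expect_identical(r1$genome$sequence, paste0(rep613, core))

  # 250-bp planted repeat
  rep250 <- h_dna(250)
  r2 <- circularize(genome_record("s", paste0(rep250, core, rep250)))
  expect_identical(r2$repeat_length, 250L)
  expect_identical(nchar(r2$genome$sequence), 5000L + 250L)

  # linearize at an arbitrary position, re-add the repeat, re-circularize:
  # sequence content (as a rotation) is conserved
  circ <- r1$genome$sequence
  cut <- 1234L
  lin <- paste0(substr(circ, cut + 1, nchar(circ)), substr(circ, 1, cut))
  relin <- paste0(lin, substr(lin, 1, 613))
  r3 <- circularize(genome_record("s", relin))
  expect_identical(r3$repeat_length, 613L)
  doubled <- paste0(circ, circ)
  expect_true(grepl(r3$genome$sequence, doubled, fixed = TRUE))
})
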