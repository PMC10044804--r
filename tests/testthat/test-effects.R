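mk_var <- function(pos, ref, alt, class, strain = "s", seq_id = "toy") {
  variant_table(strain = strain, seq_id = seq_id, pos = pos, ref = ref,
                alt = alt, class = class)
}

test_that("SNP consequences: silent, missense, nonsense, start-codon change", {
  set.seed(51)
  toy <- toy_gene_genome(n_codons = 60)
  g <- toy$genome; f <- toy$features
  seq <- g$sequence

  # engineer a silent change: find a codon where a third-position swap
  # keeps the residue (leucine CTx family is guaranteed synonymous)
  body <- substr(seq, toy$cds_start + 1, toy$cds_end)
  pos3 <- NULL
  for (ci in 2:(toy$n_codons - 1)) {
    cod <- substr(body, 3 * ci - 2, 3 * ci)
    if (substr(cod, 1, 2) %in% c("CT", "GT", "TC", "CC", "AC", "GC",
                                 "CG", "GG")) {
      pos3 <- toy$cds_start + 3 * ci - 1   # 0-based third position
      break
    }
  }
  ref <- substr(seq, pos3 + 1, pos3 + 1)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  calls <- annotate(mk_var(pos3, ref, alt, "snp"), f, g)
  expect_identical(calls$effect, "silent")

  # nonsense: put a TAC codon in and change it to TAA
  ci <- 10L
  cod_start <- toy$cds_start + 3 * (ci - 1)
  seq2 <- seq
  substr(seq2, cod_start + 1, cod_start + 3) <- "TAC"
  g2 <- genome_record("toy", seq2)
  calls2 <- annotate(mk_var(cod_start + 2, "C", "A", "snp"), f, g2)
  expect_identical(calls2$effect, "nonsense_truncation")
  expect_identical(calls2$codon_affected, ci)
  expect_identical(calls2$total_codons, toy$n_codons - 1L)
  expect_equal(calls2$fraction_lost,
               (toy$n_codons - 1 - ci + 1) / (toy$n_codons - 1))
  expect_true(calls2$knockout)

  # start codon ATG -> ATA
  calls3 <- annotate(mk_var(toy$cds_start + 2, "G", "A", "snp"), f, g)
  expect_identical(calls3$effect, "start_codon_change")
  expect_false(calls3$knockout)
  expect_identical(calls3$substitution, "ATG>ATA")
})

test_that("IS insertions and frameshifts follow the residue-loss knockout rule", {
  set.seed(52)
  # 184-codon gene: 183 residues; insertion at codon 12 loses 172/183
  toy <- toy_gene_genome(n_codons = 184)
  g <- toy$genome; f <- toy$features
  ins_pos <- toy$cds_start + 3 * 11 + 1   # inside codon 12
  el <- synthetic_is_element()
  call <- annotate(mk_var(ins_pos, "", paste0(el, "GCTTAGCAT"),
                          "is_insertion"), f, g)
  expect_identical(call$effect, "is_insertion_in_gene")
  expect_identical(call$codon_affected, 12L)
  expect_identical(call$total_codons, 183L)
  expect_equal(call$fraction_lost, 172 / 183, tolerance = 1e-12)
  expect_true(call$knockout)

  # 599-codon gene: frameshift at codon 586 of 598 loses ~2.2%: kept
  toy2 <- toy_gene_genome(n_codons = 599)
  fs_pos <- toy2$cds_start + 3 * 585 + 1
  call2 <- annotate(mk_var(fs_pos, "", "A", "insertion"),
                    toy2$features, toy2$genome)
  expect_identical(call2$effect, "frameshift")
  expect_identical(call2$codon_affected, 586L)
  expect_identical(call2$total_codons, 598L)
  expect_equal(call2$fraction_lost, 13 / 598, tolerance = 1e-12)
  expect_false(call2$knockout)

  # knockout is monotone in the loss threshold
  call3 <- annotate(mk_var(fs_pos, "", "A", "insertion"),
                    toy2$features, toy2$genome, loss_threshold = 0.01)
  expect_true(call3$knockout)
})

test_that("minus-strand genes are annotated strand-aware", {
  set.seed(53)
  toy <- toy_gene_genome(n_codons = 50, strand = "-")
  g <- toy$genome; f <- toy$features
  # mutate the genome base corresponding to transcript codon 7 position 1
  toff <- 3 * 6
  gpos <- toy$cds_end - 1 - toff          # 0-based genome position
  ref <- substr(g$sequence, gpos + 1, gpos + 1)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  call <- annotate(mk_var(gpos, ref, alt, "snp"), f, g)
  expect_true(call$effect %in% c("silent", "missense",
                                 "nonsense_truncation"))
  expect_identical(call$codon_affected, 7L)
})

test_that("effect classes agree with literal apply-and-translate", {
  set.seed(54)
  n_ok <- 0L
  for (i in 1:120) {
    toy <- toy_gene_genome(n_codons = sample(25:80, 1),
                           strand = sample(c("+", "-"), 1))
    g <- toy$genome; f <- toy$features
    kind <- sample(c("snp", "ins", "del"), 1)
    # keep away from the start codon (classified separately)
    lo <- toy$cds_start + 4L
    hi <- toy$cds_end - 5L
    pos <- sample(lo:hi, 1)
    v <- switch(kind,
      snp = {
        r <- substr(g$sequence, pos + 1, pos + 1)
        mk_var(pos, r, sample(setdiff(c("A", "C", "G", "T"), r), 1),
               "snp")
      },
      ins = mk_var(pos, "", h_dna(sample(1:4, 1)), "insertion"),
      del = {
        l <- sample(1:4, 1)
        if (pos + l > hi) l <- 1L
        mk_var(pos, substr(g$sequence, pos + 1, pos + l), "", "deletion")
      })
    v <- normalize_variants(v, g)
    if (v$pos < lo) next   # normalization slid into the start codon
    call <- annotate(v, f, g)
    if (startsWith(call$effect, "intergenic")) next

    # oracle: apply the variant, translate the mutated gene literally
    mutated <- apply_variants(g, v)
    new_cds_len <- toy$cds_end - toy$cds_start +
      nchar(v$alt) - nchar(v$ref)
    ms <- substr(mutated, toy$cds_start + 1, toy$cds_start + new_cds_len)
    if (f$strand == "-")
      ms <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(ms)))
    os <- substr(g$sequence, toy$cds_start + 1, toy$cds_end)
    if (f$strand == "-")
      os <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(os)))
    trans <- function(x) {
      n <- nchar(x) - nchar(x) %% 3
      as.character(Biostrings::translate(
        Biostrings::DNAString(substr(x, 1, n)), if.fuzzy.codon = "X"))
    }
    p_ref <- trans(os); p_mut <- trans(ms)
    first_stop <- regexpr("*", p_mut, fixed = TRUE)
    expected <- if ((nchar(v$alt) - nchar(v$ref)) %% 3 != 0) {
      "frameshift"
    } else if (first_stop > 0 && first_stop < nchar(p_mut)) {
      "nonsense_truncation"
    } else if (identical(p_mut, p_ref)) {
      "silent"
    } else {
      "missense"
    }
    expect_identical(call$effect, expected,
                     info = sprintf("case %d (%s, pos %d, %s)", i, kind,
                                    v$pos, f$strand))
    n_ok <- n_ok + 1L
  }
  expect_gt(n_ok, 80L)
})

test_that("intergenic variants report flanks and the upstream window", {
  set.seed(55)
  codons <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T")), 1, paste,
                          collapse = ""), c("TAA", "TAG", "TGA"))
  cds <- function(n) paste0("ATG", paste(sample(codons, n,
                                                replace = TRUE),
                                         collapse = ""), "TAA")
  gA <- cds(40); gB <- cds(40)
  s <- paste0(h_dna(300), gA, h_dna(400), gB, h_dna(300))
  startB <- 300L + nchar(gA) + 400L
  f <- gene_features(rep("chr", 2), c("gA", "gB"), c("t1", "t2"),
                     c(300L, startB),
                     c(300L + nchar(gA), startB + nchar(gB)),
                     c("+", "+"), c("CDS", "CDS"), c("", ""),
                     c(FALSE, FALSE))
  g <- genome_record("chr", s)
  near <- annotate(mk_var(startB - 20L,
                          substr(s, startB - 19, startB - 19),
                          "A", "snp", seq_id = "chr"), f, g)
  expect_identical(near$effect, "intergenic_upstream")
  expect_identical(near$upstream_of, "t2")
  far <- annotate(mk_var(startB - 200L,
                         substr(s, startB - 199, startB - 199),
                         "A", "snp", seq_id = "chr"), f, g)
  expect_identical(far$effect, "intergenic_other")
  expect_identical(far$flank5, "t1")
  expect_identical(far$flank3, "t2")
})

test_that("knockout sets combine whole-gene deletions and truncations", {
  anc <- tiny_ancestry(1)
  g <- anc$genome; f <- anc$features
  cds <- f[f$kind == "CDS", ]
  cds <- cds[order(cds$start), ]
  expect_identical(call_knockouts(NULL, f)$knocked_out, character())

  # a deletion spanning several genes plus one qualifying frameshift
  span <- cds[3:6, ]
  del <- mk_var(min(span$start) - 1L,
                substr(g$sequence, min(span$start),
                       max(span$end) + 1),
                "", "large_deletion", seq_id = "anc")
  fs_gene <- cds[10, ]
  fs_pos <- fs_gene$start + 9L
  fs <- mk_var(fs_pos, "", "A", "insertion", seq_id = "anc")
  calls <- annotate(rbind(del, fs), f, g)
  kos <- call_knockouts(calls, f)
  expect_setequal(kos$knocked_out,
                  c(span$locus_tag, fs_gene$locus_tag))
  expect_identical(length(kos$knocked_out), 5L)

  # an empty call set knocks out nothing
  expect_identical(call_knockouts(calls[0, ], f)$knocked_out,
                   character())
})

test_that("gene-list cross-referencing is order- and duplicate-invariant", {
  anc <- tiny_ancestry(1)
  g <- anc$genome; f <- anc$features
  cds <- f[f$kind == "CDS", ]
  v <- do.call(rbind, lapply(cds$start[1:6] + 10L, function(p) {
    r <- substr(g$sequence, p + 1, p + 1)
    mk_var(p, r, setdiff(c("A", "C", "G", "T"), r)[1], "snp",
           seq_id = "anc")
  }))
  calls <- annotate(v, f, g)
  lst <- cds$locus_tag[c(1, 3, 5)]
  x1 <- crossref_gene_sets(calls, list(targets = lst), f)
  x2 <- crossref_gene_sets(calls,
                           list(targets = rev(c(lst, lst[1]))), f)
  expect_identical(x1$summary$n_intragenic_hits, 3L)
  expect_identical(x1$summary$n_intragenic_hits,
                   x2$summary$n_intragenic_hits)
  expect_identical(x1$summary$n_genes_hit, x2$summary$n_genes_hit)
  empty <- crossref_gene_sets(calls, list(none = character()), f)
  expect_identical(empty$summary$n_intragenic_hits, 0L)
  expect_warning(crossref_gene_sets(calls, list(bad = "zz999"), f),
                 "unknown locus tags")
})
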