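# Shared fixtures and independent brute-force oracles.  Oracle helpers are
# deliberately written from scratch (plain substr/paste arithmetic) so they
# share no code with the package paths they check.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

tiny_ancestry <- function(seed = 1L) {
  cached(paste0("anc", seed), generate_ancestor(scale_params("tiny", seed)))
}

h_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                  replace = TRUE), collapse = "")

h_del <- function(seq, a, b) {
  paste0(substr(seq, 1, a), substr(seq, b + 1, nchar(seq)))
}

h_ins <- function(seq, p, allele) {
  paste0(substr(seq, 1, p), allele, substr(seq, p + 1, nchar(seq)))
}

# brute-force microhomology: count and locate every breakpoint placement
# that yields the identical post-deletion sequence
mh_oracle <- function(seq, a, b, scan = 80L) {
  size <- b - a
  target <- h_del(seq, a, b)
  cand <- max(0L, a - scan):min(a + scan, nchar(seq) - size)
  hits <- cand[vapply(cand, function(a2)
    identical(h_del(seq, a2, a2 + size), target), TRUE)]
  list(m = length(hits) - 1L, range = range(hits))
}

# brute-force leftmost equivalent placement of a pure indel
leftmost_oracle <- function(seq, pos, ref, alt, scan = 60L) {
  applied <- if (nzchar(ref)) h_del(seq, pos, pos + nchar(ref))
             else h_ins(seq, pos, alt)
  l <- max(nchar(ref), nchar(alt))
  for (p2 in max(0L, pos - scan):pos) {
    ok <- if (nzchar(ref)) {
      identical(h_del(seq, p2, p2 + l), applied)
    } else {
      identical(paste0(substr(applied, 1, p2),
                       substr(applied, p2 + l + 1, nchar(applied))), seq)
    }
    if (ok) return(p2)
  }
  pos
}

# recovery bookkeeping: truth events vs called variants, matched on
# normalized (pos, ref, alt) with the truth's event class mapped onto the
# caller's vocabulary
recovery_counts <- function(truth_vt, called_vt, exclude = NULL) {
  cmap <- c(snp = "snp", insertion = "insertion", deletion = "deletion",
            is_insertion = "insertion", large_deletion = "large_deletion",
            substitution = "substitution")
  keep <- rep(TRUE, nrow(truth_vt))
  if (!is.null(exclude) && nrow(exclude)) {
    for (i in seq_len(nrow(truth_vt))) {
      s <- truth_vt$pos[i]
      e <- s + max(nchar(truth_vt$ref[i]), 1L)
      if (any(exclude$start < e & exclude$end > s)) keep[i] <- FALSE
    }
  }
  tv <- truth_vt[keep, , drop = FALSE]
  kt <- paste(tv$pos, tv$ref, tv$alt, cmap[tv$class])
  kc <- paste(called_vt$pos, called_vt$ref, called_vt$alt,
              called_vt$class)
  c(recovered = sum(kt %in% kc), total = nrow(tv))
}

# regions of the ancestor where anchoring is inherently ambiguous:
# the identical mobile-element copies (plus the composite span)
repeat_regions <- function(features) {
  mob <- features[features$kind == "mobile_element", , drop = FALSE]
  if (nrow(mob) >= 2L)
    mob <- rbind(mob, data.frame(
      seq_id = mob$seq_id[1], gene = "", locus_tag = "",
      start = min(mob$start), end = max(mob$end), strand = "+",
      kind = "mobile_element", product = "",
      interrupted_in_reference = FALSE))
  mob[, c("start", "end")]
}

# a minimal genome with one plus-strand CDS for consequence tests:
# returns list(genome, features, cds_start)
toy_gene_genome <- function(n_codons = 20L, pad = 30L, strand = "+") {
  n_codons <- as.integer(n_codons)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste,
                  collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  body <- paste0("ATG", paste(sample(codons, n_codons - 2L,
                                     replace = TRUE), collapse = ""),
                 "TAA")
  if (strand == "-")
    body_g <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(body)))
  else body_g <- body
  seq <- paste0(h_dna(pad), body_g, h_dna(pad))
  g <- genome_record("toy", seq)
  f <- gene_features("toy", "toyA", "t0001", pad, pad + nchar(body),
                     strand, "CDS", "toy protein", FALSE)
  list(genome = g, features = f, cds_start = pad,
       cds_end = pad + nchar(body), n_codons = n_codons)
}
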