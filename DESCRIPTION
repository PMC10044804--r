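Package: evotrace
Title: Anchored Genome Comparison and Evolution Statistics for
    Laboratory-Evolved Bacteria
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for tracing the genomic record of adaptive laboratory
    evolution in bacteria. Simulates serial-passage genome evolution with a
    complete ground-truth event ledger (SNPs with a pyrimidine-collapsed
    spectrum, small indels, insertion-sequence transposition with 9-bp
    target-site duplications, large deletions at microhomologous tracts,
    precise prophage excision, sibling lineages sharing a common phase);
    recovers variants between near-identical genomes by unique-k-mer
    anchoring; characterizes deletion junctions (microhomology, in-frame
    gene fusion, precise element excision, IS-flank recombination) and
    terminal-repeat circularization; scans for insertion-sequence copies,
    composite transposons, target-site duplications and degenerate target
    consensus motifs; annotates variant consequences with a knockout rule;
    and computes per-day mutation rates with exact Poisson intervals,
    mutational spectra, expected spontaneous load under serial dilution,
    hyper-mutagenesis factors, sibling divergence dating and melting
    temperature enrichment among knocked-out genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    vcfR,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
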