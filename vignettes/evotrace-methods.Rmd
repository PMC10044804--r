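---
title: "Methods: simulating and recovering the genomic record of laboratory evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and recovering the genomic record of laboratory evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evotrace)
```

# The problem

Long serial-passage evolution experiments in bacteria leave a layered
genomic record: point mutations accumulating under a biased substitution
spectrum, small indels (often in homopolymer runs), insertion-sequence (IS)
elements transposing into new sites and leaving target-site duplications
(TSDs), large deletions joined at short microhomologous tracts, and precise
excision of prophage-like elements.  When two sibling isolates are drawn
from the same evolving culture, the partition of their differences into
shared and strain-specific changes dates their divergence.

`evotrace` packages this whole analysis: a simulator that produces
descendant genomes with a complete ground-truth event ledger, a variant
caller for near-identical genome pairs, structural-junction and mobilome
characterization, consequence annotation with a knockout rule, and the
rate/divergence/enrichment statistics.  Because the simulator's ledger is
exact, every downstream stage can be validated against known truth — the
oracle that analyses of real isolates never have.

# The simulator

## Regime

The default parameters of `evolution_params()` describe the emulated
experiment: cultures transferred every 2 days at 1:8 dilution for 2,512
days, accumulating changes at 0.092 events/day, with sibling lineages
sharing a common phase until day 2,112 (400 days of separate evolution).
The substitution spectrum puts weight 0.65 on the C:G→T:A class, the
signature of elevated C deamination; the remaining five collapsed classes
share the rest.  Event classes default to 65% SNPs, 25% small indels, 8%
IS insertions, and a small remainder of large deletions and element
excision, which approximates the composition of changes reported for
heat-evolved isolates (151 SNPs among 231 changes, 15 new IS copies, three
large deletions).

The genome itself is scaled down — 200 kb by default, 40 kb for the
`"tiny"` test preset and 150 kb for the `"paper-like"` preset — so that
whole-genome scans stay in the seconds range.  Event *sizes* scale with
it (deletions are lognormal around 2 kb rather than 8–123 kb).  Scaling
the substrate length changes nothing about per-event arithmetic, but it
does mean the simulator does not probe repeat densities or replichore
structure of a real 4.6-Mb chromosome; conclusions about anchor
uniqueness at full genome scale rest on the k-mer argument below, not on
these tests.

## The ancestor

`generate_ancestor()` builds a circular genome with non-overlapping CDSs
(ATG start, no internal stop, random strand), one annotated prophage-like
element with exact boundaries, and one composite transposon: two identical
IS copies flanking a cargo CDS, the Tn10 geometry.  It also plants
`n_homology_tracts` pairs of identical short tracts (lengths drawn from
`microhomology_length_weights`, separations from the deletion-size
distribution).

The tract pairs are the substrate for microhomology-mediated deletions.
A deletion called against a reference can only show junction microhomology
that *pre-exists in that reference* — in the motivating case, two genes
happened to share 12 bp (four identical residues) long before the deletion
joined them.  Planting the homology in the ancestor and letting deletion
events choose tract pairs as breakpoints reproduces exactly this
situation: repair at pre-existing microhomologous sites, recoverable by
the junction detector.  Deletions beyond the planted tracts fall at
random positions and carry whatever chance homology exists there (ledgered
as the measured value).

## Events and the ledger

Event count is Poisson(rate × days); timestamps are uniform.  Events are
placed in the *ancestor* coordinate frame and kept pairwise disjoint there
(an event landing on a previously affected interval is resampled, with
bounded retries), so the ledger has a replay property: applying the events
left-to-right reproduces the evolved genome byte-for-byte, and the
evolved-frame coordinates follow from cumulative length shifts.  This is
the strongest possible contract for recovery testing, at the cost of
excluding nested events (a second hit inside a deleted region, an IS
jumping into an earlier IS); a deliberate trade, since nested events make
ground truth ambiguous.

Details worth noting:

* **SNPs** — the collapsed class is drawn once per event from
  `spectrum_weights`, expanded to a strand with probability 1/2, and the
  site is then sampled from an index of positions carrying the required
  base.  Sampling the site *conditionally on the base* keeps realized
  class fractions exactly at the configured weights; the obvious
  rejection-sampling alternative (draw class and site independently,
  retry on mismatch) biases classes toward the genome's base composition
  by about one percentage point, which is measurable at the scale of the
  recovery tests.
* **IS insertions** — a site is chosen by scoring candidate 9-mers under
  the position-weight target model (`target_pwm`, a YRCTNNRNN-style
  preference by default) and sampling proportionally to likelihood among
  `n_candidate_sites` random candidates; the event writes
  target + element + target, creating the 9-bp direct repeats of
  cut-and-paste transposition.  Insertions never land inside an existing
  mobile element or the composite transposon span, keeping the copy
  census and composite pairing unambiguous.
* **Element excision** — removes the annotated prophage exactly at its
  boundaries, once.
* **Siblings** — the shared phase is drawn with a child seed derived from
  (seed, stream index), then two continuations draw independent events
  that avoid the shared footprints; shared events carry `shared = TRUE`
  in both ledgers.  All child seeds stay below 2^31.

# Variant recovery by unique-k-mer anchoring

`diff_genomes()` compares two near-identical genomes:

1. **Anchors** are 21-mers that occur exactly once in each genome and are
   shared.  Requiring uniqueness in *both* genomes is what makes IS
   expansions safe: a 1.3-kb element present in many copies contributes no
   anchors from its interior, so no chain can jump between copies.  In a
   random-composition genome the expected number of repeated 21-mers is
   vanishingly small, so anchors tile everything except genuine repeats.
   Anchors are thinned to roughly one per 7 bp before chaining (adjacent
   anchors are redundant).
2. **Chaining** is the longest strictly-increasing subsequence of query
   positions over reference-sorted anchors (patience algorithm,
   deterministic reconstruction), followed by a greedy pass that keeps
   anchors at least k apart on both sequences — measured from the last
   *kept* anchor — so inter-anchor gaps are well defined.
3. **Circular rotation** — for circular pairs the query is rotated by the
   offset of the anchor nearest the reference origin, which is zero for
   an unrotated assembly and otherwise aligns the seams so one collinear
   pass covers the genome.
4. **Gap resolution** — each inter-anchor gap is trimmed of its common
   prefix and suffix; a residue empty on one side is a pure
   insertion/deletion; single-base residues are SNPs; anything else up to
   `max_gap` (5 kb) on both sides is globally aligned
   (`Biostrings::pairwiseAlignment`, match 1 / mismatch −2 / gap open 4 /
   extend 1) and the aligned columns are run-length-decoded into events,
   with a multi-base mismatch run emitted as one substitution rather than
   split into SNPs.  Gaps larger than `max_gap` on both sides are
   reported as *unresolved regions*, never silently dropped.
5. **Normalization** — indels are shifted to their leftmost equivalent
   placement; pure homopolymer-run changes get a `A8>A7`-style note.
   Left-normalization is verified against a brute-force enumeration of
   equivalent placements.

Deletions of at least `large_threshold` (50 bp) are classed
`large_deletion` and handed to junction analysis.  The 6-bp boundary
between "small" and "large" events used in *reports* (`size_class()`) is
display convention only and deliberately separate from this structural
threshold.

The emitted edit script reconstructs the query exactly
(`apply_variants()`), and on simulations ≥99% of planted events outside
repeat regions are recovered with exact class, position and alleles
(events inside the identical composite-transposon copies are excluded by
that carve-out, since no anchoring method can place them uniquely).

# Junctions

`microhomology()` defines junction homology as the longest common suffix
of the prefixes ending at the two breakpoints plus the longest common
prefix of the suffixes starting there.  This sum is placement-invariant:
the set of breakpoints producing the identical post-deletion sequence is
an interval (`placement_range`) of width mh + 1, and the canonical
breakpoint is the leftmost, matching left-normalization elsewhere.  The
definition is validated against a brute-force oracle that literally
applies every candidate deletion and compares sequences.

`detect_fusion()` fires when both breakpoints fall inside same-strand
CDSs; the junction is in frame iff the breakpoint offsets agree modulo 3
(strand-adjusted), and the fused ORF is translated (bacterial code;
GTG/TTG accepted as annotated starts) to confirm there is no premature
stop.  Retained residue ranges are reported *maximally*: the 5' range
under the rightmost equivalent placement and the 3' range under the
leftmost.  A junction inside a shared tract therefore credits the shared
residues to both partners — the convention in which a fusion retaining
"1–152" of one protein and "80–337" of the other overlaps by the four
junction residues.

`classify_deletion()` applies, in precedence order:
`precise_element_excision` (breakpoints coincide with an annotated
element's boundaries within tolerance 0 bp, tested over every equivalent
placement), `is_flank_recombination` (a breakpoint within ±3 bp of a
detected IS-copy boundary), `microhomology` (mh ≥ 5), else `blunt`.  The
±3-bp IS tolerance and the 0-bp excision tolerance are exposed
parameters, since published breakpoint conventions vary.

`circularize()` closes a terminally redundant linear assembly: the
longest exact prefix–suffix match (KMP border array, capped at half the
scaffold) is removed once and the record flagged circular — the operation
that turns a de novo assembly with, say, 613 bp of terminal identity into
a circle 613 bp shorter than the scaffold.

# Mobilome

`find_is_copies()` seeds with non-overlapping 15-mers of the reference
element on both strands, clusters seed hits, and resolves each cluster by
iterative align-and-mask: ends-free alignment of the full element against
the cluster window, acceptance at ≥95% identity over the aligned span and
≥90% reference coverage, masking, and re-alignment until nothing further
is found.  This resolves adjacent copies (composite ends, insertions near
existing copies) that a single-alignment-per-cluster approach conflates.
Ends-free trimming of terminal mismatches is undone by extending accepted
spans to the full element length, so flank coordinates are exact and TSD
extraction (`extract_tsd()`) reads true flanking words.  Identity is
reported over the aligned span and coverage separately, so truncated
copies and diverged copies are distinguishable.  Circular genomes are
scanned across the origin by appending one element length of leading
sequence; wrapped images are deduplicated.

`flag_composite()` pairs same-family copies whose cargo gap is ≤ 15 kb
*and* contains a gene: an annotated CDS when annotation in the scanned
genome's frame exists, otherwise an ORF of ≥ 600 bp in the gap (random
sequence of cargo size routinely contains chance ORFs up to ~200 codons,
so a gene-sized ORF is the discriminative requirement).

`build_consensus()` tallies per-position bases over equal-width target
sites; a base enters the consensus set when its frequency is ≥ 0.25 (ties
included), and the reported letter is the minimal IUPAC code covering the
set.  With 15 sites the default threshold means "seen at least four
times", a standard logo-style cutoff; it is exposed because the
degenerate-consensus rule is rarely stated in publications.  The
construction is monotone: raising the threshold never enlarges a
position's base set.

`classify_against_alleles()` profiles a copy against two equal-length
reference alleles at the positions where they differ, then reports coding
changes by translating the element's longest ORF (the transposase)
against the better-matching allele — the analysis that identifies hybrid
elements and their ORF substitutions.

# Consequences and knockouts

`annotate()` classifies each variant against every affected CDS:
silent/missense/nonsense by codon translation (strand-aware); frameshift
when an indel's net length is not a multiple of 3, at the codon containing
the first shifted base; `start_codon_change` for any change to the
annotated start codon (classed separately, not auto-knockout, because
downstream near-cognate starts can rescue initiation);
`is_insertion_in_gene` at the insertion-point codon; `gene_deleted` for
genes wholly inside a deletion; truncation at the breakpoint codon for
genes cut by one.  A stop is "premature" when it falls strictly before
the mutated CDS's own final codon — so an in-frame deletion of the last
codons is an in-frame change, not a truncation; this boundary was fixed
against the literal apply-and-translate oracle.  `codon_affected` is the
first codon whose encoded residue changes; `total_codons` is the protein
length excluding the stop; for truncating classes
`fraction_lost = (total − affected + 1)/total`.

The knockout rule (`call_knockouts()`): a frameshift, truncation or IS
insertion losing more than 10% of the residues, or whole-gene deletion.
Genes annotated as already interrupted in the reference are reported
separately rather than counted.  Intergenic variants report their
flanking genes and an `intergenic_upstream` flag within 50 bp 5' of a
start codon (promoter/RBS territory); the window is exposed since no
standard distance exists.

# Statistics

* `spectrum()` collapses the 12 directional substitutions to 6 classes
  keyed to the pyrimidine of the reference pair; counts are invariant
  under complementing every SNP.
* `rate_per_day()` is count/days with the exact (Garwood) Poisson
  interval, `qgamma(0.025, n)/t` to `qgamma(0.975, n + 1)/t` — chosen
  because counts are small and the closed form is conservative.
* `doublings_from_dilution(f, Δt) = log2(f)/Δt`;
  `expected_load = doublings/day × μ × L`; `hyper_factor` is the observed
  to expected ratio.  With 1:8 dilution every 2 days, μ = 1e-9 /bp/gen
  and a 4.64-Mb genome this gives 1.5 doublings/day, 0.0046 changes per
  genome per generation, 0.0069 changes/day, and a ~13-fold excess for a
  0.092/day observed rate.
* `divergence_days()` divides the strain-specific count by the
  *unrounded* rate — the two published day counts are reproduced jointly
  only with the unrounded quotient (41/0.096 rounds a day high) — and
  propagates the Poisson interval on the count.  The rate's own
  uncertainty is not propagated; on 200 paper-like simulations the
  resulting interval still covers the planted divergence in ≥95% of
  runs, so the simpler interval is kept.
* `tm_enrichment()` restricts knockouts to proteins present in the
  melting-temperature table, computes the proportion with Tm ≤ t_max + 5,
  and adds an exact two-sided binomial test against the genome-wide
  background proportion — a formalization of what is usually an
  eyeballed comparison, and documented as such.  The strain's t_max is a
  required user input, not a constant.

# Worked example

```{r example, eval = FALSE}
library(evotrace)

dir <- tempfile("evotrace")
fx <- make_fixtures(dir, seed = 4, scale = "tiny")
res <- run_pipeline(fx$files$config)
readLines(file.path(dir, "out", "summary.txt"))[-(1:2)]
```

On the tiny preset this runs all stages in about ten seconds, recovering
the planted events, the IS census with its target-site consensus, the
knockout set and the rate arithmetic, with every output written as TSV
beside a parameter-complete summary.

# Problem sizes in the test suite

The suite validates: ledger replay over 100 lineage seeds; diff recovery
over 100 tiny-scale lineages (≥99% of planted events outside repeats,
exact class and position); microhomology and left-normalization against
brute-force oracles on 10,000 random instances each; divergence-interval
coverage and spectrum recovery over 200 paper-like sibling simulations;
and consequence classes against literal apply-and-translate on randomized
CDS/variant instances.  `scripts/acceptance.R` re-runs scaled versions of
the same computations (50/30/100 replicates) in about half a minute.

# Known limitations

* No selection, clonal interference or within-culture population
  dynamics: event times are exchangeable and lineages are single
  molecules.  Divergence dating consequently assumes strain-specific
  changes are independent post-split events; any diversity already
  present when isolates were picked would inflate apparent divergence
  time, which is exactly the caveat attached to such estimates.
* No nested events, by design (unambiguous ground truth).
* The variant caller targets near-identical pairs (≥90% shared unique
  k-mers) and refuses diverged ones rather than mis-anchoring.
* Sub-clonal frequencies are carried through I/O but never estimated:
  assemblies are consensus sequences, so `diff_genomes()` emits
  frequency 1.0.
* IS copies inside long identical repeats cannot be placed by any
  unique-anchor method; they surface as unresolved regions instead of
  calls.
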