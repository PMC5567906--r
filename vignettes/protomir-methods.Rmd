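---
title: "protomir: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{protomir: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protomir)
```

`protomir` analyses small RNA sequencing from two unreplicated plant
libraries — the motivating design is a callus library against a library
from freshly isolated protoplasts, asking which miRNAs respond to
cell-wall removal. This vignette explains the models and procedures, the
parameters that matter, and the design choices made where the published
conventions of this kind of analysis leave room.

## Read cleaning and the category ledger

Every raw read is assigned to exactly one category by the first failing
test in a fixed order:

1. **low quality** — any non-ACGT character, or mean Phred below
   `min_mean_q` (default 20);
2. **3' adapter null** — no acceptable adapter match;
3. **insert null** — the adapter starts at position one (adapter dimer);
4. **5' adapter contaminant** — the insert contains the first 10 nt of the
   5' adapter with at most one mismatch;
5. **length filter** — insert outside the `min_len`–`max_len` window
   (defaults 18 and 30 nt);
6. **poly-A** — insert at least 80 % adenine;
7. **clean** — everything else, collapsed into unique-sequence counts.

The precedence itself is a design choice: sequencing-facility summary
tables list these categories without stating an order, but a partition
needs one. The order above removes technical failures before
composition-based filters, so for example a 12-nt poly-A insert counts as
"too short", not "poly-A".

Adapter localisation scans read positions left to right and accepts the
first position where the adapter prefix overlaps by at least `min_overlap`
(6) nt with at most `max_mm` (1) mismatch, with the overlap capped by the
read end. Because the overlap at the true insert/adapter junction is
nearly the full adapter length, a spurious short match can essentially
only occur 3' of the junction, where the true junction has already won;
the probability of a ≥ 20-nt spurious match 5' of it is negligible. This
is what makes the simulator's injected category counts exactly
recoverable, which the tests assert.

The ledger invariants — `clean = high_quality − Σ categories`, percentages
to two decimals, every category bounded by `high_quality` — are enforced
in the `read_ledger()` constructor, so an inconsistent table cannot be
represented.

The 18–30 nt analysis window deserves a note: size selection in such
experiments is typically a little wider (16–30 nt at the gel), but the
bioinformatic window governs what is analysed, and the ledger's own
"smaller than 18 nt" category fixes 18 as the lower bound. Both bounds are
arguments. Inserts *longer* than the window (possible when the adapter
sits late in the read) are counted in the same length-filter category,
since the ledger has a single length row.

## Hierarchical annotation

Unique clean sequences are classified by the first match in the priority
order rRNA > tRNA > snRNA > snoRNA > known miRNA > exon/intron >
unannotated. All matching is exact: substring matching against the ncRNA
reference sets, full-length case- and U/T-insensitive equality against the
mature miRNA catalogue ("perfect match" is the standard rule for calling
conserved miRNAs, and we extend exactness to all classes for
determinism). Genome mapping finds all exact loci on both strands
(0-based, half-open), capped at `max_hits` (25) per sequence to keep
repeat-derived reads from blowing up downstream work; capped sequences are
flagged and excluded from novel miRNA discovery.

A genome-mapped sequence overlapping both exon and intron annotation is
classified by majority overlap with ties to exon; sense/antisense compares
the read strand with the feature strand. A sequence with several loci
takes the highest-priority category across them (exon before intron,
sense before antisense). These tie-breaks are arbitrary but fixed, and the
partition property — every clean read counted exactly once — is
fuzz-tested.

## Novel miRNA discovery

Unannotated genome-mapped sequences with total read support of at least
`min_reads` (5, summed over libraries) and fewer than `max_hits` loci are
clustered along the genome (gap ≤ 50 nt); the most abundant read leads
each cluster as the mature candidate. Around each lead locus three
precursor windows are excised — symmetric ± `flank` (150 nt), and two
read-anchored windows placing the read near the 5' or 3' arm — clipped at
the contig ends and strand-corrected to the transcribed sequence.

Each window is folded and screened by plant-miRNA hairpin criteria, in
order, with the rejection reason reported:

* **arm** — no base pair joins two mature positions (the mature must not
  span the terminal loop) and the mature is not fully unpaired;
* **duplex** — at most 4 unpaired mature positions, and the spans of the
  mature and star sides of the duplex differ by at most 2 nt (our
  operationalisation of "≤ 2 asymmetric bulged nucleotides");
* **mfe** — folding energy ≤ −18 kcal/mol;
* **length** — mature length 20–24 nt;
* **reads** — mature read support ≥ `min_reads`.

A sequenced star read is *not* required — many genuine plant miRNAs lack
one at realistic depth — so the duplex criterion operates on the predicted
structure. Accepted candidates are deduplicated by mature sequence,
ordered by locus and mature, and named `novel_mir_1 … novel_mir_N`, so
naming is reproducible.

### Folding engines

Two engines sit behind one interface (`fold_rna()`):

* `"vienna"` — nearest-neighbour minimum free energy via the ViennaRNA
  `RNAfold` binary (batched through one process call), used when present;
* `"nussinov"` — a self-contained maximum base-pairing dynamic programme
  (Rcpp) with minimum loop 3, A-U/G-C/G-U pairs, and a pseudo-energy of
  −1.0 kcal/mol per pair.

The Nussinov engine's traceback prefers, among co-optimal structures,
pairing the current base and pairing it with its most *distant* admissible
partner. Either choice yields a maximum-pairing structure (the tests
verify pair counts against an independent recursive oracle), but the
far-first preference resolves co-optimal ties toward long-range stems —
the natural choice when the object of interest is a hairpin arm — rather
than local helices. The −18 kcal/mol acceptance threshold is meaningful
under both energy scales for the strong stems the criteria demand, and the
hairpin test suite runs under both engines.

## Differential expression

Expression is normalised as `TPM = 10⁶ · count / library_total` with
`library_total` the library's total clean reads by default (total
miRNA-matched reads is available via `normalize_by = "mirna"` in the
pipeline configuration — published tables rarely state which denominator
was used, and both are defensible). TPM values below 0.01 are floored at
0.01: this keeps fold changes finite for miRNAs sequenced in only one
library, and is the conventional floor consistent with the very large
fold-change magnitudes (±10 and beyond) such tables print for
condition-specific miRNAs.

Fold change is `log2(TPM_protoplasts / TPM_calli)`. Significance uses the
exact conditional count test for unreplicated libraries: given `x` reads
in library 1, the count in library 2 follows

$$P(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

which is a negative binomial with size `x+1` and success probability
`N₁/(N₁+N₂)`; tail sums are computed through `pnbinom()` (log-space
internally, no factorial overflow) and verified against direct log-space
summation of the mass function to a relative error of 10⁻¹⁰. The
two-sided p-value doubles the smaller tail, with the point mass included
in both tails and a cap at 1. One consequence worth knowing: swapping the
libraries (`x,N₁ ↔ y,N₂`) is *not* an exact symmetry of this
construction — the point mass sits in both tails — though the two
orderings agree to within an order of magnitude (the tests bound the
ratio). The fold change, by contrast, is exactly antisymmetric.

Calls use `fc > 1` or `fc < −1` (strict) with `p ≤ 0.01` (inclusive), no
multiple-testing correction — matching the conventions of unreplicated
two-library sRNA studies, where the raw exact-test p-value is the
published quantity. Reports order the up block then the down block, each
by ascending fold change.

## Target prediction

Each miRNA is scanned against each transcript antiparallel (miRNA position
1, its 5' end, pairs the 3'-most base of the target window). Per-position
classes are Watson–Crick (weight 0), G·U wobble (0.5), mismatch (1); at
most one single-nucleotide bulge (weight 1) is allowed on either strand.
For every window start the best-scoring variant is kept, and windows with
score ≤ 4 proceed to the six rules listed in the README.

Two readings had to be fixed where the conventional criteria are loosely
worded:

* **G·U in positional rules.** Wobbles count 0.5 toward the *scored* rules
  (1 and 5) but count as mismatch *events* for the adjacency/run rules
  (2–4). This is the stricter reading; `gu_as_adjacent_mismatch = FALSE`
  switches to the lenient one.
* **"No more than 2 adjacent mismatches".** Interpreted as runs of length
  > 2 being forbidden (three or more consecutive non-paired positions);
  two adjacent mismatches outside the 2–12 seed region are allowed.
* **Bulges** are not mentioned by the classical rule lists at all, but
  real plant duplexes need them; we allow one, prohibited while flanking
  positions 2–12, recorded against the 5'-flanking miRNA position.

Rule 6 compares the duplex free energy with the miRNA bound to its exact
complement. The default engine is the alignment-faithful pair-count model
(−1 per WC pair, −0.5 per wobble; perfect complement = −L), under which
the 75 % ratio is nearly implied by the score-≤ 4 rule — an honest
property of that energy scale, noted rather than hidden. The `"vienna"`
engine (`RNAduplex`) gives nearest-neighbour energies where the ratio
criterion has independent bite. Both engines return ratio 1 for the
perfect complement, and a fully unpaired duplex has ratio 0.

The scanner is verified window-by-window against an exhaustive oracle on
kilobase-scale instances, and the rule filter is checked for monotonicity:
improving any position (MM → GU → WC) can never turn an accepted site
into a rejected one.

## The synthetic data generator

The simulator exists so that every stage has a knowable ground truth. It
emulates:

* a single toy chromosome (default 100 kb) carrying 30 planted hairpin
  precursors (20 "known", i.e. in the mature catalogue, and 10 withheld as
  discovery targets) and 20 exon/intron gene models;
* rRNA/tRNA/snRNA/snoRNA reference sets that are absent from the genome,
  so ncRNA contamination and genome-mapping fractions are independent;
* transcripts carrying planted target sites that satisfy the six-rule
  filter by construction (asserted at build time);
* two libraries of insert + 3' adapter reads with known defect fractions
  (all small, of order 0.2–1 %), ncRNA contamination (6 %), a dominant
  degradation mass (65 %, length mode at 24 nt as in real plant sRNA
  profiles), and the remainder miRNA reads.

Per-miRNA counts are independent gamma-Poisson (negative binomial) draws:
relative abundances come from a log-uniform grid, a shared dispersion
(default 0.15) supplies realistic between-library overdispersion, and the
planted log2 effects (default +3 on six and −3 on six known miRNAs)
multiply the protoplast means. The Poisson means are scaled by whichever
condition carries more expected miRNA mass, shared across both conditions
— so planted fold changes are exact in expectation and the miRNA mass can
never outgrow the library. The non-miRNA categories fill the remaining
reads at their relative fractions. Defective reads are constructed (with
rejection sampling against the package's own cleaning rules) to land in
their intended ledger category, which is what makes the exact
ledger-versus-truth tests possible.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: sequencing errors and quality-score structure,
multi-chromosome genomes and repeat families, ncRNA sequences homologous
to the genome, isomiR variation around mature ends, hairpins that fold
into branched or non-canonical structures, and the extreme library
compositions of real tissues (real miRNA fractions can be orders of
magnitude smaller). Recovery rates measured on the simulation are
upper bounds on what identical settings would achieve on real libraries.

### Measurement design of the round-trip benchmark

`synthetic_benchmark()` measures hairpin recall (planted novel miRNAs with
read support ≥ 5 recovered by discovery) and DEM sign accuracy (planted
|log2 effect| = 3 known miRNAs at mean count ≥ 50 called in the planted
direction). A single study plants only a dozen effects, and with an
unreplicated design at dispersion 0.15 the standard deviation of an
estimated log2 ratio is about 0.8 — so each planted call has an
irreducible 1–3 % chance of falling under the |fc| > 1 threshold, and a
single-study fraction is too noisy to compare against a 95 % bar. The
benchmark therefore aggregates four independently seeded studies
(2 × 20,000 reads each; seeds derived deterministically from the base
seed), which makes the measurement stable without changing any study
condition. The test suite runs the same benchmark; the full-scale
pipeline in `scripts/acceptance.R` additionally runs one 2 × 100,000-read
study end to end.

## Numerical and degenerate-input conventions

* Coordinates: 0-based half-open everywhere in memory; GFF3 output is
  1-based closed via `rtracklayer`.
* U/T: sequences are normalised to DNA (T) for storage and matching, to
  RNA (U) for folding; all matching is case-insensitive.
* Rounding: percentages and fold changes to two decimals in reports;
  p-values in scientific notation; internal computation at full precision.
* Empty inputs: cleaning an empty read set returns a zeroed ledger and an
  empty profile, not an error; an empty candidate list yields an empty
  novel catalogue; `length_distribution()` of an empty profile has zero
  rows.
* Duplicate catalogue entries sharing one mature sequence collapse to the
  first name with a warning.
* Determinism: all simulator randomness flows from the seed (library
  seeds are derived as `seed·31 + {1,2}`), and RNG state is restored after
  each call; identical inputs give byte-identical outputs, which the tests
  assert.

## Known limitations

* Exact-match annotation means a single SNP or isomiR shift drops a read
  to the unannotated pool; heuristic alignment is out of scope.
* The pair-count energy model makes the MFE-ratio target rule nearly
  redundant; use the ViennaRNA engine when energy discrimination matters.
* The exact count test is anticonservative in the presence of biological
  overdispersion (it models sampling only) — inherent to unreplicated
  designs, and the reason the benchmark conditions on planted effects
  rather than interpreting p-values as error rates.
* One chromosome, one bulge per duplex, no multi-interval precursor loci.
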