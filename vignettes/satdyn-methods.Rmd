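---
title: "Methods: satellitome quantification and satellite DNA dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellitome quantification and satellite DNA dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satdyn)
```

# Scope and model

`satdyn` quantifies satellite DNA families from sequence data in three
linked representations:

1. **Hits** — local alignments of queries (reads or assembly segments) to a
   family's monomer consensus, each carrying a Kimura 2-parameter (K2P)
   divergence.
2. **Divsum tables** — aligned bp per family per integer divergence bin in
   `[0, 70)`, the quantitative core from which landscapes and per-family
   statistics derive.
3. **Z-score records** — per-family abundance and mean divergence
   standardized across the families of one species, classified into gain /
   loss, with a flag for highly abundant homogenized families.

The package assumes satellite monomers are *effectively circular* (an array
is head-to-tail, so a read can start at any rotation) and that divergence
is measured *from the consensus*, not between copies. Both assumptions
follow the conventions of read-based satellitome profiling.

# Masking reads against circular consensuses

## Tandemization

To align a length-`L` query against a circular monomer of length `m`, the
consensus is repeated `ceil(L/m) + 1` times (`tandemize()`). Any window of
`L` bp of a perfect circular array then occurs contiguously in the
linearized target, so a single local alignment suffices; no rotation
enumeration is needed.

## Alignment engine

Alignment is affine-gap Smith–Waterman through Biostrings'
`pairwiseAlignment`, with a gap of length `k` costing
`gap_open + k * gap_extend`. Defaults (`scoring_scheme()`):

| parameter | default | rationale |
|---|---|---|
| match | +2 | generic DNA scoring; rewards long hits |
| mismatch | −3 | tolerates the 10–20% divergence typical of old satellite copies |
| gap_open / gap_extend | 5 / 2 | indels in satellite copies are short; discourage long gaps |
| min_score | 40 | ≥ ~20 bp of clean match before a hit is believed |
| min_hit_length | 30 bp | below this, divergence estimates are too noisy to bin |
| max_divergence | 45% | just above the most diverged copies reported in comparative satellitome surveys (~43%) |

All are user-configurable; the defaults are package decisions, since
RepeatMasker-style tools do not document a single canonical matrix for
satellites. The test suite verifies the engine's optimal scores against an
independent full-DP implementation on hundreds of random instances, so the
engine is oracle-checked rather than trusted.

A banded implementation was considered and rejected: the C engine aligns a
full 150 bp read against a tandemized consensus in well under a
millisecond, so banding would only add an approximation to rule out.

When several alignments share the optimal score, the engine's canonical
traceback is reported. Across-family ambiguity on one query is resolved
greedily: candidate hits are sorted by decreasing score (ties: earlier
query start, earlier target start, fewer gap columns) and a candidate
overlapping already-accepted hits by more than 10% of its own length is
discarded. Greedy-by-score is simple, order-independent given the tie
rules, and exactly testable.

## Kimura divergence and its comparison scale

Per hit, transitions `P` and transversions `Q` are counted over ungapped
columns and `K = −½ ln((1 − 2P − Q)√(1 − 2Q))` is reported in percent. Gap
columns are excluded. Saturated hits (`1 − 2P − Q ≤ 0` or `1 − 2Q ≤ 0`) are
discarded with a counted warning rather than given an arbitrary value;
divergences ≥ 70% are clamped into the top divsum bin, again with a
warning. CpG-adjusted variants are out of scope.

Two opposing biases matter when comparing estimates to a *planted*
substitution rate `d`:

* the K2P transform sits **above** the raw mismatch proportion (at
  `d = 15%` with a 2:1 transition bias, K2P of the expected `P`, `Q` is
  ~16.3%);
* optimal local alignment preferentially trims or avoids the most diverged
  stretches of a read, pulling the estimate **down**, increasingly so at
  high divergence.

Empirically (see the landscape and benchmark tests) these largely offset
each other, so package tests compare estimated mean Kimura divergence
directly against the realized planted substitution percentage, with a
±2 pp band for families with at least 100 hits. Both effects are inherent
to RepeatMasker-style profiling, not artifacts of this implementation.

## Abundance denominators

For reads, abundance is masked bp divided by total sampled read bp — the
natural genome proxy when profiling unassembled genomes. For assemblies,
the denominator is assembly bp (per chromosome for chromosome profiles).
Both conventions are explicit in the corresponding functions, and the
choice is the main reason read-based and assembly-based abundances can
differ on the same genome.

# Landscapes and peak ages

`build_landscape()` converts a divsum table into percent of genome per
(family, 1% divergence bin), dropping families whose total abundance does
not exceed `min_abundance` (default 0.2%, the conventional reporting
cutoff for "highly abundant" families). "Recent burst" is operationalized
as the landscape mode falling at or below bin 5 (configurable); ties
resolve to the lowest bin, biasing calls toward "recent" only when the
evidence is genuinely ambiguous. `landscape_modes()` reports all local
maxima carrying at least a set fraction of a family's mass, which is how
bimodal (two-burst) histories are detected.

# Gain/loss z-scores

Within one species, abundance and mean divergence are standardized across
families with the sample (n−1) standard deviation. The classification is:

* `z_abundance > 0` → gain (regardless of the divergence sign);
* `z_abundance < 0` → loss (irrespective of divergence);
* `z_abundance = 0` → loss, since a gain requires strictly positive
  standardized abundance (a measure-zero boundary in practice);
* `z_abundance > 1` and `z_divergence < 0` → flagged highly abundant and
  homogenized (recent amplification).

Standardization *within species* (rather than per family across species)
is the primary mode because per-species gain counts are the downstream
quantity of interest; at least two families with non-zero variance in both
variables are required, and violations raise errors naming the offending
variable. Whether abundance enters as bp, percent or copy number does not
matter: z-scores are scale-invariant, which the suite asserts.

# Superfamily grouping

All family pairs are aligned (longer consensus vs the *doubled* shorter
one, covering every circular rotation, on both strands). An edge requires
identity ≥ 70% — matches over all alignment columns, gaps included — across
≥ 50% of the shorter monomer; superfamilies are connected components. The
thresholds are package defaults made explicit (published pipelines delegate
this step to scripts without printing thresholds); both are arguments.
Component ids are renumbered 1..K in order of first appearance, making the
partition invariant to input order, rotation and strand — properties the
suite checks directly.

# Tandem confirmation

`self_kmer_matches()` records exact forward-strand k-mer self-matches
(default `k = 12`), excluding the main diagonal. A period is the smallest
offset `p ≥ k` such that offsets at multiples of `p` account for at least
half of all matches (`support_threshold = 0.5`). Two guards matter:

* **Evidence floor** (`min_matches = 10`): a random 5 kb sequence carries
  on average ~0.7 duplicated 12-mers by chance; a single chance duplicate
  would otherwise reach support 1.0 and produce spurious tandem calls in
  roughly half of random sequences. Requiring ten matches pushes the
  false-call probability to negligible levels while real tandems produce
  hundreds.
* Forward strand only: monomers within one array are co-oriented; inverted
  repeats are out of scope.

The qualitative dotplot inspection this replaces has no quantitative
criterion; the one defined here is explicit, configurable and labelled as
a package definition.

# Chromosome-level distribution

Chromosomes are tiled into segments (default 1000 bp) anchored at
position 0, overlapping by at least twice the longest monomer so that
every hit appears contiguously in at least one segment. Segments are
masked like reads, hits are mapped back to chromosome coordinates,
duplicates from overlaps removed, and overlapping hits resolved per base:
the hit set is disjoined into atoms and each atom assigned to the
highest-scoring covering hit. Satellite bp therefore count exactly once,
per-family bp partition the per-chromosome satellite bp, and — because the
tiling is anchored to chromosome coordinates — results are provably
independent of the processing window size (asserted by the
windowed-vs-unwindowed oracle test). A family with ≥ 90% of its
assembly-wide bp on one chromosome is flagged chromosome-specific ("solely
on one chromosome" needs an operational cutoff; 90% is it, configurable).
All coordinates are 0-based half-open, BED-compatible.

# Spearman correlation

Cross-species comparisons in this field involve 8–9 points, where
asymptotic p-values are unreliable and published p-values are only
meaningful under a stated null. `spearman_test()` therefore enumerates all
`n!` permutations exactly for `n ≤ 9` (also handling ties via mid-ranks,
which the standard exact algorithm in `cor.test` refuses), counting
permutations with `|rho|` at least the observed value; larger n uses the
usual t-approximation. The suite checks exact p-values against an
independent exhaustive oracle and, for tie-free inputs, against
`cor.test(..., exact = TRUE)`. Tests are two-sided throughout. A Pearson
wrapper is provided for parity because survey tables occasionally mix the
two labels; no multiple-testing correction is applied, matching practice
in the surveys this supports.

# The synthetic data generator

`build_genome()` emulates the data regime the pipeline targets:

* a random background (configurable GC) carrying per family 1–10
  head-to-tail arrays, placed disjointly by splicing into the background,
  with one orientation per array (drawn uniformly) — exercising strand
  handling the way tandem biology does;
* each monomer copy mutated *independently from the consensus* (star
  phylogeny): substitutions at the planted rate with a 2:1
  transition:transversion default, indel events at a per-site rate with
  lengths uniform on 1–5 bp (short, band-friendly, realistic for satellite
  monomers). Star phylogeny is a deliberate choice: landscapes measure
  divergence-from-consensus, so controlling that quantity directly makes
  the truth table exact. It is a stand-in, not an inference about how real
  arrays evolve;
* amplification bursts are emulated by planting low- and high-divergence
  arrays (or families sharing one consensus), not by forward-time
  homogenization dynamics;
* paired 150 bp reads from uniformly placed 350 bp fragments,
  `floor(coverage × bp / (2 × read_length))` pairs, uniform per-base
  substitution errors, constant quality strings (the pipeline never uses
  qualities).

The truth table records every array interval (0-based half-open), planted
bp, realized occupancy, and the realized substitution/transition/
transversion proportions — the exact quantities the estimators target.
Everything is reproducible from `(config, seed)`, including byte-identical
FASTQ output.

What the generator does *not* emulate — GC-biased or position-dependent
sequencing error, PCR duplicates, copy genealogies within arrays,
interspersed transposable elements, assembly gaps or N runs — bounds what
green tests demonstrate: parameter recovery on this generator shows the
estimators are calibrated for tandem arrays under uniform noise, not that
they are robust to every artifact of real libraries.

## Benchmark conditions

`benchmark_config()` fixes the recovery benchmark: 10 Mb genome, ten
families with occupancies 0.2–5% in two tiers (a rare tier near the
reporting filter and a dominant tier, mirroring the skewed abundance
structure of real satellitomes), divergences 2–20% interleaved across the
tiers, monomers 57–350 bp, 0.1× coverage. At these sizes a family at 1% of
the genome receives on the order of 60–70 read hits, so the rare tier is
intentionally in the high-noise regime while accuracy guarantees (15%
relative abundance error, ±2 pp divergence) are asserted for families
above 0.5% and 100 hits respectively. The benchmark and the full test
suite run in a few minutes on one CPU; these problem sizes were chosen so
that unit tests stay fast while the benchmark still probes the asymptotic
regime of the estimators.

# Degenerate inputs and numerical conventions

* Empty divsum → empty landscape (not an error); empty landscape →
  `peak_ages()` errors.
* Fewer than two families, or zero variance in either variable → z-score
  error naming the variable.
* Saturated K2P → hit discarded, warning counted in the pipeline manifest.
* `n < 3` or constant vectors → correlation error; exact permutation
  p-values use a `1e-12` slack when comparing `|rho|` values to avoid
  floating-point ties.
* Subsampling with `n_pairs ≥` available pairs is a pass-through; mates
  are always kept together and input order preserved.
* All interval outputs are 0-based half-open; FASTA/FASTQ I/O goes through
  Biostrings; gzip output is byte-deterministic.

# Known limitations

* Abundance from low-coverage reads is Poisson-limited: below ~0.5% of the
  genome at 0.1×, per-family estimates carry >15% sampling error by
  arithmetic, not by implementation.
* Divergence estimates inherit the local-alignment trimming bias described
  above; at planted divergences ≥ 25% the masker increasingly loses hits
  to `min_score`, shading abundance down.
* The masker assigns each query region to a single family; genuinely
  chimeric monomers are split by the greedy resolution rather than modeled.
* Superfamily grouping is transitive closure: two dissimilar families can
  share a superfamily through an intermediate — intended behavior, but
  worth remembering when interpreting large components.
* Interspersed-TE annotation, external homology databases and graph-based
  read clustering are out of scope; the package starts from a consensus
  library, it does not discover one.
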