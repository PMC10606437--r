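---
title: "Methods: circulome characterization and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circulome characterization and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circulome)
```

This vignette is the package's own account of the methods it implements:
the models and rules, the parameters that matter, the synthetic data the
tests validate against, and the design decisions taken where the design
was genuinely open.

## The analysis

Extrachromosomal circular DNAs (eccDNAs) are circular molecules excised
from the chromosomes. An eccDNA experiment of the kind this package
serves sequences circle-enriched DNA from several samples — here, plant
populations contrasting herbicide-resistant (HR) and herbicide-sensitive
(HS) phenotypes — and asks: how many distinct circles does each sample
carry, what do they encode, where in the genome do they arise, and do
the two phenotype groups differ in any of this?

All interval arithmetic is 0-based half-open (BED convention). GFF3 input
(1-based closed) is converted at the reader boundary; the readers are the
only place ±1 arithmetic occurs. Strand is recorded but ignored by all
counting operations, since none of the questions above are strand-aware.

### Redundancy collapse of circular sequences

Circle calling upstream produces redundant sequence sets; the first step
collapses them into non-redundant representatives, following the CD-hit
idiom: sequences are sorted by decreasing length (ties by id), and each
joins the *first* existing cluster whose representative it matches at
identity ≥ `threshold` (default 0.9), else founds a new cluster. A
best-hit assignment mode exists behind a flag, but first-hit is the
default because it reproduces the semantics of the tool this procedure
models.

Identity is computed from the best local alignment — match +1, mismatch
−1, a gap of length $L$ costs $2 + L$ — as identical aligned positions
divided by the length of the shorter sequence (the CD-hit denominator
convention). Only the threshold is fixed by the analysis definition; the
alignment scoring is exposed in `default_dna_scoring()`.

Because the molecules are circular, a rotated copy of a circle can share
as little as ~50% linear identity with its representative. The collapse
is therefore rotation-aware: the shorter sequence is additionally aligned
against the representative concatenated to itself (the doubling trick),
and the better identity is used. A pure rotation scores identity 1.

A shared-k-mer prefilter (k = 11, at least one shared k-mer with the —
doubled, when circular — representative) skips hopeless alignments.
Pairs whose shorter sequence cannot carry a k-mer are always aligned. The
prefilter is an optimization that must never change the result; the test
suite asserts equality with the prefilter disabled on fixtures that
include rotated, mutated near-duplicates. Clustering is per-sample by
default (per-sample non-redundant counts are the quantity of interest),
with a pooled mode available.

### Per-sample summaries

`summarize_circulome()` reports, per sample: the number of non-redundant
eccDNAs, mean/min/max length, counts with predicted genes and tRNAs, the
percentage with coding sequence, and the per-eccDNA gene-count range and
mean. Percentages are rounded half-up at two decimals, and cohort
aggregates half-up to integers — the conventions that reproduce published
summary tables of this kind exactly from their count columns. The cohort
aggregate returns the *computed* mean of the per-sample counts (the
shipped published table's counts average to 4885.3, i.e. 4885; a printed
cohort value that disagrees with its own count column is not reproduced).
Length histograms use half-open bins $[kw, (k+1)w)$, so counts always sum
to the number of records.

### Genome-window density and hotspots

Mapped circles are counted in non-overlapping windows (default
$W = 500$ kb; a short terminal window is kept so the grid tiles each
chromosome exactly). An interval increments *every* window it overlaps by
at least 1 bp — BEDtools-intersect semantics, matching how such counts
are produced in practice; midpoint assignment is available behind a flag.
Consequently the window-count sum can exceed the number of intervals
(equality holds exactly when no interval spans a window edge, a property
the tests exercise).

"Hotspot" is formalized as a z-score rule: with window counts $x$,
$z = (x - \bar x)/s$ over all windows genome-wide, and a window passes at
$z \ge k$ (default $k = 3$; a top-quantile mode exists). One consequence
worth knowing: with $n$ windows, a single extreme window can reach at
most $z = (n-1)/\sqrt n$, so the rule is uninformative on very coarse
grids (fewer than ~11 windows). Validation of hotspot recovery therefore
runs on a grid of 20+ windows.

Mapping-rate statistics (fraction of circles mapped, and anchored versus
unanchored placements) are reported separately, since unanchored
scaffolds are excluded from the window grid.

### Flanking density and the permutation test

To ask whether eccDNA-associated regions sit in gene-denser (or
TE-denser) neighbourhoods, each *unit* — an annotated gene by default, or
a window — gets a profile: the number of genes and TEs overlapping its
±200 kb flanks (the flank is $[start - f, end + f)$ minus the unit
itself, clipped to the chromosome; a gene never counts in its own flank),
and a presence label: does the unit's own interval overlap at least one
mapped eccDNA? Both unit modes are provided because "regions" can
reasonably mean either; genes are the default.

The test statistic is the difference of group means (present − absent).
The null is built by permuting the presence labels with group sizes held
fixed. When $\binom{n}{n_{present}} \le 20000$ the null is enumerated
exhaustively and the p-value is the exact fraction of labelings at least
as extreme (the observed labeling is itself one of them, so $p > 0$);
otherwise `n_perm` (default 10000) random shuffles are drawn and the
add-one estimate $(1 + \#extreme)/(1 + n_{perm})$ is reported. Two-sided
(by absolute value) is the default sidedness; a seed is mandatory
whenever sampling is used. Per phenotype group, the test is run over the
pooled mapped intervals of that group's samples.

The test's validity rests on unit exchangeability under the null. That
is also why the synthetic generator places gene models disjointly: if
gene annotations stack on top of each other, a single circle marks
several units that also share flank counts, the units become dependent,
and the permutation null underestimates the statistic's variance (we
observed type-I inflation to ~0.10 with overlapping gene models, versus
0.03–0.07, consistent with the nominal 0.05, once gene models are
disjoint). Real spatial data can violate exchangeability in similar ways
— strong spatial autocorrelation at the flank scale should make a reader
cautious about borderline p-values from this test; a covariate-matched
null is out of scope here.

### Domain set algebra

Per-sample catalogs map PFAM accessions to the number of distinct
eccDNAs annotated with them (an eccDNA counts once per accession even if
several of its genes carry the domain). The partition computes: the HR
core (intersection over HR samples), HS core, all-sample core (their
intersection), group-specific cores (HR core minus HS core, and
symmetrically), per-sample unique accessions, and pairwise shared sets
within groups. The identities
$|HR\,core| = |core| + |HR\text{-}specific|$ (and the HS analogue) hold
by construction and are asserted property-style on random catalogs.

Two interpretation choices were open and are exposed as flags:
"unique to a sample" means absent from *all* other samples (both groups)
by default, with an in-group-only mode; pairwise shared sets include the
group core by default, with an exclusive mode that subtracts accessions
present in any other sample of the group.

`term_enrichment()` is deliberately plain: upper-tail hypergeometric
p-values with Benjamini–Hochberg adjustment at FDR 0.05. It makes no
attempt at length-bias correction (the established bias-aware GO methods
are external tools); it exists so the pipeline is self-contained.

### QTL overlap and candidate homology

QTL classification uses the any-overlap rule throughout ("matched a QTL"
= ≥ 1 bp overlap, not containment — again the intersect default).
Per QTL, distinct HR and HS eccDNA ids are counted and the QTL is
classified by its coding-sequence content as HR-only / HS-only / both /
none — exactly one class per QTL. Cohort totals count each eccDNA id
once by default even when it overlaps several (possibly overlapping)
QTLs; a per-QTL-sum mode exists. `hr_exclusive_windows()` reports
windows inside QTLs carried by at least `min_samples` HR samples with
zero HS circles; relaxing `min_samples` can only grow the set.

The homology screen aligns predicted eccDNA proteins against candidate
resistance genes: best local alignment under BLOSUM62 with affine gaps
(open 11, extend 1; a gap of length $L$ costs $11 + L$), identity on the
BLAST convention (identical columns / alignment columns), `X` allowed
and scored 0. Raw scores convert to bit scores and E-values via the
Karlin–Altschul relations $bit = (\lambda S - \ln K)/\ln 2$ and
$E = mn\,2^{-bit}$ with the published gapped-BLOSUM62 constants
$\lambda = 0.267$, $K = 0.041$ (the originating tool and its parameters
are not recoverable, so the constants are declared rather than guessed
silently, and are exposed as arguments). The database length $n$ is the
total residue count of the candidate set. The default reporting cutoff
is $E \le 10^{-10}$ and is configurable. The alignment engine is
validated against an independent dynamic-programming implementation in
the test suite.

## The synthetic generator

`simulate_eccdna()` exists so that every stage above can be tested
against known truth without any external data. It emulates the study
conditions the package targets:

* 4 HR + 3 HS samples; 500 circles per sample by default.
* A 5 Mb two-chromosome genome plus a 400 kb unanchored scaffold;
  8.5% of circles excise from the scaffold (so mapping-rate statistics
  have something to measure).
* Circle lengths from a log-normal truncated to [31, 29081] bp whose
  location parameter is solved numerically (by `uniroot` on the
  closed-form truncated mean) for a target mean of 6900 bp — matching
  the scale reported for plant circulomes of this kind. The log-scale SD
  (default 1.1) is a free choice: it puts the bulk of circles below
  10 kb with a long right tail, the shape such experiments report.
  Bounds that exclude the target mean are a hard error.
* Excision origins drawn on a 10 kb sub-bin grid with weight
  (hotspot multiplier of the containing window) ×
  exp(β · genes within ±200 kb of the bin midpoint). Hotspots and
  gene-density coupling therefore act *at origin sampling*, not post
  hoc, so one knob (β) controls the effect size the enrichment test
  must detect. Defaults plant two modest hotspots (multipliers 5 and 4)
  and a weak coupling (β = 0.05).
* Gene annotations are spatially clustered (half the genes around
  Gaussian "islands", SD 100 kb) but mutually disjoint — clustering
  gives the flank-density signal spatial structure to couple to;
  disjointness keeps the enrichment test's units exchangeable under the
  null (see above). TEs are uniform.
* A fraction (default 10%) of circles is re-emitted as a mutated
  (3% substitutions), randomly rotated copy, to exercise rotation-aware
  collapse.
* Domain catalogs are built from disjoint accession blocks: 69 core
  accessions present in every sample, 11 in all HR samples only, 22 in
  all HS samples only, and 20 private accessions per sample — so set
  algebra on the emitted catalogs must recover 69/11/22 exactly, with
  80 = 69 + 11 and 91 = 69 + 22. One core accession is planted as the
  dominant domain (the "gypsy-like" rank-1 analogue).
* Determinism: one global seed; per-sample substreams are keyed by
  sample *name*, so adding a sample to a config never perturbs the
  circles of existing samples. The same seed yields byte-identical
  files.

What the generator does **not** emulate: concatemeric reads or
sequencing error (circles are exact genome substrings apart from planted
duplicates), tRNA genes (the tRNA flag exists but is never set), GC or
repeat structure (the genome is i.i.d. uniform), and realistic PAF
alignment noise (each circle maps exactly to its origin, primary only).
Passing tests therefore demonstrate that the *analysis logic* is correct
on data with planted structure — not that the pipeline is robust to
alignment artifacts or repeat-driven multi-mapping in real data.

## Numerical choices and degenerate inputs

* Half-up rounding (`floor(x·10^d + 0.5)`, with an epsilon guard against
  float representation at the .5 boundary) wherever printed tables are
  reproduced; base R's half-to-even would disagree with several printed
  values.
* Permutation p-values are never 0 (exact: the observed labeling is
  enumerated; sampled: add-one).
* Zero variance across windows → no hotspots, with a warning, rather
  than dividing by zero.
* Duplicate FASTA ids, empty sequences, empty samples, empty unit
  lists, one-sided group emptiness, malformed PFAM accessions and
  infeasible length laws are hard errors naming the offender; invalid
  alignment/feature lines (start ≥ end) are skipped with a counted
  warning, since a single bad line should not kill a long run.
* Alignment identity ties: greedy assignment is to the *first*
  qualifying representative in cluster-creation order, which together
  with the internal length-then-id sort makes clustering invariant to
  input order.

## Problem sizes used in validation

Module-level tests run at the scale each property needs (e.g. the length
law at n = 3500, window oracles at 500 intervals, clustering oracles at
50 sequences with rotated variants). The end-to-end pipeline tests and
the acceptance script run the full stage chain on a reduced generator
config (2 Mb genome, 40 circles/sample, 400 bp mean length): greedy
collapse is quadratic in both the number of sequences and their lengths,
and the reduced config exercises every code path — including planted
hotspot, duplicate, unanchored and vocabulary structure — while keeping
the suite fast. Calibration and power of the permutation test use 500
and 100 replicate simulations respectively, with 199 permutations per
replicate (the add-one p-value's resolution, 0.005, is ample at
α = 0.05).

## Known limitations

* The greedy collapse recomputes full local alignments; at study scale
  (thousands of multi-kb circles) a word-indexed implementation would be
  needed for speed. The semantics, not the speed, are the contract here.
* The permutation test assumes unit exchangeability; strongly
  autocorrelated annotation can inflate its size (discussed above).
* Term enrichment ignores length bias.
* The homology E-values depend on declared Karlin–Altschul constants
  and the candidate-set database length; they are comparable within a
  run, not across tools.
* Multi-mapping circles contribute to every window they overlap; no
  uniqueness filtering is attempted beyond the PAF primary-alignment
  flag.
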