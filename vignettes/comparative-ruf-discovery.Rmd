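---
title: "Methods: comparative RUF discovery, F84 distances and the Goldilocks Zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative RUF discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rufscan)
```

## The analysis in one paragraph

Given per-base, strand-resolved RNA-seq depth tracks and genome
annotations for a set of bacterial or archaeal strains, `rufscan`
(i) calls expressed, unannotated regions of bounded length — RNAs of
Unknown Function, RUFs; (ii) ranks every feature within each strain by
the median read depth of its annotated region and aggregates expression
across strains by minimum rank; (iii) estimates pairwise strain
distances from an SSU rRNA alignment under the F84 model and scores
each gene family's conservation as the maximum pairwise distance among
its carriers; (iv) summarises how conservation decays with distance,
classifies strain pairs against a "Goldilocks Zone" of informative
distances, and integrates three lines of evidence per RUF group; and
(v) computes dataset-level quality-control metrics. A synthetic-data
generator reproduces the statistical structure this analysis assumes,
with full ground truth, and is the basis of the test suite.

## Coordinates and containers

All intervals are 0-based half-open internally; conversion to GFF3's
1-based closed convention happens only in the readers and writers. This
makes interval lengths `end - start` and removes off-by-one cases from
masking, median and footprint arithmetic. Depth tracks are dense
per-base integer vectors, one per strand; unstranded data keep combined
depth in the forward array and are treated as strand `"both"`
everywhere, so there is a single code path for both protocols.

## RUF calling

The original surveys picked RUFs by eye from coverage plots. Manual
picking is not reproducible, so `call_rufs()` defines a deterministic
surrogate with the same intent:

1. mask positions under annotated protein or RNA genes (strand-aware
   for stranded data; RUF-kind features never mask, so previous calls
   can be re-found);
2. take maximal runs of unannotated positions with depth ≥ `min_depth`
   (default 10 reads), merging runs separated by at most `max_gap`
   (default 10 nt) below-threshold but unannotated positions —
   annotated positions always break a run;
3. keep regions with `min_len` ≤ length ≤ `max_len` (defaults 50 and
   400 nt) whose median depth over the whole region, gap positions
   included, is ≥ `min_depth`.

Two choices deserve emphasis. Overlong regions are rejected whole
rather than trimmed: trimming would invent boundaries the data do not
support, and the length filter is a selection criterion, not a
segmentation rule. And the median is taken over the full merged region
so that the retention rule is the same statistic used later for
ranking. Whether calling runs per dataset or on pooled (summed) tracks
is configurable (`pool`); per-dataset is the default because pooling
can dilute a condition-specific transcript below threshold.

## Ranking and cross-strain aggregation

Read depths are not comparable across libraries (depth, rRNA depletion
and protocol all differ), so within each strain features are ranked by
a statistic — by default the maximum over datasets of the per-dataset
median depth, so a transcript abundant in any one condition counts as
abundant. Rank 1 is the most expressed; ties break lexicographically by
feature id, making ranks a permutation of `1..n` independent of row
order. Annotated genes and RUF calls are ranked jointly, since the
question is where RUFs sit relative to everything else transcribed.

Across strains, a family or RUF homology group keeps the *minimum* of
its members' ranks. This deliberately asymmetric summary keeps
always-low-abundance transcripts low while letting a single strong
observation certify high expression. Classes use rank quartiles:
High ≤ 204 < Medium ≤ 1660 < Low. The printed defaults are quartiles of
the original 37-strain survey and are dataset-specific;
`thresholds_from_data()` recomputes them (type-1 quantiles, so the
25/50/25 partition is exact up to ties) for any other input.

## F84 distances and conservation scores

Distances are computed per pair from transition and transversion
difference proportions under pairwise deletion (sites with a gap or
ambiguity code in either row are dropped; ambiguity codes are treated
like gaps — the simplest defensible convention). Base frequencies are
pooled over the whole alignment, matching the behaviour of the classic
distance programs; a per-pair mode exists for heterogeneous alignments.
The closed form needs no transition/transversion ratio parameter: the
ratio information is absorbed through the observed *P* and *Q*.

When a log argument is non-positive the pair is saturated; the distance
is `+Inf` with a warning rather than an error, so downstream maxima
stay total (`Inf` maps to High conservation, which is the right reading
of "saturated"). A family seen in fewer than two strains scores 0 and
classifies Low.

Conserved-fraction curves report, for each grid distance `d`, the share
of families whose score is ≥ `d`. Singletons stay in the denominator by
default — "fraction of conserved families" reads most naturally over
all families — with `min_strains = 2` as the alternative; note that on
simulated data, families extinct in every strain are excluded by the
default (`min_strains = 1`), and closed-form comparisons against the
loss process must pass `min_strains = 0` to keep the root-family
denominator. `distance_at_fraction()` uses the step-function
convention (largest grid point still at or above the target) and
returns `NA` for unreachable targets instead of erroring, so callers
can flag them.

## The Goldilocks Zone

Pairs of strains closer than `d_min` share essentially everything —
conservation carries no signal ("too hot"); pairs beyond `d_max` have
diverged past the point where RNA homology is detectable ("too cold").
The default closed interval [0.0118, 0.0542] substitutions/site is
taken verbatim from the original survey, whose derivation is not
specified; a documented surrogate (`derived_zone()`) instead sets
`d_max` at the distance where 80% of RNA families are still conserved
and `d_min` at 99%. The interval is closed on both ends, matching the
inclusive reading of "between". Cross-domain (Bacteria–Archaea) pairs
are excluded from enumeration because SSU distances between domains are
saturated.

## Evidence integration

Each RUF homology group is scored on three booleans: conserved (in ≥ 2
strains), structured (an externally supplied flag — structure
prediction itself is out of scope), and expressed in ≥ 2 strains.
Expression elsewhere requires a homolog there, so
`expressed_elsewhere & !conserved` is rejected as an invariant
violation rather than silently corrected. High confidence means ≥ 2
criteria; the seven non-empty intersections plus a none-category are
reported and must sum to the group count.

## Quality control

Five metrics per (strain, dataset): strand correlation (product-moment
by default, rank-based selectable; near 1 flags an unstranded library
mislabelled as stranded), expressed fraction of 40 core protein and 16
core RNA genes, genome fraction covered at ≥ 10 reads, fraction of
mapped reads (metadata from upstream mapping), and concordance. Note
the deliberate asymmetry, kept exactly as the definitions state it:
core-gene expression requires median depth strictly > 10, while general
expression and coverage use ≥ 10. Both thresholds are configurable.

Concordance treats each position as a binary classification —
expressed (combined depth ≥ 10) versus annotated (under any protein or
RNA gene on either strand; positions, not stranded positions, define
the metric, with a strand-aware mode available). PPV = TP/(TP+FP) is
normalized by the annotated fraction ANN, giving ≈ 1 when expression is
independent of annotation; the permutation-null test verifies this.
Degenerate cases (nothing expressed, nothing annotated) yield `NA`
rather than errors.

## The synthetic-data generator

The generator is the analysis's generative twin, not a caricature of
real data. It emulates: a strain phylogeny (balanced with uniform edge
lengths, or coalescent-shaped with scaled edges); SSU sequences evolved
by drawing the root from the stationary frequencies and applying, per
branch, the exact F84 transition-probability matrix (via the
symmetrized eigendecomposition that reversibility guarantees) — not
discretized steps, so estimator-recovery tests are exact in
expectation; irreversible family loss at exponential branch rates, RNA
families (default λ = 5 per unit branch length) an order of magnitude
faster than protein families (λ = 0.5); and coverage tracks where
annotated genes follow a rank-abundance law (mean depth
`peak_depth · k^-α`, defaults 500 and α = 0.7, leaving the least
expressed genes near the 10-read threshold), planted RUF groups share a
length (uniform 50–400 nt) and expression level (uniform 30–120×)
across carrying strains, and background is negative-binomial with mean
1 and size 10 — overdispersed count noise being the realistic default
for sequencing depth; `nb_size = Inf` switches to noiseless tracks for
exact arithmetic checks.

It deliberately does **not** emulate: indels in the SSU alignment (gap
handling is tested with masked columns instead, isolating the distance
formula from alignment artifacts), read-level effects (FASTQ,
sequencing error, rRNA-depletion artifacts), operonic structure or
overlapping genes (features are placed uniformly with a 25 nt margin),
or expression correlation between neighbouring loci. Passing tests
therefore demonstrate correctness of the statistical machinery under
the stated model, not robustness to mapping artifacts or annotation
errors in real data.

Every generator stage seeds the RNG from `seed` plus a fixed stage
offset, so outputs are reproducible bit-for-bit from the configuration
and each stage can be regenerated independently.

## Numerical and testing choices

Simulation sizes in the test suite were chosen so each check has clear
statistical resolution at small cost: F84 recovery uses 50 two-strain
alignments of 5 000 sites across true distances 0.01–0.3 (mean relative
error is ~4%, against a 10% bound); the loss-model closed form uses
5 000 families per class on a two-leaf tree with 3-Monte-Carlo-SE
bounds; the RNA-vs-protein decay comparison uses 20 coalescent
replicates of 8 strains × 2 000 families with edge scale 0.15, placing
pair distances on the RNA loss scale (1/λ = 0.2) so the two curves
actually separate — on shallower trees both classes can remain fully
conserved and the comparison ties; caller recovery uses 20 strains of
40 kb with planted levels ≥ 30× over background mean 2. The concordance
implementation is checked against brute-force positional enumeration on
100 random 1 kb genomes and a 1 000-replicate permutation null.
Curve grids for zone work are anchored at 0, where the conserved
fraction is 1 by construction, making `distance_at_fraction()` total.

## Known limitations

* RUF boundaries are threshold artifacts: calls at level ≈ 10 fray at
  their edges, and two genuinely distinct adjacent transcripts closer
  than `max_gap` merge. TSS/terminator refinement is out of scope.
* The F84 estimator inherits the usual distance caveats: variance grows
  quickly beyond ~1 substitution/site and saturation collapses to
  `Inf`; no rate heterogeneity across sites is modelled.
* Homology of RUFs is taken from an input map (or, in simulation, from
  planted intervals); the package performs no sequence search.
* The default zone bounds are survey-specific constants; for any other
  strain set the derived mode should be preferred and its targets
  (99%/80% RNA-family conservation) treated as tunables.
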