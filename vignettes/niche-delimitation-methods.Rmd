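---
title: "Methods: niche comparison, Mk ancestral states, and haplotype networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: niche comparison, Mk ancestral states, and haplotype networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichedelim)
```

`nichedelim` supports integrative species delimitation: deciding whether
molecularly recognised lineages warrant species rank by combining climatic
niche comparisons, ancestral state reconstruction of diagnostic
morphological characters, and haplotype network structure. This vignette
is the package's account of the statistical machinery, the tunable
parameters, the design decisions taken where the methods literature leaves
choices open, and the limits of what the test suite demonstrates.

## Occurrence data and environmental background

Occurrence records (`lineage, lon, lat[, year]`) are filtered in three
documented steps:

* **Collection-year cutoff** (`filter_by_year()`, default 1990): records
  older than the cutoff are dropped because identifications of older
  databased collections are less reliable for taxonomically difficult
  groups. Records with *missing* year are retained — the cutoff targets
  identification reliability, not metadata completeness, and undated
  herbarium specimens are often the best-curated material. The number of
  year-less records kept is reported.
* **Environmental extraction** (`extract_env()`): the raster cell
  containing each coordinate supplies the environmental vector. Cell
  membership uses half-open intervals [west, east) × [south, north);
  points exactly on the east/north boundary of the full extent belong to
  the last cell, so no valid coordinate is orphaned. Records on nodata
  cells (sea, unmapped areas) are dropped and counted; coordinates outside
  the extent are an error rather than a silent drop.
* **Per-cell thinning** (`thin_per_cell()`, on by default in the
  pipeline): one record per lineage per raster cell. Kernel density
  estimation over-weights localities reported many times (herbarium
  duplicates, popular collecting sites); one-per-cell is the standard
  guard. It is toggleable because genuinely independent records can share
  a cell at coarse resolutions.

Collinear environmental variables are screened (`screen_collinearity()`)
until all pairwise Pearson |r| ≤ 0.70, the conventional threshold below
which collinearity does not destabilise downstream ordination. The
elimination is greedy — repeatedly drop the variable with the largest mean
|r| over the currently offending pairs — with ties broken by input column
order (the earlier variable is kept). Greedy elimination is deterministic
and auditable; it is not guaranteed to find the single largest admissible
subset in adversarial cases, but the test suite verifies it does on the
engineered cases we care about.

Rasters are read as ESRI ASCII grids, a plain-text format with a six-line
header; all layers must share extent and (square) cell size, and a cell
that is nodata in any layer is masked in all layers so the background is
defined consistently. GeoTIFF input is not supported — convert with
`gdal_translate -of AAIGrid` upstream. This keeps the package free of
heavyweight geospatial dependencies; reprojection and coordinate cleaning
beyond range checks are likewise out of scope.

## The environment-space model

All niche quantities live in the plane of the first two axes of a PCA
fitted to the environmental values of **every** background cell of the
study area ("PCA-env"), with variables centred and scaled internally. The
ordination is calibrated once, on the background alone — never on the
occurrences — so all lineages and all randomisation replicates share one
fixed coordinate system. `fit_pca_env()` returns all axes with explained
variance fractions (they sum to 1; the first two are used downstream), and
errors on constant variables rather than silently dropping them.

`build_grid()` discretises this plane into an `R × R` grid (default
`R = 100`, the conventional resolution for this family of analyses) whose
bounds are the background score range per axis expanded by a 5% margin;
the margin prevents kernels centred near the data edge from being
truncated. Two Gaussian product-kernel densities are evaluated at cell
centres:

* `o` — density of the lineage's occurrence scores,
* `e` — density of the background scores,

both using per-axis normal-reference (Silverman) bandwidths computed **on
the background** and reused for `o`. Reusing one bandwidth is deliberate:
`o` and `e` are compared cell-by-cell, and letting each cloud pick its own
bandwidth would confound niche differences with sample-size differences.
Occupancy is `z = o / max(o)` by default ("uncorrected"); a "corrected"
mode `z = (o/e)/max(o/e)` over cells with `e > 0` is available for
backgrounds with strongly uneven availability, and the two agree exactly
when `e` is uniform. The normalised occupancy `p = z / Σz` is what enters
every statistic. Occurrence scores falling outside the background bounds
are clipped to the boundary cell and counted — they represent environments
at the edge of the analysed space, not data to discard.

Numerical properties verified by the tests: the kernel mixture integrates
to 1 over the grid within 2% at `R = 100`; doubling `R` moves Schoener's D
between two smooth niches by less than 0.02; a single occurrence puts the
density mode in its own cell.

## Niche statistics and randomisation tests

**Overlap.** Schoener's `D = 1 − ½ Σ |p₁ − p₂|` is symmetric, equals 1
iff the normalised occupancies coincide and 0 iff their supports are
disjoint. **Breadth.** Levins' `B = 1/Σ p²` is the effective number of
occupied cells; `B_norm = (B − 1)/(ncells − 1)` rescales to [0, 1].

**Equivalency** asks whether two occurrence sets are interchangeable: the
pooled scores are randomly repartitioned into pseudo-groups of the
original sizes, occupancies rebuilt (same bounds, same bandwidths — only
labels change), and D recomputed, `reps` times (default 100). The test is
**one-tailed**: equivalency is rejected when observed D is significantly
*lower* than the null, `p = (1 + #{D_null ≤ D_obs})/(reps + 1)`. The +1
convention means p is never 0 and the smallest attainable p with 100
replicates is ≈ 0.0099 — matching the granularity at which such tests are
conventionally reported.

**Similarity** asks the directional question: is lineage b's niche more
similar to a's than expected, *given the environments available to b*? The
null preserves the shape of b's occurrence density: b's scores are rigidly
shifted so their centroid lands on a point drawn uniformly from the
bounding box of b's background scores (clipped to the analysis bounds),
and D against a's observed grid is recomputed. Shape-preserving relocation
is the design choice here — the alternative of resampling points uniformly
is available behind `resample_points = TRUE` — because the hypothesis
concerns *where* the niche sits, not how concentrated it is. Both
one-sided p-values are reported ("Similar" when D_obs is in the upper
tail, "Different" in the lower, "ns" otherwise, at α = 0.05). No
multiple-testing correction is applied by default (a Bonferroni flag
exists); with three pairwise comparisons the issue is minor and verdicts
stay comparable with how such tables are conventionally printed.

`compare_all()` orchestrates everything from one ordination, sorts each
lineage's scores deterministically so results do not depend on input row
order, and derives per-pair seeds from one master seed: reruns are
bit-identical, and all null distributions are retained for audit.

## The Mk1 model and ancestral states

Both diagnostic characters are modelled with the one-parameter Markov
k-state (Mk) model: all transitions share one rate α, giving the closed
form `P_ii = 1/k + (k−1)/k·e^{−kαt}`, `P_ij = (1 − e^{−kαt})/k`. The
likelihood on a fixed rooted tree is computed by Felsenstein pruning with
a uniform 1/k root prior (the Mk convention); missing tips contribute a
vector of ones; polytomies are hard multifurcations. α is maximised over
[1e-8, 1e3] on the log scale (tolerance 1e-8); an invariant character
drives α̂ to the lower bound, which is flagged rather than hidden.
Marginal per-node probabilities use the rerooting formulation — downward
partials combined with complementary rest-of-tree partials — which the
test suite proves equal to brute-force enumeration over all internal
assignments on every tree up to 6 tips and k ≤ 4 (tolerance 1e-9), with
likelihood invariant under rerooting (the model is time-reversible) to
1e-10.

Design choices: lamella height (observed states 1–7) is treated as an
**unordered** Mk character over its observed states — the default of
standard ASR software for meristic data; an ordered variant is out of
scope, but a `state_map` can bin states (e.g. ≤2 vs >2) before
reconstruction. Trees lacking branch lengths get unit lengths with a
warning. Marginal (not joint) reconstructions are reported, matching the
per-node pie-chart style in which such results are read.

## Indel coding and haplotype networks

**Simple indel coding** turns each distinct *internal* gap span (identical
start and end, 1-based inclusive) into one binary character: `1` for
sequences with exactly that gap, `0` for sequences with residues across
the span, missing when a strictly longer gap contains the span (the
subsumption rule — such sequences carry no evidence about the shorter
event), and missing wherever a terminal gap spans the character (leading
and trailing gaps are usually missing data, not deletions).

**Haplotype collapsing** treats gaps, `N` and `?` as missing: sequences
identical at every mutually observed position merge. Merging is iterative
with a deterministic order; when a sequence is compatible with two
mutually incompatible haplotypes (possible with heavy missingness) it
joins the more frequent one, and the conflict is reported. The
representative id is the lexicographically first member.

**Network construction** joins all haplotype pairs at distance 1 (missing
positions excluded), then bridges pairs at distance d = 2..limit — only
when still in separate components — through d−1 hypothetical haplotypes,
mutating differing positions in left-to-right alignment order and reusing
any existing node with a matching sequence. Within a distance, pairs with
higher total multiplicity connect first, then lexicographic ids; the edge
set is provably independent of input order. The connection limit is a
plain integer (default 10) rather than a re-derivation of the classic 95%
parsimony probability estimator: observed networks in this setting involve
a handful of steps, and a fixed limit keeps behaviour auditable. Loop
(ambiguity) resolution and median-joining networks are out of scope.

## The synthetic-data generator

Every stage is testable against ground truth without external downloads:

* `make_env_rasters()` — standardized, spatially autocorrelated layers
  (twice box-blurred white noise; radius = `smoothness` cells), with
  optional injected between-layer correlation.
* `lineage_spec()` / `sample_occurrences()` — suitability is Gaussian in
  **environment** space (the niche concept the analysis assumes), cells
  sampled proportional to suitability, coordinates jittered within cells;
  sampling works on shifted log-suitability so arbitrarily narrow niches
  do not underflow.
* `simulate_mk_characters()` — root state uniform, evolution by the Mk1
  transition matrix; all node states are attached for recovery tests.
* `make_toy_alignment()` — haplotype backbones by sequential point
  mutations at previously untouched positions (pairwise distances are
  additive), copies per multiplicity, indel spans with a known coding
  answer; mutations never fall inside indel spans so gaps cannot obscure
  the substitutions that separate haplotypes.

The default study (`simulate_study()`) has three lineages on a shared
100 × 100 background of six layers: two with strongly overlapping but
offset niches — centroids (1.0, 0.3) and (0.3, 1.0) in standardized
environmental units, variance 0.10, sample sizes 100 and 300 (the larger
sample playing the widespread invader) — and one distinct lineage at
(−1, −1) with n = 100. The offset/width combination was chosen so that
the pair is simultaneously "Similar" (directional test) and "not
equivalent" (equivalency rejected) across seeds — the pattern that makes
the integrative argument interesting; with niches much closer, no test at
these sample sizes could tell them apart, and with niches further apart
the pair would no longer be ecologically similar.

What the generator does **not** emulate: spatial sampling bias,
positional error, non-Gaussian (e.g. bimodal or truncated) niches,
niche-environment feedbacks, and realistic climate-layer covariance
structure. Passing tests therefore demonstrate correctness of the
machinery and calibration under clean conditions, not robustness to the
messiness of real occurrence data.

## Problem sizes and numerical choices

The test suite runs the randomisation machinery at `R` = 50–100 with
100 replicates per test, 200 simulation replicates for the type-I error
check of the equivalency test, and 100 scenario replicates per arm for
the directionality check of the similarity test; Mk oracles enumerate all
trees up to 6 tips × 4 states, and rate recovery uses 500 binary
characters on a fixed balanced 8-tip tree (estimates aggregated as the
median of 10 block ML fits of 50 characters each, a stable summary of a
well-behaved estimator). These sizes make the full suite complete in
about a minute on one core while keeping Monte-Carlo error well inside
the asserted bounds. Randomisation p-value comparisons against exhaustive
enumeration use a pre-chosen tolerance of one resolution step plus four
binomial standard errors.

Degenerate inputs are handled explicitly rather than defensively:
zero-length branches give exact indicator marginals at tips; impossible
data give `-Inf` log-likelihood; all-missing characters give likelihood 1;
an all-zero occupancy grid, a constant environmental variable, and a
sub-minimal background are errors that name the offender.

## Known limitations

* GeoTIFF rasters are not read; only ESRI ASCII grids.
* The similarity null relocates the whole density rigidly; nulls that
  deform the niche shape, and geographically constrained (dispersal-aware)
  backgrounds, are not implemented.
* The collinearity screen is greedy, not exhaustive.
* The parsimony connection limit is a fixed step count, not a
  probability-based limit.
* Mk reconstruction offers no ordered-state or rate-heterogeneous
  variants, no model comparison, and no stochastic mapping.
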