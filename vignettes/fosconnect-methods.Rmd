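---
title: "Mapping brain activation and functional connectivity from regional cFos densities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping brain activation and functional connectivity from regional cFos densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fosconnect)
```

## The analysis in one paragraph

Expression of the immediate-early gene cFos peaks roughly 90 minutes after
neuronal activation and is a standard proxy for recent neuronal activity.
In a four-group contextual fear design (home cage, context only, recall,
extinction), each animal contributes cFos-positive cell counts from several
histological sections in each of 16 forebrain regions spanning medial
prefrontal/retrosplenial cortex, midline thalamus, amygdala and
dorsal/ventral hippocampus. `fosconnect` turns those per-section counts
into per-animal regional densities (cells/mm²), compares groups per region
by one-way ANOVA with Sidak-family post-hoc corrections, estimates
"functional connectivity" as the across-animal Pearson correlation of
densities for every region pair within each group, and condenses each
group's correlation matrix into a thresholded network in which node size is
the fold-change of density over the home-cage baseline and an edge is a
strong, nominally significant positive correlation. Hubs are read off the
network as the highest-degree nodes.

## From sections to densities

Each section record is `(animal, group, region, section, count, area)`.
The per-animal density of a region is the **mean of per-section densities**

$$ d_{ar} = \frac{1}{S_{ar}} \sum_{s=1}^{S_{ar}} \frac{c_{ars}}{A_{ars}}, $$

not the pooled ratio $\sum c / \sum A$. With equal section areas the two
coincide; with unequal areas the mean-of-densities weights every section
equally, which matches the convention of averaging a density over sections.
The pooled alternative is available (`aggregate_densities(pooled = TRUE)`)
but off by default. Entries observed through fewer than 2 or more than 6
sections are reported and kept by default (`section_policy = "warn"`);
`"strict"` drops them instead. Sampling depth of 2–6 sections per region is
the norm for this kind of histology, but no exclusions are applied silently.
Missing animal × region entries stay missing — nothing is imputed — and
every downstream stage tolerates them.

## Activation statistics

Per region, non-missing densities enter a classical fixed-effects one-way
ANOVA, $F = \mathrm{MS}_{\text{between}} / \mathrm{MS}_{\text{within}}$ on
$(k-1,\; N-k)$ degrees of freedom, computed on whatever groups have data
(complete-case within region; no across-region correction, since each
region is reported separately). A zero-total-variance table is flagged
degenerate and reported with $p = 1$ rather than `NaN`.

Post-hoc pairwise contrasts use two-sample Welch t-tests over all
$\binom{k}{2}$ group pairs of the region — the conservative default when
the underlying pairwise estimator is not dictated by the design — followed
by either the single-step Sidak correction

$$ p' = 1 - (1 - p)^m $$

or its step-down Holm-Sidak variant, in which the $i$-th smallest p-value
is adjusted with the shrinking family size $m - i + 1$ and monotonicity is
enforced by a running maximum. Sidak is the default for the cFos
comparisons. Both are implemented in closed form in this package (the
standard `p.adjust` family offers Holm on the Bonferroni scale, not the
Sidak-scale variants) and are validated against independent brute-force
enumerations in the test suite.

Fold-changes $\bar d_{gr} / \bar d_{\text{home cage},r}$ summarise
activation per region and group; a zero or absent baseline makes the value
flagged-undefined rather than infinite, and such nodes fall back to unit
size in network displays.

## Inter-regional correlation

Within each group, every one of the $\binom{16}{2} = 120$ region pairs gets
a Pearson correlation across animals, using **pairwise-complete**
observations: each pair uses exactly the animals with both regions
measured, so the effective $n$ varies per pair. Significance is the exact
two-sided test under bivariate normality,

$$ t = r \sqrt{\frac{n-2}{1-r^2}} \sim t_{n-2}, $$

with star labels at $p<0.05/0.01/0.001$ on the raw p-values. Pairs resting
on fewer than four complete pairs are excluded outright — a correlation on
three points is sign-determined noise — as are zero-variance pairs, always
with an explicit machine-readable reason. Two-sided p-values are the
deliberate choice: sidedness is not dictated by the display convention, and
two-sided stars are the conservative reading. No multiplicity correction is
applied across the 120 pairs before star labeling; a Benjamini–Hochberg
column is exported for reference but never feeds the network filter.

## Network construction

An edge survives when all of the following hold (all comparisons
inclusive): $r \ge 0.5$, $p \le 0.1$, $n_{\text{pairs}} \ge 4$, and $r > 0$.
Negative correlations are never drawn nor counted in degree, but dropped
pairs are retained in an audit attribute with the failing condition named.
The minimum-pair threshold is configurable because the two printed
descriptions of the filter disagree ("four or more pairs" vs. "$n > 4$");
the inclusive reading `n_min = 4` is the default and `n_min = 5` reproduces
the strict one.

All 16 regions always appear as nodes, isolated or not; node weight is the
fold-change over home cage. Edge transparency maps $r$ linearly from
$[r_{\min}, 1]$ to $[0, 1]$ — the mapping from correlation strength to line
transparency is not standardised anywhere, so a linear rescale anchored at
the filter threshold is used and recorded as an edge attribute. Degree
ranking uses competition ranking: tied nodes share the top rank and ties
are flagged explicitly, with lexicographic order used only to make the
display deterministic. The canonical artifacts are the edge list and node
table (TSV) plus GraphML; figures are deterministic (fixed layout seed) but
cosmetic.

An interesting consequence of the default thresholds: at $n = 8$ animals
the two-sided $p \le 0.1$ criterion at 6 df already requires
$|r| \ge 0.6215$, so the $r \ge 0.5$ cut is inactive and the per-pair null
survival probability of a positive edge is exactly the upper 0.05 tail.
At larger $n$ the $r \ge 0.5$ cut takes over. The acceptance script
recomputes both the analytic critical $r$ and the Monte-Carlo null
survival rate.

## The synthetic cohort generator

No animal-level data accompany studies of this design, so the generator is
a first-class module that emulates their structure with known ground truth:

* **Latent densities.** Per animal, the 16 log-densities are multivariate
  normal with the group's planted correlation matrix; means are
  `mean_density × fold_change` with the log-normal mean correction, so
  planted means are recovered exactly in expectation and densities are
  strictly positive. Planted correlations therefore live on the log scale
  and attenuate mildly on the raw scale and under measurement noise — at
  the default noise settings a planted $r = 0.9$ is observed near
  $0.8$–$0.85$ after aggregation. Recovery tests either inspect the latent
  draws directly or use low observation noise.
* **Observation.** Each retained animal × region entry is seen through
  2–6 sections (uniform); each section has an area drawn uniformly from
  0.5–2.5 mm² and a count `round(latent × area × noise)` with log-normal
  multiplicative noise (`noise_cv`, default 0.2). Any positive-area
  convention would do; this one is recorded in the output.
* **Missingness** is completely at random per animal × region
  (`missing_rate`, default 0.1). Real studies report per-region group sizes
  varying from 3 to 8 without stating a mechanism, so MCAR is the neutral
  choice; the default rate reproduces pair counts in that range at
  $n = 5$–8 per group.
* **Defaults as study conditions.** Group sizes default to 7 per group
  (within the reported 5–8); baseline densities are division-typical
  (cortex 150, hippocampus 120, thalamus 100, amygdala 60 cells/mm²);
  between-animal CV is 0.3, a realistic between-subject variability for
  cFos densities at this group size. The default fold-change matrix and
  per-group correlation structures emulate the qualitative published
  pattern: familiar-context recruitment of PL/IL/PVT, broad recall and
  extinction activation sparing dorsal CA fields, control groups with
  independent regions, and a midline-thalamus-centred correlated module in
  recall plus a ventral-hippocampus–mPFC coupling in extinction.
* **Seeding.** A master seed spawns one deterministic substream per
  animal, so the same animal's records are bit-identical however many other
  animals are simulated, and the whole cohort is reproducible to the byte.

Planted structures are supplied as explicit correlation matrices and are
validated (symmetry, unit diagonal, positive semidefiniteness). Helpers
build valid matrices from factor loadings: `factor_correlation()` for one
correlated module, `hub_correlation()` for a hub at correlation $r$ with a
set of spokes.

### What a hub can and cannot look like

A hub correlated $0.9$ with six mutually *independent* spokes is not a
valid correlation structure: positive semidefiniteness forces any two
spokes sharing a hub at $0.9$ to correlate at least $2(0.9)^2 - 1 = 0.62$
(the single-factor construction used here gives $0.81$). At $n = 30$ this
means the hub and its spokes form a clique and tie at degree 6; the hub has
no structural degree advantage over its spokes, and which clique member
tops the ranking is decided by false-positive edges toward the nine
unrelated regions. In simulations the planted hub shares or holds the top
rank in roughly four of five runs, not near-certainty — an honest ceiling
of degree ranking as a hub statistic under strong, valid hub structures.
The acceptance script reports the measured rate; the edge-level power
companion (a planted $r = 0.9$ pair at $n = 8$ recovered well above chance)
is the better-behaved recovery statistic.

### What passing tests do and do not show

The generator is log-normal, MCAR, and exchangeable across animals. Real
cFos data may have region-dependent missingness, heavier tails, litter or
batch structure, and detection-threshold artifacts, none of which are
modelled. Calibration results (ANOVA type-I near 0.05; null edge survival
near its analytic value) therefore validate the implementation under the
stated model, not the robustness of the published design to violations of
it. The mild conservatism/anticonservatism of normal-theory tests on
log-normal data at $n = 6$–8 is visible but small at the default CV.

## Numerical and degenerate-input choices

* Exact-zero variance (constant vectors, all-identical ANOVA tables) is
  flagged, never propagated as `NaN`; $|r| = 1$ reports $p = 0$ with a
  collinearity flag.
* Thresholds are compared inclusively, matching their printed definitions;
  boundary cases ($r = 0.5$, $p = 0.1$, $n = 4$ exactly) are kept and are
  pinned by fixture tests.
* Edge and ranking order is lexicographic (C locale, radix sort), so
  exports are platform-stable.
* The pipeline re-reads its own exported section table before aggregating,
  so chained runs and stage-by-stage runs from files are byte-identical
  despite double-to-text rounding.
* PSD validation of planted matrices uses a $10^{-8}$ eigenvalue tolerance;
  a PSD-but-singular matrix gets a $10^{-10}$ diagonal ridge for the
  Cholesky factorisation only.

## Problem sizes used by the validation suite

The test suite and acceptance script simulate at sizes chosen to make
Monte-Carlo error small relative to the checked tolerances while keeping a
routine run comfortable on one CPU: 1000 random inputs per formula-oracle
comparison at $10^{-10}$; 2016 independent null pairs at $n = 8$ (99%
binomial band around 0.05); 1000 null cohorts at $n = 6$–8 for ANOVA
type-I; 200 hub cohorts at $n = 30$; 1000 pair-recovery cohorts at $n = 8$;
mean/correlation recovery at 250 and 200 animals per group.

## Limitations

Partial correlations, regularised covariance, cross-group network
comparison statistics and community/betweenness measures are out of scope;
the correlation-based "connectivity" here is inter-subject covariance, not
within-subject coupling, and inherits all the usual caveats of small-$n$
Pearson estimates. The ANOVA and post-hoc machinery is the classical
normal-theory toolkit; for strongly skewed real data a rank-based
sensitivity analysis would be prudent.
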