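---
title: "Consolidating multi-population wheat QTLs into meta-QTLs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consolidating multi-population wheat QTLs into meta-QTLs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mqtlr)
```

## The problem

Quantitative trait loci (QTL) reported by independent bi-parental mapping
studies in wheat are hard to use directly in breeding: each study has its
own genetic map, its own population size and its own wide confidence
interval, and the same underlying locus surfaces under different flanking
markers in different crosses. Meta-QTL analysis consolidates such a
compilation into a smaller set of consensus loci (MQTLs) with refined
positions and much narrower intervals. `mqtlr` implements the complete
chain: curation of a published QTL compilation, projection of every QTL
onto one consensus genetic map, per-chromosome consolidation by a Gaussian
mixture model, and the downstream summaries — genome distribution, trait
co-localization, physical anchoring against GWAS signals, and
cross-species synteny.

## Curation and the missing-statistic rule

Published QTL rows carry a peak position, a 95% confidence interval (CI),
and usually a LOD score and/or the explained phenotypic variance $R^2$.
When exactly one of the two effect statistics is missing it is filled from
the other through the standard population-size-aware relation

$$R^2 = 1 - 10^{-2\,\mathrm{LOD}/n},$$

inverted as $\mathrm{LOD} = -n\,\log_{10}(1 - R^2)/2$ when $R^2$ is the
one reported. The inversion is our choice (the relation is published only
in the forward direction); using a single self-consistent model for both
directions keeps round-trips exact. Records with neither statistic are
*flagged*, not dropped: the mixture model below needs only positions and
intervals, so such records still contribute to consolidation and are
excluded only from effect-size summaries. Chromosome labels are validated
against the 21-chromosome wheat nomenclature (homoeologous group 1–7 ×
subgenome A/B/D); the compilation format deliberately accepts asymmetric
CIs because published tables contain them.

## Consensus map and projection

Component maps are integrated around a fixed reference: reference marker
positions are preserved verbatim, and a component-only marker between two
shared anchor markers is placed by linear interpolation of its position
between the anchors. When several components propose the same new marker,
consistent placements (spread ≤ 5 cM) are averaged and inconsistent ones
leave the marker unplaced — a conservative conflict policy, since nothing
in a cM coordinate justifies trusting one component over another.

QTL projection uses the same flanking-shared-anchor linear rescaling. The
peak and the two CI endpoints are each mapped through their own bracketing
anchor pair, which keeps the transformation piecewise-linear and
order-preserving. Three failure modes are reported as statuses rather than
errors, because attrition is a *result* of this analysis, not an accident:
fewer than two shared anchors on the linkage group (`no_anchors`), anchor
order disagreeing between the maps (`inverted_anchor_order`), and points
falling outside the outermost shared anchors (`outside_anchors`). Points
beyond the anchored span are never extrapolated — extrapolation is
unbounded and is precisely how spurious consensus positions are minted.
This dropping rule is what makes the projected fraction of a compilation
informative (large published compilations typically lose a third or more
of their QTLs at this stage).

## The mixture model

Within one chromosome, each successfully projected QTL contributes an
observation $y_i$ (its consensus peak) with a *known* standard deviation
$s_i$ derived from its projected 95% interval, $s_i = \max(\text{width} /
3.92,\; 0.05)$ cM. The factor 3.92 is $2 \times 1.96$; the 0.05 cM floor
prevents singular likelihoods for the zero-width intervals that occur in
published tables (the packaged catalog contains a 0.01 cM interval). The
model for $K$ consensus loci is the heteroscedastic mixture

$$\mathcal{L} = \sum_i \log \sum_{k=1}^{K} \pi_k\,
  \varphi(y_i;\; \mu_k,\; s_i^2),$$

with free means $\mu_k$ and weights $\pi_k$ but component variances fixed
at each observation's own $s_i^2$ — the CI-to-variance pathway is the only
positional information a literature compilation carries, so nothing else
is estimable. The free parameter count is $p = 2K - 1$.

Fitting is by expectation-maximization: means initialized at the
$k/(K+1)$ quantiles of $y$, uniform weights, convergence when the relative
log-likelihood change drops below $10^{-8}$ (500 iterations cap), five
seeded restarts (quantile init, a k-means init, jittered variants) keeping
the best likelihood. Everything is deterministic given the seed, and the
caller's RNG state is never perturbed.

### From posteriors to a hard clustering

MQTL membership requires a hard partition. The naive choice — assign each
observation to its maximum-posterior component — is provably not optimal
for the *classification* likelihood (weights $n_k/n$, inverse-variance
cluster means): when the soft fit collapses two components onto one mean,
the arg-max partition has empty clusters, and under strong
heteroscedasticity the optimal partition can even be non-contiguous in
$y$, e.g. one wide-interval QTL belonging with a distant cluster while its
tight neighbors do not. The hard clustering is therefore refined by a
classification-EM ascent with empty-cluster reseeding, started from the
posterior arg-max and from a family of contiguous splits of the sorted
data, followed by best-improvement single-point relocation moves; small
problems ($n \le 12$), where non-contiguous optima actually occur and
moves are cheap, additionally get pairwise-exchange and merge/split moves.
The test suite holds this search to exhaustive partition enumeration on
hundreds of small instances; the enumeration lives only in the tests, so
the check stays two-route.

### Choosing K

For each $K$ from 1 to $\min(n, 10)$ five criteria are computed from the
maximized log-likelihood $\ln L$:

| criterion | penalty |
|---|---|
| AIC  | $-2\ln L + 2p$ |
| AICc | $\mathrm{AIC} + 2p(p+1)/(n-p-1)$ |
| AIC3 | $-2\ln L + 3p$ |
| BIC  | $-2\ln L + p\ln n$ |
| AWE  | $-2\ln L + 2p(\ln n + 1.5)$ |

Each criterion votes for its minimizing $K$; the final $K$ is the modal
vote. Two conventions the literature leaves open are fixed here: AICc
abstains from the whole vote whenever its correction is undefined
($n \le p + 1$) for any candidate $K$, so every vote compares the same
candidates; and ties break toward the smaller $K$ (parsimony). The
mixtures are fitted per chromosome across all traits jointly — the
alternative (per trait class) would preclude the multi-trait MQTLs that
are the point of the co-localization analysis.

### Consensus summaries

A cluster's consensus position is the inverse-variance weighted mean
$\sum y_i/s_i^2 \big/ \sum 1/s_i^2$ and its 95% interval has width
$3.92/\sqrt{\sum 1/s_i^2}$, centered on the position — so pooling always
shrinks the interval strictly below the narrowest member except for
singletons. Published MQTL interval columns are treated as full widths,
not half widths (the only reading consistent with a three-fold reduction
from a ~13.7 cM original mean to ~4.6 cM). Names follow the
`MQTL_<chromosome>_<index>` convention with indices ascending by position.
Flanking markers are the nearest consensus-map markers at or outside each
interval bound, clamped at chromosome ends.

## Distribution and co-localization statistics

Genome/group/chromosome counts are tested against uniformity with the
ordinary Pearson goodness-of-fit (`stats::chisq.test`). Density profiles
bin signed centromere offsets into half-open 50 cM bins $[50k, 50(k+1))$
with the centromere at offset 0 in the non-negative arm — the half-open
convention is ours (a printed "position 0" does not fix openness) and
makes bins exhaustive and disjoint.

The MQTL × trait incidence matrix is strictly binary. Two deliberately
non-standard conventions reproduce the published co-localization numbers
and are therefore implemented verbatim and documented rather than
"corrected": the co-localization frequency divides by the *target*
(second-named) trait's MQTL count and truncates toward zero to an integer
percentage; and the 1-df chi-squared compares the observed joint count to
the constructed expectation $n_\text{trait} \cdot n_\text{target}/N$ as a
single Pearson cell, which is not a 2×2 independence test. The orthodox
2×2 test is exposed separately (`chi2_association_2x2`) as a diagnostic.
Frequency-on-count regressions are ordinary least squares via `stats::lm`.

## Physical anchoring and synteny

An MQTL's physical interval is the Mb span of its two flanking markers;
when a flank lacks a physical position the nearest physically mapped
marker on the correct side substitutes (recorded), and an MQTL with no
mappable marker on one side is an explicit anchoring failure. GWAS overlap
uses closed intervals on Mb coordinates — published tables report
inclusive ranges — so a signal exactly on a bound counts. Orthologous MQTL
detection links an interval pair across species when at least one ortholog
gene pair overlaps both intervals; gene-in-interval uses any-overlap
rather than full containment because Mb rounding in published tables would
otherwise drop boundary genes. Ortholog pairs are a plain input table, not
a live database query, for offline reproducibility. The packaged pair
table is synthetic (one pair per published interval link, placed at
interval midpoints): it preserves the published pairing structure exactly,
which is what the overlap machinery can be tested against without an
annotation release.

## The synthetic-study generator

`generate_study()` emulates the structure of a large multi-population
compilation with known ground truth. Defaults mirror the scale of the
published study: 21 chromosomes, 27 populations (RIL-heavy, 92–485
lines), 5 true clusters per chromosome with 7 members each (735 QTLs), CI
widths log-normal with median 13.7 cM, and an attrition fraction of 0.39
— with those widths the end-to-end interval reduction comes out near
three-fold without any tuning. Mechanically: cluster means are placed
evenly with bounded jitter subject to a minimum separation; peaks are
drawn $\mathcal{N}(\mu, s_i^2)$ in reference coordinates; component maps
retain a marker subsample and distort positions by monotone per-interval
log-normal stretch factors whose breakpoints coincide with the retained
anchors, so projection inverts the distortion *exactly* and recovery
errors are attributable to the statistics, not the plumbing. Attrition is
constructed, not stochastic: a fixed count of QTLs is relocated beyond the
outermost anchor, so the projected fraction equals the configured value
exactly. Cluster trait sets are drawn with designated pair odds
multipliers calibrated so the multiplier is the exact population odds
ratio.

What the generator does **not** emulate: real marker-order conflicts
(inversions are off by default and only injectable for failure-path
tests), genotyping error, shared parents between populations, LD
structure, or any genotype/phenotype layer. Passing recovery tests
therefore demonstrates that the statistical chain is correct under its own
assumptions, not that those assumptions hold for any particular published
compilation.

The recovery benchmark used in the tests runs 200 single-chromosome
replicates with 3 planted clusters of 6 members and CI widths
log-normal(log 8, 0.25) under a 30 cM minimum separation — narrow widths
so that the benchmark's stated separation condition (≥ 5× the largest
positional SD) holds across the width distribution's support. Replicate
counts and problem sizes throughout the suite were chosen once to keep
the full run in the minutes range on a single core.

## Numerical choices and limitations

* 0.05 cM floor on positional SDs; 3.92 CI↔SD factor.
* EM tolerance $10^{-8}$ (relative), 500 iterations, 5 restarts.
* Model-selection ties break to smaller K; AICc abstains when undefined.
* Marker-placement conflicts beyond 5 cM leave markers unplaced.
* Projection never extrapolates beyond the outermost shared anchors.
* The per-chromosome mixture assumes projected positions are comparable
  across populations, i.e. the consensus map is treated as error-free;
  map-integration error is not propagated into $s_i$.
* Multiple-testing correction across trait pairs is deliberately absent,
  matching the statistical construction being reproduced; the 2×2
  diagnostic is provided for readers who want an orthodox test.
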