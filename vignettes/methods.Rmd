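---
title: "Methods: enzyme stoichiometry vectors, diversity and co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enzyme stoichiometry vectors, diversity and co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoichnet)
library(dplyr)
```

`stoichnet` analyses soil microbial nutrient limitation along agricultural
management gradients — here a plastic-film mulching chronosequence (CK, Y5,
Y10, Y15 = 0/5/10/15 years under film) sampled at two depths (0–20 and
20–40 cm) with three replicates per cell. This vignette explains the models
and procedures, the choices behind their defaults, and what the synthetic
data generator does and does not emulate.

## Ecoenzymatic stoichiometry vectors

Five extracellular hydrolases index microbial investment into nutrient
acquisition: BG and CBH (carbon), NAG and LAP (nitrogen), ALP (phosphorus).
With acquisition-group sums $C = \mathrm{BG}+\mathrm{CBH}$,
$N = \mathrm{NAG}+\mathrm{LAP}$, $P = \mathrm{ALP}$, the relative activities

$$x = \frac{C}{C + P}, \qquad y = \frac{C}{C + N}$$

define a point in the unit square. The **vector length**
$\sqrt{x^2 + y^2}$ rises with relative carbon limitation; the **vector
angle**, the angle of $(x, y)$ from the origin in degrees
($\arctan(y/x)$), indicates the nitrogen–phosphorus balance: angles above
45° mean relative P limitation, below 45° relative N limitation, and the
boundary is attained exactly when $\mathrm{ALP} = \mathrm{NAG}+\mathrm{LAP}$.

Two conventions deserve a note:

* **Angle argument order.** Spreadsheet `ATAN2(x, y)` returns the angle of
  the *point* $(x, y)$, i.e. $\arctan(y/x)$ in the first quadrant, and that
  is what `enzyme_vectors()` computes. The opposite order would place all
  eight packaged cell means near 26–39° and contradict the >45° phosphorus
  classification those profiles clearly show; with the convention used here
  they span 50.6°–64.2°.
* **Untransformed activities.** Vectors are computed on raw activities (no
  log transform). Both statistics are scale-invariant — multiplying all five
  activities by any $k > 0$ changes nothing — so units only need to be
  consistent within a table (activity units are treated as arbitrary; every
  downstream statistic is a ratio or percent change).

Group summaries can be computed per replicate and averaged, or on group
means ("means-first"). The packaged tables carry only group means, so all
published-value checks use means-first; with replicate-level data the two
differ slightly because length and angle are nonlinear in the activities.

```{r vectors}
fixture_means("table2_enzymes") |>
  enzyme_vectors() |>
  select(depth, treatment, vector_length, vector_angle, limitation)
```

Percent-change contrasts (`percent_change()`) are plain
$100\,(v - b)/b$. Depth contrasts average the four treatment means within
each layer (unweighted); mulching contrasts compare the six mulched cells
with the two unmulched ones. The per-depth "overall" rows of the packaged
tables reproduce this mean-of-treatment-means, and the soil-water depth
contrast uses the printed overall rows directly, matching how such tables
are normally summarised.

## Packaged fixtures

`load_fixture()` ships the published treatment-by-depth group means and SDs
(soil physicochemistry; enzyme activities and their C:N:P ratios;
bacterial/fungal alpha diversity), transcribed cell-for-cell at printed
precision with $n = 3$. A checksum test pins the transcription. One printed
inconsistency is worth knowing: the deep-layer BG "overall" prints 133.5
while its four treatment means average to 133.575 (all other overall cells
agree to within half a printed unit); computations therefore prefer the
treatment means except where a published contrast demonstrably used the
printed overall row.

## Synthetic data generator

`simulate_study()` draws per-replicate values independently as
Normal(mean, SD), truncated at zero **by resampling** rather than clipping,
so no point mass accumulates at zero; at the SD/mean ratios of the packaged
tables truncation is essentially never triggered and cell means are
preserved. `sd_scale = 0` returns the cell means exactly — composing it with
`group_summary()` is the identity on the means table, which anchors the
whole summary path. A single seed determines all output. The dispersion
column of the packaged tables is used as the per-cell SD; the Normal-per-cell
form is an assumption (the source tables state no distribution).

`simulate_community()` plants known structure for network validation:
latent Gaussian vectors with signed equicorrelated blocks (every
within-block pair at correlation $\rho$) are exponentiated to abundances and
converted to counts by multinomial sampling at a log-normal per-sample
depth (default $e^{\log 10^4} = 10^4$ reads, log-SD 0.25), emulating uneven
library sizes. An equicorrelated negative block of size > 2 at
$\rho \le -0.5$ is not positive definite and errors before sampling, so
strong negative associations are planted as taxon pairs. Planted truth =
within-block pairs with $|\rho| \ge 0.8$, with sign.

What the generator does **not** emulate: phylogenetic structure, real
taxon-abundance distributions, spatial autocorrelation between replicates,
or mechanistic soil processes. Passing recovery tests therefore show the
inference machinery is correct on data satisfying its assumptions, not that
those assumptions hold in any particular field soil.

### Compositional attenuation of negative associations

Counts are relative: the multinomial closure and shared library-size
denominator bias count-level correlations toward positive values. A latent
$\rho = -0.9$ pair measures around $-0.6$ to $-0.75$ in count-level
Spearman and is **not** recovered at the default $|r| > 0.8$ — precisely
the phenomenon that motivates compositionality-aware methods (SparCC,
SPIEC-EASI), which are out of scope here. Positive blocks at $\rho = 0.9$
are recovered reliably at $n = 200$ samples. The recovery validation
(precision ≥ 0.9, recall ≥ 0.8) uses two positive 3-blocks plus one
negative pair; the missed negative edge is the expected compositional cost,
and sign propagation is verified separately at a relaxed threshold.

## Alpha diversity and rarefaction

`alpha_diversity()` reports observed richness, singletons/doubletons, and

* **Chao1**, bias-corrected: $S_{obs} + f_1(f_1-1)/(2(f_2+1))$, defined even
  without doubletons (classical $S_{obs} + f_1^2/2f_2$ by flag);
* **Shannon**, default base 2 — the packaged bacterial values (≈9.5–10.1
  for ~4,600–5,200 taxa) are only attainable in bits, since $\ln$ would cap
  near 8.5; base-$e$ by flag;
* **Gini–Simpson** $1 - \sum p_i^2$, consistent with packaged values ≈1.0
  for diverse communities.

No rarefying is applied before alpha diversity by default.
`rarefaction_curve()` offers the exact hypergeometric expectation
$E[S_d] = \sum_i \left(1 - \binom{N-n_i}{d}\big/\binom{N}{d}\right)$
(via `vegan::rarefy()`) and a Monte-Carlo mode used as its independent
cross-check; curves are nondecreasing and concave in depth.
`bray_curtis()` wraps `vegan::vegdist()`:
$d = 1 - 2\sum_i \min(a_i, b_i) / (\sum a_i + \sum b_i)$, bounded in
$[0, 1]$, symmetric, not a metric (triangle inequality can fail).

## Co-occurrence networks

`correlation_matrix()` computes all-pairs Spearman (default; rank-based,
appropriate for skewed counts) or Pearson correlations with two-sided
p-values from the t approximation
$t = r\sqrt{(n-2)/(1-r^2)}$ — requiring ≥ 4 samples. Taxa present in fewer
than a third of samples are dropped first (configurable) to prevent
zero-driven spurious correlations. `build_network()` retains pairs with
$|r| > 0.8$ and $p < 0.05$ by default; raw p-values match common practice
in this literature, with Benjamini–Hochberg adjustment available and
recommended when taxon counts are large. Pairs landing exactly on the
magnitude threshold are retained, so `r_min = 1` keeps perfect
correlations.

`network_topology()` works on the undirected simple graph over the full
taxon universe: average degree $2m/n$, density $2m/(n(n-1))$, mean local
clustering (nodes of degree < 2 contribute 0), diameter and mean shortest
path on the largest connected component (any other convention yields
infinities on disconnected graphs), and modularity of the deterministic
fast-greedy partition on the unweighted sign-blind graph — deterministic
node ordering makes repeated runs identical. Empty networks report
diameter/path length as missing rather than erroring. Networks export to
GraphML (with `r`, `p`, `sign` edge attributes) or round-trippable TSV.

With only three replicates per treatment cell, per-treatment networks are
statistically meaningless (p-values at $n = 3$ carry almost no
information); network inference is intended for pooled sample sets, and the
examples use $n \ge 24$.

## Inference

**Mantel test.** $r_m$ is the Pearson correlation of upper-triangle
distances; significance comes from jointly permuting rows/columns of the
second matrix. One-sided "greater" is the default (the usual ecological
convention), $p = (1 + \#\{r^* \ge r_m\})/(n_{perm}+1)$ with 999
permutations. An exhaustive mode enumerates all $n!$ relabelings for small
$n$ — the unit tests verify the sampled and exhaustive forms agree and that
the null rejection rate at 0.05 stays in [0.03, 0.07].

**Two-way ANOVA.** Balanced depth × years with interaction; raw mode uses
`stats::aov` (type I = type II when balanced). A summary mode reconstructs
the exact sums of squares from per-cell mean/SD/n
($SS_{error} = \sum (n-1)s^2$; factor SS from cell means), enabling
qualitative checks against published F values from mean ± SD tables —
qualitative only, because 1-decimal rounding of the inputs propagates.

**Duncan's multiple range test.** Ordered means are compared with the
critical range $R_p = q\left((1-\alpha)^{p-1},\, p,\, df_e\right)\sqrt{MSE/n_h}$
(studentized-range quantile at the protected level; $n_h$ = harmonic mean
group size). A whole span is declared non-significant when its extremes
differ by less than its critical range; letters are the maximal such runs,
so groups sharing a letter are indistinguishable at $\alpha$. Ties in means
break by group label for deterministic letters. As $\alpha \to 0$ the
display collapses to a single letter.

## Pipeline

`run_pipeline()` chains simulate/read → group summary → vectors →
diversity → network → Mantel → ANOVA from a config list or YAML file, writes
deterministically named TSV/GraphML/JSON outputs plus a consolidated
`report.json` (package version, seed, parameters, per-stage summaries), and
is byte-reproducible under a fixed seed. Stages toggle independently;
disabling one leaves the others' outputs unchanged.

## Problem sizes and numerical choices

The validation suite is sized for quick desk runs: recovery tests use 30
taxa × 200 samples; null-network checks 30 × 50; Mantel calibration 500
null replicates of 20 × 20 matrices at 999 permutations; rarefaction
cross-checks up to $10^4$ Monte-Carlo draws. Numerical tolerances: exact
identities (SS decomposition, ratio identities, scale invariance) at
1e-9–1e-12; published-value checks at the printed precision (±0.01 on
vector lengths, ±0.1 on angles and percentages) because the packaged
inputs are 1-decimal group means while the original computations used
replicate-level data. Known near-misses from that rounding: the CBH depth
contrast computes −30.4 vs the published −30.5, NAG −22.2 vs −22.4; the
maximum vector length computes 0.798 where 0.79 is printed.

## Limitations

* Correlation-threshold networks on relative abundances under-detect
  negative associations (see above) and do not distinguish direct from
  indirect association.
* Summary-mode ANOVA inherits the rounding of its input table.
* The generator's independence across cells ignores block/field structure;
  its Normal-per-cell noise is an assumption.
* Published per-treatment network topology values are not reproducible here
  because the underlying sequence-derived tables are not packaged; topology
  metrics are validated on closed-form graphs and planted synthetic
  communities instead.
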