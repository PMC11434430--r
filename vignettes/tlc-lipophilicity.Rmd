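---
title: "Determining lipophilicity by RP-TLC: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining lipophilicity by RP-TLC: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlclipo)
```

## The retention model

Reversed-phase TLC estimates lipophilicity from how strongly a solute
partitions into the non-polar stationary phase as the mobile phase is made
progressively less eluting. The measured retardation factor $R_F \in (0,1)$
is transformed to the retention parameter

$$R_M = \log_{10}\!\left(\frac{1}{R_F} - 1\right),$$

which is linear in the volume fraction $C$ of organic modifier (acetone,
% v/v) over the usable range — the Soczewiński–Wachtmeister relationship

$$R_M = R_{M0} + bC.$$

`fit_retention()` estimates $R_{M0}$ (the intercept) and $b$ (the slope,
negative for RP systems: more modifier elutes faster) by ordinary least
squares. $R_{M0}$ is the retention the solute *would* show in pure water —
it cannot be measured directly for lipophilic solutes, which is exactly why
it is obtained by extrapolation. Two modelling assumptions matter:

* **Linearity over the measured window.** The model is fitted where it is
  (approximately) linear, typically 60–90% acetone for triterpenoids, and
  then extrapolated all the way to $C = 0$. The extrapolation distance is
  large relative to the measured range; every `retention_fit` therefore
  records `extrapolation_distance` rather than pretending the intercept is
  an interpolation.
* **Homoscedastic Gaussian error on the $R_M$ scale.** Replicate spots at
  the same concentration are averaged on the $R_F$ scale first (the
  conventional lab practice), then transformed once.

A fit is accepted with as few as three distinct concentrations; below that
the line is not identifiable and the function errors. Fits whose absolute
Pearson correlation falls under `r_warn = 0.98` warn rather than fail —
published reference fits in this assay sit in the 0.982–0.997 band, so
anything below 0.98 deserves a second look at the plate, not silent
rejection.

Because $b < 0$ while the published tables print positive correlation
coefficients, the package reports `r_abs = |r|` and keeps the slope's sign
separately; the two are never conflated.

## The calibration curve

`fit_calibration()` regresses literature $\log P$ values of reference
standards on their extrapolated $R_{M0}$:

$$\log P_{TLC} = \text{slope} \cdot R_{M0} + \text{intercept}.$$

At least three standards with non-identical $R_{M0}$ are required. With the
seven packaged standards (acetanilide through DDT, spanning $\log P$ 1.2 to
6.4):

```{r calibration}
curve <- fit_calibration(load_fixture("table2_standards"))
curve
```

Note the propagation of input precision: the packaged standards are printed
to two decimals, so coefficients recomputed from them can differ from
values computed on unrounded data by about $2 \times 10^{-3}$. The package
keeps full internal precision everywhere and rounds only in reporting
(`round = TRUE` mirrors the conventional table precision: $R_{M0}$ and
$\log P$ to 2 decimals, $b$ to 2, $r$ to 3). One visible artifact of this
convention: applying the calibration to betulin's 2-dp $R_{M0}$ of 4.81
yields 6.12 where the original report lists 6.11 — the original authors
evidently applied the curve to the unrounded intercept.

## QSPR statistics

`regression_table()` fits one simple regression of the response (typically
`logP_TLC`) on every other descriptor and reports, per row, the complete
inferential summary as such tables are conventionally printed: slope and
intercept with standard errors, $r$ (signed like the slope), residual
standard error $s = \sqrt{SSE/(n-2)}$, $F = MSR/MSE$, and the upper-tail
$p$ from $F(1, n-2)$ — equivalent to the two-sided test of zero slope.
These quantities obey the identities $r^2 = 1 - SSE/SS_{yy}$,
$F = r^2(n-2)/(1-r^2)$ and $s^2 = (1-r^2)\,SS_{yy}/(n-2)$, which the test
suite asserts to $10^{-9}$.

All predictors are always computed and returned; the `significant` flag
($p \le 0.05$) is attached so that presentation filters (e.g. omitting the
hydrogen-bond-donor count, whose correlation with `logP_TLC` is weak at
$n = 5$) remain a display decision, not a computation one. A perfect fit
reports $s = 0$ with $F$ and $p$ as `NA` — flagged undefined rather than
infinite.

`activity_correlation()` aligns a descriptor table with IC50 records by
compound id (complete cases; dropped ids are messaged) and computes plain
Pearson correlations. Two caveats are built in. First, correlations over
exactly three compounds carry essentially no inferential weight; the result
is flagged `low_power`. Second, the published activity-correlation table
for this dataset could not be reproduced from its printed inputs under
Pearson, Spearman, Kendall or log-transformed IC50 — e.g. plain Pearson of
IC50 (67, 156, 35 µM) against milogP (8.96, 9.08, 8.81) gives 0.946 where
0.710 was printed. The package implements documented, plain Pearson and
leaves the discrepancy on record rather than reverse-engineering an
unstated transformation.

## Chemometrics

`single_linkage()` performs agglomerative clustering with the inter-cluster
distance defined as the minimum pairwise Euclidean distance. Single linkage
cannot produce height inversions, so merge heights are non-decreasing by
construction. Two determinism choices are the package's own:

* **Tie-breaking.** When several candidate merges share the minimum
  distance (within $10^{-12}$), the pair whose sorted member labels are
  lexicographically smallest merges first. Trees are therefore
  bit-reproducible.
* **Default scaling.** Clustering runs on raw values by default. For panels
  of logP estimates this is deliberate: the absolute magnitude of each
  calculator's scale is part of what the dendrogram should expose (the
  systematically highest and lowest calculators separate out). Pass
  `standardize = TRUE` to cluster shape instead of magnitude.

`to_newick()` serializes the tree ultrametrically — a child of height
$h_c$ joined at height $h$ receives branch length $(h - h_c)/2$ — so path
lengths between leaves reproduce the merge heights exactly, which is also
how the export is tested (round trip through `ape::read.tree`).

```{r clustering}
tree <- single_linkage(lipophilicity_table())
tree
```

`descriptor_pca()` eigendecomposes the covariance matrix of the optionally
standardized data — for the table sizes this package targets (tens of
variables, a handful to hundreds of observations) the $p \times p$
eigendecomposition is exact and cheap; no truncated or iterative SVD is
warranted. Standardization uses the $n-1$ sample standard deviation, so
eigenvalues of standardized data sum to the number of variables.
Eigenvalues below `tol = 1e-10` report as exact zeros: with $n$
observations at most $n - 1$ components can be nonzero, and reporting
numerical dust as structure would be misleading. Each component is oriented
so its largest-magnitude loading is positive — an arbitrary but fixed sign
convention that makes loadings and scores reproducible across platforms.

One genuinely ambiguous choice is *which* columns enter the PCA of the
packaged dataset: the original analysis of "logP values, physicochemical
and ADME properties" may or may not have included the experimental
$R_{M0}$ alongside $\log P_{TLC}$. The package takes no position:
`lipophilicity_table()` assembles any combination of the experimental,
theoretical and property blocks, and both candidate matrices give four
nonzero components with the first explaining well over 90% of the variance
(the dominant-component share differs in the second decimal between the
two). The hydrogen-bond-donor count is the lone descriptor loading chiefly
on the second component — it is the one column not driven by the shared
lipophilicity factor.

```{r pca}
with_rm0 <- descriptor_pca(lipophilicity_table(
  c("experimental", "theoretical", "properties")))
without_rm0 <- descriptor_pca(lipophilicity_table(
  c("experimental", "theoretical", "properties"))[, -1])
head(scree(with_rm0), 4)
head(scree(without_rm0), 4)
```

## The synthetic-data generator

`simulate_plate()` draws $R_M = R_{M0} + bC + \varepsilon$ with
$\varepsilon \sim N(0, \sigma^2)$ and inverts the transform,
$R_F = 1/(1 + 10^{R_M})$. Defaults encode routine practice for lipophilic
solutes: modifier grid 65–90% v/v in 5% steps, three replicate spots per
concentration (the replicate count in the motivating study is unstated;
three is the standard plate design and is exposed as a parameter). Noise is
placed on the $R_M$ scale because that is where the model assumes linearity
and homoscedasticity; noise on $R_F$ would make the transformed errors
heteroscedastic and the simulated truth ill-defined.

What the generator emulates: the linear retention law, plate-level
Gaussian noise, replicate spots, and (via `simulate_descriptor_table()`)
descriptor panels driven by one dominant latent lipophilicity factor plus
an independent discrete column mimicking a hydrogen-bond-donor count. What
it does **not** emulate: band broadening, chamber-saturation effects,
curvature of the retention law outside the fitted window, inter-plate batch
effects, or correlated errors across concentrations. Passing recovery tests
therefore demonstrates that the estimation chain is correct and unbiased
*under the model's own assumptions* — not that real plates satisfy those
assumptions.

`recovery_experiment()` runs the full chain over `n_reps` seeded replicates
(replicate $r$ uses `seed + r`, so extending an experiment preserves the
existing replicates) and reports bias and RMSE of $R_{M0}$ and
$\log P_{TLC}$. At $\sigma = 0$ recovery is exact to numerical precision;
at plate-realistic $\sigma$ (0.02–0.1 on $R_M$) the estimator is unbiased
well within half a noise standard deviation over 200 replicates, while RMSE
grows with $\sigma$ — the extrapolation to $C = 0$ amplifies noise by the
design leverage, which is visible in the RMSE but not in the bias.

```{r recovery}
spec <- plate_sim_spec("X", true_rm0 = 6.05, true_b = -0.07,
                       noise_sd = 0.05, n_replicates = 1L, seed = 314)
recovery_experiment(spec, n_reps = 200,
                    standards = load_fixture("table2_standards"))[c("rm0", "logp_tlc")]
```

Test and validation problem sizes throughout the package (200 Monte-Carlo
replicates, descriptor panels of up to 50 compounds) are chosen so the
whole suite verifies the statistical claims in seconds on a laptop; the
estimators themselves have no size limits beyond memory.

## Degenerate inputs and numerical policy

* $R_F$ must lie strictly inside $(0,1)$: 0 and 1 are physically possible
  readings but carry no retention information, so they are rejected with a
  domain error rather than mapped to $\pm\infty$.
* Fits require three distinct concentrations / standards; identical $R_M$
  across all spots, or zero variance in $R_{M0}$ across standards, is a
  degenerate design and errors.
* The $R_F \leftrightarrow R_M$ transform round-trips to $10^{-12}$ over
  the full open interval; tests pin this.
* All logarithms are base 10 ($R_M$ and $\log P$ are decimal-log
  quantities).
* CSV ingestion normalizes the Unicode minus (U+2212), which typeset tables
  commonly contain, to ASCII hyphen-minus.
* The CLI distinguishes validation failures (exit 2) from internal errors
  (exit 1) via a dedicated condition class on all precondition checks.

## Known limitations

* Isocratic linear retention only: gradient elution, quadratic
  $R_M$–modifier relationships and HPLC $\log k_w$ extrapolation are out of
  scope.
* Simple (one-predictor) regression only; no multiple regression, variable
  selection or multiplicity correction across table rows (none is applied
  in the conventional reporting this package mirrors).
* Single linkage and Euclidean distance only; other linkages and metrics,
  bootstrap support and varimax rotation are not provided.
* The packaged fixtures are printed-table precision (2–3 decimals); every
  reproduction tolerance in the test suite is set by propagating that input
  rounding, not by the package's numerical accuracy, which is limited only
  by double precision.
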