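---
title: "Control-anchored normalization of multi-cell-line genetic screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control-anchored normalization of multi-cell-line genetic screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenorm)
```

## The problem

siRNA and CRISPR screens measure a viability phenotype for thousands of
gene perturbations. When several cell lines are screened — each in
technical triplicate, often across hundreds of micro-titer plates — the
*functional range* of the readout (the span between what a normal and a
fully lethal phenotype produce) differs between replicates, cell lines and
plates for purely technical reasons. Methods that center or standardize
each replicate in isolation (robust z-scores, median-centering, classic
quantile normalization) ignore the assay controls that define this range,
so identical numeric values can represent different phenotypes in
different screens, and genuine biology (a cell line with more lethal hits)
can be "corrected" away. Both failure modes degrade the reproducibility of
hit lists.

`screenorm` implements a control-anchored alternative in five steps.

## The model

### 1. Lethality scores

For library feature $i$ in replicate $k$ with readout $x_{ik}$,

$$Z_{ik} = \frac{x_{ik} - \operatorname{med}(Z^N_k)}
               {\operatorname{med}(Z^P_k) - \operatorname{med}(Z^N_k)},$$

where $Z^N_k$, $Z^P_k$ are the negative- and positive-control readouts of
the same scoring scope. By construction the scope's own control medians
map to exactly 0 (normal viability) and 1 (as lethal as the positive
controls), so scores are comparable across replicates regardless of each
screen's raw range. The formula is orientation-free: if lower readouts
mean more lethality the denominator is negative and the signs cancel. For
arrayed screens, `scope = "plate"` uses each plate's own control medians,
which removes additive plate effects exactly — every well on a plate
shares the offset, the numerator subtracts it, and the denominator is
offset-invariant.

Controls are scored with the same formula and retained throughout; they
anchor the scale but (see below) never drive the normalization fit.

### 2. Core sets

Scores are a mixture of biology and residual technical noise. Across
screens, the bulk of the score distribution represents phenotypes present
in all of them in similar proportions, while the upper tail carries each
screen's own lethal hits. Per replicate, the *core set* is the multiset of
library score values between the `alpha_low` and `alpha_high` empirical
quantiles of that replicate's library scores (`select_core_percentile()`).
It is a set of values, not of features: the same feature may be in one
replicate's core and outside another's.

Defaults and guidance:

* `alpha_high = 0.95`, `alpha_low = 0` — for genome-wide screens of
  untreated cell lines, 90–95% of the phenotype range can be assumed
  common to all screens.
* When a condition is expected to enlarge the lethal fraction — say a
  treatment expected to turn ~20% of features lethal — the affected
  replicates should use `alpha_high` reduced accordingly (0.80 in that
  example), passed as a named per-replicate vector. If the enriched tail
  is left inside the core, the normalization will partly absorb the effect
  and can distort null features (we verify both behaviours in the test
  suite's with-effect checks, which use the 0.95/0.80 prescription).
* `alpha_low > 0` trims the lower tail too, for assays where increased
  proliferation is a real phenotype.
* `select_core_distance(gamma)` is the fallback when no percentile
  suggests itself: keep values $v$ with $|v - m_N| \le \gamma\,|v - m_P|$,
  i.e. close to the negative controls relative to the positive ones
  ($\gamma = 1$: closer to negative than to positive).

### 3–4. Core-restricted quantile normalization, as a linear map

Core sets differ in size, so each is represented by its empirical
quantiles at $j/1000$, $j = 1, \dots, 1000$ (`quantile_grid()`), and the
reference distribution is the pointwise mean grid over replicates
(`mean_quantile_grid()`). Rather than interpolating the grid directly,
each replicate's normalization is re-expressed as ordinary least squares
of the mean grid on the replicate's grid (`fit_linear_map()`), giving an
intercept $a_k$ and slope $b_k$ that apply to *every* value in the core:
$Z^{\text{norm}}_{ik} = a_k + b_k Z_{ik}$. When the quantile–quantile
relation is exactly linear the fit is exact, and if every core is the full
score set this reproduces classic quantile normalization (a property the
test suite asserts to $10^{-9}$ against the package's own
`classic_quantile_normalize()`).

### 5. Tails

Values outside the core are *shifted* by the same amount as the nearest
core bound:

$$Z^{\text{norm}}_{ik} = a_k + (b_k - 1)\,Z^{\max}_k + Z_{ik}
  \quad (Z_{ik} > Z^{\max}_k),$$

and symmetrically with $Z^{\min}_k$ below the core. This keeps each
replicate's tail geometry — distances between extreme scores, and the
proportion of values beyond the core bound — exactly intact, which is the
entire point: screens with genuinely more lethal hits keep their heavier
tails. The map is continuous at both bounds and strictly increasing
whenever $b_k > 0$.

`tail_mode = "literal"` replaces the lower-tail shift with the reflection
$a_k + (b_k + 1) Z^{\min}_k - Z_{ik}$. It is also continuous at
$Z^{\min}_k$ but reverses the order of lower-tail values; we default to
the shift form because rank preservation is what downstream testing
assumes, and we see no statistical argument for reflecting
proliferation-side scores.

## Comparator methods

`robust_z()` (median/MAD per replicate, 1.4826 consistency factor by
default, raw MAD optional), `median_center()`, and
`classic_quantile_normalize()` (row-means of column-sorted matrix, ties
given the mean of their positions' reference values) are provided behind
the same `normalize_screen()` front-end. All fit their parameters on
library features only and transform controls along. They are baselines,
deliberately ignoring the assay controls the way common pipelines do.

## Hit calling and reproducibility metrics

`per_feature_test()` fits, per feature, OLS of the score on a two-level
group factor (plus optional covariates) and tests the group coefficient
with a two-sided t-test; all features share one QR decomposition.
`moderation = "pooled"` shrinks the residual variance toward the
across-feature mean with weight $\mathrm{df}/(\mathrm{df} + d_0)$
(default $d_0 = 4$) and tests on $\mathrm{df} + d_0$ degrees of freedom —
adding the prior degrees of freedom is the standard behaviour of
moderated-variance statistics, and the spec-level choice we made where the
convention was open. This is a simple stand-in for a full empirical-Bayes
fit, adequate for method comparison on synthetic data.

Multiplicity is handled by Benjamini–Hochberg (`bh_adjust()`, a wrapper
over `stats::p.adjust`). `false_discovery_proportion()` uses the
$V/\max(R, 1)$ convention. `concordance()` cross-tabulates two analyses'
significance calls and reports agreement, discordance, hit- and
non-hit-confirmation fractions, plus the non-hit overlap under both the
union and the common-total denominator (both conventions appear in
published comparisons, so both are emitted and labelled).

## The synthetic-data generator

`simulate_study()` emulates the study design the method targets: 6 cell
lines × 3 technical replicates; per replicate 1000 library features and
200 + 200 controls drawn from independent normals — controls at means 0
and 1 with sd 0.1, features at means $\mu_i \sim \mathrm{Beta}(2, 6)$
(expectation 0.25; most features yield little lethality) with sd 0.2. A
per-cell-line *stretch* multiplies the means of library features and
positive controls by 0.7 / 1 / 1.4 (balanced across the two groups of
lines, hence orthogonal to the group effect); negative-control means are
0, so mean-scaling leaves them put. In with-effect mode the first 200
features (a deterministic truth mask, chosen for test stability) get mean
0.5 in cell lines 4–6.

Choices worth flagging:

* $\mu_i$ is drawn once per feature and shared across replicates by
  default — features are properties of the library, and sharing them is
  what makes a per-feature group test meaningful. `mu_per_replicate =
  TRUE` gives fully independent means per replicate for users who want
  the literal independent-draws reading.
* Simulated values *are* lethality scores; normalization of simulated
  data starts at core selection. Re-deriving scores from the simulated
  controls would divide out the stretch through the denominator and make
  the exercise vacuous.
* `pos_bias` shifts positive-control means per cell line, for studying
  miscalibrated controls; it defaults to 0.

What the generator does not emulate: spatial plate artefacts (a separate
additive-offset fixture, `simulate_arrayed_plates()`, covers the additive
case), count noise (pooled screens produce overdispersed counts, not
normals), correlated off-target structure between features, and
cell-line-specific feature means. Passing tests on this generator
demonstrate the method's behaviour under its own stated model — range
standardization, plate-effect removal, tail preservation, FDR control —
not performance on any particular real dataset.

`run_fdr_experiment()` wraps the loop simulate → normalize → test → BH →
FDP/power used for method comparison. Under the balanced stretch and the
no-effect setup, note what *should* be expected of unnormalized scores:
the group contrast is unbiased (the stretch sets are identical in both
groups) while the between-line spread of feature means inflates the
pooled residual variance, so the raw-score t-test is *conservative*, not
anti-conservative. Normalization's measurable benefit in this design is
power and score comparability, not type-I rescue; inflated false
discovery rates require an imbalance or within-line dependence that this
generator deliberately does not produce.

## Numerical conventions

* Empirical quantiles everywhere use linear interpolation between order
  statistics at $h = (m - 1)p + 1$ (type 7), so 1001 equally spaced core
  values give $j/1000$ at grid point $j$ exactly, and $p = 1$ is the
  maximum.
* Medians are plain sample medians (mean of the middle two for even
  counts).
* Core boundary ties are included — the core is a value multiset.
* The functional range must satisfy
  $|\operatorname{med}(Z^P) - \operatorname{med}(Z^N)| > 10^{-8}$ on the
  transformed scale, per scope; below that the scope is reported as
  degenerate rather than silently producing huge scores.
* A zero-variance quantile grid (possible in practice, e.g. all positive
  controls at zero reads and a collapsed core) falls back to pure
  centering ($b = 1$) with a warning instead of failing.
* Missing readouts are dropped with a message, never imputed.

## Problem sizes in the shipped checks

The test suite and the acceptance script use 100 simulated datasets for
the no-effect false-discovery summary and 25 for the with-effect power
comparison — sizes we chose so the full suite runs in well under a minute
while keeping Monte-Carlo standard errors an order of magnitude below the
effects being asserted; stochastic assertions allow three Monte-Carlo
standard errors. The generator's own calibration check uses $10^5$
feature-mean draws.

## Known limitations

* The per-plate scoring corrects additive plate effects exactly and
  multiplicative ones approximately (through the denominator); it does
  not model within-plate spatial gradients (no B-score/loess option).
* `alpha` is a user choice; the package provides the distance rule but no
  data-driven selection of the percentile.
* The pooled moderation is not a full empirical-Bayes model; for real
  data a dedicated implementation is preferable.
* Reading starts at well readouts or guide counts; FASTQ processing and
  guide quantification are out of scope.
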