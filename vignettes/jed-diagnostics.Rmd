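---
title: "Measuring numerical dependence in expression summaries with the JED"
author: "jedr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring numerical dependence in expression summaries with the JED}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jedr)
```

## Why numerical dependence matters

Differential-expression tests treat a gene's summaries across arrays as
independent observations. Preprocessing can silently break that assumption:
any step that pools information across arrays — quantile normalization,
cross-array summarization such as median polish, cross-array background
models — makes each array's summary a function of *all* arrays' raw
intensities. The statistical cost of wrongly assuming independence is real:
in the two-group scenario of the last section, a true error correlation of
0.5 roughly halves the power of the naive test.

For almost all preprocessing methods the distribution of the summaries is
unknown, so this dependence cannot be estimated as a correlation. The
Jackknife Expression Difference (JED) instead measures it *numerically*: how
much does a summary move when another array is removed from every step of
the computation? This is a robustness notion, and it is a diagnostic of
preprocessing methods only — not a per-array QC score, not a correlation
proxy, and not an ingredient for inference.

## The statistic

Let `y_i` be a gene's positive log-scale summary on array `i` from the run
over all `A` arrays, and `y_i(-j)` the same summary when array `j` is
excluded from every preprocessing step, with the convention `y_i(-i) = 0`
(an excluded array carries no information about itself). Then

$$\mathrm{JED}_{ij} = \frac{1}{2}\left(\frac{|y_i - y_{i(-j)}|}{y_i} +
\frac{|y_j - y_{j(-i)}|}{y_j}\right).$$

Its properties, each enforced by a unit test:

* symmetric in `(i, j)`, non-negative, and 0 exactly when both leave-one-out
  summaries equal the full-data summaries (strict numerical independence);
* `JED_ii = 1` for every gene and method (forced by the `y_i(-i) = 0`
  convention);
* interpretable as the average percent change in the gene's summary caused
  by including/excluding the pair: summaries `(8, 10)` moving to
  `(6, 7.5)` under mutual exclusion give `JED = 0.25`, an average 25 %
  change;
* scale-equivariant: rescaling `{y_i, y_i(-j)}` and `{y_j, y_j(-i)}` by
  arbitrary positive constants leaves JED unchanged;
* not capped at 1 — relative changes can exceed 100 % and are reported as
  such, not truncated.

The associated distance is taken to be `d_ij = JED_ij` off the diagonal and
0 on it. This is a working assumption (we do not assert the triangle
inequality), recorded here because the exact form of the distance is the one
genuinely open design point in the statistic's definition.

The jackknife driver performs exactly `A + 1` preprocessing runs (full data
plus each leave-one-out subset) and caches them, so every pair `(i, j)`
reuses the runs excluding `j` and `i`. `run_jackknife()` accepts any method
satisfying the subset contract `f(data, arrays) -> expression_matrix`, and
`read_external_jackknife()` lets you compute JED for full + leave-one-out
summary matrices produced by any tool outside the package.

## The reset rule and sign-change banding

Some methods (PLIER, PUMA) can emit negative summaries. We treat a
non-positive raw summary as showing very little evidence of expression and
reset it to the smallest positive raw summary observed for all genes on
that array (the array's *floor*); each jackknife run applies the rule with
its own floors. JED is computed on post-reset values (so its denominators
are positive); sign-change counting uses the raw ones.

The reset creates a recognizable artifact. If excluding array `j` flips the
sign of `y_i`'s raw summary, the reset maps it to a floor `ε` that is tiny
relative to `y_i`, and the affected half-term becomes
`|y_i − ε| / y_i ≈ 1`, contributing ≈ 1/2 to JED; two flips drive JED ≈ 1.
A JED-vs-sign-change display therefore bands at 0.5 and 1 for such methods.
`gen_sign_change_fixture()` constructs fixtures realizing 0, 1 or 2 flips
with a pinned floor; at floor 1e-6 and summaries of 8 the package reproduces
the limits to within 1e-3 (`0.4999999…`, `0.9999999…`).

## MINDEP: a reference method with known covariance

To relate numerical dependence to honest statistical dependence we need a
method whose summary covariance is known. MINDEP is contrived for exactly
that purpose (we do not recommend it for analysis). Per gene, on the
balanced probes × arrays layout, it fits by OLS the two-way model

$$x_{pi} = \mu_i + \beta_p + \varepsilon_{pi},$$

takes the per-array LSMEAN (array effect plus average probe effect — the
gene's column mean in the balanced case), and summarizes

$$y_i = \mathrm{LSMEAN}_i - \lambda \min_k \mathrm{LSMEAN}_k,
\qquad \lambda \in [0, 1].$$

The subtraction acts as a pseudo background correction; because the minimum
is shared, any λ > 0 couples the arrays and larger λ couples them more. Each
summary is a linear form `c_i' θ̂` (with `c_i` = the LSMEAN coefficient
vector of array `i` minus λ times that of the minimizing array), so

$$\mathrm{Cov}(y_i, y_j) = c_i'\,\hat\sigma^2 (X'X)^{-1} c_j$$

from least-squares theory. Implementation choices:

* **Identifiability**: sum-to-zero probe effects by default; a
  reference-level parameterization is provided and the tests verify LSMEANs
  are identical under both.
* **Residual variance**: MSE with `df = N − (A + P − 1)`; degenerate layouts
  (< 2 probes or < 2 arrays) warn. Residual variance below 1e-20 is snapped
  to exact 0 so noise-free data hit the zero-variance conventions.
* **The argmin is treated as fixed** at its observed index. The closed form
  cannot account for the minimizing array switching between hypothetical
  replicates; this is a documented limitation, and the covariance oracle
  test uses well-separated array effects so switching is vanishingly rare.
* **Zero-variance convention**: at λ = 1 the minimizing array's summary is
  identically 0, its variance 0, and its correlations are reported as 0.

At λ = 0 the summary is the array's own column mean: all off-diagonal JED
values and all closed-form correlations are exactly 0 — the package's
strictest independence check, and the jackknife minimum is always taken
over the included arrays only, so the excluded array truly contributes
nothing. The closed form is validated against the empirical covariance of
5,000 simulated replicates (within 3 Monte-Carlo standard errors, for
λ ∈ {0, 0.5, 1}) in the acceptance suite.

One aggregate subtlety: the mean absolute between-array correlation grows
with λ on `[0, 0.9]` (tested), but dips *at* λ = 1, where the minimizing
array's correlations jump from their λ→1 limit (±1/√2) to the 0 assigned by
the zero-variance convention. The monotone-dependence property is therefore
asserted strictly below λ = 1.

## The built-in preprocessing contrast

MAS5, RMA and friends are deliberately **not** reimplemented (nor are CEL
files parsed). Instead two built-in methods realize the properties that
matter for JED:

* `summarize_per_array()` — per-gene, per-array (optionally trimmed) mean of
  log2 PM intensities. Provably local: its summaries are bit-identical no
  matter which other arrays participate, hence JED ≡ 0 off-diagonal. This is
  the independence property MAS5 has.
* `summarize_rma_like()` — quantile normalization over the chosen subset
  (via `limma::normalizeQuantiles`, average-of-tied-ranks ties), then
  per-gene median polish, summary = overall + array effect. Both steps share
  information across arrays, so JED > 0 for some pairs on generic data. This
  is the sharing structure of RMA-style pipelines.

Median polish uses `stats::medpolish` (row-first sweeps) with a cap of 10
iterations and relative tolerance 0.01 on the change in summed absolute
residuals; the decomposition `overall + probe + array + residual` equals the
input exactly at every iteration, so no accuracy is at stake in the stopping
rule. Ties in quantile normalization get the average of the tied ranks.
Inputs are assumed log2 throughout; `probe_data(..., log2_transform = TRUE)`
applies `log2(x + 1)` to raw-scale intensities.

## The power illustration

A deliberately small scenario, not a model of real expression testing: a
two-group comparison with `n` replicates per group whose `2n` errors are
jointly normal with unit-ish variance `sigma2` and a common pairwise
correlation ρ (compound symmetry; eigenvalues `1 + (2n−1)ρ` and `1 − ρ`, so
ρ must exceed `−1/(2n−1)`; the default range is `[0, 1)` with negative ρ
behind an explicit override). The treatment effect `beta1` is defined as the
difference in group means, which makes the power invariant to how the group
column is coded (±1 by default, 0/1 available) — the tests enforce this
invariance, and it is why the coding is a display choice rather than a
modeling one.

Two z-tests of `beta1 = 0` are compared, with variances computed from the
matrix identities rather than transcribed constants:

* **OLS, dependence ignored**: the slope is standardized by
  `sqrt(sigma2·[(X'X)^{-1}]_22)`, but its true sampling variance is the
  sandwich `sigma2·[(X'X)^{-1} X' R X (X'X)^{-1}]_22` with `R` the CS
  correlation matrix. For ρ > 0 the assumed SE is too large: the test is
  conservative (size < α) and under-powered.
* **WLS/GLS, dependence modeled**: variance `sigma2·[(X' R^{-1} X)^{-1}]_22`;
  exact size α for every ρ.

Both closed forms are validated against a 200,000-draw Monte-Carlo oracle
(within 3 binomial SEs at a 3 × 3 grid of scenarios) before being trusted —
the oracle, not a printed formula, is the source of truth here.
`power_grid()` maps the loss `P_wls − P_ols` over (ρ, β₁): it is 0 at ρ = 0,
non-negative for ρ ≥ 0, and grows with ρ at fixed moderate effect size. At
large effects (e.g. β₁ = 2 with n = 4) both powers saturate near 1 and the
gap necessarily closes again, so monotonicity in ρ is asserted only in the
non-saturated regime β₁ ≤ 1.

## Synthetic data: what it emulates, and what it does not

`gen_probe_data()` simulates the additive two-way structure MINDEP assumes:
gene baselines uniform on 4–10 log2 units, array effects evenly spaced over
1 log2 unit, probe effects N(0, 0.5²) centered within genes, iid
N(0, 0.25²) noise, optional group effects on the second half of the arrays;
defaults of 200 genes × 11 probes (a typical probeset size) × 6 arrays. The
layout is exactly balanced and a single seed fixes everything.

This emulates enough structure to exercise every operation in the package,
but real arrays have none of its innocence: intensity-dependent variance,
probe-sequence effects, spatial artifacts, unbalanced/missing probes and
heavy-tailed noise are all absent. Passing tests on these data therefore
demonstrate the *correctness of the computations and their structural
properties* (locality, sharing, closed forms), not the field behaviour of
any real preprocessing method — which is precisely why the JED itself takes
arbitrary external summaries as input.

## Sizes and numerical conventions

The test and acceptance workloads are desk-scale by design: the λ = 0
independence check uses 200 genes × 8 probes × 6 arrays (7 preprocessing
runs, < 1 s); the covariance oracle 5,000 replicates of an 8 × 3 layout; the
power oracle 200,000 draws per scenario at 9 scenarios. Text I/O uses a
fixed dialect (tab-delimited, '.' decimal, 10 significant digits); JED
tables are written gene-major with i < j pairs before the diagonal, and a
flag suppresses the always-1 diagonal as JED displays conventionally do.
Zero raw summaries are treated like negatives by the reset rule; a run in
which some array has no positive summary at all is a fatal error naming the
array; LSMEAN ties for the minimum resolve to the first array in order.
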