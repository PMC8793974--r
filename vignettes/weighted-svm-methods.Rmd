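---
title: "Point-biserial feature weighting for support vector classification: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-biserial feature weighting for support vector classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsvm)
```

## The model

`wsvm` classifies a binary clinical outcome `y ∈ {−1, +1}` from a mixed
table of `p` predictors by a two-stage procedure.

**Stage 1 — relevance weighting.** Each predictor's association with the
outcome is the point-biserial correlation in group-mean form,

$$ r_j \;=\; \frac{\bar X_{+1} - \bar X_{-1}}{S_X}\,
   \sqrt{p_{+1}\,p_{-1}\,\frac{n}{n-1}}, $$

with \(S_X\) the usual \(n-1\)-denominator standard deviation. This is
identical to the Pearson correlation of \(X_j\) against the labels recoded
0/1 — a fact the test suite exploits as an exhaustive oracle. The weights
are the normalised absolute correlations,
\(\omega_j = |r_j| / \sum_k |r_k|\), so \(\omega \ge 0\) and
\(\mathrm{tr}(\mathrm{diag}(\omega)) = 1\), and the classifier is trained
on \(Z = X\,\mathrm{diag}(\omega)\). Signed correlations are kept alongside
the weights because the sign carries direction-of-effect information the
weight discards.

**Stage 2 — RBF-kernel SVM on the weighted data.** The soft-margin dual

$$ \max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{i,j}
   \alpha_i\alpha_j y_i y_j K(z_i, z_j),
   \qquad 0 \le \alpha_i \le C,\; \textstyle\sum_i \alpha_i y_i = 0 $$

with \(K(u,v) = \exp(-\gamma\|u-v\|^2)\) is solved by a
sequential-minimal-optimization (SMO) sweep with maximal-violating-pair
working-set selection, implemented in C++ for this package. The printed
form of the dual in the method's source is hard-margin
(\(\alpha_i \ge 0\) only); we deliberately fit the standard soft-margin
box-constrained dual because real clinical data are not separable — a
hard-margin program would simply fail there, and the cost parameter is
what cross-validation tunes.

Because weighting acts inside the kernel distance,
\(\|Z_u - Z_v\|^2 = \sum_j \omega_j^2 (x_{uj}-x_{vj})^2\), uniform weights
\(\omega_j = 1/p\) at width \(\gamma\) are *algebraically identical* to the
unweighted SVM at width \(\gamma/p^2\). This exact equivalence is asserted
on random data in the suite; it is the cleanest internal consistency check
available for the weighted kernel.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `cost` (C) | soft-margin box constraint (unitless) | 1 | neutral midpoint of the grid; tuned in the full protocol |
| `gamma` (γ) | RBF width (1 / squared feature units) | `1/p` | the `e1071`/libsvm convention the method's original environment used |
| tuning grid | candidate `(C, γ)` | C ∈ 2^{−3,−1,…,9}, γ ∈ 2^{−9,−7,…,1} | log₂ ladder centred on the defaults; the source prints no grid |
| `k` | CV folds for tuning | 10 | matches the stated 10-fold selection |
| `ratio` | training fraction | 0.8 | the 80:20 rule of thumb the source recommends |
| `n_iter` | MCCV iterations | 1000 | the stated protocol; scale down for exploration |

Tie-breaks in tuning go to the smallest `C`, then the smallest `γ` —
smoother, lower-variance models are preferred when CV cannot distinguish
candidates.

Continuous predictors are z-scored with *training-set* statistics before
weighting (configurable off); integer factor codes are left as printed,
since the method computes one biserial correlation per factor on its code
scale and one-hot expansion would change `p` and the weight normalisation.
The correlation itself is invariant to affine rescaling of a predictor, so
standardisation affects only the kernel geometry, not the weights.

## Resampling protocol

`make_split()` stratifies by label and rounds each class's training share
to the nearest integer (half rounds up). On 137/160 class counts at ratio
0.80 this gives 110 + 128 = 238 training and 59 test records — for every
seed, since only membership, not size, is random. `mccv()` derives each
iteration's seed from the master seed and the iteration counter
(`seed * 1000003 + k mod 2³¹−1`), so iteration `k` can be reproduced in
isolation and the whole report is bit-reproducible.

Two leakage-relevant choices are exposed rather than hidden:

* **Weights per split or from the full data.** Computing the weight table
  once on all records mirrors a published full-data table but leaks test
  information into every iteration; the default (`weights_mode =
  "per_split"`) recomputes weights inside each training portion. Both modes
  exist because the original protocol does not state which was used.
* **Tuning nested, once, or off.** `tune_mode = "nested"` re-runs 10-fold
  selection inside every training split (default, no leakage); `"once"`
  tunes a single time on the full data and freezes `(C, γ)`; `"off"` uses
  the configured values. Again both readings of the protocol are available.

Mean indices are arithmetic means of per-iteration indices (matching an
"average over runs" protocol), with a pooled-count alternative reported
alongside. An index with a zero denominator in some iteration — plausible
at 95:5, where test sets hold ~15 patients — is recorded as `NA`, excluded
from that index's mean, and counted in `undefined_counts`; it is never
silently treated as zero.

## The synthetic generator

`synthetic_spec()` emulates the structure the method assumes: `n` records,
a +1 prevalence `class_prob`, continuous features
`x_j ~ Normal(δ_j y/2, 1)` and integer-coded factors drawn from
class-conditional category probabilities. The continuous
parameterisation makes target correlations analytically reachable:
`r = δ√(q(1−q)) / √(1 + δ² q(1−q))` at prevalence `q` (`delta_to_r()` /
`r_to_delta()`), reducing to `r = δ/(2√(1+δ²/4))` for balanced classes.

The defaults are fixed to the Cleveland-like condition: 297 records,
46.1% prevalence, five continuous features whose `δ` are back-computed
from the published correlation magnitudes, and eight factors whose
marginals follow the published frequency table with a between-class tilt
sized to keep the published association ordering (THAL and CA strongest,
FBS essentially null). These defaults are the study condition, not a dial.

What the generator does **not** emulate: correlations *among* predictors
(features are conditionally independent given the class), heavier-tailed
or skewed continuous distributions (cholesterol is right-skewed in
practice), and missingness mechanisms. Tests passing on this generator
therefore demonstrate correctness of the algorithmic pipeline and the
advertised statistical behaviour under the assumed model — not clinical
performance on real angiographic data, which additionally depends on those
unmodelled features.

A note on attainable error: with class means `±δ/2` and unit variance, a
single informative feature at `δ = 3` has Bayes error `Φ(−1.5) ≈ 6.7%`.
"Near-separable" test constructions therefore use two informative features
at `δ = 3` (Bayes ≈ 1.7%) so that a ≤ 5% error bound is actually reachable
by a correct implementation.

## Numerical choices

* SMO stops when the projected-gradient gap `m − M ≤ 1e−8`; the fit errors
  (rather than returning silently) if the gap still exceeds `1e−4` or the
  iteration cap (5·10⁵) is hit.
* Support vectors are the multipliers with `α_i > 1e−8·C`; the bias is the
  mean of the KKT-implied value over *unbounded* support vectors, falling
  back to the midpoint of the violating-pair bounds when all are at the
  box.
* `sign(0) → +1` is the documented deterministic tie rule for the decision
  function.
* A predictor constant within a training sample has undefined correlation;
  inside automatic weighting it receives weight 0 (it carries no
  association information) instead of aborting the resampling iteration.
  Called directly, `point_biserial()` still errors on constant input.
* All-zero correlation vectors (Σ|r| < 10⁻¹⁰) are an error: the weight
  normalisation is undefined there.
* Baseline learners in the comparison harness are seeded per
  (iteration, method) so stochastic baselines (random forest) preserve the
  run-to-run determinism contract.

## Problem sizes used in the checks

The shipped suite exercises: exhaustive label enumeration at n = 5 plus
1,000 randomised draws for the correlation oracle; 50 random dual programs
at n ≤ 8 against an interior-point QP oracle; 20 datasets for the exact
uniform-weight equivalence; 10,000 random confusion matrices for the index
identities; 100 replicates at n = 500, p = 10 for weight-rank recovery;
and a paired 50-iteration MCCV at n = 300 for the weighting-helps
property. These sizes were chosen as the smallest at which each property
is statistically unambiguous.

## Known limitations

* Only binary outcomes; multi-grade angiographic results are dichotomised.
* Missing data are dropped, not imputed (complete-case analysis, as in the
  source protocol).
* Only the RBF kernel path is tuned; other kernels are out of scope.
* No probability calibration and no significance testing between
  classifiers — the comparison harness reports paired mean MER only.
* The weight is a *marginal* association measure: a predictor useful only
  in interaction with others will be down-weighted.
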