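---
title: "Kernel mean embedding regression on EEG spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel mean embedding regression on EEG spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmereg)
```

## 1. Spectra as probability distributions

An EEG power spectrum on one channel assigns non-negative power to each
bin of an equally spaced frequency grid. Divided by its total, it is a
probability distribution over frequency, and `kmereg` commits to that
reading: every downstream quantity treats the bin weights as point masses
at the bin centers.

```{r}
g <- frequency_grid(seq(1.17, by = 0.39, length.out = 47))
s <- rescale_unit_mass(channel_spectrum(rep(1, 47), g))
sum(s$weights)
```

Two practical consequences:

* **Scale invariance.** Overall power (amplifier gain, electrode
  impedance) cancels; only the *shape* of the spectrum matters.
* **A principled distance.** Distances between subjects become distances
  between distributions, for which the kernel mean embedding framework
  provides a complete, computable theory.

## 2. The MMD and its estimators

Given an *inner kernel* $k(\cdot,\cdot)$ on frequency values, each
distribution $P$ embeds as $\mu_P = \mathbb{E}_{x\sim P}[k(x,\cdot)]$ in
the kernel's RKHS, and the **maximum mean discrepancy** is
$\mathrm{MMD}(P,Q) = \lVert \mu_P - \mu_Q \rVert$. For distributions
supported on the grid, the embedding never has to be materialised; with
$K_{ab} = k(f_a, f_b)$ and bin weights $w, v$:

$$
\mathrm{MMD}^2(P, Q) = w^\top K w + v^\top K v - 2\, w^\top K v
  = (w - v)^\top K (w - v).
$$

`mmd_squared_weighted()` implements this closed form. The estimator is the
**biased V-statistic**: when a distribution is represented by samples, the
within-sample double sums include the self-pairs $k(x_i, x_i)$. We keep
that convention because it is what the quadratic form above computes, and
it guarantees $\mathrm{MMD}^2 \ge 0$ (the expression is a squared norm).
An unbiased U-statistic variant, which subtracts the self-pairs and can go
negative, is available in sample mode (`u_statistic = TRUE`).

### Deterministic sampling

Sample mode makes the "distribution of samples" reading literal:
`deterministic_sample()` converts a unit-mass spectrum into $n$ samples at
the bin centers, so a bin of height 0.2 receives $0.2\,n$ samples. When
the targets $n\,w_b$ are fractional, counts are apportioned by the
largest-remainder (Hamilton) rule — floor every target, then hand the
leftover samples to the largest fractional remainders, ties toward lower
frequency — so counts always sum to exactly $n$:

```{r}
sp <- channel_spectrum(c(0.5, 0.2, 0.3), frequency_grid(c(8, 10, 12)))
deterministic_sample(sp, 1000)$counts
```

The count-weighted sample estimator coincides with the closed form exactly
whenever all $n\,w_b$ are integers, which the test suite checks against a
brute-force expansion of the double sums.

### Why the MMD is a metric here

With a characteristic inner kernel (the RBF is characteristic), the
embedding is injective, so the MMD is a genuine metric: zero iff the
distributions agree, symmetric, and satisfying the triangle inequality.
With the linear inner kernel $k(x,z) = xz$ the embedding collapses to the
mean, and the MMD degenerates to $|\mathbb{E}_P f - \mathbb{E}_Q f|$ — a
useful sanity oracle, and a reminder that the inner kernel decides *which*
spectral differences are visible.

## 3. The outer kernel and the regression

Subject-by-subject distances $D_{ij}$ feed an outer RBF kernel, and the
trait is predicted by dual-form (kernel) ridge regression:

$$
K^{(o)}_{ij} = \exp(-\gamma D_{ij}^2), \qquad
\beta = (K^{(o)} + \alpha I)^{-1}(y - \bar y), \qquad
\hat y_t = \textstyle\sum_i \beta_i K^{(o)}_{ti} + \bar y .
$$

Two conventions deserve a note, because sign and centering errors here are
easy to make and hard to see:

* **The exponent is negative.** $\exp(-\gamma D^2)$ is the only
  orientation under which the kernel is a similarity (unit diagonal,
  values in $(0,1]$) and positive semidefinite for a Hilbertian metric
  such as the MMD; the positive orientation diverges with distance and is
  not a kernel. `outer_kernel()` hard-codes the negative sign.
* **Targets are centered, and the system is solved, not inverted.**
  `fit_dual_ridge()` solves $(K + \alpha I)\beta = y - \bar y$ by a
  Cholesky factorisation and restores $\bar y$ at prediction. Centering
  plays the role of an unpenalised intercept: without it, ridge shrinkage
  pulls predictions toward zero rather than toward the mean trait, which
  is visibly wrong for targets like age. The same centering is what makes
  primal ridge on centered features exactly equal to the dual solution
  with $K = X_c X_c^\top$ — an identity the tests exploit.

The three predictors share this machinery:

| method | distance | regression |
|---|---|---|
| `kmer` | MMD between spectra-as-distributions | dual ridge on $\exp(-\gamma D^2)$ |
| `krr`  | Euclidean between bin-power vectors  | same dual ridge |
| `rr`   | — | primal linear ridge on bin powers |

Configuring KMER with Euclidean feature distances
(`options = list(distance = "euclidean")`) reproduces KRR exactly, which
pins down that the two differ *only* in the metric.

## 4. Site-grouped nested cross-validation

Acquisition sites differ in hardware, preprocessing and — crucially — age
demographics. The evaluation protocol therefore never splits a site: outer
folds hold out whole sites (`leave-site-out`, or whole-site `grouped-k-fold`),
and hyperparameters are chosen on **inner folds built from the
outer-training sites only**, by minimum inner mean absolute error in years
(ties prefer smaller $\alpha$, then smaller $\gamma$). When an outer
training set retains fewer than two sites, inner selection falls back to
subject-level k-fold with a warning. Every subject receives exactly one
out-of-sample prediction, and scores are pooled over all of them.

One deliberate deviation from a fixed bandwidth grid: the $\gamma$ grid is
decade-spaced but **relative**, rescaled per training fold by the median
squared training distance (the median heuristic). MMD distances between
unit-mass spectra live on scales of $10^{-2}$–$10^{-1}$ while Euclidean
feature distances live elsewhere; a literal shared grid would silently
favour one method. `gamma_scale = "none"` restores the literal grid.

```{r}
cfg <- synth_config(n_per_site = 25L, channels = c("C3", "O1", "Cz"), seed = 2L)
co <- rescale_cohort(exclude_channels(simulate_cohort(cfg)$cohort, "Cz"))
plan <- make_site_folds(co, "leave-site-out")
res <- nested_cv_fit_predict(co, "C3", "kmer", plan)
res$metrics[c("r2", "mae")]
res$fold_summary[, c("test_sites", "alpha", "gamma_grid", "test_mae")]
```

## 5. Delta, bias correction, and what "corrected" means

The brain-age **delta** $\hat y - y$ is the quantity of scientific
interest, but ridge-type predictors systematically over-predict young and
under-predict old subjects (shrinkage toward the mean). `bias_correct()`
fits the training residual on chronological age, $r = a + b\,y$, and adds
the fitted trend into the test predictions:
$\hat y' = \hat y + a + b\,y_\text{test}$. After correction the training
residual is exactly orthogonal to age.

The caveat is intrinsic: the correction *uses the test subject's
chronological age*. Corrected values are therefore age-orthogonalised
deltas for association analyses — not blind predictions — and the package
reports corrected metrics alongside, never instead of, the raw ones.

`log_space = TRUE` fits $\log y$ and exponentiates predictions back, which
helps when errors scale multiplicatively with age.

## 6. Comparing methods: paired sign-flip permutation test

Per-channel scores of two methods are paired (same channels, same
subjects). `permutation_test_paired()` tests the mean paired difference by
independently sign-flipping the per-channel differences; with $C$ channels
the achievable two-sided p-value is floored by the $2^{-C}$ enumeration
scale, and the reported value uses the add-one form
$p = (1 + \#\{|T_\pi| \ge |T_\text{obs}|\})/(1 + n_\text{perm})$, which is
valid (never anti-conservative) at any $n_\text{perm}$.

## 7. The synthetic cohort generator

`simulate_cohort()` draws seeded cohorts from the field-standard spectral
decomposition — an aperiodic $b f^{-\chi}$ component plus a Gaussian
alpha-like peak — with age entering through a saturating map
$u = \text{age}/(\text{age} + a_\text{sat})$ (steeper change in youth):

* the peak center slows, $\mu(u) = \mu_0 - \text{pace}\cdot s_\mu u$;
* the peak amplitude declines, $A(u) = A_0 (1 - s_A u)$, scaled by a
  posterior-dominant channel gain;
* the aperiodic exponent flattens, $\chi(u) = \chi_0 - \text{pace}\cdot
  s_\chi u$, **and varies between subjects** (`chi_sd`).

That last item is the design decision worth explaining. With a single
smooth latent (a moving peak), a linear model on bin powers can assemble a
serviceable bump basis and nearly match the kernel methods, which would
make the generator useless for telling the methods apart. Individual
variability of the 1/f exponent is a documented EEG phenomenon, and adding
it creates a realistic nuisance dimension that distribution-level methods
absorb gracefully while bin-level linear regression does not — on the
default scenario, leave-site-out $R^2$ orders as KMER > KRR > RR with the
kernels above 0.7. Sites impose multiplicative spectral tilts and strongly
different age ranges; `make_prior_shift_scenario()` pushes the latter to
the extreme of disjoint young/old sites, where within-site accuracy beats
cross-site accuracy — the signature of prior shift.

Sexes age at the same pace by default. `sex_slope_mult > 1` gives males a
faster spectral trajectory; note that large multipliers also make the
pooled cohort intrinsically harder (two spectrum-age maps in one fit), and
if the male peak slides below the alpha-sensitive band its extra per-year
signal saturates, so the male-accuracy advantage is only observable when
the doubled trajectory stays on-grid.

What the synthetic experiments do show: estimator correctness, protocol
guarantees, method ordering under a controlled nuisance structure, and
prior-shift behaviour. What they do not show: accuracy on real EEG, for
which the generator is far too kind.

## 8. Problem sizes and costs

Everything is dense linear algebra on $N \times N$ matrices. The MMD
distance matrix for one channel costs one $B \times B$ Gram plus two
matrix products ($O(N B^2 + N^2 B)$); nested leave-site-out CV over a
$7 \times 6$ grid on $N = 400$, $B = 47$ runs in about a second per
method on one CPU. Distance matrices are cached in memory, keyed by
spectra content and kernel settings, so cross-validation folds and CLI
reruns never recompute them.

## 9. Limitations

* Bin values are point masses at bin centers; no within-bin smearing, and
  grids must align exactly (heterogeneous cutoffs are truncated, not
  interpolated).
* Single-channel models only; no cross-channel pooling beyond running
  channels separately and comparing with the permutation test.
* The bias correction is leakage-free for *deltas* but must not be read
  as improving blind prediction.
* Synthetic recovery numbers are properties of the generator, not claims
  about real-data accuracy.
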