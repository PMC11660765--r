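# kmereg — kernel mean embedding regression for EEG spectra

`kmereg` predicts scalar subject traits — chiefly chronological age — from
single-channel EEG power spectra. Its central idea is to stop treating a
power spectrum as a feature vector and instead treat it as what it
physically is once rescaled to unit mass: a **probability distribution over
frequency**. Distances between subjects are then distances between
distributions, computed with the kernel mean embedding machinery, and
prediction is kernel ridge regression on those distances.

## The method in brief

For subject $i$, the spectrum on one channel is a set of non-negative
weights $w_{i}$ over a common frequency grid $f_1 < \dots < f_B$, rescaled
so $\sum_b w_{ib} = 1$. With an *inner kernel* $k(\cdot,\cdot)$ on raw
frequencies (default: RBF, $k(x,z) = e^{-\gamma_\text{in}(x-z)^2}$), the
squared **maximum mean discrepancy** between two spectra reduces to a
quadratic form in the bin weights:

$$
\mathrm{MMD}^2(P_i, P_j) \;=\; w_i^\top K w_i + w_j^\top K w_j
  - 2\, w_i^\top K w_j,
\qquad K_{ab} = k(f_a, f_b).
$$

This is the biased V-statistic form of the empirical estimator
(self-pairs included); an unbiased U-statistic variant is available in
sample mode. A spectrum can also be expanded into $n$ deterministic
samples at the bin centers — a bin of height 0.2 receives $0.2\,n$
samples, with fractional targets apportioned by the largest-remainder
rule — and the count-weighted estimator on those samples coincides with
the closed form whenever $n\,w_{ib}$ are integers.

The subject-by-subject distance matrix $D$ feeds an *outer* RBF kernel
$K^{(o)} = \exp(-\gamma D^2)$ (positive semidefinite because the MMD is a
Hilbertian metric), and predictions come from dual-form ridge regression:

$$
\beta = (K^{(o)} + \alpha I)^{-1} (y - \bar y), \qquad
\hat y_t = \sum_i \beta_i\, K^{(o)}(t, i) + \bar y .
$$

Two baselines share the pipeline: **KRR** (the same dual machine on
Euclidean distances between bin-power vectors) and **RR** (linear ridge on
bin powers). Hyperparameters $(\alpha, \gamma)$ are selected by **nested
cross-validation that never splits acquisition sites**: outer folds hold
out whole sites (leave-site-out by default) and inner folds are built from
the outer-training sites only. The outer bandwidth grid is relative — it
is rescaled per training fold by the median squared training distance — so
one decade grid serves distance matrices of any scale.

Also included: brain-age **delta** ($\hat y - y$) with post-hoc
residual-on-age **bias correction**, **paired sign-flip permutation
tests** for method comparisons across channels, and a seeded
**synthetic-cohort generator** (1/f aperiodic component plus an
age-slowing alpha peak, site-level spectral tilt and prior shift,
optional sex-dependent ageing pace).

## Worked example

```r
library(kmereg)

cfg <- synth_config(seed = 1L)              # 4 sites x 100 subjects, ages 5-90
sim <- simulate_cohort(cfg)
co  <- rescale_cohort(exclude_channels(sim$cohort, "Cz"))  # drop reference

plan <- make_site_folds(co, "leave-site-out")
res  <- nested_cv_fit_predict(co, "C3", "kmer", plan)
res
#> KMER on channel C3 (leave-site-out): R^2 = 0.789, MAE = 7.28 over 400 subjects

head(res$predictions[, c("subject_id", "site", "age", "y_pred", "delta")], 3)
#>  subject_id   site  age   y_pred     delta
#>       S0001 site_A 14.3 27.62324 13.323242
#>       S0002 site_A 18.0 23.07853  5.078532
#>       S0003 site_A 25.0 26.68538  1.685381

nested_cv_fit_predict(co, "C3", "rr", plan)
#> RR on channel C3 (leave-site-out): R^2 = 0.657, MAE = 9.64 over 400 subjects

subgroup_eval(res, "site")
#>   group   n        r2      mae
#>  site_A 100 0.3004488 5.783894
#>  site_B 100 0.7091316 5.694305
#>  site_C 100 0.3558922 9.571918
#>  site_D 100 0.7932969 8.057481
```

The per-site drop relative to the pooled R² is the expected signature of
site-level **prior shift**: each site's age distribution is unseen during
training, so cross-site predictions are pulled toward the training sites'
age ranges.

## Command-line interface

A thin CLI wraps the same functions (installed at
`system.file("cli", "kmereg", package = "kmereg")`):

```sh
kmereg simulate --out bundle --seed 7 --n-per-site 100
kmereg distances --bundle bundle --out dist --channels C3,O1
kmereg evaluate  --bundle bundle --out results --method kmer,krr,rr --channels C3
kmereg report    --results results
```

`evaluate` writes tidy per-subject `predictions.csv`, a versioned
`summary.json` and a `run.log` recording the seed, grids, fold assignments
and per-fold selected hyperparameters. Options resolve as command-line
flag > `--config` file (JSON/YAML) > default, and identical invocations
produce identical output files.

## Design notes and limitations

- The outer kernel is written $\exp(-\gamma D^2)$ and the dual solve uses
  the regularised inverse with mean-centered targets; see the methods
  vignette (`vignettes/kmer-methods.Rmd`) for why these sign/centering
  conventions are the consistent ones.
- Bias-corrected predictions use the test subject's chronological age and
  are therefore corrected *deltas* for association analyses, not blind
  predictions.
- Synthetic cohorts are a controlled testbed for protocol and estimator
  properties — recovery numbers on them say nothing about accuracy on
  real EEG.
- Spectra must share one equally spaced frequency grid; heterogeneous
  cutoffs are handled by truncation to the lowest common maximum
  (`truncate_common_grid()`), not by interpolation.
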