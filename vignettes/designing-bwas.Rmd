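---
title: "Designing brain-wide association studies: the accuracy scaling law, its validation, and cost optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing brain-wide association studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwasplan)
library(dplyr)
```

## The problem

Brain-wide association studies (BWAS) predict individual phenotypes
(cognition, mental health, physical traits) from functional connectivity
(FC) — the matrix of Pearson correlations between parcel-level fMRI time
courses. Two resources drive prediction accuracy: the number of training
participants $N$ and the scan time per participant $T$, which controls how
precisely each participant's FC is estimated. Because every participant
carries a fixed overhead cost (recruitment, testing, other modalities) on
top of the per-minute scanner cost, $N$ and $T$ are economically
asymmetric, and a study designer must trade them off deliberately.

## The accuracy scaling law

The package is built around a closed-form model of expected prediction
accuracy (Pearson's correlation between predicted and observed phenotype):

$$
E(\hat\rho) \;\approx\; K_0\sqrt{\frac{1}{1 + K_1/N + K_2/(NT)}}
$$

* $K_0 \in (0, 1]$ is the asymptotic accuracy with unlimited data. It is
  bounded by 1 because it is itself a correlation, attenuated by
  phenotypic reliability.
* $K_1 \ge 0$ (participants) scales the sample-size-limited error: the
  uncertainty of the regression-coefficient estimate and of the average
  prediction, both of which shrink as $1/N$.
* $K_2 \ge 0$ (participant·minutes) scales the error due to FC
  measurement noise, whose variance shrinks as $1/T$ per participant and
  therefore as $1/(NT)$ in aggregate.

Two structural consequences matter for design. When $T$ is small the
$K_2/(NT)$ term dominates and accuracy depends on $N$ and $T$ almost only
through the total scan duration $NT$ — sample size and scan time are
interchangeable, and accuracy grows linearly in $\log_2(NT)$ (the
companion *logarithmic model* `fit_logarithmic()`,
$y = z\,\log_2(NT) + k$, fitted only up to a scan-time cap, 20 min by
default, beyond which it breaks down). As $T$ grows, FC reliability
saturates, the $K_1/N$ term takes over, and sample size becomes strictly
more valuable: at fixed $NT$, accuracy is strictly decreasing in $T$
whenever $K_1 > 0$ (`iso_duration_slice()`).

### Fitting

`fit_theoretical()` minimizes the mean squared error between the law and
the repetition-averaged accuracy of each $(N, T)$ cell. The surface can be
multi-modal for noisy grids, so the optimizer is a bounded quasi-Newton
(L-BFGS-B) on transformed parameters — $K_0$ box-bounded in $(0, 1]$,
$K_1$ and $K_2$ on the log scale — restarted from 20 seeded
Latin-hypercube points plus a moment-matching warm start (for positive
accuracies, $(K_0/y)^2 - 1$ is linear in $1/N$ and $1/(NT)$, giving
starting values by least squares). Fits are deterministic given the seed;
on noiseless model-generated grids all three parameters are recovered to
better than $10^{-3}$ relative error, and the tests verify the optimizer
is at least as good as a dense brute-force parameter grid. A grid of
identical accuracies is returned as $K_1 = K_2 = 0$, $K_0$ equal to that
value and $R^2 = 1$: the law is then exact, and this convention avoids a
0/0 in the coefficient of determination. Error terms that converge to the
lower bound of the log transform (below $10^{-8}$) are snapped to zero.

Goodness of fit is the coefficient of determination
$1 - SS_{res}/SS_{tot}$ (`cod()`). Model comparison across phenotypes uses
a two-sided paired Wilcoxon signed-rank test (`compare_model_fits()`); the
association between fit quality and predictability uses Spearman's rank
correlation with a seeded permutation p-value (1,000 label shuffles by
default, `adherence_correlation()`). Before fitting, phenotypes can be
screened by predictability (`filter_phenotypes()`): the primary rule keeps
phenotypes whose best cell exceeds $r = 0.1$; the looser rule keeps those
positive in at least 90% of cells.

## Design surfaces and cost optimization

Because $K_0$ cancels, each fitted phenotype yields a *fraction of
maximum achievable accuracy* at any recruited sample size and scan time
(`fraction_of_max()`); `design_surface()` averages these fractions,
unweighted, across phenotypes. The surface is stored analytically (the
fits themselves), so contours and optima need no interpolation. The
default assumes tenfold cross-validation: accuracy is evaluated at the
training size $0.9\,N$ while costs are charged on the recruited $N$.

The cost model is $(T/60 \times S + O) \times N$ with scanner cost $S$
per hour and per-participant overhead $O$. Two optimizers are provided:

* `optimize_within_budget()` walks $T$ over a grid (1–200 min in 1-min
  steps by default), buys $N = \lfloor B /(T/60 \cdot S + O)\rfloor$
  participants at each $T$, and maximizes the surface fraction, breaking
  ties toward shorter scans.
* `optimize_for_target()` samples the iso-accuracy contour of a target
  fraction (`contour_sample()`; for a single phenotype the closed form
  $N = (K_1 + K_2/T)/(f\,(1/\text{target}^2 - 1))$ is used, for averaged
  surfaces a monotone bisection to 0.01 participant) and minimizes study
  cost along it, rounding $N$ up to whole participants at costing time.

Scenario analyses cross the per-dataset surfaces with 12 conditions —
targets $\{0.80, 0.90, 0.95\}$, $O \in \{500, 1000\}$, $S \in
\{500, 1000\}$ per hour (`scenario_conditions()`). Cost inefficiency at a
fixed scan time is $\text{cost}(T)/\text{cost}(T_{opt}) - 1$ per scenario,
averaged across scenarios; the curve is also reported normalized by
subtracting its minimum, so the best fixed scan time sits at zero
(`cost_inefficiency_curve()`). Savings relative to a reference scan time
(10 min by default) are $100(1 - \overline{\text{cost}(T)/
\text{cost}(T_{ref})})$. The fixed-time grid is 5–100 min in 5-min steps.
Uncertainty in the most cost-effective fixed time is bootstrapped by
resampling phenotypes with replacement within each dataset (1,000
replicates and a percentile 95% interval by default,
`bootstrap_best_fixed_time()`); the resampling unit is a documented
assumption, since nothing finer is identifiable from fitted surfaces
alone.

Raising the overhead never shortens, and raising the scan cost never
lengthens, the optimal scan time; both monotonicities are asserted in the
tests. The inefficiency curves are asymmetric around their minimum —
overshooting the optimum is cheaper than undershooting it — because the
contour's $N$ explodes as $T$ falls while cost grows only linearly as $T$
rises.

## The synthetic cohort generator

No public individual-level imaging data can ship with a package, so every
engine is validated on synthetic cohorts (`cohort_config()`,
`generate_cohort()`) that embody exactly the structure the law assumes:

* **True FC.** Each subject has a true edge vector, drawn i.i.d. with sd
  `edge_signal_sd` (default 0.1, the order of between-subject FC edge
  variability). Optionally a low-rank latent factor structure
  (`n_edge_factors`, `edge_factor_share`) gives edges the shared
  covariance that real FC networks have; this is off by default and used
  where spatial structure matters (see reliability below).
* **Observation noise.** In the default `direct_noise` mode, observing at
  scan time $T$ adds Gaussian noise of variance `obs_noise_sd`$^2/T$
  (default 0.12 per $\sqrt{\text{minute}}$, matching the sampling sd of a
  Pearson correlation over one minute of TR-0.8 s data). Noise is drawn
  per physical run and combined time-weighted, so the $1/T$ law holds
  exactly while run order remains meaningful. The `time_series` mode
  instead synthesizes stationary Gaussian parcel series from a
  subject-specific factor-model correlation matrix and computes Pearson
  FC from the first $T$ minutes — this mode exists to validate the $1/T$
  assumption itself (the empirical edge sd matches the Fisher
  approximation $(1-\rho^2)/\sqrt{\text{frames}}$).
* **Phenotype.** A sparse weight vector over edges (density 0.2 by
  default), rescaled so the noise-free linear part has unit variance;
  additive noise with sd 0.75 then fixes the population brain–phenotype
  correlation at $1/\sqrt{1 + 0.75^2} \approx 0.8$, a deliberately
  optimistic but attainable asymptote.
* **Structure.** Contiguous sibling blocks (`family_block_size`), site
  assignments with optional additive site effects, and 4 runs of 5
  minutes at TR 0.8 s by default. Fifty parcels (1,225 edges) keep
  kernel computations at desk scale.

What the generator does **not** emulate: haemodynamics, motion and
physiological artifacts, censoring, non-Gaussian phenotypes, heavy-tailed
edge distributions, and realistic network topology. Passing tests
therefore show that the estimators and optimizers behave as designed
*when the generative assumptions hold* — they are evidence about the
software and the theory's internal consistency, not about any particular
empirical dataset.

### Non-stationarity

Arousal drifts across an fMRI session, so FC computed from early minutes
can differ systematically from late minutes. `inject_nonstationarity()`
models this as a transient per-run "state" disturbance of the generative
edges whose amplitude ramps with the run's position in the session (first
run clean, last run at `drift_sd` times the signal sd). In acquisition
order the effective measurement noise then *grows* with $T$, violating
the law; after per-subject run-order randomization
(`randomize_run_order()`) the disturbed minutes are exchangeable and the
extra noise again scales as $1/T$, so the law fits better
(`randomized_run_fit_change()`). An earlier design — a fixed shared
offset direction scaled per subject — was abandoned because a rank-one,
phenotype-orthogonal shift measurably does not move kernel-ridge
accuracy; the per-run transient design reproduces the phenomenon while
keeping drift-free cohorts untouched. The randomized analysis draws a
single randomization realization per analysis rather than re-drawing per
cross-validation split: re-drawing would average observation noise over
realizations and spuriously improve the fit even for stationary cohorts
(a +0.04–0.08 $R^2$ bias at desk scale), which a single realization
removes.

## The prediction engine

`nested_cv_accuracy()` reproduces the study workflow at desk scale: folds
that never split sibling blocks (greedy largest-first balancing of family
blocks), or leave-$p$-site-clusters-out splits built by greedy
size-balanced packing of sites into clusters; within each repetition the
test split is fixed while the training complement is subsampled to each
requested size, so accuracies are comparable across training sizes; the
predictor is kernel ridge regression with a correlation kernel between FC
feature vectors (or linear ridge regression), with the regularization
strength selected by inner k-fold cross-validation over 16 log-spaced
values in $[10^{-4}, 10^4]$; accuracy is reported as Pearson's
correlation and as COD with the training-mean null predictor,
$1 - \sum(y - \hat y)^2/\sum(y - \bar y_{train})^2$. Optional site
regression residualizes the phenotype on training-set site means and
applies those means to the test set (unseen sites fall back to the
training grand mean). KRR with a linear kernel and LRR are exact duals at
matched regularization — the tests assert their predictions agree to
$10^{-8}$ — and for that identity the features enter uncentered, with the
intercept carried by the training phenotype mean.

Supporting statistics: the Haufe transform (`haufe_transform()`, the
feature–prediction covariance across training subjects, which converts
decoding weights into encoding-direction activations), the corrected
resampled t-test (`corrected_resampled_ttest()`, variance inflated by
$1/J + n_{test}/n_{train}$ to account for overlapping CV training sets),
and Benjamini–Yekutieli FDR control (`by_fdr()`, the step-up rule with
the harmonic-sum correction, delegated to `stats::p.adjust`).

## Split-half reliability

`reliability_experiment()` measures how reliable edge-level BWAS
statistics are at a given half-sample size and scan time: subjects are
split into two disjoint halves; each half yields either the univariate
edge t-statistics ($t = r\sqrt{(n-2)/(1-r^2)}$,
`univariate_edge_stats()`) or the Haufe activation pattern of a predictor
trained on that half; agreement between the halves is the one-way
random, single-measurement intraclass correlation
$(MS_{between} - MS_{within})/(MS_{between} + MS_{within})$ over edges
(`split_half_icc()`), a form that penalizes mean offsets between halves —
a consistency-type ICC is available via `type = "consistency"` since the
literature does not pin the variant down. Degenerate (zero-variance)
edges are dropped pairwise with a reported count.

Reliability grids are nondecreasing in both half size and scan time, with
diminishing scan-time returns, mirroring the accuracy law. The
Haufe-pattern advantage over univariate maps only exists when edges share
covariance structure — with independent edges the multivariate pattern
has nothing to pool, and simulation shows the advantage vanishes or
reverses — so the reliability experiments use factor-structured cohorts
(10 latent factors carrying 60% of edge variance).

## Numerical choices and problem sizes

All stochastic functions take explicit seeds and restore the caller's RNG
state; the same seed reproduces outputs bit-for-bit. Ties in both
optimizers break toward shorter scans. Contour bisection stops at 0.01
participant; $N$ is kept real-valued until costing, where it is rounded
up. The self-validation experiments run at deliberately modest sizes
chosen once: the end-to-end accuracy grid uses a 900-subject, 50-parcel
cohort (6 runs × 5 min), training sizes 100–800, $T \in \{2, 5, 10, 20,
30\}$ min, 10 repetitions with 3 test folds each and 5 inner folds; the
noise-response experiment uses 520-subject cohorts at three noise levels;
the run-randomization experiment uses twenty 400-subject cohorts with
drift amplitude 3 and a single fixed regularization ($\lambda = 10$) so
hyperparameter-selection noise does not swamp the fit-quality contrast;
reliability grids use a 500-subject cohort with 50 split repetitions. At
these sizes the full validation runs in minutes on one core while leaving
the qualitative phenomena (law adherence, $K_2$–noise response,
randomization gain, ICC monotonicity) clearly resolved.

## Known limitations

* The law models expected accuracy; its fit degrades for poorly predicted
  phenotypes, where accuracy grids are dominated by sampling noise — on
  real data, fit quality and predictability are strongly associated, and
  the same pattern appears in simulation as noise levels rise.
* Surfaces extrapolate the fitted law beyond the observed $(N, T)$ range
  by construction; conclusions far outside the fitted range inherit the
  model's assumptions, not the data's support.
* Cost optimization ignores currency effects, multi-site cost
  heterogeneity, and attrition beyond a simple recruitment-inflation
  factor (`expected_usable_fraction` in the CLI configuration).
* The synthetic generator's stationary, Gaussian, linear world is a
  best-case regime; empirical deviations (non-stationarity being the one
  deliberately modelled) generally lengthen the scan time needed for a
  given FC precision.
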