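# bwasplan

Sample-size and scan-time planning for brain-wide association studies
(BWAS) that predict individual phenotypes from fMRI functional
connectivity (FC).

## The problem and who this is for

A BWAS designer must split a budget between recruiting more participants
(`N`) and scanning each participant longer (`T`). Longer scans estimate
each participant's FC more precisely; more participants pin down the
FC-phenotype relationship. Because every participant also carries a fixed
overhead cost (recruitment, neuropsychological testing, other
modalities), the two resources are economically asymmetric. This package
is for investigators planning such studies and for methodologists
studying the trade-off.

## The model at the core

Expected phenotypic prediction accuracy (Pearson's correlation) follows
the scaling law

```
E(rho) ≈ K0 * sqrt( 1 / (1 + K1/N + K2/(N*T)) )
```

with asymptotic accuracy `K0`, a sample-size-limited error term `K1/N`
and an FC-measurement-noise term `K2/(N*T)`. For short scans the `NT`
term dominates and accuracy rises linearly in `log2(N*T)` — sample size
and scan time are interchangeable; for long scans FC reliability
saturates and sample size wins. The package fits this law (and the
companion logarithmic model `y = z*log2(N*T) + k`) to long-form accuracy
tables, converts fits into fraction-of-maximum-accuracy design surfaces,
and optimizes designs under a cost model `(T/60 * S + O) * N` (scanner
cost `S` per hour, overhead `O` per participant): maximum accuracy within
a budget, or minimum cost for a target accuracy, with cost-inefficiency
and savings curves and a bootstrap CI for the most cost-effective fixed
scan time.

Everything is validated end to end on synthetic cohorts: a generator
produces subject-level FC features whose estimation noise shrinks as
`1/T`, a linear phenotype, sibling blocks, sites, multi-run sessions and
injectable run-level non-stationarity; a kernel/linear ridge regression
engine with family-aware nested cross-validation turns cohorts into
accuracy grids; split-half reliability (ICC) of univariate edge maps and
Haufe activation patterns completes the picture.

## A worked example

```r
library(bwasplan)

# an accuracy table lying exactly on the law (in practice: read_accuracy_table())
grid <- tidyr::expand_grid(n_train = seq(100, 700, 100), t_min = seq(2, 58, 4)) |>
  dplyr::mutate(dataset = "demo", phenotype = "cognition", metric = "pearson",
                accuracy = theoretical_accuracy(n_train, t_min, 0.5, 50, 500))

fits <- fit_theoretical(grid)
glance(fits)
#> # A tibble: 1 × 6
#>   dataset phenotype metric     r2 converged n_cells
#>   <chr>   <chr>     <chr>   <dbl> <lgl>       <int>
#> 1 demo    cognition pearson     1 TRUE          105

surface <- design_surface(fits, train_fraction = 0.9)
optimize_within_budget(surface, budget = 1e6,
                       scan_cost_per_hour = 500, overhead_per_participant = 500)
#> # A tibble: 1 × 4
#>   t_min n_recruited fraction   cost
#>   <dbl>       <dbl>    <dbl>  <dbl>
#> 1    24        1428    0.974 999600

optimize_for_target(surface, 0.9, scan_cost_per_hour = 500,
                    overhead_per_participant = 500)
#> # A tibble: 1 × 6
#>   target_fraction scan_cost_per_hour overhead_per_participant optimal_t_min optimal_n min_cost
#>             <dbl>              <dbl>                    <dbl>         <dbl>     <dbl>    <dbl>
#> 1             0.9                500                      500            26       328  235067
```

Reading the output: with a US$1M budget at these rates, the best design
scans 1,428 recruits for 24 min each, reaching 97.4% of this phenotype's
maximum achievable accuracy; conversely, 90% of the maximum can be had
for about US$235,000 by scanning 328 recruits for 26 min. `autoplot(surface)`
draws the design surface with its iso-accuracy contours,
`contour_sample()` extracts them, and `cost_inefficiency_curve()` /
`savings_vs_reference()` / `bootstrap_best_fixed_time()` summarize whole
scenario grids. A command-line front end covering the same operations
ships at `inst/cli/bwasplan` (see `bwasplan --help`).

The methods vignette (`vignettes/designing-bwas.Rmd`) documents the
model, the synthetic-cohort generator and all numerical choices.

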