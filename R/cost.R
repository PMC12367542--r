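#' Total cost of scanning a cohort
#'
#' The study cost of recruiting `n` participants and scanning each for
#' `t_min` minutes is `(t_min / 60 * scan_cost_per_hour +
#' overhead_per_participant) * n`. The overhead term is everything paid per
#' participant regardless of scan length (recruitment, neuropsychological
#' testing, other modalities); it is what makes sample size and scan time
#' economically asymmetric.
#'
#' @param n Number of participants (>= 0).
#' @param t_min Scan time per participant, minutes (>= 0).
#' @param scan_cost_per_hour Scanner cost per hour (currency).
#' @param overhead_per_participant Per-participant overhead (currency).
#'
#' @return Cost(s), recycled over the inputs.
#' @export
#' @examples
#' study_cost(100, 60, 500, 500) # 100000
study_cost <- function(n, t_min, scan_cost_per_hour = 500,
                       overhead_per_participant = 500) {
  if (any(n < 0) || any(t_min < 0)) {
    abort("`n` and `t_min` must be >= 0.")
  }
  if (any(scan_cost_per_hour < 0) || any(overhead_per_participant < 0)) {
    abort("Costs must be >= 0.")
  }
  (t_min / 60 * scan_cost_per_hour + overhead_per_participant) * n
}

#' Economic assumptions for study design
#'
#' A light record of the cost model inputs: scanner cost per hour `S`,
#' per-participant overhead `O` and (optionally) a total budget `B`.
#'
#' @inheritParams study_cost
#' @param budget Optional total budget (> 0).
#'
#' @return A list of class `"cost_spec"`.
#' @export
cost_spec <- function(scan_cost_per_hour = 500,
                      overhead_per_participant = 500, budget = NULL) {
  assert_scalar_number(scan_cost_per_hour, "scan_cost_per_hour", lower = 0)
  assert_scalar_number(overhead_per_participant, "overhead_per_participant",
                       lower = 0)
  if (!is.null(budget)) {
    assert_scalar_number(budget, "budget", lower = 0, strict_lower = TRUE)
  }
  structure(list(scan_cost_per_hour = scan_cost_per_hour,
                 overhead_per_participant = overhead_per_participant,
                 budget = budget),
            class = "cost_spec")
}

#' Maximize accuracy within a fixed scanning budget
#'
#' Walks scan time along `t_grid`; at each `t` the budget buys
#' `n = floor(B / (t/60 * S + O))` participants, and the design surface
#' gives the fraction of maximum accuracy at that (n, t). Returns the
#' accuracy-maximizing pair, breaking ties toward shorter scans.
#'
#' @param surface A `"bwas_surface"`.
#' @param budget Total budget (> 0).
#' @inheritParams study_cost
#' @param t_grid Candidate scan times (default 1..200 min in 1-min steps).
#' @param expected_usable_fraction Fraction of recruited participants whose
#'   data survives quality control and drop-out, in (0, 1]; accuracy is
#'   evaluated on the usable participants while the budget pays for all
#'   recruits (default 1).
#'
#' @return A one-row tibble: `t_min`, `n_recruited`, `fraction`, `cost`.
#'   The full per-`t` path is attached as attribute `"path"`.
#' @export
optimize_within_budget <- function(surface, budget,
                                   scan_cost_per_hour = 500,
                                   overhead_per_participant = 500,
                                   t_grid = seq(1, 200, by = 1),
                                   expected_usable_fraction = 1) {
  stopifnot(inherits(surface, "bwas_surface"))
  assert_scalar_number(budget, "budget", lower = 0, strict_lower = TRUE)
  assert_scalar_number(expected_usable_fraction, "expected_usable_fraction",
                       lower = 0, upper = 1, strict_lower = TRUE)
  n <- floor(budget / (t_grid / 60 * scan_cost_per_hour +
                         overhead_per_participant))
  n_usable <- floor(n * expected_usable_fraction)
  feasible <- n_usable * surface$train_fraction >= 1
  if (!any(feasible)) {
    abort("infeasible: the budget cannot recruit a single participant.")
  }
  t_grid <- t_grid[feasible]
  n <- n[feasible]
  n_usable <- n_usable[feasible]
  frac <- eval_surface(surface, n_usable, t_grid)
  best <- which(frac == max(frac))[1] # t_grid ascending: ties -> smaller t
  path <- tibble::tibble(t_min = t_grid, n_recruited = n, fraction = frac)
  out <- tibble::tibble(
    t_min = t_grid[best], n_recruited = n[best], fraction = frac[best],
    cost = study_cost(n[best], t_grid[best], scan_cost_per_hour,
                      overhead_per_participant)
  )
  attr(out, "path") <- path
  out
}

# Vectorized contour solver: smallest recruited n reaching `target` on the
# averaged surface, for every t in `t_values` at once. Bisection on
# x = 1/(train_fraction * n), where each phenotype contributes
# 1/sqrt(1 + (k1 + k2/t) * x).
contour_n_vec <- function(fits, train_fraction, target, t_values) {
  a <- outer(fits$k1, rep(1, length(t_values))) +
    outer(fits$k2, 1 / t_values) # P x T
  a <- pmax(a, 1e-15) # guard k1 = k2 = 0 phenotypes (flat fraction 1)
  c0 <- 1 / target^2 - 1
  if (nrow(a) == 1) {
    n <- a[1, ] * 1 / (train_fraction * c0)
    return(pmax(n, 1 / train_fraction))
  }
  x_per <- c0 / a # per-phenotype closed-form x
  lo <- apply(x_per, 2, min) # smallest x -> largest n: surely >= target
  hi <- apply(x_per, 2, max)
  mean_frac <- function(x) {
    colMeans(1 / sqrt(1 + a * rep(x, each = nrow(a))))
  }
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    ok <- mean_frac(mid) >= target # larger x = smaller n
    lo <- ifelse(ok, mid, lo)
    hi <- ifelse(ok, hi, mid)
  }
  pmax(1 / (train_fraction * lo), 1 / train_fraction)
}

#' Minimize study cost for a target accuracy fraction
#'
#' Samples the `target_fraction` contour of the design surface over
#' `t_grid`, prices each (n, t) pair (rounding n up to a whole
#' participant), and returns the cheapest design, breaking ties toward
#' shorter scans.
#'
#' @inheritParams optimize_within_budget
#' @param target_fraction Target fraction of maximum accuracy, in (0, 1).
#' @param max_session_min Optional maximum scan minutes per MRI session;
#'   only adds an `n_sessions` column to the result (splitting a scan
#'   across sessions is a reporting convenience, not a model term).
#'
#' @return A one-row tibble: `target_fraction`, `scan_cost_per_hour`,
#'   `overhead_per_participant`, `optimal_t_min`, `optimal_n`, `min_cost`
#'   (plus `n_sessions` when `max_session_min` is given). The full costed
#'   contour is attached as attribute `"contour"`.
#' @export
optimize_for_target <- function(surface, target_fraction,
                                scan_cost_per_hour = 500,
                                overhead_per_participant = 500,
                                t_grid = seq(1, 200, by = 0.5),
                                expected_usable_fraction = 1,
                                max_session_min = NULL) {
  stopifnot(inherits(surface, "bwas_surface"))
  assert_scalar_number(target_fraction, "target_fraction", lower = 0,
                       upper = 1, strict_lower = TRUE)
  assert_scalar_number(expected_usable_fraction, "expected_usable_fraction",
                       lower = 0, upper = 1, strict_lower = TRUE)
  if (target_fraction >= 1) abort("infeasible: target fraction must be < 1.")
  n <- contour_n_vec(surface$fits, surface$train_fraction, target_fraction,
                     t_grid)
  ok <- is.finite(n)
  if (!any(ok)) abort("infeasible: target unattainable at every scan time.")
  t_ok <- t_grid[ok]
  n_int <- ceiling(n[ok] / expected_usable_fraction)
  cost <- study_cost(n_int, t_ok, scan_cost_per_hour,
                     overhead_per_participant)
  best <- which(cost == min(cost))[1]
  out <- tibble::tibble(
    target_fraction = target_fraction,
    scan_cost_per_hour = scan_cost_per_hour,
    overhead_per_participant = overhead_per_participant,
    optimal_t_min = t_ok[best],
    optimal_n = n_int[best],
    min_cost = cost[best]
  )
  if (!is.null(max_session_min)) {
    out$n_sessions <- ceiling(out$optimal_t_min / max_session_min)
  }
  attr(out, "contour") <- tibble::tibble(t_min = t_ok, n_recruited = n_int,
                                         cost = cost)
  out
}

#' The default scenario conditions
#'
#' Three accuracy targets (80%, 90%, 95% of maximum) crossed with two
#' per-participant overheads (500, 1000) and two scan costs per hour
#' (500, 1000): 12 conditions. Crossed with a set of dataset surfaces these
#' form the scenario grid of the cost analyses.
#'
#' @param targets,overheads,scan_costs Condition levels.
#'
#' @return A tibble with `target_fraction`, `overhead_per_participant`,
#'   `scan_cost_per_hour`.
#' @export
scenario_conditions <- function(targets = c(0.80, 0.90, 0.95),
                                overheads = c(500, 1000),
                                scan_costs = c(500, 1000)) {
  tidyr::expand_grid(target_fraction = targets,
                     overhead_per_participant = overheads,
                     scan_cost_per_hour = scan_costs)
}

as_surface_list <- function(surfaces) {
  if (inherits(surfaces, "bwas_surface")) {
    surfaces <- list(dataset = surfaces)
  }
  if (!is.list(surfaces) || !all(vapply(surfaces, inherits, logical(1),
                                        "bwas_surface"))) {
    abort("`surfaces` must be a bwas_surface or a named list of them.")
  }
  if (is.null(names(surfaces))) {
    names(surfaces) <- paste0("dataset", seq_along(surfaces))
  }
  surfaces
}

# Cost of hitting each scenario's target at every t in `t_values`.
# Returns a long tibble: dataset, target_fraction, S, O, t_min, cost.
scenario_costs <- function(surfaces, conditions, t_values) {
  surfaces <- as_surface_list(surfaces)
  targets <- unique(conditions$target_fraction)
  contours <- purrr::imap_dfr(surfaces, function(surf, ds) {
    purrr::map_dfr(targets, function(tg) {
      tibble::tibble(
        dataset = ds, target_fraction = tg, t_min = t_values,
        n_recruited = ceiling(
          contour_n_vec(surf$fits, surf$train_fraction, tg, t_values))
      )
    })
  })
  out <- dplyr::inner_join(
    tidyr::expand_grid(conditions, dataset = names(surfaces)),
    contours,
    by = c("dataset", "target_fraction"),
    relationship = "many-to-many"
  )
  out$cost <- study_cost(out$n_recruited, out$t_min,
                         out$scan_cost_per_hour,
                         out$overhead_per_participant)
  out
}

#' Cost inefficiency of fixed scan times
#'
#' For every scenario (dataset surface x condition), the cost of achieving
#' the scenario's accuracy target with scan time fixed at each value of
#' `fixed_t_grid`, relative to the scenario's own optimal cost:
#' `cost(t) / cost(t_opt) - 1`. Curves are averaged across scenarios; the
#' `normalized` column additionally subtracts the curve's minimum, so the
#' best fixed scan time sits at zero.
#'
#' @param surfaces A `"bwas_surface"` or named list of them (one per
#'   dataset).
#' @param conditions A conditions tibble (default [scenario_conditions()]).
#' @param fixed_t_grid Candidate fixed scan times (default 5..100 min in
#'   5-min steps).
#' @param opt_t_grid Grid on which each scenario's optimum is located
#'   (default 1..200 min in 0.5-min steps).
#'
#' @return A tibble with `t_min`, `inefficiency` and `normalized`.
#'   Attributes: `"scenarios"` (per-scenario optima, a tibble with
#'   `dataset`, condition columns, `optimal_t_min`, `optimal_n`,
#'   `min_cost`) and `"per_scenario"` (long per-scenario inefficiencies).
#' @export
cost_inefficiency_curve <- function(surfaces,
                                    conditions = scenario_conditions(),
                                    fixed_t_grid = seq(5, 100, by = 5),
                                    opt_t_grid = seq(1, 200, by = 0.5)) {
  t_values <- sort(unique(c(fixed_t_grid, opt_t_grid)))
  costs <- scenario_costs(surfaces, conditions, t_values)
  keycols <- c("dataset", "target_fraction", "overhead_per_participant",
               "scan_cost_per_hour")

  opt <- dplyr::slice_min(
    dplyr::group_by(costs[costs$t_min %in% opt_t_grid, ],
                    dplyr::across(dplyr::all_of(keycols))),
    .data$cost, n = 1, with_ties = FALSE
  )
  opt <- dplyr::ungroup(opt)
  opt <- dplyr::rename(opt, optimal_t_min = "t_min",
                       optimal_n = "n_recruited", min_cost = "cost")

  fixed <- dplyr::inner_join(
    costs[costs$t_min %in% fixed_t_grid, ],
    opt[, c(keycols, "optimal_t_min", "min_cost")],
    by = keycols
  )
  fixed$inefficiency <- fixed$cost / fixed$min_cost - 1

  curve <- dplyr::summarise(
    dplyr::group_by(fixed, .data$t_min),
    inefficiency = mean(.data$inefficiency),
    n_scenarios = dplyr::n(),
    .groups = "drop"
  )
  curve$normalized <- curve$inefficiency - min(curve$inefficiency)
  attr(curve, "scenarios") <- opt
  attr(curve, "per_scenario") <- fixed[, c(keycols, "t_min", "cost",
                                           "inefficiency")]
  curve
}

#' Cost savings of fixed scan times relative to a reference
#'
#' For each fixed scan time, the percentage saving in mean relative study
#' cost compared with fixing scan time at `reference_t`:
#' `100 * (1 - mean_scenarios(cost(t) / cost(reference_t)))`.
#'
#' @inheritParams cost_inefficiency_curve
#' @param reference_t Reference scan time; must be in `fixed_t_grid`
#'   (default 10 min).
#'
#' @return A tibble with `t_min` and `savings_pct`.
#' @export
savings_vs_reference <- function(surfaces,
                                 conditions = scenario_conditions(),
                                 fixed_t_grid = seq(5, 100, by = 5),
                                 reference_t = 10) {
  if (!reference_t %in% fixed_t_grid) {
    abort("`reference_t` must be one of `fixed_t_grid`.")
  }
  costs <- scenario_costs(surfaces, conditions, sort(unique(fixed_t_grid)))
  keycols <- c("dataset", "target_fraction", "overhead_per_participant",
               "scan_cost_per_hour")
  ref <- costs[costs$t_min == reference_t, c(keycols, "cost")]
  ref <- dplyr::rename(ref, ref_cost = "cost")
  joined <- dplyr::inner_join(costs, ref, by = keycols)
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$t_min),
    savings_pct = 100 * (1 - mean(.data$cost / .data$ref_cost)),
    .groups = "drop"
  )
  out
}

#' Bootstrap the most cost-effective fixed scan time
#'
#' The point estimate is the arg-minimum of the scenario-averaged cost
#' inefficiency curve built from `fits`. Uncertainty is assessed by
#' resampling phenotypes with replacement *within each dataset*, rebuilding
#' the per-dataset surfaces and the averaged curve, and taking the 2.5/97.5
#' percentiles of the resampled arg-minima.
#'
#' @param fits A `"theor_fit"` tibble with a `dataset` column (one row per
#'   phenotype).
#' @param conditions Condition grid (default [scenario_conditions()]).
#' @param n_boot Number of bootstrap replicates (default 1000; >= 100
#'   recommended).
#' @param seed Seed for the resampling.
#' @param fixed_t_grid,opt_t_grid As in [cost_inefficiency_curve()].
#' @param train_fraction Train fraction for the rebuilt surfaces.
#'
#' @return A one-row tibble: `best_t`, `ci_low`, `ci_high`, `n_boot`.
#'   Attribute `"boot"` holds the resampled arg-minima.
#' @export
bootstrap_best_fixed_time <- function(fits,
                                      conditions = scenario_conditions(),
                                      n_boot = 1000, seed = 1,
                                      fixed_t_grid = seq(5, 100, by = 5),
                                      opt_t_grid = seq(1, 200, by = 0.5),
                                      train_fraction = 0.9) {
  fits <- tibble::as_tibble(fits)
  if (!"dataset" %in% names(fits)) abort("`fits` must have a `dataset` column.")
  split_fits <- split(fits, fits$dataset)
  make_surfaces <- function(fit_list) {
    purrr::map(fit_list, design_surface, train_fraction = train_fraction)
  }
  best_of <- function(fit_list) {
    curve <- cost_inefficiency_curve(make_surfaces(fit_list), conditions,
                                     fixed_t_grid, opt_t_grid)
    curve$t_min[which.min(curve$inefficiency)]
  }
  best_t <- best_of(split_fits)

  if (nrow(fits) == 1) {
    warn("Only one phenotype: the bootstrap CI degenerates to the estimate.")
    out <- tibble::tibble(best_t = best_t, ci_low = best_t,
                          ci_high = best_t, n_boot = 0L)
    attr(out, "boot") <- rep(best_t, 0)
    return(out)
  }

  boots <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      resampled <- purrr::map(split_fits, function(f) {
        f[sample(nrow(f), nrow(f), replace = TRUE), , drop = FALSE]
      })
      best_of(resampled)
    }, numeric(1))
  })
  ci <- unname(quantile(boots, c(0.025, 0.975), type = 1))
  out <- tibble::tibble(best_t = best_t, ci_low = ci[1], ci_high = ci[2],
                        n_boot = n_boot)
  attr(out, "boot") <- boots
  out
}
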