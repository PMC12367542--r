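#' Fit the logarithmic total-scan-duration model
#'
#' For scan times up to `t_cap_min` per participant, prediction accuracy is
#' well described by a straight line in the base-2 logarithm of the total
#' scan duration (training sample size x scan time per participant):
#' `y = slope_z * log2(n_train * t_min) + intercept_k`. The fit is ordinary
#' least squares on the qualifying cells of each grid; `slope_z` is the
#' accuracy gained per doubling of total scan duration.
#'
#' @param data An accuracy table (see [as_accuracy_grid()]).
#' @param t_cap_min Only cells with `t_min <= t_cap_min` are fitted
#'   (default 20 minutes, beyond which the log relationship breaks down).
#'
#' @return A tibble of class `"log_fit"` with one row per grid: `slope_z`,
#'   `intercept_k`, `r2`, `t_cap_min`, `n_cells`.
#' @export
fit_logarithmic <- function(data, t_cap_min = 20) {
  assert_scalar_number(t_cap_min, "t_cap_min", lower = 0, strict_lower = TRUE)
  data <- as_accuracy_grid(data)
  out <- dplyr::reframe(
    grid_groups(data),
    {
      keep <- t_min <= t_cap_min
      if (sum(keep) < 2) {
        abort(sprintf(
          "Grid %s/%s has %d cell(s) with t_min <= %g; need at least 2.",
          dataset[1], phenotype[1], sum(keep), t_cap_min))
      }
      x <- log2(n_train[keep] * t_min[keep])
      y <- accuracy[keep]
      fit <- lm(y ~ x)
      tibble::tibble(
        slope_z = unname(coef(fit)[2]),
        intercept_k = unname(coef(fit)[1]),
        r2 = cod(y, stats::fitted(fit)),
        t_cap_min = t_cap_min,
        n_cells = sum(keep)
      )
    }
  )
  class(out) <- c("log_fit", class(out))
  out
}

#' @method tidy log_fit
#' @export
tidy.log_fit <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("dataset", "phenotype", "metric",
                             "slope_z", "intercept_k")],
    cols = c("slope_z", "intercept_k"),
    names_to = "term", values_to = "estimate"
  )
}

#' @method glance log_fit
#' @export
glance.log_fit <- function(x, ...) {
  tibble::as_tibble(x)[, c("dataset", "phenotype", "metric", "r2",
                           "t_cap_min", "n_cells")]
}

#' Normalize accuracies onto the common log2 scale
#'
#' Rescales each grid's accuracies by its fitted logarithmic model,
#' `(y - intercept_k) / slope_z`, so that a phenotype following the model
#' exactly lands on the standard `log2(total scan duration)` curve. This
#' puts phenotypes from different datasets, metrics and predictors on one
#' normalized accuracy scale.
#'
#' @param data An accuracy table.
#' @param fits A `"log_fit"` tibble from [fit_logarithmic()] covering every
#'   grid in `data`. Grids with `slope_z = 0` cannot be normalized and
#'   raise an error.
#'
#' @return `data` with `accuracy` replaced by its normalized value and an
#'   additional `total_duration` column (`n_train * t_min`, minutes).
#' @export
normalize_accuracies <- function(data, fits) {
  data <- as_accuracy_grid(data)
  fits <- tibble::as_tibble(fits)
  if (any(fits$slope_z == 0)) {
    abort("Cannot normalize with a degenerate (zero) logarithmic slope.")
  }
  out <- dplyr::inner_join(
    data, fits[, c("dataset", "phenotype", "metric",
                   "slope_z", "intercept_k")],
    by = c("dataset", "phenotype", "metric")
  )
  if (nrow(out) < nrow(data)) {
    abort("`fits` does not cover every grid in `data`.")
  }
  out$accuracy <- (out$accuracy - out$intercept_k) / out$slope_z
  out$total_duration <- out$n_train * out$t_min
  out[, c(names(data), "total_duration")]
}
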