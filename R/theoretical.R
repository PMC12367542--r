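#' The accuracy scaling law
#'
#' Expected phenotypic prediction accuracy (Pearson's correlation) as a
#' function of training sample size `n` and scan time per participant `t`:
#'
#' \deqn{E(\hat\rho) \approx K_0 \sqrt{\frac{1}{1 + K_1/N + K_2/(NT)}}}
#'
#' `k0` is the asymptotic accuracy achievable with unlimited data (attenuated
#' by phenotypic reliability), `k1` scales the sample-size-limited error term
#' (units: participants) and `k2` scales the brain-measurement-noise term
#' (units: participant-minutes). Infinite `n` or `t` are accepted and treated
#' as limits.
#'
#' @param n Training sample size(s), > 0 (may be `Inf`).
#' @param t Scan time(s) per participant in minutes, > 0 (may be `Inf`).
#' @param k0 Asymptotic accuracy in (0, 1].
#' @param k1 Sample-size error coefficient, >= 0.
#' @param k2 Measurement-noise error coefficient, >= 0.
#'
#' @return Predicted accuracy, recycled over the inputs. Nondecreasing in
#'   both `n` and `t`; strictly below `k0` at finite arguments unless
#'   `k1 = k2 = 0`.
#' @export
#' @examples
#' theoretical_accuracy(100, 10, k0 = 0.6, k1 = 100, k2 = 1000) # 0.6/sqrt(3)
theoretical_accuracy <- function(n, t, k0, k1 = 0, k2 = 0) {
  if (any(!is.numeric(n)) || any(is.na(n)) || any(n <= 0)) {
    abort("`n` must be positive (Inf allowed).")
  }
  if (any(!is.numeric(t)) || any(is.na(t)) || any(t <= 0)) {
    abort("`t` must be positive (Inf allowed).")
  }
  if (any(k0 <= 0) || any(k0 > 1)) abort("`k0` must lie in (0, 1].")
  if (any(k1 < 0) || any(k2 < 0)) abort("`k1` and `k2` must be >= 0.")
  k0 * sqrt(1 / (1 + k1 / n + k2 / (n * t)))
}

# Loss and analytic gradient on transformed parameters
# theta = (k0, log k1, log k2); returns mean squared error to `y`.
theor_loss <- function(theta, n, t, y) {
  k0 <- theta[1]
  k1 <- exp(theta[2])
  k2 <- exp(theta[3])
  d <- 1 + k1 / n + k2 / (n * t)
  f <- k0 / sqrt(d)
  mean((y - f)^2)
}

theor_grad <- function(theta, n, t, y) {
  k0 <- theta[1]
  k1 <- exp(theta[2])
  k2 <- exp(theta[3])
  d <- 1 + k1 / n + k2 / (n * t)
  f <- k0 / sqrt(d)
  r <- f - y
  m <- length(y)
  dk0 <- 2 * sum(r * f / k0) / m
  # df/dk1 = -k0/2 * d^{-3/2} / n ; chain through k1 = exp(theta2)
  dk1 <- 2 * sum(r * (-0.5) * k0 * d^(-1.5) / n) / m * k1
  dk2 <- 2 * sum(r * (-0.5) * k0 * d^(-1.5) / (n * t)) / m * k2
  c(dk0, dk1, dk2)
}

# Moment-matching warm start: for positive accuracies,
# (k0/y)^2 - 1 is linear in 1/n and 1/(nt).
theor_warm_start <- function(n, t, y) {
  k0 <- min(1, max(y) * 1.02)
  pos <- y > 0.02 * k0
  if (sum(pos) >= 3) {
    z <- (k0 / y[pos])^2 - 1
    X <- cbind(1 / n[pos], 1 / (n[pos] * t[pos]))
    fit <- tryCatch(stats::lm.fit(X, z)$coefficients, error = function(e) c(NA, NA))
    k1 <- max(fit[1], 1, na.rm = TRUE)
    k2 <- max(fit[2], 1, na.rm = TRUE)
  } else {
    k1 <- 100
    k2 <- 1000
  }
  c(k0, log(k1), log(k2))
}

fit_theoretical_one <- function(n, t, y, n_starts = 20, seed = 1) {
  if (length(y) < 4) {
    abort("Theoretical fit requires at least 4 (n_train, t_min) cells.")
  }
  if (any(!is.finite(y))) abort("Accuracies must be finite.")
  if (diff(range(y)) < .Machine$double.eps^0.5) {
    # Flat grid: the law is exact with no error terms.
    if (y[1] <= 0 || y[1] > 1) {
      warn("Flat grid value outside (0, 1]; returning it as k0 regardless.")
    }
    return(list(k0 = y[1], k1 = 0, k2 = 0, r2 = 1, converged = TRUE))
  }

  lower <- c(1e-6, -23, -23)
  upper <- c(1, 26, 30)
  starts <- with_local_seed(seed, {
    u <- lhs::randomLHS(n_starts, 3)
    cbind(
      0.05 + 0.95 * u[, 1],
      log(1) + u[, 2] * (log(1e5) - log(1)),
      log(1) + u[, 3] * (log(1e6) - log(1))
    )
  })
  starts <- rbind(theor_warm_start(n, t, y), starts)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- pmin(pmax(starts[i, ], lower), upper)
    res <- tryCatch(
      optim(th0, theor_loss, gr = theor_grad, n = n, t = t, y = y,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) abort("Theoretical model fit failed from every start.")
  k0 <- best$par[1]
  k1 <- exp(best$par[2])
  k2 <- exp(best$par[3])
  # Snap vanishing error terms (at the transform's lower bound) to zero.
  if (k1 < 1e-8) k1 <- 0
  if (k2 < 1e-8) k2 <- 0
  fitted <- theoretical_accuracy(n, t, k0, k1, k2)
  list(k0 = k0, k1 = k1, k2 = k2, r2 = cod(y, fitted),
       converged = best$convergence == 0)
}

#' Fit the accuracy scaling law to accuracy grids
#'
#' Minimizes the mean squared error between the law and the rep-averaged
#' accuracy of each (N, T) cell, independently for each
#' (dataset, phenotype, metric) grid in `data`. The optimizer is a bounded
#' quasi-Newton (L-BFGS-B) on transformed parameters (`k0` box-bounded in
#' (0, 1], `k1` and `k2` on the log scale) restarted from a seeded
#' Latin-hypercube of initial values plus a moment-matching warm start, so
#' the result is deterministic given `seed`.
#'
#' A grid whose accuracies are all identical is returned with `k1 = k2 = 0`,
#' `k0` equal to that value and `r2 = 1` (the law is then exact).
#'
#' @param data An accuracy table (see [as_accuracy_grid()]); each grid must
#'   have at least 4 cells.
#' @param n_starts Number of Latin-hypercube restarts (default 20).
#' @param seed Seed for the restart design.
#'
#' @return A tibble of class `"theor_fit"` with one row per grid:
#'   `dataset`, `phenotype`, `metric`, `k0`, `k1`, `k2`, `r2`, `converged`,
#'   `n_cells`.
#' @export
fit_theoretical <- function(data, n_starts = 20, seed = 1) {
  data <- as_accuracy_grid(data)
  out <- dplyr::reframe(
    grid_groups(data),
    {
      fit <- fit_theoretical_one(n_train, t_min, accuracy,
                                 n_starts = n_starts, seed = seed)
      tibble::tibble(k0 = fit$k0, k1 = fit$k1, k2 = fit$k2, r2 = fit$r2,
                     converged = fit$converged, n_cells = length(accuracy))
    }
  )
  class(out) <- c("theor_fit", class(out))
  out
}

#' @method tidy theor_fit
#' @export
tidy.theor_fit <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x)[, c("dataset", "phenotype", "metric",
                             "k0", "k1", "k2")],
    cols = c("k0", "k1", "k2"),
    names_to = "term", values_to = "estimate"
  )
}

#' @method glance theor_fit
#' @export
glance.theor_fit <- function(x, ...) {
  tibble::as_tibble(x)[, c("dataset", "phenotype", "metric", "r2",
                           "converged", "n_cells")]
}

#' Predicted accuracies from fitted scaling laws
#'
#' Evaluates each fitted law in `fits` on a grid of sample sizes and scan
#' times (or on the cells of an observed accuracy table when `data` is
#' given), returning a long tibble suitable for plotting against
#' observations.
#'
#' @param fits A `"theor_fit"` tibble from [fit_theoretical()].
#' @param n,t Numeric vectors crossed into an (N, T) grid.
#' @param data Optional accuracy table; when supplied, predictions are made
#'   at its observed cells instead and returned alongside `accuracy`.
#'
#' @return A tibble with `dataset`, `phenotype`, `metric`, `n_train`,
#'   `t_min`, `predicted` (and `accuracy` when `data` is given).
#' @export
predict_accuracy <- function(fits, n = NULL, t = NULL, data = NULL) {
  if (is.null(data)) {
    if (is.null(n) || is.null(t)) {
      abort("Supply either `data` or both `n` and `t`.")
    }
    cells <- tidyr::expand_grid(n_train = n, t_min = t)
    out <- tidyr::crossing(
      tibble::as_tibble(fits)[, c("dataset", "phenotype", "metric",
                                  "k0", "k1", "k2")],
      cells
    )
  } else {
    data <- as_accuracy_grid(data)
    out <- dplyr::inner_join(
      data,
      tibble::as_tibble(fits)[, c("dataset", "phenotype", "metric",
                                  "k0", "k1", "k2")],
      by = c("dataset", "phenotype", "metric")
    )
  }
  out$predicted <- theoretical_accuracy(out$n_train, out$t_min,
                                        out$k0, out$k1, out$k2)
  out[, setdiff(names(out), c("k0", "k1", "k2"))]
}
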