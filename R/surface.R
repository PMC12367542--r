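#' Fraction of maximum achievable accuracy
#'
#' Normalizes the accuracy scaling law by its own asymptote `k0`, yielding
#' the fraction of a phenotype's maximum achievable accuracy reached at a
#' given recruited sample size and scan time. Accuracy is evaluated at the
#' *training* sample size `train_fraction * n`, while `n` itself is the
#' recruited size (the quantity that is costed): under tenfold
#' cross-validation, 90% of recruits train the model.
#'
#' @param n Recruited sample size(s); `train_fraction * n` must be >= 1.
#' @param t Scan time(s) per participant, minutes.
#' @param k1,k2 Error coefficients of the fitted law (`k0` cancels).
#' @param train_fraction Fraction of recruits used for training, in (0, 1]
#'   (default 0.9).
#'
#' @return Fractions in \[0, 1\], nondecreasing in `n` and `t`.
#' @export
#' @examples
#' fraction_of_max(100, 10, k1 = 100, k2 = 1000, train_fraction = 1) # 1/sqrt(3)
fraction_of_max <- function(n, t, k1, k2, train_fraction = 0.9) {
  assert_scalar_number(train_fraction, "train_fraction", lower = 0,
                       upper = 1, strict_lower = TRUE)
  if (any(n * train_fraction < 1)) {
    abort("`train_fraction * n` must be >= 1 (at least one training subject).")
  }
  sqrt(1 / (1 + k1 / (train_fraction * n) + k2 / (train_fraction * n * t)))
}

#' Build a fraction-of-maximum-accuracy design surface
#'
#' Converts one or more fitted scaling laws into a design surface over
#' (recruited sample size, scan time per participant): the per-phenotype
#' fraction of maximum achievable accuracy, averaged cell-wise (unweighted)
#' across phenotypes. The surface is stored analytically (the fits
#' themselves), so it can be evaluated at arbitrary (N, T) — use
#' [eval_surface()] — and materialized on its grid with
#' [tibble::as_tibble()].
#'
#' @param fits A `"theor_fit"` tibble from [fit_theoretical()]; all rows
#'   must have converged.
#' @param train_fraction Fraction of recruits used for training (default
#'   0.9, a tenfold cross-validation design).
#' @param n_grid,t_grid Default evaluation grid (recruited N; T in
#'   minutes).
#'
#' @return An object of class `"bwas_surface"`.
#' @export
design_surface <- function(fits, train_fraction = 0.9,
                           n_grid = seq(25, 10000, by = 25),
                           t_grid = seq(1, 200, by = 1)) {
  fits <- tibble::as_tibble(fits)
  if (nrow(fits) == 0) abort("`fits` must contain at least one fitted grid.")
  if (!all(c("k1", "k2") %in% names(fits))) {
    abort("`fits` must carry `k1` and `k2` columns (see fit_theoretical()).")
  }
  if ("converged" %in% names(fits) && !all(fits$converged)) {
    abort("All fits must have converged to build a surface.")
  }
  assert_scalar_number(train_fraction, "train_fraction", lower = 0,
                       upper = 1, strict_lower = TRUE)
  structure(
    list(fits = fits, train_fraction = train_fraction,
         n_grid = n_grid, t_grid = t_grid),
    class = "bwas_surface"
  )
}

#' @export
print.bwas_surface <- function(x, ...) {
  cat(sprintf(
    "<bwas_surface> %d phenotype fit(s), train_fraction = %g\n",
    nrow(x$fits), x$train_fraction))
  cat(sprintf("  n grid: %g..%g (%d), t grid: %g..%g min (%d)\n",
              min(x$n_grid), max(x$n_grid), length(x$n_grid),
              min(x$t_grid), max(x$t_grid), length(x$t_grid)))
  invisible(x)
}

#' Evaluate a design surface at arbitrary (N, T)
#'
#' @param surface A `"bwas_surface"`.
#' @param n,t Recruited sample sizes and scan times (recycled together).
#'
#' @return Mean fraction of maximum accuracy across the surface's
#'   phenotypes at each (n, t).
#' @export
eval_surface <- function(surface, n, t) {
  stopifnot(inherits(surface, "bwas_surface"))
  pieces <- purrr::pmap(
    list(surface$fits$k1, surface$fits$k2),
    function(k1, k2) fraction_of_max(n, t, k1, k2, surface$train_fraction)
  )
  Reduce(`+`, pieces) / length(pieces)
}

#' @method as_tibble bwas_surface
#' @export
as_tibble.bwas_surface <- function(x, ...) {
  grid <- tidyr::expand_grid(n_recruited = x$n_grid, t_min = x$t_grid)
  grid$fraction <- eval_surface(x, grid$n_recruited, grid$t_min)
  grid
}

#' Export / import a design surface
#'
#' Writes the surface as a delimited table (`n_recruited, t_min, fraction`)
#' plus a JSON sidecar (`<path>.json`) holding provenance: the contributing
#' phenotype fits, the train fraction and the package version.
#'
#' @param surface A `"bwas_surface"`.
#' @param path Output table path (`.tsv` for tab, comma otherwise).
#'
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  stopifnot(inherits(surface, "bwas_surface"))
  tab <- tibble::as_tibble(surface)
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(tab, path, delim = delim)
  meta <- list(
    train_fraction = surface$train_fraction,
    source_phenotypes = surface$fits[, intersect(
      c("dataset", "phenotype", "metric", "k0", "k1", "k2", "r2"),
      names(surface$fits))],
    n_grid = range(surface$n_grid),
    t_grid = range(surface$t_grid),
    package_version = as.character(utils::packageVersion("bwasplan"))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' Smallest recruited sample size reaching a target fraction
#'
#' Closed form for a single fitted law: the fraction-of-maximum contour at
#' level `target` satisfies
#' `n = (k1 + k2 / t) / (train_fraction * (1 / target^2 - 1))`, floored at
#' the minimum recruitable size `1 / train_fraction` (one training
#' subject).
#'
#' @param target Target fraction of maximum accuracy, in (0, 1).
#' @param t Scan time(s) per participant, minutes.
#' @inheritParams fraction_of_max
#'
#' @return Recruited sample size(s), as reals (round up when costing).
#' @export
required_sample_size <- function(target, t, k1, k2, train_fraction = 0.9) {
  assert_scalar_number(target, "target", lower = 0, upper = 1,
                       strict_lower = TRUE)
  if (target >= 1) abort("A fraction of 1 is only attainable in the limit.")
  n <- (k1 + k2 / t) / (train_fraction * (1 / target^2 - 1))
  pmax(n, 1 / train_fraction)
}

#' Sample an iso-accuracy contour of a design surface
#'
#' For each scan time in `t_grid`, finds the smallest recruited sample size
#' at which the surface reaches `target_fraction`. For a single-phenotype
#' surface this uses the closed form; for averaged surfaces the monotone
#' n-axis is bisected to a tolerance of 0.01 participant.
#'
#' @param surface A `"bwas_surface"`.
#' @param target_fraction Target fraction in (0, 1).
#' @param t_grid Scan times to sample (default: the surface's grid).
#'
#' @return A tibble with `t_min`, `n_recruited` and `fraction` (the surface
#'   value at the returned point).
#' @export
contour_sample <- function(surface, target_fraction, t_grid = NULL) {
  stopifnot(inherits(surface, "bwas_surface"))
  if (target_fraction >= 1) {
    abort("`target_fraction` must be < 1; the asymptote is unattainable.")
  }
  assert_scalar_number(target_fraction, "target_fraction", lower = 0,
                       upper = 1, strict_lower = TRUE)
  t_grid <- t_grid %||% surface$t_grid
  f <- surface$train_fraction
  n_min <- 1 / f

  n_req <- vapply(t_grid, function(t) {
    # Per-phenotype closed forms bracket the averaged contour.
    per <- required_sample_size(target_fraction, t,
                                surface$fits$k1, surface$fits$k2, f)
    if (nrow(surface$fits) == 1) return(per[1])
    lo <- max(min(per), n_min)
    hi <- max(per)
    if (eval_surface(surface, lo, t) >= target_fraction) return(lo)
    while (hi - lo > 0.01) {
      mid <- (lo + hi) / 2
      if (eval_surface(surface, mid, t) >= target_fraction) hi <- mid
      else lo <- mid
    }
    hi
  }, numeric(1))

  tibble::tibble(
    t_min = t_grid,
    n_recruited = n_req,
    fraction = eval_surface(surface, n_req, t_grid)
  )
}

#' Accuracy along a fixed total-scan-duration budget
#'
#' Holds the total scan duration `N * T` fixed and slides scan time per
#' participant along `t_grid`, reporting the law's accuracy at each
#' `(n = total_minutes / t, t)`. Whenever `k1 > 0` the slice is strictly
#' decreasing in `t`: with NT fixed, trading participants for scan time
#' always loses accuracy.
#'
#' @param fits A `"theor_fit"` tibble (one row per phenotype).
#' @param total_minutes Total scan duration, `n * t` (training participants
#'   x minutes).
#' @param t_grid Scan times per participant; `total_minutes / t` must be
#'   >= 1 for all.
#'
#' @return A tibble with one row per (fit, t): `dataset`, `phenotype`,
#'   `metric`, `n_train`, `t_min`, `accuracy`.
#' @export
iso_duration_slice <- function(fits, total_minutes, t_grid) {
  assert_scalar_number(total_minutes, "total_minutes", lower = 0,
                       strict_lower = TRUE)
  if (any(total_minutes / t_grid < 1)) {
    abort("`total_minutes / t` must be >= 1 for every t in `t_grid`.")
  }
  fits <- tibble::as_tibble(fits)
  out <- tidyr::crossing(
    fits[, c("dataset", "phenotype", "metric", "k0", "k1", "k2")],
    tibble::tibble(t_min = t_grid)
  )
  out$n_train <- total_minutes / out$t_min
  out$accuracy <- theoretical_accuracy(out$n_train, out$t_min,
                                       out$k0, out$k1, out$k2)
  out[, c("dataset", "phenotype", "metric", "n_train", "t_min", "accuracy")]
}
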