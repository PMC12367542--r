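#' Univariate edge-wise association statistics
#'
#' Pearson correlation between each FC edge and the phenotype across
#' subjects, converted to a t statistic via
#' `t = r * sqrt((n - 2) / (1 - r^2))`. These are the edge-wise
#' brain-wide-association statistics whose split-half agreement defines
#' univariate BWAS reliability.
#'
#' @param features Subjects x edges matrix.
#' @param phenotype Per-subject phenotype vector (nonzero variance).
#'
#' @return A per-edge t-statistic vector with the underlying correlations
#'   as attribute `"r"`. Zero-variance edges yield `NA` with a count
#'   reported via attribute `"n_degenerate"`.
#' @export
univariate_edge_stats <- function(features, phenotype) {
  if (nrow(features) < 3) abort("Need at least 3 subjects.")
  if (length(phenotype) != nrow(features)) {
    abort("`phenotype` must have one value per subject.")
  }
  if (sd(phenotype) == 0) abort("Phenotype has zero variance.")
  n <- nrow(features)
  r <- suppressWarnings(as.numeric(cor(features, phenotype)))
  if (any(abs(r) >= 1, na.rm = TRUE)) {
    abort(sprintf("Edge %d is perfectly correlated with the phenotype; t is infinite.",
                  which(abs(r) >= 1)[1]))
  }
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  attr(t_stat, "r") <- r
  attr(t_stat, "n_degenerate") <- sum(is.na(r))
  t_stat
}

#' Split-half intraclass correlation
#'
#' Agreement between two half-sample vectors of edge-wise statistics,
#' using the one-way random, single-measurement ICC: the grouping unit is
#' the edge, the two halves are the two measurements, and
#' `ICC = (MS_between - MS_within) / (MS_between + MS_within)`. This form
#' penalizes mean offsets between halves; `type = "consistency"` switches
#' to the two-way consistency ICC (ICC(3,1)), which does not.
#'
#' @param vec_a,vec_b Equal-length (>= 3) statistic vectors. Pairs with a
#'   missing value (degenerate edges) are dropped with a message.
#' @param type `"oneway"` (default) or `"consistency"`.
#'
#' @return The ICC, in \[-1, 1\].
#' @export
split_half_icc <- function(vec_a, vec_b, type = c("oneway", "consistency")) {
  type <- rlang::arg_match(type)
  if (length(vec_a) != length(vec_b)) {
    abort("Half vectors must have the same length.")
  }
  ok <- is.finite(vec_a) & is.finite(vec_b)
  if (sum(!ok) > 0) {
    rlang::inform(sprintf("Dropping %d degenerate edge pair(s).", sum(!ok)))
    vec_a <- vec_a[ok]
    vec_b <- vec_b[ok]
  }
  n <- length(vec_a)
  if (n < 3) abort("Need at least 3 edge pairs.")
  row_means <- (vec_a + vec_b) / 2
  grand <- mean(row_means)
  ms_between <- 2 * sum((row_means - grand)^2) / (n - 1)
  ms_within <- sum((vec_a - row_means)^2 + (vec_b - row_means)^2) / n
  if (type == "oneway") {
    if (ms_between + ms_within == 0) {
      abort("Zero total variance; ICC undefined.")
    }
    (ms_between - ms_within) / (ms_between + ms_within)
  } else {
    if (sd(vec_a) == 0 || sd(vec_b) == 0) {
      abort("Zero variance in a half; consistency ICC undefined.")
    }
    cor(vec_a, vec_b)
  }
}

#' Split-half BWAS reliability over sample sizes and scan times
#'
#' For each (half size, scan time) combination: subjects are split into
#' two disjoint halves of the requested size, the edge-wise association
#' statistic is computed in each half — either univariate edge t
#' statistics, or the Haufe activation pattern of a predictor trained on
#' that half — and their ICC is recorded, averaged over `n_reps` random
#' disjoint splits.
#'
#' @param cohort A `"bwas_cohort"`.
#' @param half_sizes Half-sample sizes; the cohort must hold at least
#'   `2 * max(half_sizes)` subjects.
#' @param t_list Scan times, minutes.
#' @param n_reps Random split repetitions (default 10).
#' @param seed Seed.
#' @param stat_kind `"univariate_t"` or `"haufe"`.
#' @param spec Predictor for `stat_kind = "haufe"` (default
#'   [predictor_spec()] with a reduced lambda grid would also work; the
#'   full default is used).
#' @param icc_type Passed to [split_half_icc()].
#'
#' @return A tibble with `half_size`, `t_min`, `icc`, `stat_kind`
#'   (averaged over repetitions) and attribute `"per_rep"`.
#' @export
reliability_experiment <- function(cohort, half_sizes, t_list, n_reps = 10,
                                   seed = 1,
                                   stat_kind = c("univariate_t", "haufe"),
                                   spec = predictor_spec(),
                                   icc_type = "oneway") {
  stat_kind <- rlang::arg_match(stat_kind)
  stopifnot(inherits(cohort, "bwas_cohort"))
  n <- cohort$config$n_subjects
  if (n < 2 * max(half_sizes)) {
    abort("Cohort must hold at least twice the largest half size.")
  }
  y <- cohort$subjects$phenotype

  half_stat <- function(X, idx) {
    if (stat_kind == "univariate_t") {
      univariate_edge_stats(X[idx, , drop = FALSE], y[idx])
    } else {
      K <- if (spec$model == "krr") feature_kernel(X, spec$kernel) else NULL
      fit <- fit_predict_nested(X, K, y, idx, idx[1], spec,
                                seed = child_seed(seed, 99))
      haufe_transform(X[idx, , drop = FALSE], fit$pred_train)
    }
  }

  rows <- list()
  for (ti in seq_along(t_list)) {
    X <- observe_fc(cohort, t_list[ti],
                    seed = child_seed(cohort$config$seed, 23, ti))
    for (h in half_sizes) {
      for (rep_i in seq_len(n_reps)) {
        pick <- with_local_seed(child_seed(seed, ti, h, rep_i), {
          sample(n, 2 * h)
        })
        a_idx <- pick[seq_len(h)]
        b_idx <- pick[h + seq_len(h)]
        stopifnot(length(intersect(a_idx, b_idx)) == 0)
        icc <- split_half_icc(half_stat(X, a_idx), half_stat(X, b_idx),
                              type = icc_type)
        rows[[length(rows) + 1]] <- tibble::tibble(
          half_size = h, t_min = t_list[ti], rep = rep_i, icc = icc)
      }
    }
  }
  per_rep <- dplyr::bind_rows(rows)
  out <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$half_size, .data$t_min),
    icc = mean(.data$icc), .groups = "drop"
  )
  out$stat_kind <- stat_kind
  attr(out, "per_rep") <- per_rep
  out
}
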