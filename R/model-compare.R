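#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken about the mean
#' of the observed values. This is the goodness-of-fit measure reported for
#' both scaling-law and logarithmic fits; it can be negative when the model
#' predicts worse than the observed mean.
#'
#' @param observed,predicted Equal-length numeric vectors (>= 2 points).
#'
#' @return A single number (<= 1).
#' @export
#' @examples
#' cod(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.4)) # 0.5
cod <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have the same length.")
  }
  if (length(observed) < 2) {
    abort("Need at least 2 points to compute a coefficient of determination.")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    abort("Observed values have zero variance; COD is undefined.")
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Paired comparison of goodness of fit across phenotypes
#'
#' Compares two models' per-phenotype goodness-of-fit values (for example,
#' the scaling law versus the logarithmic model, fitted to the same
#' phenotype grids) with a two-sided paired Wilcoxon signed-rank test. The
#' test is exact when the sample is small and untied; identical lists
#' short-circuit to `p = 1`.
#'
#' @param r2_a,r2_b Equal-length numeric vectors of per-phenotype fit
#'   quality (length >= 5).
#'
#' @return A one-row tibble: `statistic`, `p_value`, `n`, `method`.
#' @export
compare_model_fits <- function(r2_a, r2_b) {
  if (length(r2_a) != length(r2_b)) {
    abort("`r2_a` and `r2_b` must have the same length.")
  }
  if (length(r2_a) < 5) {
    abort("Need at least 5 paired phenotypes to compare model fits.")
  }
  d <- r2_a - r2_b
  if (all(d == 0)) {
    return(tibble::tibble(statistic = NA_real_, p_value = 1,
                          n = length(d),
                          method = "Wilcoxon signed rank (paired)"))
  }
  res <- suppressWarnings(wilcox.test(r2_a, r2_b, paired = TRUE,
                                      alternative = "two.sided"))
  tibble::tibble(statistic = unname(res$statistic),
                 p_value = res$p.value,
                 n = length(d),
                 method = "Wilcoxon signed rank (paired)")
}

#' Does predictability track adherence to the scaling law?
#'
#' Spearman rank correlation between per-phenotype fit quality and
#' per-phenotype maximum prediction accuracy, with a permutation p-value
#' obtained by shuffling the pairing `n_perm` times.
#'
#' @param fit_r2 Per-phenotype goodness of fit of the scaling law.
#' @param max_accuracy Per-phenotype maximum observed accuracy.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Seed for the permutations.
#'
#' @return A one-row tibble: `rho`, `p_value`, `n`, `n_perm`.
#' @export
adherence_correlation <- function(fit_r2, max_accuracy, n_perm = 1000,
                                  seed = 1) {
  if (length(fit_r2) != length(max_accuracy)) {
    abort("`fit_r2` and `max_accuracy` must have the same length.")
  }
  if (length(fit_r2) < 5) {
    abort("Need at least 5 phenotypes.")
  }
  if (sd(fit_r2) == 0 || sd(max_accuracy) == 0) {
    abort("Spearman's rho is undefined for a constant list.")
  }
  rho <- cor(fit_r2, max_accuracy, method = "spearman")
  perm <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      cor(fit_r2, sample(max_accuracy), method = "spearman")
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
  tibble::tibble(rho = rho, p_value = p, n = length(fit_r2), n_perm = n_perm)
}
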