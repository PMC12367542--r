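#' Functional connectivity from parcel time series
#'
#' Pearson correlation among parcel time courses, restricted to the first
#' `floor(first_t_min * 60 / tr_seconds)` frames — the "first T minutes"
#' convention under which scan time is varied.
#'
#' @param time_series A parcels x frames numeric matrix.
#' @param first_t_min Scan time to use, minutes.
#' @param tr_seconds Repetition time, seconds.
#'
#' @return A symmetric parcels x parcels correlation matrix with unit
#'   diagonal.
#' @export
compute_fc <- function(time_series, first_t_min, tr_seconds) {
  if (!is.matrix(time_series) || nrow(time_series) < 2) {
    abort("`time_series` must be a parcels x frames matrix with >= 2 parcels.")
  }
  frames <- floor(first_t_min * 60 / tr_seconds)
  if (frames < 2) abort("`first_t_min` yields fewer than 2 frames.")
  if (frames > ncol(time_series)) {
    abort(sprintf("Need %d frames for %g min but only %d are available.",
                  frames, first_t_min, ncol(time_series)))
  }
  x <- t(time_series[, seq_len(frames), drop = FALSE])
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("Parcel %d has a constant time course; correlation undefined.",
                  which(sds == 0)[1]))
  }
  fc <- cor(x)
  diag(fc) <- 1
  fc
}

#' Pack and unpack FC matrices
#'
#' `vectorize_fc()` extracts the strictly-lower-triangular entries of a
#' square symmetric matrix in row-major order (length `p(p-1)/2`);
#' `unvectorize_fc()` is its inverse, restoring a symmetric matrix with
#' unit diagonal.
#'
#' @param fc A square symmetric matrix.
#' @param v A packed edge vector.
#'
#' @return A numeric vector, or the restored matrix.
#' @export
vectorize_fc <- function(fc) {
  if (!is.matrix(fc) || nrow(fc) != ncol(fc)) {
    abort("`fc` must be a square matrix.")
  }
  idx <- which(lower.tri(fc), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  fc[idx]
}

#' @rdname vectorize_fc
#' @export
unvectorize_fc <- function(v) {
  p <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (p != round(p)) abort("Length of `v` is not p(p-1)/2 for integer p.")
  p <- as.integer(p)
  m <- diag(p)
  idx <- which(lower.tri(m), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  m[idx] <- v
  m[idx[, c(2, 1)]] <- v
  m
}

#' Cross-validation scheme
#'
#' Describes how a cohort is split for nested cross-validation. With
#' `kind = "kfold_family"` subjects are divided into `n_folds` folds such
#' that sibling blocks are never split across folds (so folds are only
#' approximately equal-sized). With `kind = "leave_p_siteclusters_out"`,
#' sites are first packed into `n_clusters` size-balanced clusters and
#' every combination of `p` clusters serves as a test set. Within a
#' repetition, the test set is identical across all training subsample
#' sizes, so accuracies are comparable across sizes.
#'
#' @param kind `"kfold_family"` or `"leave_p_siteclusters_out"`.
#' @param n_folds Folds for `kfold_family` (default 10).
#' @param p Clusters left out per split (default 3).
#' @param n_clusters Number of site clusters (default 10).
#' @param subsample_sizes Training sizes to evaluate.
#' @param n_reps Repetitions with different fold splits.
#' @param seed Seed controlling folds and subsampling.
#' @param site_regression Residualize the phenotype on site (estimated on
#'   the training set, applied to the test set)?
#' @param max_splits_per_rep Cap on test splits evaluated per repetition
#'   (useful at desk scale; default all).
#'
#' @return A list of class `"cv_scheme"`.
#' @export
cv_scheme <- function(kind = c("kfold_family", "leave_p_siteclusters_out"),
                      n_folds = 10, p = 3, n_clusters = 10,
                      subsample_sizes, n_reps = 1, seed = 1,
                      site_regression = FALSE, max_splits_per_rep = Inf) {
  kind <- rlang::arg_match(kind)
  if (missing(subsample_sizes) || length(subsample_sizes) < 1) {
    abort("`subsample_sizes` must list at least one training size.")
  }
  assert_flag(site_regression, "site_regression")
  structure(
    list(kind = kind, n_folds = as.integer(n_folds), p = as.integer(p),
         n_clusters = as.integer(n_clusters),
         subsample_sizes = sort(as.integer(subsample_sizes)),
         n_reps = as.integer(n_reps), seed = as.integer(seed),
         site_regression = site_regression,
         max_splits_per_rep = max_splits_per_rep),
    class = "cv_scheme"
  )
}

#' Predictor specification
#'
#' Kernel ridge regression (`"krr"`, the default, with a correlation
#' kernel between FC feature vectors) or linear ridge regression
#' (`"lrr"`). The regularization strength is selected on each training set
#' by `inner_folds`-fold cross-validation over `lambda_grid`.
#'
#' @param model `"krr"` or `"lrr"`.
#' @param kernel `"correlation"` or `"linear"` (KRR only).
#' @param lambda_grid Positive regularization candidates (default 16
#'   log-spaced values in `[1e-4, 1e4]`).
#' @param inner_folds Inner CV folds for hyperparameter selection.
#'
#' @return A list of class `"predictor_spec"`.
#' @export
predictor_spec <- function(model = c("krr", "lrr"),
                           kernel = c("correlation", "linear"),
                           lambda_grid = 10^seq(-4, 4, length.out = 16),
                           inner_folds = 10) {
  model <- rlang::arg_match(model)
  kernel <- rlang::arg_match(kernel)
  if (length(lambda_grid) < 1 || any(lambda_grid <= 0)) {
    abort("`lambda_grid` must be non-empty and strictly positive.")
  }
  structure(list(model = model, kernel = kernel,
                 lambda_grid = sort(lambda_grid),
                 inner_folds = as.integer(inner_folds)),
            class = "predictor_spec")
}

# Family-aware fold assignment: sibling blocks are atomic; blocks are
# dealt largest-first onto the currently smallest fold (ties randomized
# by the pre-shuffle).
make_family_folds <- function(family_id, n_folds, seed) {
  fams <- with_local_seed(seed, sample(unique(family_id)))
  sizes <- table(family_id)[as.character(fams)]
  ord <- order(-as.integer(sizes))
  fold_of_family <- integer(length(fams))
  load <- numeric(n_folds)
  for (i in ord) {
    f <- which.min(load)
    fold_of_family[i] <- f
    load[f] <- load[f] + sizes[i]
  }
  fold_of_family[match(family_id, fams)]
}

# Greedy size-balancing bin-packing of sites into k clusters.
make_site_clusters <- function(site_id, k, seed) {
  sites <- with_local_seed(seed, sample(unique(site_id)))
  sizes <- table(site_id)[as.character(sites)]
  ord <- order(-as.integer(sizes))
  cluster_of_site <- integer(length(sites))
  load <- numeric(k)
  for (i in ord) {
    f <- which.min(load)
    cluster_of_site[i] <- f
    load[f] <- load[f] + sizes[i]
  }
  cluster_of_site[match(site_id, sites)]
}

# Residualize a phenotype on site: means estimated on the training set,
# applied to train and test; unseen test sites fall back to the train mean.
site_residualize <- function(y, site, train_idx) {
  mtab <- tapply(y[train_idx], site[train_idx], mean)
  grand <- mean(y[train_idx])
  adj <- mtab[as.character(site)]
  adj[is.na(adj)] <- grand
  y - as.numeric(adj)
}

# Multi-lambda KRR solve via one eigendecomposition of the training kernel.
krr_solve <- function(K_tr, y_tr, lambdas) {
  ybar <- mean(y_tr)
  yc <- y_tr - ybar
  eg <- eigen(K_tr, symmetric = TRUE)
  uy <- crossprod(eg$vectors, yc)
  alphas <- vapply(lambdas, function(l) {
    as.numeric(eg$vectors %*% (uy / (eg$values + l)))
  }, numeric(length(y_tr)))
  list(alphas = alphas, ybar = ybar) # alphas: n_tr x n_lambda
}

# Multi-lambda LRR solve via one SVD of the training features. The
# intercept is the training phenotype mean (features enter uncentered, the
# exact primal of the linear-kernel KRR dual).
lrr_solve <- function(X_tr, y_tr, lambdas) {
  ybar <- mean(y_tr)
  sv <- svd(X_tr, nu = min(dim(X_tr)), nv = min(dim(X_tr)))
  uy <- crossprod(sv$u, y_tr - ybar)
  ws <- vapply(seq_along(lambdas), function(i) {
    as.numeric(sv$v %*% (sv$d * uy / (sv$d^2 + lambdas[i])))
  }, numeric(ncol(X_tr)))
  list(ws = ws, ybar = ybar) # ws: p x n_lambda
}

# Select lambda by inner k-fold CV (MSE), then fit on the full training
# set and predict the test set. `K` is the full-cohort kernel (KRR) and
# `X` the full feature matrix (LRR); indices address cohort rows.
fit_predict_nested <- function(X, K, y, train_idx, test_idx, spec, seed) {
  lambdas <- spec$lambda_grid
  n_tr <- length(train_idx)
  inner_folds <- if (length(lambdas) == 1) 0L else spec$inner_folds
  inner <- with_local_seed(seed, {
    sample(rep_len(seq_len(max(inner_folds, 1L)), n_tr))
  })
  sse <- numeric(length(lambdas))
  for (f in seq_len(inner_folds)) {
    fit_i <- train_idx[inner != f]
    val_i <- train_idx[inner == f]
    if (length(val_i) == 0 || length(fit_i) < 2) next
    if (spec$model == "krr") {
      sol <- krr_solve(K[fit_i, fit_i, drop = FALSE], y[fit_i], lambdas)
      pred <- K[val_i, fit_i, drop = FALSE] %*% sol$alphas + sol$ybar
    } else {
      sol <- lrr_solve(X[fit_i, , drop = FALSE], y[fit_i], lambdas)
      pred <- X[val_i, , drop = FALSE] %*% sol$ws + sol$ybar
    }
    sse <- sse + colSums((pred - y[val_i])^2)
  }
  best <- which.min(sse)
  if (spec$model == "krr") {
    sol <- krr_solve(K[train_idx, train_idx, drop = FALSE], y[train_idx],
                     lambdas[best])
    pred_test <- as.numeric(
      K[test_idx, train_idx, drop = FALSE] %*% sol$alphas + sol$ybar)
    pred_train <- as.numeric(
      K[train_idx, train_idx, drop = FALSE] %*% sol$alphas + sol$ybar)
  } else {
    sol <- lrr_solve(X[train_idx, , drop = FALSE], y[train_idx],
                     lambdas[best])
    pred_test <- as.numeric(
      X[test_idx, , drop = FALSE] %*% sol$ws + sol$ybar)
    pred_train <- as.numeric(
      X[train_idx, , drop = FALSE] %*% sol$ws + sol$ybar)
  }
  list(pred_test = pred_test, pred_train = pred_train,
       lambda = lambdas[best])
}

feature_kernel <- function(X, kernel) {
  if (kernel == "correlation") {
    cor(t(X))
  } else {
    tcrossprod(X)
  }
}

# COD with the training-set mean as the null predictor, so test sets are
# comparable across training sizes.
cod_trainmean <- function(y_test, pred, train_mean) {
  1 - sum((y_test - pred)^2) / sum((y_test - train_mean)^2)
}

#' Prediction accuracy over training sizes and scan times
#'
#' Runs the full nested cross-validation workflow on a synthetic cohort:
#' for each scan time in `t_list`, observed FC features are generated; for
#' each repetition, subjects are split into folds (sibling blocks intact,
#' or site-cluster combinations); each test split is held fixed while the
#' training complement is subsampled to each size in
#' `scheme$subsample_sizes`; the predictor of `spec` (with inner-CV
#' hyperparameter selection) is trained and evaluated. Accuracies (Pearson
#' and COD with the training-mean null) are averaged over splits and
#' repetitions.
#'
#' @param cohort A `"bwas_cohort"`.
#' @param t_list Scan times (minutes) at which to observe features.
#' @param scheme A [cv_scheme()].
#' @param spec A [predictor_spec()].
#' @param randomize_runs Randomize each subject's run order independently
#'   for every repetition (non-stationarity analysis)? Default `FALSE`.
#'
#' @return An accuracy table (see [as_accuracy_grid()]) with metrics
#'   `"pearson"` and `"cod"`; per-repetition accuracies are attached as
#'   attribute `"per_rep"`.
#' @export
nested_cv_accuracy <- function(cohort, t_list, scheme, spec = predictor_spec(),
                               randomize_runs = FALSE) {
  stopifnot(inherits(cohort, "bwas_cohort"), inherits(scheme, "cv_scheme"),
            inherits(spec, "predictor_spec"))
  subj <- cohort$subjects
  n <- nrow(subj)
  y_raw <- subj$phenotype
  if (scheme$site_regression && length(unique(subj$site_id)) < 2) {
    abort("Site regression requested but the cohort has a single site.")
  }
  if (randomize_runs && cohort$config$n_runs < 2) {
    abort("Run-order randomization needs at least 2 runs.")
  }

  # Features are a property of the (possibly re-ordered) cohort: they are
  # observed once per scan time and shared by every repetition, which only
  # reshuffles the folds — as in a real study. Under `randomize_runs` a
  # single per-subject randomization realization is drawn (same physical-run
  # noise draws as the original-order analysis; only the consumption order
  # differs), so both analyses rest on one dataset realization each.
  obs_cohort <- if (randomize_runs) {
    randomize_run_order(cohort, seed = child_seed(scheme$seed, 7))
  } else {
    cohort
  }
  X_cache <- lapply(seq_along(t_list), function(ti) {
    observe_fc(obs_cohort, t_list[ti],
               seed = child_seed(cohort$config$seed, 17, ti))
  })
  K_cache <- if (spec$model == "krr") {
    lapply(X_cache, feature_kernel, kernel = spec$kernel)
  }

  records <- list()
  for (rep_i in seq_len(scheme$n_reps)) {
    splits <- make_splits(subj, scheme, rep_i)
    for (ti in seq_along(t_list)) {
      X <- X_cache[[ti]]
      K <- K_cache[[ti]]
      for (sp in seq_along(splits)) {
        test_idx <- splits[[sp]]
        pool <- setdiff(seq_len(n), test_idx)
        y <- if (scheme$site_regression) {
          site_residualize(y_raw, subj$site_id, pool)
        } else {
          y_raw
        }
        for (size in scheme$subsample_sizes) {
          if (size > length(pool)) {
            abort(sprintf(
              "Training size %d exceeds the %d subjects outside the test split.",
              size, length(pool)))
          }
          train_idx <- with_local_seed(
            child_seed(scheme$seed, rep_i, sp, size),
            sample(pool, size)
          )
          fit <- fit_predict_nested(
            X, K, y, train_idx, test_idx, spec,
            seed = child_seed(scheme$seed, 5, rep_i, sp, size))
          r <- suppressWarnings(cor(fit$pred_test, y[test_idx]))
          if (is.na(r)) r <- 0 # degenerate constant predictions
          records[[length(records) + 1]] <- tibble::tibble(
            t_min = t_list[ti], n_train = size, rep = rep_i, split = sp,
            pearson = r,
            cod = cod_trainmean(y[test_idx], fit$pred_test,
                                mean(y[train_idx]))
          )
        }
      }
    }
  }
  per_rep <- dplyr::bind_rows(records)
  long <- tidyr::pivot_longer(per_rep, c("pearson", "cod"),
                              names_to = "metric", values_to = "accuracy")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$metric, .data$n_train, .data$t_min),
    accuracy = mean(.data$accuracy),
    n_reps = dplyr::n(),
    .groups = "drop"
  )
  out$dataset <- "synthetic"
  out$phenotype <- "simulated"
  out <- as_accuracy_grid(out)
  attr(out, "per_rep") <- per_rep
  out
}

# Test splits for one repetition: a list of test-index vectors.
make_splits <- function(subj, scheme, rep_i) {
  if (scheme$kind == "kfold_family") {
    folds <- make_family_folds(subj$family_id, scheme$n_folds,
                               seed = child_seed(scheme$seed, 1, rep_i))
    splits <- lapply(seq_len(scheme$n_folds), function(f) which(folds == f))
  } else {
    clusters <- make_site_clusters(subj$site_id, scheme$n_clusters,
                                   seed = child_seed(scheme$seed, 2, rep_i))
    combos <- combn(scheme$n_clusters, scheme$p, simplify = FALSE)
    splits <- lapply(combos, function(cl) which(clusters %in% cl))
  }
  if (is.finite(scheme$max_splits_per_rep) &&
      length(splits) > scheme$max_splits_per_rep) {
    pick <- with_local_seed(child_seed(scheme$seed, 3, rep_i), {
      sample(length(splits), scheme$max_splits_per_rep)
    })
    splits <- splits[pick]
  }
  splits
}

#' Haufe-transformed activation pattern
#'
#' Converts a predictive model into an interpretable activation vector:
#' the covariance, across training subjects, between each feature and the
#' model's predicted phenotype. Unlike raw weights, activations have the
#' sign and scale of the encoding direction.
#'
#' @param X_train Training features (subjects x features).
#' @param y_hat Predicted phenotype for the training subjects.
#'
#' @return A per-feature activation vector.
#' @export
haufe_transform <- function(X_train, y_hat) {
  if (nrow(X_train) < 2) abort("Need at least 2 training subjects.")
  if (length(y_hat) != nrow(X_train)) {
    abort("`y_hat` must have one value per training subject.")
  }
  if (sd(y_hat) == 0) {
    abort("Predictions have zero variance; the Haufe transform is undefined.")
  }
  as.numeric(crossprod(sweep(X_train, 2, colMeans(X_train)),
                       y_hat - mean(y_hat))) / (nrow(X_train) - 1)
}

#' Corrected resampled t-test for cross-validated comparisons
#'
#' Paired t-test on per-split accuracy differences with the variance
#' inflated by `1/J + n_test/n_train` (J = number of differences) to
#' account for the overlap of cross-validation training sets, which makes
#' the naive paired t-test anticonservative.
#'
#' @param diffs Paired accuracy differences, one per CV split/repetition.
#' @param n_train,n_test Training and test set sizes of the CV design.
#'
#' @return A one-row tibble: `statistic`, `p_value`, `df`.
#' @export
corrected_resampled_ttest <- function(diffs, n_train, n_test) {
  j <- length(diffs)
  if (j < 2) abort("Need at least 2 paired differences.")
  if (n_train <= 0 || n_test <= 0) abort("`n_train` and `n_test` must be > 0.")
  v <- var(diffs)
  m <- mean(diffs)
  if (v == 0) {
    if (m == 0) {
      return(tibble::tibble(statistic = 0, p_value = 1, df = j - 1))
    }
    abort("Zero variance with nonzero mean difference; test is degenerate.")
  }
  stat <- m / sqrt((1 / j + n_test / n_train) * v)
  tibble::tibble(statistic = stat,
                 p_value = 2 * pt(-abs(stat), df = j - 1),
                 df = j - 1)
}

#' Benjamini-Yekutieli FDR rejections
#'
#' Step-up false-discovery-rate control valid under arbitrary dependence:
#' rejects all hypotheses up to the largest i with
#' `p_(i) <= i * q / (m * c(m))`, `c(m) = sum_{k=1}^m 1/k`.
#'
#' @param p_values P-values in \[0, 1\].
#' @param q FDR level in (0, 1) (default 0.05).
#'
#' @return A logical rejection flag per p-value.
#' @export
by_fdr <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values)) {
    abort("`p_values` must lie in [0, 1] with no missing values.")
  }
  assert_scalar_number(q, "q", lower = 0, upper = 1, strict_lower = TRUE)
  if (q >= 1) abort("`q` must be < 1.")
  p.adjust(p_values, method = "BY") <= q
}

#' Effect of run-order randomization on scaling-law fit
#'
#' Recomputes the accuracy grid of [nested_cv_accuracy()] twice — once
#' with runs in acquisition order, once with each subject's run order
#' independently re-randomized for every repetition — fits the scaling law
#' to both Pearson grids, and reports the goodness of fit before and
#' after. When the FC-phenotype relationship drifts across runs,
#' randomization restores exchangeability of scan minutes and the fit
#' improves.
#'
#' @inheritParams nested_cv_accuracy
#'
#' @return A one-row tibble: `r2_original`, `r2_randomized`.
#' @export
randomized_run_fit_change <- function(cohort, t_list, scheme,
                                      spec = predictor_spec()) {
  if (cohort$config$n_runs < 2) {
    abort("Non-stationarity analysis needs at least 2 runs.")
  }
  grid_o <- nested_cv_accuracy(cohort, t_list, scheme, spec,
                               randomize_runs = FALSE)
  grid_r <- nested_cv_accuracy(cohort, t_list, scheme, spec,
                               randomize_runs = TRUE)
  fit_o <- fit_theoretical(grid_o[grid_o$metric == "pearson", ])
  fit_r <- fit_theoretical(grid_r[grid_r$metric == "pearson", ])
  tibble::tibble(r2_original = fit_o$r2, r2_randomized = fit_r$r2)
}
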