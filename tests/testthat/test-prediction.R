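test_that("FC computation restricts to the first T minutes and validates parcels", {
  set.seed(1)
  ts <- matrix(rnorm(5 * 600), 5, 600)
  fc <- compute_fc(ts, first_t_min = 4, tr_seconds = 0.8) # 300 frames
  expect_equal(dim(fc), c(5, 5))
  expect_equal(diag(fc), rep(1, 5))
  expect_equal(fc, t(fc))
  expect_equal(fc[1, 2], cor(ts[1, 1:300], ts[2, 1:300]))

  # two identical series correlate at exactly 1
  ts2 <- rbind(ts[1, ], ts[1, ], ts[2, ])
  expect_equal(compute_fc(ts2, 4, 0.8)[1, 2], 1)

  # long independent white noise: off-diagonals near 0 (3/sqrt(frames))
  set.seed(2)
  big <- matrix(rnorm(4 * 8000), 4, 8000)
  fc_big <- compute_fc(big, 100, 0.75) # 8000 frames
  expect_lt(max(abs(fc_big[lower.tri(fc_big)])), 3 / sqrt(8000))

  expect_error(compute_fc(ts, 10, 0.8), "frames")
  ts[2, ] <- 1
  expect_error(compute_fc(ts, 4, 0.8), "Parcel 2")
})

test_that("FC vectorization is strict-lower-triangular row-major and invertible", {
  m <- matrix(0, 3, 3)
  m[lower.tri(m)] <- c(21, 31, 32) # column-major fill: (2,1),(3,1),(3,2)
  m <- m + t(m)
  diag(m) <- 1
  v <- vectorize_fc(m)
  expect_equal(v, c(21, 31, 32)) # row-major order (2,1),(3,1),(3,2)
  expect_equal(unvectorize_fc(v), m)

  # p parcels pack into p(p-1)/2 edges
  p <- 20
  expect_length(vectorize_fc(diag(p)), p * (p - 1) / 2)
  expect_error(vectorize_fc(matrix(0, 2, 3)), "square")
  expect_error(unvectorize_fc(1:4), "p\\(p-1\\)/2")
})

test_that("KRR with a linear kernel and LRR agree at matched regularization", {
  set.seed(11)
  n <- 40; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% rnorm(p) + rnorm(n)
  lambda <- 3.7
  train <- 1:30
  test <- 31:40
  K <- bwasplan:::feature_kernel(X, "linear")
  krr <- bwasplan:::fit_predict_nested(
    X, K, as.numeric(y), train, test,
    predictor_spec("krr", "linear", lambda_grid = lambda), seed = 1)
  lrr <- bwasplan:::fit_predict_nested(
    X, NULL, as.numeric(y), train, test,
    predictor_spec("lrr", lambda_grid = lambda), seed = 1)
  expect_equal(krr$pred_test, lrr$pred_test, tolerance = 1e-8)
  expect_equal(krr$pred_train, lrr$pred_train, tolerance = 1e-8)
})

test_that("a noise-free linear phenotype is predicted almost perfectly", {
  ch <- small_cohort(n_subjects = 150, n_parcels = 10, seed = 3,
                     phenotype_noise_sd = 0, obs_noise_sd = 0.005,
                     phenotype_weight_density = 1)
  sch <- cv_scheme("kfold_family", n_folds = 5, subsample_sizes = 120,
                   n_reps = 1, seed = 1, max_splits_per_rep = 2)
  g <- nested_cv_accuracy(ch, t_list = 20, scheme = sch,
                          spec = predictor_spec("lrr", inner_folds = 5))
  expect_gt(g$accuracy[g$metric == "pearson"], 0.95)
  expect_gt(g$accuracy[g$metric == "cod"], 0.85)
})

test_that("a permuted phenotype predicts at chance", {
  ch <- small_cohort(n_subjects = 160, n_parcels = 12, seed = 4)
  ch$subjects$phenotype <- withr::with_seed(9, sample(ch$subjects$phenotype))
  sch <- cv_scheme("kfold_family", n_folds = 4, subsample_sizes = 100,
                   n_reps = 5, seed = 2, max_splits_per_rep = 2)
  g <- nested_cv_accuracy(ch, t_list = 10, scheme = sch,
                          spec = predictor_spec(lambda_grid = 10))
  per_rep <- attr(g, "per_rep")
  r <- per_rep$pearson
  expect_lt(abs(mean(r)), 2 * sd(r) / sqrt(length(r)) + 0.05)
  # metrics stay within their ranges
  expect_true(all(abs(per_rep$pearson) <= 1))
  expect_true(all(per_rep$cod <= 1))
})

test_that("folds never split sibling blocks and subsampling errors when oversized", {
  ch <- small_cohort(n_subjects = 120, n_parcels = 8, seed = 5,
                     family_block_size = 3)
  folds <- bwasplan:::make_family_folds(ch$subjects$family_id, 5, seed = 1)
  per_family <- tapply(folds, ch$subjects$family_id,
                       function(f) length(unique(f)))
  expect_true(all(per_family == 1))
  expect_lte(diff(range(table(folds))), 3) # balanced up to one block

  sch <- cv_scheme("kfold_family", n_folds = 4, subsample_sizes = 115,
                   n_reps = 1, seed = 1)
  expect_error(nested_cv_accuracy(ch, 10, sch, predictor_spec(lambda_grid = 1)),
               "exceeds")
})

test_that("site-cluster splits are balanced and site regression needs sites", {
  ch <- small_cohort(n_subjects = 120, n_parcels = 8, seed = 6, n_sites = 9)
  clusters <- bwasplan:::make_site_clusters(ch$subjects$site_id, 3, seed = 2)
  sizes <- table(clusters)
  expect_equal(length(sizes), 3L)
  expect_lte(diff(range(sizes)), 14) # sites are atomic

  single_site <- small_cohort(n_subjects = 60, n_parcels = 8, seed = 7)
  sch <- cv_scheme("kfold_family", n_folds = 3, subsample_sizes = 30,
                   site_regression = TRUE)
  expect_error(nested_cv_accuracy(single_site, 10, sch), "single site")

  # residualization removes training-site means, applied out of sample
  y <- c(1, 2, 3, 11, 12, 13, 100)
  site <- c("a", "a", "a", "b", "b", "b", "c")
  res <- bwasplan:::site_residualize(y, site, train_idx = 1:6)
  expect_equal(res[1:3], c(-1, 0, 1))
  expect_equal(res[4:6], c(-1, 0, 1))
  expect_equal(res[7], 100 - mean(y[1:6])) # unseen site -> grand mean
})

test_that("identical test folds are reused across subsample sizes", {
  ch <- small_cohort(n_subjects = 80, n_parcels = 8, seed = 8)
  sch <- cv_scheme("kfold_family", n_folds = 4,
                   subsample_sizes = c(20, 40, 60), n_reps = 2, seed = 3)
  splits_r1 <- bwasplan:::make_splits(ch$subjects, sch, 1)
  splits_r1_again <- bwasplan:::make_splits(ch$subjects, sch, 1)
  expect_identical(splits_r1, splits_r1_again)
  # and the engine evaluates every size against the same split index
  g <- nested_cv_accuracy(ch, 10, sch, predictor_spec(lambda_grid = 1))
  per_rep <- attr(g, "per_rep")
  counts <- dplyr::count(per_rep, rep, split, n_train)
  expect_true(all(counts$n == 1))
  expect_equal(nrow(counts), 2 * 4 * 3)
})

test_that("the Haufe transform is the feature-prediction covariance", {
  set.seed(12)
  x <- scale(rnorm(50))[, 1] # sample sd exactly 1
  expect_equal(haufe_transform(matrix(x, ncol = 1), x), 1)

  # identity feature covariance: activation proportional to the weights
  n <- 4000; p <- 6
  X <- matrix(rnorm(n * p), n, p)
  w <- c(2, -1, 0.5, 0, 1, -0.25)
  a <- haufe_transform(X, as.numeric(X %*% w))
  expect_equal(a, w, tolerance = 0.1)
  expect_equal(haufe_transform(X, -as.numeric(X %*% w)), -a)

  expect_error(haufe_transform(X, rep(1, n)), "zero variance")
  expect_error(haufe_transform(X[1, , drop = FALSE], 1), "at least 2")
})

test_that("the corrected resampled t-test matches hand arithmetic and its limits", {
  expect_equal(corrected_resampled_ttest(rep(0, 10), 90, 10),
               tibble::tibble(statistic = 0, p_value = 1, df = 9))

  # mean 0.05, variance 0.01, J = 100, n_test/n_train = 1/9
  set.seed(14)
  d <- as.numeric(scale(rnorm(100))) * 0.1 + 0.05
  res <- corrected_resampled_ttest(d, n_train = 900, n_test = 100)
  expect_equal(res$statistic, 0.05 / sqrt((1 / 100 + 1 / 9) * 0.01),
               tolerance = 1e-12)
  expect_equal(res$statistic, 1.437, tolerance = 1e-3)

  # vanishing test/train ratio recovers the classical paired t statistic
  res0 <- corrected_resampled_ttest(d, n_train = 1e12, n_test = 1)
  expect_equal(res0$statistic, mean(d) / sqrt(var(d) / 100),
               tolerance = 1e-5)

  expect_error(corrected_resampled_ttest(rep(0.2, 5), 90, 10), "degenerate")
  expect_error(corrected_resampled_ttest(0.1, 90, 10), "at least 2")
})

test_that("BY-FDR matches hand thresholds and never beats BH", {
  expect_equal(by_fdr(rep(1, 5)), rep(FALSE, 5))
  expect_true(by_fdr(0.01, q = 0.05)) # c(1) = 1
  # c(3) = 11/6; thresholds i*q/(m*c) ~ (0.00909, 0.01818, 0.02727)
  expect_equal(by_fdr(c(0.001, 0.02, 0.8), q = 0.05),
               c(TRUE, FALSE, FALSE))

  set.seed(15)
  for (i in 1:10) {
    p <- runif(20)^2
    by <- by_fdr(p, 0.05)
    bh <- p.adjust(p, "BH") <= 0.05
    expect_true(all(!by | bh)) # BY rejections are a subset of BH's
  }
  expect_error(by_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
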