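test_that("configurations are validated with every problem listed", {
  expect_s3_class(cohort_config(), "cohort_config")
  err <- tryCatch(cohort_config(n_subjects = 1, obs_noise_sd = -1),
                  error = identity)
  expect_match(conditionMessage(err), "n_subjects")
  expect_match(conditionMessage(err), "obs_noise_sd")
})

test_that("cohorts are bit-identical under the same seed", {
  c1 <- generate_cohort(cohort_config(n_subjects = 60, n_parcels = 10,
                                      seed = 9))
  c2 <- generate_cohort(cohort_config(n_subjects = 60, n_parcels = 10,
                                      seed = 9))
  expect_identical(c1$true_features, c2$true_features)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$true_weights, c2$true_weights)
  expect_identical(observe_fc(c1, 7, seed = 4), observe_fc(c2, 7, seed = 4))

  c3 <- generate_cohort(cohort_config(n_subjects = 60, n_parcels = 10,
                                      seed = 10))
  expect_false(identical(c1$true_features, c3$true_features))
})

test_that("the phenotype is linear in the true features, attenuated by its noise", {
  ch0 <- generate_cohort(cohort_config(n_subjects = 80, n_parcels = 10,
                                       phenotype_noise_sd = 0,
                                       phenotype_weight_density = 1,
                                       seed = 11))
  lin <- as.numeric(ch0$true_features %*% ch0$true_weights)
  expect_equal(cor(ch0$subjects$phenotype, lin), 1, tolerance = 1e-12)

  ch <- generate_cohort(cohort_config(n_subjects = 6000, n_parcels = 12,
                                      phenotype_noise_sd = 0.75, seed = 12))
  lin <- as.numeric(ch$true_features %*% ch$true_weights)
  expect_equal(cor(ch$subjects$phenotype, lin),
               1 / sqrt(1 + 0.75^2 / var(lin)), tolerance = 0.02)
})

test_that("observation noise variance shrinks as 1/t in direct mode", {
  ch <- generate_cohort(cohort_config(n_subjects = 400, n_parcels = 15,
                                      obs_noise_sd = 0.12, seed = 13))
  d2 <- observe_fc(ch, 2, seed = 1) - ch$true_features
  d4 <- observe_fc(ch, 4, seed = 2) - ch$true_features
  expect_equal(mean(d2^2), 0.12^2 / 2, tolerance = 0.02)
  expect_equal(mean(d2^2) / mean(d4^2), 2, tolerance = 0.1)

  t_max <- ch$config$n_runs * ch$config$run_length_min
  d_max <- observe_fc(ch, t_max, seed = 3) - ch$true_features
  expect_equal(mean(d_max^2), 0.12^2 / t_max, tolerance = 0.05)
  expect_error(observe_fc(ch, t_max + 1), "t_min")
})

test_that("time-series mode yields valid FC whose edge noise follows the Fisher variance", {
  cfg <- cohort_config(n_subjects = 3, n_parcels = 10, mode = "time_series",
                       edge_signal_sd = 0.15, run_length_min = 5,
                       tr_seconds = 0.8, seed = 14)
  ch <- generate_cohort(cfg)
  obs <- observe_fc(ch, 10, seed = 5)
  expect_true(all(abs(obs) <= 1))

  # repeated observations of one subject: edge sd ~ (1 - rho^2)/sqrt(frames)
  reps <- vapply(1:60, function(i) observe_fc(ch, 5, seed = 100 + i)[1, ],
                 numeric(ncol(obs)))
  frames <- 5 * 60 / 0.8
  rho <- ch$true_features[1, ]
  emp_sd <- apply(reps, 1, sd)
  theo_sd <- (1 - rho^2) / sqrt(frames)
  expect_equal(median(emp_sd / theo_sd), 1, tolerance = 0.2)
})

test_that("run drift leaves t = first-run FC clean and is removed by drift 0", {
  cfg <- cohort_config(n_subjects = 150, n_parcels = 12, n_runs = 4,
                       run_length_min = 5, seed = 15)
  ch <- generate_cohort(cfg)
  expect_identical(inject_nonstationarity(ch, 0)$drift_sd, 0)

  chd <- inject_nonstationarity(ch, drift_sd = 3, seed = 15)
  # same noise stream: the only difference at t = 5 comes from which run
  # is consumed first; in acquisition order run 1 carries no drift
  first_clean <- observe_fc(chd, 5, seed = 7)
  first_plain <- observe_fc(ch, 5, seed = 7)
  expect_equal(first_clean, first_plain)

  # consuming the last (most drifted) run first changes FC markedly
  chd_rev <- chd
  chd_rev$run_perm <- matrix(rep(4:1, each = 150), 150, 4)
  first_drifted <- observe_fc(chd_rev, 5, seed = 7)
  base_gap <- mean(abs(first_plain - ch$true_features))
  drift_gap <- mean(abs(first_drifted - ch$true_features))
  expect_gt(drift_gap, 1.5 * base_gap)
})

test_that("per-subject run randomization is seeded, uniform and restores exchangeability", {
  cfg <- cohort_config(n_subjects = 1200, n_parcels = 6, n_runs = 3,
                       run_length_min = 5, seed = 16)
  ch <- generate_cohort(cfg)
  r1 <- randomize_run_order(ch, seed = 8)
  r2 <- randomize_run_order(ch, seed = 8)
  expect_identical(r1$run_perm, r2$run_perm)

  # all 3! orders appear with frequency ~ 1/6
  keys <- apply(r1$run_perm, 1, paste, collapse = "")
  freq <- table(keys) / length(keys)
  expect_equal(length(freq), 6L)
  expect_lt(max(abs(freq - 1 / 6)), 3 * sqrt((1 / 6) * (5 / 6) / 1200))

  # single-run cohorts cannot be permuted
  ch1 <- generate_cohort(cohort_config(n_subjects = 10, n_parcels = 6,
                                       n_runs = 1, seed = 17))
  expect_identical(randomize_run_order(ch1, seed = 1)$run_perm,
                   ch1$run_perm)

  # with drift, randomization equalizes early vs late scan minutes:
  # the first-5-min FC error matches its permutation-averaged expectation
  chd <- inject_nonstationarity(
    generate_cohort(cohort_config(n_subjects = 600, n_parcels = 12,
                                  n_runs = 4, run_length_min = 5,
                                  seed = 18)),
    drift_sd = 2, seed = 18)
  chr <- randomize_run_order(chd, seed = 9)
  err <- observe_fc(chr, 5, seed = 10) - chd$true_features
  expected_var <- 0.12^2 / 5 +
    2^2 * mean(chd$run_levels^2) * chd$config$edge_signal_sd^2
  expect_equal(mean(err^2), expected_var, tolerance = 0.05)
})
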