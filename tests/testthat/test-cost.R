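test_that("study cost matches the cost model and is linear in n, affine in t", {
  expect_equal(study_cost(100, 60, 500, 500), 100000)
  expect_equal(study_cost(0, 37, 500, 500), 0)
  expect_equal(study_cost(2000, 10, 500, 500), (10 / 60 * 500 + 500) * 2000)
  expect_equal(study_cost(2000, 10, 500, 500), 1166666.67, tolerance = 1e-8)

  set.seed(3)
  for (i in 1:10) {
    n <- sample(1000, 1); t <- runif(1, 1, 120)
    s <- runif(1, 100, 2000); o <- runif(1, 100, 5000)
    expect_equal(study_cost(2 * n, t, s, o), 2 * study_cost(n, t, s, o))
    expect_equal(study_cost(n, t + 60, s, o) - study_cost(n, t, s, o),
                 n * s) # one extra hour costs n * S
  }
  expect_error(study_cost(-1, 10), ">= 0")
  expect_error(cost_spec(budget = -5))
})

test_that("budget optimization matches exhaustive enumeration and degenerate cases", {
  # scan time worthless (k2 = 0): spend everything on sample size
  flat <- design_surface(
    tibble::tibble(dataset = "d", phenotype = "p", metric = "pearson",
                   k0 = 0.5, k1 = 100, k2 = 0),
    train_fraction = 0.9)
  res <- optimize_within_budget(flat, 1e6, 500, 500, t_grid = 5:60)
  expect_equal(res$t_min, 5)

  set.seed(17)
  for (i in 1:10) {
    surf <- random_surface(sample(1:3, 1))
    budget <- runif(1, 2e5, 3e6)
    s <- sample(c(500, 1000), 1); o <- sample(c(500, 1000), 1)
    t_grid <- seq(2, 120, by = 2)
    res <- optimize_within_budget(surf, budget, s, o, t_grid = t_grid)
    # oracle: enumerate every t on the same grid
    n_all <- floor(budget / (t_grid / 60 * s + o))
    ok <- n_all * 0.9 >= 1
    fr <- eval_surface(surf, n_all[ok], t_grid[ok])
    best <- which(fr == max(fr))[1]
    expect_equal(res$t_min, t_grid[ok][best])
    expect_equal(res$n_recruited, n_all[ok][best])
    expect_equal(res$fraction, fr[best])
  }

  expect_error(optimize_within_budget(flat, 100, 500, 5000), "infeasible")
})

test_that("target optimization matches enumeration over the costed contour", {
  flat <- design_surface(
    tibble::tibble(dataset = "d", phenotype = "p", metric = "pearson",
                   k0 = 0.5, k1 = 100, k2 = 0))
  res <- optimize_for_target(flat, 0.9, 500, 500, t_grid = seq(5, 60, 5))
  expect_equal(res$optimal_t_min, 5)

  set.seed(23)
  for (i in 1:10) {
    surf <- random_surface(sample(1:3, 1))
    s <- sample(c(500, 1000), 1); o <- sample(c(500, 1000), 1)
    tg <- sample(c(0.8, 0.9, 0.95), 1)
    t_grid <- seq(2, 120, by = 2)
    res <- optimize_for_target(surf, tg, s, o, t_grid = t_grid)
    n_c <- ceiling(contour_sample(surf, tg, t_grid)$n_recruited)
    cost <- study_cost(n_c, t_grid, s, o)
    best <- which(cost == min(cost))[1]
    expect_equal(res$optimal_t_min, t_grid[best])
    expect_equal(res$min_cost, cost[best], tolerance = 1e-9)
    expect_equal(res$min_cost,
                 study_cost(res$optimal_n, res$optimal_t_min, s, o))
  }
})

test_that("higher overhead never shortens, higher scan cost never lengthens, the optimum", {
  set.seed(29)
  for (i in 1:5) {
    surf <- random_surface(2)
    t_grid <- seq(2, 150, by = 2)
    base_b <- optimize_within_budget(surf, 1e6, 500, 500, t_grid = t_grid)
    hi_o_b <- optimize_within_budget(surf, 1e6, 500, 2000, t_grid = t_grid)
    hi_s_b <- optimize_within_budget(surf, 1e6, 2000, 500, t_grid = t_grid)
    expect_gte(hi_o_b$t_min, base_b$t_min)
    expect_lte(hi_s_b$t_min, base_b$t_min)

    base_t <- optimize_for_target(surf, 0.9, 500, 500, t_grid = t_grid)
    hi_o_t <- optimize_for_target(surf, 0.9, 500, 2000, t_grid = t_grid)
    hi_s_t <- optimize_for_target(surf, 0.9, 2000, 500, t_grid = t_grid)
    expect_gte(hi_o_t$optimal_t_min, base_t$optimal_t_min)
    expect_lte(hi_s_t$optimal_t_min, base_t$optimal_t_min)
  }
})

test_that("inefficiency curves are anchored at the optimum and agree with savings", {
  set.seed(37)
  surfaces <- list(a = random_surface(3), b = random_surface(2))
  conditions <- scenario_conditions()
  curve <- cost_inefficiency_curve(surfaces, conditions)
  expect_true(all(curve$inefficiency >= 0))
  expect_equal(min(curve$normalized), 0)
  expect_equal(curve$n_scenarios, rep(24, nrow(curve)))

  # single scenario: the curve minimum sits at that scenario's optimum
  one <- cost_inefficiency_curve(
    surfaces$a, conditions[1, ], fixed_t_grid = seq(5, 100, 5))
  opt <- attr(one, "scenarios")
  grid_opt <- one$t_min[which.min(one$inefficiency)]
  expect_lte(abs(grid_opt - opt$optimal_t_min), 5) # within one grid step

  # savings and inefficiency name the same best fixed time
  sav <- savings_vs_reference(surfaces, conditions, reference_t = 10)
  expect_equal(sav$savings_pct[sav$t_min == 10], 0)
  expect_equal(curve$t_min[which.min(curve$inefficiency)],
               sav$t_min[which.max(sav$savings_pct)])
})

test_that("the bootstrap of the best fixed time is seeded and degenerates gracefully", {
  set.seed(43)
  fits <- purrr::map_dfr(1:3, function(i) {
    p <- random_params()
    tibble::tibble(dataset = c("d1", "d1", "d2")[i],
                   phenotype = paste0("p", i), metric = "pearson",
                   k0 = p$k0, k1 = p$k1, k2 = p$k2)
  })
  b1 <- bootstrap_best_fixed_time(fits, n_boot = 30, seed = 7)
  b2 <- bootstrap_best_fixed_time(fits, n_boot = 30, seed = 7)
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, b1$best_t)
  expect_gte(b1$ci_high, b1$best_t)

  expect_warning(one <- bootstrap_best_fixed_time(fits[1, ], n_boot = 10),
                 "one phenotype")
  expect_equal(one$ci_low, one$best_t)
  expect_equal(one$ci_high, one$best_t)
})

test_that("bootstrap CIs bracket heterogeneous per-phenotype optima", {
  # three phenotypes with very different noise terms -> different optima
  fits <- tibble::tibble(
    dataset = "d1", phenotype = c("fast", "mid", "slow"),
    metric = "pearson", k0 = 0.6,
    k1 = c(200, 100, 20), k2 = c(200, 3000, 30000))
  conditions <- scenario_conditions(targets = 0.9, overheads = 1000,
                                    scan_costs = 500)
  per_opt <- vapply(1:3, function(i) {
    cv <- cost_inefficiency_curve(design_surface(fits[i, ]), conditions)
    cv$t_min[which.min(cv$inefficiency)]
  }, numeric(1))
  boot <- bootstrap_best_fixed_time(fits, conditions, n_boot = 200, seed = 11)
  draws <- attr(boot, "boot")
  # resampling reaches every single-phenotype optimum (all-one-phenotype
  # draws occur), so the resampled arg-minima bracket all three
  expect_lte(min(draws), min(per_opt))
  expect_gte(max(draws), max(per_opt))
  expect_gte(boot$ci_low, min(draws))
  expect_lte(boot$ci_high, max(draws))
  expect_true(boot$best_t >= boot$ci_low && boot$best_t <= boot$ci_high)
})

test_that("attrition inflates recruitment and session caps are reported", {
  surf <- design_surface(
    tibble::tibble(dataset = "d", phenotype = "p", metric = "pearson",
                   k0 = 0.6, k1 = 100, k2 = 2000))
  full <- optimize_for_target(surf, 0.9, 500, 500)
  lossy <- optimize_for_target(surf, 0.9, 500, 500,
                               expected_usable_fraction = 0.8)
  expect_gte(lossy$optimal_n, ceiling(full$optimal_n / 0.8) - 1)
  expect_gt(lossy$min_cost, full$min_cost)

  capped <- optimize_for_target(surf, 0.9, 500, 500, max_session_min = 20)
  expect_equal(capped$n_sessions, ceiling(capped$optimal_t_min / 20))

  # with attrition the same budget buys fewer usable subjects
  b_full <- optimize_within_budget(surf, 1e6, 500, 500)
  b_lossy <- optimize_within_budget(surf, 1e6, 500, 500,
                                    expected_usable_fraction = 0.7)
  expect_lte(b_lossy$fraction, b_full$fraction)
})
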