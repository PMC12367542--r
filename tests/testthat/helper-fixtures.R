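# Shared fixture builders. Everything is generated in code; no data files.

# An accuracy grid lying exactly on the scaling law.
law_grid <- function(k0 = 0.5, k1 = 50, k2 = 500,
                     n_vec = seq(100, 700, by = 100),
                     t_vec = seq(2, 58, by = 4),
                     dataset = "d1", phenotype = "p1", metric = "pearson") {
  g <- tidyr::expand_grid(n_train = n_vec, t_min = t_vec)
  tibble::tibble(
    dataset = dataset, phenotype = phenotype, metric = metric,
    n_train = g$n_train, t_min = g$t_min,
    accuracy = theoretical_accuracy(g$n_train, g$t_min, k0, k1, k2),
    n_reps = 1L
  )
}

# An accuracy grid lying exactly on the logarithmic model.
log_grid <- function(slope = 0.05, intercept = 0.1,
                     n_vec = c(100, 200, 400), t_vec = c(2, 5, 10, 20),
                     dataset = "d1", phenotype = "p1") {
  g <- tidyr::expand_grid(n_train = n_vec, t_min = t_vec)
  tibble::tibble(
    dataset = dataset, phenotype = phenotype, metric = "pearson",
    n_train = g$n_train, t_min = g$t_min,
    accuracy = slope * log2(g$n_train * g$t_min) + intercept,
    n_reps = 1L
  )
}

# Random plausible law parameters.
random_params <- function() {
  list(k0 = runif(1, 0.2, 0.95),
       k1 = runif(1, 5, 500),
       k2 = runif(1, 50, 5000))
}

# A surface over a few random phenotype fits.
random_surface <- function(n_phen = 3, train_fraction = 0.9) {
  fits <- purrr::map_dfr(seq_len(n_phen), function(i) {
    p <- random_params()
    tibble::tibble(dataset = "d1", phenotype = paste0("p", i),
                   metric = "pearson", k0 = p$k0, k1 = p$k1, k2 = p$k2,
                   r2 = 1, converged = TRUE, n_cells = 16L)
  })
  design_surface(fits, train_fraction = train_fraction)
}

# A small cohort for engine tests.
small_cohort <- function(n_subjects = 120, n_parcels = 12, seed = 1, ...) {
  generate_cohort(cohort_config(n_subjects = n_subjects,
                                n_parcels = n_parcels, seed = seed, ...))
}
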