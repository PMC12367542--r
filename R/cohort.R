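#' Configuration of a synthetic BWAS cohort
#'
#' Describes a simulated cohort with the statistical structure the accuracy
#' scaling law assumes: subject-level true functional-connectivity (FC)
#' edges, observation noise whose variance shrinks as 1/T with scan time,
#' a sparse linear FC-phenotype relationship with additive phenotype noise,
#' and optional sibling blocks, site clusters, multi-run sessions and
#' run-level non-stationarity.
#'
#' Two observation modes are supported. `"direct_noise"` (the default, and
#' fast) adds Gaussian noise with per-edge variance `obs_noise_sd^2 / t` to
#' the true edges, run by run; `"time_series"` synthesizes stationary
#' Gaussian parcel time series whose population correlations encode the
#' true edges and computes Pearson FC from the first `t` minutes, which is
#' how the 1/T noise assumption itself can be validated.
#'
#' @param n_subjects Number of subjects.
#' @param n_parcels Number of parcels (edges = `p(p-1)/2`).
#' @param edge_signal_sd Between-subject sd of true edge values
#'   (`direct_noise`) or of the subject-specific loading perturbation
#'   (`time_series`).
#' @param obs_noise_sd Observation noise sd per edge at 1 minute of scan
#'   (variance scales as `obs_noise_sd^2 / t`); `direct_noise` mode only.
#' @param phenotype_weight_density Fraction of edges with nonzero weight,
#'   in (0, 1].
#' @param phenotype_noise_sd Phenotype noise sd; the noise-free linear part
#'   is scaled to unit variance, so the population brain-phenotype
#'   correlation is `1 / sqrt(1 + phenotype_noise_sd^2)`.
#' @param n_runs Runs per session; `n_runs * run_length_min` is the maximum
#'   usable scan time.
#' @param run_length_min Run length, minutes.
#' @param tr_seconds Repetition time of the simulated acquisition.
#' @param n_edge_factors Number of latent edge factors giving the true
#'   edges a shared low-rank covariance structure (the network structure
#'   of real FC); 0 (default) draws edges independently.
#' @param edge_factor_share Fraction of true edge variance carried by the
#'   latent factors when `n_edge_factors > 0`.
#' @param family_block_size Subjects per sibling block (1 = unrelated).
#' @param n_sites Number of acquisition sites.
#' @param site_effect_sd Sd of additive per-site phenotype offsets.
#' @param mode `"direct_noise"` or `"time_series"`.
#' @param seed Seed; fully determines the cohort.
#'
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 2000, n_parcels = 50,
                          edge_signal_sd = 0.1, obs_noise_sd = 0.12,
                          phenotype_weight_density = 0.2,
                          phenotype_noise_sd = 0.75,
                          n_runs = 4, run_length_min = 5, tr_seconds = 0.8,
                          n_edge_factors = 0, edge_factor_share = 0.5,
                          family_block_size = 1, n_sites = 1,
                          site_effect_sd = 0,
                          mode = c("direct_noise", "time_series"),
                          seed = 1) {
  mode <- rlang::arg_match(mode)
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(n_subjects) && n_subjects >= 2, "n_subjects must be >= 2")
  chk(is.numeric(n_parcels) && n_parcels >= 2, "n_parcels must be >= 2")
  chk(is.numeric(edge_signal_sd) && edge_signal_sd >= 0,
      "edge_signal_sd must be >= 0")
  chk(is.numeric(obs_noise_sd) && obs_noise_sd >= 0,
      "obs_noise_sd must be >= 0")
  chk(is.numeric(phenotype_weight_density) &&
        phenotype_weight_density > 0 && phenotype_weight_density <= 1,
      "phenotype_weight_density must be in (0, 1]")
  chk(is.numeric(phenotype_noise_sd) && phenotype_noise_sd >= 0,
      "phenotype_noise_sd must be >= 0")
  chk(is.numeric(n_runs) && n_runs >= 1, "n_runs must be >= 1")
  chk(is.numeric(run_length_min) && run_length_min > 0,
      "run_length_min must be > 0")
  chk(is.numeric(tr_seconds) && tr_seconds > 0, "tr_seconds must be > 0")
  chk(is.numeric(n_edge_factors) && n_edge_factors >= 0,
      "n_edge_factors must be >= 0")
  chk(is.numeric(edge_factor_share) && edge_factor_share >= 0 &&
        edge_factor_share < 1, "edge_factor_share must be in [0, 1)")
  chk(is.numeric(family_block_size) && family_block_size >= 1,
      "family_block_size must be >= 1")
  chk(is.numeric(n_sites) && n_sites >= 1, "n_sites must be >= 1")
  chk(is.numeric(site_effect_sd) && site_effect_sd >= 0,
      "site_effect_sd must be >= 0")
  chk(is.numeric(seed) && length(seed) == 1, "seed must be a single number")
  if (length(problems) > 0) {
    abort(paste0("Invalid cohort configuration: ",
                 paste(problems, collapse = "; "), "."))
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_parcels = as.integer(n_parcels),
         edge_signal_sd = edge_signal_sd, obs_noise_sd = obs_noise_sd,
         phenotype_weight_density = phenotype_weight_density,
         phenotype_noise_sd = phenotype_noise_sd,
         n_runs = as.integer(n_runs), run_length_min = run_length_min,
         tr_seconds = tr_seconds,
         n_edge_factors = as.integer(n_edge_factors),
         edge_factor_share = edge_factor_share,
         family_block_size = as.integer(family_block_size),
         n_sites = as.integer(n_sites), site_effect_sd = site_effect_sd,
         mode = mode, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

n_edges <- function(p) p * (p - 1L) / 2L

#' Generate a synthetic cohort
#'
#' Draws a cohort from its configuration: true FC edges (and, in
#' `time_series` mode, subject-specific factor loadings defining valid
#' correlation matrices), a sparse weight vector over edges scaled so the
#' noise-free linear phenotype part has unit population variance, the noisy
#' phenotype, contiguous sibling blocks and site assignments. The same seed
#' always reproduces the identical cohort.
#'
#' @param config A [cohort_config()].
#'
#' @return An object of class `"bwas_cohort"`: a list with `config`,
#'   `true_features` (subjects x edges), `true_weights`, `subjects` (a
#'   tibble with `subject_id`, `phenotype`, `family_id`, `site_id`),
#'   `run_levels`, `run_perm`, and drift fields (zeroed until
#'   [inject_nonstationarity()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n <- cfg$n_subjects
  p <- cfg$n_parcels
  e <- n_edges(p)

  with_local_seed(child_seed(cfg$seed, 1), {
    if (cfg$mode == "direct_noise") {
      if (cfg$n_edge_factors > 0) {
        # Low-rank + diagonal covariance: latent factors carry
        # `edge_factor_share` of each edge's between-subject variance.
        q <- cfg$n_edge_factors
        lam <- matrix(rnorm(e * q,
                            sd = cfg$edge_signal_sd *
                              sqrt(cfg$edge_factor_share / q)), e, q)
        true_features <- matrix(rnorm(n * q), n, q) %*% t(lam) +
          matrix(rnorm(n * e,
                       sd = cfg$edge_signal_sd *
                         sqrt(1 - cfg$edge_factor_share)), n, e)
      } else {
        true_features <- matrix(rnorm(n * e, sd = cfg$edge_signal_sd), n, e)
      }
      loadings <- NULL
    } else {
      # Factor model: a shared loading matrix plus subject perturbations
      # yields a valid, subject-specific correlation matrix per subject.
      q <- 5L
      base_loadings <- matrix(rnorm(p * q, sd = 0.6), p, q)
      loadings <- lapply(seq_len(n), function(s) {
        base_loadings + matrix(rnorm(p * q, sd = cfg$edge_signal_sd), p, q)
      })
      true_features <- t(vapply(loadings, function(a) {
        cmat <- stats::cov2cor(tcrossprod(a) + diag(p))
        vectorize_fc(cmat)
      }, numeric(e)))
    }

    n_nz <- max(1L, round(cfg$phenotype_weight_density * e))
    w <- numeric(e)
    nz <- sample(e, n_nz)
    w[nz] <- rnorm(n_nz)
    # Scale weights so the population linear part has unit variance.
    lin <- as.numeric(true_features %*% w)
    s_lin <- sd(lin)
    if (s_lin > 0) {
      w <- w / s_lin
      lin <- lin / s_lin
    }
    lin <- lin - mean(lin)

    family_id <- rep(seq_len(ceiling(n / cfg$family_block_size)),
                     each = cfg$family_block_size)[seq_len(n)]
    site_id <- rep_len(seq_len(cfg$n_sites), n)
    site_fx <- rnorm(cfg$n_sites, sd = cfg$site_effect_sd)
    phen <- lin + rnorm(n, sd = cfg$phenotype_noise_sd) + site_fx[site_id]

    structure(
      list(
        config = cfg,
        true_features = true_features,
        true_weights = w,
        loadings = loadings,
        subjects = tibble::tibble(
          subject_id = seq_len(n), phenotype = phen,
          family_id = family_id, site_id = site_id),
        # Drift expression by acquisition position: first run clean,
        # last run at full strength.
        run_levels = if (cfg$n_runs > 1) {
          (seq_len(cfg$n_runs) - 1) / (cfg$n_runs - 1)
        } else {
          0
        },
        drift_sd = 0,
        drift_seed = NA_integer_,
        run_perm = matrix(rep(seq_len(cfg$n_runs), each = n), n,
                          cfg$n_runs)
      ),
      class = "bwas_cohort"
    )
  })
}

#' @export
print.bwas_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<bwas_cohort> %d subjects, %d parcels (%d edges), %d run(s) x %g min, mode = %s\n",
    cfg$n_subjects, cfg$n_parcels, n_edges(cfg$n_parcels), cfg$n_runs,
    cfg$run_length_min, cfg$mode))
  if (x$drift_sd > 0) {
    cat(sprintf("  run drift sd = %g\n", x$drift_sd))
  }
  invisible(x)
}

#' Inject run-level non-stationarity
#'
#' Gives every run its own transient, phenotype-unrelated "state"
#' disturbance of each subject's generative edge values (in `time_series`
#' mode, a run-mean shift of the parcel series), with an amplitude that
#' grows with the run's position in the session — an arousal-like drift.
#' The first run is undisturbed; run `j` is disturbed with amplitude
#' `drift_sd * (j-1) / (n_runs-1)` relative to `edge_signal_sd`. FC
#' computed from early minutes is then systematically cleaner than FC
#' computed from late minutes: in acquisition order the effective
#' measurement noise grows with scan time instead of shrinking as 1/T,
#' violating the stationarity assumption of the scaling law in a
#' controlled way. [randomize_run_order()] makes the disturbed minutes
#' exchangeable again, restoring 1/T behaviour.
#'
#' @param cohort A `"bwas_cohort"` with at least 2 runs.
#' @param drift_sd Drift amplitude of the last run, relative to
#'   `edge_signal_sd` (0 = identity).
#' @param seed Seed for the per-run state disturbances.
#'
#' @return The cohort with drift fields set.
#' @export
inject_nonstationarity <- function(cohort, drift_sd, seed = 1) {
  stopifnot(inherits(cohort, "bwas_cohort"))
  if (drift_sd == 0) {
    cohort$drift_sd <- 0
    return(cohort)
  }
  if (cohort$config$n_runs < 2) {
    abort("Run drift needs at least 2 runs.")
  }
  cohort$drift_sd <- drift_sd
  cohort$drift_seed <- as.integer(seed)
  cohort
}

#' Randomize the run order independently per subject
#'
#' Permutes, for each subject independently, the order in which that
#' subject's runs are consumed when FC is computed from the first `t`
#' minutes. Under non-stationary drift this restores exchangeability of
#' early and late scan minutes.
#'
#' @param cohort A `"bwas_cohort"`.
#' @param seed Seed; the same seed reproduces the same permutations.
#'
#' @return The cohort with its `run_perm` replaced.
#' @export
randomize_run_order <- function(cohort, seed = 1) {
  stopifnot(inherits(cohort, "bwas_cohort"))
  r <- cohort$config$n_runs
  if (r == 1) {
    return(cohort)
  }
  n <- cohort$config$n_subjects
  cohort$run_perm <- with_local_seed(child_seed(seed, 3), {
    t(vapply(seq_len(n), function(s) sample.int(r), integer(r)))
  })
  cohort
}

# Minutes consumed at each within-session position for a total of t_min.
position_minutes <- function(t_min, n_runs, run_length_min) {
  used <- pmin(pmax(t_min - (seq_len(n_runs) - 1) * run_length_min, 0),
               run_length_min)
  used
}

#' Observed FC features at a given scan time
#'
#' Produces each subject's observed FC feature vector from the first
#' `t_min` minutes of their (possibly permuted) run sequence. In
#' `direct_noise` mode, each run contributes an independent noisy estimate
#' of the true edges (noise variance `obs_noise_sd^2` per minute used),
#' and the estimates are combined time-weighted, so the combined noise
#' variance is exactly `obs_noise_sd^2 / t_min`; run drift, if injected,
#' shifts each run's estimate. In `time_series` mode, stationary Gaussian
#' parcel series are synthesized run by run and Pearson FC is computed
#' from the concatenated first `t_min` minutes.
#'
#' @param cohort A `"bwas_cohort"`.
#' @param t_min Scan time, minutes; at most `n_runs * run_length_min`.
#' @param seed Seed for the observation noise (per-run noise is tied to
#'   the physical run, so re-ordering runs under the same seed reuses the
#'   same run-level draws).
#'
#' @return A subjects x edges matrix of observed features, with attribute
#'   `t_min`.
#' @export
observe_fc <- function(cohort, t_min, seed = 1) {
  stopifnot(inherits(cohort, "bwas_cohort"))
  cfg <- cohort$config
  t_max <- cfg$n_runs * cfg$run_length_min
  if (t_min <= 0 || t_min > t_max) {
    abort(sprintf("`t_min` must be in (0, %g] for this cohort.", t_max))
  }
  if (cfg$mode == "direct_noise") {
    observe_fc_direct(cohort, t_min, seed)
  } else {
    observe_fc_series(cohort, t_min, seed)
  }
}

observe_fc_direct <- function(cohort, t_min, seed) {
  cfg <- cohort$config
  n <- cfg$n_subjects
  e <- ncol(cohort$true_features)
  r <- cfg$n_runs
  mins <- position_minutes(t_min, r, cfg$run_length_min)
  obs <- cohort$true_features
  drift <- cohort$drift_sd > 0

  with_local_seed(child_seed(seed, 11), {
    # One standardized noise draw per (subject, physical run); a run used
    # for m minutes contributes sd obs_noise_sd/sqrt(m), weighted m/t.
    for (run in seq_len(r)) {
      z <- matrix(rnorm(n * e), n, e)
      pos_of_run <- apply(cohort$run_perm, 1, function(p) which(p == run))
      m <- mins[pos_of_run] # minutes this physical run contributes, per subj
      use <- m > 0
      if (!any(use)) next
      scale_noise <- cfg$obs_noise_sd * sqrt(m[use]) / t_min
      obs[use, ] <- obs[use, ] + z[use, , drop = FALSE] * scale_noise
      if (drift && cohort$run_levels[run] > 0) {
        # Per-(subject, physical run) state disturbance: the draw is keyed
        # to the physical run, so re-ordering runs re-orders, but does not
        # re-draw, the states.
        v <- with_local_seed(child_seed(cohort$drift_seed, 21, run), {
          matrix(rnorm(n * e, sd = cfg$edge_signal_sd), n, e)
        })
        amp <- cohort$drift_sd * cohort$run_levels[run] * (m[use] / t_min)
        obs[use, ] <- obs[use, ] + v[use, , drop = FALSE] * amp
      }
    }
  })
  attr(obs, "t_min") <- t_min
  obs
}

observe_fc_series <- function(cohort, t_min, seed) {
  cfg <- cohort$config
  n <- cfg$n_subjects
  p <- cfg$n_parcels
  frames_per_run <- round(cfg$run_length_min * 60 / cfg$tr_seconds)
  mins <- position_minutes(t_min, cfg$n_runs, cfg$run_length_min)
  frames_pos <- round(mins * 60 / cfg$tr_seconds)
  drift <- cohort$drift_sd > 0

  obs <- with_local_seed(child_seed(seed, 12), {
    t(vapply(seq_len(n), function(s) {
      a <- cohort$loadings[[s]]
      cmat <- stats::cov2cor(tcrossprod(a) + diag(p))
      ch <- chol(cmat)
      segs <- list()
      for (k in seq_len(cfg$n_runs)) {
        if (frames_pos[k] == 0) next
        run <- cohort$run_perm[s, k]
        z <- matrix(rnorm(frames_per_run * p), frames_per_run, p) %*% ch
        if (drift && cohort$run_levels[run] > 0) {
          mu <- with_local_seed(child_seed(cohort$drift_seed, 22, run, s), {
            rnorm(p, sd = cohort$drift_sd * cohort$run_levels[run])
          })
          z <- sweep(z, 2, mu, `+`)
        }
        segs[[length(segs) + 1]] <- z[seq_len(frames_pos[k]), , drop = FALSE]
      }
      series <- do.call(rbind, segs)
      vectorize_fc(cor(series))
    }, numeric(n_edges(p))))
  })
  attr(obs, "t_min") <- t_min
  obs
}
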