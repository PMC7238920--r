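#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of a small mild-TBI tractometry
#' study: 31 controls and 34 patients over 22 association tract bundles;
#' correlated control FA (compound symmetry, rho = 0.4 — the regime where a
#' covariance-aware distance has its advantage over per-tract z-scores); a
#' weak negative linear age trend; spatially heterogeneous injury (each
#' patient has a random subset of 5-12 tracts reduced by 0.5-1.5 control
#' SDs); and a 4-test cognitive battery loaded on total injury burden, with
#' one test log-skewed so the Box-Cox branch is exercised.
#'
#' @param n_controls,n_patients,n_tracts cohort dimensions.
#' @param tract_names tract labels (default [association_tracts_22()] when
#'   `n_tracts` is 22, else `tract_01`...).
#' @param control_mu mean FA per tract at the reference age (recycled).
#' @param control_sd per-tract FA standard deviation (recycled).
#' @param cov_spec `"compound_symmetry"`, `"ar1"`, `"identity"`, or
#'   `"custom"` (then supply `cov_matrix`, a PD correlation matrix).
#' @param rho correlation parameter for compound symmetry / AR(1).
#' @param cov_matrix custom correlation matrix (tracts x tracts).
#' @param age_range sampling range of ages in years.
#' @param age_slope FA change per year, per tract (recycled); applied around
#'   the midpoint of `age_range`.
#' @param n_affected_range per-patient range (inclusive) of the number of
#'   injured tracts.
#' @param effect_range per-tract injury effect size range, in control-SD
#'   units.
#' @param effect_sign `-1` (default, FA reduction) or `+1`.
#' @param n_tests number of cognitive tests.
#' @param cog_loading loading of standardized total injury burden on each
#'   test (recycled), in test-SD units; applied negatively (injury lowers
#'   performance) since test scores are higher-is-better by default.
#' @param cog_noise_sd residual SD of each test on its standardized scale.
#' @param cog_skewed logical per test (recycled): pass the test score
#'   through `exp()` (log-normal) to plant skew.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_controls = 31L, n_patients = 34L,
                              n_tracts = 22L, tract_names = NULL,
                              control_mu = 0.45, control_sd = 0.025,
                              cov_spec = c("compound_symmetry", "ar1",
                                           "identity", "custom"),
                              rho = 0.4, cov_matrix = NULL,
                              age_range = c(18, 60), age_slope = -0.0008,
                              n_affected_range = NULL,
                              effect_range = c(0.5, 1.5), effect_sign = -1,
                              n_tests = 4L, cog_loading = 0.8,
                              cog_noise_sd = 0.6,
                              cog_skewed = c(FALSE, FALSE, FALSE, TRUE)) {
  cov_spec <- match.arg(cov_spec)
  n_tracts <- as.integer(n_tracts)
  if (is.null(tract_names)) {
    tract_names <- if (n_tracts == 22L) association_tracts_22()
                   else sprintf("tract_%02d", seq_len(n_tracts))
  }
  if (is.null(n_affected_range))
    n_affected_range <- c(min(5L, n_tracts), min(12L, n_tracts))
  stopifnot(length(tract_names) == n_tracts,
            length(age_range) == 2L, diff(age_range) > 0,
            n_affected_range[1L] >= 0L,
            n_affected_range[2L] <= n_tracts,
            effect_sign %in% c(-1, 1))
  R <- switch(cov_spec,
    identity = diag(n_tracts),
    compound_symmetry = {
      m <- matrix(rho, n_tracts, n_tracts); diag(m) <- 1; m
    },
    ar1 = rho^abs(outer(seq_len(n_tracts), seq_len(n_tracts), "-")),
    custom = {
      if (is.null(cov_matrix)) stop("config error: cov_matrix required")
      as.matrix(cov_matrix)
    })
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("config error: covariance specification is not positive definite")
  sds <- rep_len(control_sd, n_tracts)
  Sigma <- R * tcrossprod(sds)
  structure(
    list(n_controls = as.integer(n_controls),
         n_patients = as.integer(n_patients),
         n_tracts = n_tracts, tract_names = tract_names,
         control_mu = rep_len(control_mu, n_tracts),
         control_sd = sds, cov_spec = cov_spec, rho = rho, Sigma = Sigma,
         age_range = age_range,
         age_slope = rep_len(age_slope, n_tracts),
         n_affected_range = as.integer(n_affected_range),
         effect_range = effect_range, effect_sign = effect_sign,
         n_tests = as.integer(n_tests),
         cog_loading = rep_len(cog_loading, n_tests),
         cog_noise_sd = rep_len(cog_noise_sd, n_tests),
         cog_skewed = rep_len(cog_skewed, n_tests)),
    class = "simulation_config"
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Controls are drawn from a multivariate Gaussian over tract FA with the
#' configured covariance plus a linear age trend. Patients are drawn from the
#' same healthy distribution and then injured: a per-patient random subset of
#' tracts is shifted by per-tract random effects (in control-SD units), so
#' injuries are spatially heterogeneous across patients. Cognitive test
#' scores are generated as standardized baselines minus a loading times the
#' patient's standardized total injury burden plus noise; skew-flagged tests
#' are exponentiated (monotone), planting the skew the Box-Cox rule must
#' detect. Controls' burden is zero.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; the draw is fully reproducible given it.
#' @return list with `cohort` (a [cohort_table()]) and `truth`
#'   (`simulation_truth`: per-patient affected tracts and effects, total
#'   burden, true covariance, age slopes, cognition loadings).
#' @export
generate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  n_c <- config$n_controls
  n_p <- config$n_patients
  p <- config$n_tracts
  n <- n_c + n_p
  mid_age <- mean(config$age_range)

  age <- stats::runif(n, config$age_range[1L], config$age_range[2L])
  base <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = config$Sigma)
  trend <- outer(age - mid_age, config$age_slope)
  fa <- sweep(base + trend, 2L, config$control_mu, "+")
  colnames(fa) <- config$tract_names

  group <- c(rep("control", n_c), rep("patient", n_p))
  ids <- sprintf("%s_%02d", ifelse(group == "control", "ctrl", "pat"),
                 c(seq_len(n_c), seq_len(n_p)))

  affected <- vector("list", n)
  effects <- vector("list", n)
  burden <- numeric(n)
  kr <- config$n_affected_range
  for (i in which(group == "patient")) {
    k <- if (kr[2L] > kr[1L]) sample(seq(kr[1L], kr[2L]), 1L) else kr[1L]
    tr <- sort(sample.int(p, k))
    ef <- stats::runif(k, config$effect_range[1L], config$effect_range[2L])
    fa[i, tr] <- fa[i, tr] + config$effect_sign * ef * config$control_sd[tr]
    affected[[i]] <- config$tract_names[tr]
    effects[[i]] <- ef
    burden[i] <- sum(ef)
  }

  cognition <- NULL
  if (config$n_tests > 0L) {
    b_std <- if (stats::sd(burden) > 0) (burden - mean(burden)) / stats::sd(burden)
             else burden
    cognition <- matrix(NA_real_, n, config$n_tests,
                        dimnames = list(NULL, sprintf("test_%d",
                                                      seq_len(config$n_tests))))
    for (j in seq_len(config$n_tests)) {
      sc <- -config$cog_loading[j] * b_std +
        stats::rnorm(n, 0, config$cog_noise_sd[j])
      if (config$cog_skewed[j]) sc <- exp(sc)
      cognition[, j] <- sc
    }
  }

  cohort <- cohort_table(
    subjects = data.frame(subject_id = ids, group = group, age = age,
                          stringsAsFactors = FALSE),
    fa = fa, cognition = cognition
  )
  truth <- structure(
    list(seed = seed,
         affected_tracts = stats::setNames(affected, ids),
         effect_sizes = stats::setNames(effects, ids),
         burden = stats::setNames(burden, ids),
         Sigma = config$Sigma, age_slope = config$age_slope,
         cog_loading = config$cog_loading, cog_skewed = config$cog_skewed,
         config = config),
    class = "simulation_truth"
  )
  list(cohort = cohort, truth = truth)
}

#' Empirical null distribution of held-out control scores
#'
#' Generates `n_replicates` injury-free cohorts from `config` (effects forced
#' to zero), scores every control with leave-one-out permutation subsampling,
#' and pools the resulting median-M draws. This is the reference distribution
#' against which observed patient scores can be judged, and the oracle used
#' to check null calibration of the scoring pipeline.
#'
#' @param config a [simulation_config()].
#' @param n_replicates number of independent cohorts.
#' @param subset_size,n_perm,method passed to [score_cohort()].
#' @param seed master seed; replicate r uses `seed + r`.
#' @return list with `m_null` (pooled draws), `quantiles` (1/5/25/50/75/95/99
#'   percentiles), and the settings used.
#' @export
null_reference <- function(config, n_replicates = 20L, subset_size = 25L,
                           n_perm = 100L, method = "shrinkage", seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  cfg$n_affected_range <- c(0L, 0L)
  draws <- lapply(seq_len(n_replicates), function(r) {
    sim <- generate_cohort(cfg, seed = seed + r)
    am <- fit_age_model(sim$cohort, "controls_only")
    res <- residualize_cohort(sim$cohort, am)
    st <- score_cohort(res, subset_size = subset_size, n_perm = n_perm,
                       seed = seed + r, method = method)
    st$m_median[st$group == "control"]
  })
  m_null <- unlist(draws)
  list(m_null = m_null,
       quantiles = stats::quantile(m_null,
                                   c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99)),
       n_replicates = n_replicates, subset_size = subset_size,
       n_perm = n_perm, method = method, seed = seed)
}
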