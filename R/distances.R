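#' Mahalanobis distance of a residual profile from the control model
#'
#' `M = sqrt( (s - mu)' C^-1 (s - mu) )`, where `s` is a subject's vector of
#' age-residualized FA values, `mu` the control mean vector and `C` the
#' control between-tract covariance. M is zero iff `s = mu` and grows with
#' covariance-adjusted distance from the control centroid, so spatially
#' different injuries of equal "unusualness" map to the same score.
#'
#' @param s numeric vector of residuals, tract order matching the model.
#' @param model a `control_model` (the Cholesky factor is computed on the fly
#'   if [invert_model()] has not been applied).
#' @return Nonnegative scalar.
#' @export
mahalanobis_dist <- function(s, model) {
  stopifnot(inherits(model, "control_model"))
  s <- as.numeric(s)
  if (length(s) != length(model$mu))
    stop("schema error: profile length ", length(s),
         " does not match model dimension ", length(model$mu))
  if (is.null(model$chol)) model <- invert_model(model)
  sqrt(quad_form_chol(model$chol, s - model$mu))
}

#' Per-tract absolute z-scores against the control model
#'
#' The univariate comparator to [mahalanobis_dist()]: for each tract `t`,
#' `|Z_t| = |s_t - mu_t| / sd_t`, ignoring between-tract covariance.
#'
#' @inheritParams mahalanobis_dist
#' @return Named nonnegative vector, one entry per tract.
#' @export
univariate_z <- function(s, model) {
  stopifnot(inherits(model, "control_model"))
  s <- as.numeric(s)
  if (length(s) != length(model$mu))
    stop("schema error: profile length ", length(s),
         " does not match model dimension ", length(model$mu))
  z <- abs(s - model$mu) / model$sd
  names(z) <- model$tracts
  z
}

# deterministic per-subject seed: polynomial hash of the id folded into the
# master seed, mod 2^31 - 1, so scores do not depend on cohort row order
subject_seed <- function(master, id) {
  h <- 0
  for (b in utf8ToInt(as.character(id))) h <- (h * 31 + b) %% 2147483647
  as.integer((h + as.numeric(master)) %% 2147483646) + 1L
}

#' Conservative permutation-subsampled distance scores for one subject
#'
#' Repeats `n_perm` times: draw `subset_size` controls without replacement
#' from the pool, fit a [fit_control_model()] (mu, sd and C all from that
#' subsample), and compute the subject's M and per-tract |Z| against it. The
#' per-subject score is the median across permutations, a conservative
#' estimate that is robust to any single unrepresentative control subsample.
#' If the subject is itself in the pool it is removed first (leave-one-out),
#' so a control is never scored against a model it helped build.
#'
#' @param subject numeric residual vector for the subject being scored.
#' @param control_pool numeric matrix (controls x tracts) of control
#'   residuals, or a `residual_profiles` object (its controls are used).
#' @param subset_size controls per subsample (default 25).
#' @param n_perm number of subsamples (default 1000).
#' @param seed integer seed; results are bit-reproducible given it.
#' @param method covariance estimator passed to the per-subsample model fit.
#' @param sd_pool `"subsample"` (default) divides |Z| by each subsample's SD;
#'   `"full"` uses the full-pool SD for every permutation.
#' @param subject_id optional identifier stored in the result.
#' @param pool_ids optional ids of pool rows; if `subject_id` matches one,
#'   that row is held out.
#' @return An object of class `distance_result`: list with `subject_id`,
#'   `m_median`, `z_median` (named vector), `n_perm`, `subset_size`, `seed`,
#'   `held_out`.
#' @export
permuted_scores <- function(subject, control_pool, subset_size = 25L,
                            n_perm = 1000L, seed = 1L,
                            method = c("shrinkage", "sample"),
                            sd_pool = c("subsample", "full"),
                            subject_id = NA_character_, pool_ids = NULL) {
  method <- match.arg(method)
  sd_pool <- match.arg(sd_pool)
  if (inherits(control_pool, "residual_profiles")) {
    keep <- control_pool$group == "control"
    pool_ids <- control_pool$subject_id[keep]
    control_pool <- control_pool$fa_r[keep, , drop = FALSE]
  }
  X <- as.matrix(control_pool)
  held_out <- FALSE
  if (!is.null(pool_ids)) {
    # canonical id order: subsampling must not depend on cohort row order
    ord <- order(pool_ids)
    X <- X[ord, , drop = FALSE]
    pool_ids <- pool_ids[ord]
    if (!is.na(subject_id) && subject_id %in% pool_ids) {
      X <- X[pool_ids != subject_id, , drop = FALSE]
      held_out <- TRUE
    }
  }
  n_pool <- nrow(X)
  p <- ncol(X)
  subset_size <- as.integer(subset_size)
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("validation error: n_perm must be >= 1")
  if (subset_size > n_pool)
    stop("sample-size error: subset_size (", subset_size,
         ") exceeds available control pool (", n_pool, ")")
  if (subset_size < 3L)
    stop("sample-size error: subset_size must be >= 3")
  if (length(subject) != p)
    stop("schema error: subject profile length does not match pool tracts")

  set.seed(seed)
  idx <- matrix(0L, n_perm, subset_size)
  for (r in seq_len(n_perm)) idx[r, ] <- sample.int(n_pool, subset_size)
  sd_fixed <- if (sd_pool == "full") apply(X, 2L, stats::sd) else numeric(0L)
  res <- perm_scores_cpp(X, as.numeric(subject), idx,
                         as.integer(method == "shrinkage"), sd_fixed)
  z_med <- apply(res$z, 2L, stats::median)
  names(z_med) <- colnames(X)
  structure(
    list(subject_id = subject_id,
         m_median = stats::median(res$m),
         z_median = z_med,
         n_perm = n_perm, subset_size = subset_size, seed = seed,
         held_out = held_out),
    class = "distance_result"
  )
}

#' Score every subject in a cohort
#'
#' Patients are scored against the full control pool; each control is scored
#' with itself held out of every subsample. One master seed spawns an
#' independent, id-keyed stream per subject, so a subject's scores do not
#' depend on cohort row order.
#'
#' @param residuals a `residual_profiles` object for the whole cohort.
#' @inheritParams permuted_scores
#' @param seed master integer seed.
#' @return A data.frame of class `distance_table`: columns `subject_id`,
#'   `group`, `held_out`, `m_median`, and one `z_<tract>` column per tract;
#'   attributes `n_perm`, `subset_size`, `seed`, `method`, `sd_pool`,
#'   `tracts`.
#' @export
score_cohort <- function(residuals, subset_size = 25L, n_perm = 1000L,
                         seed = 1L, method = c("shrinkage", "sample"),
                         sd_pool = c("subsample", "full")) {
  method <- match.arg(method)
  sd_pool <- match.arg(sd_pool)
  stopifnot(inherits(residuals, "residual_profiles"))
  is_control <- residuals$group == "control"
  n_controls <- sum(is_control)
  if (n_controls < subset_size + 1L)
    stop("sample-size error: need at least subset_size + 1 = ",
         subset_size + 1L, " controls for leave-one-out scoring, have ",
         n_controls)
  pool <- residuals$fa_r[is_control, , drop = FALSE]
  pool_ids <- residuals$subject_id[is_control]
  tracts <- colnames(residuals$fa_r)

  rows <- lapply(seq_along(residuals$subject_id), function(i) {
    id <- residuals$subject_id[i]
    r <- permuted_scores(residuals$fa_r[i, ], pool,
                         subset_size = subset_size, n_perm = n_perm,
                         seed = subject_seed(seed, id), method = method,
                         sd_pool = sd_pool, subject_id = id,
                         pool_ids = pool_ids)
    c(m_median = r$m_median, r$z_median)
  })
  scores <- do.call(rbind, rows)
  out <- data.frame(subject_id = residuals$subject_id,
                    group = residuals$group,
                    held_out = is_control,
                    m_median = scores[, "m_median"],
                    stringsAsFactors = FALSE, row.names = NULL)
  zmat <- scores[, -1L, drop = FALSE]
  colnames(zmat) <- paste0("z_", tracts)
  out <- cbind(out, as.data.frame(zmat, row.names = NULL))
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "subset_size") <- as.integer(subset_size)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "method") <- method
  attr(out, "sd_pool") <- sd_pool
  attr(out, "tracts") <- tracts
  class(out) <- c("distance_table", "data.frame")
  out
}
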