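# shared fixture builders; everything is generated in code at test time

# small cohort data.frame in the on-disk layout (fa_/cog_ prefixed columns)
make_cohort_df <- function(n_controls = 5L, n_patients = 4L, n_tracts = 3L,
                           seed = 1L, cognition = FALSE) {
  set.seed(seed)
  n <- n_controls + n_patients
  df <- data.frame(
    subject_id = sprintf("s%02d", seq_len(n)),
    group = c(rep("control", n_controls), rep("patient", n_patients)),
    age = round(runif(n, 20, 60), 1),
    stringsAsFactors = FALSE
  )
  for (t in seq_len(n_tracts))
    df[[sprintf("fa_tract%02d", t)]] <- round(runif(n, 0.3, 0.6), 4)
  if (cognition)
    for (j in 1:2) df[[sprintf("cog_test%d", j)]] <- round(rnorm(n, 50, 10), 2)
  df
}

write_cohort_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# correlated Gaussian residual matrix with compound-symmetry correlation
make_residuals <- function(n, p, rho = 0.4, sd = 1, seed = 1L) {
  set.seed(seed)
  R <- matrix(rho, p, p); diag(R) <- 1
  X <- MASS::mvrnorm(n, rep(0, p), R * sd^2)
  colnames(X) <- sprintf("t%02d", seq_len(p))
  X
}

# residual_profiles object straight from a matrix, for distance-level tests
make_profiles <- function(X, groups = NULL) {
  if (is.null(groups)) groups <- rep("control", nrow(X))
  structure(list(subject_id = sprintf("s%03d", seq_len(nrow(X))),
                 group = groups, age = rep(40, nrow(X)), fa_r = X,
                 fit_population = "controls_only"),
            class = "residual_profiles")
}

# naive (triple-loop) diagonal-target shrinkage estimator: independent oracle
# for the vectorized implementation, written directly from the intensity rule
naive_shrink <- function(X) {
  n <- nrow(X); p <- ncol(X)
  xb <- colMeans(X)
  S <- matrix(0, p, p)
  varS <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    w <- (X[, i] - xb[i]) * (X[, j] - xb[j])
    S[i, j] <- sum(w) / (n - 1)
    varS[i, j] <- n / (n - 1)^3 * sum((w - mean(w))^2)
  }
  num <- 0; den <- 0
  for (i in seq_len(p)) for (j in seq_len(p)) if (i != j) {
    num <- num + varS[i, j]; den <- den + S[i, j]^2
  }
  lambda <- if (den <= 0) 1 else min(1, max(num / den, 0))
  lambda <- max(lambda, 1e-12)
  C <- (1 - lambda) * S
  diag(C) <- diag(S)
  list(C = C, lambda = lambda)
}
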