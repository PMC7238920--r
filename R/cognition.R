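#' Standardized skewness and kurtosis (z-moments)
#'
#' Adjusted Fisher-Pearson sample skewness and excess kurtosis, each divided
#' by its exact normal-theory standard error:
#' `SE_skew = sqrt(6 n (n-1) / ((n-2)(n+1)(n+3)))`,
#' `SE_kurt = 2 * SE_skew * sqrt((n^2 - 1) / ((n-3)(n+5)))`.
#' A |z| above 1.96 flags a test score distribution as too skewed/kurtotic
#' for PCA and triggers the Box-Cox branch in [build_composite()].
#'
#' @param x numeric vector, `n >= 8`, non-constant.
#' @return named vector `c(z_skewness, z_kurtosis)`.
#' @export
z_moments <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8L) stop("input error: need n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop("degenerate error: constant input")
  g1 <- mean((x - m)^3) / m2^1.5
  G1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  se_skew <- sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3)))
  g2 <- mean((x - m)^4) / m2^2 - 3
  G2 <- ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3))
  se_kurt <- 2 * se_skew * sqrt((n^2 - 1) / ((n - 3) * (n + 5)))
  c(z_skewness = G1 / se_skew, z_kurtosis = G2 / se_kurt)
}

# profile log-likelihood of the Box-Cox model at lambda
boxcox_loglik <- function(x, lambda) {
  n <- length(x)
  y <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  -n / 2 * log(mean((y - mean(y))^2)) + (lambda - 1) * sum(log(x))
}

#' Box-Cox power transformation with maximum-likelihood lambda
#'
#' `y = (x^lambda - 1) / lambda` for `lambda != 0`, `y = log(x)` at
#' `lambda = 0`. When `lambda = NULL` it is chosen by profile maximum
#' likelihood: a coarse grid over \[-5, 5\] followed by golden-section
#' refinement in the best grid cell. The transform is strictly monotone for
#' every lambda, so rank-based statistics downstream are unchanged by it.
#'
#' @param x positive numeric vector.
#' @param lambda fixed exponent, or `NULL` to estimate.
#' @return list with `y` (transformed values) and `lambda`.
#' @export
box_cox <- function(x, lambda = NULL) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("input error: Box-Cox requires strictly positive finite values")
  if (is.null(lambda)) {
    grid <- seq(-5, 5, by = 0.1)
    ll <- vapply(grid, function(l) boxcox_loglik(x, l), numeric(1L))
    best <- which.max(ll)
    lo <- grid[max(best - 1L, 1L)]
    hi <- grid[min(best + 1L, length(grid))]
    lambda <- stats::optimize(function(l) boxcox_loglik(x, l),
                              c(lo, hi), maximum = TRUE, tol = 1e-8)$maximum
  }
  y <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  list(y = y, lambda = lambda)
}

#' Consolidated neurocognitive score (Box-Cox + PCA first component)
#'
#' Builds one summary score per subject from a battery of test scores: tests
#' whose distribution is flagged by [z_moments()] (|z skewness| or
#' |z kurtosis| above 1.96) are shifted to positivity if needed and Box-Cox
#' transformed; all tests are then standardized (zero mean, unit variance)
#' and the first principal component of the standardized matrix is taken as
#' the composite, sign-oriented so that higher = poorer performance.
#'
#' @param scores numeric matrix, subjects x tests, rownames = subject ids;
#'   or a [cohort_table()] with a cognition block (then `subjects` selects
#'   which rows enter the fit).
#' @param subjects `"patient"` (default: the composite is the patients'
#'   outcome variable) or `"all"`; ignored when `scores` is a bare matrix.
#' @param higher_is_worse logical, per test (recycled): does a higher raw
#'   score mean poorer performance? Used only to orient the component.
#' @param z_threshold flagging threshold on the z-moments (default 1.96).
#' @return An object of class `cognitive_summary`: list with `tests`
#'   (per-test audit: z moments, flagged, shift, lambda), `pc1_score` (named,
#'   zero-mean over included subjects), `variance_explained_pc1`,
#'   `orientation` (+1/-1 sign applied), `loadings`, `n_subjects`.
#' @export
build_composite <- function(scores, subjects = c("patient", "all"),
                            higher_is_worse = FALSE, z_threshold = 1.96) {
  subjects <- match.arg(subjects)
  if (inherits(scores, "cohort_table")) {
    if (is.null(scores$cognition))
      stop("input error: cohort has no cognition block")
    keep <- if (subjects == "patient") scores$subjects$group == "patient"
            else rep(TRUE, nrow(scores$subjects))
    scores <- scores$cognition[keep, , drop = FALSE]
  }
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("s", seq_len(nrow(scores)))
  all_missing <- colSums(is.finite(scores)) == 0L
  if (any(all_missing)) {
    warning("dropping all-missing test(s): ",
            paste(colnames(scores)[all_missing], collapse = ", "))
    scores <- scores[, !all_missing, drop = FALSE]
  }
  if (ncol(scores) < 2L) stop("input error: need >= 2 usable tests")
  cc <- stats::complete.cases(scores)
  if (sum(cc) < 5L)
    stop("input error: need >= 5 subjects with complete scores, have ",
         sum(cc))
  X <- scores[cc, , drop = FALSE]
  n_tests <- ncol(X)
  higher_is_worse <- rep_len(as.logical(higher_is_worse), n_tests)

  audit <- data.frame(test = colnames(X), z_skewness = NA_real_,
                      z_kurtosis = NA_real_, flagged = FALSE,
                      shift = 0, lambda = NA_real_,
                      stringsAsFactors = FALSE)
  Xt <- X
  for (j in seq_len(n_tests)) {
    zm <- z_moments(X[, j])
    audit$z_skewness[j] <- zm[["z_skewness"]]
    audit$z_kurtosis[j] <- zm[["z_kurtosis"]]
    if (abs(zm[["z_skewness"]]) > z_threshold ||
        abs(zm[["z_kurtosis"]]) > z_threshold) {
      audit$flagged[j] <- TRUE
      v <- X[, j]
      shift <- if (min(v) <= 0) 1 - min(v) else 0
      audit$shift[j] <- shift
      bc <- box_cox(v + shift)
      audit$lambda[j] <- bc$lambda
      Xt[, j] <- bc$y
    }
  }
  Xs <- scale(Xt)
  pca <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  pc1 <- pca$x[, 1L]
  varexp <- pca$sdev[1L]^2 / sum(pca$sdev^2)
  # orient: pc1 should rise with poorer performance on the majority of tests
  direction <- ifelse(higher_is_worse, 1, -1)
  align <- sum(sign(stats::cor(pc1, Xs)) * direction)
  orientation <- if (align >= 0) 1 else -1
  pc1 <- orientation * pc1
  names(pc1) <- rownames(X)
  structure(
    list(tests = audit, pc1_score = pc1,
         variance_explained_pc1 = varexp,
         orientation = orientation,
         loadings = orientation * pca$rotation[, 1L],
         n_subjects = sum(cc)),
    class = "cognitive_summary"
  )
}

#' @export
print.cognitive_summary <- function(x, ...) {
  cat(sprintf(
    "cognitive_summary: %d tests (%d Box-Cox transformed), %d subjects, PC1 explains %.1f%% of variance\n",
    nrow(x$tests), sum(x$tests$flagged), x$n_subjects,
    100 * x$variance_explained_pc1))
  invisible(x)
}
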