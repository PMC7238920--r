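#' Shrinkage covariance with a diagonal (variance-preserving) target
#'
#' Ledoit-Wolf-type linear shrinkage of the unbiased sample covariance S
#' toward its own diagonal: `C = (1 - lambda) * S + lambda * diag(S)`, with
#' the data-driven intensity
#' `lambda = sum_{i != j} Var^(S_ij) / sum_{i != j} S_ij^2`
#' (clipped to \[0, 1\]), where `Var^(S_ij)` is the usual plug-in estimate of
#' the sampling variance of each covariance entry. Only off-diagonal entries
#' are attenuated — exactly the "spurious correlations" that destabilize the
#' quadratic form when the number of tracts approaches the number of controls
#' — while per-tract variances are preserved. A strictly positive intensity
#' floor (1e-12) makes the result positive definite by construction even when
#' there are fewer observations than variables.
#'
#' @param X numeric matrix, observations x variables.
#' @return list with `C` (shrunk covariance), `S` (sample covariance) and
#'   `lambda` (shrinkage intensity in \[0, 1\]).
#' @export
shrink_covariance <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  stopifnot(n >= 3L, p >= 1L)
  Xc <- sweep(X, 2L, colMeans(X))
  cp <- crossprod(Xc)
  S <- cp / (n - 1)
  # Var^(S_ij) = n/(n-1)^3 * sum_k (w_kij - wbar_ij)^2, w_kij = xc_ki * xc_kj
  W2 <- crossprod(Xc^2)
  wbar <- cp / n
  varS <- n / (n - 1)^3 * (W2 - n * wbar^2)
  offdiag <- row(S) != col(S)
  den <- sum(S[offdiag]^2)
  lambda <- if (den <= 0) 1 else min(1, max(sum(varS[offdiag]) / den, 0))
  lambda <- max(lambda, 1e-12)
  C <- (1 - lambda) * S
  diag(C) <- diag(S)
  list(C = C, S = S, lambda = lambda)
}

#' Estimate the control population model from residual profiles
#'
#' Computes the per-tract mean (mu) and standard deviation of age-residualized
#' FA and the between-tract covariance matrix C from a (sub)sample of control
#' profiles. With `method = "shrinkage"` (the default used throughout
#' scoring), C is the [shrink_covariance()] estimate; `method = "sample"`
#' gives the plain unbiased sample covariance and exists for oracle testing
#' and large-sample use.
#'
#' @param profiles a `residual_profiles` object or a numeric matrix
#'   (subjects x tracts) of residuals.
#' @param method `"shrinkage"` or `"sample"`.
#' @return An object of class `control_model`: list with `mu`, `sd`, `C`,
#'   `shrink_intensity`, `n_controls_used`, `method`, `tracts`.
#' @export
fit_control_model <- function(profiles, method = c("shrinkage", "sample")) {
  method <- match.arg(method)
  X <- if (inherits(profiles, "residual_profiles")) profiles$fa_r
       else as.matrix(profiles)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 3L) stop("sample-size error: need >= 3 profiles, have ", n)
  if (p < 1L) stop("validation error: need >= 1 tract")
  v <- apply(X, 2L, stats::var)
  if (any(v <= 0)) {
    bad <- colnames(X)[which(v <= 0)[1L]]
    if (is.null(bad)) bad <- which(v <= 0)[1L]
    stop("degenerate-variance error: zero variance in tract ", bad)
  }
  if (method == "shrinkage") {
    sh <- shrink_covariance(X)
    C <- sh$C
    lambda <- sh$lambda
  } else {
    C <- stats::cov(X)
    lambda <- 0
  }
  structure(
    list(mu = colMeans(X), sd = sqrt(v), C = C, shrink_intensity = lambda,
         n_controls_used = n, method = method,
         tracts = colnames(X)),
    class = "control_model"
  )
}

#' @export
print.control_model <- function(x, ...) {
  cat(sprintf(
    "control_model: %d tracts, n = %d, method = %s, shrink intensity = %.4g\n",
    length(x$mu), x$n_controls_used, x$method, x$shrink_intensity))
  invisible(x)
}

#' Precision representation of a control model
#'
#' Attaches the upper Cholesky factor R of C (C = R'R) so that quadratic
#' forms d' C^-1 d are evaluated by triangular solves rather than explicit
#' inversion, which is the numerically stable route when C is poorly
#' conditioned.
#'
#' @param model a `control_model`.
#' @return The model with an added `chol` component.
#' @export
invert_model <- function(model) {
  stopifnot(inherits(model, "control_model"))
  R <- tryCatch(chol(model$C), error = function(e) {
    ev <- eigen(model$C, symmetric = TRUE, only.values = TRUE)$values
    stop(sprintf(
      "numerical error: covariance not positive definite (eigenvalue range [%g, %g], condition number %g)",
      min(ev), max(ev), max(ev) / max(min(ev), .Machine$double.xmin)))
  })
  model$chol <- R
  model
}

# d' C^-1 d via one triangular solve against the upper Cholesky factor
quad_form_chol <- function(R, d) {
  u <- backsolve(R, d, transpose = TRUE)
  sum(u^2)
}
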