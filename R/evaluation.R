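#' ROC curve and AUC for patient/control discrimination
#'
#' Higher score is taken as more patient-like. The AUC is the tie-corrected
#' Mann-Whitney statistic, `P(score_patient > score_control) + 0.5 *
#' P(equal)`, i.e. the probability that a randomly chosen patient outscores a
#' randomly chosen control.
#'
#' @param scores numeric vector, one per subject.
#' @param labels vector of `"control"`/`"patient"` (or a logical, `TRUE` =
#'   patient), same length.
#' @return An object of class `roc_curve`: list with `thresholds` (sorted
#'   decreasing, starting at `Inf`), `fpr`, `tpr` (each monotone
#'   nondecreasing, from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "patient"
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (any(!is.finite(scores))) stop("input error: scores must be finite")
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("input error: both classes must be nonempty")
  r <- rank(scores)          # midranks: ties counted half
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(th, function(t) mean(scores[labels] >= t), numeric(1L))
  fpr <- vapply(th, function(t) mean(scores[!labels] >= t), numeric(1L))
  structure(list(thresholds = th, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC = %.4f (%d thresholds)\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' Spearman rank correlation with small-sample exact p-value
#'
#' rho is the Pearson correlation of midranks (average ranks on ties). The
#' two-sided p-value uses the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` with n-2 df; for `n <= 9` without ties
#' the exact permutation null is used instead (`method = "auto"`).
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param method `"auto"`, `"asymptotic"`, or `"exact"`.
#' @return list with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(x, y, method = c("auto", "asymptotic", "exact")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("input error: need >= 4 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined-correlation error: constant input vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  use_exact <- switch(method,
                      exact = TRUE,
                      asymptotic = FALSE,
                      auto = n <= 9L && !ties)
  if (use_exact && !ties) {
    # without ties ranks are 1..n, so each permutation row is a candidate ry;
    # rho under permutation reduces to sum(ry_perm * crx) / denom
    perms <- all_permutations(n)
    crx <- rx - mean(rx)
    denom <- sqrt(sum(crx^2) * sum((ry - mean(ry))^2))
    rho_perm <- as.vector(perms %*% crx) / denom
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    p_method <- "exact"
  } else {
    if (use_exact)
      warning("ties present; falling back to the t approximation")
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    p_method <- "asymptotic"
  }
  list(rho = rho, p_value = max(min(p, 1), .Machine$double.xmin), n = n,
       method = p_method)
}

# all permutations of seq_len(n) as rows (n! x n); n <= 9 only
all_permutations <- function(n) {
  stopifnot(n <= 9L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (pos in seq_len(n)) {
    block <- (pos - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[block, pos] <- n
    out[block, -pos] <- sub
  }
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values with enforced monotonicity, capped at 1.
#'
#' @param p_values numeric vector with entries in (0, 1\].
#' @return vector of q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("input error: p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Robust line fit with Tukey bisquare weights
#'
#' Iteratively reweighted least squares: weights
#' `w = (1 - (r / (c * s))^2)^2` for `|r| < c * s` else 0, with tuning
#' constant `c = 4.685` and scale `s = MAD(r) / 0.6745` re-estimated each
#' iteration. Converged when the coefficient change drops below 1e-8
#' (relative) or after 100 iterations, in which case the last iterate is
#' returned with `converged = FALSE` and a warning.
#'
#' @param x,y numeric vectors, `length >= 3`, `x` non-constant.
#' @return list with `slope`, `intercept`, `converged`, `iterations`,
#'   `weights`.
#' @export
robust_line <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("input error: need >= 3 points")
  if (stats::var(x) == 0) stop("input error: constant x (degenerate design)")
  cc <- 4.685
  X <- cbind(1, x)
  beta <- stats::lm.fit(X, y)$coefficients
  converged <- FALSE
  it <- 0L
  w <- rep(1, n)
  for (it in seq_len(100L)) {
    r <- y - X %*% beta
    s <- stats::median(abs(r - stats::median(r))) / 0.6745
    if (s <= .Machine$double.eps) { converged <- TRUE; break }
    u <- as.vector(r) / (cc * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 2L) break
    fit <- stats::lm.wfit(X, y, w)
    beta_new <- fit$coefficients
    if (max(abs(beta_new - beta)) <
        1e-8 * max(1, max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  if (!converged)
    warning("bisquare IRLS did not converge in 100 iterations; returning last iterate")
  list(slope = unname(beta[2L]), intercept = unname(beta[1L]),
       converged = converged, iterations = it, weights = w)
}

#' Per-tract and multivariate discrimination AUCs
#'
#' One ROC AUC for each tract's median |Z| and one for the multivariate
#' median M, plus which univariate tract discriminates best and whether the
#' multivariate score beats it.
#'
#' @param dist_tab a `distance_table` from [score_cohort()].
#' @return data.frame (`measure`, `tract`, `auc`), one row per tract plus a
#'   final `multivariate` row; attributes `best_univariate_tract`,
#'   `best_univariate_auc`, `auc_m`, `m_exceeds_best_univariate`.
#' @export
evaluate_discrimination <- function(dist_tab) {
  stopifnot(inherits(dist_tab, "distance_table"))
  tracts <- attr(dist_tab, "tracts")
  if (length(tracts) < 1L) stop("input error: no tracts in distance table")
  labels <- dist_tab$group
  auc_z <- vapply(tracts, function(t)
    roc_auc(dist_tab[[paste0("z_", t)]], labels)$auc, numeric(1L))
  auc_m <- roc_auc(dist_tab$m_median, labels)$auc
  out <- data.frame(
    measure = c(rep("univariate_z", length(tracts)), "multivariate_m"),
    tract = c(tracts, NA_character_),
    auc = c(auc_z, auc_m),
    stringsAsFactors = FALSE
  )
  best <- which.max(auc_z)
  attr(out, "best_univariate_tract") <- tracts[best]
  attr(out, "best_univariate_auc") <- unname(auc_z[best])
  attr(out, "auc_m") <- auc_m
  attr(out, "m_exceeds_best_univariate") <- auc_m > auc_z[best]
  out
}

#' Brain-behaviour correlations against the cognitive composite
#'
#' Spearman correlation of each tract's median |Z|, and of the multivariate
#' median M, with the consolidated cognitive score (oriented so higher =
#' poorer performance; a positive rho means more injury, worse cognition).
#' The 22-test univariate family is BH-adjusted; the single multivariate test
#' is reported unadjusted since only one comparison is performed. A bisquare
#' robust fit line for M vs the composite is attached.
#'
#' @param dist_tab a `distance_table` from [score_cohort()].
#' @param composite named numeric vector of per-subject composite scores
#'   (names = subject_id); typically `pc1_score` from [build_composite()].
#' @param subjects which subjects to correlate over (default `"patient"`).
#' @param p_method passed to [spearman_cor()].
#' @return list with `table` (variable, rho, p_value, q_value; q is `NA` for
#'   the unadjusted multivariate row) and `m_line` (robust fit of composite
#'   on M).
#' @export
evaluate_cognition <- function(dist_tab, composite,
                               subjects = c("patient", "all"),
                               p_method = "auto") {
  subjects <- match.arg(subjects)
  stopifnot(inherits(dist_tab, "distance_table"))
  keep <- if (subjects == "patient") dist_tab$group == "patient"
          else rep(TRUE, nrow(dist_tab))
  tab <- dist_tab[keep, , drop = FALSE]
  if (is.null(names(composite)))
    stop("input error: composite must be named by subject_id")
  common <- intersect(tab$subject_id, names(composite))
  if (length(common) < 4L)
    stop("input error: fewer than 4 subjects with both scores")
  tab <- tab[match(common, tab$subject_id), , drop = FALSE]
  y <- composite[common]
  tracts <- attr(dist_tab, "tracts")
  uni <- lapply(tracts, function(t)
    spearman_cor(tab[[paste0("z_", t)]], y, method = p_method))
  m_cor <- spearman_cor(tab$m_median, y, method = p_method)
  p_uni <- vapply(uni, `[[`, numeric(1L), "p_value")
  out <- data.frame(
    variable = c(paste0("z_", tracts), "m_median"),
    rho = c(vapply(uni, `[[`, numeric(1L), "rho"), m_cor$rho),
    p_value = c(p_uni, m_cor$p_value),
    q_value = c(bh_fdr(p_uni), NA_real_),
    stringsAsFactors = FALSE
  )
  list(table = out, m_line = robust_line(tab$m_median, y), n = length(common))
}
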