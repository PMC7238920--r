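#' Fit the per-tract linear age model
#'
#' Ordinary least squares of each tract's FA on age, fit on the chosen
#' population. The residuals of this model (FA^r) are the features all
#' distance computations consume, so that distance from the control centroid
#' reflects injury rather than normal ageing.
#'
#' @param cohort a [cohort_table()].
#' @param fit_population `"controls_only"` (default; the normative model
#'   should not absorb patient pathology) or `"all_subjects"`.
#' @return An object of class `age_model`: data.frame with columns `tract`,
#'   `intercept`, `slope`, plus attribute `fit_population`.
#' @export
fit_age_model <- function(cohort,
                          fit_population = c("controls_only", "all_subjects")) {
  fit_population <- match.arg(fit_population)
  stopifnot(inherits(cohort, "cohort_table"))
  keep <- if (fit_population == "controls_only")
    cohort$subjects$group == "control" else rep(TRUE, nrow(cohort$subjects))
  if (sum(keep) < 3L)
    stop("sample-size error: need >= 3 subjects in the fit population, have ",
         sum(keep))
  age <- cohort$subjects$age[keep]
  if (stats::var(age) <= 0)
    stop("degenerate-design error: zero age variance in the fit population")
  X <- cbind(intercept = 1, age = age)
  fit <- stats::lm.fit(X, cohort$fa[keep, , drop = FALSE])
  coefs <- fit$coefficients
  if (is.null(dim(coefs)))   # single-tract fit returns a bare vector
    coefs <- matrix(coefs, 2L, 1L, dimnames = list(names(coefs), NULL))
  if (any(!is.finite(coefs)))
    stop("degenerate-design error: non-finite age-model coefficients")
  out <- data.frame(tract = colnames(cohort$fa),
                    intercept = coefs["intercept", ],
                    slope = coefs["age", ],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fit_population") <- fit_population
  class(out) <- c("age_model", "data.frame")
  out
}

#' Remove the age trend from every subject's FA profile
#'
#' Applies a single fitted [fit_age_model()] to all subjects (controls and
#' patients alike): `fa_r = FA - (intercept + slope * age)` per tract.
#'
#' @param cohort a [cohort_table()].
#' @param model an `age_model` whose tract set equals the cohort's, in order.
#' @return An object of class `residual_profiles`: list with `subject_id`,
#'   `group`, `age`, and `fa_r` (subjects x tracts residual matrix).
#' @export
residualize_cohort <- function(cohort, model) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(model, "age_model"))
  if (!identical(model$tract, colnames(cohort$fa)))
    stop("schema error: age model tract set does not match cohort tracts")
  fitted <- outer(cohort$subjects$age, model$slope) +
    matrix(model$intercept, nrow(cohort$fa), ncol(cohort$fa), byrow = TRUE)
  fa_r <- cohort$fa - fitted
  structure(
    list(subject_id = cohort$subjects$subject_id,
         group = cohort$subjects$group,
         age = cohort$subjects$age,
         fa_r = fa_r,
         fit_population = attr(model, "fit_population")),
    class = "residual_profiles"
  )
}

#' @export
print.residual_profiles <- function(x, ...) {
  cat(sprintf("residual_profiles: %d subjects x %d tracts (age model: %s)\n",
              nrow(x$fa_r), ncol(x$fa_r), x$fit_population))
  invisible(x)
}
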