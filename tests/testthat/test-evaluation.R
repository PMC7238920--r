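# brute-force AUC oracle: count patient/control pairs, ties worth half
pair_auc <- function(scores, labels) {
  pat <- scores[labels == "patient"]
  ctl <- scores[labels == "control"]
  tot <- 0
  for (a in pat) for (b in ctl) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pat) * length(ctl))
}

test_that("AUC reproduces hand-computable cases", {
  lab <- c("patient", "patient", "control", "control")
  expect_equal(roc_auc(c(10, 11, 1, 2), lab)$auc, 1.0)
  expect_equal(roc_auc(c(5, 5, 5, 5), lab)$auc, 0.5)
  # patients {2, 3}, controls {1, 2.5}: 3 wins out of 4 pairs
  expect_equal(roc_auc(c(2, 3, 1, 2.5), lab)$auc, 0.75)
  expect_error(roc_auc(c(1, 2), c("patient", "patient")), "nonempty")
})

test_that("AUC equals brute-force pair counting and is antisymmetric", {
  set.seed(20)
  for (k in 1:20) {
    n <- sample(6:20, 1)
    lab <- sample(c("control", "patient"), n, replace = TRUE,
                  prob = c(0.5, 0.5))
    if (length(unique(lab)) < 2) lab[1:2] <- c("control", "patient")
    scores <- sample(round(rnorm(n), 1))  # rounding forces ties
    r <- roc_auc(scores, lab)
    expect_equal(r$auc, pair_auc(scores, lab), tolerance = 1e-12)
    expect_equal(r$auc + roc_auc(-scores, lab)$auc, 1, tolerance = 1e-12)
  }
})

test_that("ROC curves run from (0,0) to (1,1) monotonically", {
  set.seed(21)
  scores <- round(rnorm(30), 1)
  lab <- rep(c("control", "patient"), 15)
  r <- roc_auc(scores, lab)
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
})

test_that("AUC agrees with the pROC cross-check", {
  skip_if_not_installed("pROC")
  set.seed(22)
  scores <- rnorm(40)
  lab <- sample(rep(c("control", "patient"), 20))
  got <- roc_auc(scores, lab)$auc
  want <- suppressMessages(as.numeric(
    pROC::auc(pROC::roc(lab, scores, levels = c("control", "patient"),
                        direction = "<"))))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("spearman reproduces hand-rank computations and cor.test", {
  x <- 1:8
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -x^3)$rho, -1)
  # d^2 sum = 4: rho = 1 - 6*4/(5*24) = 0.8
  r <- spearman_cor(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4))
  expect_equal(r$rho, 0.8)
  expect_identical(r$method, "exact")
  want <- suppressWarnings(cor.test(c(1, 2, 3, 4, 5), c(1, 3, 2, 5, 4),
                                    method = "spearman", exact = TRUE))
  expect_equal(r$p_value, want$p.value, tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
})

test_that("asymptotic spearman p matches the t approximation at study n", {
  set.seed(23)
  x <- rnorm(34); y <- 0.4 * x + rnorm(34)
  r <- spearman_cor(x, y)
  expect_identical(r$method, "asymptotic")
  tstat <- r$rho * sqrt((34 - 2) / (1 - r$rho^2))
  expect_equal(r$p_value, 2 * pt(-abs(tstat), 32), tolerance = 1e-12)
  # invariant to strictly monotone transforms of either argument
  expect_equal(spearman_cor(exp(x), y)$rho, r$rho)
  expect_equal(spearman_cor(x, qlogis(plogis(y)))$rho, r$rho, tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.5, 10)), rep(0.5, 10))
  set.seed(24)
  p <- runif(30)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # monotone in the order statistics
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_error(bh_fdr(c(0.5, 0)), "input error")
  expect_error(bh_fdr(c(0.5, 1.2)), "input error")
})

test_that("bisquare line resists a gross outlier where OLS does not", {
  # noiseless line: recovered exactly
  x <- seq(0, 10, length.out = 20)
  r0 <- robust_line(x, 2 * x + 1)
  expect_equal(r0$slope, 2, tolerance = 1e-8)
  expect_equal(r0$intercept, 1, tolerance = 1e-8)
  expect_true(r0$converged)

  set.seed(25)
  y <- 2 * x + 1 + rnorm(20, 0, 0.1)
  y[20] <- y[20] + 60   # gross outlier
  rb <- robust_line(x, y)
  ols <- coef(lm(y ~ x))
  expect_lt(abs(rb$slope - 2) / 2, 0.05)
  expect_gt(abs(ols[2] - 2), abs(rb$slope - 2))
  # outlier fully downweighted
  expect_equal(rb$weights[20], 0)
  expect_error(robust_line(rep(1, 5), rnorm(5)), "constant x")
})

test_that("bisquare line matches MASS::rlm on clean noisy data", {
  set.seed(26)
  x <- rnorm(50)
  y <- 1.5 * x - 2 + rnorm(50, 0, 0.5)
  got <- robust_line(x, y)
  want <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, maxit = 100)
  expect_equal(got$slope, unname(coef(want)[2]), tolerance = 0.02)
  expect_equal(got$intercept, unname(coef(want)[1]), tolerance = 0.02)
})

test_that("discrimination table covers every tract plus the multivariate row", {
  sim <- generate_cohort(simulation_config(n_tracts = 6L,
                                           cov_spec = "identity",
                                           n_affected_range = c(0L, 0L)),
                         seed = 31L)
  res <- residualize_cohort(sim$cohort, fit_age_model(sim$cohort))
  # plant a huge isolated shift in tract 3 for patients only
  res$fa_r[res$group == "patient", 3] <-
    res$fa_r[res$group == "patient", 3] - 1
  tab <- score_cohort(res, subset_size = 25L, n_perm = 25L, seed = 1L)
  auc <- evaluate_discrimination(tab)
  expect_equal(nrow(auc), 7L)
  expect_equal(sum(auc$measure == "univariate_z"), 6L)
  shifted <- auc$auc[auc$tract == attr(tab, "tracts")[3]]
  expect_gt(shifted[!is.na(shifted)], 0.99)
  expect_identical(attr(auc, "best_univariate_tract"), attr(tab, "tracts")[3])
})

test_that("null cohorts give near-chance AUCs everywhere", {
  sim <- generate_cohort(simulation_config(n_tracts = 5L,
                                           n_affected_range = c(0L, 0L)),
                         seed = 32L)
  res <- residualize_cohort(sim$cohort, fit_age_model(sim$cohort))
  tab <- score_cohort(res, subset_size = 25L, n_perm = 25L, seed = 2L)
  auc <- evaluate_discrimination(tab)
  # null sampling band for AUC at 31 vs 34: SE ~ 0.072, allow ~4 SE
  expect_true(all(abs(auc$auc - 0.5) < 0.3))
})

test_that("cognition evaluation BH-adjusts the tract family but not M", {
  sim <- generate_cohort(simulation_config(), seed = 33L)
  res <- residualize_cohort(sim$cohort, fit_age_model(sim$cohort))
  tab <- score_cohort(res, subset_size = 25L, n_perm = 25L, seed = 3L)
  comp <- build_composite(sim$cohort)
  ev <- evaluate_cognition(tab, comp$pc1_score)
  expect_equal(nrow(ev$table), 23L)
  m_row <- ev$table[ev$table$variable == "m_median", ]
  expect_true(is.na(m_row$q_value))
  uni <- ev$table[ev$table$variable != "m_median", ]
  expect_equal(uni$q_value, bh_fdr(uni$p_value))
  expect_true(all(uni$q_value >= uni$p_value))
  expect_equal(ev$n, 34L)
  expect_type(ev$m_line$slope, "double")
})
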