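# Downstream analytics: fluid strategies, SOFA strata, stabilized IPW,
# the weighted interaction model, Kaplan-Meier curves, the early
# classifier and prognostic comparison.

test_that("fluid strategies band weight-indexed volume at 30 and 50 mL/kg", {
  expect_equal(fluid_strategy(2000, 80), 0L)  # 25 mL/kg
  expect_equal(fluid_strategy(3200, 80), 1L)  # 40 mL/kg
  expect_equal(fluid_strategy(4800, 80), 2L)  # 60 mL/kg
  # closed middle band at both boundaries
  expect_equal(fluid_strategy(c(30, 50) * 80, 80), c(1L, 1L))
  expect_equal(fluid_strategy(80 * 50 + 1e-6, 80), 2L)
  expect_error(fluid_strategy(-1, 80), "non-negative")
  expect_error(fluid_strategy(100, 0), "positive")
})

test_that("SOFA strata follow the printed cut points", {
  expect_equal(sofa_stratum(c(2, 6, 7, 10, 11, 20)),
               c("2-6", "2-6", "7-10", "7-10", ">=11", ">=11"))
  expect_error(sofa_stratum(1), "outside")
})

test_that("stabilized weights are near 1 under a null design and balance confounders", {
  set.seed(21)
  n <- 2000
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  trt_null <- sample(0:2, n, replace = TRUE)
  w <- propensity_weights(X, trt_null)
  expect_true(all(w > 0))
  expect_lt(abs(mean(w) - 1), 0.05)
  expect_lt(sd(w), 0.25)

  # confounded design: weighting balances covariate means across arms
  ps <- plogis(X$a)
  trt <- rbinom(n, 2, ps / 1.5)
  w2 <- propensity_weights(X, trt)
  expect_lt(abs(mean(w2) - 1), 0.05)
  std_diff <- function(x, t, w) {
    m <- sapply(0:2, function(k) weighted.mean(x[t == k], w[t == k]))
    (max(m) - min(m)) / sd(x)
  }
  expect_gt(std_diff(X$a, trt, rep(1, n)), 0.1)   # imbalanced unweighted
  expect_lt(std_diff(X$a, trt, w2), 0.1)          # balanced after weighting
  expect_error(propensity_weights(X, rep(1, n)), "two observed levels")
})

test_that("the weighted interaction model and LRT behave as nested models must", {
  set.seed(22)
  n <- 1500
  strat <- sample(0:2, n, replace = TRUE)
  pheno <- sample(c("A", "B", "C"), n, replace = TRUE)
  # no interaction in truth
  eta <- -1.5 + 0.3 * (strat == 2) + 0.8 * (pheno == "C")
  y <- rbinom(n, 1, plogis(eta))
  fe <- fluid_effect_model(y, strat, pheno)
  expect_gte(fe$lrt, 0)
  expect_equal(fe$df, 4)  # (3-1) strategy x (3-1) phenotype interaction terms
  expect_true(all(fe$coefficients$CI_low <= fe$coefficients$OR + 1e-12))
  expect_true(all(fe$coefficients$OR <= fe$coefficients$CI_high + 1e-12))
  # identical specifications give LRT exactly 0
  red_vs_red <- 2 * (fe$logLik_reduced - fe$logLik_reduced)
  expect_equal(red_vs_red, 0)

  # a strong planted interaction is detected
  eta2 <- -1 + 1.5 * (strat == 2) * (pheno == "C")
  y2 <- rbinom(n, 1, plogis(eta2))
  fe2 <- fluid_effect_model(y2, strat, pheno)
  expect_lt(fe2$p_value, 0.01)
})

test_that("a planted odds ratio is covered by its confidence interval", {
  set.seed(23)
  covered <- replicate(100, {
    n <- 2000
    strat <- sample(0:1, n, replace = TRUE)
    pheno <- sample(c("A", "B"), n, replace = TRUE)
    y <- rbinom(n, 1, plogis(-1 + log(2) * (strat == 1)))
    fe <- fluid_effect_model(y, strat, pheno)
    row <- fe$coefficients[fe$coefficients$term == "..s1", ]
    row$CI_low <= 2 && 2 <= row$CI_high
  })
  expect_gte(mean(covered), 0.88)  # nominal 95%, binomial tolerance
})

test_that("Kaplan-Meier estimates match hand-computed product limits", {
  # two patients: death at 5, censoring at 10 -> S = 0.5 from t = 5
  km <- km_estimate(c(5, 10), c(1, 0))
  expect_equal(unname(km_survival_at(km, 4)), 1)
  expect_equal(unname(km_survival_at(km, 5)), 0.5)
  expect_equal(unname(km_survival_at(km, 10)), 0.5)
  # three patients: deaths at 2 and 4, censored at 6
  km2 <- km_estimate(c(2, 4, 6), c(1, 1, 0))
  expect_equal(unname(km_survival_at(km2, 2)), 2 / 3)
  expect_equal(unname(km_survival_at(km2, 5)), 1 / 3)
  # censoring before a death shrinks the risk set
  km3 <- km_estimate(c(2, 3, 5, 7), c(1, 0, 1, 0))
  expect_equal(unname(km_survival_at(km3, 5)), (3 / 4) * (1 / 2))
  # when the last patient at risk dies the curve reaches zero
  km3b <- km_estimate(c(2, 3, 5), c(1, 0, 1))
  expect_equal(unname(km_survival_at(km3b, 5)), 0)
  # no events: flat at 1
  km4 <- km_estimate(c(7, 9), c(0, 0))
  expect_equal(unname(km_survival_at(km4, 28)), 1)
  expect_error(km_estimate(c(-1, 2), c(1, 0)), "non-negative")
})

test_that("synthetic 28-day survival curves are ordered A above B above C", {
  coh <- make_cohort(n = 2000, seed = 24)
  truth <- truth_for(coh, coh$outcomes$patient_id)
  km <- km_estimate(coh$outcomes$time_to_event_days, coh$outcomes$death, truth)
  s <- km_survival_at(km, 27.9)
  expect_gt(s[["A"]], s[["B"]])
  expect_gt(s[["B"]], s[["C"]])
})

test_that("the early classifier separates separable labels and not shuffled ones", {
  set.seed(25)
  n <- 150
  lab <- sample(c("A", "B", "C"), n, replace = TRUE)
  x <- matrix(rnorm(n * 4), n)
  x[, 1] <- x[, 1] + 6 * (lab == "A")
  x[, 2] <- x[, 2] + 6 * (lab == "B")
  clf <- fit_phenotype_classifier(x, lab, nfolds = 3, seed = 1,
                                  nrounds = 40, n_boot = 25)
  expect_gt(clf$macro_auroc, 0.98)
  expect_true(all(clf$metrics$auprc <= 1))
  # shuffled labels: chance-level discrimination
  clf0 <- fit_phenotype_classifier(x, sample(lab), nfolds = 3, seed = 1,
                                   nrounds = 40, n_boot = 25)
  expect_lt(abs(clf0$macro_auroc - 0.5), 0.12)
  # determinism under a fixed seed
  clf2 <- fit_phenotype_classifier(x, lab, nfolds = 3, seed = 1,
                                   nrounds = 40, n_boot = 25)
  expect_identical(clf$metrics, clf2$metrics)
})

test_that("prognostic comparison ranks informative predictors above noise", {
  set.seed(26)
  n <- 500
  y <- rbinom(n, 1, 0.3)
  preds <- data.frame(perfect = y + rnorm(n, sd = 1e-6),
                      noise = rnorm(n))
  # the near-perfect predictor separates completely; the fit warning is expected
  pc <- suppressWarnings(prognostic_compare(y, preds))
  expect_equal(pc$auroc[pc$predictor == "perfect"], 1, tolerance = 1e-6)
  expect_lt(abs(pc$auroc[pc$predictor == "noise"] - 0.5), 0.1)
  expect_true(all(pc$recall >= 0 & pc$recall <= 1, na.rm = TRUE))
  expect_error(prognostic_compare(y, data.frame(const = rep(1, n))), "constant")
})

test_that("phenotypes are predictable from 4-h features on the default cohort", {
  coh <- generate_cohort(cohort_config())
  pp <- preprocess_pipeline(coh$events, seed = 7)
  x4 <- features_at(pp$tensor, coh$demographics, hours = 4)
  expect_equal(ncol(x4), dim(pp$tensor$values)[3] + 3)
  truth <- truth_for(coh, pp$tensor$patient_ids)
  clf <- fit_phenotype_classifier(x4, truth, nfolds = 5, seed = 2,
                                  nrounds = 150, n_boot = 25)
  # the archetypes are only partially visible at 4 h, yet well above chance
  expect_gt(clf$macro_auroc, 0.8)
  # and essentially fully visible once the whole window is observed
  x48 <- features_at(pp$tensor, coh$demographics, hours = 48)
  clf48 <- fit_phenotype_classifier(x48, truth, nfolds = 5, seed = 2,
                                    nrounds = 150, n_boot = 25)
  expect_gt(clf48$macro_auroc, clf$macro_auroc)
})
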