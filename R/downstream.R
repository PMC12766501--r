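# Downstream analyses around the phenotypes: early gradient-boosted
# phenotype classification, Kaplan-Meier survival stratification,
# prognostic-value comparison, and the heterogeneous-treatment-effect
# analysis of intravenous fluid strategies with stabilized inverse
# probability weighting.

#' Categorize fluid volume into the three weight-indexed strategies
#'
#' Strategy 0: < 30 mL/kg (low), Strategy 1: 30-50 mL/kg inclusive
#' (moderate), Strategy 2: > 50 mL/kg (high).
#'
#' @param volume_mL fluid volume in mL (vectorized).
#' @param weight_kg body weight in kg.
#' @return Integer vector in \{0, 1, 2\}.
#' @examples
#' fluid_strategy(c(2000, 3200, 4800), 80)  # 0 1 2
#' @export
fluid_strategy <- function(volume_mL, weight_kg) {
  if (any(volume_mL < 0)) stop("fluid volumes must be non-negative")
  if (any(weight_kg <= 0)) stop("weight must be positive")
  mlkg <- volume_mL / weight_kg
  ifelse(mlkg < 30, 0L, ifelse(mlkg <= 50, 1L, 2L))
}

#' SOFA score stratum
#'
#' Bands the SOFA score into the strata 2-6, 7-10 and >= 11. Scores
#' below 2 are outside the sepsis cohort definition and raise an error.
#'
#' @param score integer SOFA score(s), each >= 2.
#' @return Character vector with levels "2-6", "7-10", ">=11".
#' @export
sofa_stratum <- function(score) {
  if (any(score < 2)) stop("SOFA scores below 2 are outside the cohort definition")
  ifelse(score <= 6, "2-6", ifelse(score <= 10, "7-10", ">=11"))
}

#' Stabilized inverse probability weights for a 3-level treatment
#'
#' Fits a multinomial logistic propensity model of treatment on baseline
#' covariates and returns \eqn{w_i = \Pr(T = t_i) / \Pr(T = t_i | X_i)},
#' the stabilized weight with the marginal treatment probability in the
#' numerator. Near-zero fitted probabilities trigger weight truncation
#' at a configurable upper percentile.
#'
#' @param X data frame or matrix of baseline covariates.
#' @param treatment treatment indicator with >= 2 observed levels
#'   (e.g. fluid strategy 0/1/2).
#' @param truncate_at percentile at which weights are capped when
#'   near-positivity violations are detected (default 0.99).
#' @return Numeric vector of positive weights, mean approximately 1.
#' @export
propensity_weights <- function(X, treatment, truncate_at = 0.99) {
  treatment <- factor(treatment)
  if (nlevels(treatment) < 2) stop("treatment needs at least two observed levels")
  df <- data.frame(..T = treatment, as.data.frame(X))
  fit <- nnet::multinom(..T ~ ., data = df, trace = FALSE)
  ps <- stats::fitted(fit)
  if (nlevels(treatment) == 2 && is.null(dim(ps))) {
    ps <- cbind(1 - ps, ps)  # multinom returns a vector for 2 levels
  }
  denom <- ps[cbind(seq_along(treatment), as.integer(treatment))]
  num <- as.numeric(prop.table(table(treatment)))[as.integer(treatment)]
  w <- num / denom
  if (any(denom < 1e-6)) {
    cap <- stats::quantile(w, truncate_at)
    message(sprintf("near-positivity violation: truncating %d weight(s) at the %.0fth percentile",
                    sum(w > cap), 100 * truncate_at))
    w <- pmin(w, cap)
  }
  w
}

#' Weighted fluid-strategy outcome model with interaction test
#'
#' Fits a weighted logistic regression of in-hospital mortality on fluid
#' strategy, phenotype, their interaction and optional covariates
#' (weights from [propensity_weights()]; Strategy 0 is the reference),
#' plus the reduced model without the interaction, and compares them
#' with a likelihood-ratio test on the weighted log-likelihoods. Odds
#' ratios carry robust (sandwich) Wald 95\% confidence intervals, the
#' standard choice under estimated weights.
#'
#' @param outcome binary 0/1 mortality.
#' @param strategy fluid strategy (0/1/2), coerced to a factor with
#'   reference 0.
#' @param phenotype phenotype labels, coerced to a factor.
#' @param covariates optional data frame of adjustment covariates.
#' @param weights stabilized IP weights (default: unweighted).
#' @return An object of class \code{fluid_effect}: coefficient table
#'   (term, OR, CI, p), the LRT statistic, df and p-value, and both
#'   fitted models.
#' @export
fluid_effect_model <- function(outcome, strategy, phenotype, covariates = NULL,
                               weights = NULL) {
  n <- length(outcome)
  if (is.null(weights)) weights <- rep(1, n)
  strategy <- stats::relevel(factor(strategy), ref = levels(factor(strategy))[1])
  phenotype <- factor(phenotype)
  if (any(table(strategy, phenotype) == 0)) {
    warning("empty treatment-by-phenotype cell(s); interaction estimates may be unstable")
  }
  df <- data.frame(..y = outcome, ..s = strategy, ..ph = phenotype)
  rhs_full <- "..s * ..ph"
  rhs_red <- "..s + ..ph"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
    extra <- paste(names(covariates), collapse = " + ")
    rhs_full <- paste(rhs_full, "+", extra)
    rhs_red <- paste(rhs_red, "+", extra)
  }
  df$..w <- weights
  full <- stats::glm(stats::as.formula(paste("..y ~", rhs_full)), data = df,
                     family = stats::quasibinomial(), weights = ..w)
  red <- stats::glm(stats::as.formula(paste("..y ~", rhs_red)), data = df,
                    family = stats::quasibinomial(), weights = ..w)
  if (!full$converged || !red$converged) stop("weighted logistic fit failed to converge")
  wll <- function(fit) {
    p <- pmin(pmax(stats::fitted(fit), 1e-12), 1 - 1e-12)
    sum(weights * (outcome * log(p) + (1 - outcome) * log(1 - p)))
  }
  lrt <- max(0, 2 * (wll(full) - wll(red)))
  df_lrt <- length(stats::coef(full)) - length(stats::coef(red))
  p_lrt <- stats::pchisq(lrt, df_lrt, lower.tail = FALSE)

  se <- sqrt(diag(sandwich::vcovHC(full, type = "HC0")))
  est <- stats::coef(full)
  tab <- data.frame(term = names(est),
                    OR = exp(est),
                    CI_low = exp(est - 1.96 * se),
                    CI_high = exp(est + 1.96 * se),
                    p = 2 * stats::pnorm(-abs(est / se)),
                    row.names = NULL)
  structure(list(coefficients = tab, lrt = lrt, df = df_lrt, p_value = p_lrt,
                 logLik_full = wll(full), logLik_reduced = wll(red),
                 full = full, reduced = red),
            class = "fluid_effect")
}

#' @export
print.fluid_effect <- function(x, ...) {
  cat("Weighted fluid-strategy outcome model (reference: Strategy 0)\n")
  print(transform(x$coefficients, OR = round(OR, 3), CI_low = round(CI_low, 3),
                  CI_high = round(CI_high, 3), p = signif(p, 3)),
        row.names = FALSE)
  cat(sprintf("Interaction LRT: chi2 = %.3f, df = %d, p = %.4g\n",
              x$lrt, x$df, x$p_value))
  invisible(x)
}

#' Kaplan-Meier survival curves by group
#'
#' Product-limit survival estimates per group (right censoring handled
#' in the standard way), used to compare 28-day survival across
#' phenotypes.
#'
#' @param times follow-up times (days).
#' @param events 1 = death observed, 0 = censored.
#' @param groups group labels (e.g. phenotype); a single group is allowed.
#' @return An object of class \code{km_est} wrapping the
#'   \code{survival::survfit} fit with a tidy \code{curves} data frame
#'   (group, time, n_risk, n_event, surv).
#' @export
km_estimate <- function(times, events, groups = NULL) {
  if (any(times < 0)) stop("survival times must be non-negative")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  if (is.null(groups)) groups <- rep("all", length(times))
  groups <- factor(groups)
  if (any(tabulate(groups) == 0)) stop("empty group")
  df <- data.frame(t = times, e = events, g = groups)
  fit <- survival::survfit(survival::Surv(t, e) ~ g, data = df)
  sm <- summary(fit, censored = TRUE)
  gl <- if (is.null(sm$strata)) rep(levels(groups)[1], length(sm$time))
        else sub("^g=", "", as.character(sm$strata))
  curves <- data.frame(group = gl, time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, surv = sm$surv)
  structure(list(fit = fit, curves = curves), class = "km_est")
}

#' Survival probability at a time point
#'
#' @param km a [km_estimate()] object.
#' @param at time at which to evaluate the step function.
#' @return Named vector of survival probabilities per group.
#' @export
km_survival_at <- function(km, at) {
  stopifnot(inherits(km, "km_est"))
  vapply(split(km$curves, km$curves$group), function(cv) {
    cv <- cv[cv$time <= at & cv$n_event > 0, ]
    if (!nrow(cv)) 1 else min(cv$surv)
  }, 0)
}

#' @export
print.km_est <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' Plot Kaplan-Meier curves
#'
#' @param x a [km_estimate()] object.
#' @param ... passed to \code{plot.survfit}.
#' @export
plot.km_est <- function(x, ...) {
  ng <- length(unique(x$curves$group))
  plot(x$fit, col = seq_len(ng), xlab = "days since diagnosis",
       ylab = "survival probability", ...)
  graphics::legend("bottomleft", legend = unique(x$curves$group),
                   col = seq_len(ng), lty = 1)
  invisible(x)
}

# rank-based AUROC (equivalent to the Mann-Whitney statistic)
auroc <- function(score, label) {
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# area under the precision-recall curve by step integration over
# descending score thresholds (average precision)
auprc <- function(score, label) {
  n1 <- sum(label == 1)
  if (n1 == 0) return(NA_real_)
  ord <- order(score, decreasing = TRUE)
  lab <- label[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab == 1]) / n1
}

# stratified fold assignment: every class spread evenly over folds
stratified_folds <- function(labels, nfolds) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  fold
}

#' Early phenotype classifier (gradient-boosted trees)
#'
#' Trains a multiclass XGBoost classifier to predict the model-derived
#' phenotype from features available early in the ICU stay (e.g. the 4-h
#' bin), with stratified k-fold cross-validation. Reports per-class
#' one-vs-rest AUROC and AUPRC on the pooled out-of-fold predictions,
#' with percentile bootstrap confidence intervals, and returns a final
#' model refit on all data.
#'
#' @param x numeric feature matrix (patients x features).
#' @param labels phenotype labels from the clustering model.
#' @param nfolds folds for cross-validation (default 5).
#' @param seed integer seed (folding, boosting, bootstrap).
#' @param nrounds,max_depth,eta boosting hyperparameters.
#' @param n_boot bootstrap resamples for the CIs.
#' @return An object of class \code{phenotype_classifier} with
#'   \code{metrics} (per class and macro), \code{oof} probabilities and
#'   the fitted \code{model}.
#' @export
fit_phenotype_classifier <- function(x, labels, nfolds = 5, seed = 1,
                                     nrounds = 200, max_depth = 4, eta = 0.1,
                                     n_boot = 200) {
  x <- as.matrix(x)
  labels <- factor(labels)
  K <- nlevels(labels)
  yi <- as.integer(labels) - 1L
  if (min(table(labels)) < nfolds) stop("every class needs at least nfolds patients")
  with_seed(seed, {
    params <- list(objective = "multi:softprob", num_class = K,
                   max_depth = max_depth, eta = eta, nthread = 1)
    fold <- stratified_folds(as.integer(labels), nfolds)
    oof <- matrix(NA_real_, nrow(x), K)
    for (f in seq_len(nfolds)) {
      tr <- fold != f
      bst <- xgboost::xgb.train(params = params,
                                data = xgboost::xgb.DMatrix(x[tr, , drop = FALSE],
                                                            label = yi[tr]),
                                nrounds = nrounds, verbose = 0)
      pred <- stats::predict(bst, xgboost::xgb.DMatrix(x[!tr, , drop = FALSE]))
      oof[!tr, ] <- matrix(pred, ncol = K)
    }
    per_class <- lapply(seq_len(K), function(k) {
      lab <- as.integer(yi == k - 1L)
      boots <- vapply(seq_len(n_boot), function(b) {
        i <- sample.int(length(lab), replace = TRUE)
        c(auroc(oof[i, k], lab[i]), auprc(oof[i, k], lab[i]))
      }, numeric(2))
      data.frame(class = levels(labels)[k],
                 auroc = auroc(oof[, k], lab),
                 auroc_lo = stats::quantile(boots[1, ], 0.025, na.rm = TRUE),
                 auroc_hi = stats::quantile(boots[1, ], 0.975, na.rm = TRUE),
                 auprc = auprc(oof[, k], lab),
                 auprc_lo = stats::quantile(boots[2, ], 0.025, na.rm = TRUE),
                 auprc_hi = stats::quantile(boots[2, ], 0.975, na.rm = TRUE),
                 row.names = NULL)
    })
    metrics <- do.call(rbind, per_class)
    final <- xgboost::xgb.train(params = params,
                                data = xgboost::xgb.DMatrix(x, label = yi),
                                nrounds = nrounds, verbose = 0)
    structure(list(metrics = metrics,
                   macro_auroc = mean(metrics$auroc),
                   macro_auprc = mean(metrics$auprc),
                   oof = oof, folds = fold, model = final,
                   classes = levels(labels)),
              class = "phenotype_classifier")
  })
}

#' @export
print.phenotype_classifier <- function(x, ...) {
  cat("Early phenotype classifier (gradient-boosted trees, one-vs-rest)\n")
  print(transform(x$metrics, auroc = round(auroc, 3), auprc = round(auprc, 3),
                  auroc_lo = round(auroc_lo, 3), auroc_hi = round(auroc_hi, 3),
                  auprc_lo = round(auprc_lo, 3), auprc_hi = round(auprc_hi, 3)),
        row.names = FALSE)
  cat(sprintf("macro AUROC %.3f, macro AUPRC %.3f\n", x$macro_auroc, x$macro_auprc))
  invisible(x)
}

#' Compare the prognostic value of competing predictors
#'
#' Fits a separate univariate logistic regression of the binary outcome
#' on each supplied predictor (factors allowed) and reports AUROC plus
#' recall, precision, F1 and specificity at the 0.5 predicted-probability
#' threshold.
#'
#' @param outcome binary 0/1 outcome (e.g. in-hospital mortality).
#' @param predictors data frame; one model per column.
#' @return Data frame, one row per predictor.
#' @export
prognostic_compare <- function(outcome, predictors) {
  predictors <- as.data.frame(predictors)
  rows <- lapply(names(predictors), function(nm) {
    xv <- predictors[[nm]]
    if (length(unique(xv[!is.na(xv)])) < 2) stop("constant predictor: ", nm)
    fit <- stats::glm(outcome ~ xv, family = stats::binomial())
    p <- stats::fitted(fit)
    pred <- as.integer(p >= 0.5)
    tp <- sum(pred == 1 & outcome == 1); fp <- sum(pred == 1 & outcome == 0)
    fn <- sum(pred == 0 & outcome == 1); tn <- sum(pred == 0 & outcome == 0)
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA
    data.frame(predictor = nm,
               auroc = auroc(p, outcome),
               recall = recall, precision = precision,
               f1 = if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
                 2 * precision * recall / (precision + recall) else NA,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Early-window feature matrix for the phenotype classifier
#'
#' Extracts each patient's observed feature values at the bins up to
#' \code{hours} (e.g. the first 4-h bin) and appends demographics.
#'
#' @param tensor a preprocessed \code{feature_tensor}.
#' @param demographics data frame with patient_id, age, gender, weight_kg.
#' @param hours horizon in hours (default 4: the first bin).
#' @return Numeric matrix, patients x features.
#' @export
features_at <- function(tensor, demographics, hours = 4) {
  stopifnot(inherits(tensor, "feature_tensor"))
  bin_h <- diff(tensor$bin_edges)[1]
  nb <- max(1L, as.integer(hours / bin_h))
  d <- dim(tensor$values)
  m <- matrix(tensor$values[, seq_len(nb), , drop = FALSE], nrow = d[1])
  colnames(m) <- as.vector(outer(seq_len(nb), tensor$feature_ids,
                                 function(t, f) paste0(f, ".", t)))
  di <- match(tensor$patient_ids, demographics$patient_id)
  cbind(m, age = demographics$age[di], gender = demographics$gender[di],
        weight_kg = demographics$weight_kg[di])
}
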