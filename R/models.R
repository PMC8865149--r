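# Linear mixed models for MADRS prediction, leave-one-subject-out
# cross-validation, and the model zoo.

MODEL_PHONE <- list(
  A = "phq8",
  B = "PC1",
  C = c("phq8", "PC1"),
  D = character(0),
  E = c("PC1", "PC2"),
  F = "weekend_distance_km")

TIER_COVARIATES <- list(
  full = c("baseline_madrs", "age", "sex", "diagnosis"),
  demographics = c("age", "sex", "diagnosis"),
  none = character(0))

#' Model specification for the MADRS prediction zoo
#'
#' Six phone-predictor sets crossed with three covariate tiers. Models:
#' `A` PHQ-8 only; `B` first principal component of the 32 passive
#' statistics; `C` both; `D` no phone-based predictors; `E` first and second
#' principal components; `F` weekend distance traveled as a single raw
#' passive predictor. Tiers: `"full"` adds baseline MADRS and demographics
#' (age, sex, diagnostic category with healthy controls as reference);
#' `"demographics"` adds demographics only; `"none"` adds nothing (model D
#' at tier `"none"` is intercept-only).
#'
#' @param model one of `"A"`-`"F"`.
#' @param tier one of `"full"`, `"demographics"`, `"none"`.
#' @return List of class `"model_spec"` with `model`, `tier`, `phone`,
#'   `covariates`, `label`, and `uses_pca`.
#' @export
model_spec <- function(model = c("A", "B", "C", "D", "E", "F"),
                       tier = c("full", "demographics", "none")) {
  model <- match.arg(model)
  tier <- match.arg(tier)
  suffix <- switch(tier, full = "", demographics = "'", none = "''")
  structure(list(model = model, tier = tier,
                 phone = MODEL_PHONE[[model]],
                 covariates = TIER_COVARIATES[[tier]],
                 label = paste0("Model ", model, suffix),
                 uses_pca = any(c("PC1", "PC2") %in% MODEL_PHONE[[model]])),
            class = "model_spec")
}

#' Fit a linear mixed model for MADRS prediction
#'
#' Fits the outcome MADRS on the spec's predictors with a random intercept
#' per subject (multiple visits per subject form the clusters), by maximum
#' likelihood. Rows with a missing value in any predictor are excluded
#' before fitting (complete-case), with the count recorded. When the spec
#' uses principal components and no fitted `pca` is supplied, the
#' standardizer and loadings are estimated from the training rows (the
#' complete 32-feature rows among them).
#'
#' @param data analysis table from [analysis_table()] (follow-up visit
#'   rows).
#' @param model,tier passed to [model_spec()]; alternatively give `spec`.
#' @param spec a ready-made [model_spec()].
#' @param pca optional fitted `"passive_pca"` to reuse (e.g. a global fit);
#'   default refits on the training data.
#' @param hc_label reference level for the diagnostic-category dummies.
#' @return Object of class `"madrs_fit"`.
#' @export
fit_madrs <- function(data, model = "A", tier = "full", spec = NULL,
                      pca = NULL, hc_label = "HC") {
  if (is.null(spec)) spec <- model_spec(model, tier)
  data <- as.data.frame(data)
  if (spec$uses_pca) {
    if (is.null(pca)) pca <- standardize_and_pca(data[, passive_feature_names()])
    sc <- predict(pca, data[, passive_feature_names()])
    data$PC1 <- sc[, 1]
    data$PC2 <- if (ncol(sc) >= 2) sc[, 2] else 0
  }
  if ("weekend_distance_km" %in% spec$phone) # keep lme4 on a sane scale
    data$weekend_distance_km <- data$weekend_distance_m / 1000
  vars <- c(spec$phone, spec$covariates)
  diag_levels <- NULL
  if ("diagnosis" %in% vars) {
    diag_levels <- c(hc_label, setdiff(sort(unique(data$diagnosis)), hc_label))
    data$diagnosis <- factor(data$diagnosis, levels = diag_levels)
  }
  if ("sex" %in% vars) data$sex <- factor(data$sex)
  keep <- stats::complete.cases(data[, c("madrs", "subject", vars),
                                     drop = FALSE])
  excluded <- sum(!keep)
  rows <- data[keep, , drop = FALSE]
  if (length(unique(rows$subject)) < 2)
    stop(sprintf("cannot fit mixed model: %d subject(s) with complete rows",
                 length(unique(rows$subject))))
  rhs <- if (length(vars)) paste(vars, collapse = " + ") else "1"
  form <- stats::as.formula(paste("madrs ~", rhs, "+ (1 | subject)"))
  fit <- lme4::lmer(form, data = rows, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fit = fit, spec = spec, pca = if (spec$uses_pca) pca,
                 fixed_rhs = rhs, vars = vars,
                 xlev = Filter(Negate(is.null), list(
                   diagnosis = diag_levels,
                   sex = if ("sex" %in% vars) levels(rows$sex))),
                 sigma_b = sqrt(vc$vcov[vc$grp == "subject"]),
                 sigma_e = sqrt(vc$vcov[vc$grp == "Residual"]),
                 n_rows = nrow(rows), n_subjects = length(unique(rows$subject)),
                 n_excluded = excluded),
            class = "madrs_fit")
}

#' @export
print.madrs_fit <- function(x, ...) {
  cat(sprintf("%s (+%s covariates): linear mixed model, ML\n",
              x$spec$label, x$spec$tier))
  cat(sprintf("  %d visits, %d subjects (%d rows excluded for missing predictors)\n",
              x$n_rows, x$n_subjects, x$n_excluded))
  cat(sprintf("  random-intercept SD %.2f, residual SD %.2f\n",
              x$sigma_b, x$sigma_e))
  print(round(lme4::fixef(x$fit), 3))
  invisible(x)
}

#' @export
summary.madrs_fit <- function(object, ...) summary(object$fit, ...)

#' @export
coef.madrs_fit <- function(object, ...) lme4::fixef(object$fit)

#' @export
residuals.madrs_fit <- function(object, ...) stats::residuals(object$fit, ...)

#' Fixed-effects predictions for new subjects
#'
#' Predictions use only the population-level (fixed-effect) part of the
#' model: the random intercept of an unseen subject is zero. Rows with a
#' missing predictor yield `NA` and are counted in attribute `n_skipped`.
#'
#' @param object a `"madrs_fit"`.
#' @param newdata rows in the analysis-table layout.
#' @param ... unused.
#' @return Numeric predictions (NA where predictors are missing).
#' @export
predict.madrs_fit <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  if (object$spec$uses_pca) {
    sc <- predict(object$pca, newdata[, passive_feature_names()])
    newdata$PC1 <- sc[, 1]
    newdata$PC2 <- if (ncol(sc) >= 2) sc[, 2] else 0
  }
  if ("weekend_distance_km" %in% object$spec$phone)
    newdata$weekend_distance_km <- newdata$weekend_distance_m / 1000
  for (v in names(object$xlev))
    newdata[[v]] <- factor(newdata[[v]], levels = object$xlev[[v]])
  form <- stats::as.formula(paste("~", object$fixed_rhs))
  mf <- stats::model.frame(form, newdata, na.action = stats::na.pass,
                           xlev = object$xlev)
  beta <- lme4::fixef(object$fit)
  ok <- stats::complete.cases(mf)
  pred <- rep(NA_real_, nrow(newdata))
  if (any(ok)) {
    mm <- stats::model.matrix(form, mf[ok, , drop = FALSE],
                              xlev = object$xlev)
    pred[ok] <- drop(mm[, names(beta), drop = FALSE] %*% beta)
  }
  attr(pred, "n_skipped") <- sum(!ok)
  pred
}

#' Leave-one-subject-out cross-validation
#'
#' Holds out each subject in turn, fits the model on all other subjects
#' (re-estimating the feature standardizer and PCA loadings inside the
#' training fold unless `pca_global = TRUE`), predicts the held-out visits
#' from the fixed effects alone, and computes the per-subject RMSE over the
#' scored visits. The reported accuracy is the arithmetic mean of the
#' per-subject RMSEs (not the pooled RMSE). Subjects with no scorable visit
#' are excluded from the average and logged.
#'
#' @param data analysis table (follow-up visit rows).
#' @param model,tier,spec model selection as in [fit_madrs()].
#' @param pca_global if `TRUE`, fit the PCA once on all subjects and reuse
#'   it in every fold (descriptive variant); default refits per fold for
#'   leakage-free validation.
#' @param hc_label reference diagnosis level.
#' @return Object of class `"madrs_cv"`: `avg_rmse`, `per_subject`
#'   (data.frame `subject`, `n_scored`, `rmse`), `predictions` (the input
#'   rows with `predicted` added), `excluded_subjects`.
#' @export
loso_cv <- function(data, model = "A", tier = "full", spec = NULL,
                    pca_global = FALSE, hc_label = "HC") {
  if (is.null(spec)) spec <- model_spec(model, tier)
  data <- as.data.frame(data)
  subjects <- unique(data$subject)
  if (length(subjects) < 3) stop("leave-one-subject-out needs >= 3 subjects")
  gpca <- NULL
  if (spec$uses_pca && pca_global)
    gpca <- standardize_and_pca(data[, passive_feature_names()])
  pred_all <- rep(NA_real_, nrow(data))
  per <- vector("list", length(subjects))
  for (k in seq_along(subjects)) {
    hold <- data$subject == subjects[k]
    fit <- fit_madrs(data[!hold, , drop = FALSE], spec = spec, pca = gpca,
                     hc_label = hc_label)
    pred_all[hold] <- as.numeric(predict(fit, data[hold, , drop = FALSE]))
    err <- data$madrs[hold] - pred_all[hold]
    scored <- !is.na(err)
    per[[k]] <- data.frame(subject = subjects[k], n_scored = sum(scored),
                           rmse = if (any(scored))
                             sqrt(mean(err[scored]^2)) else NA_real_)
  }
  per <- do.call(rbind, per)
  excluded <- per$subject[per$n_scored == 0]
  if (length(excluded))
    message(sprintf("%d subject(s) with no scorable visits excluded from the average RMSE",
                    length(excluded)))
  preds <- data[, c("subject", "visit_index", "madrs")]
  preds$predicted <- pred_all
  structure(list(avg_rmse = mean(per$rmse, na.rm = TRUE),
                 per_subject = per, predictions = preds,
                 excluded_subjects = excluded, spec = spec),
            class = "madrs_cv")
}

#' @export
print.madrs_cv <- function(x, ...) {
  cat(sprintf("%s (+%s): LOSO-CV average RMSE %.2f over %d subjects\n",
              x$spec$label, x$spec$tier, x$avg_rmse,
              sum(x$per_subject$n_scored > 0)))
  invisible(x)
}

#' Run the full model zoo
#'
#' Cross-validates every phone-predictor model against every covariate tier
#' and assembles the average-RMSE grid (models A-F as rows; predictor-only,
#' +demographics, +baseline MADRS & demographics as columns). Cells whose
#' predictors are entirely missing are `NA`.
#'
#' @param data analysis table.
#' @param models,tiers subsets to run.
#' @param pca_global see [loso_cv()].
#' @return data.frame of class `"rmse_grid"`, rows models, columns tiers.
#' @export
run_model_zoo <- function(data, models = c("A", "B", "C", "D", "E", "F"),
                          tiers = c("none", "demographics", "full"),
                          pca_global = FALSE) {
  grid <- matrix(NA_real_, length(models), length(tiers),
                 dimnames = list(models, tiers))
  for (m in models) for (tr in tiers) {
    cv <- tryCatch(loso_cv(data, m, tr, pca_global = pca_global),
                   error = function(e) NULL)
    if (!is.null(cv)) grid[m, tr] <- cv$avg_rmse
  }
  out <- as.data.frame(grid)
  class(out) <- c("rmse_grid", "data.frame")
  out
}

#' @export
print.rmse_grid <- function(x, ...) {
  labels <- c(A = "Model A (PHQ-8)", B = "Model B (passive data)",
              C = "Model C (PHQ-8 & passive)",
              D = "Model D (no phone-based predictors)",
              E = "Model E (PC1 + PC2)",
              F = "Model F (weekend distance traveled)")
  hdr <- c(none = "predictors only", demographics = "+ demographics",
           full = "+ baseline MADRS + demographics")
  y <- as.data.frame(lapply(x, function(col) sprintf("%.2f", col)))
  names(y) <- hdr[names(x)]
  rownames(y) <- labels[rownames(x)]
  cat("Average LOSO-CV RMSE in predicting MADRS (scale 0-60)\n")
  print(y)
  invisible(x)
}
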