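# PCA, mixed-model fitting, fixed-effects prediction, and LOSO-CV.

test_that("PCA recovers a planted one-factor structure", {
  nm <- passive_feature_names()
  withr::with_seed(3, {
    f <- rnorm(200)
    X <- sapply(seq_along(nm), function(j)
      rnorm(1, 1, 0.5) * f + rnorm(200, 0, 0.1))
    colnames(X) <- nm
  })
  pc <- standardize_and_pca(X)
  expect_gt(pc$explained[1], 0.9)
  # orthonormal loadings
  G <- t(pc$loadings) %*% pc$loadings
  expect_equal(G, diag(ncol(G)), tolerance = 1e-8, ignore_attr = TRUE)
  # explained fractions: nonincreasing, sum to 1
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_equal(sum(pc$explained), 1)
  # the training mean row projects to the origin
  mid <- as.data.frame(t(colMeans(X)))
  expect_equal(unname(predict(pc, mid)[1, ]), rep(0, ncol(pc$loadings)),
               tolerance = 1e-8)
  # sign anchor: weekend distance loading nonnegative everywhere
  expect_true(all(pc$loadings["weekend_distance_m", ] >= 0))
})

test_that("constant features are dropped from PCA with a warning", {
  nm <- passive_feature_names()
  X <- matrix(rnorm(50 * 32), 50, dimnames = list(NULL, nm))
  X[, "accel_missing_minutes"] <- 0
  expect_warning(pc <- standardize_and_pca(X), "accel_missing_minutes")
  expect_false("accel_missing_minutes" %in% pc$features)
  expect_equal(length(pc$features), 31)
})

test_that("noise-free coefficients are recovered exactly", {
  toy <- lmm_toy(n_subjects = 12, sigma_b = 0, sigma_e = 0, seed = 4)
  fit <- suppressWarnings(fit_madrs(toy, spec = structure(
    list(model = "A", tier = "custom", phone = "phq8",
         covariates = "baseline_madrs", label = "toy", uses_pca = FALSE),
    class = "model_spec")))
  expect_equal(unname(coef(fit)), c(2, 1.5, 0.6), tolerance = 1e-6)
  expect_equal(fit$sigma_e, 0, tolerance = 1e-4)
})

test_that("an intercept-only fit returns roughly the grand mean", {
  toy <- lmm_toy(n_subjects = 10, sigma_b = 0.001, sigma_e = 2, seed = 5)
  fit <- fit_madrs(toy, model = "D", tier = "none")
  expect_equal(unname(coef(fit)[1]), mean(toy$madrs), tolerance = 0.05)
})

test_that("coefficient estimates cover the truth across replicates", {
  # 3-SE coverage of each coefficient in >= 95% of seeded replicates
  beta <- c(2, 1.5, 0.6)
  n_rep <- 60
  cover <- matrix(FALSE, n_rep, 3)
  for (r in seq_len(n_rep)) {
    toy <- lmm_toy(n_subjects = 40, beta = beta, sigma_b = 3, sigma_e = 4,
                   seed = 9000 + r)
    fit <- fit_madrs(toy, spec = structure(
      list(model = "A", tier = "custom", phone = "phq8",
           covariates = "baseline_madrs", label = "toy", uses_pca = FALSE),
      class = "model_spec"))
    est <- lme4::fixef(fit$fit)
    se <- sqrt(diag(as.matrix(vcov(fit$fit))))
    cover[r, ] <- abs(est - beta) <= 3 * se
  }
  expect_gte(min(colMeans(cover)), 0.95)
})

test_that("fixed-effects predictions are exact linear combinations", {
  toy <- lmm_toy(n_subjects = 10, seed = 6)
  spec <- structure(list(model = "A", tier = "custom", phone = "phq8",
                         covariates = "baseline_madrs", label = "toy",
                         uses_pca = FALSE), class = "model_spec")
  fit <- fit_madrs(toy, spec = spec)
  beta <- coef(fit)
  new <- toy[1:3, ]
  manual <- beta[1] + beta["phq8"] * new$phq8 +
    beta["baseline_madrs"] * new$baseline_madrs
  expect_equal(unname(as.numeric(predict(fit, new))), unname(manual),
               tolerance = 1e-12)

  # intercept-only model predicts a constant
  fit0 <- fit_madrs(toy, model = "D", tier = "none")
  p0 <- predict(fit0, toy[1:5, ])
  expect_equal(length(unique(round(as.numeric(p0), 10))), 1)

  # a missing predictor yields NA and is counted
  new$phq8[2] <- NA
  p <- predict(fit, new)
  expect_true(is.na(p[2]))
  expect_equal(attr(p, "n_skipped"), 1)
})

test_that("LOSO-CV reaches zero error on deterministic outcomes", {
  toy <- lmm_toy(n_subjects = 8, sigma_b = 0, sigma_e = 0, seed = 7)
  toy$madrs <- 5 # constant outcome
  cv <- suppressWarnings(loso_cv(toy, model = "D", tier = "none"))
  expect_equal(cv$avg_rmse, 0, tolerance = 1e-8)

  toy2 <- lmm_toy(n_subjects = 8, sigma_b = 0, sigma_e = 0, seed = 8)
  spec <- structure(list(model = "A", tier = "custom", phone = "phq8",
                         covariates = "baseline_madrs", label = "toy",
                         uses_pca = FALSE), class = "model_spec")
  cv2 <- suppressWarnings(loso_cv(toy2, spec = spec))
  expect_lt(cv2$avg_rmse, 1e-6)
})

test_that("LOSO-CV equals an independent explicit fold loop", {
  toy <- lmm_toy(n_subjects = 5, n_visits = 3, sigma_b = 2, sigma_e = 3,
                 seed = 10)
  spec <- structure(list(model = "A", tier = "custom", phone = "phq8",
                         covariates = "baseline_madrs", label = "toy",
                         uses_pca = FALSE), class = "model_spec")
  cv <- loso_cv(toy, spec = spec)

  # brute force: explicit loop, direct lme4 call, manual dot products
  rmses <- sapply(unique(toy$subject), function(s) {
    train <- toy[toy$subject != s, ]
    hold <- toy[toy$subject == s, ]
    fit <- lme4::lmer(madrs ~ phq8 + baseline_madrs + (1 | subject),
                      data = train, REML = FALSE)
    b <- lme4::fixef(fit)
    pred <- b[1] + b["phq8"] * hold$phq8 +
      b["baseline_madrs"] * hold$baseline_madrs
    sqrt(mean((hold$madrs - pred)^2))
  })
  expect_equal(cv$per_subject$rmse, unname(rmses), tolerance = 1e-8)
  expect_equal(cv$avg_rmse, mean(rmses), tolerance = 1e-8)
})

test_that("held-out data never influences the training fold", {
  toy <- small_table()
  toy <- toy[!is.na(toy$phq8), ]
  spec <- model_spec("C", "full")
  subjects <- unique(toy$subject)
  hold <- subjects[1]

  fit_clean <- fit_madrs(toy[toy$subject != hold, ], spec = spec)
  # perturb the held-out subject's features and outcome wildly
  toy2 <- toy
  sel <- toy2$subject == hold
  toy2$madrs[sel] <- 60
  toy2[sel, passive_feature_names()] <-
    toy2[sel, passive_feature_names()] * 100 + 7
  fit_pert <- fit_madrs(toy2[toy2$subject != hold, ], spec = spec)
  expect_identical(coef(fit_clean), coef(fit_pert))
  expect_identical(fit_clean$pca$loadings, fit_pert$pca$loadings)
})

test_that("the average is over per-subject RMSEs, not pooled", {
  # unbalanced toy where the two conventions differ
  toy <- rbind(
    data.frame(subject = "a", visit_index = 1:4, phq8 = 0,
               baseline_madrs = 0, madrs = c(10, 10, 10, 10)),
    data.frame(subject = "b", visit_index = 1, phq8 = 0,
               baseline_madrs = 0, madrs = 40),
    data.frame(subject = "c", visit_index = 1:2, phq8 = 0,
               baseline_madrs = 0, madrs = c(20, 20)))
  cv <- suppressWarnings(loso_cv(toy, model = "D", tier = "none"))
  per <- cv$per_subject
  pooled <- with(cv$predictions,
                 sqrt(mean((madrs - predicted)^2)))
  per_subject_avg <- mean(per$rmse)
  expect_false(isTRUE(all.equal(pooled, per_subject_avg)))
  expect_equal(cv$avg_rmse, per_subject_avg)
})

test_that("fitting fails informatively with too few subjects", {
  toy <- lmm_toy(n_subjects = 1, seed = 11)
  expect_error(fit_madrs(toy, model = "D", tier = "none"), "subject")
  expect_error(loso_cv(lmm_toy(n_subjects = 2, seed = 12), model = "D",
                       tier = "none"), "3 subjects")
})
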