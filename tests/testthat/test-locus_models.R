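test_that("logistic fit recovers planted parameters on noiseless data", {
  withr::with_seed(1, x <- runif(100))
  y <- plogis(3 * x - 1)
  fit <- fit_logistic(y, x)
  expect_lt(abs(fit$coefficients - 3), 1e-3)
  expect_lt(abs(fit$intercept - (-1)), 1e-3)
  expect_false(fit$flagged)

  # constant response at 0.5 gives the flat model
  flat <- fit_logistic(rep(0.5, 50), x[1:50])
  expect_lt(abs(flat$coefficients), 1e-6)
  expect_lt(abs(flat$intercept), 1e-6)

  # predictions stay strictly inside (0,1)
  p <- predict_locus("logistic", fit$coefficients, fit$intercept,
                     c(-5, 0, 0.5, 1, 5))
  expect_true(all(p > 0 & p < 1))

  # degenerate constant feature is flagged
  expect_true(fit_logistic(y[1:50], rep(0.3, 50))$flagged)
})

test_that("logistic deviance is convex: refits from different starts agree to 1e-8", {
  withr::with_seed(2, {
    x <- runif(120)
    y <- pmin(pmax(plogis(2 * x - 1) + rnorm(120, 0, 0.1), 0), 1)
  })
  f1 <- fit_logistic(y, x, start = c(0, 0))
  f2 <- fit_logistic(y, x, start = c(5, -5))
  expect_lt(abs(f1$coefficients - f2$coefficients), 1e-8)
  expect_lt(abs(f1$intercept - f2$intercept), 1e-8)

  # independent IRLS implementation (fractional-response binomial glm)
  # lands on the same optimum
  ref <- suppressWarnings(stats::glm.fit(
    cbind(1, x), pmin(pmax(y, 1e-6), 1 - 1e-6),
    family = stats::quasibinomial(),
    control = stats::glm.control(epsilon = 1e-12)))$coefficients
  expect_equal(f1$intercept, unname(ref[1]), tolerance = 1e-7)
  expect_equal(f1$coefficients, unname(ref[2]), tolerance = 1e-7)
})

test_that("OLS fit matches the closed-form normal equations and clips predictions", {
  x <- seq(0, 1, length.out = 50)
  fit <- fit_ols(0.5 * x + 0.2, x)
  expect_equal(fit$coefficients, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.2, tolerance = 1e-12)

  expect_equal(predict_locus("ols", 1, 0.8, 0.5), 1.0)  # 1.3 pre-clip
  expect_equal(predict_locus("ols", 1, -0.8, 0.5), 0.0)

  withr::with_seed(3, {
    x <- runif(200)
    y <- pmin(pmax(0.4 * x + 0.1 + rnorm(200, 0, 0.05), 0), 1)
  })
  fit <- fit_ols(y, x)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)  # normal-equations oracle
  expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit$coefficients, beta[2], tolerance = 1e-10)

  expect_true(fit_ols(y, cbind(x, x))$flagged)  # rank-deficient
})

test_that("slope sign follows the feature-target correlation", {
  withr::with_seed(4, {
    for (i in 1:10) {
      x <- runif(60)
      sign_true <- sample(c(-1, 1), 1)
      y <- pmin(pmax(0.5 + sign_true * 0.3 * (x - 0.5) + rnorm(60, 0, 0.05), 0), 1)
      r <- cor(x, y)
      expect_equal(sign(fit_logistic(y, x)$coefficients), sign(r))
      expect_equal(sign(fit_ols(y, x)$coefficients), sign(r))
    }
  })
})

test_that("cross-validation recovers a noiseless planted sigmoid as super_high", {
  tr <- make_linked_training(n = 100, w = 3, b = -1, sd = 0, seed = 5)
  cv <- cross_validate("M", one_row_assignment(), tr, family = "logistic",
                       seed = 1)
  expect_lt(cv$model$cv_metrics[["rmse"]], 1e-3)
  expect_identical(cv$model$category, "super_high")
  expect_lt(abs(cv$model$coefficients - 3), 1e-3)
  expect_lt(abs(cv$model$intercept - (-1)), 1e-3)
  expect_length(cv$oof, 100)

  # same seed gives identical folds, metrics and coefficients
  cv2 <- cross_validate("M", one_row_assignment(), tr, family = "logistic",
                        seed = 1)
  expect_identical(cv$model, cv2$model)
  expect_identical(cv$oof, cv2$oof)
})

test_that("metrics match independent formulas, including the hand confusion example", {
  m <- compute_metrics(c(0.2, 0.8), c(0.2, 0.8))
  expect_equal(unname(m[c("rmse", "mae", "acc", "mcc")]), c(0, 0, 1, 1))

  # hand confusion count: TP=1, FN=1, FP=1, TN=1
  m <- compute_metrics(c(0.9, 0.9, 0.1, 0.1), c(0.8, 0.2, 0.7, 0.3))
  expect_equal(unname(m[c("acc", "mcc", "se", "sp")]), c(0.5, 0, 0.5, 0.5))

  withr::with_seed(6, {
    for (i in 1:100) {
      pred <- runif(100)
      obs <- runif(100)
      expect_equal(compute_metrics(pred, obs), oracle_metrics(pred, obs),
                   tolerance = 1e-12)
    }
  })

  # single observed class: SE or SP and AUC are missing, never 0
  m <- compute_metrics(runif(20), runif(20, 0.6, 0.9))
  expect_true(is.na(m[["sp"]]))
  expect_true(is.na(m[["auc"]]))
  expect_false(is.na(m[["se"]]))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(7, {
    pred <- runif(200)
    obs <- runif(200)
  })
  m <- compute_metrics(pred, obs)
  ref <- as.numeric(pROC::auc(pROC::roc(response = obs > 0.5,
                                        predictor = pred, quiet = TRUE,
                                        direction = "<")))
  expect_equal(m[["auc"]], ref, tolerance = 1e-12)
})

test_that("RMSE categories follow the published boundaries", {
  expect_identical(categorize(c(0.03, 0.05, 0.1, 0.15)),
                   c("super_high", "high", "medium", "low"))
  expect_identical(categorize(0.0499999), "super_high")
  expect_identical(categorize(0.0999999), "high")
  expect_identical(categorize(0.1499999), "medium")
  expect_identical(categorize(10), "low")
  expect_error(categorize(-0.01), "non-negative")
})

test_that("model files round-trip losslessly and reject unknown schemas", {
  fx <- generate_fixture(simulation_spec(n_model_loci = 8, n_feature_loci = 40,
                                         n_samples = 60, seed = 13))
  parts <- partition_loci(fx$manifest)
  asg <- build_assignments(fx$manifest, fx$betas,
                           model_loci = parts$model_loci,
                           feature_loci = parts$feature_loci, min_samples = 20)
  models <- lapply(seq_len(nrow(asg$assignments)), function(i) {
    cross_validate(asg$assignments$model_probe[i],
                   asg$assignments[i, ], fx$betas,
                   min_fit_samples = 20)$model
  })
  path <- withr::local_tempfile(fileext = ".jsonl")
  save_models(models, path)
  loaded <- load_models(path)
  expect_length(loaded, length(models))
  for (i in seq_along(models)) {
    expect_identical(loaded[[i]]$model_probe, models[[i]]$model_probe)
    # full double precision survives the round trip
    expect_identical(loaded[[i]]$coefficients, models[[i]]$coefficients)
    expect_identical(loaded[[i]]$intercept, models[[i]]$intercept)
    expect_equal(loaded[[i]]$cv_metrics, models[[i]]$cv_metrics)
    expect_identical(loaded[[i]]$category, models[[i]]$category)
  }

  bad <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"schema_version":99,"model_probe":"x"}', bad)
  expect_error(load_models(bad), "schema version")
})

test_that("pooled CV RMSE degrades monotonically with planted noise", {
  noise <- c(0.02, 0.07, 0.12, 0.2)
  mean_rmse <- sapply(noise, function(s) {
    mean(sapply(1:5, function(seed) {
      tr <- make_linked_training(n = 80, w = 2.5, b = -1.25, sd = s,
                                 seed = 100 * seed)
      cross_validate("M", one_row_assignment(), tr,
                     seed = seed)$model$cv_metrics[["rmse"]]
    }))
  })
  expect_gt(cor(noise, mean_rmse, method = "spearman"), 0)
  expect_true(all(diff(mean_rmse) > 0))
})

test_that("logistic wins on sigmoid-planted data, OLS on interior linear data", {
  rmse_of <- function(family, gen, seeds = 1:5) {
    mean(sapply(seeds, function(s) {
      tr <- gen(s)
      cross_validate("M", one_row_assignment(), tr, family = family,
                     seed = s)$model$cv_metrics[["rmse"]]
    }))
  }
  gen_sig <- function(s) make_linked_training(n = 120, w = 8, b = -4,
                                              sd = 0.03, seed = s)
  gen_lin <- function(s) withr::with_seed(s, {
    x <- runif(120)
    tr <- rbind(M = pmin(pmax(0.3 + 0.4 * x + rnorm(120, 0, 0.03), 0), 1),
                F = x)
    colnames(tr) <- sprintf("s%03d", 1:120)
    tr
  })
  expect_lte(rmse_of("logistic", gen_sig), rmse_of("ols", gen_sig) + 1e-6)
  expect_lte(rmse_of("ols", gen_lin), rmse_of("logistic", gen_lin) + 0.002)
})
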