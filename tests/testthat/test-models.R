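test_that("feature sets match the published model configurations", {
  expect_equal(feature_set("CONV5"),
               c("height", "age", "gender", "weight", "h2_r50"))
  expect_equal(feature_set("PROP8"),
               c("height", "age", "gender", "weight", "h2_r50",
                 "hip", "waist", "waist_hip"))
  expect_equal(feature_set("NET1_M1"),
               c("height", "age", "gender", "weight", "r50_prop"))
  expect_equal(setdiff(feature_set("NET1_M2"), feature_set("NET1_M1")),
               "h2_imp")
  # the two largest index-estimation variants differ only by waist/hip
  expect_equal(setdiff(feature_set("NET1_M3"), feature_set("NET1_M2")),
               "waist_hip")
  expect_length(feature_set("NET1_M3"), 7)
  expect_length(feature_set("NET2_PROP"), 8)
})

test_that("build_features computes derived quantities in declared order", {
  subj <- data.frame(height_cm = 178, age_yr = 21, gender = 1,
                     weight_kg = 83.6, waist_cm = 83.5, hip_cm = 100.7)
  X <- build_features(subj, "NET1_M3", settled_ohms = 600)
  expect_equal(colnames(X), feature_set("NET1_M3"))
  expect_equal(unname(X[1, "h2_imp"]), 178^2 / 600, tolerance = 1e-3)
  expect_equal(unname(X[1, "h2_imp"]), 52.8067, tolerance = 1e-3)
  expect_equal(unname(X[1, "waist_hip"]), 0.82920, tolerance = 1e-4)
  expect_equal(unname(X[1, "gender"]), 1)

  expect_error(build_features(subj[, -1], "NET1_M1", settled_ohms = 600),
               "height_cm")
  expect_error(build_features(subj, "NET1_M1"), "settled_ohms")
  expect_error(build_features(subj, "CONV5"), "h2r_values")
})

test_that("fit_ols recovers exact and randomly generated coefficients", {
  x <- cbind(x1 = as.numeric(1:10))
  m <- suppressWarnings(fit_ols(x, 2 * (1:10) + 1))
  expect_equal(unname(m$coefficients["x1"]), 2.0, tolerance = 1e-10)
  expect_equal(m$intercept, 1.0, tolerance = 1e-10)

  # random 8-feature design, zero noise, vs normal-equations oracle
  set.seed(21)
  X <- matrix(rnorm(200 * 8), 200, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  beta <- rnorm(8); alpha <- 2.5
  y <- alpha + X %*% beta
  m <- suppressWarnings(fit_ols(X, y))
  expect_lt(max(abs(m$coefficients - beta)), 1e-8)
  expect_lt(abs(m$intercept - alpha), 1e-8)
  Xd <- cbind(1, X)
  oracle <- solve(crossprod(Xd), crossprod(Xd, y))  # normal equations
  expect_equal(unname(c(m$intercept, m$coefficients)), c(oracle),
               tolerance = 1e-8)

  expect_error(fit_ols(cbind(a = 1:10, b = 2 * (1:10)), rnorm(10)),
               "singular")
  expect_error(fit_ols(X[1:5, ], y[1:5]), "more rows")
})

test_that("a pure-noise feature is rarely significant", {
  set.seed(33)
  hits <- 0
  for (i in 1:100) {
    X <- matrix(rnorm(80 * 3), 80, 3,
                dimnames = list(NULL, c("a", "b", "noise")))
    y <- 1 + 2 * X[, 1] - X[, 2] + rnorm(80)
    m <- fit_ols(X, y)
    if (m$p_values["noise"] > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("published coefficients evaluate to the printed predictions", {
  m <- published_pbf_model("conventional")
  expect_identical(m$intercept, 59.6240)
  expect_equal(predict_linear(m, c(0, 0, 0, 0, 0)), 59.6240)
  expect_equal(predict_linear(m, c(age = 20, gender = 1, height = 170,
                                   weight = 60, h2_r50 = 50)),
               1.0954, tolerance = 1e-4)
  p <- published_pbf_model("proposed")
  expect_equal(p$intercept, -16.2929)
  expect_equal(unname(p$coefficients["waist_hip"]), 78.5731)
  expect_length(p$feature_names, 8)

  # zero-coefficient model returns the intercept for any features
  z <- linear_model(c("a", "b"), 7.5, c(0, 0))
  expect_equal(predict_linear(z, c(123, -4)), 7.5)
})

test_that("predict_linear is exactly affine and order-safe", {
  m <- published_pbf_model("conventional")
  x <- c(age = 20, gender = 1, height = 170, weight = 60, h2_r50 = 50)
  y <- c(age = 30, gender = 0, height = 182, weight = 85, h2_r50 = 60)
  for (al in c(0.25, 0.5, 0.9)) {
    expect_equal(predict_linear(m, al * x + (1 - al) * y),
                 al * predict_linear(m, x) + (1 - al) * predict_linear(m, y),
                 tolerance = 1e-10)
  }
  # permuted columns with names are realigned
  X <- rbind(x, y)
  Xp <- X[, c("h2_r50", "age", "height", "gender", "weight")]
  expect_equal(predict_linear(m, Xp), predict_linear(m, X))
  expect_error(predict_linear(m, c(1, 2, 3)), "length mismatch")
})

test_that("adding features never reduces OLS training r-squared", {
  coh <- simulate_cohort(default_cohort_config(), seed = 4)
  s <- coh$subjects
  h2r <- s$ref_h2r
  X5 <- build_features(s, "CONV5", h2r_values = h2r)
  X8 <- build_features(s, "PROP8", h2r_values = h2r)
  r2 <- function(X) {
    m <- fit_ols(X, s$true_pbf_pct)
    cor(predict_linear(m, X), s$true_pbf_pct)^2
  }
  expect_gte(r2(X8), r2(X5))
})

test_that("train_mlp learns a noise-free linear target and is deterministic", {
  set.seed(0)
  X <- matrix(rnorm(500 * 3), 500, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 3 + 2 * X[, 1] - X[, 2] + 0.5 * X[, 3]
  spec <- tiny_mlp(3, seed = 0)
  m <- train_mlp(spec, X, y)
  p <- predict_mlp(m, X)
  expect_gte(cor(p, y)^2, 0.99)

  m2 <- train_mlp(spec, X, y)
  expect_identical(m2$stopped_epoch, m$stopped_epoch)
  expect_identical(predict_mlp(m2, X), p)
})

test_that("early stopping halts within patience and restores best weights", {
  set.seed(1)
  X <- matrix(rnorm(60 * 2), 60, 2)
  y <- rnorm(60)  # pure noise: validation loss cannot keep improving
  spec <- tiny_mlp(2, seed = 1, patience = 10, max_epochs = 500)
  m <- train_mlp(spec, X, y)
  expect_lt(m$stopped_epoch, 500)
  expect_lte(m$stopped_epoch, m$best_epoch + 10)
  expect_equal(min(m$history$val_loss), m$history$val_loss[m$best_epoch])
  expect_lte(m$stopped_epoch, m$spec$max_epochs)
})

test_that("predict_mlp is batch-invariant and validates dimensions", {
  set.seed(2)
  X <- matrix(rnorm(50 * 4), 50, 4)
  y <- X %*% c(1, -1, 2, 0.5)
  m <- train_mlp(tiny_mlp(4, seed = 2), X, y)
  batch <- predict_mlp(m, X)
  rowwise <- vapply(seq_len(nrow(X)), function(i) predict_mlp(m, X[i, ]),
                    numeric(1))
  expect_equal(batch, rowwise, tolerance = 1e-12)
  expect_error(predict_mlp(m, matrix(0, 2, 3)), "dimension mismatch")
})

test_that("zeroed output layer predicts the (rescaled) output bias", {
  set.seed(3)
  X <- matrix(rnorm(40 * 2), 40, 2)
  m <- train_mlp(tiny_mlp(2, seed = 3, max_epochs = 5, patience = 4),
                 X, rnorm(40))
  L <- length(m$weights)
  m$weights[[L]][] <- 0
  m$biases[[L]][] <- 0.25
  expect_equal(unique(round(predict_mlp(m, X), 12)),
               round(0.25 * m$y_scale + m$y_center, 12))
})

test_that("standardization flag is a no-op on pre-standardized inputs", {
  set.seed(4)
  X <- matrix(rnorm(100 * 3), 100, 3)
  X <- scale(X)[, ]  # exactly zero mean, unit sd
  y <- X %*% c(1, 2, -1) + rnorm(100, 0, 0.1)
  m_on <- train_mlp(tiny_mlp(3, seed = 4, standardize = TRUE), X, y)
  m_off <- train_mlp(tiny_mlp(3, seed = 4, standardize = FALSE), X, y)
  expect_equal(predict_mlp(m_on, X), predict_mlp(m_off, X),
               tolerance = 1e-10)
})

test_that("index and body-fat estimators expose the regime structure", {
  coh <- simulate_cohort(linear_cohort_config(), seed = 2)
  cal <- calibrate_series(coh$series)
  s <- coh$subjects[cal$valid, ]
  settled <- setNames(cal$settled_ohms[cal$valid],
                      cal$subject_id[cal$valid])[s$id]

  # noise-free index that is exactly linear in the 5 base features
  s2 <- s
  s2$ref_h2r <- 2 * s$height_cm - 0.5 * s$age_yr + 3 * s$gender +
    0.1 * s$weight_kg + 0.01 * settled
  fr <- suppressWarnings(fit_h2r(s2, settled, "REGRESSION"))
  expect_equal(cor(estimate_h2r(fr, s2, settled), s2$ref_h2r), 1,
               tolerance = 1e-8)

  # PBF predictions are clipped to the physiologic range
  fit <- fit_pbf(s, s$ref_h2r, "L_CONV")
  fit$model$intercept <- fit$model$intercept + 1000
  expect_true(all(estimate_pbf(fit, s, s$ref_h2r) <= 60))
  fit$model$intercept <- fit$model$intercept - 2000
  expect_true(all(estimate_pbf(fit, s, s$ref_h2r) >= 0))
})

test_that("linear regime recovers an affine zero-noise cohort", {
  coh <- simulate_cohort(linear_cohort_config(), seed = 0)
  res <- run_experiment(coh, regimes = c("L_PROP"), seed = 0)
  expect_gte(res$reports$r_squared[1], 0.99)
})
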