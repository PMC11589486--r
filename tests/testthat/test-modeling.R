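test_that("split plans honour sizes, determinism and the benchmark contract", {
  p40 <- make_splits(40, seed = 1)
  expect_equal(p40$n_train, 28)
  expect_true(all(vapply(p40$assignments, sum, numeric(1)) == 28))
  expect_true(all(vapply(p40$assignments, function(a) sum(!a), numeric(1)) == 12))
  # n = 45: round-half-even on the exact decimal 31.5 gives 32/13
  p45 <- make_splits(45, seed = 1)
  expect_equal(p45$n_train, 32)
  expect_equal(p45$n - p45$n_train, 13)
  expect_equal(p45$n_iterations, 5)
  expect_identical(make_splits(45, seed = 9)$assignments,
                   make_splits(45, seed = 9)$assignments)
  expect_false(identical(make_splits(45, seed = 9)$assignments,
                         make_splits(45, seed = 10)$assignments))
  expect_error(make_splits(9, seed = 1), "size error")
})

test_that("OLS recovers exact coefficients and rejects rank deficiency", {
  set.seed(8)
  n <- 45
  design <- data.frame(red = runif(n, 80, 180), green = runif(n, 80, 180),
                       blue = runif(n, 40, 120))
  y <- 2.71 + 0.28 * design$red - 0.25 * design$green + 0.15 * design$blue
  fit <- fit_linear(y, design)
  expect_equal(unname(fit$coefficients),
               c(2.71, 0.28, -0.25, 0.15), tolerance = 1e-8)
  expect_true(all(fit$p_values[-1] < 1e-10))
  expect_length(fit$vif, 3)
  # constant response: zero slopes
  fit0 <- fit_linear(rep(7, n), design)
  expect_equal(unname(fit0$coefficients[-1]), c(0, 0, 0), tolerance = 1e-8)
  # duplicated predictor column
  design2 <- design; design2$red2 <- design$red
  expect_error(fit_linear(y, design2), "rank error")
  expect_error(fit_linear(y[1:3], design[1:3, ]), "rows > predictors")
  # single-predictor fit carries no VIF
  expect_null(fit_linear(y, design["red"])$vif)
})

test_that("VIF equals 1/(1 - r^2) and detects perfect collinearity", {
  # exactly orthogonal two-column design
  x1 <- rep(c(1, -1), 10); x2 <- rep(c(1, 1, -1, -1), 5)
  expect_equal(unname(vif(data.frame(x1, x2))), c(1, 1), tolerance = 1e-12)
  # closed form on correlated predictors, cross-checked against car::vif
  set.seed(3)
  a <- rnorm(60); b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(60)
  d <- data.frame(a, b)
  r2 <- cor(a, b)^2
  expect_equal(unname(vif(d)), rep(1 / (1 - r2), 2), tolerance = 1e-9)
  y <- a + b + rnorm(60)
  expect_equal(unname(vif(d)),
               unname(car::vif(lm(y ~ a + b))), tolerance = 1e-9)
  # exact linear dependence among three predictors
  d3 <- data.frame(a, b, s = a + b)
  expect_true(all(is.infinite(vif(d3))))
  expect_true(is.na(vif(data.frame(a, k = rep(1, 60)))["k"]))
})

test_that("VIF reduction drops the worst predictor until all pass", {
  set.seed(5)
  n <- 50
  green <- runif(n, 80, 180)
  blue <- runif(n, 40, 120)
  # red is a near-exact combination of the others, so its VIF is highest
  red <- 0.7 * green + 0.5 * blue + rnorm(n, 0, 2)
  d <- data.frame(red = red, green = green, blue = blue)
  kept <- reduce_by_vif(d, threshold = 5)
  expect_setequal(as.character(kept), c("green", "blue"))
  expect_equal(attr(kept, "removed"), "red")
  # all below threshold: no-op
  ortho <- data.frame(x = rnorm(n), y = rnorm(n))
  expect_length(reduce_by_vif(ortho), 2)
  # perfect collinearity: exactly one of the pair survives
  dup <- data.frame(a = green, b = green)
  expect_length(reduce_by_vif(dup), 1)
})

test_that("evaluation metrics follow their definitions", {
  set.seed(2)
  d <- data.frame(x = runif(30, 0, 10))
  y <- 1 + 2 * d$x
  fit <- fit_linear(y, d)
  ev <- evaluate(fit, d, y)
  expect_equal(ev$r2, 1)
  expect_equal(ev$rmse, 0, tolerance = 1e-10)
  expect_equal(ev$mae, 0, tolerance = 1e-10)
  # constant offset: correlation-based R2 stays 1, errors equal |c|
  ev2 <- evaluate(fit, d, y + 3)
  expect_equal(ev2$r2, 1)
  expect_equal(ev2$rmse, 3, tolerance = 1e-10)
  expect_equal(ev2$mae, 3, tolerance = 1e-10)
  expect_lt(ev2$r2_holdout, 1)
  # RMSE >= MAE on arbitrary residuals (power-mean inequality)
  for (i in 1:20) {
    obs <- rnorm(25, 10, 3)
    ev3 <- evaluate(fit, d[1:25, , drop = FALSE], obs)
    expect_gte(ev3$rmse, ev3$mae)
  }
  # constant predictions: undefined R2, errors still reported
  fit0 <- fit_linear(rep(5, 30) + rnorm(30, 0, 1e-12), d)
  ev4 <- evaluate(fit0, d, rnorm(30, 5))
  expect_true(is.finite(ev4$rmse) && is.finite(ev4$mae))
})

test_that("the model suite emits one metrics row per model x iteration", {
  # bands with well-separated dynamics: no VIF reduction triggered
  p <- tiny_params(n_dates = 15, replicates = 3,
                   band_base = c(95, 120, 60), band_rise_amp = c(65, 25, 20),
                   band_fall_amp = c(85, 70, 25),
                   band_fall_onset = c(90, 76, 95))
  s <- generate_season(p, 21)
  it <- cbind(s, compute_indexes(s$red, s$green, s$blue))
  sel <- select_predictors(score_predictors(it))
  chosen <- head(sel$ci_name[sel$selected], 7)
  plan <- make_splits(nrow(it), seed = 4)
  suite <- run_model_suite(it, chosen, plan)
  vifs <- vif(it[, c("red", "green", "blue")])
  if (all(vifs <= 5)) {
    expect_equal(nrow(suite$metrics), 5 * (1 + length(chosen)))
    expect_false("RGB_reduced" %in% suite$metrics$model_id)
  } else {
    expect_equal(nrow(suite$metrics), 5 * (2 + length(chosen)))
  }
  # benchmark contract: all models share the identical partitions
  per_iter <- split(suite$metrics, suite$metrics$iteration)
  for (mi in per_iter) {
    expect_equal(length(unique(mi$n_train)), 1)
    expect_equal(length(unique(mi$n_test)), 1)
  }
  # pooled residual mean compatible with 0 at test scale
  for (mid in unique(suite$residuals$model_id)) {
    r <- suite$residuals$residual[suite$residuals$model_id == mid]
    expect_lt(abs(mean(r)), 2 * sd(r) / sqrt(length(r)) + 0.35)
  }
  expect_error(run_model_suite(it, "absent_ci", plan), "missing")
})

test_that("an RGB-linear generator is recovered with high test accuracy", {
  set.seed(6)
  n <- 45
  it <- data.frame(red = runif(n, 80, 180), green = runif(n, 80, 180),
                   blue = runif(n, 40, 120))
  it$oil <- 2.71 + 0.28 * it$red - 0.25 * it$green + 0.15 * it$blue +
    rnorm(n, 0, 0.5)
  plan <- make_splits(n, seed = 2)
  suite <- run_model_suite(it, character(0), plan)
  r2 <- suite$metrics$r2[suite$metrics$model_id == "RGB"]
  expect_length(r2, 5)
  expect_gte(median(r2), 0.9)
  # noiseless data generated from a fitted model: perfect evaluation
  fit <- fit_linear(it$oil, it[, c("red", "green", "blue")])
  yhat <- as.numeric(predict(fit$lm, it))
  ev <- evaluate(fit, it, yhat)
  expect_equal(ev$r2, 1)
  expect_equal(ev$rmse, 0, tolerance = 1e-10)
})
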