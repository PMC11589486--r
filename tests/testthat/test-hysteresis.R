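test_that("turning point is the first maximum in time order", {
  expect_equal(turning_point(trajectory(c(1, 2, 3, 4), c(1, 2, 3, 4))), 4)
  expect_equal(turning_point(trajectory(c(1, 4, 3, 2), c(1, 2, 3, 4))), 2)
  # tie rule: first occurrence, checked against brute-force argmax-first
  ci <- c(1, 4, 4, 2)
  expect_equal(turning_point(trajectory(ci, 1:4)), which(ci == max(ci))[1])
  expect_error(trajectory(c(1, 2, 3), c(1, 2, 3)), ">= 4")
})

test_that("arm rotation reflects about ci_max and is an involution", {
  expect_equal(rotate_arm(200, 200), 200)
  expect_equal(rotate_arm(150, 200), 250)
  x <- c(10, 55.5, 199.99)
  # the reflection is an involution: applying the map twice restores x
  expect_equal(2 * 200 - rotate_arm(x, 200), x)
  # distance preservation
  expect_equal(abs(rotate_arm(x, 200) - 200), abs(x - 200))
  expect_error(rotate_arm(201, 200), "exceed")
})

test_that("fit_and_integrate reproduces closed-form areas", {
  x <- c(0, 1 / 3, 2 / 3, 1)
  expect_equal(fit_and_integrate(x, rep(10, 4), 0, 1), 10, tolerance = 1e-6)
  x2 <- seq(0, 2, length.out = 6)
  expect_equal(fit_and_integrate(x2, x2, 0, 2), 2, tolerance = 1e-3)
  expect_equal(fit_and_integrate(x2, x2, 1, 1), 0)
  # < 4 distinct x: logged fallback to the piecewise-linear route
  expect_message(
    val <- fit_and_integrate(c(0, 0, 1, 1), c(0, 0, 2, 2), 0, 1),
    "falling back")
  expect_equal(val, 1, tolerance = 1e-9)
  # spline AUC within 5% of the raw trapezoid-on-points oracle
  set.seed(7)
  for (i in 1:10) {
    xs <- sort(runif(25, 0, 10))
    ys <- 2 + 0.8 * xs + rnorm(25, 0, 0.1)
    spl <- fit_and_integrate(xs, ys, min(xs), max(xs))
    expect_lt(abs(spl - brute_trapz_points(xs, ys)) / brute_trapz_points(xs, ys),
              0.05)
  }
})

test_that("hyst_index matches its boundary cases and the brute-force oracle", {
  # strictly increasing ci: empty downward arm, hyst = -1 exactly
  h <- hyst_index(trajectory(c(1, 2, 3, 4, 5), c(5, 6, 8, 10, 12)))
  expect_identical(h$hyst, -1)
  expect_identical(h$hyst_area, 0)
  # mirror arm: hyst_area = tot_area/2, hyst = 0 (piecewise-linear route)
  tr0 <- trajectory(c(0, 1, 2, 1, 0), c(1, 2, 3, 2, 1))
  expect_equal(hyst_index(tr0, method = "trapezoid")$hyst, 0, tolerance = 1e-9)
  # pinned toy value against the independent oracle (= 1/3 here)
  ci <- c(0, 1, 2, 1, 0); oil <- c(1, 2, 3, 4, 5)
  tr <- trajectory(ci, oil)
  expect_equal(brute_hyst(ci, oil), 1 / 3, tolerance = 1e-12)
  expect_equal(hyst_index(tr, method = "trapezoid")$hyst, brute_hyst(ci, oil),
               tolerance = 1e-9)
  expect_lt(abs(hyst_index(tr)$hyst - brute_hyst(ci, oil)), 0.05 * 2)
  # decomposition invariants
  hh <- hyst_index(tr, method = "trapezoid")
  expect_true(hh$hyst_area >= 0 && hh$hyst_area <= hh$tot_area)
  expect_equal(hh$hyst, (2 * hh$hyst_area - hh$tot_area) / hh$tot_area)
})

test_that("hyst stays in [-1, 1] and is invariant to axis rescaling", {
  set.seed(11)
  for (i in 1:40) {
    onset <- runif(1, 0, 160)
    p <- tiny_params(n_dates = 10, band_fall_onset = onset,
                     noise_oil = runif(1, 0, 1), noise_band = runif(1, 0, 5))
    s <- generate_season(p, i)
    h <- hyst_index(trajectory(s$green, s$oil))$hyst
    expect_true(h >= -1 && h <= 1)
  }
  # positive affine rescale of CI axis; positive scaling of oil axis
  p <- tiny_params(n_dates = 12, band_fall_onset = 50)
  s <- generate_season(p, 5)
  base <- hyst_index(trajectory(s$green, s$oil), method = "trapezoid")$hyst
  resc <- hyst_index(trajectory(3.7 * s$green + 12, 2.5 * s$oil),
                     method = "trapezoid")$hyst
  expect_equal(resc, base, tolerance = 1e-9)
  spl_base <- hyst_index(trajectory(s$green, s$oil))$hyst
  spl_resc <- hyst_index(trajectory(3.7 * s$green + 12, 2.5 * s$oil))$hyst
  expect_equal(spl_resc, spl_base, tolerance = 1e-6)
})

test_that("earlier fall onset never decreases Hyst (noise-free sweep)", {
  onsets <- seq(150, 20, by = -10)
  hy <- vapply(onsets, function(on) {
    p <- tiny_params(n_dates = 14, replicates = 1, noise_oil = 0,
                     noise_band = 0, band_fall_onset = on)
    s <- generate_season(p, 1)
    hyst_index(trajectory(s$green, s$oil), method = "trapezoid")$hyst
  }, numeric(1))
  expect_true(all(diff(hy) >= -1e-9))
  expect_equal(hy[1], -1)      # onset beyond the season: no hysteresis
  expect_gt(tail(hy, 1), 0.5)  # early onset: loop spans most of the season
  # |rho| is high where Hyst is near +/-1 (qualitative concordance)
  rho <- vapply(onsets, function(on) {
    p <- tiny_params(n_dates = 14, replicates = 1, noise_oil = 0,
                     noise_band = 0, band_fall_onset = on)
    s <- generate_season(p, 1)
    abs(spearman_rho(s$green, s$oil))
  }, numeric(1))
  expect_gt(suppressWarnings(cor(rho, abs(hy), method = "spearman")), 0)
})

test_that("spearman_rho handles monotone data and ties like the rank formula", {
  expect_equal(spearman_rho(1:6, c(2, 3, 5, 8, 9, 20)), 1)
  expect_equal(spearman_rho(1:6, -c(2, 3, 5, 8, 9, 20)), -1)
  # hand-expanded average ranks for x = [1,2,2,3], y = [1,3,2,4]
  rx <- c(1, 2.5, 2.5, 4); ry <- c(1, 3, 2, 4)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_rho(c(1, 2, 2, 3), c(1, 3, 2, 4)), oracle,
               tolerance = 1e-12)
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
})

test_that("fitness index adds absolute components within [0, 2]", {
  expect_equal(fitness_index(-1, -0.94), 1.94)
  expect_equal(fitness_index(0, 0), 0)
  expect_error(fitness_index(1.2, 0), "\\[-1, 1\\]")
  set.seed(2)
  h <- runif(50, -1, 1); r <- runif(50, -1, 1)
  expect_true(all(fitness_index(h, r) >= 0 & fitness_index(h, r) <= 2))
})

test_that("top-quintile selection follows the type-7 threshold with ties", {
  rec <- function(fi) data.frame(ci_name = paste0("c", seq_along(fi)),
                                 hyst = 0, rho = 0, fi = fi, selected = FALSE)
  # 35 distinct values: 7 selected (sort-and-slice oracle)
  set.seed(1); fi35 <- sample(seq(0.1, 2, length.out = 35))
  out <- select_predictors(rec(fi35))
  expect_equal(sum(out$selected), 7)
  expect_setequal(out$ci_name[out$selected],
                  paste0("c", order(-fi35)[1:7]))
  # 38 distinct values: 8 selected (interpolated threshold semantics)
  fi38 <- sample(seq(0.1, 2, length.out = 38))
  expect_equal(sum(select_predictors(rec(fi38))$selected), 8)
  # all equal: everyone ties at the threshold
  expect_equal(sum(select_predictors(rec(rep(1.5, 12)))$selected), 12)
  # undefined FIs are excluded from pool and threshold
  fi <- c(rep(NA, 3), seq(0.5, 1.5, length.out = 10))
  out2 <- select_predictors(rec(fi))
  expect_equal(sum(out2$selected), sum(fi >= quantile(fi, 0.8, na.rm = TRUE),
                                       na.rm = TRUE))
  expect_error(select_predictors(rec(rep(NA_real_, 6))), "selection error")
})

test_that("score_predictors pools replicates and flags unusable candidates", {
  p <- tiny_params(n_dates = 10, band_fall_onset = c(120, 40, 60))
  s <- generate_season(p, 3)
  it <- cbind(s, compute_indexes(s$red, s$green, s$blue))
  sc <- score_predictors(it)
  expect_equal(nrow(sc), 38)
  expect_true(all(sc$fi >= 0 & sc$fi <= 2, na.rm = TRUE))
  expect_equal(sc$fi, abs(sc$hyst) + abs(sc$rho), tolerance = 1e-12)
  # a constant candidate gets an undefined score, not an error
  it$constant_ci <- 1
  sc2 <- score_predictors(it, candidates = c("constant_ci", "green"))
  expect_true(is.na(sc2$fi[sc2$ci_name == "constant_ci"]))
  expect_error(score_predictors(it, candidates = "nope"), "missing")
})
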