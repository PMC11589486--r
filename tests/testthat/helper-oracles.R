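# Independent brute-force oracles, reimplemented from first principles
# (no calls into the package's hysteresis/ranking code paths).

# Hysteresis index by explicit rotation + trapezoid on the raw points.
brute_hyst <- function(ci, oil) {
  k <- which(ci == max(ci))[1]
  n <- length(ci)
  x <- ci
  if (k < n) x[(k + 1):n] <- ci[k] + (ci[k] - ci[(k + 1):n])
  ord <- order(x)
  xs <- x[ord]; ys <- oil[ord]
  xu <- unique(xs)
  yu <- vapply(xu, function(v) mean(ys[xs == v]), numeric(1))
  area <- function(lo, hi) {
    if (hi <= lo) return(0)
    grid <- sort(unique(c(lo, hi, xu[xu > lo & xu < hi])))
    yg <- pmax(stats::approx(xu, yu, xout = grid, rule = 2)$y, 0)
    sum(diff(grid) * (yg[-length(yg)] + yg[-1]) / 2)
  }
  lo <- min(x)
  hi <- if (k < n) max(x[(k + 1):n]) else ci[k]
  tot <- area(lo, hi)
  hy <- area(ci[k], hi)
  (2 * hy - tot) / tot
}

# Trapezoid integral on the raw sorted points over their full span.
brute_trapz_points <- function(x, y) {
  ord <- order(x)
  xs <- x[ord]; ys <- pmax(y[ord], 0)
  sum(diff(xs) * (ys[-length(ys)] + ys[-1]) / 2)
}

# GPI by naive triple loop on a long normalized table.
brute_gpi <- function(norm_long, model) {
  alpha <- c(r2 = -1, rmse = 1, mae = 1)
  g <- 0
  for (mc in unique(norm_long$metric)) {
    obar <- stats::median(norm_long$norm[norm_long$metric == mc])
    rows <- norm_long[norm_long$model_id == model & norm_long$metric == mc, ]
    for (j in seq_len(nrow(rows)))
      g <- g + alpha[[mc]] * (obar - rows$norm[j])
  }
  g
}

# 2 models x 2 iterations metric table with hand-picked values.
toy_metrics <- function() {
  data.frame(
    model_id = rep(c("A", "B"), each = 2),
    iteration = rep(1:2, 2),
    r2  = c(0.9, 0.8, 0.5, 0.4),
    rmse = c(1.0, 1.2, 2.0, 2.4),
    mae = c(0.8, 0.9, 1.6, 1.8))
}

# A tiny fast cultivar for tests.
tiny_params <- function(name = "toy", ...) {
  defaults <- list(name = name, n_dates = 8, replicates = 2,
                   noise_oil = 0.3, noise_band = 2,
                   fruit_count_start = 6, fruit_count_end = 4)
  args <- utils::modifyList(defaults, list(...))
  do.call(cultivar_params, args)
}
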