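#' Time-ordered oil-vs-index trajectory
#'
#' @param ci Numeric index (or band) values in time order.
#' @param oil Oil concentrations (%FW), same length, same order.
#' @param ci_name,cultivar Optional labels.
#' @return Object of class `trajectory`. NA cells in `ci` are removed
#'   pairwise (with their oil partner) before construction.
#' @export
trajectory <- function(ci, oil, ci_name = NA_character_,
                       cultivar = NA_character_) {
  keep <- is.finite(ci) & is.finite(oil)
  ci <- as.numeric(ci[keep]); oil <- as.numeric(oil[keep])
  if (length(ci) < 4)
    stop("trajectory error: need >= 4 finite (ci, oil) pairs", call. = FALSE)
  structure(list(ci = ci, oil = oil, ci_name = ci_name, cultivar = cultivar),
            class = "trajectory")
}

#' Turning point of a trajectory
#'
#' Time-order position of the maximum index value (CI_max); ties are
#' broken by the FIRST occurrence so the downward arm is maximal and
#' deterministic. Points after this position form the downward
#' (hysteretic) arm.
#'
#' @param traj A [trajectory()].
#' @return Integer position (1-based).
#' @export
turning_point <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  which.max(traj$ci)
}

#' Rotate downward-arm index values about CI_max
#'
#' Reflects each post-maximum index value about the maximum:
#' `ci_syn = ci_max + (ci_max - ci_orig)`. Distances to `ci_max` are
#' preserved and the map is an involution.
#'
#' @param ci_values Downward-arm index values; each must be <= `ci_max`.
#' @param ci_max The maximum index value of the trajectory.
#' @return Rotated (synthetic) index values.
#' @export
rotate_arm <- function(ci_values, ci_max) {
  if (any(ci_values > ci_max))
    stop("rotate_arm: values must not exceed ci_max", call. = FALSE)
  ci_max + (ci_max - ci_values)
}

#' Fit a curve through (x, y) points and integrate it
#'
#' Sorts by x (averaging y at duplicate x), fits a cubic smoothing
#' spline (GCV-chosen smoothness by default), clamps the fitted curve at
#' 0, and integrates by composite trapezoid on a 513-point grid over
#' `[lo, hi]`. With fewer than 4 distinct x values, or with
#' `method = "trapezoid"`, the curve is the piecewise-linear
#' interpolant of the points instead (the brute-force reference route).
#'
#' @param x,y Numeric vectors.
#' @param lo,hi Integration bounds (within the data span; `lo == hi`
#'   returns 0).
#' @param smoothing NULL for GCV, or equivalent degrees of freedom
#'   passed to [stats::smooth.spline()].
#' @param method `"spline"` (default) or `"trapezoid"`.
#' @return Non-negative area.
#' @export
fit_and_integrate <- function(x, y, lo, hi, smoothing = NULL,
                              method = c("spline", "trapezoid")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (lo > hi) stop("fit_and_integrate: lo > hi", call. = FALSE)
  if (lo == hi) return(0)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  xu <- unique(x)
  yu <- vapply(xu, function(v) mean(y[x == v]), numeric(1))
  grid <- seq(lo, hi, length.out = 513)
  if (method == "spline" && length(xu) < 4)
    message("fit_and_integrate: < 4 distinct x; falling back to ",
            "piecewise-linear trapezoid")
  yhat <- NULL
  if (method == "spline" && length(xu) >= 4) {
    # GCV can fail on degenerate spacing (e.g. saturated trajectories with
    # near-duplicate x); those cases drop to the piecewise-linear route
    sm <- tryCatch(suppressWarnings(
      if (is.null(smoothing)) stats::smooth.spline(xu, yu)
      else stats::smooth.spline(xu, yu, df = smoothing)),
      error = function(e) NULL)
    if (!is.null(sm)) yhat <- stats::predict(sm, grid)$y
  }
  if (is.null(yhat)) yhat <- stats::approx(xu, yu, xout = grid, rule = 2)$y
  pracma::trapz(grid, pmax(yhat, 0))
}

#' Hysteresis index of an oil-vs-index trajectory
#'
#' Decomposes the looped oil-vs-CI relation: detects the turning point
#' (first maximum of CI), rotates the downward-arm abscissae about
#' CI_max ([rotate_arm()]) so the loop becomes single-valued, fits one
#' curve through all points, and computes
#' `hyst = (hyst_area - (tot_area - hyst_area)) / tot_area`, where
#' `tot_area` is the area under the curve over the full (rotated) span
#' and `hyst_area` the portion over the rotated arm
#' (`[ci_max, max(ci_syn)]`). An empty downward arm gives `hyst = -1`
#' exactly (no hysteresis); a loop spanning the whole season approaches
#' +1. The clamped-at-0 fit guarantees `0 <= hyst_area <= tot_area`,
#' hence `hyst` in \[-1, 1\].
#'
#' @param traj A [trajectory()].
#' @param smoothing,method Passed to [fit_and_integrate()];
#'   `method = "trapezoid"` is the spline-free reference route.
#' @return Object of class `hyst_decomposition`: `turn_index`, `ci_max`,
#'   `ci_syn`, `x` (fitted abscissae), `hyst_area`, `tot_area`, `hyst`.
#' @export
hyst_index <- function(traj, smoothing = NULL,
                       method = c("spline", "trapezoid")) {
  method <- match.arg(method)
  stopifnot(inherits(traj, "trajectory"))
  k <- turning_point(traj)
  n <- length(traj$ci)
  ci_max <- traj$ci[k]
  x <- traj$ci
  ci_syn <- numeric(0)
  if (k < n) {
    ci_syn <- rotate_arm(traj$ci[(k + 1):n], ci_max)
    x[(k + 1):n] <- ci_syn
  }
  lo <- min(x)
  hi <- if (length(ci_syn)) max(ci_syn) else ci_max
  tot_area <- fit_and_integrate(x, traj$oil, lo, hi,
                                smoothing = smoothing, method = method)
  if (!is.finite(tot_area) || tot_area <= 0)
    stop("hyst_index: degenerate trajectory (zero total area)", call. = FALSE)
  hyst_area <- if (length(ci_syn) && hi > ci_max)
    fit_and_integrate(x, traj$oil, ci_max, hi,
                      smoothing = smoothing, method = method)
  else 0
  hyst <- (2 * hyst_area - tot_area) / tot_area
  structure(list(turn_index = k, ci_max = ci_max, ci_syn = ci_syn, x = x,
                 hyst_area = hyst_area, tot_area = tot_area,
                 hyst = min(1, max(-1, hyst)),
                 ci_name = traj$ci_name, cultivar = traj$cultivar),
            class = "hyst_decomposition")
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties get the mean rank).
#' Returns `NA` for a constant vector (undefined marker).
#'
#' @param x,y Numeric vectors, length >= 3.
#' @return rho in \[-1, 1\], or NA.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Fitness Index of a candidate predictor
#'
#' `FI = |Hyst| + |rho|`, in \[0, 2\]. High values flag candidates that
#' are both monotone with oil (|rho| near 1) and either hysteresis-free
#' (Hyst = -1) or fully hysteretic (Hyst near 1).
#'
#' @param hyst Hysteresis index in \[-1, 1\].
#' @param rho Spearman coefficient in \[-1, 1\].
#' @return FI, or NA if either input is NA.
#' @export
fitness_index <- function(hyst, rho) {
  if (any(abs(hyst) > 1, na.rm = TRUE) || any(abs(rho) > 1, na.rm = TRUE))
    stop("fitness_index: inputs must lie in [-1, 1]", call. = FALSE)
  abs(hyst) + abs(rho)
}

#' Score candidate predictors of one cultivar
#'
#' For every candidate column, builds the pooled seasonal oil-vs-value
#' trajectory (all replicates, time order as given), computes the
#' hysteresis index, Spearman's rho and the Fitness Index.
#'
#' @param index_table Rows of one cultivar in time order, containing the
#'   candidate columns and `oil`.
#' @param candidates Candidate column names; by default the 35 registry
#'   indexes plus the three raw bands.
#' @param smoothing,method Passed to [hyst_index()].
#' @return data.frame (`selection_record`): `ci_name`, `hyst`, `rho`,
#'   `fi`, `selected` (all FALSE; see [select_predictors()]).
#' @export
score_predictors <- function(index_table,
                             candidates = c(names(ci_registry()),
                                            "red", "green", "blue"),
                             smoothing = NULL,
                             method = c("spline", "trapezoid")) {
  method <- match.arg(method)
  miss <- setdiff(candidates, names(index_table))
  if (length(miss))
    stop(sprintf("candidate column(s) missing: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  rows <- lapply(candidates, function(nm) {
    ci <- index_table[[nm]]; oil <- index_table$oil
    ok <- is.finite(ci) & is.finite(oil)
    h <- r <- NA_real_
    if (sum(ok) >= 4 && stats::sd(ci[ok]) > 0) {
      tr <- trajectory(ci, oil, ci_name = nm)
      h <- tryCatch(hyst_index(tr, smoothing = smoothing, method = method)$hyst,
                    error = function(e) NA_real_)
      r <- spearman_rho(ci[ok], oil[ok])
    }
    data.frame(ci_name = nm, hyst = h, rho = r,
               fi = if (is.na(h) || is.na(r)) NA_real_ else fitness_index(h, r))
  })
  out <- do.call(rbind, rows)
  out$selected <- FALSE
  rownames(out) <- NULL
  out
}

#' Select top-quintile predictors by Fitness Index
#'
#' Marks as selected every record whose FI is at or above the empirical
#' `1 - quintile` quantile (linear-interpolation, type 7) of the finite
#' FIs; ties at the threshold are all included. Undefined FIs are
#' excluded from both the pool and the threshold.
#'
#' @param records Output of [score_predictors()].
#' @param quintile Selected fraction (default 0.2, the top quintile).
#' @return `records` with `selected` filled; the threshold is attached
#'   as attribute `"fi_threshold"`.
#' @export
select_predictors <- function(records, quintile = 0.2) {
  fi <- records$fi
  finite <- is.finite(fi)
  if (sum(finite) < 5)
    stop("selection error: need >= 5 records with finite FI", call. = FALSE)
  thr <- stats::quantile(fi[finite], probs = 1 - quintile, type = 7,
                         names = FALSE)
  records$selected <- finite & fi >= thr
  attr(records, "fi_threshold") <- thr
  records
}
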