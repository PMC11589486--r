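#' Min-max normalize model performance metrics
#'
#' Reshapes a metric table to long form and normalizes each metric to
#' \[0, 1\] by min-max over ALL models and iterations (within a cultivar,
#' if a `cultivar` column is present). A zero-range metric normalizes to
#' all 0 with a warning (degenerate comparison).
#'
#' @param metrics data.frame with `model_id`, `iteration` and the metric
#'   columns; optionally `cultivar`.
#' @param metric_cols Metric column names (default `r2`, `rmse`, `mae`).
#' @return Long data.frame: (`cultivar`,) `model_id`, `iteration`,
#'   `metric`, `raw`, `norm`.
#' @export
normalize_metrics <- function(metrics, metric_cols = c("r2", "rmse", "mae")) {
  stopifnot(all(c("model_id", "iteration", metric_cols) %in% names(metrics)))
  has_cult <- "cultivar" %in% names(metrics)
  long <- do.call(rbind, lapply(metric_cols, function(mc) {
    data.frame(
      cultivar = if (has_cult) metrics$cultivar else "all",
      model_id = metrics$model_id, iteration = metrics$iteration,
      metric = mc, raw = metrics[[mc]])
  }))
  long$norm <- NA_real_
  for (cu in unique(long$cultivar)) for (mc in metric_cols) {
    i <- long$cultivar == cu & long$metric == mc
    x <- long$raw[i]
    rng <- range(x, finite = TRUE)
    if (!all(is.finite(rng)) || diff(rng) == 0) {
      warning(sprintf("zero range for metric '%s' (%s); normalized to 0", mc, cu))
      long$norm[i] <- 0
    } else {
      long$norm[i] <- (x - rng[1]) / diff(rng)
    }
  }
  long
}

#' Global Performance Indicator per model
#'
#' `GPI_m = sum_i sum_j alpha_i * (Obar_i - O_ij)` over the metrics
#' i in (R-squared, RMSE, MAE) and the iterations j, with `alpha = -1`
#' for R-squared and `+1` for RMSE and MAE, on the \[0, 1\] normalized
#' values `O`. `Obar_i` is the median of metric i pooled over all
#' models and iterations within the cultivar (the default; the
#' per-model median variant, which centres every model near 0, is
#' available for sensitivity analysis). Higher GPI = more accurate
#' model.
#'
#' @param norm_long Output of [normalize_metrics()].
#' @param median_scope `"pooled"` (default) or `"per_model"`.
#' @return data.frame: (`cultivar`,) `model_id`, `gpi`.
#' @export
gpi <- function(norm_long, median_scope = c("pooled", "per_model")) {
  median_scope <- match.arg(median_scope)
  stopifnot(all(c("cultivar", "model_id", "iteration", "metric", "norm") %in%
                  names(norm_long)))
  cnt <- stats::aggregate(iteration ~ cultivar + model_id + metric,
                          norm_long, length)
  if (length(unique(cnt$iteration)) != 1)
    stop("completeness error: models have unequal (iteration, metric) cells",
         call. = FALSE)
  alpha <- c(r2 = -1, rmse = 1, mae = 1)
  if (!all(norm_long$metric %in% names(alpha)))
    alpha <- stats::setNames(
      ifelse(unique(norm_long$metric) == "r2", -1, 1),
      unique(norm_long$metric))
  out <- list()
  for (cu in unique(norm_long$cultivar)) {
    sub <- norm_long[norm_long$cultivar == cu, ]
    for (m in unique(sub$model_id)) {
      g <- 0
      for (mc in unique(sub$metric)) {
        o_model <- sub$norm[sub$model_id == m & sub$metric == mc]
        obar <- if (median_scope == "pooled")
          stats::median(sub$norm[sub$metric == mc])
        else stats::median(o_model)
        g <- g + sum(alpha[[mc]] * (obar - o_model))
      }
      out[[length(out) + 1L]] <- data.frame(cultivar = cu, model_id = m,
                                            gpi = g)
    }
  }
  do.call(rbind, out)
}

#' Rank models by GPI
#'
#' Descending GPI; tied GPIs share the minimum rank. Optionally flags
#' the model built from the candidate with the highest Fitness Index.
#'
#' @param gpis Output of [gpi()] (one cultivar, or with a `cultivar`
#'   column ranked within cultivar).
#' @param max_fi_model Optional `model_id` (or named character vector by
#'   cultivar) to flag as `is_max_fi`.
#' @return `gpis` with `rank` and `is_max_fi`, ordered by
#'   (`cultivar`,) `rank`.
#' @export
rank_models <- function(gpis, max_fi_model = NULL) {
  if (nrow(gpis) < 2) stop("rank_models: need >= 2 models", call. = FALSE)
  if (!"cultivar" %in% names(gpis)) gpis$cultivar <- "all"
  out <- do.call(rbind, lapply(split(gpis, gpis$cultivar), function(sub) {
    sub$rank <- rank(-sub$gpi, ties.method = "min")
    flag <- if (is.null(max_fi_model)) NA_character_
            else if (!is.null(names(max_fi_model)))
              max_fi_model[[sub$cultivar[1]]]
            else max_fi_model
    sub$is_max_fi <- !is.na(flag) & sub$model_id == flag
    sub[order(sub$rank), ]
  }))
  rownames(out) <- NULL
  out
}
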