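#' Run the full oil-prediction analysis on synthetic seasons
#'
#' Chains the pipeline for each cultivar: generate a season, compute the
#' 35 colorimetric indexes, score candidates (Hyst, Spearman's rho,
#' Fitness Index), select the top FI quintile, fit the benchmark model
#' suite on a shared 70/30 x 5 split plan, and rank models by the Global
#' Performance Indicator.
#'
#' @param config Named list of [cultivar_params()]; defaults to the six
#'   built-in presets.
#' @param seed Integer master seed (per-cultivar seeds derived from it).
#' @param quintile Selected FI fraction (default 0.2).
#' @param include_bands If TRUE (default) the raw bands enter the
#'   candidate pool alongside the 35 indexes (38 candidates).
#' @param method Curve-fitting route for Hyst (`"spline"` or
#'   `"trapezoid"`).
#' @param vif_threshold,train_fraction,n_iterations Modeling settings.
#' @return Named list per cultivar, each with `season`, `index_table`,
#'   `selection`, `plan`, `metrics`, `residuals`, `ranking`,
#'   `max_fi_model`; plus `summary`, a one-row-per-cultivar data.frame
#'   with the max-FI model and its GPI rank.
#' @export
run_oil_analysis <- function(config = default_cultivar_params(), seed = 1,
                             quintile = 0.2, include_bands = TRUE,
                             method = c("spline", "trapezoid"),
                             vif_threshold = 5, train_fraction = 0.7,
                             n_iterations = 5) {
  method <- match.arg(method)
  registry <- ci_registry()
  candidates <- names(registry)
  if (include_bands) candidates <- c(candidates, "red", "green", "blue")
  out <- list()
  for (i in seq_along(config)) {
    p <- config[[i]]
    season <- generate_season(p, (seed * 131L + i) %% 2147483629L)
    itab <- cbind(season,
                  compute_indexes(season$red, season$green, season$blue,
                                  registry))
    sel <- select_predictors(
      score_predictors(itab, candidates = candidates, method = method),
      quintile = quintile)
    plan <- make_splits(nrow(itab), seed = (seed * 977L + i) %% 2147483629L,
                        train_fraction = train_fraction,
                        n_iterations = n_iterations)
    suite <- run_model_suite(itab, sel$ci_name[sel$selected], plan,
                             vif_threshold = vif_threshold)
    suite$metrics$cultivar <- p$name
    max_fi <- sel$ci_name[which.max(sel$fi)]
    ranking <- rank_models(gpi(normalize_metrics(suite$metrics)),
                           max_fi_model = stats::setNames(max_fi, p$name))
    out[[p$name]] <- list(season = season, index_table = itab,
                          selection = sel, plan = plan,
                          metrics = suite$metrics,
                          residuals = suite$residuals,
                          ranking = ranking, max_fi_model = max_fi)
  }
  out$summary <- do.call(rbind, lapply(out, function(r) {
    rk <- r$ranking
    data.frame(cultivar = rk$cultivar[1], max_fi_model = r$max_fi_model,
               max_fi = max(r$selection$fi, na.rm = TRUE),
               max_fi_rank = rk$rank[rk$is_max_fi][1],
               n_models = nrow(rk),
               best_model = rk$model_id[1], best_gpi = rk$gpi[1])
  }))
  rownames(out$summary) <- NULL
  out
}
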