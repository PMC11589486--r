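#' Benchmark train/test split plan
#'
#' Draws `n_iterations` independent 70/30 splits. The plan is reused for
#' every model of a cultivar so all models see byte-identical benchmark
#' partitions. Training size is `round(train_fraction * n)` with
#' round-half-even on the exact decimal (n = 45 gives 32/13).
#'
#' @param n Sample count (>= 10).
#' @param seed Integer seed.
#' @param train_fraction Training fraction (default 0.7).
#' @param n_iterations Number of repeated splits (default 5).
#' @return Object of class `split_plan`: `n`, `n_train`,
#'   `assignments` (list of logical vectors, TRUE = training).
#' @export
make_splits <- function(n, seed, train_fraction = 0.7, n_iterations = 5) {
  if (n < 10) stop("size error: need n >= 10", call. = FALSE)
  # signif() recovers the exact decimal (0.7*45 is 31.4999... in doubles)
  # so round-half-even applies to 31.5, not to its float neighbour
  n_train <- round(signif(train_fraction * n, 10))
  if (n_train < 2 || n_train >= n)
    stop("size error: degenerate train fraction", call. = FALSE)
  assignments <- with_seed(seed, lapply(seq_len(n_iterations), function(j) {
    tr <- sample.int(n, n_train)
    seq_len(n) %in% tr
  }))
  structure(list(n = n, n_train = n_train, train_fraction = train_fraction,
                 n_iterations = n_iterations, seed = seed,
                 assignments = assignments),
            class = "split_plan")
}

#' Ordinary least squares fit with intercept
#'
#' @param response Numeric response (oil, %FW).
#' @param design data.frame of predictor columns.
#' @return Object of class `linear_fit`: `predictors`, `coefficients`
#'   (intercept first), `p_values`, `vif` (NULL for a single predictor),
#'   `aic` (Gaussian profile form `n*log(RSS/n) + 2k`, k = predictors + 2
#'   counting intercept and variance), and the underlying `lm`.
#' @export
fit_linear <- function(response, design) {
  design <- as.data.frame(design)
  if (nrow(design) <= ncol(design) + 1)
    stop("fit error: need rows > predictors + 1", call. = FALSE)
  if (anyNA(design) || anyNA(response))
    stop("fit error: undefined cells in design or response", call. = FALSE)
  dat <- cbind(.y = response, design)
  fit <- stats::lm(.y ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("rank error: collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  # exact fits (noiseless designs) are legitimate here; silence the
  # "essentially perfect fit" warning and let p-values be NaN
  sm <- suppressWarnings(summary(fit))
  rss <- sum(stats::residuals(fit)^2)
  n <- nrow(design); p <- ncol(design)
  structure(list(
    predictors = names(design),
    coefficients = stats::coef(fit),
    p_values = sm$coefficients[, 4],
    vif = if (p >= 2) vif(design) else NULL,
    aic = n * log(rss / n) + 2 * (p + 2),
    r_squared_train = sm$r.squared,
    lm = fit
  ), class = "linear_fit")
}

#' Variance inflation factors
#'
#' `VIF_p = 1 / (1 - R2_p)` where `R2_p` comes from regressing predictor
#' p on the remaining predictors (with intercept). Perfect collinearity
#' reports `Inf`; a constant column reports `NA`.
#'
#' @param design data.frame with >= 2 predictor columns.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design) {
  design <- as.data.frame(design)
  if (ncol(design) < 2) stop("vif: need >= 2 predictors", call. = FALSE)
  vapply(names(design), function(nm) {
    y <- design[[nm]]
    if (stats::sd(y) == 0) return(NA_real_)
    others <- design[, setdiff(names(design), nm), drop = FALSE]
    r2 <- suppressWarnings(
      summary(stats::lm(y ~ ., data = cbind(y = y, others)))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Iterative VIF-based predictor reduction
#'
#' While any VIF exceeds `threshold` and more than one predictor
#' remains, drops the single predictor with the highest VIF (ties broken
#' by column order).
#'
#' @param design data.frame of predictor columns.
#' @param threshold VIF threshold (default 5).
#' @return Character vector of retained names, with attribute
#'   `"removed"` logging the drop order.
#' @export
reduce_by_vif <- function(design, threshold = 5) {
  design <- as.data.frame(design)
  removed <- character(0)
  while (ncol(design) >= 2) {
    v <- vif(design)
    v[is.na(v)] <- Inf  # constant columns carry no information; drop first
    if (all(v <= threshold)) break
    worst <- names(design)[which.max(v)]
    removed <- c(removed, worst)
    design <- design[, setdiff(names(design), worst), drop = FALSE]
  }
  structure(names(design), removed = removed)
}

#' Evaluate a fitted model on a test set
#'
#' R-squared is the squared Pearson correlation of predicted vs true
#' values (the scatter-plot convention); `r2_holdout` additionally
#' reports `1 - RSS/TSS`. RMSE and MAE are on raw residuals
#' (observed - fitted), in response units.
#'
#' @param fit A [fit_linear()] object.
#' @param newdata data.frame containing the fit's predictors.
#' @param observed Observed response values.
#' @return List: `r2`, `r2_holdout`, `rmse`, `mae`, `residuals`,
#'   `predicted`.
#' @export
evaluate <- function(fit, newdata, observed) {
  stopifnot(inherits(fit, "linear_fit"))
  if (nrow(newdata) == 0) stop("evaluate: empty test set", call. = FALSE)
  pred <- as.numeric(stats::predict(fit$lm, newdata = newdata))
  res <- observed - pred
  r2 <- if (stats::sd(pred) == 0 || stats::sd(observed) == 0) NA_real_
        else stats::cor(pred, observed)^2
  tss <- sum((observed - mean(observed))^2)
  list(r2 = r2,
       r2_holdout = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
       rmse = sqrt(mean(res^2)), mae = mean(abs(res)),
       residuals = res, predicted = pred)
}

#' Fit and evaluate the benchmark model suite of one cultivar
#'
#' Runs, for every split of `plan`: the full RGB model
#' (`oil ~ red + green + blue`), its VIF-reduced version when reduction
#' (computed once on the full dataset) changed the predictor set, and
#' one single-predictor model per selected candidate. Rows with an
#' undefined value of a candidate are deleted pairwise for that model
#' only. Models with too few usable rows are skipped with a log entry.
#'
#' @param index_table One cultivar's rows (time order), with `oil`,
#'   `red`, `green`, `blue` and CI columns.
#' @param selected Names of selected single-predictor candidates.
#' @param plan A [make_splits()] plan with `plan$n == nrow(index_table)`.
#' @param vif_threshold Threshold for [reduce_by_vif()] (default 5).
#' @return List: `metrics` (one row per model x iteration: `model_id`,
#'   `iteration`, `r2`, `r2_holdout`, `rmse`, `mae`, `aic`, `n_train`,
#'   `n_test`, `predictors`, `removed_by_vif`), `residuals` (pooled over
#'   iterations per model), `skipped` (log of skipped fits).
#' @export
run_model_suite <- function(index_table, selected, plan, vif_threshold = 5) {
  stopifnot(inherits(plan, "split_plan"), plan$n == nrow(index_table))
  miss <- setdiff(selected, names(index_table))
  if (length(miss))
    stop(sprintf("selected predictor(s) missing from table: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  rgb <- c("red", "green", "blue")
  retained <- reduce_by_vif(index_table[, rgb], threshold = vif_threshold)
  models <- list(RGB = rgb)
  removed_log <- list(RGB = "")
  if (length(retained) < 3) {
    models$RGB_reduced <- as.character(retained)
    removed_log$RGB_reduced <- paste(attr(retained, "removed"), collapse = ",")
  }
  for (nm in setdiff(selected, names(models)))
    models[[nm]] <- nm
  metrics <- list(); resids <- list(); skipped <- character(0)
  for (mid in names(models)) {
    preds <- models[[mid]]
    ok <- rowSums(!is.finite(as.matrix(index_table[, preds, drop = FALSE]))) == 0 &
      is.finite(index_table$oil)
    for (j in seq_len(plan$n_iterations)) {
      train <- plan$assignments[[j]] & ok
      test <- !plan$assignments[[j]] & ok
      if (sum(train) <= length(preds) + 1 || sum(test) < 2) {
        skipped <- c(skipped, sprintf("%s/iter%d: insufficient rows", mid, j))
        next
      }
      fit <- fit_linear(index_table$oil[train],
                        index_table[train, preds, drop = FALSE])
      ev <- evaluate(fit, index_table[test, preds, drop = FALSE],
                     index_table$oil[test])
      metrics[[length(metrics) + 1L]] <- data.frame(
        model_id = mid, iteration = j, r2 = ev$r2,
        r2_holdout = ev$r2_holdout, rmse = ev$rmse, mae = ev$mae,
        aic = fit$aic, n_train = sum(train), n_test = sum(test),
        predictors = paste(preds, collapse = "+"),
        removed_by_vif = if (!is.null(removed_log[[mid]])) removed_log[[mid]] else "")
      resids[[length(resids) + 1L]] <- data.frame(
        model_id = mid, iteration = j,
        observed = index_table$oil[test], predicted = ev$predicted,
        residual = ev$residuals)
    }
  }
  if (!length(metrics)) stop("run_model_suite: every model was skipped",
                             call. = FALSE)
  list(metrics = do.call(rbind, metrics),
       residuals = do.call(rbind, resids),
       skipped = skipped)
}
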