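#' Registry of the 35 colorimetric indexes
#'
#' Returns the definitions of the 35 RGB-derived colorimetric indexes
#' (CIs) used as oil-prediction candidates. The raw bands Red/Green/Blue
#' are not part of the registry; they are carried separately as
#' candidate predictors. The core set (NGRDI, VARI, GLI, NDGBI, NG, GR,
#' GB, BplusG, mio_stRGB, mio_ndRGB) is fixed; the remaining slots are
#' filled from the standard RGB vegetation-index literature (normalized
#' chromatic coordinates, excess-colour indexes, CIVE, MGRVI, RGBVI,
#' band sums/differences/ratios, TGI, VEG, ...). `mio_stRGB` (= R+G+B)
#' and `mio_ndRGB` (= (R-B)/(R+B)) are documented placeholders for two
#' bespoke indexes whose exact published formulas are external to this
#' package; override them (or any entry) via `override`.
#'
#' @param override Optional named list of expression strings in variables
#'   `R`, `G`, `B` (e.g. `list(mio_stRGB = "(R+G)/(2*B)")`), or the path
#'   of a YAML file of `name: expression` entries. Entries replace
#'   same-named defaults or are appended.
#' @return A named list of index definitions; each has `name`, `fun`
#'   (function of R, G, B), `expr` (source string), `domain_note`.
#' @export
ci_registry <- function(override = NULL) {
  defs <- list(
    NGRDI    = c("(G - R)/(G + R)",            "G + R != 0"),
    VARI     = c("(G - R)/(G + R - B)",        "G + R - B != 0"),
    GLI      = c("(2*G - R - B)/(2*G + R + B)","2*G + R + B != 0"),
    NDGBI    = c("(G - B)/(G + B)",            "G + B != 0"),
    NG       = c("G/(R + G + B)",              "R + G + B != 0"),
    GR       = c("G/R",                        "R != 0"),
    GB       = c("G/B",                        "B != 0"),
    BplusG   = c("B + G",                      "always defined"),
    mio_stRGB = c("R + G + B",                 "always defined (placeholder formula)"),
    mio_ndRGB = c("(R - B)/(R + B)",           "R + B != 0 (placeholder formula)"),
    NR       = c("R/(R + G + B)",              "R + G + B != 0"),
    NB       = c("B/(R + G + B)",              "R + G + B != 0"),
    ExG      = c("2*G - R - B",                "always defined"),
    ExR      = c("1.4*R - G",                  "always defined"),
    ExB      = c("1.4*B - G",                  "always defined"),
    ExGR     = c("3*G - 2.4*R - B",            "always defined"),
    CIVE     = c("0.441*R - 0.811*G + 0.385*B + 18.78745", "always defined"),
    MGRVI    = c("(G^2 - R^2)/(G^2 + R^2)",    "G^2 + R^2 != 0"),
    RGBVI    = c("(G^2 - R*B)/(G^2 + R*B)",    "G^2 + R*B != 0"),
    RGRI     = c("R/G",                        "G != 0"),
    RB       = c("R/B",                        "B != 0"),
    BR       = c("B/R",                        "R != 0"),
    RplusG   = c("R + G",                      "always defined"),
    RplusB   = c("R + B",                      "always defined"),
    RminusG  = c("R - G",                      "always defined"),
    RminusB  = c("R - B",                      "always defined"),
    GminusB  = c("G - B",                      "always defined"),
    BminusR  = c("B - R",                      "always defined"),
    INT      = c("(R + G + B)/3",              "always defined"),
    WI       = c("(G - B)/(R - G)",            "R != G"),
    TGI      = c("G - 0.39*R - 0.61*B",        "always defined"),
    VEG      = c("G/(R^0.667 * B^0.333)",      "R > 0 and B > 0"),
    MExG     = c("1.262*G - 0.884*R - 0.311*B","always defined"),
    COM1     = c("(2*G - R - B) + (0.441*R - 0.811*G + 0.385*B + 18.78745) + (3*G - 2.4*R - B) + G/(R^0.667 * B^0.333)", "R > 0 and B > 0"),
    PSRI_rgb = c("(R - G)/B",                  "B != 0")
  )
  if (!is.null(override)) {
    if (is.character(override) && length(override) == 1L)
      override <- yaml::read_yaml(override)
    for (nm in names(override))
      defs[[nm]] <- c(as.character(override[[nm]]), "user-supplied")
  }
  out <- lapply(names(defs), function(nm) {
    expr <- defs[[nm]][1]
    fn <- eval(parse(text = paste0("function(R, G, B) ", expr)))
    list(name = nm, fun = fn, expr = expr, domain_note = defs[[nm]][2])
  })
  names(out) <- names(defs)
  out
}

#' Compute colorimetric indexes from mean R, G, B
#'
#' Evaluates every registry formula at the given band means. A zero (or
#' otherwise invalid) denominator yields `NA` — an explicit undefined
#' marker that downstream steps treat by pairwise deletion of that
#' (sample, CI) cell, never by dropping the whole sample.
#'
#' @param red,green,blue Numeric vectors of mean pixel values (0-255),
#'   recycled to a common length.
#' @param registry Output of [ci_registry()].
#' @return data.frame with one column per index, one row per sample.
#' @export
compute_indexes <- function(red, green, blue, registry = ci_registry()) {
  n <- max(length(red), length(green), length(blue))
  R <- rep_len(as.numeric(red), n)
  G <- rep_len(as.numeric(green), n)
  B <- rep_len(as.numeric(blue), n)
  if (any(c(R, G, B) < 0 | c(R, G, B) > 255, na.rm = TRUE))
    stop("band means must lie in [0, 255]", call. = FALSE)
  cols <- lapply(registry, function(def) {
    v <- suppressWarnings(def$fun(R, G, B))
    v[!is.finite(v)] <- NA_real_
    v
  })
  as.data.frame(cols, optional = TRUE)
}

#' Normalize a band value per unit oil concentration
#'
#' @param band_mean Mean pixel value(s).
#' @param oil Oil concentration(s), %FW; must be > 0.
#' @return `band_mean / oil` (pixels per %FW).
#' @export
normalize_by_oil <- function(band_mean, oil) {
  if (any(oil <= 0)) stop("normalize_by_oil: oil must be > 0", call. = FALSE)
  band_mean / oil
}

#' Join colour samples to oil records and compute the index table
#'
#' Inner join of per-sample mean RGB and oil on a shared key, then
#' computes the 35 colorimetric indexes. Duplicate keys on either side
#' or an empty join are errors; unmatched keys are reported as a
#' warning.
#'
#' @param colors data.frame with the key column plus `red`, `green`,
#'   `blue`.
#' @param oils data.frame with the key column plus `oil`.
#' @param by Key column name (default `"sample_id"`).
#' @param registry Output of [ci_registry()].
#' @return data.frame: key, 35 CI columns, `red`, `green`, `blue`, `oil`
#'   (plus any extra columns of `colors`, e.g. `cultivar`, `date_index`).
#' @export
build_index_table <- function(colors, oils, by = "sample_id",
                              registry = ci_registry()) {
  for (df in list(colors, oils))
    if (!by %in% names(df)) stop(sprintf("key column '%s' missing", by),
                                 call. = FALSE)
  dup_c <- unique(colors[[by]][duplicated(colors[[by]])])
  dup_o <- unique(oils[[by]][duplicated(oils[[by]])])
  if (length(dup_c) || length(dup_o))
    stop(sprintf("join error: duplicated key(s): %s",
                 paste(c(dup_c, dup_o), collapse = ", ")), call. = FALSE)
  merged <- merge(colors, oils[, c(by, "oil")], by = by, sort = FALSE)
  if (nrow(merged) == 0) stop("join error: no matching keys", call. = FALSE)
  unmatched <- c(setdiff(colors[[by]], oils[[by]]),
                 setdiff(oils[[by]], colors[[by]]))
  if (length(unmatched))
    warning(sprintf("unmatched key(s) dropped: %s",
                    paste(unmatched, collapse = ", ")))
  ci <- compute_indexes(merged$red, merged$green, merged$blue, registry)
  out <- cbind(merged[, setdiff(names(merged), c("red", "green", "blue", "oil")),
                      drop = FALSE],
               ci, merged[, c("red", "green", "blue", "oil")])
  rownames(out) <- NULL
  out
}
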