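#' Cultivar parameter set for the seasonal generator
#'
#' Bundles the parameters that shape one cultivar's synthetic season:
#' a logistic (sigmoidal) oil-accumulation curve and, per color band, a
#' double-logistic rise-then-fall mean-pixel trajectory whose decline
#' onset (`band_fall_onset`) controls when the oil-vs-band hysteresis
#' loop opens. Time is an integer `date_index` 0..`n_dates`-1 with a
#' nominal `day_spacing`-day step; calendar dates are cosmetic.
#'
#' @param name Cultivar label.
#' @param oil_min,oil_max Oil concentration (%FW) at season start and the
#'   asymptote. Must satisfy `0 <= oil_min < oil_max <= 30`.
#' @param oil_midpoint Day-of-season at which oil is halfway to the
#'   asymptote.
#' @param oil_rate Logistic rate of oil accumulation (1/day).
#' @param band_base Length-3 numeric (R, G, B), early-season mean pixel
#'   value of each band, in \[0, 255\].
#' @param band_rise_amp,band_fall_amp Length-3 amplitudes (pixel value)
#'   of the rising and falling logistic components per band.
#' @param band_fall_onset Day-of-season at which each band's decline is
#'   centred; length 1 or 3 (recycled). A value beyond the last sampled
#'   day yields a monotone band and hence a hysteresis-free trajectory.
#' @param band_rise_mid,band_rise_rate,band_fall_rate Shape constants of
#'   the double logistic (day, 1/day, 1/day).
#' @param noise_oil,noise_band Gaussian cell noise s.d. (%FW, pixel).
#' @param n_dates Number of sampling dates (>= 4).
#' @param replicates Replicate samples per date (>= 1).
#' @param fruit_count_start,fruit_count_end Fruits per image at the first
#'   and last date (counts shrink as fruit grow).
#' @param day_spacing Nominal days between consecutive dates.
#' @return An object of class `cultivar_params` (a named list).
#' @seealso [generate_season()], [default_cultivar_params()]
#' @export
cultivar_params <- function(name,
                            oil_min = 5, oil_max = 15.5,
                            oil_midpoint = 55, oil_rate = 0.06,
                            band_base = c(95, 110, 60),
                            band_rise_amp = c(60, 50, 30),
                            band_fall_amp = c(80, 70, 30),
                            band_fall_onset = 90,
                            band_rise_mid = 30, band_rise_rate = 0.08,
                            band_fall_rate = 0.15,
                            noise_oil = 0.5, noise_band = 3,
                            n_dates = 15, replicates = 3,
                            fruit_count_start = 120, fruit_count_end = 70,
                            day_spacing = 8) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_field("name", "must be a non-empty string")
  if (!is.numeric(oil_min) || oil_min < 0) stop_field("oil_min", "must be >= 0")
  if (!is.numeric(oil_max) || oil_max > 30) stop_field("oil_max", "must be <= 30")
  if (oil_min >= oil_max) stop_field("oil_min", "must be < oil_max")
  if (n_dates < 4) stop_field("n_dates", "must be >= 4")
  if (replicates < 1) stop_field("replicates", "must be >= 1")
  band_base <- rep_len(as.numeric(band_base), 3L)
  band_rise_amp <- rep_len(as.numeric(band_rise_amp), 3L)
  band_fall_amp <- rep_len(as.numeric(band_fall_amp), 3L)
  band_fall_onset <- rep_len(as.numeric(band_fall_onset), 3L)
  if (any(band_base < 0 | band_base > 255))
    stop_field("band_base", "must lie in [0, 255]")
  if (any(band_rise_amp < 0)) stop_field("band_rise_amp", "must be >= 0")
  if (any(band_fall_amp < 0)) stop_field("band_fall_amp", "must be >= 0")
  if (noise_oil < 0) stop_field("noise_oil", "must be >= 0")
  if (noise_band < 0) stop_field("noise_band", "must be >= 0")
  if (fruit_count_start < 1 || fruit_count_end < 1)
    stop_field("fruit_count_start", "fruit counts must be >= 1")
  structure(list(
    name = name, oil_min = oil_min, oil_max = oil_max,
    oil_midpoint = oil_midpoint, oil_rate = oil_rate,
    band_base = band_base, band_rise_amp = band_rise_amp,
    band_fall_amp = band_fall_amp, band_fall_onset = band_fall_onset,
    band_rise_mid = band_rise_mid, band_rise_rate = band_rise_rate,
    band_fall_rate = band_fall_rate,
    noise_oil = noise_oil, noise_band = noise_band,
    n_dates = as.integer(n_dates), replicates = as.integer(replicates),
    fruit_count_start = as.integer(fruit_count_start),
    fruit_count_end = as.integer(fruit_count_end),
    day_spacing = day_spacing
  ), class = "cultivar_params")
}

#' Default six-cultivar presets
#'
#' Presets for Arbequina, Fasola, Frantoio, Koroneiki, Leccino and
#' Maiatica emulating the qualitative seasonal behaviour reported for
#' these cultivars: oil rising from ~5 %FW to asymptotes of ~15.5 %FW
#' (~20 in Maiatica, ~24 in Frantoio); all bands rise then fall, with
#' the green band declining earlier and more steeply than red (the
#' green-to-dark ripening colour shift, which makes green-contrast
#' indexes quasi-monotone with oil); red/green declines start late
#' October in Arbequina and Fasola but roughly a month earlier in
#' Frantoio and Leccino; no red decline in Koroneiki and Maiatica
#' (hysteresis-free red band); a nearly flat green band in Maiatica
#' (~116-125); a weaker blue decline throughout. Dataset sizes are 45,
#' 40, 40, 45, 45 and 30 rows respectively.
#'
#' @return Named list of [cultivar_params()] objects.
#' @export
default_cultivar_params <- function() {
  list(
    Arbequina = cultivar_params("Arbequina",
      oil_max = 15.5, band_base = c(95, 120, 60),
      band_rise_amp = c(65, 25, 20), band_fall_amp = c(85, 70, 25),
      band_fall_onset = c(90, 76, 95), n_dates = 15, replicates = 3,
      fruit_count_start = 169, fruit_count_end = 97),
    Fasola = cultivar_params("Fasola",
      oil_max = 15.5, oil_midpoint = 60, band_base = c(90, 120, 70),
      band_rise_amp = c(60, 15, 22), band_fall_amp = c(80, 85, 30),
      band_fall_onset = c(95, 55, 105), n_dates = 20, replicates = 2,
      fruit_count_start = 47, fruit_count_end = 37),
    Frantoio = cultivar_params("Frantoio",
      oil_max = 24, band_base = c(100, 130, 65),
      band_rise_amp = c(60, 15, 20), band_fall_amp = c(90, 95, 30),
      band_fall_onset = c(70, 45, 80), n_dates = 20, replicates = 2,
      fruit_count_start = 97, fruit_count_end = 57),
    Koroneiki = cultivar_params("Koroneiki",
      oil_max = 15.5, band_base = c(100, 122, 60),
      band_rise_amp = c(55, 18, 20), band_fall_amp = c(70, 55, 22),
      band_fall_onset = c(500, 80, 95), n_dates = 15, replicates = 3,
      fruit_count_start = 195, fruit_count_end = 111),
    Leccino = cultivar_params("Leccino",
      oil_max = 15.5, band_base = c(95, 115, 65),
      band_rise_amp = c(55, 20, 20), band_fall_amp = c(85, 75, 30),
      band_fall_onset = c(62, 48, 70), n_dates = 15, replicates = 3,
      fruit_count_start = 118, fruit_count_end = 71),
    Maiatica = cultivar_params("Maiatica",
      oil_max = 20, band_base = c(105, 116, 70),
      band_rise_amp = c(50, 9, 20), band_fall_amp = c(60, 12, 35),
      band_fall_onset = c(500, 105, 30), n_dates = 10, replicates = 3,
      fruit_count_start = 82, fruit_count_end = 52)
  )
}

#' Noiseless expected trajectories for a cultivar
#'
#' Closed-form expected oil and band values at each sampling date
#' (the generator's mean function, before noise and clipping except the
#' \[0, 255\] band clip).
#'
#' @param params A [cultivar_params()] object.
#' @return data.frame with columns `date_index`, `day`, `oil`, `red`,
#'   `green`, `blue`.
#' @export
expected_season <- function(params) {
  stopifnot(inherits(params, "cultivar_params"))
  t <- params$day_spacing * (seq_len(params$n_dates) - 1L)
  oil <- params$oil_min + (params$oil_max - params$oil_min) *
    stats::plogis(params$oil_rate * (t - params$oil_midpoint))
  bands <- vapply(1:3, function(c) {
    clip(params$band_base[c] +
      params$band_rise_amp[c] *
        stats::plogis(params$band_rise_rate * (t - params$band_rise_mid)) -
      params$band_fall_amp[c] *
        stats::plogis(params$band_fall_rate * (t - params$band_fall_onset[c])),
      0, 255)
  }, numeric(length(t)))
  data.frame(date_index = seq_along(t) - 1L, day = t, oil = oil,
             red = bands[, 1], green = bands[, 2], blue = bands[, 3])
}

#' Generate one cultivar's synthetic season table
#'
#' Draws `n_dates x replicates` rows: oil follows a logistic accumulation
#' curve, each band a double-logistic rise-then-fall trajectory, both
#' with independent Gaussian cell noise. Bands are clipped to \[0, 255\]
#' and oil to a 0.1 %FW floor. Identical `(params, seed)` give an
#' identical table.
#'
#' @param params A [cultivar_params()] object.
#' @param seed Integer seed.
#' @return data.frame (`season_table`) with columns `cultivar`,
#'   `date_index`, `replicate`, `oil`, `red`, `green`, `blue`, ordered
#'   by (`date_index`, `replicate`).
#' @export
generate_season <- function(params, seed) {
  stopifnot(inherits(params, "cultivar_params"))
  if (missing(seed) || !is.numeric(seed))
    stop_field("seed", "an integer seed is required")
  mu <- expected_season(params)
  nd <- params$n_dates
  nr <- params$replicates
  idx <- rep(seq_len(nd), each = nr)
  tab <- with_seed(seed, {
    oil <- pmax(mu$oil[idx] + stats::rnorm(nd * nr, 0, params$noise_oil), 0.1)
    red <- clip(mu$red[idx] + stats::rnorm(nd * nr, 0, params$noise_band), 0, 255)
    green <- clip(mu$green[idx] + stats::rnorm(nd * nr, 0, params$noise_band), 0, 255)
    blue <- clip(mu$blue[idx] + stats::rnorm(nd * nr, 0, params$noise_band), 0, 255)
    data.frame(
      cultivar = params$name,
      date_index = mu$date_index[idx],
      replicate = rep(seq_len(nr), times = nd),
      oil = oil, red = red, green = green, blue = blue
    )
  })
  tab <- tab[order(tab$date_index, tab$replicate), ]
  rownames(tab) <- NULL
  class(tab) <- c("season_table", "data.frame")
  tab
}

#' Render a synthetic multi-fruit image fixture
#'
#' Draws `n_fruits` non-overlapping ellipses ("fruit") on a uniform blue
#' background, with per-fruit colour jitter re-centred so the exact
#' foreground mean matches `target_rgb` within +/-0.5 per channel after
#' 8-bit quantization. Placement uses a jittered grid, which makes the
#' non-overlap guarantee and the capacity check deterministic.
#'
#' @param target_rgb Numeric length-3 target mean (R, G, B) in \[0, 255\].
#' @param n_fruits Number of fruit ellipses (>= 1).
#' @param seed Integer seed.
#' @param width,height Canvas size in pixels.
#' @param fruit_radius Semi-major axis of each ellipse (px).
#' @param jitter_sd Per-fruit Gaussian colour jitter s.d.
#' @param background Background RGB; must be blue-dominant so that
#'   [segment_background()]'s rule recovers the mask.
#' @return A list of class `image_fixture`: `image` (H x W x 3 integer
#'   array, 0-255), `true_mask` (H x W logical), `true_mean_rgb` (the
#'   exact foreground mean of the stored image), `target_rgb`.
#' @export
render_sample_image <- function(target_rgb, n_fruits, seed,
                                width = 640, height = 480,
                                fruit_radius = 12, jitter_sd = 6,
                                background = c(40, 70, 200)) {
  target_rgb <- as.numeric(target_rgb)
  if (length(target_rgb) != 3 || any(target_rgb < 0 | target_rgb > 255))
    stop_field("target_rgb", "must be 3 values in [0, 255]")
  if (n_fruits < 1) stop_field("n_fruits", "must be >= 1")
  d <- 2 * fruit_radius + 2
  nx <- floor(width / d); ny <- floor(height / d)
  if (n_fruits > nx * ny)
    stop(sprintf(
      "capacity error: cannot place %d fruits of radius %d on a %dx%d canvas (max %d)",
      n_fruits, fruit_radius, width, height, nx * ny), call. = FALSE)

  with_seed(seed, {
    cells <- sample.int(nx * ny, n_fruits)
    cx0 <- ((cells - 1L) %% nx) * d + d / 2
    cy0 <- ((cells - 1L) %/% nx) * d + d / 2
    wiggle <- 1
    cx <- cx0 + stats::runif(n_fruits, -wiggle, wiggle)
    cy <- cy0 + stats::runif(n_fruits, -wiggle, wiggle)
    a <- fruit_radius
    b <- round(fruit_radius * stats::runif(n_fruits, 0.7, 0.85))
    jit <- matrix(stats::rnorm(3 * n_fruits, 0, jitter_sd), ncol = 3)

    img <- array(0, dim = c(height, width, 3))
    for (ch in 1:3) img[, , ch] <- background[ch]
    mask <- matrix(FALSE, height, width)
    col_idx <- matrix(0L, height, width)
    for (k in seq_len(n_fruits)) {
      xr <- max(1, floor(cx[k] - a)):min(width, ceiling(cx[k] + a))
      yr <- max(1, floor(cy[k] - b[k])):min(height, ceiling(cy[k] + b[k]))
      gx <- outer(rep(1, length(yr)), xr)
      gy <- outer(yr, rep(1, length(xr)))
      inside <- ((gx - cx[k]) / a)^2 + ((gy - cy[k]) / b[k])^2 <= 1
      mask[yr, xr][inside] <- TRUE
      col_idx[yr, xr][inside] <- k
    }
    nfg <- sum(mask)
    for (ch in 1:3) {
      plane <- img[, , ch]
      vals <- target_rgb[ch] + jit[col_idx[mask], ch]
      # re-centre jittered colours, quantize, then correct the rounding
      # bias iteratively so the integer-image mean hits the target
      vals <- vals + (target_rgb[ch] - mean(vals))
      q <- round(clip(vals, 0, 255))
      for (it in 1:20) {
        err <- target_rgb[ch] - mean(q)
        if (abs(err) <= 0.25) break
        vals <- vals + err
        q <- round(clip(vals, 0, 255))
      }
      if (abs(target_rgb[ch] - mean(q)) > 0.5)
        stop("render error: could not match target mean after quantization",
             call. = FALSE)
      plane[mask] <- q
      img[, , ch] <- plane
    }
    storage.mode(img) <- "integer"
    structure(list(
      image = img, true_mask = mask,
      true_mean_rgb = vapply(1:3, function(ch) mean(img[, , ch][mask]),
                             numeric(1)),
      target_rgb = target_rgb, n_fruits = n_fruits
    ), class = "image_fixture")
  })
}

#' Generate a multi-cultivar synthetic dataset
#'
#' Runs [generate_season()] for each cultivar in `config`, optionally
#' rendering one image fixture per (date, replicate) row whose foreground
#' mean matches that row's band values.
#'
#' @param config List of [cultivar_params()] (e.g.
#'   [default_cultivar_params()]). Cultivar names must be unique.
#' @param seed Integer seed; per-cultivar seeds are derived from it.
#' @param with_images If TRUE also render image fixtures (slow for the
#'   full-size default canvas; tune `...`).
#' @param ... Passed to [render_sample_image()] (canvas size etc.).
#' @return List with `seasons` (named list of season tables) and, when
#'   `with_images`, `fixtures` (named list of lists of `image_fixture`).
#' @export
generate_dataset <- function(config, seed, with_images = FALSE, ...) {
  if (length(config) < 1) stop_field("config", "needs at least one cultivar")
  nms <- vapply(config, function(p) p$name, character(1))
  if (anyDuplicated(nms))
    stop(sprintf("config error: duplicate cultivar name(s): %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")),
         call. = FALSE)
  seasons <- list(); fixtures <- list()
  for (i in seq_along(config)) {
    p <- config[[i]]
    sub_seed <- (seed * 131L + i) %% 2147483629L
    tab <- generate_season(p, sub_seed)
    seasons[[p$name]] <- tab
    if (isTRUE(with_images)) {
      counts <- round(seq(p$fruit_count_start, p$fruit_count_end,
                          length.out = p$n_dates))
      fx <- vector("list", nrow(tab))
      for (r in seq_len(nrow(tab))) {
        fx[[r]] <- render_sample_image(
          target_rgb = as.numeric(tab[r, c("red", "green", "blue")]),
          n_fruits = counts[tab$date_index[r] + 1L],
          seed = (sub_seed + r) %% 2147483629L, ...)
      }
      names(fx) <- sprintf("%s_d%02d_r%d", p$name, tab$date_index,
                           tab$replicate)
      fixtures[[p$name]] <- fx
    }
  }
  out <- list(seasons = seasons)
  if (isTRUE(with_images)) out$fixtures <- fixtures
  out
}

#' Read cultivar configuration from YAML
#'
#' One YAML block per cultivar, mirroring [cultivar_params()] field
#' names; unspecified fields take the function defaults.
#'
#' @param path YAML file path.
#' @return Named list of `cultivar_params`.
#' @export
read_cultivar_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(names(cfg), function(nm) {
    do.call(cultivar_params, c(list(name = nm), cfg[[nm]]))
  }) |> stats::setNames(names(cfg))
}

#' Write / read a season table as CSV
#'
#' Plain-CSV persistence with full double precision, so a table written
#' and re-read is value-identical.
#'
#' @param tab A season table ([generate_season()]).
#' @param path CSV file path.
#' @return `path` invisibly (write); the season table (read).
#' @export
write_season_csv <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_season_csv
#' @export
read_season_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cultivar", "date_index", "replicate", "oil", "red", "green", "blue")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("season CSV missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  class(tab) <- c("season_table", "data.frame")
  tab
}

#' Write an image fixture to PNG files
#'
#' @param fixture An `image_fixture`.
#' @param image_path Output PNG path for the image.
#' @param mask_path Optional output PNG path for the ground-truth mask.
#' @return `image_path`, invisibly.
#' @export
write_fixture_png <- function(fixture, image_path, mask_path = NULL) {
  stopifnot(inherits(fixture, "image_fixture"))
  png::writePNG(fixture$image / 255, image_path)
  if (!is.null(mask_path))
    png::writePNG(fixture$true_mask * 1, mask_path)
  invisible(image_path)
}
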