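#' Read an RGB image as a 0-255 array
#'
#' @param path PNG file path (JPEG would require the jpeg package).
#' @return H x W x 3 numeric array with values in \[0, 255\].
#' @export
read_rgb_image <- function(path) {
  if (grepl("\\.jpe?g$", path, ignore.case = TRUE))
    stop("JPEG input requires the 'jpeg' package; convert to PNG", call. = FALSE)
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
  px <- px[, , 1:3, drop = FALSE] * 255
  px
}

#' Segment fruit foreground from a blue background
#'
#' A pixel is background iff its blue value exceeds both red and green by
#' more than `margin` (blue dominance). Connected foreground components
#' smaller than `min_object_px` pixels (8-connectivity) are removed as
#' speckle.
#'
#' @param image H x W x 3 array, values 0-255.
#' @param margin Additive blue-dominance margin (default 20).
#' @param min_object_px Minimum surviving component size in pixels.
#' @return H x W logical mask (TRUE = fruit).
#' @export
segment_background <- function(image, margin = 20, min_object_px = 50) {
  if (length(dim(image)) != 3L || dim(image)[3] < 3)
    stop("image must be an H x W x 3 array", call. = FALSE)
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  fg <- !(b > r + margin & b > g + margin)
  if (any(fg)) {
    lab <- EBImage::bwlabel(fg)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_object_px)
    fg <- matrix(lab %in% keep, nrow = nrow(fg))
  }
  if (!any(fg))
    stop("segmentation error: no foreground object after filtering",
         call. = FALSE)
  fg
}

#' Mean R, G, B over a segmentation mask
#'
#' Arithmetic mean of each channel over masked pixels, in real
#' arithmetic (no 8-bit rounding of the result).
#'
#' @param image H x W x 3 array, values 0-255.
#' @param mask H x W logical mask; must contain at least one TRUE pixel.
#' @param source_id Optional sample label.
#' @return data.frame (one row) with `source_id`, `red`, `green`,
#'   `blue`, `n_foreground`.
#' @export
mean_rgb <- function(image, mask, source_id = NA_character_) {
  if (!any(mask)) stop("mean_rgb: empty mask", call. = FALSE)
  if (!all(dim(mask) == dim(image)[1:2]))
    stop("mean_rgb: mask and image dimensions differ", call. = FALSE)
  m <- vapply(1:3, function(ch) mean(image[, , ch][mask]), numeric(1))
  data.frame(source_id = source_id, red = m[1], green = m[2], blue = m[3],
             n_foreground = sum(mask))
}

#' Extract mean RGB from a batch of image files
#'
#' Reads each file, segments the background and measures mean R, G, B.
#' Per-file failures are recorded in the `error` column rather than
#' dropped; row order follows the input order.
#'
#' @param paths Character vector of PNG paths.
#' @param margin,min_object_px Passed to [segment_background()].
#' @return data.frame with `source_id`, `red`, `green`, `blue`,
#'   `n_foreground`, `error` (NA on success).
#' @export
process_image_batch <- function(paths, margin = 20, min_object_px = 50) {
  if (length(paths) == 0) stop("no input files", call. = FALSE)
  rows <- lapply(paths, function(p) {
    res <- tryCatch({
      img <- read_rgb_image(p)
      mask <- segment_background(img, margin = margin,
                                 min_object_px = min_object_px)
      out <- mean_rgb(img, mask, source_id = basename(p))
      out$error <- NA_character_
      out
    }, error = function(e) {
      data.frame(source_id = basename(p), red = NA_real_, green = NA_real_,
                 blue = NA_real_, n_foreground = NA_integer_,
                 error = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (all(!is.na(out$error)))
    stop("batch error: every input file failed", call. = FALSE)
  out
}
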