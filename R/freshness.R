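#' RGB ranges describing a fresh powder
#'
#' The freshness index counts pixels whose red, green and blue intensities
#' all lie inside per-channel intervals calibrated on a fresh sample. The
#' defaults are the intervals established for fresh instant coffee powder:
#' R 70–190, G 55–170, B 10–90 (8-bit intensities). Bounds are inclusive.
#'
#' @param r_min,r_max,g_min,g_max,b_min,b_max Integer channel bounds
#'   in \[0, 255\], each min <= max.
#' @return Object of class `rgb_ranges`.
#' @export
rgb_ranges <- function(r_min = 70, r_max = 190, g_min = 55, g_max = 170,
                       b_min = 10, b_max = 90) {
  v <- c(r_min, r_max, g_min, g_max, b_min, b_max)
  if (any(v < 0) || any(v > 255) || any(v != round(v)))
    stop("channel bounds must be integers in [0, 255]", call. = FALSE)
  if (r_min > r_max || g_min > g_max || b_min > b_max)
    stop("each channel minimum must not exceed its maximum", call. = FALSE)
  structure(list(r_min = r_min, r_max = r_max, g_min = g_min, g_max = g_max,
                 b_min = b_min, b_max = b_max), class = "rgb_ranges")
}

#' @export
print.rgb_ranges <- function(x, ...) {
  cat(sprintf("RGB fresh ranges: R %d-%d, G %d-%d, B %d-%d\n",
              x$r_min, x$r_max, x$g_min, x$g_max, x$b_min, x$b_max))
  invisible(x)
}

#' Binary fresh-pixel mask of a powder image
#'
#' A pixel is "fresh" (white, TRUE) when all three of its channel intensities
#' lie inclusively within the calibrated ranges; otherwise black.
#'
#' @param image Integer array `h x w x 3` with 8-bit values in \[0, 255\]
#'   (as returned by [read_image_rgb()]).
#' @param ranges An [rgb_ranges()] object.
#' @return Logical matrix `h x w`; TRUE marks in-range (fresh) pixels.
#' @export
fresh_mask <- function(image, ranges = rgb_ranges()) {
  stopifnot(inherits(ranges, "rgb_ranges"))
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be a 3-channel (h x w x 3) RGB array; ",
         "grayscale or alpha-only input is not supported", call. = FALSE)
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  r >= ranges$r_min & r <= ranges$r_max &
    g >= ranges$g_min & g <= ranges$g_max &
    b >= ranges$b_min & b <= ranges$b_max
}

#' Freshness index of a powder image
#'
#' The percentage ratio between the in-range (white) pixel count of an image
#' and the in-range count of the time-zero baseline image, so the baseline
#' itself scores 100. Values above 100 are reported as-is, not clamped.
#'
#' @param image RGB array as in [fresh_mask()].
#' @param ranges An [rgb_ranges()] object.
#' @param baseline_in_range In-range pixel count of the baseline image, > 0.
#' @return List of class `freshness_result`: `n_in_range`, `n_total`,
#'   `baseline_in_range`, `index` (percent).
#' @export
freshness_index <- function(image, ranges = rgb_ranges(), baseline_in_range) {
  if (!is.numeric(baseline_in_range) || baseline_in_range <= 0)
    stop("'baseline_in_range' must be a positive pixel count", call. = FALSE)
  m <- fresh_mask(image, ranges)
  n_in <- sum(m)
  structure(list(n_in_range = n_in, n_total = length(m),
                 baseline_in_range = baseline_in_range,
                 index = 100 * n_in / baseline_in_range,
                 ranges = ranges),
            class = "freshness_result")
}

#' @export
print.freshness_result <- function(x, ...) {
  cat(sprintf("freshness index: %.1f%% (%d of %d pixels in range, baseline %d)\n",
              x$index, x$n_in_range, x$n_total, x$baseline_in_range))
  invisible(x)
}

#' Calibrate fresh RGB ranges from a reference image
#'
#' Stand-in for manual screening of a fresh sample: per channel the symmetric
#' quantile interval \[(1-coverage)/2, 1-(1-coverage)/2\] is taken and rounded
#' outward to integers. With `coverage = 1` this is the per-channel min/max.
#'
#' @param reference RGB array of a fresh sample.
#' @param coverage Fraction of each channel's pixels the interval must cover
#'   (default 0.99).
#' @return An [rgb_ranges()] object.
#' @export
calibrate_ranges <- function(reference, coverage = 0.99) {
  if (!is.array(reference) || length(dim(reference)) != 3L ||
      dim(reference)[3] != 3L)
    stop("reference must be a 3-channel RGB array", call. = FALSE)
  if (coverage <= 0 || coverage > 1)
    stop("'coverage' must lie in (0, 1]", call. = FALSE)
  q <- c((1 - coverage) / 2, 1 - (1 - coverage) / 2)
  bnd <- function(ch) {
    qs <- stats::quantile(ch, probs = q, names = FALSE, type = 7)
    c(floor(qs[1]), ceiling(qs[2]))
  }
  r <- bnd(reference[, , 1]); g <- bnd(reference[, , 2])
  b <- bnd(reference[, , 3])
  rgb_ranges(r[1], r[2], g[1], g[2], b[1], b[2])
}

#' Pearson correlation between two quality series
#'
#' Product-moment correlation used to relate moisture to colour parameters and
#' to the freshness index. Both series need at least 3 points and nonzero
#' variance; the signed coefficient is returned without interpretation.
#'
#' @param x,y Equal-length numeric vectors.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the series", call. = FALSE)
  stats::cor(x, y)
}

#' Read an image as an 8-bit RGB array
#'
#' PNG and TIFF input; alpha channels are dropped, values are rescaled to
#' integers 0–255. Colour profiles are ignored. Grayscale images are
#' rejected — the freshness index is defined on three channels.
#'
#' @param path Image file (.png, .tif/.tiff).
#' @return Integer array `h x w x 3` in \[0, 255\].
#' @export
read_image_rgb <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "': use PNG or TIFF",
         call. = FALSE)
  )
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("image has fewer than 3 channels; RGB input required", call. = FALSE)
  out <- round(img[, , 1:3] * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write a binary mask as a 1-bit-style PNG
#'
#' @param mask Logical matrix from [fresh_mask()].
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}
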