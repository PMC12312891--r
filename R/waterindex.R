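#' Normalized-difference water index
#'
#' `(green - infrared) / (green + infrared)` per pixel: the NDWI/MNDWI
#' family, positive over open water (which is dark in the near- and
#' shortwave infrared) and negative over vegetation. A zero denominator
#' yields nodata.
#'
#' @param image A [spectral_image()].
#' @param green_band Index or name of the green band.
#' @param nir_or_swir_band Index or name of the infrared band.
#' @return Numeric matrix of index values in [-1, 1] (NA where nodata).
#' @export
water_index <- function(image, green_band = "green", nir_or_swir_band = "nir") {
  stopifnot(inherits(image, "spectral_image"))
  pick <- function(b) {
    if (is.character(b)) b <- match(b, image$band_names)
    if (is.na(b) || b < 1 || b > n_bands(image)) stopf("band out of range")
    as.integer(b)
  }
  d <- dim(image$values)
  band <- function(b) matrix(image$values[, , b], d[1], d[2])
  g <- band(pick(green_band))
  ir <- band(pick(nir_or_swir_band))
  denom <- g + ir
  idx <- (g - ir) / denom
  idx[denom == 0] <- NA_real_
  idx
}

#' Threshold a water index into a lake mask
#'
#' @param index Matrix from [water_index()].
#' @param threshold Finite scalar; the mask is `index >= threshold`.
#' @return List with `mask` (logical matrix, NA where the index is nodata)
#'   and `n_true`.
#' @export
threshold_mask <- function(index, threshold = 0) {
  if (!is_scalar(threshold)) stopf("threshold must be finite")
  mask <- index >= threshold
  list(mask = mask, n_true = sum(mask, na.rm = TRUE))
}
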