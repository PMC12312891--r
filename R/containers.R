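#' Multiband reflectance scene
#'
#' Container for a dated multiband reflectance grid. Values are stored as a
#' rows x cols x bands array of surface reflectance in [0, 1]; masked (nodata)
#' cells carry NA in every band.
#'
#' @param values Numeric array (rows x cols x bands) of reflectance.
#' @param date Acquisition date (ISO-8601 string or Date).
#' @param pixel_size Ground pixel size in metres (> 0).
#' @param band_names Optional character vector naming the bands.
#' @param origin Numeric length-2 upper-left corner (x, y) of the grid in
#'   projected metres; row 0 is the northernmost row.
#'
#' @return An object of class `spectral_image`.
#' @export
spectral_image <- function(values, date, pixel_size = 30,
                           band_names = NULL, origin = c(0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stopf("values must be a rows x cols x bands array")
  }
  if (dim(values)[3] < 2L) stopf("a spectral image needs at least 2 bands")
  if (!is_scalar(pixel_size) || pixel_size <= 0) stopf("pixel_size must be > 0")
  if (is.null(band_names)) band_names <- paste0("b", seq_len(dim(values)[3]))
  bad <- !is.finite(values) & !is.na(values)
  if (any(bad)) stopf("non-finite reflectance values outside the nodata mask")
  structure(
    list(values = values, date = as.character(date),
         pixel_size = pixel_size, band_names = band_names,
         origin = as.numeric(origin)),
    class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<spectral_image> %s  %d x %d, %d bands, %g m pixels, %d nodata cells\n",
              x$date, d[1], d[2], d[3], x$pixel_size, sum(is.na(x$values[, , 1]))))
  invisible(x)
}

#' @export
dim.spectral_image <- function(x) dim(x$values)

n_bands <- function(image) dim(image$values)[3]

# rows*cols x bands matrix of the non-nodata pixels plus their flat indices
image_matrix <- function(image) {
  d <- dim(image$values)
  m <- matrix(image$values, nrow = d[1] * d[2], ncol = d[3])
  keep <- which(stats::complete.cases(m))
  list(x = m[keep, , drop = FALSE], idx = keep, shape = d[1:2])
}

#' Categorical land-cover map
#'
#' A dated categorical grid over the project class codes (0 nodata, 1 water,
#' 2 vegetation, 3 mudflat, 4 sand).
#'
#' @param labels Integer matrix of class codes.
#' @param date Acquisition date (ISO-8601 string or Date).
#' @param pixel_size Ground pixel size in metres.
#' @param origin Upper-left corner (x, y) in projected metres.
#'
#' @return An object of class `class_map`.
#' @export
class_map <- function(labels, date = NA, pixel_size = 30, origin = c(0, 0)) {
  if (!is.matrix(labels)) stopf("labels must be a matrix")
  lab <- labels
  storage.mode(lab) <- "integer"
  known <- lab %in% LAKE_CLASSES | is.na(lab)
  if (!all(known)) {
    stopf("unknown class code(s): %s",
          paste(sort(unique(lab[!known])), collapse = ", "))
  }
  lab[is.na(lab)] <- LAKE_CLASSES[["nodata"]]
  if (!is_scalar(pixel_size) || pixel_size <= 0) stopf("pixel_size must be > 0")
  structure(
    list(labels = lab, date = as.character(date), pixel_size = pixel_size,
         origin = as.numeric(origin)),
    class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  tab <- table(factor(class_name(x$labels), levels = names(LAKE_CLASSES)))
  cat(sprintf("<class_map> %s  %d x %d, %g m pixels\n", x$date,
              nrow(x$labels), ncol(x$labels), x$pixel_size))
  print(tab)
  invisible(x)
}

#' @export
dim.class_map <- function(x) dim(x$labels)

#' Labeled spectral training samples
#'
#' Per-class sample matrices drawn from regions of interest, as used to fit
#' both the maximum-likelihood and the SVM classifiers.
#'
#' @param samples Named list of numeric matrices (n_l x bands), one per class;
#'   names are class names or codes.
#' @param indices Optional named list of source flat pixel indices per class.
#'
#' @return An object of class `training_set`.
#' @export
training_set <- function(samples, indices = NULL) {
  if (!is.list(samples) || length(samples) < 2L) {
    stopf("need samples for at least 2 classes")
  }
  codes <- class_code(names(samples))
  if (anyDuplicated(codes)) stopf("duplicate class in training set")
  m <- unique(vapply(samples, ncol, 1L))
  if (length(m) != 1L) stopf("all classes must share the band count")
  for (i in seq_along(samples)) {
    if (nrow(samples[[i]]) < 2L) {
      stopf("class %s has fewer than 2 samples", names(samples)[i])
    }
    if (!all(is.finite(samples[[i]]))) {
      stopf("non-finite sample values in class %s", names(samples)[i])
    }
  }
  ord <- order(codes)
  structure(
    list(samples = samples[ord], codes = codes[ord],
         indices = if (!is.null(indices)) indices[ord]),
    class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat("<training_set>\n")
  for (i in seq_along(x$samples)) {
    cat(sprintf("  %s (code %d): %d samples x %d bands\n",
                names(x$samples)[i], x$codes[i],
                nrow(x$samples[[i]]), ncol(x$samples[[i]])))
  }
  invisible(x)
}
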