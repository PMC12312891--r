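#' Binarize a class map against a target class
#'
#' @param map A [class_map()].
#' @param target Class name or code.
#' @return Integer 0/1 matrix (NA where nodata).
#' @export
binarize <- function(map, target) {
  stopifnot(inherits(map, "class_map"))
  code <- class_code(target)
  if (code == LAKE_CLASSES[["nodata"]]) stopf("cannot binarize against nodata")
  out <- (map$labels == code) * 1L
  out[map$labels == LAKE_CLASSES[["nodata"]]] <- NA_integer_
  out
}

check_shapes <- function(grids) {
  d <- dim(grids[[1]])
  for (g in grids) if (!identical(dim(g), d)) stopf("grid shapes differ")
  invisible(d)
}

# rows x cols x k array from a list of equal-shape matrices (simplify2array
# degenerates on 1x1 grids, so build it explicitly)
grid_stack <- function(grids) {
  d <- check_shapes(grids)
  array(unlist(grids, use.names = FALSE), c(d, length(grids)))
}

#' Annual presence from one year's indicator grids
#'
#' Majority rule over the year's scenes: a pixel is present (1) when the
#' mean of its indicators is `>= 0.5` (ties count as present). With
#' `rule = "any"`, a single presence in the year suffices.
#'
#' @param grids List of 0/1 indicator matrices from [binarize()].
#' @param rule `"majority"` (default) or `"any"`.
#' @return Integer 0/1 matrix; NA only where every scene is nodata.
#' @export
annual_presence <- function(grids, rule = c("majority", "any")) {
  rule <- match.arg(rule)
  if (!length(grids)) stopf("need at least one indicator grid")
  stack <- grid_stack(grids)
  m <- apply(stack, c(1, 2), mean, na.rm = TRUE)
  out <- if (rule == "majority") (m >= 0.5) * 1L else (m > 0) * 1L
  out[is.nan(m)] <- NA_integer_
  out
}

#' Accumulate annual presence into a frequency raster
#'
#' @param annual_grids List of per-year 0/1 presence matrices (one per
#'   monitored year).
#' @return A `frequency_raster`: integer count matrix in `[0, n_years]`
#'   with attribute `n_years`.
#' @export
accumulate_frequency <- function(annual_grids) {
  if (!length(annual_grids)) stopf("need at least one annual grid")
  stack <- grid_stack(annual_grids)
  counts <- apply(stack, c(1, 2), function(v) {
    if (all(is.na(v))) NA_integer_ else sum(v, na.rm = TRUE)
  })
  structure(counts, n_years = length(annual_grids),
            class = c("frequency_raster", "matrix", "array"))
}

frequency_bin_labels <- list(
  water = c("low", "medium", "relatively high", "high"),
  vegetation = c("low", "relatively low", "medium", "high"))

#' Bin a frequency raster into named frequency classes
#'
#' Half-open bins exactly as the reclassification rule states for a 9-year
#' record: `(0, 3]`, `(3, 5]`, `(5, 7]`, `(7, 9]`; a count of 0 means the
#' class never occurred there and maps to null (NA). The water scheme names
#' the bins low / medium / relatively high / high; the vegetation scheme
#' low / relatively low / medium / high.
#'
#' @param freq A [accumulate_frequency()] raster.
#' @param scheme `"water"` or `"vegetation"`.
#' @param breaks Upper bin edges; default `c(3, 5, 7, n_years)`.
#' @return A `frequency_class_map`: integer matrix of bin indices 1-4 (NA
#'   for null) with attributes `labels` and `breaks`.
#' @export
classify_frequency <- function(freq, scheme = c("water", "vegetation"),
                               breaks = NULL) {
  scheme <- match.arg(scheme)
  ny <- attr(freq, "n_years")
  if (is.null(breaks)) breaks <- c(3, 5, 7, max(ny, 9))
  if (any(freq > max(breaks), na.rm = TRUE)) {
    stopf("frequency count exceeds the top bin edge %d", max(breaks))
  }
  bin <- matrix(findInterval(freq, c(0, breaks), left.open = TRUE),
                nrow(freq), ncol(freq))
  bin[!is.na(freq) & freq == 0L] <- NA_integer_
  structure(bin, labels = frequency_bin_labels[[scheme]], breaks = breaks,
            scheme = scheme, class = c("frequency_class_map", "matrix", "array"))
}

#' Frequency-class proportions
#'
#' @param fmap A [classify_frequency()] map.
#' @param mask_size Optional total analysis-mask pixel count used for the
#'   inundated fraction; defaults to the full grid.
#' @return List with `proportions` (named, over non-null pixels, summing to
#'   1), `counts`, and `covered_fraction` (non-null share of the mask).
#' @export
frequency_share <- function(fmap, mask_size = length(fmap)) {
  labels <- attr(fmap, "labels")
  counts <- tabulate(fmap[!is.na(fmap)], nbins = length(labels))
  names(counts) <- labels
  if (sum(counts) == 0) stopf("all-null frequency map: proportions undefined")
  list(proportions = counts / sum(counts), counts = counts,
       covered_fraction = sum(counts) / mask_size)
}

#' Coefficient-of-variation stability raster
#'
#' Per pixel over the annual presence series `F_i`:
#' `CV = (1 / mean(F)) * sqrt(sum((F_i - mean(F))^2) / n) * 100%`
#' (population divisor `n`). Pixels never present (`mean(F) = 0`) are null.
#'
#' @param annual_grids List of per-year 0/1 presence matrices (n >= 2).
#' @return A `cv_raster`: matrix of CV percentages (NA where null), with
#'   the per-pixel mean presence in attribute `mean_presence`.
#' @export
cv_map <- function(annual_grids) {
  n <- length(annual_grids)
  if (n < 2L) stopf("CV needs at least 2 years")
  stack <- grid_stack(annual_grids)
  fbar <- apply(stack, c(1, 2), mean)
  ss <- apply(stack, c(1, 2), function(v) sum((v - mean(v))^2))
  cv <- sqrt(ss / n) / fbar * 100
  cv[!is.na(fbar) & fbar == 0] <- NA_real_
  structure(cv, mean_presence = fbar, n_years = n,
            class = c("cv_raster", "matrix", "array"))
}

#' Bin a CV raster into stability categories
#'
#' Lower CV means higher stability. With `breaks = NULL` the default uses
#' CV terciles over the non-null pixels, yielding the three-way summary
#' high / medium / low-or-relatively-low; explicit breaks (strictly
#' increasing CV percentages) are honoured as given.
#'
#' @param cv A [cv_map()] raster.
#' @param breaks `NULL` (terciles) or strictly increasing numeric CV break
#'   points.
#' @param labels Category names, length `length(breaks) + 1`, ordered from
#'   most to least stable.
#' @return A `stability_map`: integer matrix of category indices (1 = most
#'   stable; NA null) with attributes `labels` and `breaks`.
#' @export
stability_classes <- function(cv, breaks = NULL,
                              labels = NULL) {
  vals <- cv[!is.na(cv)]
  if (!length(vals)) stopf("all-null CV raster")
  if (is.null(breaks)) {
    breaks <- unname(stats::quantile(vals, c(1 / 3, 2 / 3), type = 7))
    breaks <- unique(breaks)
  }
  if (is.unsorted(breaks, strictly = TRUE)) {
    stopf("stability breaks must be strictly increasing")
  }
  if (is.null(labels)) {
    labels <- if (length(breaks) == 2) {
      c("high", "medium", "low or relatively low")
    } else paste0("stability_", seq_len(length(breaks) + 1))
  }
  if (length(labels) != length(breaks) + 1) {
    stopf("need %d labels for %d breaks", length(breaks) + 1, length(breaks))
  }
  cat_idx <- matrix(findInterval(cv, breaks, left.open = TRUE) + 1L,
                    nrow(cv), ncol(cv))
  cat_idx[is.na(cv)] <- NA_integer_
  structure(cat_idx, labels = labels, breaks = breaks,
            class = c("stability_map", "matrix", "array"))
}

#' Per-pixel modal class map of a period
#'
#' The categorical analogue of a period average: each pixel takes its most
#' frequent label across the period's maps; ties break to the lowest class
#' code, and a pixel is nodata only where every input is nodata.
#'
#' @param maps List of [class_map()]s of common shape.
#' @return A [class_map()] dated by the period span.
#' @export
modal_map <- function(maps) {
  if (!length(maps)) stopf("need at least one map")
  stack <- grid_stack(lapply(maps, `[[`, "labels"))
  lab <- apply(stack, c(1, 2), function(v) {
    v <- v[v != LAKE_CLASSES[["nodata"]]]
    if (!length(v)) return(LAKE_CLASSES[["nodata"]])
    tab <- tabulate(v, nbins = max(LAKE_CLASSES))
    which.max(tab)   # ties resolve to the lowest code
  })
  class_map(matrix(as.integer(lab), dim(stack)[1], dim(stack)[2]),
            date = sprintf("%s..%s", maps[[1]]$date, maps[[length(maps)]]$date),
            pixel_size = maps[[1]]$pixel_size, origin = maps[[1]]$origin)
}

#' Land-category transfer matrix between two periods
#'
#' Cross-tabulates per-pixel class membership between an origin and a
#' destination map and converts counts to areas. The layout follows the
#' conventional land-use transfer table: rows are origin classes, columns
#' destination classes, with row/column totals and per-class `decreasing`
#' (row total minus diagonal: area lost by the class) and `increasing`
#' (column total minus diagonal: area gained).
#'
#' @param origin,destination [class_map()]s of equal shape and pixel size.
#' @param classes Class codes to tabulate; defaults to the four land
#'   classes.
#' @return A `transfer_matrix`: list with `matrix_km2`, `row_total`,
#'   `col_total`, `decreasing`, `increasing`, `grand_total_km2`.
#' @export
transfer_matrix <- function(origin, destination,
                            classes = lake_classes()[-1]) {
  stopifnot(inherits(origin, "class_map"), inherits(destination, "class_map"))
  if (!identical(dim(origin$labels), dim(destination$labels))) {
    stopf("origin and destination shapes differ")
  }
  if (origin$pixel_size != destination$pixel_size) {
    stopf("origin and destination pixel sizes differ")
  }
  px_km2 <- (origin$pixel_size / 1000)^2
  keep <- origin$labels != LAKE_CLASSES[["nodata"]] &
    destination$labels != LAKE_CLASSES[["nodata"]]
  o <- factor(origin$labels[keep], levels = classes)
  d <- factor(destination$labels[keep], levels = classes)
  counts <- unclass(table(o, d))
  m <- counts * px_km2
  dimnames(m) <- list(origin = class_name(classes),
                      destination = class_name(classes))
  row_total <- rowSums(m); col_total <- colSums(m)
  structure(
    list(matrix_km2 = m, row_total = row_total, col_total = col_total,
         decreasing = row_total - diag(m), increasing = col_total - diag(m),
         grand_total_km2 = sum(m),
         origin_date = origin$date, destination_date = destination$date),
    class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("<transfer_matrix> %s -> %s, total %.4f km2\n",
              x$origin_date, x$destination_date, x$grand_total_km2))
  out <- cbind(x$matrix_km2, total = x$row_total, decreasing = x$decreasing)
  out <- rbind(out, total = c(x$col_total, x$grand_total_km2, NA),
               increasing = c(x$increasing, NA, NA))
  print(round(out, 4), na.print = "")
  invisible(x)
}

#' Write a transfer matrix as CSV
#'
#' Classes x classes area block plus the total/decreasing column pair and
#' total/increasing row pair of the conventional table layout.
#'
#' @param x A [transfer_matrix()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_transfer_csv <- function(x, path) {
  stopifnot(inherits(x, "transfer_matrix"))
  block <- cbind(as.data.frame(x$matrix_km2), total_km2 = x$row_total,
                 decreasing_km2 = x$decreasing)
  block <- rbind(block,
                 total_km2 = c(x$col_total, x$grand_total_km2, NA),
                 increasing_km2 = c(x$increasing, NA, NA))
  write.csv(round(block, 6), path, na = "")
  invisible(path)
}
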