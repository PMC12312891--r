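#' Write a raster grid as an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange (readable by GDAL/QGIS).
#' Class maps are written as integers with nodata 0; continuous grids as
#' full-precision floats with nodata -9999. Band metadata (date, band name)
#' travels in a JSON sidecar written by the scene-pack writers.
#'
#' @param grid Numeric or integer matrix (row 1 = northernmost row).
#' @param path Output path (conventionally `.asc`).
#' @param pixel_size Cell size in metres.
#' @param origin Lower-left corner (x, y); default places the grid at (0,0).
#' @param nodata Nodata sentinel written to the header.
#' @param integer Write integer cells (class maps) instead of floats.
#' @return `path`, invisibly.
#' @export
write_asc <- function(grid, path, pixel_size = 30, origin = NULL,
                      nodata = if (integer) 0 else -9999, integer = FALSE) {
  stopifnot(is.matrix(grid))
  nr <- nrow(grid); nc <- ncol(grid)
  if (is.null(origin)) origin <- c(0, 0)
  vals <- grid
  vals[is.na(vals)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", nc),
               sprintf("nrows %d", nr),
               sprintf("xllcorner %.6f", origin[1]),
               sprintf("yllcorner %.6f", origin[2]),
               sprintf("cellsize %.6f", pixel_size),
               sprintf("NODATA_value %s",
                       if (integer) format(as.integer(nodata))
                       else format(nodata))), con)
  fmt <- if (integer) function(v) format(as.integer(v)) else
    function(v) formatC(v, format = "g", digits = 10)
  for (i in seq_len(nr)) writeLines(paste(fmt(vals[i, ]), collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file.
#' @param integer Coerce cells to integer (class maps).
#' @return List with `grid` (matrix, NA at nodata), `pixel_size`, `origin`
#'   (lower-left corner), `nodata`.
#' @export
read_asc <- function(path, integer = FALSE) {
  if (!file.exists(path)) stopf("no such raster: %s", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stopf("corrupt ASCII grid header in %s", path)
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(body) != nr * nc) {
    stopf("raster body of %s has %d cells, header promises %d",
          path, length(body), nr * nc)
  }
  grid <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else NA
  if (!is.na(nodata)) grid[grid == nodata] <- NA
  if (integer) storage.mode(grid) <- "integer"
  list(grid = grid, pixel_size = hdr$cellsize,
       origin = c(hdr$xllcorner %||% 0, hdr$yllcorner %||% 0),
       nodata = nodata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a class map to disk
#'
#' @param map A [class_map()].
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_class_map <- function(map, path) {
  stopifnot(inherits(map, "class_map"))
  write_asc(map$labels, path, pixel_size = map$pixel_size,
            origin = map$origin, integer = TRUE)
}

#' Read a class map from disk
#'
#' @param path `.asc` path written by [write_class_map()].
#' @param date Date to attach.
#' @return A [class_map()]; unknown codes raise a validation error.
#' @export
read_class_map <- function(path, date = NA) {
  r <- read_asc(path, integer = TRUE)
  g <- r$grid
  g[is.na(g)] <- LAKE_CLASSES[["nodata"]]
  class_map(g, date = date, pixel_size = r$pixel_size, origin = r$origin)
}

#' Write a spectral image as per-band ASCII grids plus a JSON sidecar
#'
#' @param image A [spectral_image()].
#' @param stem Path stem; bands land at `<stem>_<band>.asc` and metadata at
#'   `<stem>.json`.
#' @return Character vector of written paths, invisibly.
#' @export
write_spectral_image <- function(image, stem) {
  stopifnot(inherits(image, "spectral_image"))
  paths <- character(0)
  for (b in seq_len(n_bands(image))) {
    p <- sprintf("%s_%s.asc", stem, image$band_names[b])
    write_asc(image$values[, , b], p, pixel_size = image$pixel_size,
              origin = image$origin)
    paths <- c(paths, p)
  }
  meta <- list(date = image$date, band_names = image$band_names,
               pixel_size = image$pixel_size, origin = image$origin,
               bands = basename(paths))
  jp <- paste0(stem, ".json")
  jsonlite::write_json(meta, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}

#' Read a spectral image written by [write_spectral_image()]
#'
#' @param stem The path stem used at write time.
#' @return A [spectral_image()].
#' @export
read_spectral_image <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  bands <- lapply(meta$band_names, function(bn)
    read_asc(sprintf("%s_%s.asc", stem, bn)))
  vals <- simplify2array(lapply(bands, `[[`, "grid"))
  spectral_image(vals, date = meta$date, pixel_size = meta$pixel_size,
                 band_names = meta$band_names, origin = meta$origin)
}

#' Write a simulated scene pack to a directory
#'
#' Per scene: the multiband reflectance image, the 8-bit-style truth class
#' map, and a row in `manifest.csv` (date, level, file stems); the
#' generator config echo goes to `config.json` and the DEM to `dem.asc`.
#'
#' @param pack A [simulate_scenes()] pack.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene_pack <- function(pack, dir) {
  stopifnot(inherits(pack, "scene_pack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_asc(unclass(pack$dem), file.path(dir, "dem.asc"),
            pixel_size = pack$config$pixel_size)
  rows <- vector("list", length(pack$scenes))
  for (i in seq_along(pack$scenes)) {
    sc <- pack$scenes[[i]]
    stem <- sprintf("scene_%03d", i)
    write_spectral_image(sc$image, file.path(dir, stem))
    write_class_map(sc$truth, file.path(dir, paste0(stem, "_truth.asc")))
    rows[[i]] <- data.frame(date = sc$date, level = sc$level, stem = stem,
                            truth = paste0(stem, "_truth.asc"))
  }
  write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
            row.names = FALSE)
  cfg <- pack$config
  cfg$signature_table <- as.data.frame(cfg$signature_table)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Read a scene pack directory
#'
#' @param dir Directory written by [write_scene_pack()].
#' @return List with `dem`, `manifest`, `scenes` (list of
#'   `(date, level, truth, image)`).
#' @export
read_scene_pack <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  dem <- read_asc(file.path(dir, "dem.asc"))$grid
  scenes <- lapply(seq_len(nrow(manifest)), function(i) {
    list(date = manifest$date[i], level = manifest$level[i],
         truth = read_class_map(file.path(dir, manifest$truth[i]),
                                date = manifest$date[i]),
         image = read_spectral_image(file.path(dir, manifest$stem[i])))
  })
  list(dem = dem, manifest = manifest, scenes = scenes)
}

#' Packaged monthly area-series table
#'
#' The in-package monitoring table of per-scene water, vegetation and
#' merged mudflat&sand areas (km2) for 41 dated scenes of a 2013-2021
#' seasonal-lake campaign, at 4-decimal printed precision.
#'
#' @return An `area_series` with 41 records.
#' @export
load_area_fixture <- function() {
  path <- system.file("extdata", "lake_area_series.csv",
                      package = "lakecover", mustWork = TRUE)
  as_area_series(read.csv(path, stringsAsFactors = FALSE),
                 source = "packaged fixture")
}

#' Read an area series CSV
#'
#' @param path CSV with columns `date`, `water_km2`, `vegetation_km2`,
#'   `mudflat_sand_km2` (or split mudflat/sand columns).
#' @return An `area_series`.
#' @export
read_area_series <- function(path) {
  as_area_series(read.csv(path, stringsAsFactors = FALSE), source = path)
}
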