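#' Default spectral signature table
#'
#' Mean surface reflectance per class for six reflective bands
#' (blue, green, red, NIR, SWIR1, SWIR2), shaped after the canonical
#' reflectance curves of the four cover types of a seasonal lake: water is
#' dark everywhere and darkest in the infrared, vegetation has the red edge
#' (low red, high NIR), wet mudflat sediment sits between, and dry sand is
#' the brightest surface.
#'
#' @return Numeric matrix (4 classes x 6 bands) with class and band dimnames.
#' @export
default_signatures <- function() {
  sig <- rbind(
    water      = c(0.06, 0.08, 0.06, 0.03, 0.02, 0.01),
    vegetation = c(0.04, 0.08, 0.05, 0.45, 0.25, 0.12),
    mudflat    = c(0.08, 0.11, 0.14, 0.20, 0.25, 0.20),
    sand       = c(0.15, 0.20, 0.26, 0.32, 0.38, 0.33))
  colnames(sig) <- c("blue", "green", "red", "nir", "swir1", "swir2")
  sig
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-scene generator: grid size, scene
#' calendar, spectral signatures, sensor noise, and the hypsometry of the
#' simulated basin. Defaults emulate a 9-year quarterly monitoring campaign
#' of a seasonal monsoon lake at 30 m resolution.
#'
#' @param grid_rows,grid_cols Grid dimensions (>= 8).
#' @param n_years Number of monitored years.
#' @param scenes_per_year Scenes per year, spread evenly over the calendar.
#' @param band_count Number of spectral bands (columns used from
#'   `signature_table`).
#' @param signature_table Per-class per-band mean reflectance in [0, 1];
#'   rows water/vegetation/mudflat/sand.
#' @param noise_sd Gaussian sensor noise, reflectance units.
#' @param water_level_base Mean lake stage, elevation units.
#' @param water_level_amplitude Seasonal stage half-range: the stage sinusoid
#'   peaks at `base + amplitude` in July and troughs in January.
#' @param interannual_sd Standard deviation of yearly stage anomalies.
#' @param mudflat_band_width Elevation band above the waterline mapped to
#'   mudflat.
#' @param vegetation_band_width Elevation band above the mudflat fringe
#'   mapped to vegetation; terrain above it is sand.
#' @param relief Total bowl depth of the basin, elevation units.
#' @param dem_roughness Amplitude of the low-frequency random field added to
#'   the bowl (0 gives a pure radial bowl).
#' @param sediment_offset Optional additive visible-band (blue/green/red)
#'   reflectance offset applied to water pixels, emulating suspended
#'   sediment; default off.
#' @param pixel_size Ground pixel size, metres.
#' @param seed Integer master seed; every random draw derives from it.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid_rows = 64, grid_cols = 64,
                       n_years = 9, scenes_per_year = 4,
                       band_count = 6,
                       signature_table = default_signatures(),
                       noise_sd = 0.02,
                       water_level_base = 4,
                       water_level_amplitude = 2,
                       interannual_sd = 0.3,
                       mudflat_band_width = 0.8,
                       vegetation_band_width = 1.5,
                       relief = 8,
                       dem_roughness = 0.5,
                       sediment_offset = 0,
                       pixel_size = 30,
                       seed = 1L) {
  if (!is_count(grid_rows) || !is_count(grid_cols) || grid_rows < 8 || grid_cols < 8) {
    stopf("grid dimensions must be integers >= 8")
  }
  if (!is_count(n_years) || !is_count(scenes_per_year)) {
    stopf("n_years and scenes_per_year must be positive integers")
  }
  if (!is_count(band_count) || band_count < 2 || band_count > ncol(signature_table)) {
    stopf("band_count must be in 2..%d", ncol(signature_table))
  }
  sig <- signature_table[, seq_len(band_count), drop = FALSE]
  if (any(sig < 0 | sig > 1)) stopf("signature means must lie in [0, 1]")
  needed <- c("water", "vegetation", "mudflat", "sand")
  if (!all(needed %in% rownames(sig))) {
    stopf("signature_table must have rows %s", paste(needed, collapse = ", "))
  }
  bn <- colnames(sig)
  # spectral ordering the classifiers rely on (red edge, dark-water infrared)
  if (all(c("nir", "red", "swir1", "swir2") %in% bn)) {
    if (!(sig["water", "nir"] < sig["vegetation", "nir"])) {
      stopf("signature ordering violated: water NIR must be below vegetation NIR")
    }
    if (!(sig["vegetation", "red"] < sig["mudflat", "red"])) {
      stopf("signature ordering violated: vegetation red must be below mudflat red")
    }
    for (b in c("swir1", "swir2")) {
      if (sig["water", b] != min(sig[, b])) {
        stopf("signature ordering violated: water must be darkest in %s", b)
      }
    }
  }
  if (!is_scalar(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  if (mudflat_band_width < 0 || vegetation_band_width < 0) {
    stopf("zonation band widths must be >= 0")
  }
  if (relief <= 0) stopf("relief must be > 0")
  if (water_level_base <= 0 || water_level_base >= relief) {
    stopf("water_level_base must lie inside (0, relief) so the lake is neither empty nor total")
  }
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         n_years = as.integer(n_years),
         scenes_per_year = as.integer(scenes_per_year),
         band_count = as.integer(band_count), signature_table = sig,
         noise_sd = noise_sd, water_level_base = water_level_base,
         water_level_amplitude = water_level_amplitude,
         interannual_sd = interannual_sd,
         mudflat_band_width = mudflat_band_width,
         vegetation_band_width = vegetation_band_width,
         relief = relief, dem_roughness = dem_roughness,
         sediment_offset = sediment_offset,
         pixel_size = pixel_size, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d x %d grid, %d years x %d scenes, %d bands, ",
                     "noise %.3g, seed %d\n"),
              x$grid_rows, x$grid_cols, x$n_years, x$scenes_per_year,
              x$band_count, x$noise_sd, x$seed))
  invisible(x)
}

#' Synthesize a basin elevation model
#'
#' Builds a smooth single-basin surface: a radial paraboloid bowl of depth
#' `relief` centred on the grid, plus a low-frequency random cosine field of
#' amplitude `dem_roughness`. Reproducible from the config seed.
#'
#' @param config A [sim_config()].
#' @return Numeric matrix of elevations (class `elevation_grid`).
#' @export
make_dem <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  # normalized coordinates in [-1, 1] around the basin centre
  u <- (seq_len(nr) - (nr + 1) / 2) / ((nr - 1) / 2)
  v <- (seq_len(nc) - (nc + 1) / 2) / ((nc - 1) / 2)
  r2 <- outer(u^2, v^2, `+`)
  dem <- config$relief * r2 / 2   # corners reach `relief` (r2 = 2 there)
  if (config$dem_roughness > 0) {
    dem <- dem + with_seed(derive_seed(config$seed, 11L), {
      field <- matrix(0, nr, nc)
      for (k in 1:6) {  # a handful of long waves: smooth, not speckle
        fr <- runif(1, 0.5, 2.0); fc <- runif(1, 0.5, 2.0)
        ph <- runif(2, 0, 2 * pi)
        field <- field + outer(cos(pi * fr * u + ph[1]),
                               cos(pi * fc * v + ph[2]))
      }
      config$dem_roughness * field / 6
    })
  }
  structure(dem, class = c("elevation_grid", "matrix", "array"))
}

#' Seasonal water-level series
#'
#' Lake stage for every scene date: an annual sinusoid peaking in July
#' (high-water season June-September, trough in January) plus one Gaussian
#' anomaly per year with sd `interannual_sd`. Scene months are spread evenly
#' over the calendar and dates fall on the 15th (mid-month).
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `date` (ISO-8601), `year`, `month`,
#'   `level`.
#' @export
water_level_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  spy <- config$scenes_per_year
  step <- 12 / spy
  months <- floor(step / 2 + step * (seq_len(spy) - 1)) + 1L
  months <- pmin(months, 12L)
  anomalies <- with_seed(derive_seed(config$seed, 23L),
                         rnorm(config$n_years, 0, config$interannual_sd))
  rows <- vector("list", config$n_years * spy)
  k <- 0L
  for (y in seq_len(config$n_years)) {
    year <- 2000L + y
    for (m in months) {
      k <- k + 1L
      level <- config$water_level_base +
        config$water_level_amplitude * sin(2 * pi * (m - 4) / 12) +
        anomalies[y]
      rows[[k]] <- data.frame(
        date = sprintf("%04d-%02d-15", year, m),
        year = year, month = m, level = level)
    }
  }
  do.call(rbind, rows)
}

#' Ground-truth zonation from elevation and stage
#'
#' Deterministic elevation-banded labels: water below the waterline, then a
#' mudflat fringe of width `mudflat_band_width`, then a vegetation belt of
#' width `vegetation_band_width`, and sand above. This encodes the
#' submergence logic of a fluctuating lake: a rising stage drowns mudflat
#' and vegetation in order.
#'
#' @param dem Elevation matrix from [make_dem()].
#' @param level Water level (same units as the DEM).
#' @param config A [sim_config()].
#' @param date Optional date attached to the returned map.
#' @return A [class_map()].
#' @export
render_truth <- function(dem, level, config, date = NA) {
  stopifnot(is.matrix(dem), all(is.finite(dem)), is_scalar(level))
  lab <- matrix(LAKE_CLASSES[["sand"]], nrow(dem), ncol(dem))
  lab[dem < level + config$mudflat_band_width + config$vegetation_band_width] <-
    LAKE_CLASSES[["vegetation"]]
  lab[dem < level + config$mudflat_band_width] <- LAKE_CLASSES[["mudflat"]]
  lab[dem < level] <- LAKE_CLASSES[["water"]]
  class_map(lab, date = date, pixel_size = config$pixel_size)
}

#' Render a noisy multiband scene from a truth map
#'
#' Each pixel's spectrum is its class signature mean plus independent
#' Gaussian noise of sd `noise_sd`, clipped to [0, 1]. With
#' `sediment_offset > 0`, water pixels get that additive offset in the
#' visible bands (turbid-water brightening). Nodata cells propagate as NA.
#'
#' @param truth A [class_map()].
#' @param config A [sim_config()].
#' @param seed Seed for the noise draw; defaults to one derived from the
#'   config seed.
#' @return A [spectral_image()].
#' @export
render_spectra <- function(truth, config, seed = derive_seed(config$seed, 31L)) {
  stopifnot(inherits(truth, "class_map"))
  sig <- config$signature_table
  lab <- truth$labels
  present <- setdiff(unique(as.vector(lab)), LAKE_CLASSES[["nodata"]])
  missing <- setdiff(class_name(present), rownames(sig))
  if (length(missing)) stopf("no signature for class: %s", paste(missing, collapse = ", "))
  nr <- nrow(lab); nc <- ncol(lab); nb <- config$band_count
  vals <- array(NA_real_, c(nr, nc, nb))
  noise <- with_seed(seed, rnorm(nr * nc * nb, 0, max(config$noise_sd, 0)))
  dim(noise) <- c(nr, nc, nb)
  visible <- which(colnames(sig) %in% c("blue", "green", "red"))
  for (code in present) {
    cells <- lab == code
    mu <- sig[class_name(code), ]
    if (config$sediment_offset > 0 && code == LAKE_CLASSES[["water"]] &&
        length(visible)) {
      mu[visible] <- mu[visible] + config$sediment_offset
    }
    for (b in seq_len(nb)) {
      band <- vals[, , b]
      band[cells] <- mu[b] + if (config$noise_sd > 0) noise[, , b][cells] else 0
      vals[, , b] <- band
    }
  }
  vals <- pmin(pmax(vals, 0), 1)
  vals[array(rep(lab == LAKE_CLASSES[["nodata"]], nb), c(nr, nc, nb))] <- NA_real_
  spectral_image(vals, date = truth$date, pixel_size = config$pixel_size,
                 band_names = colnames(sig))
}

#' Sample training regions of interest from a labeled scene
#'
#' Uniform random sample without replacement of `per_class_n` pixels per
#' class present in the truth map, returned as a [training_set()].
#'
#' @param truth A [class_map()] providing the labels.
#' @param image The matching [spectral_image()].
#' @param per_class_n Samples per class.
#' @param seed Integer seed.
#' @return A [training_set()].
#' @export
sample_rois <- function(truth, image, per_class_n, seed) {
  stopifnot(inherits(truth, "class_map"), inherits(image, "spectral_image"))
  if (!identical(dim(truth$labels), dim(image$values)[1:2])) {
    stopf("truth and image shapes differ")
  }
  if (!is_count(per_class_n)) stopf("per_class_n must be a positive integer")
  d <- dim(image$values)
  m <- matrix(image$values, nrow = d[1] * d[2], ncol = d[3])
  lab <- as.vector(truth$labels)
  present <- sort(setdiff(unique(lab), LAKE_CLASSES[["nodata"]]))
  samples <- list(); indices <- list()
  with_seed(seed, {
    for (code in present) {
      pool <- which(lab == code)
      if (length(pool) < per_class_n) {
        stopf("class %s has only %d pixels, %d requested",
              class_name(code), length(pool), per_class_n)
      }
      take <- if (length(pool) == per_class_n) pool else
        sample(pool, per_class_n)
      nm <- class_name(code)
      samples[[nm]] <- m[take, , drop = FALSE]
      indices[[nm]] <- take
    }
  })
  training_set(samples, indices)
}

#' Simulate a full multitemporal scene pack
#'
#' Runs the generator end to end: one basin DEM, a seeded stage series, and
#' per scene the deterministic truth map plus a noisy spectral rendering.
#'
#' @param config A [sim_config()].
#' @return An object of class `scene_pack`: list with `dem`, `levels`
#'   (the stage data frame), `scenes` (list of `(date, level, truth, image)`),
#'   and the `config`.
#' @export
simulate_scenes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  dem <- make_dem(config)
  levels <- water_level_series(config)
  scenes <- vector("list", nrow(levels))
  for (i in seq_len(nrow(levels))) {
    truth <- render_truth(dem, levels$level[i], config, date = levels$date[i])
    image <- render_spectra(truth, config, seed = derive_seed(config$seed, 100L + i))
    scenes[[i]] <- list(date = levels$date[i], level = levels$level[i],
                        truth = truth, image = image)
  }
  structure(list(dem = dem, levels = levels, scenes = scenes, config = config),
            class = "scene_pack")
}

#' @export
print.scene_pack <- function(x, ...) {
  cat(sprintf("<scene_pack> %d scenes (%s .. %s), %d x %d grid, seed %d\n",
              length(x$scenes), x$levels$date[1],
              x$levels$date[nrow(x$levels)],
              x$config$grid_rows, x$config$grid_cols, x$config$seed))
  invisible(x)
}
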