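test_that("make_dem is seeded, seed-sensitive, and a pure bowl when smooth", {
  cfg <- tiny_config()
  expect_identical(make_dem(cfg), make_dem(cfg))
  cfg2 <- tiny_config(); cfg2$seed <- 43L
  expect_false(identical(make_dem(cfg), make_dem(cfg2)))

  smooth <- sim_config(grid_rows = 25, grid_cols = 25, dem_roughness = 0,
                       relief = 8, seed = 1)
  dem <- make_dem(smooth)
  # pure radial paraboloid: minimum at the exact centre cell, value 0
  expect_equal(which(dem == min(dem)), 13L + 12L * 25L)
  expect_equal(dem[13, 13], 0)
  # bowl formula at an off-centre cell: relief * (u^2 + v^2) / 2
  u <- (1 - 13) / 12; v <- (25 - 13) / 12
  expect_equal(dem[1, 25], 8 * (u^2 + v^2) / 2)
  # lake is neither empty nor total at the base stage
  expect_lt(min(dem), smooth$water_level_base)
  expect_gt(max(dem), smooth$water_level_base)
})

test_that("sim_config validates dimensions and signature orderings", {
  expect_error(sim_config(grid_rows = 4), "dimensions")
  sig <- default_signatures()
  sig["water", "nir"] <- 0.9
  expect_error(sim_config(signature_table = sig), "NIR")
  sig <- default_signatures()
  sig["water", "swir1"] <- 0.5
  expect_error(sim_config(signature_table = sig), "swir1")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(water_level_base = 99), "water_level_base")
})

test_that("water_level_series peaks in the June-September high-water season", {
  cfg <- tiny_config()
  lv <- water_level_series(cfg)
  expect_equal(nrow(lv), cfg$n_years * cfg$scenes_per_year)
  expect_true(all(is.finite(lv$level)))
  expect_true(!is.unsorted(as.Date(lv$date), strictly = TRUE))
  for (y in unique(lv$year)) {
    yr <- lv[lv$year == y, ]
    expect_true(yr$month[which.max(yr$level)] %in% 6:9)
  }

  # degenerate: no amplitude, no anomalies -> constant at base
  flat <- sim_config(water_level_amplitude = 0, interannual_sd = 0, seed = 3)
  expect_true(all(water_level_series(flat)$level == flat$water_level_base))

  # monthly sampling of the pure sinusoid spans exactly 2a
  mo <- sim_config(scenes_per_year = 12, interannual_sd = 0,
                   water_level_amplitude = 1.5, seed = 3)
  lv12 <- water_level_series(mo)
  yr1 <- lv12$level[lv12$year == min(lv12$year)]
  expect_equal(max(yr1) - min(yr1), 2 * 1.5)
})

test_that("render_truth zonation is elevation-banded and monotone in stage", {
  cfg <- tiny_config()
  dem <- make_dem(cfg)
  cls <- lake_classes()

  all_water <- render_truth(dem, max(dem) + 1, cfg)
  expect_true(all(all_water$labels == cls[["water"]]))
  no_water <- render_truth(dem, min(dem) - 1, cfg)
  expect_true(all(no_water$labels != cls[["water"]]))

  levels <- seq(min(dem), max(dem), length.out = 12)
  water_n <- veg_n <- numeric(0)
  for (lv in levels) {
    m <- render_truth(dem, lv, cfg)
    water_n <- c(water_n, sum(m$labels == cls[["water"]]))
    veg_n <- c(veg_n, sum(m$labels == cls[["vegetation"]]))
    # truth maps partition the grid
    expect_equal(sum(m$labels %in% cls[-1]), length(dem))
  }
  expect_true(all(diff(water_n) >= 0))
})

test_that("render_spectra follows the class signatures and the noise model", {
  cfg <- tiny_config()
  dem <- make_dem(cfg)
  truth <- render_truth(dem, cfg$water_level_base, cfg)

  noiseless <- tiny_config(noise_sd = 0)
  img0 <- render_spectra(truth, noiseless)
  w <- which(truth$labels == lake_classes()[["water"]], arr.ind = TRUE)[1, ]
  expect_equal(unname(img0$values[w[1], w[2], ]),
               unname(cfg$signature_table["water", ]))

  img <- render_spectra(truth, cfg)
  nir <- match("nir", img$band_names)
  water_nir <- mean(img$values[, , nir][truth$labels == 1])
  veg_nir <- mean(img$values[, , nir][truth$labels == 2])
  expect_lt(water_nir, veg_nir)

  # law of large numbers on a big single-class map; mudflat signatures sit
  # at least 4 noise sds from the [0, 1] clip, so clipping bias is negligible
  big_truth <- class_map(matrix(3L, 120, 120))
  big <- render_spectra(big_truth, cfg, seed = 9L)
  n <- 120 * 120
  for (b in seq_len(cfg$band_count)) {
    expect_lt(abs(mean(big$values[, , b]) - cfg$signature_table["mudflat", b]),
              3 * cfg$noise_sd / sqrt(n) + 1e-6)
  }

  # sediment offset brightens water in the visible bands only
  sed <- tiny_config(noise_sd = 0, sediment_offset = 0.05)
  imgs <- render_spectra(truth, sed)
  expect_equal(imgs$values[w[1], w[2], match("green", imgs$band_names)],
               unname(cfg$signature_table["water", "green"]) + 0.05)
  expect_equal(imgs$values[w[1], w[2], nir],
               unname(cfg$signature_table["water", "nir"]))
})

test_that("sample_rois is exhaustive, seeded, and names short classes", {
  pack <- tiny_pack()
  sc <- pack$scenes[[1]]
  counts <- table(factor(sc$truth$labels, levels = 1:4))
  smallest <- min(counts)
  tr1 <- sample_rois(sc$truth, sc$image, smallest, seed = 11)
  tr2 <- sample_rois(sc$truth, sc$image, smallest, seed = 11)
  expect_identical(tr1$indices, tr2$indices)
  # exhaustive sample returns the full class
  small_name <- names(lake_classes())[-1][which.min(counts)]
  expect_equal(nrow(tr1$samples[[small_name]]), smallest)
  expect_setequal(tr1$indices[[small_name]],
                  which(as.vector(sc$truth$labels) == lake_classes()[[small_name]]))
  # requesting one more than the rarest class has must fail naming it
  expect_error(sample_rois(sc$truth, sc$image, smallest + 1L, seed = 1),
               small_name)
})

test_that("scene packs share shape, have increasing dates, and match the level oracle", {
  pack <- tiny_pack()
  dims <- vapply(pack$scenes, function(s) dim(s$image$values)[1:2], c(1, 1))
  expect_true(all(dims == dims[, 1]))
  expect_true(!is.unsorted(as.Date(pack$levels$date), strictly = TRUE))
  # per-pixel water occurrence count equals direct re-evaluation of dem < level
  counted <- Reduce(`+`, lapply(pack$scenes, function(s)
    (s$truth$labels == 1) * 1L))
  oracle <- Reduce(`+`, lapply(pack$levels$level, function(lv)
    (pack$dem < lv) * 1L))
  expect_identical(counted, oracle)
})
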