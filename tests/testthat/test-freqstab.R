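test_that("binarize is an indicator partition over the class set", {
  map <- map_from(c(1, 1, 2, 3, 4, 0, 1, 2, 3), 3, 3)
  w <- binarize(map, "water")
  expect_equal(sum(w, na.rm = TRUE), 3)
  expect_true(is.na(w[3, 2]))   # nodata propagates
  parts <- lapply(c("water", "vegetation", "mudflat", "sand"),
                  function(cl) binarize(map, cl))
  tot <- Reduce(`+`, parts)
  expect_true(all(tot[!is.na(tot)] == 1))
  expect_equal(sum(binarize(map_from(rep(1, 9), 3, 3), "sand")), 0)
  expect_error(binarize(map, "nodata"), "nodata")
})

test_that("annual_presence applies the majority rule with ties present", {
  g <- function(...) matrix(c(...), 1, 1)
  expect_equal(annual_presence(list(g(1), g(1), g(0)))[1, 1], 1L)   # 2/3
  expect_equal(annual_presence(list(g(0), g(0), g(0), g(1)))[1, 1], 0L) # 1/4
  expect_equal(annual_presence(list(g(1), g(0)))[1, 1], 1L)         # tie
  expect_equal(annual_presence(list(g(1)))[1, 1], 1L)               # identity
  expect_equal(annual_presence(list(g(1), g(0), g(0), g(0)),
                               rule = "any")[1, 1], 1L)
  expect_error(annual_presence(list(matrix(1, 2, 2), matrix(1, 3, 3))),
               "shapes")
})

test_that("frequency accumulation matches the elevation/stage oracle", {
  pack <- tiny_pack()
  years <- pack$levels$year
  truth_maps <- lapply(pack$scenes, function(s) s$truth)
  annual <- lapply(unique(years), function(y)
    annual_presence(lapply(truth_maps[years == y], binarize, target = "water")))
  fr <- accumulate_frequency(annual)
  expect_equal(attr(fr, "n_years"), length(unique(years)))
  expect_true(all(fr >= 0 & fr <= length(unique(years))))

  # oracle: recompute per year directly from dem < level, majority rule
  oracle <- Reduce(`+`, lapply(unique(years), function(y) {
    wet <- lapply(pack$levels$level[years == y], function(lv)
      (pack$dem < lv) * 1L)
    (Reduce(`+`, wet) / length(wet) >= 0.5) * 1L
  }))
  expect_true(all(unclass(fr) == oracle))

  # permutation-invariance in year order
  fr2 <- accumulate_frequency(rev(annual))
  expect_equal(unclass(fr2), unclass(fr))
})

test_that("frequency bins honour the printed half-open edges", {
  counts <- matrix(c(0L, 1L, 3L, 4L, 5L, 6L, 7L, 8L, 9L), 3, 3)
  fr <- structure(counts, n_years = 9L,
                  class = c("frequency_raster", "matrix", "array"))
  fm <- classify_frequency(fr, "water")
  expect_equal(attr(fm, "labels"),
               c("low", "medium", "relatively high", "high"))
  expect_true(is.na(fm[1, 1]))                     # 0 -> null
  expect_equal(fm[3, 1], 1L)                       # 3 in (0, 3]
  expect_equal(fm[1, 2], 2L)                       # 4 in (3, 5]
  expect_equal(fm[3, 2], 3L)                       # 6 in (5, 7]
  expect_equal(fm[2, 3], 4L)                       # 8 in (7, 9]
  fv <- classify_frequency(fr, "vegetation")
  expect_equal(attr(fv, "labels")[2:3], c("relatively low", "medium"))
  expect_equal(fv[1, 2], 2L)                       # count 4 -> relatively low

  too_big <- structure(matrix(10L, 2, 2), n_years = 9L,
                       class = c("frequency_raster", "matrix", "array"))
  expect_error(classify_frequency(too_big, "water"), "exceeds")

  sh <- frequency_share(fm)
  expect_equal(sum(sh$proportions), 1)
  expect_equal(sh$covered_fraction, 8 / 9)
  all9 <- classify_frequency(structure(matrix(9L, 2, 2), n_years = 9L,
                                       class = class(fr)), "water")
  expect_equal(unname(frequency_share(all9)$proportions["high"]), 1)
})

test_that("cv_map implements the population-divisor formula", {
  g <- function(x) matrix(x, 1, 1)
  # F = {1,1,0,0}: mean .5, population sd .5 -> CV 100%
  cv <- cv_map(list(g(1), g(1), g(0), g(0)))
  expect_equal(cv[1, 1], 100)
  # constant presence -> 0; never present -> null
  expect_equal(cv_map(list(g(1), g(1), g(1)))[1, 1], 0)
  expect_true(is.na(cv_map(list(g(0), g(0)))[1, 1]))
  expect_error(cv_map(list(g(1))), "2 years")

  # brute-force oracle on a random stack, plus year-order invariance
  set.seed(8)
  grids <- lapply(1:9, function(i) matrix(rbinom(36, 1, 0.5), 6, 6))
  cv9 <- cv_map(grids)
  f <- simplify2array(grids)
  for (i in 1:6) for (j in 1:6) {
    fi <- f[i, j, ]
    expected <- if (mean(fi) == 0) NA_real_ else
      sqrt(sum((fi - mean(fi))^2) / 9) / mean(fi) * 100
    expect_equal(cv9[i, j], expected)
  }
  expect_equal(unclass(cv_map(rev(grids))), unclass(cv9))
})

test_that("stability classes are monotone in CV and partition the lake", {
  cv <- structure(matrix(c(0, 10, 40, 80, NA, 120), 2, 3),
                  class = c("cv_raster", "matrix", "array"))
  st <- stability_classes(cv, breaks = c(30, 90))
  expect_equal(attr(st, "labels")[1], "high")
  expect_equal(st[1, 1], 1L)   # CV 0 -> most stable
  expect_equal(st[1, 2], 2L)   # CV 40 between breaks
  expect_equal(st[2, 3], 3L)   # CV 120 -> least stable
  expect_true(is.na(st[1, 3]))
  expect_error(stability_classes(cv, breaks = c(90, 30)), "increasing")

  # all-zero CV -> everything in the top class even with tercile breaks
  flat <- structure(matrix(0, 3, 3), class = class(cv))
  stf <- stability_classes(flat, breaks = c(30, 90))
  expect_true(all(stf == 1L))

  # deep-basin pixels are maximally stable; shore pixels are not
  pack <- tiny_pack()
  years <- pack$levels$year
  annual <- lapply(unique(years), function(y)
    annual_presence(lapply(pack$scenes[years == y],
                           function(s) binarize(s$truth, "water"))))
  cvp <- cv_map(annual)
  center <- which(pack$dem == min(pack$dem), arr.ind = TRUE)[1, ]
  expect_equal(cvp[center[1], center[2]], 0)
  expect_gt(max(cvp, na.rm = TRUE), 0)
})

test_that("modal_map takes the per-pixel mode with low-code ties", {
  m1 <- map_from(c(1, 1, 2, 0), 2, 2)
  m2 <- map_from(c(1, 2, 2, 0), 2, 2)
  m3 <- map_from(c(2, 2, 3, 4), 2, 2)
  mode3 <- modal_map(list(m1, m2, m3))
  expect_equal(mode3$labels[1, 1], 1L)  # {1,1,2} -> 1
  expect_equal(mode3$labels[2, 1], 2L)  # {1,2,2} -> 2
  expect_equal(mode3$labels[1, 2], 2L)  # {2,2,3} -> 2
  expect_equal(mode3$labels[2, 2], 4L)  # nodata ignored when data exists
  expect_identical(modal_map(list(m1))$labels, m1$labels)
  # two-way tie -> lowest class code
  tie <- modal_map(list(m1, m2))
  expect_equal(tie$labels[2, 1], 1L)    # {1,2} -> 1
  expect_equal(tie$labels[2, 2], 0L)    # all nodata stays nodata
})

test_that("transfer_matrix reproduces the 2x2 toy and conserves area", {
  origin <- map_from(c(1, 1, 2, 2), 2, 2)
  dest <- map_from(c(1, 2, 2, 2), 2, 2)
  tm <- transfer_matrix(origin, dest)
  expect_equal(tm$matrix_km2["water", "vegetation"], 0.0009)
  expect_equal(unname(tm$decreasing["water"]), 0.0009)
  expect_equal(unname(tm$increasing["vegetation"]), 0.0009)
  expect_equal(tm$grand_total_km2, 4 * 0.0009)
  expect_equal(sum(tm$row_total), sum(tm$col_total))

  # identity: diagonal matrix, no flux
  ident <- transfer_matrix(origin, origin)
  expect_true(all(ident$matrix_km2[row(ident$matrix_km2) !=
                                   col(ident$matrix_km2)] == 0))
  expect_true(all(ident$decreasing == 0) && all(ident$increasing == 0))

  # marginals reproduce the period class areas on synthetic maps
  pack <- tiny_pack()
  a <- pack$scenes[[1]]$truth; b <- pack$scenes[[7]]$truth
  tmx <- transfer_matrix(a, b)
  ar <- class_areas(a); br <- class_areas(b)
  expect_equal(unname(tmx$row_total),
               c(ar$water_km2, ar$vegetation_km2, ar$mudflat_km2, ar$sand_km2))
  expect_equal(unname(tmx$col_total),
               c(br$water_km2, br$vegetation_km2, br$mudflat_km2, br$sand_km2))
  expect_equal(tmx$grand_total_km2, ar$total_km2)
  expect_error(transfer_matrix(a, map_from(1, 1, 1)), "shapes")
})
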