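test_that("confusion reproduces the hand-computed 2x2 metrics", {
  # counts [[45, 5], [5, 45]]: OA .90, p_e .5, kappa .80
  pred <- rep(c(1L, 1L, 2L, 2L), c(45, 5, 5, 45))
  ref <- rep(c(1L, 2L, 1L, 2L), c(45, 5, 5, 45))
  cm <- confusion(pred, ref)
  expect_equal(cm$oa, 0.90)
  expect_equal(cm$kappa, 0.80)
  expect_equal(unname(cm$ua), c(0.9, 0.9))
  expect_equal(unname(cm$pa), c(0.9, 0.9))

  perfect <- confusion(ref, ref)
  expect_equal(perfect$oa, 1)
  expect_equal(perfect$kappa, 1)
  expect_true(all(perfect$ua == 1) && all(perfect$pa == 1))

  # a class never predicted has undefined (NA) UA, not zero
  cm2 <- confusion(c(1L, 1L, 1L), c(1L, 1L, 2L))
  expect_true(is.na(cm2$ua[["vegetation"]]))
  expect_equal(cm2$pa[["vegetation"]], 0)
  expect_error(confusion(integer(0), integer(0)), "empty")
})

test_that("kappa is near zero under marginal-preserving shuffles and permutation-invariant", {
  set.seed(17)
  ref <- sample(1:4, 3000, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  kappas <- replicate(200, confusion(sample(ref), ref)$kappa)
  expect_lt(abs(mean(kappas)), 0.05)

  pred <- ifelse(runif(3000) < 0.85, ref, sample(1:4, 3000, replace = TRUE))
  k1 <- confusion(pred, ref)$kappa
  perm <- c(3L, 1L, 4L, 2L)
  k2 <- confusion(perm[pred], perm[ref])$kappa
  expect_equal(k1, k2)
})

test_that("confusion reads reference pixels addressed on the map grid", {
  map <- map_from(c(1, 1, 2, 2, 3, 4, 4, 4, 1), 3, 3)
  ref <- data.frame(row = c(1, 2, 3, 1), col = c(1, 1, 2, 3),
                    class = c("water", "water", "sand", "water"))
  cm <- confusion(map, ref)
  expect_equal(cm$n, 4)
  expect_equal(cm$oa, 0.75)
  expect_error(confusion(map, data.frame(row = 9, col = 1, class = "water")),
               "outside")
})

test_that("mcnemar matches its worked example and is symmetric", {
  ref <- rep(1L, 40)
  a <- c(rep(1L, 10), rep(2L, 2), rep(1L, 20), rep(2L, 8))
  b <- c(rep(2L, 10), rep(1L, 2), rep(1L, 20), rep(2L, 8))
  m <- mcnemar(a, b, ref)
  expect_equal(m$b, 10); expect_equal(m$c, 2)
  expect_equal(m$statistic, 49 / 12)
  expect_lt(m$p_value, 0.05)

  swapped <- mcnemar(b, a, ref)
  expect_equal(swapped$b, m$c)
  expect_equal(swapped$p_value, m$p_value)

  same <- mcnemar(a, a, ref)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)

  # large-sample branch uses the df-1 chi-square tail
  a2 <- c(rep(1L, 30), rep(2L, 10))
  b2 <- c(rep(2L, 30), rep(1L, 10))
  m2 <- mcnemar(a2, b2, rep(1L, 40))
  expect_equal(m2$method, "chi-square with continuity correction")
  expect_equal(m2$p_value,
               pchisq((abs(30 - 10) - 1)^2 / 40, 1, lower.tail = FALSE))
})

fake_metrics <- function(oa, kappa, mean_ua = 0.9) {
  structure(list(oa = oa, kappa = kappa, mean_ua = mean_ua),
            class = "confusion_matrix")
}

test_that("select_method applies dominance, kappa override, and tie-breaks", {
  # dominance on OA and kappa
  sel <- select_method(fake_metrics(0.952, 0.91), fake_metrics(0.935, 0.89))
  expect_equal(sel$choice, 1)
  sel <- select_method(fake_metrics(0.935, 0.89), fake_metrics(0.952, 0.91))
  expect_equal(sel$choice, 2)
  # OA/kappa disagreement + non-significant difference -> higher kappa
  sel <- select_method(fake_metrics(0.945, 0.88), fake_metrics(0.930, 0.92),
                       mcnemar_p = 0.4)
  expect_equal(sel$choice, 2)
  expect_match(sel$rationale, "kappa")
  # full tie -> method A
  sel <- select_method(fake_metrics(0.9, 0.8), fake_metrics(0.9, 0.8),
                       mcnemar_p = 0.6)
  expect_equal(sel$choice, 1)
})

test_that("Jeffries-Matusita separability matches its closed forms", {
  set.seed(21)
  a <- matrix(rnorm(40000), ncol = 2)
  # identical distributions -> JM near 0
  tr0 <- training_set(list(water = a[1:10000, ], vegetation = a[10001:20000, ]))
  expect_lt(separability(tr0, "water", "vegetation"), 0.01)

  # equal-variance shift by 4 sds per band: B = 2 * (16/8)/2 per band... use 1 band pair
  b <- sweep(a, 2, c(-4, 0))
  tr1 <- training_set(list(water = a[, 1, drop = FALSE],
                           vegetation = b[, 1, drop = FALSE]))
  expect_equal(separability(tr1, "water", "vegetation"), 2 * (1 - exp(-2)),
               tolerance = 0.02)

  # huge separation saturates at 2
  far <- training_set(list(water = a, vegetation = sweep(a, 2, -1e3)))
  expect_equal(separability(far, "water", "vegetation"), 2, tolerance = 1e-9)
})

test_that("water index and threshold mask behave on the synthetic signatures", {
  # hand case: green .06, NIR .02 -> 0.5
  vals <- array(NA_real_, c(1, 2, 4))
  vals[1, 1, ] <- c(0.04, 0.06, 0.05, 0.02)
  vals[1, 2, ] <- c(0.04, 0.08, 0.05, 0.45)
  img <- spectral_image(vals, date = "x",
                        band_names = c("blue", "green", "red", "nir"))
  wi <- water_index(img)
  expect_equal(wi[1, 1], 0.5)
  expect_lt(wi[1, 2], 0)   # vegetation: NIR far above green
  # green == NIR -> 0; zero denominator -> nodata
  vals2 <- vals; vals2[1, 1, c(2, 4)] <- 0.3; vals2[1, 2, c(2, 4)] <- 0
  wi2 <- water_index(spectral_image(vals2, date = "x",
                                    band_names = c("blue", "green", "red", "nir")))
  expect_equal(wi2[1, 1], 0)
  expect_true(is.na(wi2[1, 2]))
  expect_error(water_index(img, "green", "swir9"), "band")

  # noiseless scene: index >= 0 recovers the truth water extent exactly
  cfg <- tiny_config(noise_sd = 0)
  pack <- simulate_scenes(cfg)
  sc <- pack$scenes[[2]]
  wi3 <- water_index(sc$image, "green", "nir")
  mask <- threshold_mask(wi3, 0)
  expect_identical(mask$mask, sc$truth$labels == 1)
  expect_equal(threshold_mask(wi3, -1)$n_true, length(wi3))
  expect_equal(threshold_mask(wi3, max(wi3) + 0.1)$n_true, 0)
})
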