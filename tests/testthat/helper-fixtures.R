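# Shared fixtures, built in code at test time.

# small fast default config for unit tests
tiny_config <- function(...) {
  defaults <- list(grid_rows = 24, grid_cols = 24, n_years = 3,
                   scenes_per_year = 4, noise_sd = 0.015, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# one cached small pack per test run
tiny_pack <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_scenes(tiny_config())
    cache
  }
})

# noisier pack: enough sensor noise that MLC and SVM disagree on some
# shore pixels, so the fusion path actually retrains
noisy_pack <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_scenes(sim_config(grid_rows = 32, grid_cols = 32,
                                           n_years = 3, scenes_per_year = 4,
                                           noise_sd = 0.06, seed = 42L))
    }
    cache
  }
})

# deterministic 4-class map from a label vector
map_from <- function(labels, nrow, ncol, pixel_size = 30, date = NA) {
  class_map(matrix(as.integer(labels), nrow, ncol), date = date,
            pixel_size = pixel_size)
}

# well-separated 2-D Gaussian training set
gaussian_train <- function(n = 60, sep = 6, sd = 0.5, seed = 7) {
  set.seed(seed)
  centers <- list(water = c(0, 0), vegetation = c(sep, 0),
                  mudflat = c(0, sep), sand = c(sep, sep))
  training_set(lapply(centers, function(mu)
    cbind(rnorm(n, mu[1], sd), rnorm(n, mu[2], sd))))
}
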