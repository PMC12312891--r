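#' Fit per-class Gaussian models
#'
#' Fits one multivariate Gaussian per training class: the sample mean vector
#' and the population covariance (divisor n), with a ridge `epsilon` added to
#' the covariance diagonal for numerical stability on degenerate regions of
#' interest.
#'
#' @param train A [training_set()].
#' @param epsilon Diagonal regularization. The default `NULL` uses
#'   `1e-6 * mean(diag(Sigma))` per class; pass 0 to disable.
#' @return List of `gaussian_class_model` objects (fields `code`, `name`,
#'   `mean`, `cov`, `epsilon`), one per class.
#' @export
fit_mlc <- function(train, epsilon = NULL) {
  stopifnot(inherits(train, "training_set"))
  models <- vector("list", length(train$samples))
  for (i in seq_along(train$samples)) {
    x <- train$samples[[i]]
    n <- nrow(x)
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    sigma <- crossprod(xc) / n          # population covariance, divisor n
    # relative ridge, floored so zero-scatter (noiseless) regions still fit
    eps <- if (is.null(epsilon)) max(1e-6 * mean(diag(sigma)), 1e-10) else epsilon
    sigma_r <- sigma + diag(eps, ncol(x))
    ch <- tryCatch(chol(sigma_r), error = function(e) NULL)
    if (is.null(ch)) {
      stopf("covariance of class %s is singular; refit with epsilon > 0",
            names(train$samples)[i])
    }
    models[[i]] <- structure(
      list(code = train$codes[i], name = names(train$samples)[i],
           mean = mu, cov = sigma_r, epsilon = eps, chol = ch),
      class = "gaussian_class_model")
  }
  models
}

#' @export
print.gaussian_class_model <- function(x, ...) {
  cat(sprintf("<gaussian_class_model> %s (code %d), %d bands, eps %.3g\n",
              x$name, x$code, length(x$mean), x$epsilon))
  invisible(x)
}

# log N(x; mu, Sigma) for a matrix of row vectors, via the stored Cholesky
gaussian_logdensity <- function(model, x) {
  ch <- model$chol
  m <- ncol(x)
  xc <- sweep(x, 2, model$mean)
  z <- backsolve(ch, t(xc), transpose = TRUE)   # solve t(ch) %*% z = t(xc)
  maha <- colSums(z^2)
  -0.5 * (m * log(2 * pi) + 2 * sum(log(diag(ch))) + maha)
}

#' Maximum-likelihood classification of a scene
#'
#' Labels every non-nodata pixel with the class whose fitted multivariate
#' Gaussian log-density (plus log prior, if priors are given) is highest.
#' Ties break to the lowest class code; nodata propagates.
#'
#' @param image A [spectral_image()].
#' @param models Output of [fit_mlc()].
#' @param priors Optional per-class prior weights (recycled to sum 1),
#'   ordered as `models`.
#' @return A [class_map()].
#' @export
mlc_classify <- function(image, models, priors = NULL) {
  stopifnot(inherits(image, "spectral_image"))
  if (length(models) < 2L) stopf("need at least 2 class models")
  m <- length(models[[1]]$mean)
  if (m != n_bands(image)) {
    stopf("model has %d bands but image has %d", m, n_bands(image))
  }
  if (!is.null(priors)) {
    if (length(priors) != length(models) || any(priors <= 0)) {
      stopf("priors must be positive, one per class")
    }
    priors <- priors / sum(priors)
  }
  im <- image_matrix(image)
  scores <- matrix(-Inf, nrow(im$x), length(models))
  for (j in seq_along(models)) {
    scores[, j] <- gaussian_logdensity(models[[j]], im$x) +
      if (is.null(priors)) 0 else log(priors[j])
  }
  codes <- vapply(models, `[[`, 0L, "code")
  ord <- order(codes)                 # ensure ties resolve to lowest code
  pick <- ord[max.col(scores[, ord, drop = FALSE], ties.method = "first")]
  lab <- matrix(LAKE_CLASSES[["nodata"]], im$shape[1], im$shape[2])
  lab[im$idx] <- codes[pick]
  class_map(lab, date = image$date, pixel_size = image$pixel_size,
            origin = image$origin)
}
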