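#' Kernel specification
#'
#' @param type `"rbf"` (default) or `"linear"`.
#' @param gamma RBF width. `NULL` (default) resolves at training time to
#'   `1 / (M * mean feature variance)` of the pooled training samples.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(type = c("rbf", "linear"), gamma = NULL) {
  type <- match.arg(type)
  if (!is.null(gamma) && (!is_scalar(gamma) || gamma <= 0)) {
    stopf("gamma must be a positive scalar")
  }
  structure(list(type = type, gamma = gamma), class = "kernel_spec")
}

resolve_gamma <- function(kernel, x) {
  if (kernel$type == "linear") return(kernel)
  if (is.null(kernel$gamma)) {
    v <- mean(apply(x, 2, var))
    kernel$gamma <- 1 / (ncol(x) * max(v, .Machine$double.eps))
  }
  kernel
}

# kernel cross-matrix K[i, j] = k(a_i, b_j) for row-sample matrices a, b
kernel_cross <- function(kernel, a, b) {
  if (kernel$type == "linear") return(tcrossprod(a, b))
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  exp(-kernel$gamma * pmax(d2, 0))
}

#' Train a binary soft-margin kernel SVM
#'
#' Solves the soft-margin dual (constraints `sum a_i y_i = 0`,
#' `0 <= a_i <= C`) by sequential minimal optimization, then keeps the
#' support samples and their signed dual weights so the kernel decision
#' function `f(x) = sum a_i y_i k(x_i, x) + b` is computable.
#'
#' @param pos Matrix of positive-class samples (rows).
#' @param neg Matrix of negative-class samples.
#' @param kernel A [kernel_spec()].
#' @param C Box bound (> 0), default 1.
#' @param tol KKT violation tolerance for the solver.
#' @return An object of class `svm_binary` with fields `sv` (support
#'   samples), `coef` (`a_i * y_i`), `b`, `kernel`, `C`.
#' @export
train_svm_binary <- function(pos, neg, kernel = kernel_spec(), C = 1,
                             tol = 1e-3) {
  if (!is.matrix(pos) || nrow(pos) == 0L) stopf("positive class is empty")
  if (!is.matrix(neg) || nrow(neg) == 0L) stopf("negative class is empty")
  if (ncol(pos) != ncol(neg)) stopf("pos/neg band counts differ")
  x <- rbind(pos, neg)
  if (!all(is.finite(x))) stopf("non-finite training samples")
  if (!is_scalar(C) || C <= 0) stopf("C must be > 0")
  y <- c(rep(1, nrow(pos)), rep(-1, nrow(neg)))
  kernel <- resolve_gamma(kernel, x)
  fit <- .smo_train(x, y, C,
                    kernel_type = if (kernel$type == "linear") 0L else 1L,
                    gamma = if (is.null(kernel$gamma)) 0 else kernel$gamma,
                    tol = tol, max_passes = 5L,
                    max_iter = max(200L, 40L * nrow(x)))
  if (!fit$converged) {
    lake_log("SMO hit the iteration cap before full KKT convergence", "warning")
  }
  keep <- which(fit$alpha > 1e-8)
  structure(
    list(sv = x[keep, , drop = FALSE], coef = fit$alpha[keep] * y[keep],
         alpha = fit$alpha[keep], y = y[keep], b = fit$b,
         kernel = kernel, C = C, n_train = nrow(x)),
    class = "svm_binary")
}

#' @export
print.svm_binary <- function(x, ...) {
  cat(sprintf("<svm_binary> %s kernel%s, C = %g, %d/%d support vectors\n",
              x$kernel$type,
              if (x$kernel$type == "rbf") sprintf(" (gamma %.4g)", x$kernel$gamma) else "",
              x$C, nrow(x$sv), x$n_train))
  invisible(x)
}

#' Evaluate the SVM decision function
#'
#' `f(x) = sum_i a_i y_i k(x_i, x) + b` over the retained support samples.
#'
#' @param svm An [train_svm_binary()] fit.
#' @param x A single spectral vector or a matrix of row vectors.
#' @return Numeric decision value(s).
#' @export
svm_decision <- function(svm, x) {
  stopifnot(inherits(svm, "svm_binary"))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(svm$sv) && nrow(svm$sv) > 0) {
    stopf("decision input has %d bands, model has %d", ncol(x), ncol(svm$sv))
  }
  if (nrow(svm$sv) == 0L) return(rep(svm$b, nrow(x)))
  drop(kernel_cross(svm$kernel, x, svm$sv) %*% svm$coef) + svm$b
}

#' Train a one-vs-rest SVM decision tree
#'
#' Builds the sequential multiclass scheme: node t separates class
#' `order[t]` (positives) from the pooled remaining classes
#' `order[t+1..K]` (negatives); the last class needs no node of its own.
#'
#' @param train A [training_set()].
#' @param order Class order for the tree, as class codes or names. Default:
#'   descending training-sample count (largest class peeled first).
#' @param kernel A [kernel_spec()].
#' @param C Box bound.
#' @return An object of class `svm_tree` (fields `order` as class codes,
#'   `nodes` as `svm_binary` list).
#' @export
train_svm_tree <- function(train, order = NULL, kernel = kernel_spec(), C = 1) {
  stopifnot(inherits(train, "training_set"))
  k <- length(train$samples)
  if (is.null(order)) {
    counts <- vapply(train$samples, nrow, 1L)
    order <- train$codes[order(-counts, train$codes)]
  } else {
    order <- class_code(order)
  }
  if (!setequal(order, train$codes) || length(order) != k) {
    stopf("order must be a permutation of the training classes")
  }
  nodes <- vector("list", k - 1L)
  for (t in seq_len(k - 1L)) {
    pos <- train$samples[[match(order[t], train$codes)]]
    rest <- order[(t + 1L):k]
    neg <- do.call(rbind, train$samples[match(rest, train$codes)])
    nodes[[t]] <- train_svm_binary(pos, neg, kernel = kernel, C = C)
  }
  structure(list(order = order, nodes = nodes), class = "svm_tree")
}

#' @export
print.svm_tree <- function(x, ...) {
  cat(sprintf("<svm_tree> order: %s (%d nodes)\n",
              paste(class_name(x$order), collapse = " > "),
              length(x$nodes)))
  invisible(x)
}

# decision-tree labelling of a plain sample matrix
svm_tree_predict <- function(tree, x) {
  lab <- rep(NA_integer_, nrow(x))
  pending <- seq_len(nrow(x))
  for (t in seq_along(tree$nodes)) {
    if (!length(pending)) break
    f <- svm_decision(tree$nodes[[t]], x[pending, , drop = FALSE])
    fire <- f >= 0
    lab[pending[fire]] <- tree$order[t]
    pending <- pending[!fire]
  }
  lab[pending] <- tree$order[length(tree$order)]
  lab
}

#' Classify a scene with an SVM decision tree
#'
#' Walks the one-vs-rest nodes in order; the first node whose decision value
#' is `>= 0` assigns its positive class, pixels rejected by every node get
#' the final class of the order. Nodata propagates.
#'
#' @param image A [spectral_image()].
#' @param tree A [train_svm_tree()] fit.
#' @return A [class_map()].
#' @export
svm_tree_classify <- function(image, tree) {
  stopifnot(inherits(image, "spectral_image"), inherits(tree, "svm_tree"))
  im <- image_matrix(image)
  lab <- matrix(LAKE_CLASSES[["nodata"]], im$shape[1], im$shape[2])
  lab[im$idx] <- svm_tree_predict(tree, im$x)
  class_map(lab, date = image$date, pixel_size = image$pixel_size,
            origin = image$origin)
}
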