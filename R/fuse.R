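#' Agreement-fusion classification
#'
#' Combines the maximum-likelihood and SVM-tree labelings of a scene.
#' Pixels where the two classifiers agree keep that label and are treated as
#' correctly classified; the SVM tree is then retrained on the original
#' training set augmented with a seeded sample of agreed pixels (at most
#' `max_extra_train` per class), and only the disagreeing pixels are
#' relabeled by the retrained tree. Agreed pixels are never altered.
#'
#' @param image A [spectral_image()].
#' @param train A [training_set()].
#' @param kernel A [kernel_spec()].
#' @param C SVM box bound.
#' @param epsilon MLC covariance ridge (see [fit_mlc()]).
#' @param max_extra_train Cap on agreed pixels added per class to the
#'   retraining set.
#' @param seed Seed for the agreed-pixel subsample.
#' @param order Optional SVM tree class order.
#' @return List with `map` (fused [class_map()]), `agreement` (logical
#'   matrix, TRUE where MLC and SVM agreed), `mlc`, `svm` (the two initial
#'   maps), and `n_reclassified`.
#' @export
fuse_classify <- function(image, train, kernel = kernel_spec(), C = 1,
                          epsilon = NULL, max_extra_train = 2000,
                          seed = 1L, order = NULL) {
  stopifnot(inherits(image, "spectral_image"), inherits(train, "training_set"))
  models <- fit_mlc(train, epsilon)
  mlc_map <- mlc_classify(image, models)
  tree <- train_svm_tree(train, order = order, kernel = kernel, C = C)
  svm_map <- svm_tree_classify(image, tree)

  agree <- mlc_map$labels == svm_map$labels
  fused <- mlc_map$labels
  nodata <- mlc_map$labels == LAKE_CLASSES[["nodata"]]
  disagree_idx <- which(!agree & !nodata)

  if (length(disagree_idx)) {
    # augment the ROI samples with agreed ("correctly classified") pixels
    d <- dim(image$values)
    pix <- matrix(image$values, nrow = d[1] * d[2], ncol = d[3])
    aug <- train$samples
    with_seed(seed, {
      for (i in seq_along(train$codes)) {
        code <- train$codes[i]
        pool <- which(agree & fused == code)
        if (!length(pool)) {
          lake_log(sprintf(
            "no agreed pixels for class %s; retraining falls back to the ROI samples",
            class_name(code)), "warning")
          next
        }
        take <- if (length(pool) > max_extra_train) {
          sample(pool, max_extra_train)
        } else pool
        aug[[i]] <- rbind(aug[[i]], pix[take, , drop = FALSE])
      }
    })
    retrained <- train_svm_tree(training_set(aug), order = tree$order,
                                kernel = kernel, C = C)
    fused[disagree_idx] <- svm_tree_predict(
      retrained, pix[disagree_idx, , drop = FALSE])
  }

  list(map = class_map(fused, date = image$date,
                       pixel_size = image$pixel_size, origin = image$origin),
       agreement = agree & !nodata,
       mlc = mlc_map, svm = svm_map,
       n_reclassified = length(disagree_idx))
}
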