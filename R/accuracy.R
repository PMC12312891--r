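#' Confusion matrix and accuracy metrics
#'
#' Cross-tabulates predicted against reference labels (rows = predicted,
#' columns = reference) and derives overall accuracy, per-class user's and
#' producer's accuracy, and Cohen's kappa. A class absent from the
#' prediction (or reference) marginal has its UA (or PA) reported as NA,
#' not 0.
#'
#' @param pred A [class_map()] or an integer vector of predicted labels.
#' @param reference Reference labels: a data frame with columns
#'   `row`, `col`, `class` (1-based grid indices into the map), or an
#'   integer vector aligned with `pred`.
#' @return An object of class `confusion_matrix`: fields `table`, `oa`,
#'   `ua`, `pa`, `kappa`, `n`, plus `mean_ua`/`mean_pa`.
#' @export
confusion <- function(pred, reference) {
  if (inherits(pred, "class_map")) {
    if (is.data.frame(reference)) {
      if (!all(c("row", "col", "class") %in% names(reference))) {
        stopf("reference data frame needs columns row, col, class")
      }
      inside <- reference$row >= 1 & reference$row <= nrow(pred$labels) &
        reference$col >= 1 & reference$col <= ncol(pred$labels)
      if (!all(inside)) stopf("reference pixels fall outside the map")
      p <- pred$labels[cbind(reference$row, reference$col)]
      r <- class_code(reference$class)
    } else {
      p <- as.vector(pred$labels)
      r <- as.integer(reference)
    }
  } else {
    p <- as.integer(pred)
    r <- as.integer(reference)
  }
  keep <- !is.na(p) & !is.na(r) & r != LAKE_CLASSES[["nodata"]]
  p <- p[keep]; r <- r[keep]
  if (!length(p)) stopf("empty reference set")
  classes <- sort(union(unique(p), unique(r)))
  classes <- setdiff(classes, LAKE_CLASSES[["nodata"]])
  tab <- table(factor(p, levels = classes), factor(r, levels = classes))
  tab <- unclass(tab)
  dimnames(tab) <- list(predicted = class_name(classes),
                        reference = class_name(classes))
  n <- sum(tab)
  diag_counts <- diag(tab)
  row_tot <- rowSums(tab); col_tot <- colSums(tab)
  oa <- sum(diag_counts) / n
  ua <- ifelse(row_tot > 0, diag_counts / row_tot, NA_real_)
  pa <- ifelse(col_tot > 0, diag_counts / col_tot, NA_real_)
  pe <- sum(as.numeric(row_tot) * as.numeric(col_tot)) / n^2
  kappa <- if (pe < 1) (oa - pe) / (1 - pe) else 1
  structure(list(table = tab, oa = oa, ua = ua, pa = pa, kappa = kappa,
                 n = n, mean_ua = mean(ua, na.rm = TRUE),
                 mean_pa = mean(pa, na.rm = TRUE)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> n = %d, OA = %.3f, kappa = %.3f\n", x$n, x$oa, x$kappa))
  print(x$table)
  cat("UA:", paste(sprintf("%s %.3f", names(x$ua), x$ua), collapse = ", "), "\n")
  cat("PA:", paste(sprintf("%s %.3f", names(x$pa), x$pa), collapse = ", "), "\n")
  invisible(x)
}

#' McNemar comparison of two classifications
#'
#' Tests whether two classifiers differ on paired per-pixel correctness
#' against a common reference. With `b` = A-correct/B-wrong and `c` =
#' A-wrong/B-correct discordant counts, reports the continuity-corrected
#' chi-square `(|b - c| - 1)^2 / (b + c)`; the p-value uses the df-1
#' chi-square tail when `b + c >= 25` and the exact two-sided binomial
#' otherwise.
#'
#' @param predA,predB Two [class_map()]s (or label vectors) covering the
#'   reference pixels.
#' @param reference As in [confusion()].
#' @return List with `statistic`, `p_value`, `b`, `c`, `method`,
#'   `degenerate`.
#' @export
mcnemar <- function(predA, predB, reference) {
  get_labels <- function(pred) {
    if (inherits(pred, "class_map")) {
      if (is.data.frame(reference)) {
        pred$labels[cbind(reference$row, reference$col)]
      } else as.vector(pred$labels)
    } else as.integer(pred)
  }
  a <- get_labels(predA); bb <- get_labels(predB)
  r <- if (is.data.frame(reference)) class_code(reference$class) else as.integer(reference)
  keep <- r != LAKE_CLASSES[["nodata"]] & !is.na(a) & !is.na(bb)
  a <- a[keep]; bb <- bb[keep]; r <- r[keep]
  if (!length(r)) stopf("empty reference set")
  b <- sum(a == r & bb != r)
  c_ <- sum(a != r & bb == r)
  if (b + c_ == 0L) {
    return(list(statistic = 0, p_value = 1, b = b, c = c_,
                method = "degenerate", degenerate = TRUE))
  }
  stat <- (abs(b - c_) - 1)^2 / (b + c_)
  if (b + c_ >= 25L) {
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-square with continuity correction"
  } else {
    m <- min(b, c_); nn <- b + c_
    p <- min(1, 2 * sum(dbinom(0:m, nn, 0.5)))
    method <- "exact binomial"
  }
  list(statistic = stat, p_value = p, b = b, c = c_, method = method,
       degenerate = FALSE)
}

#' Per-scene method selection
#'
#' Picks between two assessed classifications the way a per-scene
#' accuracy-comparison table is read: a method dominating on both OA and
#' kappa wins outright; when OA and kappa disagree and the McNemar
#' difference is not significant (p > 0.05), the higher kappa wins (ties
#' fall back to higher mean UA, then to method A).
#'
#' @param metricsA,metricsB [confusion()] results for methods A and B.
#' @param mcnemar_p McNemar p-value comparing the two maps.
#' @param names Length-2 labels for the methods.
#' @return List with `choice` (1 or 2), `name`, `rationale`.
#' @export
select_method <- function(metricsA, metricsB, mcnemar_p = NA_real_,
                          names = c("A", "B")) {
  a <- metricsA; b <- metricsB
  pick <- function(i, why) {
    lake_log(sprintf("selected %s: %s", names[i], why))
    list(choice = i, name = names[i], rationale = why)
  }
  if (a$oa > b$oa && a$kappa > b$kappa) {
    return(pick(1, sprintf("dominates on OA (%.3f > %.3f) and kappa (%.3f > %.3f)",
                           a$oa, b$oa, a$kappa, b$kappa)))
  }
  if (b$oa > a$oa && b$kappa > a$kappa) {
    return(pick(2, sprintf("dominates on OA (%.3f > %.3f) and kappa (%.3f > %.3f)",
                           b$oa, a$oa, b$kappa, a$kappa)))
  }
  if (!is.na(mcnemar_p) && mcnemar_p > 0.05) {
    if (a$kappa != b$kappa) {
      i <- if (a$kappa > b$kappa) 1 else 2
      return(pick(i, sprintf(
        "OA and kappa disagree, difference not significant (p = %.3f); higher kappa wins",
        mcnemar_p)))
    }
    if (!isTRUE(all.equal(a$mean_ua, b$mean_ua))) {
      i <- if (a$mean_ua > b$mean_ua) 1 else 2
      return(pick(i, "kappa tied; higher mean user's accuracy wins"))
    }
    return(pick(1, "all metrics tied; method A by declared tie-break"))
  }
  # metrics split and no (or significant) McNemar: fall back to kappa, then OA
  if (a$kappa != b$kappa) {
    i <- if (a$kappa > b$kappa) 1 else 2
    return(pick(i, "mixed dominance; higher kappa wins"))
  }
  if (a$oa != b$oa) {
    i <- if (a$oa > b$oa) 1 else 2
    return(pick(i, "kappa tied; higher OA wins"))
  }
  pick(1, "all metrics tied; method A by declared tie-break")
}

#' Jeffries-Matusita separability of two training classes
#'
#' `JM = 2 (1 - exp(-B))` with `B` the Bhattacharyya distance between the
#' Gaussian fits of the two classes; the conventional remote-sensing
#' separability on the [0, 2] scale (values above ~1.9 indicate excellent
#' sample separability).
#'
#' @param train A [training_set()].
#' @param class_a,class_b Class names or codes.
#' @param epsilon Covariance ridge passed to [fit_mlc()].
#' @return JM distance in [0, 2].
#' @export
separability <- function(train, class_a, class_b, epsilon = NULL) {
  stopifnot(inherits(train, "training_set"))
  models <- fit_mlc(train, epsilon)
  codes <- vapply(models, `[[`, 0L, "code")
  ma <- models[[match(class_code(class_a), codes)]]
  mb <- models[[match(class_code(class_b), codes)]]
  s <- (ma$cov + mb$cov) / 2
  dmu <- ma$mean - mb$mean
  chs <- tryCatch(chol(s), error = function(e)
    stopf("pooled covariance singular; refit with a larger epsilon"))
  z <- backsolve(chs, dmu, transpose = TRUE)
  logdet <- function(ch) 2 * sum(log(diag(ch)))
  bh <- sum(z^2) / 8 +
    0.5 * (logdet(chs) - 0.5 * (logdet(ma$chol) + logdet(mb$chol)))
  2 * (1 - exp(-bh))
}

#' All pairwise Jeffries-Matusita separabilities
#'
#' @inheritParams separability
#' @return Data frame with columns `class_a`, `class_b`, `jm`.
#' @export
separability_matrix <- function(train, epsilon = NULL) {
  k <- length(train$codes)
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    out[[length(out) + 1L]] <- data.frame(
      class_a = names(train$samples)[i], class_b = names(train$samples)[j],
      jm = separability(train, train$codes[i], train$codes[j], epsilon))
  }
  do.call(rbind, out)
}
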