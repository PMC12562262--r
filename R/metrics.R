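#' Canonical class ordering for heart-sound labels
#'
#' Binary tasks order as (normal, abnormal) with "abnormal" the positive
#' class; three-class murmur tasks as (present, unknown, absent), the
#' ordering the class-weighted accuracy convention expects. Any other label
#' set is sorted alphabetically.
#'
#' @param labels Character vector of labels.
#' @return Character vector of class levels.
#' @export
class_levels <- function(labels) {
  u <- unique(as.character(labels))
  if (setequal(u, c("normal", "abnormal"))) return(c("normal", "abnormal"))
  if (setequal(u, c("present", "absent", "unknown"))) {
    return(c("present", "unknown", "absent"))
  }
  sort(u)
}

default_positive <- function(classes) {
  if ("abnormal" %in% classes) "abnormal"
  else if ("present" %in% classes) "present"
  else classes[length(classes)]
}

#' Confusion matrix and the evaluation metric suite
#'
#' Binary mode computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' `F1 = 2TP/(2TP+FP+FN)`, accuracy and `score = (sensitivity +
#' specificity)/2` from the positive-class counts. Multi-class mode reports
#' the same quantities as macro averages of per-class one-vs-rest values,
#' plus class-weighted accuracy (see [weighted_accuracy()]). A class absent
#' from the truth has undefined one-vs-rest sensitivity; it is dropped from
#' the macro mean with a warning.
#'
#' @param truth,pred Equal-length label vectors.
#' @param positive Positive class for binary mode (default "abnormal" /
#'   "present" when recognized).
#' @param classes Class levels; defaults to [class_levels()] of the truth.
#' @param class_weights Weights for [weighted_accuracy()], named by class;
#'   defaults to the murmur convention (present 5, unknown 3, absent 1) in
#'   three-class mode and equal weights otherwise.
#' @return An object of class `pcg_metrics`: confusion matrix, counts and a
#'   named list of metric fractions in [0, 1].
#' @export
compute_metrics <- function(truth, pred, positive = NULL, classes = NULL,
                            class_weights = NULL) {
  if (length(truth) == 0 || length(truth) != length(pred)) {
    stop("truth and pred must be equal-length, non-empty", call. = FALSE)
  }
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- classes %||% class_levels(truth)
  if (!all(pred %in% classes) || !all(truth %in% classes)) {
    stop("labels outside the class set", call. = FALSE)
  }
  K <- length(classes)
  conf <- table(factor(truth, classes), factor(pred, classes))
  conf <- matrix(as.numeric(conf), K, K, dimnames = dimnames(conf))

  if (is.null(class_weights)) {
    class_weights <- if (setequal(classes, c("present", "unknown", "absent"))) {
      c(present = 5, unknown = 3, absent = 1)[classes]
    } else {
      stats::setNames(rep(1, K), classes)
    }
  }

  if (K == 2) {
    positive <- positive %||% default_positive(classes)
    neg <- setdiff(classes, positive)
    TP <- conf[positive, positive]; FN <- conf[positive, neg]
    TN <- conf[neg, neg]; FP <- conf[neg, positive]
    sens <- TP / (TP + FN)
    spec <- TN / (TN + FP)
    f1 <- 2 * TP / (2 * TP + FP + FN)
    acc <- (TP + TN) / (TP + TN + FP + FN)
    metrics <- list(accuracy = acc, sensitivity = sens, specificity = spec,
                    f1 = f1, score = (sens + spec) / 2,
                    weighted_accuracy = weighted_accuracy(conf, class_weights))
    counts <- list(TP = TP, TN = TN, FP = FP, FN = FN)
    per_class <- NULL
  } else {
    n <- sum(conf)
    present_in_truth <- rowSums(conf) > 0
    per_class <- purrr::map_dfr(seq_len(K), function(i) {
      TP <- conf[i, i]
      FN <- sum(conf[i, -i])
      FP <- sum(conf[-i, i])
      TN <- n - TP - FN - FP
      tibble::tibble(
        class = classes[i],
        sensitivity = if (present_in_truth[i]) TP / (TP + FN) else NA_real_,
        specificity = TN / (TN + FP),
        f1 = if (present_in_truth[i]) 2 * TP / (2 * TP + FP + FN) else NA_real_
      )
    })
    if (any(!present_in_truth)) {
      warning("class(es) absent from truth excluded from macro averages: ",
              paste(classes[!present_in_truth], collapse = ", "),
              call. = FALSE)
    }
    sens <- mean(per_class$sensitivity, na.rm = TRUE)
    spec <- mean(per_class$specificity[present_in_truth])
    f1 <- mean(per_class$f1, na.rm = TRUE)
    metrics <- list(accuracy = sum(diag(conf)) / n, sensitivity = sens,
                    specificity = spec, f1 = f1, score = (sens + spec) / 2,
                    weighted_accuracy = weighted_accuracy(conf, class_weights))
    counts <- NULL
  }
  structure(list(confusion = conf, classes = classes, counts = counts,
                 per_class = per_class, metrics = metrics,
                 n = length(truth)),
            class = "pcg_metrics")
}

#' Class-weighted accuracy
#'
#' `sum_c w_c * conf[c, c] / sum_c w_c * rowsum_c` for truth-classes `c`.
#' With equal weights this reduces to plain accuracy. The default weights
#' for the murmur task are present 5, unknown 3, absent 1.
#'
#' @param confusion Square confusion matrix, rows = truth.
#' @param weights Per-class weights, in row order of `confusion` (may be
#'   named to match its rownames).
#' @return A fraction in [0, 1].
#' @export
weighted_accuracy <- function(confusion, weights = NULL) {
  stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
  if (sum(confusion) == 0) stop("all-zero confusion matrix", call. = FALSE)
  K <- nrow(confusion)
  if (is.null(weights)) {
    weights <- if (!is.null(rownames(confusion)) &&
                   setequal(rownames(confusion),
                            c("present", "unknown", "absent"))) {
      c(present = 5, unknown = 3, absent = 1)[rownames(confusion)]
    } else rep(1, K)
  }
  if (!is.null(names(weights)) && !is.null(rownames(confusion))) {
    weights <- weights[rownames(confusion)]
  }
  sum(weights * diag(confusion)) / sum(weights * rowSums(confusion))
}

#' @export
print.pcg_metrics <- function(x, ...) {
  cat("Heart-sound classification metrics (n = ", x$n, ")\n", sep = "")
  print(x$confusion)
  m <- x$metrics
  cat(sprintf("accuracy %.4f | sensitivity %.4f | specificity %.4f | f1 %.4f | score %.4f | weighted acc %.4f\n",
              m$accuracy, m$sensitivity, m$specificity, m$f1, m$score,
              m$weighted_accuracy))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a metrics object into one row per metric
#'
#' @param x A `pcg_metrics` object.
#' @param ... Unused.
#' @return A tibble with columns `metric` and `value`.
#' @method tidy pcg_metrics
#' @export
tidy.pcg_metrics <- function(x, ...) {
  tibble::tibble(metric = names(x$metrics),
                 value = unlist(x$metrics, use.names = FALSE))
}

#' One-row summary of a metrics object
#'
#' @param x A `pcg_metrics` object.
#' @param ... Unused.
#' @return A one-row tibble of all metrics plus `n`.
#' @method glance pcg_metrics
#' @export
glance.pcg_metrics <- function(x, ...) {
  dplyr::bind_cols(tibble::as_tibble(x$metrics), tibble::tibble(n = x$n))
}
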