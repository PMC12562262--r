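#' Subject-wise test split and cross-validation folds
#'
#' Partitions *subjects* (never individual recordings): about
#' `test_frac` of subjects form a held-out test set, and the remaining
#' subjects are dealt into `n_folds` cross-validation folds. Within a fold,
#' the fold's subjects are the validation set and all other non-test
#' subjects the training set, so no subject ever appears in two subsets of
#' the same fold and no identity leaks between training and evaluation.
#'
#' @param data A data frame with a `subject_id` column (one row per
#'   recording), or a character vector of subject ids.
#' @param test_frac Fraction of subjects held out for final testing.
#' @param n_folds Number of cross-validation folds.
#' @param seed Integer seed; plans are deterministic given it.
#' @return A list of class `pcg_split_plan` with `test_subjects` and
#'   `folds`, each fold a list of `train_subjects` and `val_subjects`.
#' @export
make_splits <- function(data, test_frac = 0.1, n_folds = 10L, seed = 1L) {
  subjects <- if (is.data.frame(data)) unique(data$subject_id)
              else unique(as.character(data))
  n <- length(subjects)
  if (n < n_folds + 1L) {
    stop("need at least n_folds + 1 = ", n_folds + 1L,
         " distinct subjects, got ", n, call. = FALSE)
  }
  set.seed(seed)
  shuffled <- sample(subjects)
  n_test <- max(1L, round(test_frac * n))
  test_subjects <- shuffled[seq_len(n_test)]
  rest <- shuffled[-seq_len(n_test)]
  assign <- rep(seq_len(n_folds), length.out = length(rest))
  folds <- lapply(seq_len(n_folds), function(f) {
    list(train_subjects = rest[assign != f],
         val_subjects = rest[assign == f])
  })
  structure(list(test_subjects = test_subjects, folds = folds,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "pcg_split_plan")
}

#' @export
print.pcg_split_plan <- function(x, ...) {
  cat("Subject-wise split plan: ", length(x$test_subjects),
      " test subject(s), ", x$n_folds, " folds\n", sep = "")
  invisible(x)
}
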