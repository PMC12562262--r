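#' Training configuration
#'
#' The optimization protocol: Adam at a fixed learning rate of 0.008 with
#' no scheduling, batch size 32, up to 400 epochs, early stopping on
#' validation performance with patience 15 and best-epoch weight restore.
#' The monitored quantity is validation accuracy (class-weighted accuracy
#' for the three-class task), i.e. a maximized validation performance.
#'
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience in epochs.
#' @param class_weighting Use inverse-frequency sample weights in the loss.
#' @param seed Integer seed for shuffling.
#' @param verbose Print a line per epoch.
#' @return A list of class `pcg_train_config`.
#' @export
train_config <- function(lr = 0.008, batch_size = 32L, max_epochs = 400L,
                         patience = 15L, class_weighting = FALSE,
                         seed = 1L, verbose = FALSE) {
  if (lr <= 0) stop("lr must be positive", call. = FALSE)
  if (patience >= max_epochs) stop("patience must be < max_epochs", call. = FALSE)
  structure(
    list(lr = lr, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         class_weighting = isTRUE(class_weighting), seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "pcg_train_config"
  )
}

one_hot <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

# forward a list of per-record patch stacks in chunks; returns probs matrix
forward_in_chunks <- function(params, cfg, Xs_all, Xl_all, idx, chunk = 64L) {
  nps <- cfg$branch_small$n_patches
  npl <- cfg$branch_large$n_patches
  out <- vector("list", ceiling(length(idx) / chunk))
  for (ci in seq_along(out)) {
    ids <- idx[((ci - 1L) * chunk + 1L):min(ci * chunk, length(idx))]
    rows_s <- as.vector(outer(seq_len(nps), (ids - 1L) * nps, `+`))
    rows_l <- as.vector(outer(seq_len(npl), (ids - 1L) * npl, `+`))
    pt <- list(Xs = Xs_all[rows_s, , drop = FALSE],
               Xl = Xl_all[rows_l, , drop = FALSE], B = length(ids))
    out[[ci]] <- nn_forward(params, cfg, pt)$probs
  }
  do.call(rbind, out)
}

monitor_metric <- function(truth, pred, classes) {
  conf <- table(factor(truth, classes), factor(pred, classes))
  conf <- matrix(as.numeric(conf), length(classes), length(classes),
                 dimnames = list(classes, classes))
  if (length(classes) == 3) weighted_accuracy(conf) else
    sum(diag(conf)) / sum(conf)
}

#' Train the model on one cross-validation fold
#'
#' Minibatch Adam on the fold's training subjects with per-epoch evaluation
#' on its validation subjects. Training stops at `max_epochs` or once the
#' monitored validation metric has not improved for `patience` consecutive
#' epochs, and the weights of the best validation epoch are restored.
#' Per-channel standardization statistics are computed on the training
#' records only and stored in the model for inference.
#'
#' @param model A freshly built `pcg_model` (see [build_model()]).
#' @param data Manifest tibble with list-column `image` (from
#'   [extract_features()]), plus `label` and `subject_id`.
#' @param fold A list with `train_subjects` and `val_subjects` (one element
#'   of a [make_splits()] plan).
#' @param cfg A [train_config()].
#' @return The trained model; `$history` holds a per-epoch tibble and
#'   `$best_epoch`, `$best_val` the restored optimum.
#' @export
train_model <- function(model, data, fold, cfg = train_config()) {
  stopifnot(inherits(model, "pcg_model"), is.data.frame(data))
  if (length(fold$train_subjects) == 0 || length(fold$val_subjects) == 0) {
    stop("fold subject sets must be non-empty", call. = FALSE)
  }
  classes <- model$classes %||% class_levels(data$label)
  if (length(classes) != model$cfg$n_classes) {
    stop("data has ", length(classes), " classes but the model head has ",
         model$cfg$n_classes, call. = FALSE)
  }
  model$classes <- classes

  tr_idx <- which(data$subject_id %in% fold$train_subjects)
  va_idx <- which(data$subject_id %in% fold$val_subjects)
  stats <- channel_stats(data$image[tr_idx])
  model$norm_stats <- stats
  images <- lapply(data$image, standardize_image, stats = stats)

  mcfg <- model$cfg
  all_pt <- precompute_patches(images, mcfg)
  nps <- mcfg$branch_small$n_patches
  npl <- mcfg$branch_large$n_patches
  Y <- one_hot(data$label, classes)

  w_sample <- NULL
  if (cfg$class_weighting) {
    freq <- table(factor(data$label[tr_idx], classes))
    wc <- sum(freq) / (length(classes) * pmax(as.numeric(freq), 1))
    names(wc) <- classes
    w_sample <- wc[data$label]
  }

  params <- model$params
  opt <- adam_init(params)
  best <- list(val = -Inf, epoch = 0L, params = params)
  since_best <- 0L
  hist <- vector("list", cfg$max_epochs)
  set.seed(cfg$seed)

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(tr_idx)
    n_batches <- ceiling(length(ord) / cfg$batch_size)
    tr_loss <- 0; tr_correct <- 0
    for (bi in seq_len(n_batches)) {
      ids <- ord[((bi - 1L) * cfg$batch_size + 1L):
                   min(bi * cfg$batch_size, length(ord))]
      rows_s <- as.vector(outer(seq_len(nps), (ids - 1L) * nps, `+`))
      rows_l <- as.vector(outer(seq_len(npl), (ids - 1L) * npl, `+`))
      pt <- list(Xs = all_pt$Xs[rows_s, , drop = FALSE],
                 Xl = all_pt$Xl[rows_l, , drop = FALSE], B = length(ids))
      fwd <- nn_forward(params, mcfg, pt, cache = TRUE)
      lg <- ce_loss_grad(fwd$probs, Y[ids, , drop = FALSE],
                         if (is.null(w_sample)) NULL else w_sample[ids])
      if (!is.finite(lg$loss)) {
        stop("non-finite training loss at epoch ", epoch,
             " batch ", bi, "; aborting", call. = FALSE)
      }
      grads <- nn_backward(params, mcfg, pt, fwd, lg$dlogits)
      st <- adam_step(params, grads, opt, lr = cfg$lr)
      params <- st$params; opt <- st$state
      tr_loss <- tr_loss + lg$loss * length(ids)
      tr_correct <- tr_correct +
        sum(max.col(fwd$probs, ties.method = "first") ==
              match(data$label[ids], classes))
    }
    tr_loss <- tr_loss / length(ord)
    tr_acc <- tr_correct / length(ord)

    va_probs <- forward_in_chunks(params, mcfg, all_pt$Xs, all_pt$Xl, va_idx)
    va_pred <- classes[max.col(va_probs, ties.method = "first")]
    va_lg <- ce_loss_grad(va_probs, Y[va_idx, , drop = FALSE])
    va_metric <- monitor_metric(data$label[va_idx], va_pred, classes)

    hist[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = tr_loss,
                                    train_acc = tr_acc, val_loss = va_lg$loss,
                                    val_acc = va_metric)
    if (cfg$verbose) {
      message(sprintf("epoch %3d  loss %.4f acc %.3f | val loss %.4f val acc %.3f",
                      epoch, tr_loss, tr_acc, va_lg$loss, va_metric))
    }
    if (va_metric > best$val) {
      best <- list(val = va_metric, epoch = epoch, params = params)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= cfg$patience) break
    }
  }

  model$params <- best$params
  model$history <- dplyr::bind_rows(hist)
  model$best_epoch <- best$epoch
  model$best_val <- best$val
  model
}

#' Evaluate a trained model on a subset of records
#'
#' @param model A trained `pcg_model`.
#' @param data Manifest tibble with `image` and `label`.
#' @param subjects Optional subject ids to restrict to (e.g. the held-out
#'   test subjects).
#' @return A `pcg_metrics` object.
#' @export
evaluate_model <- function(model, data, subjects = NULL) {
  if (!is.null(subjects)) data <- data[data$subject_id %in% subjects, ]
  if (nrow(data) == 0) stop("no records to evaluate", call. = FALSE)
  pred <- predict(model, data)
  compute_metrics(data$label, pred$.pred_class, classes = model$classes)
}

#' Cross-validated experiment with fusion-mode sweep
#'
#' The full protocol: a subject-wise split plan (held-out test subjects +
#' cross-validation folds), one model trained per fold per fusion mode, and
#' each fold-model evaluated on the common held-out test set. Mirrors the
#' fusion-ablation comparison: run with
#' `fusion_modes = c("attention", "average", "min", "max", "concat")` to
#' compare strategies on identical splits and seeds.
#'
#' @param data Manifest tibble with `image`, `label`, `subject_id`.
#' @param model_cfg A [model_config()] (its `fusion_mode` is overridden by
#'   each swept mode).
#' @param train_cfg A [train_config()].
#' @param fusion_modes Character vector of fusion modes to sweep.
#' @param test_frac,n_folds,seed Split-plan parameters ([make_splits()]).
#' @return A list of class `pcg_experiment` with tibbles `per_fold` and
#'   `summary` (mean and sd of each test metric by mode).
#' @export
run_experiment <- function(data, model_cfg = model_config(),
                           train_cfg = train_config(),
                           fusion_modes = "attention",
                           test_frac = 0.1, n_folds = 10L, seed = 1L) {
  plan <- make_splits(data, test_frac, n_folds, seed)
  classes <- class_levels(data$label)
  rows <- list()
  for (mode in fusion_modes) {
    mcfg <- model_cfg
    mcfg$fusion_mode <- mode
    for (f in seq_len(plan$n_folds)) {
      mcfg$seed <- model_cfg$seed + (f - 1L)
      model <- build_model(mcfg, classes = classes)
      fit <- train_model(model, data, plan$folds[[f]], train_cfg)
      met <- evaluate_model(fit, data, subjects = plan$test_subjects)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(fusion_mode = mode, fold = f,
                       best_epoch = fit$best_epoch,
                       epochs_run = nrow(fit$history),
                       val_acc = fit$best_val),
        glance(met)
      )
    }
  }
  per_fold <- dplyr::bind_rows(rows)
  summary <- per_fold |>
    dplyr::group_by(.data$fusion_mode) |>
    dplyr::summarise(dplyr::across(
      c("accuracy", "sensitivity", "specificity", "f1", "score",
        "weighted_accuracy"),
      list(mean = mean, sd = stats::sd)), .groups = "drop")
  structure(list(per_fold = per_fold, summary = summary, plan = plan,
                 model_cfg = model_cfg, train_cfg = train_cfg),
            class = "pcg_experiment")
}

#' @export
print.pcg_experiment <- function(x, ...) {
  cat("Cross-validated heart-sound experiment\n")
  print(x$summary)
  invisible(x)
}

#' Per-fold test metrics of an experiment
#'
#' @param x A `pcg_experiment`.
#' @param ... Unused.
#' @return The per-fold tibble.
#' @method tidy pcg_experiment
#' @export
tidy.pcg_experiment <- function(x, ...) x$per_fold

#' Aggregate experiment summary (mean and sd by fusion mode)
#'
#' @param x A `pcg_experiment`.
#' @param ... Unused.
#' @return The summary tibble.
#' @method glance pcg_experiment
#' @export
glance.pcg_experiment <- function(x, ...) x$summary
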