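#' Model configuration
#'
#' Assembles the full two-stream classifier: a small-patch branch (P = 4)
#' and a large-patch branch (P = 8) over the same 64 x 64 x 3 feature
#' image, a fusion stage, and a classifier head of two 64-unit ReLU layers
#' plus a softmax output.
#'
#' @param branch_small,branch_large [branch_config()]s for the two streams;
#'   they must share `embed_dim` so the pooled features align.
#' @param fusion_mode `"attention"` (the trainable attention fusion block)
#'   or one of the baselines `"average"`, `"min"`, `"max"`, `"concat"`.
#' @param n_classes 2 (normal/abnormal) or 3 (present/absent/unknown).
#' @param classifier_hidden Widths of the two hidden head layers.
#' @param seed Integer seed for weight initialization.
#' @return A list of class `pcg_model_config`.
#' @export
model_config <- function(branch_small = branch_config(patch_size = 4L),
                         branch_large = branch_config(patch_size = 8L),
                         fusion_mode = c("attention", "average", "min",
                                         "max", "concat"),
                         n_classes = 2L, classifier_hidden = c(64L, 64L),
                         seed = 1L) {
  fusion_mode <- match.arg(fusion_mode)
  if (branch_small$embed_dim != branch_large$embed_dim) {
    stop("branches must share embed_dim (fusion vectors must align)",
         call. = FALSE)
  }
  if (!n_classes %in% c(2L, 3L)) {
    stop("n_classes must be 2 or 3", call. = FALSE)
  }
  if (length(classifier_hidden) != 2L) {
    stop("classifier_hidden must give the two hidden layer widths",
         call. = FALSE)
  }
  structure(
    list(branch_small = branch_small, branch_large = branch_large,
         fusion_mode = fusion_mode, n_classes = as.integer(n_classes),
         classifier_hidden = as.integer(classifier_hidden),
         seed = as.integer(seed)),
    class = "pcg_model_config"
  )
}

#' Build the two-stream model
#'
#' Initializes all trainable parameters (Glorot uniform weights, zero
#' biases, unit LayerNorm gains) in a fixed draw order, so two builds from
#' the same configuration and seed are identical. Both branches consume the
#' same feature image.
#'
#' @param cfg A [model_config()].
#' @param classes Optional character vector of class labels (length
#'   `n_classes`); filled in by the trainer otherwise.
#' @return A list of class `pcg_model` with elements `params`, `cfg`,
#'   `classes`, `norm_stats`.
#' @export
build_model <- function(cfg = model_config(), classes = NULL) {
  if (!is.null(classes) && length(classes) != cfg$n_classes) {
    stop("classes must have length n_classes", call. = FALSE)
  }
  D <- cfg$branch_small$embed_dim
  head_in <- if (cfg$fusion_mode == "concat") 2L * D else D
  h1 <- cfg$classifier_hidden[1]; h2 <- cfg$classifier_hidden[2]
  set.seed(cfg$seed)
  params <- list(
    s = init_branch(cfg$branch_small),
    l = init_branch(cfg$branch_large)
  )
  if (cfg$fusion_mode == "attention") {
    params$fus <- list(k = init_kernel(D))
  }
  params$head <- list(
    W1 = glorot_uniform(head_in, h1), b1 = rep(0, h1),
    W2 = glorot_uniform(h1, h2), b2 = rep(0, h2),
    W3 = glorot_uniform(h2, cfg$n_classes), b3 = rep(0, cfg$n_classes)
  )
  structure(list(params = params, cfg = cfg, classes = classes,
                 norm_stats = NULL, history = NULL),
            class = "pcg_model")
}

#' Count trainable parameters at runtime
#'
#' Sum of the lengths of every registered parameter array in the built
#' model. [param_count_formula()] computes the same number in closed form
#' from the configuration alone; the two must agree exactly.
#'
#' @param model A [build_model()] result.
#' @return Integer scalar.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "pcg_model"))
  sum(unlist(rapply(model$params, length, how = "unlist")))
}

#' Closed-form parameter count
#'
#' Adds up, per branch: patch embedding `P^2 C x D`, class token `D`,
#' positional table `(Np + 1) D`, and per encoder block two LayerNorms
#' (`2D` each), four `D x D` projections with biases, and the two MLP
#' layers; plus the fusion kernel (`D`, attention mode only) and the
#' three-layer head.
#'
#' @param cfg A [model_config()].
#' @return Integer scalar.
#' @export
param_count_formula <- function(cfg) {
  per_branch <- function(b) {
    D <- b$embed_dim; Np <- b$n_patches; pc <- b$patch_size^2 * b$input_shape[3]
    blk <- 2 * D +                       # LN1
      4 * (D * D + D) +                  # Wq, Wk, Wv, Wo with biases
      2 * D +                            # LN2
      D * b$mlp_hidden + b$mlp_hidden +  # MLP in
      b$mlp_hidden * D + D               # MLP out
    pc * D + D + (Np + 1) * D + b$depth * blk
  }
  D <- cfg$branch_small$embed_dim
  head_in <- if (cfg$fusion_mode == "concat") 2 * D else D
  h1 <- cfg$classifier_hidden[1]; h2 <- cfg$classifier_hidden[2]
  head <- head_in * h1 + h1 + h1 * h2 + h2 + h2 * cfg$n_classes + cfg$n_classes
  kern <- if (cfg$fusion_mode == "attention") D else 0
  as.integer(per_branch(cfg$branch_small) + per_branch(cfg$branch_large) +
               kern + head)
}

#' Predict class probabilities for feature images
#'
#' Deterministic inference: both branches encode the (standardized) image,
#' the configured fusion merges the pooled features, and the head returns
#' softmax probabilities.
#'
#' @param object A trained or freshly built `pcg_model`.
#' @param images A single `64 x 64 x 3` array, a list of such arrays, or a
#'   manifest tibble with an `image` list-column.
#' @param ... Unused.
#' @return A tibble with `record_id` (when available), one probability
#'   column per class, and `.pred_class`.
#' @export
predict.pcg_model <- function(object, images, ...) {
  rid <- NULL
  if (is.data.frame(images)) {
    rid <- images$record_id
    images <- images$image
  } else if (is.array(images) && length(dim(images)) == 3) {
    images <- list(images)
  }
  shp <- object$cfg$branch_small$input_shape
  ok <- vapply(images, function(im) identical(dim(im), as.integer(shp)),
               logical(1))
  if (!all(ok)) {
    stop("images must be ", paste(shp, collapse = "x"), " arrays",
         call. = FALSE)
  }
  if (!is.null(object$norm_stats)) {
    images <- lapply(images, standardize_image, stats = object$norm_stats)
  }
  probs <- nn_forward(object$params, object$cfg,
                      precompute_patches(images, object$cfg))$probs
  cls <- object$classes %||% paste0("class", seq_len(object$cfg$n_classes))
  out <- tibble::as_tibble(as.data.frame(probs))
  names(out) <- paste0(".prob_", cls)
  out$.pred_class <- cls[max.col(probs, ties.method = "first")]
  if (!is.null(rid)) out <- dplyr::bind_cols(tibble::tibble(record_id = rid), out)
  out
}

#' Save a model checkpoint with a JSON config sidecar
#'
#' The checkpoint is an RDS file; `<path>.json` records the configuration,
#' class labels and parameter count, and [load_model()] verifies the stored
#' weights against it.
#'
#' @param model A `pcg_model`.
#' @param path Checkpoint path (e.g. `model.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "pcg_model"))
  saveRDS(model, path)
  sidecar <- list(
    fusion_mode = model$cfg$fusion_mode,
    n_classes = model$cfg$n_classes,
    classes = model$classes,
    patch_sizes = c(model$cfg$branch_small$patch_size,
                    model$cfg$branch_large$patch_size),
    embed_dim = model$cfg$branch_small$embed_dim,
    depth = model$cfg$branch_small$depth,
    heads = model$cfg$branch_small$heads,
    n_parameters = count_parameters(model)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a model checkpoint, verifying it against its sidecar
#'
#' @param path Checkpoint path written by [save_model()].
#' @return A `pcg_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    if (!identical(as.integer(side$n_parameters),
                   as.integer(count_parameters(model)))) {
      stop("checkpoint does not match its sidecar (parameter count)",
           call. = FALSE)
    }
    if (!identical(side$fusion_mode, model$cfg$fusion_mode)) {
      stop("checkpoint does not match its sidecar (fusion mode)",
           call. = FALSE)
    }
  }
  model
}

#' @export
print.pcg_model <- function(x, ...) {
  cfg <- x$cfg
  cat("Two-stream ViT heart-sound classifier\n")
  cat(sprintf("  branches: P=%d (%d patches) / P=%d (%d patches), D=%d, L=%d, h=%d\n",
              cfg$branch_small$patch_size, cfg$branch_small$n_patches,
              cfg$branch_large$patch_size, cfg$branch_large$n_patches,
              cfg$branch_small$embed_dim, cfg$branch_small$depth,
              cfg$branch_small$heads))
  cat(sprintf("  fusion: %s | classes: %s\n", cfg$fusion_mode,
              paste(x$classes %||% rep("?", cfg$n_classes), collapse = ", ")))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
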