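#' Global average pooling over patch tokens
#'
#' Mean of the patch-token rows of an encoded sequence, excluding the class
#' token in row 1, giving the length-D vector each fusion strategy consumes.
#'
#' @param tokens An `(Np + 1) x D` matrix whose first row is the class
#'   token, or an `Np x D` matrix with `has_class_token = FALSE`.
#' @param has_class_token Whether row 1 is a class token to exclude.
#' @return A length-D numeric vector.
#' @export
gap_tokens <- function(tokens, has_class_token = TRUE) {
  stopifnot(is.matrix(tokens))
  if (has_class_token) {
    if (nrow(tokens) < 2) stop("no patch tokens to pool", call. = FALSE)
    tokens <- tokens[-1, , drop = FALSE]
  } else if (nrow(tokens) < 1) {
    stop("no patch tokens to pool", call. = FALSE)
  }
  colMeans(tokens)
}

#' Attention fusion of two pooled feature vectors
#'
#' The trainable kernel `k` scores each stream elementwise
#' (`s = f * k`), a per-stream softmax over the D feature positions turns
#' scores into weights, and the weighted features of both streams are
#' summed: `fused = w_small * f_small + w_large * f_large`. With `k = 0`
#' both weight vectors are uniform `1/D`.
#'
#' @param f_small,f_large Length-D pooled features of the two branches.
#' @param k Length-D kernel.
#' @return A length-D fused feature vector.
#' @export
attention_fuse <- function(f_small, f_large, k) {
  if (length(f_small) != length(f_large) || length(k) != length(f_small)) {
    stop("f_small, f_large and k must share length D", call. = FALSE)
  }
  if (any(!is.finite(c(f_small, f_large, k)))) {
    stop("non-finite fusion inputs", call. = FALSE)
  }
  w_s <- softmax_vec(f_small * k)
  w_l <- softmax_vec(f_large * k)
  w_s * f_small + w_l * f_large
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Baseline fusion strategies
#'
#' The non-learned alternatives the ablation compares against: elementwise
#' average, min or max (length D) or concatenation (length 2D).
#'
#' @param f_small,f_large Length-D pooled features.
#' @param mode One of `"average"`, `"min"`, `"max"`, `"concat"`.
#' @return A numeric vector (length D, or 2D for `"concat"`).
#' @export
baseline_fuse <- function(f_small, f_large,
                          mode = c("average", "min", "max", "concat")) {
  mode <- match.arg(mode)
  switch(mode,
    average = (f_small + f_large) / 2,
    min = pmin(f_small, f_large),
    max = pmax(f_small, f_large),
    concat = c(f_small, f_large)
  )
}

#' Initialize the fusion kernel
#'
#' Glorot uniform draw for a `D x 1` parameter vector (fan_in = D,
#' fan_out = 1), trainable jointly with the rest of the network.
#'
#' @param D Feature dimension.
#' @param seed Optional seed; if `NULL` the current RNG state is used.
#' @return A length-D numeric vector.
#' @export
init_kernel <- function(D, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as.vector(glorot_uniform(D, 1))
}

# fused-vector gradients used by the training loop; returns grads wrt both
# stream features and the kernel given the upstream gradient d_fused.
# Shared by the finite-difference tests.
attention_fuse_grad <- function(f_small, f_large, k, d_fused) {
  grad_stream <- function(f, d) {
    w <- softmax_vec(f * k)
    dw <- d * f
    ds <- w * (dw - sum(dw * w))       # softmax backward
    list(df = d * w + ds * k, dk = ds * f)
  }
  gs <- grad_stream(f_small, d_fused)
  gl <- grad_stream(f_large, d_fused)
  list(df_small = gs$df, df_large = gl$df, dk = gs$dk + gl$dk)
}
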