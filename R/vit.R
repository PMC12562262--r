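#' Transformer branch configuration
#'
#' One ViT branch of the two-stream model. With the default 64 x 64 x 3
#' feature image, the small branch (`patch_size = 4`) sees 256 patches and
#' the large branch (`patch_size = 8`) sees 64 patches; both embed into
#' `embed_dim = 64` and stack `depth = 5` pre-LN encoder blocks.
#'
#' @param patch_size Patch edge length P in pixels.
#' @param embed_dim Token dimension D.
#' @param depth Number of encoder blocks L.
#' @param heads Number of attention heads h (must divide `embed_dim`).
#' @param mlp_hidden Hidden width of the encoder MLP (default `4 * embed_dim`).
#' @param input_shape Image shape `c(H, W, C)`.
#' @return A list of class `pcg_branch_config` with derived fields
#'   `n_patches` and `head_dim`.
#' @export
branch_config <- function(patch_size = 4L, embed_dim = 64L, depth = 5L,
                          heads = 4L, mlp_hidden = 4L * embed_dim,
                          input_shape = c(64L, 64L, 3L)) {
  H <- input_shape[1]; W <- input_shape[2]
  if (H %% patch_size != 0 || W %% patch_size != 0) {
    stop("image dimensions must be divisible by patch_size", call. = FALSE)
  }
  if (embed_dim %% heads != 0) {
    stop("embed_dim must be divisible by heads", call. = FALSE)
  }
  structure(
    list(patch_size = as.integer(patch_size), embed_dim = as.integer(embed_dim),
         depth = as.integer(depth), heads = as.integer(heads),
         mlp_hidden = as.integer(mlp_hidden),
         input_shape = as.integer(input_shape),
         n_patches = as.integer(H * W / patch_size^2),
         head_dim = as.integer(embed_dim / heads)),
    class = "pcg_branch_config"
  )
}

#' Glorot (Xavier) uniform initialization
#'
#' Draws from `U(-l, l)` with `l = sqrt(6 / (fan_in + fan_out))`. For a
#' weight matrix the fans are its row and column counts.
#'
#' @param nrow,ncol Matrix dimensions.
#' @return An `nrow x ncol` matrix.
#' @export
glorot_uniform <- function(nrow, ncol) {
  l <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -l, l), nrow, ncol)
}

#' Split an image into flattened patches
#'
#' Non-overlapping `P x P` patches ordered left-to-right, top-to-bottom;
#' each row of the result is one patch flattened in array (column-major,
#' channel-last) order. [unpatchify()] inverts the operation exactly.
#'
#' @param image An `H x W x C` array.
#' @param patch_size Patch edge length P; H and W must be divisible by it.
#' @return An `Np x (P^2 * C)` matrix with `Np = H * W / P^2`.
#' @export
patchify <- function(image, patch_size) {
  d <- dim(image)
  if (length(d) != 3) stop("image must be an H x W x C array", call. = FALSE)
  H <- d[1]; W <- d[2]; C <- d[3]; P <- patch_size
  if (H %% P != 0 || W %% P != 0) {
    stop("image dimensions (", H, "x", W, ") not divisible by patch size ", P,
         call. = FALSE)
  }
  gh <- H %/% P; gw <- W %/% P
  out <- matrix(0, gh * gw, P * P * C)
  k <- 0L
  for (i in seq_len(gh)) {          # top to bottom
    for (j in seq_len(gw)) {        # left to right
      k <- k + 1L
      out[k, ] <- as.vector(image[(i - 1L) * P + seq_len(P),
                                  (j - 1L) * P + seq_len(P), , drop = FALSE])
    }
  }
  out
}

#' Reassemble an image from flattened patches
#'
#' @param patches An `Np x (P^2 * C)` matrix from [patchify()].
#' @param patch_size Patch edge length P.
#' @param image_shape The original `c(H, W, C)`.
#' @return An `H x W x C` array.
#' @export
unpatchify <- function(patches, patch_size, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]; C <- image_shape[3]
  P <- patch_size
  gh <- H %/% P; gw <- W %/% P
  img <- array(0, dim = c(H, W, C))
  k <- 0L
  for (i in seq_len(gh)) {
    for (j in seq_len(gw)) {
      k <- k + 1L
      img[(i - 1L) * P + seq_len(P), (j - 1L) * P + seq_len(P), ] <-
        array(patches[k, ], dim = c(P, P, C))
    }
  }
  img
}

#' Embed patches, prepend the class token, add positions
#'
#' Row 1 of the result is the class token plus its positional vector; row
#' `i + 1` is `patches[i, ] %*% E` plus positional vector `i + 1`.
#'
#' @param patches `Np x (P^2 C)` matrix.
#' @param E `(P^2 C) x D` embedding matrix.
#' @param cls `1 x D` class token.
#' @param pos `(Np + 1) x D` positional embedding matrix.
#' @return An `(Np + 1) x D` token matrix.
#' @export
embed_sequence <- function(patches, E, cls, pos) {
  if (ncol(patches) != nrow(E)) stop("patch width does not match E", call. = FALSE)
  if (nrow(pos) != nrow(patches) + 1L || ncol(pos) != ncol(E)) {
    stop("positional embedding must be (Np + 1) x D", call. = FALSE)
  }
  rbind(cls, patches %*% E) + pos
}

# subtracting the global max is enough for overflow stability and far
# cheaper than a per-row max; underflow to 0 is harmless here
softmax_rows <- function(x) {
  e <- exp(x - max(x))
  e / rowSums(e)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(dk)) V`, the softmax taken within each query row.
#'
#' @param Q,K,V Matrices with the same row count; `ncol(Q) == ncol(K)`.
#' @return A matrix of shape `nrow(Q) x ncol(V)`.
#' @export
scaled_dot_attention <- function(Q, K, V) {
  if (ncol(Q) != ncol(K)) stop("dq must equal dk", call. = FALSE)
  A <- softmax_rows(Q %*% t(K) / sqrt(ncol(K)))
  A %*% V
}

#' Multi-head self-attention
#'
#' Projects tokens to per-head queries/keys/values (head `i` owns columns
#' `(i-1)*ds + 1 .. i*ds` of the joint D x D projections), runs scaled
#' dot-product attention per head, concatenates the head outputs and
#' applies the output projection `U`.
#'
#' @param Z `(N + 1) x D` token matrix.
#' @param p Parameter list with `Wq, bq, Wk, bk, Wv, bv, Wo, bo`.
#' @param heads Number of heads.
#' @return A matrix of the same shape as `Z`.
#' @export
msa <- function(Z, p, heads) {
  D <- ncol(Z)
  if (D %% heads != 0) stop("embed_dim not divisible by heads", call. = FALSE)
  ds <- D %/% heads
  Q <- Z %*% p$Wq + rep(1, nrow(Z)) %*% t(p$bq)
  K <- Z %*% p$Wk + rep(1, nrow(Z)) %*% t(p$bk)
  V <- Z %*% p$Wv + rep(1, nrow(Z)) %*% t(p$bv)
  H <- matrix(0, nrow(Z), D)
  for (h in seq_len(heads)) {
    cols <- (h - 1L) * ds + seq_len(ds)
    H[, cols] <- scaled_dot_attention(Q[, cols, drop = FALSE],
                                      K[, cols, drop = FALSE],
                                      V[, cols, drop = FALSE])
  }
  H %*% p$Wo + rep(1, nrow(Z)) %*% t(p$bo)
}

layernorm <- function(x, g, b, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  xhat <- xc / sqrt(v + eps)
  sweep(sweep(xhat, 2, g, `*`), 2, b, `+`)
}

# sigmoid-approximate GELU (the fast x * sigmoid(1.702 x) variant)
gelu <- function(x) {
  x / (1 + exp(-1.702 * x))
}

#' One pre-LN transformer encoder block
#'
#' `Z' = MSA(LN(Z)) + Z` followed by `Zout = MLP(LN(Z')) + Z'`, where the
#' MLP is two fully connected layers with a GELU in between.
#'
#' @param Z `(N + 1) x D` token matrix.
#' @param p Block parameters: `ln1_g, ln1_b`, the [msa()] parameters,
#'   `ln2_g, ln2_b`, `Wm1, bm1, Wm2, bm2`.
#' @param heads Number of attention heads.
#' @param eps LayerNorm epsilon.
#' @return A matrix of the same shape as `Z`.
#' @export
encoder_block <- function(Z, p, heads, eps = 1e-6) {
  Zp <- Z + msa(layernorm(Z, p$ln1_g, p$ln1_b, eps), p, heads)
  ones <- rep(1, nrow(Z))
  H <- gelu(layernorm(Zp, p$ln2_g, p$ln2_b, eps) %*% p$Wm1 + ones %*% t(p$bm1))
  Zp + H %*% p$Wm2 + ones %*% t(p$bm2)
}

#' Run a full encoder branch over an embedded token sequence
#'
#' Applies the branch's `depth` encoder blocks in order; the class-token row
#' is retained in the output (downstream fusion pools the patch rows only).
#'
#' @param Z0 `(Np + 1) x D` embedded tokens from [embed_sequence()].
#' @param branch Branch parameters (`$blocks` list of block parameters).
#' @param cfg A [branch_config()].
#' @return The final `(Np + 1) x D` token matrix.
#' @export
encode <- function(Z0, branch, cfg) {
  Z <- Z0
  for (blk in branch$blocks) Z <- encoder_block(Z, blk, cfg$heads)
  Z
}

# parameter initialization for one branch (order of draws is fixed so a
# given seed reproduces the same network)
init_branch <- function(cfg) {
  D <- cfg$embed_dim
  pc <- cfg$patch_size^2 * cfg$input_shape[3]
  blocks <- lapply(seq_len(cfg$depth), function(l) {
    list(ln1_g = rep(1, D), ln1_b = rep(0, D),
         Wq = glorot_uniform(D, D), bq = rep(0, D),
         Wk = glorot_uniform(D, D), bk = rep(0, D),
         Wv = glorot_uniform(D, D), bv = rep(0, D),
         Wo = glorot_uniform(D, D), bo = rep(0, D),
         ln2_g = rep(1, D), ln2_b = rep(0, D),
         Wm1 = glorot_uniform(D, cfg$mlp_hidden), bm1 = rep(0, cfg$mlp_hidden),
         Wm2 = glorot_uniform(cfg$mlp_hidden, D), bm2 = rep(0, D))
  })
  list(E = glorot_uniform(pc, D),
       cls = glorot_uniform(1, D),
       pos = glorot_uniform(cfg$n_patches + 1L, D),
       blocks = blocks)
}
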