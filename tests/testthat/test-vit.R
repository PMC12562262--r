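test_that("patchify yields the documented patch counts and roundtrips", {
  img <- random_image(seed = 1)
  p4 <- patchify(img, 4L)
  p8 <- patchify(img, 8L)
  expect_identical(dim(p4), c(256L, 48L))
  expect_identical(dim(p8), c(64L, 192L))
  expect_equal(unpatchify(p4, 4L, dim(img)), img)
  expect_equal(unpatchify(p8, 8L, dim(img)), img)
  # single-patch case equals the flattened image
  small <- array(1:4, dim = c(2L, 2L, 1L))
  expect_equal(patchify(small, 2L), matrix(as.vector(small), 1))
  expect_error(patchify(img, 5L), "divisible")
})

test_that("patch rows are ordered left-to-right, top-to-bottom", {
  # mark each 4x4 block with its grid position (row-major index)
  img <- array(0, dim = c(8L, 8L, 1L))
  k <- 0
  for (i in 1:2) for (j in 1:2) {
    k <- k + 1
    img[(i - 1) * 4 + 1:4, (j - 1) * 4 + 1:4, 1] <- k
  }
  p <- patchify(img, 4L)
  expect_equal(p[, 1], c(1, 2, 3, 4))
})

test_that("embedded sequences have the two-branch dimensions", {
  img <- random_image(seed = 2)
  for (cfg in list(branch_config(4L), branch_config(8L))) {
    set.seed(9)
    br <- pcgvit:::init_branch(cfg)
    Z0 <- embed_sequence(patchify(img, cfg$patch_size), br$E, br$cls, br$pos)
    expect_identical(dim(Z0), c(cfg$n_patches + 1L, 64L))
  }
})

test_that("embedding is linear: zero patches and E give the token + positions", {
  cfg <- tiny_branch(4L)
  br <- local({ set.seed(1); pcgvit:::init_branch(cfg) })
  patches <- matrix(0, cfg$n_patches, cfg$patch_size^2 * 3L)
  Z0 <- embed_sequence(patches, br$E * 0, br$cls, br$pos)
  expected <- rbind(br$cls, matrix(0, cfg$n_patches, cfg$embed_dim)) + br$pos
  expect_equal(Z0, expected)
  expect_error(embed_sequence(patches, br$E[-1, ], br$cls, br$pos), "match")
})

test_that("scaled dot-product attention matches a per-query loop oracle", {
  set.seed(11)
  for (rep in 1:20) {
    m <- sample(2:8, 1); dk <- sample(2:6, 1); dv <- sample(2:6, 1)
    Q <- matrix(rnorm(m * dk), m); K <- matrix(rnorm(m * dk), m)
    V <- matrix(rnorm(m * dv), m)
    out <- scaled_dot_attention(Q, K, V)
    # independent oracle: per query, explicit weights and weighted sum
    oracle <- t(sapply(seq_len(m), function(i) {
      a <- sapply(seq_len(m), function(j) sum(Q[i, ] * K[j, ]) / sqrt(dk))
      w <- exp(a - max(a)); w <- w / sum(w)
      colSums(w * V)
    }))
    expect_equal(out, oracle, tolerance = 1e-12)
  }
})

test_that("attention degenerate cases: single token and identical keys", {
  set.seed(12)
  Q <- matrix(rnorm(4), 1); K <- matrix(rnorm(4), 1); V <- matrix(rnorm(3), 1)
  expect_equal(scaled_dot_attention(Q, K, V), V)   # softmax of scalar is 1
  m <- 6
  K2 <- matrix(rep(rnorm(4), each = m), m)         # all keys identical
  Q2 <- matrix(rnorm(m * 4), m); V2 <- matrix(rnorm(m * 3), m)
  out <- scaled_dot_attention(Q2, K2, V2)
  expect_equal(out, matrix(rep(colMeans(V2), each = m), m), tolerance = 1e-12)
})

test_that("attention outputs are convex combinations of value rows", {
  set.seed(13)
  for (rep in 1:10) {
    m <- sample(3:10, 1)
    Q <- matrix(rnorm(m * 4), m); K <- matrix(rnorm(m * 4), m)
    V <- matrix(rnorm(m * 5), m)
    out <- scaled_dot_attention(Q, K, V)
    for (j in seq_len(ncol(V))) {
      expect_true(all(out[, j] >= min(V[, j]) - 1e-12))
      expect_true(all(out[, j] <= max(V[, j]) + 1e-12))
    }
  }
})

test_that("msa equals a concatenate-then-project oracle over heads", {
  D <- 8L; heads <- 4L; ds <- D %/% heads; m <- 7L
  set.seed(14)
  p <- list(Wq = matrix(rnorm(D * D), D), bq = rnorm(D),
            Wk = matrix(rnorm(D * D), D), bk = rnorm(D),
            Wv = matrix(rnorm(D * D), D), bv = rnorm(D),
            Wo = matrix(rnorm(D * D), D), bo = rnorm(D))
  Z <- matrix(rnorm(m * D), m)
  out <- msa(Z, p, heads)
  Q <- Z %*% p$Wq + rep(1, m) %*% t(p$bq)
  K <- Z %*% p$Wk + rep(1, m) %*% t(p$bk)
  V <- Z %*% p$Wv + rep(1, m) %*% t(p$bv)
  headouts <- lapply(seq_len(heads), function(h) {
    cols <- (h - 1L) * ds + seq_len(ds)
    scaled_dot_attention(Q[, cols], K[, cols], V[, cols])
  })
  oracle <- do.call(cbind, headouts) %*% p$Wo + rep(1, m) %*% t(p$bo)
  expect_equal(out, oracle, tolerance = 1e-12)
})

test_that("single-head msa with identity projection is scaled_dot_attention", {
  D <- 6L; m <- 5L
  set.seed(15)
  p <- list(Wq = diag(D), bq = rep(0, D), Wk = diag(D), bk = rep(0, D),
            Wv = diag(D), bv = rep(0, D), Wo = diag(D), bo = rep(0, D))
  Z <- matrix(rnorm(m * D), m)
  expect_equal(msa(Z, p, 1L), scaled_dot_attention(Z, Z, Z), tolerance = 1e-12)
})

test_that("msa is equivariant to token permutations", {
  D <- 8L; m <- 9L
  set.seed(16)
  p <- list(Wq = matrix(rnorm(D * D), D), bq = rnorm(D),
            Wk = matrix(rnorm(D * D), D), bk = rnorm(D),
            Wv = matrix(rnorm(D * D), D), bv = rnorm(D),
            Wo = matrix(rnorm(D * D), D), bo = rnorm(D))
  Z <- matrix(rnorm(m * D), m)
  perm <- sample(m)
  expect_equal(msa(Z[perm, ], p, 2L), msa(Z, p, 2L)[perm, ], tolerance = 1e-12)
})

test_that("zeroing residual-branch outputs makes encoder blocks the identity", {
  cfg <- branch_config(4L)
  set.seed(17)
  br <- pcgvit:::init_branch(cfg)
  for (l in seq_along(br$blocks)) {
    br$blocks[[l]]$Wo <- br$blocks[[l]]$Wo * 0
    br$blocks[[l]]$bo <- br$blocks[[l]]$bo * 0
    br$blocks[[l]]$Wm2 <- br$blocks[[l]]$Wm2 * 0
    br$blocks[[l]]$bm2 <- br$blocks[[l]]$bm2 * 0
  }
  Z <- matrix(rnorm(257 * 64), 257)
  expect_equal(encoder_block(Z, br$blocks[[1]], cfg$heads), Z)
  expect_equal(encode(Z, br, cfg), Z)
})

test_that("encode preserves shape and equals a manual fold of blocks", {
  img <- random_image(seed = 18)
  for (P in c(4L, 8L)) {
    cfg <- branch_config(P, depth = 5L)
    set.seed(19)
    br <- pcgvit:::init_branch(cfg)
    Z0 <- embed_sequence(patchify(img, P), br$E, br$cls, br$pos)
    out <- encode(Z0, br, cfg)
    expect_identical(dim(out), c(cfg$n_patches + 1L, 64L))
    manual <- Reduce(function(Z, blk) encoder_block(Z, blk, cfg$heads),
                     br$blocks, Z0)
    expect_equal(out, manual)
  }
})

test_that("positional embeddings break patch-permutation invariance", {
  cfg <- tiny_branch(4L)
  set.seed(20)
  br <- pcgvit:::init_branch(cfg)
  img <- random_image(c(8L, 8L, 3L), seed = 21)
  patches <- patchify(img, 4L)
  perm <- c(2L, 1L, 3L, 4L)
  run <- function(pos) {
    a <- encode(embed_sequence(patches, br$E, br$cls, pos), br, cfg)
    b <- encode(embed_sequence(patches[perm, ], br$E, br$cls, pos), br, cfg)
    list(a = a, b = b)
  }
  # without positions: patch rows permute, class row unchanged
  r0 <- run(br$pos * 0)
  expect_equal(r0$b[-1, ], r0$a[-1, ][perm, ], tolerance = 1e-10)
  expect_equal(r0$b[1, ], r0$a[1, ], tolerance = 1e-10)
  # with positions: the permuted image encodes differently
  r1 <- run(br$pos)
  expect_gt(max(abs(r1$b[-1, ] - r1$a[-1, ][perm, ])), 1e-4)
})

test_that("branch parameter shapes follow the configuration arithmetic", {
  for (P in c(4L, 8L)) {
    cfg <- branch_config(P)
    set.seed(22)
    br <- pcgvit:::init_branch(cfg)
    expect_identical(dim(br$E), c(as.integer(P^2 * 3L), cfg$embed_dim))
    expect_identical(dim(br$pos), c(cfg$n_patches + 1L, cfg$embed_dim))
    expect_length(br$blocks, cfg$depth)
    blk <- br$blocks[[1]]
    expect_identical(dim(blk$Wq), c(64L, 64L))
    expect_identical(dim(blk$Wm1), c(64L, 256L))
    expect_identical(dim(blk$Wm2), c(256L, 64L))
  }
  expect_error(branch_config(4L, embed_dim = 62L), "divisible")
})
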