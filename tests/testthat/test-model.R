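test_that("builds are deterministic under seed and vary across seeds", {
  m1 <- build_model(model_config(seed = 5L))
  m2 <- build_model(model_config(seed = 5L))
  m3 <- build_model(model_config(seed = 6L))
  expect_identical(m1$params, m2$params)
  expect_false(identical(m1$params$s$E, m3$params$s$E))
})

test_that("runtime parameter count agrees with the closed form everywhere", {
  cfgs <- list(
    model_config(),
    model_config(fusion_mode = "concat"),
    model_config(fusion_mode = "average"),
    model_config(n_classes = 3L),
    tiny_model_cfg()
  )
  for (cfg in cfgs) {
    expect_identical(count_parameters(build_model(cfg)),
                     param_count_formula(cfg))
  }
})

test_that("tiny-config count equals an independently written sum", {
  # D=8, L=1, h=1, mlp=16, P=32 on 64x64x3, 2 classes, head 64/64
  b <- branch_config(32L, embed_dim = 8L, depth = 1L, heads = 1L,
                     mlp_hidden = 16L)
  cfg <- model_config(b, b, n_classes = 2L, classifier_hidden = c(64L, 64L))
  # written out term by term, independent of param_count_formula:
  embed <- (32^2 * 3) * 8        # E
  cls <- 8
  pos <- (4 + 1) * 8             # Np = 64*64/32^2 = 4
  block <- (2 * 8) + 4 * (8 * 8 + 8) + (2 * 8) + (8 * 16 + 16) + (16 * 8 + 8)
  branch <- embed + cls + pos + 1 * block
  kern <- 8
  head <- 8 * 64 + 64 + 64 * 64 + 64 + 64 * 2 + 2
  expect_identical(count_parameters(build_model(cfg)),
                   as.integer(2 * branch + kern + head))
})

test_that("doubling depth adds exactly two per-block counts", {
  mk <- function(L) {
    model_config(branch_config(4L, depth = L), branch_config(8L, depth = L))
  }
  c5 <- param_count_formula(mk(5L))
  c10 <- param_count_formula(mk(10L))
  per_block <- 2 * 64 + 4 * (64 * 64 + 64) + 2 * 64 +
    (64 * 256 + 256) + (256 * 64 + 64)
  expect_identical(c10 - c5, as.integer(2L * 5L * per_block))
})

test_that("parameter count is independent of the head split", {
  counts <- sapply(c(1L, 2L, 4L, 8L), function(h) {
    count_parameters(build_model(model_config(
      branch_config(4L, heads = h), branch_config(8L, heads = h))))
  })
  expect_true(all(counts == counts[1]))
})

test_that("predictions are simplex-valued, deterministic, batch-consistent", {
  m <- build_model(model_config(seed = 2L), classes = c("normal", "abnormal"))
  imgs <- lapply(1:4, function(i) random_image(seed = 30 + i))
  p <- predict(m, imgs)
  expect_equal(rowSums(as.matrix(p[, c(".prob_normal", ".prob_abnormal")])),
               rep(1, 4), tolerance = 1e-12)
  expect_identical(predict(m, imgs), p)            # no stochastic layers
  # batch prediction equals per-item prediction
  singles <- dplyr::bind_rows(lapply(imgs, function(im) predict(m, im)))
  expect_equal(as.data.frame(singles), as.data.frame(p), tolerance = 1e-12)
  expect_error(predict(m, random_image(c(32L, 32L, 3L))), "64x64x3")
})

test_that("concat fusion widens the first head layer to 128 inputs", {
  m <- build_model(model_config(fusion_mode = "concat"))
  expect_identical(nrow(m$params$head$W1), 128L)
})

test_that("batch order permutation only permutes the outputs", {
  cfg <- tiny_model_cfg()
  m <- build_model(cfg)
  imgs <- lapply(1:5, function(i) random_image(c(8L, 8L, 3L), seed = 40 + i))
  p1 <- pcgvit:::nn_forward(m$params, cfg,
                            pcgvit:::precompute_patches(imgs, cfg))$probs
  perm <- c(3L, 1L, 5L, 2L, 4L)
  p2 <- pcgvit:::nn_forward(m$params, cfg,
                            pcgvit:::precompute_patches(imgs[perm], cfg))$probs
  expect_equal(p2, p1[perm, ], tolerance = 1e-12)
})

test_that("batched forward reproduces the modular per-image composition", {
  cfg <- model_config(seed = 3L)
  m <- build_model(cfg)
  imgs <- lapply(1:2, function(i) random_image(seed = 50 + i))
  pt <- pcgvit:::precompute_patches(imgs, cfg)
  probs <- pcgvit:::nn_forward(m$params, cfg, pt)$probs
  ref <- t(sapply(imgs, function(im) {
    enc <- function(br, bcfg) {
      encode(embed_sequence(patchify(im, bcfg$patch_size), br$E, br$cls,
                            br$pos), br, bcfg)
    }
    fs <- gap_tokens(enc(m$params$s, cfg$branch_small))
    fl <- gap_tokens(enc(m$params$l, cfg$branch_large))
    fused <- attention_fuse(fs, fl, m$params$fus$k)
    hp <- m$params$head
    a1 <- pmax(fused %*% hp$W1 + hp$b1, 0)
    a2 <- pmax(a1 %*% hp$W2 + hp$b2, 0)
    lo <- a2 %*% hp$W3 + hp$b3
    e <- exp(lo - max(lo)); e / sum(e)
  }))
  expect_equal(probs, ref, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences for every parameter", {
  for (mode in c("attention", "concat")) {
    cfg <- tiny_model_cfg(fusion_mode = mode)
    m <- build_model(cfg)
    set.seed(60)
    imgs <- lapply(1:3, function(i) array(rnorm(8 * 8 * 3), dim = c(8, 8, 3)))
    Y <- pcgvit:::one_hot(c("a", "b", "a"), c("a", "b"))
    pt <- pcgvit:::precompute_patches(imgs, cfg)
    fwd <- pcgvit:::nn_forward(m$params, cfg, pt, cache = TRUE)
    lg <- pcgvit:::ce_loss_grad(fwd$probs, Y)
    gr <- pcgvit:::nn_backward(m$params, cfg, pt, fwd, lg$dlogits)
    fp <- flatten_params(m$params)
    fg <- flatten_params(gr)
    expect_identical(names(fp), names(fg))
    # end-to-end gradient reaches every parameter group (class tokens and
    # their positional rows excepted: they are pooled out by design)
    dead_ok <- grepl("\\.cls$", names(fg))
    nonzero <- vapply(fg, function(g) any(g != 0), logical(1))
    expect_true(all(nonzero | dead_ok))
    eps <- 1e-6
    set.seed(61)
    loss_at <- function(params) {
      pcgvit:::ce_loss_grad(pcgvit:::nn_forward(params, cfg, pt)$probs, Y)$loss
    }
    for (nm in names(fp)) {
      j <- sample(length(fp[[nm]]), 1)
      path <- strsplit(nm, ".", fixed = TRUE)[[1]]
      bump <- function(delta) {
        p2 <- m$params
        expr <- paste0("p2", paste0("[['", path, "']]", collapse = ""))
        v <- eval(parse(text = expr))
        v[j] <- v[j] + delta
        eval(parse(text = paste0(expr, " <- v")))
        p2
      }
      fd <- (loss_at(bump(eps)) - loss_at(bump(-eps))) / (2 * eps)
      an <- fg[[nm]][j]
      expect_equal(an, fd, tolerance = 1e-4,
                   label = paste0(mode, " grad ", nm, "[", j, "]"))
    }
  }
})

test_that("checkpoints roundtrip and are validated against the sidecar", {
  dir <- withr::local_tempdir()
  m <- build_model(tiny_model_cfg(), classes = c("normal", "abnormal"))
  path <- file.path(dir, "model.rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  # tamper with the sidecar: loading must fail
  side <- jsonlite::read_json(paste0(path, ".json"))
  side$n_parameters <- side$n_parameters + 1L
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(load_model(path), "sidecar")
})
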