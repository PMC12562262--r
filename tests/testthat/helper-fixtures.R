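# Shared fixtures. The expensive trained-model experiment is memoised in an
# environment so the learning smoke test and the fusion-ablation direction
# test share one set of real training runs.

tiny_branch <- function(patch_size = 4L) {
  branch_config(patch_size = patch_size, embed_dim = 8L, depth = 2L,
                heads = 2L, mlp_hidden = 16L, input_shape = c(8L, 8L, 3L))
}

tiny_model_cfg <- function(fusion_mode = "attention", seed = 42L) {
  model_config(tiny_branch(4L), tiny_branch(8L), fusion_mode = fusion_mode,
               n_classes = 2L, classifier_hidden = c(6L, 5L), seed = seed)
}

random_image <- function(shape = c(64L, 64L, 3L), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(prod(shape)), dim = shape)
}

# flatten a nested parameter list into a named list of leaves
flatten_params <- function(x, prefix = "") {
  if (is.list(x)) {
    out <- list()
    for (nm in names(x)) {
      out <- c(out, flatten_params(x[[nm]], paste0(prefix, nm, ".")))
    }
    out
  } else {
    stats::setNames(list(x), sub("\\.$", "", prefix))
  }
}

.fixture_env <- new.env(parent = emptyenv())

# the standard synthetic benchmark: 40 subjects, murmur SNR +10 dB, 2-fold
# subject-wise CV, up to 60 epochs; trained once for attention and average
# fusion and reused by every test that needs trained models
benchmark_experiment <- function() {
  if (is.null(.fixture_env$experiment)) {
    ds <- generate_dataset(synth_config(seed = 101L))
    feats <- extract_features(ds)
    .fixture_env$experiment <- run_experiment(
      feats, model_config(seed = 101L),
      train_config(max_epochs = 60L, seed = 101L),
      fusion_modes = c("attention", "average"),
      test_frac = 0.1, n_folds = 2L, seed = 101L
    )
  }
  .fixture_env$experiment
}

# small feature-extracted dataset for fast pipeline tests
small_feature_data <- function() {
  if (is.null(.fixture_env$small_data)) {
    ds <- generate_dataset(synth_config(n_subjects = 8L,
                                        records_per_subject = 2L,
                                        duration_range = c(5, 8),
                                        seed = 7L))
    .fixture_env$small_data <- extract_features(ds)
  }
  .fixture_env$small_data
}
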