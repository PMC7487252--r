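# Shared fixtures, built once per test run.

# Small, clean scenes whose stomata (60-90 px) fit entirely inside at least
# one stride-30 window, keeping detection geometry exact.
small_scene_config <- function(seed, n_stomata = 3L, width = 480L,
                               height = 400L) {
  synth_config(width_px = width, height_px = height, n_stomata = n_stomata,
               stoma_major_axis_px = c(60, 90), min_separation_px = 140,
               artifact_rate = 1, seed = seed)
}

small_scene <- function(seed, image_id = sprintf("scene_%03d", seed), ...) {
  generate_micrograph(small_scene_config(seed, ...), image_id)
}

.fixtures <- new.env(parent = emptyenv())

# A briefly trained basic_shallow classifier on clean synthetic patches,
# plus its held-out scenes; trained once and reused across tests.
fixture_classifier <- function() {
  if (!is.null(.fixtures$clf)) return(.fixtures)
  train_scenes <- lapply(1:3, function(i) small_scene(400 + i, n_stomata = 4L))
  ds <- build_training_set(train_scenes, patch_config(120L, 30L),
                           neg_pos_ratio = 6, seed = 1L)
  clf <- build_classifier(architecture_spec("basic_shallow"),
                          training_hyperparams("basic_shallow",
                                               learning_rate = 1e-3,
                                               batch_size = 16L, epochs = 40L,
                                               dropout_rate = 0.1, seed = 1L))
  .fixtures$clf <- train_classifier(clf, ds)
  .fixtures$train_scenes <- train_scenes
  .fixtures$ds <- ds
  .fixtures$heldout <- lapply(1:2, function(i) small_scene(500 + i,
                                                          n_stomata = 4L))
  .fixtures
}
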