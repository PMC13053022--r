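# Shared fixtures: tiny deterministic scenes and parameter presets.

# A scene with explicit, well-separated gaze directions on the 60-degree cap.
manual_scene <- function(features, target_index = 1L,
                         phantom_mask = rep(FALSE, nrow(features))) {
  features <- as.matrix(features)
  n <- nrow(features)
  angles <- seq(0, pi / 4, length.out = n)
  locs <- cbind(sin(angles), 0, cos(angles))
  if (any(phantom_mask)) {
    locs[phantom_mask, ] <- matrix(c(0, 0, 1), sum(phantom_mask), 3,
                                   byrow = TRUE)
    features[phantom_mask, ] <- 0
  }
  scene(
    object_ids = sprintf("o%d", seq_len(n)),
    locations = locs,
    features = features,
    target_index = target_index,
    phantom_mask = phantom_mask
  )
}

tiny_params <- function(theta = 0.9, budget = 12L, ...) {
  meta_mdp_params(theta = theta, fixation_budget = budget, ...)
}

small_ensemble <- function(n_scenes = 8L, n_objects = 8L, n_features = 2L,
                           seed = 101L, similarity = 0) {
  gen <- scene_generator_config(n_objects = c(n_objects, n_objects),
                                n_features = n_features,
                                distractor_similarity = similarity)
  generate_scenes(gen, n_scenes, seed = seed)
}
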