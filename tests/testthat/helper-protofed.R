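# Shared fixtures: all data is generated in code at test time.

# Small in-memory synthetic dataset for pipeline tests; valid_frac is kept
# high so every class clears the 2-way 2-shot 2-query validation episodes.
tiny_synth <- function(n = 100, image_size = 16, seed = 42,
                       props = c(0.2, 0.2, 0.2, 0.2, 0.2),
                       depth_range = c(4, 9), valid_frac = 0.3) {
  cfg <- synth_config(n_exams = n, class_proportions = props,
                      depth_range = depth_range, image_size = image_size,
                      signal_strength = 5, noise_sd = 1,
                      valid_frac = valid_frac, seed = seed)
  generate_index(cfg)
}

# Desk-scale training configuration for fast tests.
tiny_train_cfg <- function(..., out_size = 16) {
  defaults <- list(tasks_per_epoch_train = 3L, tasks_per_epoch_val = 2L,
                   epochs = 1L, n_query = 2L, k_shot = 2L,
                   val_n_way = 2L, val_k_shot = 2L, val_n_query = 2L,
                   augment = augment_config(out_size = out_size))
  do.call(train_config, utils::modifyList(defaults, list(...)))
}

# Random raw volume (depth, H, W).
rand_volume <- function(D, H = 8, W = 8, seed = 1) {
  with_rng(rng_stream(seed), array(stats::rnorm(D * H * W), dim = c(D, H, W)))
}

expect_same_weights <- function(w1, w2, tol = 0) {
  expect_identical(names(w1), names(w2))
  for (nm in names(w1)) {
    if (tol == 0) {
      expect_identical(w1[[nm]], w2[[nm]])
    } else {
      expect_equal(w1[[nm]], w2[[nm]], tolerance = tol)
    }
  }
}
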