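# Independent brute-force oracle for the slice-standardization rule: place
# output slice j at fractional position j*(D-1)/(T-1); copy at integers,
# otherwise combine the two neighbours with fixed weights 0.2 (preceding)
# and 0.8 (subsequent).
oracle_standardize <- function(v, T) {
  D <- dim(v)[1]
  out <- array(NA_real_, dim = c(T, dim(v)[2], dim(v)[3]))
  for (j in 0:(T - 1)) {
    p <- j * (D - 1) / (T - 1)
    if (abs(p - round(p)) < 1e-12) {
      out[j + 1, , ] <- v[round(p) + 1, , ]
    } else {
      out[j + 1, , ] <- 0.2 * v[floor(p) + 1, , ] + 0.8 * v[floor(p) + 2, , ]
    }
  }
  out
}

test_that("slice standardization yields 15 slices with the 0.2/0.8 weighting", {
  for (D in c(17, 23, 37, 61)) {
    v <- rand_volume(D, seed = D)
    s <- standardize_slices(v)
    expect_identical(dim(s), c(15L, 8L, 8L))
    expect_equal(s, oracle_standardize(v, 15))
    # endpoints are exact copies (positions 0 and D-1 are integers)
    expect_identical(s[1, , ], v[1, , ])
    expect_identical(s[15, , ], v[D, , ])
    # convexity: output bounded by input extrema
    expect_true(min(s) >= min(v) - 1e-12)
    expect_true(max(s) <= max(v) + 1e-12)
  }
})

test_that("slice standardization handles degenerate inputs per contract", {
  # 2-slice toy with scalar slices 0 and 10: every interior position is
  # strictly between the two originals, so the fixed weights give 8
  v <- array(c(0, 10), dim = c(2, 1, 1))
  s <- standardize_slices(v)
  expect_equal(as.vector(s), c(0, rep(0.2 * 0 + 0.8 * 10, 13), 10))

  # constant volume stays constant (convex combination, up to float rounding)
  vc <- array(3.5, dim = c(20, 4, 4))
  expect_equal(max(abs(standardize_slices(vc) - 3.5)), 0, tolerance = 1e-12)

  expect_error(standardize_slices(array(1, dim = c(1, 4, 4))), "too few slices")
  expect_error(standardize_slices(rand_volume(5), target_depth = 1), "target_depth")
  expect_error(standardize_slices(array(c(NA, 1), dim = c(2, 1, 1))), "non-finite")
  # non-default target depth
  expect_identical(dim(standardize_slices(rand_volume(9), 21))[1], 21L)
})

test_that("intensity normalization scales to [0,1] and replicates 3 channels", {
  v <- rand_volume(5) * 100 + 50
  p <- preprocess_volume(v)
  expect_identical(dim(p), c(3L, 5L, 8L, 8L))
  expect_equal(min(p), 0)
  expect_equal(max(p), 1)
  expect_identical(p[1, , , ], p[2, , , ])
  expect_identical(p[1, , , ], p[3, , , ])

  # constant volume maps to all zeros by convention
  expect_true(all(preprocess_volume(array(7, dim = c(4, 3, 3))) == 0))

  # already-normalized volume is unchanged up to float tolerance
  u <- (v - min(v)) / (max(v) - min(v))
  expect_equal(preprocess_volume(u)[1, , , ], u, tolerance = 1e-12)

  v[2, 1, 1] <- Inf
  expect_error(preprocess_volume(v), "non-finite")
})

test_that("augmentation resizes to the configured size and is seed-reproducible", {
  v <- preprocess_volume(rand_volume(4, H = 64, W = 64))
  out <- augment_volume(v, augment_config(out_size = 224))
  expect_identical(dim(out), c(3L, 4L, 224L, 224L))

  cfg <- augment_config(out_size = 32)
  a1 <- augment_volume(v, cfg, rng_stream(9), train_mode = TRUE)
  a2 <- augment_volume(v, cfg, rng_stream(9), train_mode = TRUE)
  expect_identical(a1, a2) # bit-reproducible under a fixed seed
  a3 <- augment_volume(v, cfg, rng_stream(10), train_mode = TRUE)
  expect_false(identical(a1, a3))

  # eval mode is deterministic without any rng
  e1 <- augment_volume(v, cfg)
  e2 <- augment_volume(v, cfg)
  expect_identical(e1, e2)
})

test_that("identity-parameter augmentation equals plain resizing and flips are involutions", {
  v <- preprocess_volume(rand_volume(3, H = 16, W = 16))
  ident <- augment_config(out_size = 16, p_hflip = 0, p_vflip = 0,
                          rot_range = c(0, 0), affine_scale = c(1, 1),
                          affine_translate = c(0, 0), affine_rot = c(0, 0))
  out <- augment_volume(v, ident, rng_stream(1), train_mode = TRUE)
  expect_equal(out, augment_volume(v, ident), tolerance = 1e-10)

  # horizontal flip applied twice restores the image
  hf <- augment_config(out_size = 16, p_hflip = 1, p_vflip = 0,
                       rot_range = c(0, 0), affine_scale = c(1, 1),
                       affine_translate = c(0, 0), affine_rot = c(0, 0))
  once <- augment_volume(v, hf, rng_stream(1), train_mode = TRUE)
  twice <- augment_volume(once, hf, rng_stream(2), train_mode = TRUE)
  expect_equal(twice, augment_volume(v, ident), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(once, augment_volume(v, ident))))
})

test_that("the full preprocessing chain maps any raw depth to (3, 15, S, S)", {
  idx <- tiny_synth(n = 10, image_size = 16, depth_range = c(2, 9))$train
  cfg <- augment_config(out_size = 12)
  ids <- vapply(idx$records, `[[`, "", "exam_id")
  batch <- protofed:::prepare_batch(idx, ids, cfg, 15L,
                                    rng = rng_stream(3), train_mode = TRUE)
  expect_identical(dim(batch), c(length(ids), 3L, 15L, 12L, 12L))
  expect_true(all(is.finite(batch)))
  # channels replicated identically
  expect_identical(batch[, 1, , , ], batch[, 2, , , ])
})

test_that("augmentation configuration validates its fields", {
  expect_error(augment_config(out_size = 0), "out_size")
  expect_error(augment_config(p_hflip = 1.5), "probabilities")
  expect_error(augment_config(rot_range = c(10, -10)), "ordered")
})
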