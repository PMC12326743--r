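test_that("episode sampling respects the n-way k-shot geometry", {
  idx <- tiny_synth(n = 150, image_size = 8, depth_range = c(3, 4),
                    valid_frac = 0.1)$train
  ep <- sample_episode(idx, 3, 5, 10, rng_stream(1))
  expect_length(ep$support_ids, 15)
  expect_length(ep$query_ids, 30)
  expect_identical(sort(unique(ep$support_labels)), 0:2)
  expect_identical(length(intersect(ep$support_ids, ep$query_ids)), 0L)
  expect_true(all(table(ep$support_labels) == 5))
  expect_true(all(table(ep$query_labels) == 10))
  # items unique within the episode
  expect_false(anyDuplicated(c(ep$support_ids, ep$query_ids)) > 0)
  # episode labels map back to global class ids
  for (i in seq_along(ep$support_ids)) {
    rec_class <- vapply(idx$records, `[[`, 0L, "class_id")[
      vapply(idx$records, `[[`, "", "exam_id") == ep$support_ids[i]]
    expect_identical(rec_class, ep$class_map[ep$support_labels[i] + 1L])
  }

  # validation geometry: 2-way 8-shot
  ep2 <- sample_episode(idx, 2, 8, 2, rng_stream(2))
  expect_length(ep2$support_ids, 16)

  # determinism and JSON dump round trip
  ep3 <- sample_episode(idx, 3, 5, 10, rng_stream(1))
  expect_identical(ep, ep3)
  j <- jsonlite::fromJSON(episode_to_json(ep))
  expect_identical(j$support_ids, ep$support_ids)
  expect_identical(as.integer(j$class_map), ep$class_map)
})

test_that("episode sampling rejects deficient classes by name", {
  idx <- tiny_synth(n = 30, image_size = 8, depth_range = c(3, 4),
                    props = c(0.45, 0.45, 0.1, 0, 0))$train
  counts <- idx$class_counts
  small <- as.integer(names(counts)[counts > 0][which.min(counts[counts > 0])])
  need <- counts[[as.character(small)]] + 1L
  expect_error(sample_episode(idx, 3, need - 1L, 1, rng_stream(1)),
               paste("class", small))
  expect_error(sample_episode(idx, 4, 1, 1, rng_stream(1)), "classes")
})

test_that("prototypes are group means, invariant to support order", {
  # mean of one equals the embedding itself
  p1 <- compute_prototypes(matrix(c(3, 7), 1), 0L)
  expect_equal(as.vector(p1$vectors), c(3, 7))

  # arithmetic mean of (1,1) and (3,3) is (2,2)
  p2 <- compute_prototypes(rbind(c(1, 1), c(3, 3), c(10, 0)), c(0L, 0L, 1L))
  expect_equal(p2$vectors[1, ], c(2, 2))
  expect_equal(p2$vectors[2, ], c(10, 0))
  expect_identical(p2$classes, c(0L, 1L))

  # brute force over all 24 permutations of a 4-item support
  emb <- with_rng(rng_stream(4), matrix(rnorm(8), 4, 2))
  labs <- c(0L, 1L, 0L, 1L)
  ref <- compute_prototypes(emb, labs)
  perms <- list(1:4, c(2, 1, 3, 4), c(4, 3, 2, 1), c(3, 1, 4, 2),
                c(2, 4, 1, 3), c(4, 1, 2, 3))
  for (pm in perms) {
    expect_equal(compute_prototypes(emb[pm, ], labs[pm]), ref)
  }

  # groupwise-mean oracle on random small supports
  for (s in 1:5) {
    nw <- sample(2:4, 1)
    ks <- sample(1:3, 1)
    emb <- with_rng(rng_stream(100 + s), matrix(rnorm(nw * ks * 3), nw * ks, 3))
    labs <- rep(seq_len(nw) - 1L, each = ks)
    got <- compute_prototypes(emb, labs)
    for (k in seq_len(nw)) {
      manual <- colSums(emb[labs == k - 1L, , drop = FALSE]) / ks
      expect_equal(got$vectors[k, ], manual)
    }
  }
  expect_error(compute_prototypes(matrix(0, 2, 2), c(0L, 0L, 1L)), "label")
})

test_that("queries go to the nearest prototype with softmax over negative squared distances", {
  protos <- compute_prototypes(rbind(c(0, 0), c(10, 0)), c(0L, 1L))
  r <- classify_queries(protos, matrix(c(1, 0), 1))
  expect_equal(as.vector(r$logits), c(-1, -81))
  expect_identical(r$pred, 0L)
  expect_equal(r$probs[1, 1], exp(-1) / (exp(-1) + exp(-81)))
  expect_equal(sum(r$probs[1, ]), 1, tolerance = 1e-6)

  # exact equidistance: lowest episode-class id wins
  tie <- classify_queries(protos, matrix(c(5, 0), 1))
  expect_identical(tie$pred, 0L)

  # query equal to a prototype: distance 0, that class predicted
  hit <- classify_queries(protos, matrix(c(10, 0), 1))
  expect_identical(hit$pred, 1L)
  expect_equal(hit$logits[1, 2], 0)

  # translation invariance of predictions and probabilities
  q <- with_rng(rng_stream(6), matrix(rnorm(10), 5, 2))
  base <- classify_queries(protos, q)
  shift <- c(3.7, -1.2)
  protos2 <- protos
  protos2$vectors <- sweep(protos$vectors, 2, shift, "+")
  moved <- classify_queries(protos2, sweep(q, 2, shift, "+"))
  expect_identical(base$pred, moved$pred)
  expect_equal(base$probs, moved$probs, tolerance = 1e-9)

  expect_error(classify_queries(protos, matrix(0, 1, 3)), "dimension")
})

test_that("episode loss is mean cross-entropy with the documented extremes", {
  # uniform predictive distribution: ln 2
  expect_equal(episode_loss(matrix(c(1, 1), 1), 0L), log(2))
  expect_equal(episode_loss(matrix(c(1, 1), 1), 1L), log(2))
  # confident correct prediction: ~0
  expect_lt(episode_loss(matrix(c(0, -1e6), 1), 0L), 1e-10)
  # batch loss equals the mean of per-query losses (brute force)
  lg <- with_rng(rng_stream(7), matrix(rnorm(12), 4, 3))
  labs <- c(0L, 2L, 1L, 1L)
  per <- vapply(1:4, function(i) {
    episode_loss(lg[i, , drop = FALSE], labs[i])
  }, numeric(1))
  expect_equal(episode_loss(lg, labs), mean(per))
  expect_gt(episode_loss(lg, labs), 0)
  expect_error(episode_loss(lg, c(0L, 1L, 2L, 3L)), "outside")
})

test_that("episode-loss gradients with respect to embeddings match finite differences", {
  set.seed(31)
  se <- matrix(rnorm(6 * 4), 6, 4)
  sl <- rep(0:2, each = 2)
  qe <- matrix(rnorm(5 * 4), 5, 4)
  ql <- c(0L, 1L, 2L, 0L, 1L)
  lg <- protofed:::episode_loss_grad(se, sl, qe, ql)
  eps <- 1e-6
  f <- function(s, q) {
    protos <- compute_prototypes(s, sl)
    episode_loss(classify_queries(protos, q)$logits, ql)
  }
  expect_equal(lg$loss, f(se, qe))
  for (probe in list(c(1, 2), c(4, 1), c(6, 4))) {
    sp <- se; sm <- se
    sp[probe[1], probe[2]] <- sp[probe[1], probe[2]] + eps
    sm[probe[1], probe[2]] <- sm[probe[1], probe[2]] - eps
    expect_equal(lg$grad_support[probe[1], probe[2]],
                 (f(sp, qe) - f(sm, qe)) / (2 * eps), tolerance = 1e-4)
  }
  for (probe in list(c(1, 1), c(3, 4), c(5, 2))) {
    qp <- qe; qm <- qe
    qp[probe[1], probe[2]] <- qp[probe[1], probe[2]] + eps
    qm[probe[1], probe[2]] <- qm[probe[1], probe[2]] - eps
    expect_equal(lg$grad_query[probe[1], probe[2]],
                 (f(se, qp) - f(se, qm)) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("1-shot episodes with queries equal to supports are perfectly classified", {
  emb <- with_rng(rng_stream(13), matrix(rnorm(4 * 3), 4, 3))
  labs <- 0:3
  protos <- compute_prototypes(emb, labs)
  r <- classify_queries(protos, emb)
  expect_identical(r$pred, labs)
})
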