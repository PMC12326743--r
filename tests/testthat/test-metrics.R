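test_that("confusion matrices tally pooled predictions exactly", {
  # all correct -> diagonal
  cm <- confusion_from_predictions(c(0, 3, 0, 3), c(0, 3, 0, 3), c(0, 3))
  expect_identical(unname(diag(cm$counts)), c(2L, 2L))
  expect_identical(sum(cm$counts) - sum(diag(cm$counts)), 0L)

  # empty inputs -> zero matrix with the requested labels
  z <- confusion_from_predictions(integer(0), integer(0), c(0, 1))
  expect_true(all(z$counts == 0L))
  expect_identical(dim(z$counts), c(2L, 2L))

  # random labels against a tally-by-hand oracle
  set.seed(14)
  tr <- sample(c(2, 3, 4), 20, replace = TRUE)
  pr <- sample(c(2, 3, 4), 20, replace = TRUE)
  cm <- confusion_from_predictions(tr, pr, c(2, 3, 4))
  for (i in 1:3) {
    for (j in 1:3) {
      expect_identical(cm$counts[i, j],
                       sum(tr == c(2, 3, 4)[i] & pr == c(2, 3, 4)[j]))
    }
  }
  expect_error(confusion_from_predictions(c(0, 9), c(0, 0), c(0, 1)), "label")
  expect_error(confusion_from_predictions(c(0, 1), c(0), c(0, 1)), "equal length")
})

test_that("macro metrics reproduce the reference confusion-count arithmetic", {
  # axial test pair: true class 0 -> 826 / 174, true class 3 -> 121 / 879
  axial <- matrix(c(826, 174, 121, 879), 2, 2, byrow = TRUE,
                  dimnames = list(c("0", "3"), c("0", "3")))
  m <- macro_metrics_from_counts(axial)
  expect_equal(round_half_away(m$macro_precision, 3), 0.853)
  expect_equal(round_half_away(m$macro_f1, 3), 0.852)
  expect_equal(round_half_away(100 * m$accuracy, 1), 85.3)

  # sagittal pair: TP 905, FN 95, FP 264, TN 736
  sag <- matrix(c(905, 95, 264, 736), 2, 2, byrow = TRUE)
  ms <- macro_metrics_from_counts(sag)
  expect_equal(round_half_away(ms$macro_precision, 3), 0.830)
  expect_equal(round_half_away(ms$macro_f1, 3), 0.819)

  # coronal pair: TP 658, FN 342, FP 238, TN 762
  cor <- matrix(c(658, 342, 238, 762), 2, 2, byrow = TRUE)
  mc <- macro_metrics_from_counts(cor)
  expect_equal(round_half_away(100 * mc$accuracy, 1), 71.0)
  expect_equal(round_half_away(mc$macro_precision, 3), 0.712)
  expect_equal(round_half_away(mc$macro_f1, 3), 0.709)

  # perfect diagonal: everything 1
  perf <- macro_metrics_from_counts(diag(c(5L, 9L, 3L)))
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$macro_precision, 1)
  expect_equal(perf$macro_recall, 1)
  expect_equal(perf$macro_f1, 1)

  # never-predicted class: precision 0 with a warning
  nv <- matrix(c(4, 0, 2, 0), 2, 2, byrow = TRUE)
  expect_warning(mn <- macro_metrics_from_counts(nv), "never predicted")
  expect_equal(mn$per_class$precision[2], 0)
  expect_error(macro_metrics_from_counts(matrix(0, 2, 2)), "empty")

  # 2-class balanced identities: micro accuracy = trace/total and macro
  # recall = mean of per-class accuracies
  expect_equal(mc$accuracy, (658 + 762) / 2000)
  expect_equal(mc$macro_recall, mean(c(658 / 1000, 762 / 1000)))
})

test_that("round-half-away-from-zero differs from banker's rounding where it matters", {
  expect_equal(round_half_away(0.8525, 3), 0.853)
  expect_equal(round_half_away(85.25, 1), 85.3)
  expect_equal(round_half_away(-0.8525, 3), -0.853)
  expect_equal(round_half_away(0.8524, 3), 0.852)
})

test_that("rank-based AUC honours its conventions and matches pROC", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(roc_auc(c(0.5, 0.5, 0.5, 0.5), c(0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")

  set.seed(7)
  sc <- runif(40)
  lb <- rbinom(40, 1, 0.5)
  a <- roc_auc(sc, lb)
  # invariance under strictly monotone transforms of the scores
  expect_equal(roc_auc(qlogis(sc), lb), a)
  expect_equal(roc_auc(sc^3, lb), a)
  # independent implementation
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(a, ref)
})

test_that("episodic evaluation pools predictions and is chance-level for a degenerate backbone", {
  idx <- tiny_synth(n = 100, image_size = 8, depth_range = c(3, 4))
  test_idx <- suppressWarnings(subset_by_class(idx$valid, c(0, 3)))
  cfg <- tiny_train_cfg(out_size = 8)

  # zero out every weight: all embeddings collapse to one point, every
  # distance ties, and the tie-break always picks the lower class
  net <- build_backbone("tiny3d", embed_dim = 8, seed = 1)
  w <- get_weights(net)
  for (nm in names(w)) w[[nm]] <- w[[nm]] * 0
  net <- set_weights(net, w)
  # the collapsed model never predicts the higher class, so the per-class
  # precision warning must fire
  expect_warning(
    r <- evaluate_model(net, test_idx, n_tasks = 10, n_way = 2, k_shot = 2,
                        n_query = 2, rng = rng_stream(3), cfg = cfg),
    "never predicted")
  expect_equal(r$accuracy, 0.5)
  expect_identical(sum(r$confusion$counts), r$n)
  expect_identical(r$n, 10L * 2L * 2L)

  # determinism under a fixed seed
  net2 <- build_backbone("tiny3d", embed_dim = 8, seed = 1)
  r1 <- evaluate_model(net2, test_idx, n_tasks = 8, n_way = 2, k_shot = 2,
                       n_query = 2, rng = rng_stream(5), cfg = cfg)
  r2 <- evaluate_model(net2, test_idx, n_tasks = 8, n_way = 2, k_shot = 2,
                       n_query = 2, rng = rng_stream(5), cfg = cfg)
  expect_identical(r1$confusion$counts, r2$confusion$counts)
  expect_equal(r1$accuracy, r2$accuracy)
  expect_true(is.null(r1$auc) || (r1$auc >= 0 && r1$auc <= 1))

  # report writer emits the JSON/CSV artifacts
  d <- withr::local_tempdir()
  write_metrics(r1, d)
  expect_true(file.exists(file.path(d, "metrics.json")))
  expect_true(file.exists(file.path(d, "per_class.csv")))
  expect_true(file.exists(file.path(d, "confusion.csv")))
  j <- jsonlite::read_json(file.path(d, "metrics.json"))
  expect_equal(j$accuracy, r1$accuracy)
})
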