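# Episodic n-way k-shot sampling and Prototypical-Network classification.
#
# An episode is one self-contained few-shot task: n_way classes, k_shot
# labeled support exams per class, and n_query held-out query exams per
# class. Class prototypes are the arithmetic means of the support
# embeddings; queries are scored by (negative squared) Euclidean distance
# to each prototype.

#' Sample one n-way k-shot episode from a dataset index
#'
#' Classes are drawn without replacement from those present in the index,
#' and exams without replacement within each class; support and query sets
#' are disjoint by construction. Labels inside the episode are re-indexed
#' `0 .. n_way-1`; the mapping back to global class ids is recorded in
#' `class_map` (ascending global id order).
#'
#' @param index A dataset index.
#' @param n_way Number of classes per episode.
#' @param k_shot Support exams per class.
#' @param n_query Query exams per class.
#' @param rng An [rng_stream()].
#' @return An object of class `episode` with fields `support_ids`,
#'   `support_labels`, `query_ids`, `query_labels`, `class_map`, `n_way`,
#'   `k_shot`, `n_query`.
#' @export
sample_episode <- function(index, n_way, k_shot, n_query, rng) {
  n_way <- as.integer(n_way)
  classes <- index_classes(index)
  if (length(classes) < n_way) {
    stop(sprintf("episode needs %d classes but index has %d", n_way,
                 length(classes)))
  }
  need <- k_shot + n_query
  short <- classes[index$class_counts[as.character(classes)] < need]
  if (length(short) > 0) {
    stop(sprintf("class %d has %d exams, episode needs %d (k_shot + n_query)",
                 short[1], index$class_counts[[as.character(short[1])]], need))
  }
  by_class <- split(
    vapply(index$records, function(r) r$exam_id, character(1)),
    vapply(index$records, function(r) r$class_id, integer(1))
  )
  with_rng(rng, {
    chosen <- sort(sample(classes, n_way))
    support_ids <- character(0); support_labels <- integer(0)
    query_ids <- character(0); query_labels <- integer(0)
    for (i in seq_along(chosen)) {
      ids <- sample(by_class[[as.character(chosen[i])]], need)
      support_ids <- c(support_ids, ids[seq_len(k_shot)])
      support_labels <- c(support_labels, rep(i - 1L, k_shot))
      query_ids <- c(query_ids, ids[k_shot + seq_len(n_query)])
      query_labels <- c(query_labels, rep(i - 1L, n_query))
    }
    structure(
      list(support_ids = support_ids, support_labels = support_labels,
           query_ids = query_ids, query_labels = query_labels,
           class_map = chosen, n_way = n_way, k_shot = as.integer(k_shot),
           n_query = as.integer(n_query)),
      class = "episode"
    )
  })
}

#' Serialize an episode to JSON
#'
#' Records exam ids, episode labels and the episode-to-global class mapping
#' so a sampled task can be reproduced or audited.
#'
#' @param episode An [sample_episode()] result.
#' @param path Optional file; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
episode_to_json <- function(episode, path = NULL) {
  j <- jsonlite::toJSON(unclass(episode), auto_unbox = FALSE, digits = NA)
  if (!is.null(path)) {
    writeLines(j, path)
    return(invisible(j))
  }
  j
}

#' Compute class prototypes from support embeddings
#'
#' The prototype of episode class `k` is the arithmetic mean of the
#' embeddings of its support examples. Rows of the result are ordered by
#' ascending episode-class id.
#'
#' @param support_embeddings Matrix `(n_support, embed_dim)`.
#' @param support_labels Integer episode-class ids (`0 .. n_way-1`), one per
#'   row.
#' @return An object of class `prototype_set`: list with `classes` (ordered
#'   episode-class ids) and `vectors` (matrix, one prototype per row).
#' @export
compute_prototypes <- function(support_embeddings, support_labels) {
  support_embeddings <- as.matrix(support_embeddings)
  support_labels <- as.integer(support_labels)
  if (nrow(support_embeddings) != length(support_labels)) {
    stop("one label per support embedding required")
  }
  classes <- sort(unique(support_labels))
  vectors <- matrix(0, length(classes), ncol(support_embeddings))
  for (i in seq_along(classes)) {
    rows <- support_labels == classes[i]
    if (!any(rows)) stop("episode class without support examples")
    vectors[i, ] <- colMeans(support_embeddings[rows, , drop = FALSE])
  }
  structure(list(classes = classes, vectors = vectors), class = "prototype_set")
}

#' Classify query embeddings against a prototype set
#'
#' Scores each query by the negative squared Euclidean distance to every
#' prototype (the logits), turns the logits into class probabilities by
#' softmax, and predicts the nearest prototype; exact distance ties break
#' toward the lowest episode-class id.
#'
#' @param protos A [compute_prototypes()] result.
#' @param query_embeddings Matrix `(n_query, embed_dim)`.
#' @return List with `logits` (n_query x n_way), `probs` (softmax rows),
#'   `pred` (episode-class ids).
#' @export
classify_queries <- function(protos, query_embeddings) {
  query_embeddings <- as.matrix(query_embeddings)
  if (ncol(query_embeddings) != ncol(protos$vectors)) {
    stop(sprintf("embedding dimension %d does not match prototypes (%d)",
                 ncol(query_embeddings), ncol(protos$vectors)))
  }
  # squared distances via ||q||^2 + ||c||^2 - 2 q.c
  qn <- rowSums(query_embeddings^2)
  cn <- rowSums(protos$vectors^2)
  d2 <- outer(qn, cn, "+") - 2 * query_embeddings %*% t(protos$vectors)
  d2[d2 < 0] <- 0 # guard tiny negative rounding
  logits <- -d2
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  probs <- e / rowSums(e)
  pred <- protos$classes[apply(logits, 1, which.max)] # first max = lowest id
  list(logits = logits, probs = probs, pred = pred)
}

#' Mean cross-entropy loss of episode logits
#'
#' @param logits Matrix `(n_query, n_way)` of prototype scores.
#' @param query_labels Integer episode-class ids in `0 .. n_way-1`.
#' @return Scalar loss (non-negative).
#' @export
episode_loss <- function(logits, query_labels) {
  logits <- as.matrix(logits)
  query_labels <- as.integer(query_labels)
  if (nrow(logits) != length(query_labels)) stop("one label per query required")
  if (any(query_labels < 0 | query_labels >= ncol(logits))) {
    stop("query label outside 0..n_way-1")
  }
  mx <- apply(logits, 1, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  logp <- logits[cbind(seq_len(nrow(logits)), query_labels + 1L)] - lse
  -mean(logp)
}

# Loss plus exact gradient with respect to all episode embeddings.
# Embeddings enter the loss along two routes: queries directly, supports
# through the class-mean prototypes. With G = softmax(logits) - onehot and
# logit(q, k) = -||e_q - c_k||^2 (rows of G sum to zero):
#   dL/dE_q = (2/m) G C
#   dL/dC   = (2/m) (G^T E_q - diag(colSums(G)) C)
# and the prototype gradient is shared equally by the k_shot supports.
episode_loss_grad <- function(support_emb, support_labels, query_emb,
                              query_labels) {
  protos <- compute_prototypes(support_emb, support_labels)
  cls <- classify_queries(protos, query_emb)
  loss <- episode_loss(cls$logits, query_labels)
  m <- nrow(query_emb)
  K <- length(protos$classes)
  Y <- matrix(0, m, K)
  Y[cbind(seq_len(m), match(query_labels, protos$classes))] <- 1
  G <- cls$probs - Y
  gq <- (2 / m) * G %*% protos$vectors
  gc <- (2 / m) * (t(G) %*% query_emb - diag(colSums(G), K) %*% protos$vectors)
  gs <- matrix(0, nrow(support_emb), ncol(support_emb))
  for (i in seq_len(K)) {
    rows <- which(support_labels == protos$classes[i])
    gs[rows, ] <- matrix(gc[i, ] / length(rows), length(rows),
                         ncol(support_emb), byrow = TRUE)
  }
  list(loss = loss, grad_support = gs, grad_query = gq,
       pred = cls$pred, probs = cls$probs)
}
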