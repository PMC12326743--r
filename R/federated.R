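# Simulated horizontal federated protocol: local episodic training on
# disjoint client shards, size-weighted averaging of the best local weights,
# redistribution, and local fine-tuning on the held-out classes. Clients are
# simulated in process, sequentially, with independent derived seeds; only
# weights and scalar metrics cross the client/server boundary.

#' Federated configuration
#'
#' @param n_clients Number of clients (>= 2; default 2).
#' @param rounds Train/average rounds before the fine-tuning stage
#'   (default 1: one local-training pass, one aggregation, then local
#'   fine-tuning).
#' @param partition_seed Seed for the stratified client partition.
#' @param aggregate_after_finetune If `TRUE` (default) the evaluated global
#'   model is a second size-weighted average of the fine-tuned client
#'   weights; otherwise the fine-tuned client checkpoint with the best
#'   validation accuracy is returned.
#' @param train A [train_config()] for the local training stage.
#' @param ft A [train_config()] for the local fine-tuning stage (defaults
#'   to `train` with `val_k_shot = 5`).
#' @return An object of class `fed_config`.
#' @export
fed_config <- function(n_clients = 2L, rounds = 1L, partition_seed = 0L,
                       aggregate_after_finetune = TRUE,
                       train = train_config(), ft = NULL) {
  if (n_clients < 2) stop("n_clients must be at least 2")
  if (rounds < 1) stop("rounds must be at least 1")
  if (is.null(ft)) {
    ft <- train
    ft$val_k_shot <- 5L
  }
  structure(
    list(n_clients = as.integer(n_clients), rounds = as.integer(rounds),
         partition_seed = as.integer(partition_seed),
         aggregate_after_finetune = isTRUE(aggregate_after_finetune),
         train = train, ft = ft),
    class = "fed_config"
  )
}

#' Partition a dataset index across clients
#'
#' Disjoint, exhaustive, class-stratified partition: each class's exams are
#' shuffled and dealt evenly (remainders round-robin), so every client sees
#' every class in near-original proportions.
#'
#' @param index A dataset index.
#' @param n_clients Number of shards.
#' @param rng An [rng_stream()].
#' @return List of `n_clients` dataset indices.
#' @export
partition_clients <- function(index, n_clients, rng) {
  n_clients <- as.integer(n_clients)
  if (n_exams(index) == 0) stop("cannot partition an empty index")
  cls <- vapply(index$records, function(r) r$class_id, integer(1))
  short <- index_classes(index)[index$class_counts[
    as.character(index_classes(index))] < n_clients]
  if (length(short) > 0) {
    stop(sprintf("class %d has fewer exams (%d) than clients (%d); cannot stratify",
                 short[1], index$class_counts[[as.character(short[1])]],
                 n_clients))
  }
  assign_client <- integer(length(cls))
  with_rng(rng, {
    for (k in unique(cls)) {
      rows <- sample(which(cls == k))
      assign_client[rows] <- rep_len(seq_len(n_clients), length(rows))
    }
  })
  lapply(seq_len(n_clients), function(ci) {
    out <- dataset_index(index$records[assign_client == ci], index$split,
                         index$plane, root = index$root)
    out$cache <- index$cache
    out
  })
}

#' Size-weighted average of client weights
#'
#' Per parameter, `W = sum(n_i * W_i) / sum(n_i)` -- the federated-averaging
#' rule with aggregation weights equal to client shard sizes (with the equal
#' two-client split this reduces to the plain mean). Every coordinate of the
#' result lies in the min/max envelope of the client values.
#'
#' @param client_weights List of `model_weights` (see [get_weights()]) with
#'   identical names and shapes.
#' @param client_sizes Positive client data sizes, one per client.
#' @return A `model_weights` list.
#' @export
fedavg <- function(client_weights, client_sizes) {
  if (length(client_weights) == 0) stop("no client weights to average")
  if (length(client_weights) != length(client_sizes)) {
    stop("one size per client required")
  }
  client_sizes <- as.numeric(client_sizes)
  if (any(client_sizes <= 0)) stop("client sizes must be positive")
  ref <- client_weights[[1]]
  nms <- names(ref)
  for (cw in client_weights[-1]) {
    if (!identical(names(cw), nms)) stop("client weight names do not align")
  }
  out <- ref
  total <- sum(client_sizes)
  for (nm in nms) {
    acc <- client_sizes[1] * ref[[nm]]
    for (i in seq_along(client_weights)[-1]) {
      o <- client_weights[[i]][[nm]]
      if (length(o) != length(ref[[nm]]) ||
          !identical(dim(o), dim(ref[[nm]]))) {
        stop("shape mismatch for parameter ", nm)
      }
      acc <- acc + client_sizes[i] * o
    }
    out[[nm]] <- acc / total
  }
  out
}

#' Run the two-stage federated protocol
#'
#' Per round, each client trains locally on its shard
#' ([train_centralized()]); the best-validation weights are collected and
#' averaged with shard-size weights ([fedavg()]); the average is sent back.
#' After the final round each client fine-tunes locally on its shard of the
#' held-out classes, and the evaluated global model is either a second
#' aggregation of the fine-tuned weights (default) or the best-validation
#' client model. Clients only ever expose weights and scalar metrics to the
#' aggregation step.
#'
#' @param backbone Initial backbone (shared architecture).
#' @param train_index Training-class index (pooled; partitioned internally).
#' @param val_index Validation index covering both stages' classes.
#' @param finetune_index Held-out-class index (pooled; partitioned
#'   internally).
#' @param cfg A [fed_config()].
#' @return A `federated_report`: the global `checkpoint`, per-client
#'   histories, client validation accuracies and shard sizes.
#' @export
run_federated <- function(backbone, train_index, val_index, finetune_index,
                          cfg) {
  part_rng <- rng_stream(derive_seed(cfg$partition_seed, "partition/train"))
  shards <- partition_clients(train_index, cfg$n_clients, part_rng)
  ft_rng <- rng_stream(derive_seed(cfg$partition_seed, "partition/ft"))
  ft_shards <- partition_clients(finetune_index, cfg$n_clients, ft_rng)
  train_val <- suppressWarnings(
    subset_by_class(val_index, index_classes(train_index)))
  ft_val <- suppressWarnings(
    subset_by_class(val_index, index_classes(finetune_index)))

  sizes <- vapply(shards, n_exams, integer(1))
  ft_sizes <- vapply(ft_shards, n_exams, integer(1))
  histories <- vector("list", cfg$n_clients)
  client_ckpts <- vector("list", cfg$n_clients)
  global <- backbone

  for (round in seq_len(cfg$rounds)) {
    weights <- vector("list", cfg$n_clients)
    for (ci in seq_len(cfg$n_clients)) {
      ccfg <- cfg$train
      ccfg$seed <- derive_seed(cfg$train$seed,
                               sprintf("round%d/client%d", round, ci))
      ck <- train_centralized(global, shards[[ci]], train_val, ccfg)
      weights[[ci]] <- get_weights(ck$net)
      histories[[ci]] <- rbind(histories[[ci]],
                               cbind(round = round, stage = "train",
                                     ck$history))
    }
    global <- set_weights(global, fedavg(weights, sizes))
  }

  ft_weights <- vector("list", cfg$n_clients)
  ft_accs <- numeric(cfg$n_clients)
  for (ci in seq_len(cfg$n_clients)) {
    fcfg <- cfg$ft
    fcfg$seed <- derive_seed(cfg$ft$seed, sprintf("ft/client%d", ci))
    start <- make_checkpoint(
      list(net = global, val_accuracy = NA_real_, epoch = 0L,
           task_counter = 0L),
      classes = index_classes(train_index), history = NULL
    )
    ck <- finetune(start, ft_shards[[ci]], ft_val, fcfg)
    ft_weights[[ci]] <- get_weights(ck$net)
    ft_accs[ci] <- ck$val_accuracy
    client_ckpts[[ci]] <- ck
    if (!is.null(ck$history)) {
      histories[[ci]] <- rbind(histories[[ci]],
                               cbind(round = NA_integer_, stage = "finetune",
                                     ck$history))
    }
  }

  if (cfg$aggregate_after_finetune) {
    final_net <- set_weights(global, fedavg(ft_weights, ft_sizes))
    final <- make_checkpoint(
      list(net = final_net, val_accuracy = mean(ft_accs),
           epoch = NA_integer_, task_counter = NA_integer_),
      classes = index_classes(finetune_index), history = NULL
    )
    rule <- "aggregate_after_finetune"
  } else {
    final <- client_ckpts[[which.max(ft_accs)]]
    rule <- "best_client_after_finetune"
  }

  structure(
    list(checkpoint = final, client_histories = histories,
         client_val_accuracy = ft_accs, shard_sizes = sizes,
         ft_shard_sizes = ft_sizes, final_model_rule = rule,
         n_clients = cfg$n_clients, rounds = cfg$rounds),
    class = "federated_report"
  )
}

#' @export
print.federated_report <- function(x, ...) {
  cat(sprintf("<federated_report> clients=%d rounds=%d rule=%s\n",
              x$n_clients, x$rounds, x$final_model_rule))
  cat(sprintf("  shard sizes: %s | client ft val acc: %s\n",
              paste(x$shard_sizes, collapse = "/"),
              paste(sprintf("%.3f", x$client_val_accuracy), collapse = "/")))
  invisible(x)
}
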