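# Centralized episodic training and disjoint-class fine-tuning.
#
# One optimizer step per episode (task): sample -> preprocess/augment ->
# embed -> prototypes -> cross-entropy loss -> SGD with momentum and weight
# decay, with a multi-step learning-rate schedule counted in tasks.

#' Training configuration
#'
#' Defaults follow the reference protocol: SGD with initial learning rate
#' 0.01, momentum 0.9, weight decay 5e-4; a multi-step schedule dropping the
#' rate by `gamma = 0.1` at tasks 120 and 160 (counted globally over
#' episodes); 500 training tasks (3-way 5-shot) and 100 validation tasks
#' (2-way 8-shot) per epoch. The query count per class is not part of the
#' stated protocol; the default is 10. `milestone_unit` switches the
#' schedule between task-counted (default, the literal reading) and
#' epoch-counted milestones.
#'
#' @param lr Initial learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty folded into the gradient step.
#' @param milestones Increasing task (or epoch) indices where the rate drops.
#' @param gamma Multiplicative rate decay per milestone.
#' @param tasks_per_epoch_train,tasks_per_epoch_val Episodes per epoch.
#' @param epochs Number of epochs.
#' @param n_way,k_shot,n_query Training-episode geometry.
#' @param val_n_way,val_k_shot,val_n_query Validation-episode geometry.
#' @param target_depth Standardized slice count fed to the backbone.
#' @param augment An [augment_config()] (its `out_size` sets the slice size
#'   seen by the backbone).
#' @param milestone_unit `"task"` or `"epoch"`.
#' @param seed Integer root seed for sampling/augmentation streams.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 0.01, momentum = 0.9, weight_decay = 5e-4,
                         milestones = c(120L, 160L), gamma = 0.1,
                         tasks_per_epoch_train = 500L,
                         tasks_per_epoch_val = 100L, epochs = 10L,
                         n_way = 3L, k_shot = 5L, n_query = 10L,
                         val_n_way = 2L, val_k_shot = 8L, val_n_query = 10L,
                         target_depth = 15L, augment = augment_config(),
                         milestone_unit = c("task", "epoch"), seed = 0L) {
  milestone_unit <- match.arg(milestone_unit)
  if (lr < 0) stop("lr must be non-negative")
  if (gamma <= 0 || gamma >= 1) stop("gamma must lie in (0, 1)")
  if (is.unsorted(milestones, strictly = TRUE)) {
    stop("milestones must be strictly increasing")
  }
  structure(
    list(lr = lr, momentum = momentum, weight_decay = weight_decay,
         milestones = as.integer(milestones), gamma = gamma,
         tasks_per_epoch_train = as.integer(tasks_per_epoch_train),
         tasks_per_epoch_val = as.integer(tasks_per_epoch_val),
         epochs = as.integer(epochs), n_way = as.integer(n_way),
         k_shot = as.integer(k_shot), n_query = as.integer(n_query),
         val_n_way = as.integer(val_n_way), val_k_shot = as.integer(val_k_shot),
         val_n_query = as.integer(val_n_query),
         target_depth = as.integer(target_depth), augment = augment,
         milestone_unit = milestone_unit, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Learning rate at a given task counter
#'
#' Closed form of the multi-step schedule:
#' `lr * gamma^(number of milestones <= task_counter)`.
#'
#' @param cfg A [train_config()].
#' @param task_counter Non-negative task index (0-based, counted globally
#'   across epochs).
#' @return The learning rate in effect for that task.
#' @export
lr_at_task <- function(cfg, task_counter) {
  if (task_counter < 0) stop("task_counter must be non-negative")
  cfg$lr * cfg$gamma^sum(cfg$milestones <= task_counter)
}

# ---- SGD with momentum -----------------------------------------------------

# Classical momentum with weight decay folded into the gradient:
#   v <- momentum * v + (g + wd * w);  w <- w - lr * v
# so lr = 0 freezes the parameters exactly.
sgd_update <- function(layers, grads, state, lr, momentum, wd) {
  if (is.null(state)) state <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    l <- layers[[i]]
    if (l$type == "res") {
      st <- state[[i]]
      if (is.null(st)) st <- list(main = NULL, down = NULL)
      rm_ <- sgd_update(l$main, g$main, st$main, lr, momentum, wd)
      l$main <- rm_$layers; st$main <- rm_$state
      if (!is.null(l$down)) {
        rd <- sgd_update(l$down, g$down, st$down, lr, momentum, wd)
        l$down <- rd$layers; st$down <- rd$state
      }
      state[[i]] <- st
    } else {
      st <- state[[i]]
      if (is.null(st)) st <- list()
      for (f in names(g)) {
        v <- st[[f]]
        if (is.null(v)) v <- 0 * l[[f]]
        v <- momentum * v + (g[[f]] + wd * l[[f]])
        l[[f]] <- l[[f]] - lr * v
        st[[f]] <- v
      }
      state[[i]] <- st
    }
    layers[[i]] <- l
  }
  list(layers = layers, state = state)
}

# ---- episodic loops --------------------------------------------------------

# Run validation episodes in evaluation mode; embeddings are cached per exam
# for the duration of the phase (the weights are fixed).
validate_accuracy <- function(net, val_index, cfg, rng, n_way = NULL,
                              k_shot = NULL) {
  if (is.null(n_way)) n_way <- cfg$val_n_way
  if (is.null(k_shot)) k_shot <- cfg$val_k_shot
  n_way <- min(n_way, length(index_classes(val_index)))
  emb_cache <- new.env(parent = emptyenv())
  accs <- numeric(cfg$tasks_per_epoch_val)
  for (t in seq_len(cfg$tasks_per_epoch_val)) {
    ep <- sample_episode(val_index, n_way, k_shot, cfg$val_n_query, rng)
    ids <- c(ep$support_ids, ep$query_ids)
    emb <- embed_with_cache(net, val_index, ids, cfg, emb_cache)
    ns <- length(ep$support_ids)
    protos <- compute_prototypes(emb[seq_len(ns), , drop = FALSE],
                                 ep$support_labels)
    cls <- classify_queries(protos, emb[-seq_len(ns), , drop = FALSE])
    accs[t] <- mean(cls$pred == ep$query_labels)
  }
  mean(accs)
}

embed_with_cache <- function(net, index, ids, cfg, emb_cache) {
  todo <- unique(ids[!vapply(ids, function(i) !is.null(emb_cache[[i]]),
                             logical(1))])
  if (length(todo) > 0) {
    batch <- prepare_batch(index, todo, cfg$augment, cfg$target_depth,
                           train_mode = FALSE)
    em <- embed_volumes(net, batch)
    for (i in seq_along(todo)) emb_cache[[todo[i]]] <- em[i, ]
  }
  t(vapply(ids, function(i) emb_cache[[i]], numeric(net$embed_dim)))
}

train_loop <- function(net, train_index, val_index, cfg, stage = "train") {
  opt_state <- NULL
  task_counter <- 0L
  rng_sample <- rng_stream(derive_seed(cfg$seed, paste0(stage, "/sample")))
  rng_aug <- rng_stream(derive_seed(cfg$seed, paste0(stage, "/augment")))
  n_way <- min(cfg$n_way, length(index_classes(train_index)))
  if (n_way < cfg$n_way) {
    message(sprintf("%s: only %d classes available; episodes run %d-way",
                    stage, n_way, n_way))
  }

  val0 <- validate_accuracy(net, val_index, cfg,
                            rng_stream(derive_seed(cfg$seed,
                                                   paste0(stage, "/val0"))))
  best <- list(net = net, val_accuracy = val0, epoch = 0L, task_counter = 0L)
  history <- data.frame(epoch = 0L, mean_train_loss = NA_real_,
                        val_accuracy = val0)

  for (e in seq_len(cfg$epochs)) {
    losses <- numeric(cfg$tasks_per_epoch_train)
    for (t in seq_len(cfg$tasks_per_epoch_train)) {
      ep <- sample_episode(train_index, n_way, cfg$k_shot, cfg$n_query,
                           rng_sample)
      ids <- c(ep$support_ids, ep$query_ids)
      batch <- prepare_batch(train_index, ids, cfg$augment, cfg$target_depth,
                             rng = rng_aug, train_mode = TRUE)
      fw <- net_forward(net, batch, train = TRUE)
      net <- fw$net
      ns <- length(ep$support_ids)
      emb <- fw$out
      lg <- episode_loss_grad(emb[seq_len(ns), , drop = FALSE],
                              ep$support_labels,
                              emb[-seq_len(ns), , drop = FALSE],
                              ep$query_labels)
      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite loss at %s epoch %d task %d (counter %d)",
                     stage, e, t, task_counter))
      }
      losses[t] <- lg$loss
      gemb <- rbind(lg$grad_support, lg$grad_query)
      bw <- net_backward(net, fw$caches, gemb)
      milestone_idx <- if (cfg$milestone_unit == "task") task_counter else e - 1L
      lr <- cfg$lr * cfg$gamma^sum(cfg$milestones <= milestone_idx)
      upd <- sgd_update(net$layers, bw$grads, opt_state, lr, cfg$momentum,
                        cfg$weight_decay)
      net$layers <- upd$layers
      opt_state <- upd$state
      task_counter <- task_counter + 1L
    }
    val <- validate_accuracy(net, val_index, cfg,
                             rng_stream(derive_seed(cfg$seed,
                                                    paste0(stage, "/val", e))))
    history <- rbind(history,
                     data.frame(epoch = e, mean_train_loss = mean(losses),
                                val_accuracy = val))
    if (val > best$val_accuracy) {
      best <- list(net = net, val_accuracy = val, epoch = e,
                   task_counter = task_counter)
    }
  }
  list(best = best, history = history, final_net = net)
}

make_checkpoint <- function(best, classes, history) {
  structure(
    list(net = best$net, val_accuracy = best$val_accuracy,
         epoch = best$epoch, task_counter = best$task_counter,
         classes = classes, history = history),
    class = "checkpoint"
  )
}

#' @export
print.checkpoint <- function(x, ...) {
  cat(sprintf("<checkpoint> %s  epoch=%d  task=%d  val_accuracy=%.3f  classes=(%s)\n",
              x$net$name, x$epoch, x$task_counter, x$val_accuracy,
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Centralized episodic training
#'
#' Runs `epochs` epochs of `tasks_per_epoch_train` episodic SGD steps on
#' `train_index` (restricted beforehand to the training classes), validating
#' with `tasks_per_epoch_val` episodes after every epoch (and once at
#' initialization, so `epochs = 0` returns the untrained backbone with its
#' validation accuracy). The checkpoint with the highest mean validation
#' accuracy is returned. Fully reproducible given `cfg$seed`.
#'
#' @param backbone A backbone from [build_backbone()].
#' @param train_index,val_index Dataset indices for the two phases.
#' @param cfg A [train_config()].
#' @return A `checkpoint`: backbone with best weights, `val_accuracy`,
#'   `epoch`, `task_counter`, trained `classes` and the epoch `history`.
#' @export
train_centralized <- function(backbone, train_index, val_index, cfg) {
  r <- train_loop(backbone, train_index, val_index, cfg, stage = "train")
  make_checkpoint(r$best, index_classes(train_index), r$history)
}

#' Fine-tune a checkpoint on disjoint classes
#'
#' Continues episodic training from a trained checkpoint on classes not seen
#' during the initial stage (the protocol's second stage; validation there
#' uses 2-way 5-shot episodes by convention -- pass a `cfg` with
#' `val_k_shot = 5` to match). When the fine-tuning index holds fewer
#' classes than the configured `n_way`, episodes are clamped to the
#' available number (with a message).
#'
#' @param start A `checkpoint` to initialize from.
#' @param finetune_index Dataset index of the new classes.
#' @param val_index Validation index (restricted to the new classes).
#' @param cfg A [train_config()] for this stage.
#' @param allow_overlap Permit class overlap with the initial stage
#'   (protocol violation guard; default `FALSE`).
#' @return A `checkpoint` with the best fine-tuned weights.
#' @export
finetune <- function(start, finetune_index, val_index, cfg,
                     allow_overlap = FALSE) {
  overlap <- intersect(start$classes, index_classes(finetune_index))
  if (length(overlap) > 0 && !allow_overlap) {
    stop("fine-tuning classes overlap the training stage (",
         paste(overlap, collapse = ", "),
         "); pass allow_overlap = TRUE to override")
  }
  if (cfg$epochs == 0) {
    return(start)
  }
  r <- train_loop(start$net, finetune_index, val_index, cfg,
                  stage = "finetune")
  make_checkpoint(r$best, index_classes(finetune_index), r$history)
}
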