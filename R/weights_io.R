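# Portable weight archives: a directory of .npy tensors plus a JSON
# manifest recording parameter order and shapes, so archives round-trip
# across languages. Checkpoints add a JSON sidecar with the run metadata.

#' Save model weights as a portable tensor archive
#'
#' @param weights A `model_weights` list (see [get_weights()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_model_weights <- function(weights, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(names(weights), function(nm) {
    d <- dim(weights[[nm]])
    list(name = nm, file = paste0(nm, ".npy"),
         shape = if (is.null(d)) length(weights[[nm]]) else d)
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(weights)) {
    write_npy(weights[[nm]], file.path(dir, paste0(nm, ".npy")),
              dtype = "float64")
  }
  invisible(dir)
}

#' Load a model weight archive
#'
#' @param dir Directory written by [save_model_weights()].
#' @return A `model_weights` list in manifest order.
#' @export
load_model_weights <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  out <- list()
  for (entry in manifest) {
    arr <- read_npy(file.path(dir, entry$file))
    out[[entry$name]] <- arr
  }
  structure(out, class = "model_weights")
}

#' Save a training checkpoint
#'
#' Writes the backbone weights as a tensor archive under `weights/` plus a
#' `meta.json` sidecar (architecture, seed, config hash, best epoch and
#' validation accuracy, trained classes).
#'
#' @param checkpoint A `checkpoint`.
#' @param dir Output directory.
#' @param config_hash Optional configuration digest to record.
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(checkpoint, dir, config_hash = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_model_weights(get_weights(checkpoint$net), file.path(dir, "weights"))
  meta <- list(
    backbone = checkpoint$net$name,
    embed_dim = checkpoint$net$embed_dim,
    init_seed = checkpoint$net$seed,
    val_accuracy = checkpoint$val_accuracy,
    epoch = checkpoint$epoch,
    task_counter = checkpoint$task_counter,
    classes = checkpoint$classes,
    config_hash = config_hash
  )
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(checkpoint$history)) {
    utils::write.csv(checkpoint$history, file.path(dir, "history.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Load a training checkpoint
#'
#' Rebuilds the backbone architecture recorded in `meta.json` and installs
#' the archived weights.
#'
#' @param dir Directory written by [save_checkpoint()].
#' @return A `checkpoint`.
#' @export
load_checkpoint <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  net <- build_backbone(meta$backbone, embed_dim = meta$embed_dim,
                        seed = meta$init_seed)
  net <- set_weights(net, load_model_weights(file.path(dir, "weights")))
  hist_path <- file.path(dir, "history.csv")
  history <- if (file.exists(hist_path)) utils::read.csv(hist_path) else NULL
  structure(
    list(net = net, val_accuracy = meta$val_accuracy,
         epoch = meta$epoch, task_counter = meta$task_counter,
         classes = as.integer(unlist(meta$classes)), history = history),
    class = "checkpoint"
  )
}
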