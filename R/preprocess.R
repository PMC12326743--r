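# Volume preprocessing: slice-count standardization, intensity normalization,
# channel replication, and the training augmentation stack.

#' Standardize the number of slices of a volume
#'
#' Raw exams carry a variable number of slices (17 to 61 in the MRNet
#' layout). The output places slice `j` (0-based) at fractional position
#' `p_j = j * (D - 1) / (target_depth - 1)` along the original stack. At
#' integer positions the original slice is copied; between two original
#' slices the new slice is the fixed-weight combination
#' `0.2 * preceding + 0.8 * subsequent`. The weights are position-independent
#' by design (this is the stated interpolation rule, not classical linear
#' interpolation), so every output voxel is a convex combination of input
#' voxels and the intensity range can only shrink.
#'
#' @param v Numeric array `(depth, height, width)` with at least 2 slices.
#' @param target_depth Number of output slices (default 15).
#' @return Numeric array `(target_depth, height, width)`.
#' @export
standardize_slices <- function(v, target_depth = 15L) {
  target_depth <- as.integer(target_depth)
  if (target_depth < 2) stop("target_depth must be at least 2")
  d <- dim(v)
  if (is.null(d) || length(d) != 3) stop("volume must be a 3-D array (depth, H, W)")
  D <- d[1]
  if (D < 2) stop("too few slices: volume has ", D, ", need at least 2")
  if (any(!is.finite(v))) stop("volume contains non-finite voxels")
  out <- array(0, dim = c(target_depth, d[2], d[3]))
  for (j in seq_len(target_depth) - 1L) {
    num <- j * (D - 1L)                  # position numerator over (target-1)
    lo <- num %/% (target_depth - 1L)
    rem <- num %% (target_depth - 1L)
    if (rem == 0L) {
      out[j + 1L, , ] <- v[lo + 1L, , ]
    } else {
      out[j + 1L, , ] <- 0.2 * v[lo + 1L, , ] + 0.8 * v[lo + 2L, , ]
    }
  }
  out
}

#' Normalize intensities and replicate the grayscale channel
#'
#' Min-max scales the volume to `[0, 1]` (a constant volume maps to all
#' zeros) and replicates the single grayscale channel three times, matching
#' the three-channel input convention of the embedding backbones.
#'
#' @param v Numeric array `(depth, height, width)`.
#' @return Numeric array `(3, depth, height, width)` with three identical
#'   channels.
#' @export
preprocess_volume <- function(v) {
  d <- dim(v)
  if (is.null(d) || length(d) != 3) stop("volume must be a 3-D array (depth, H, W)")
  if (any(!is.finite(v))) stop("volume contains non-finite voxels")
  ext <- range(v)
  v <- if (ext[2] > ext[1]) (v - ext[1]) / (ext[2] - ext[1]) else array(0, d)
  out <- array(0, dim = c(3L, d))
  for (ch in 1:3) out[ch, , , ] <- v
  out
}

#' Augmentation configuration
#'
#' Parameters of the per-exam training augmentation stack: resize target,
#' flip probabilities, in-plane rotation range, and the random affine
#' transform (scale / translation / rotation). One random draw is made per
#' exam and applied identically to all slices (and channels), preserving
#' intra-volume spatial coherence.
#'
#' @param out_size Output slice side in pixels (default 224).
#' @param p_hflip,p_vflip Flip probabilities (default 0.5 each).
#' @param rot_range Rotation range in degrees, length 2 (default -45..45).
#' @param affine_scale Scale factor interval (default 0.9..1.1).
#' @param affine_translate Translation interval as a fraction of the image
#'   side (default -0.1..0.1, drawn independently per axis).
#' @param affine_rot Affine rotation interval in degrees (default -15..15).
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(out_size = 224L, p_hflip = 0.5, p_vflip = 0.5,
                           rot_range = c(-45, 45),
                           affine_scale = c(0.9, 1.1),
                           affine_translate = c(-0.1, 0.1),
                           affine_rot = c(-15, 15)) {
  out_size <- as.integer(out_size)
  if (out_size < 1) stop("out_size must be positive")
  for (p in list(p_hflip, p_vflip)) {
    if (p < 0 || p > 1) stop("flip probabilities must lie in [0, 1]")
  }
  for (iv in list(rot_range, affine_scale, affine_translate, affine_rot)) {
    if (length(iv) != 2 || iv[1] > iv[2]) stop("intervals must be ordered pairs")
  }
  structure(list(out_size = out_size, p_hflip = p_hflip, p_vflip = p_vflip,
                 rot_range = rot_range, affine_scale = affine_scale,
                 affine_translate = affine_translate, affine_rot = affine_rot),
            class = "augment_config")
}

# Draw one set of augmentation parameters for an exam.
draw_augment_params <- function(cfg, rng) {
  with_rng(rng, list(
    hflip = stats::runif(1) < cfg$p_hflip,
    vflip = stats::runif(1) < cfg$p_vflip,
    rot = stats::runif(1, cfg$rot_range[1], cfg$rot_range[2]),
    scale = stats::runif(1, cfg$affine_scale[1], cfg$affine_scale[2]),
    tx = stats::runif(1, cfg$affine_translate[1], cfg$affine_translate[2]),
    ty = stats::runif(1, cfg$affine_translate[1], cfg$affine_translate[2]),
    arot = stats::runif(1, cfg$affine_rot[1], cfg$affine_rot[2])
  ))
}

# Apply resize + (optionally) flips, rotation and affine to a stack of
# slices stored as an EBImage-style array (x, y, frames).
apply_augment_frames <- function(frames, cfg, params) {
  img <- EBImage::Image(frames)
  img <- EBImage::resize(img, w = cfg$out_size, h = cfg$out_size,
                         filter = "bilinear")
  if (!is.null(params)) {
    if (params$hflip) img <- EBImage::flop(img) # mirror along x
    if (params$vflip) img <- EBImage::flip(img) # mirror along y
    if (params$rot != 0) {
      img <- EBImage::rotate(img, params$rot, filter = "bilinear",
                             output.dim = c(cfg$out_size, cfg$out_size),
                             bg.col = 0)
    }
    # affine about the image center: scale, rotate, then translate
    th <- params$arot * pi / 180
    s <- params$scale
    A <- s * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    ctr <- (cfg$out_size + 1) / 2
    shift <- c(ctr, ctr) - A %*% c(ctr, ctr) +
      c(params$tx, params$ty) * cfg$out_size
    m <- rbind(A, as.numeric(shift))
    img <- EBImage::affine(img, m, filter = "bilinear",
                           output.dim = c(cfg$out_size, cfg$out_size),
                           bg.col = 0)
  }
  EBImage::imageData(img)
}

#' Resize and (in training mode) randomly augment a preprocessed volume
#'
#' Every slice is resized to `out_size x out_size` (bilinear). In training
#' mode one random draw per exam -- horizontal/vertical flip decisions, a
#' rotation angle, and affine scale/translation/rotation parameters -- is
#' applied identically to all slices, with bilinear resampling and zero
#' padding outside the frame. In evaluation mode only the resize is applied,
#' so the output is deterministic.
#'
#' @param v Numeric array `(3, depth, H, W)` (or `(depth, H, W)` for a
#'   single-channel volume).
#' @param cfg An [augment_config()].
#' @param rng An [rng_stream()] supplying the augmentation draw (required in
#'   training mode).
#' @param train_mode If `FALSE`, only resizing is performed.
#' @return Array with the same channel/depth structure and
#'   `out_size x out_size` slices.
#' @export
augment_volume <- function(v, cfg = augment_config(), rng = NULL,
                           train_mode = FALSE) {
  d <- dim(v)
  has_ch <- length(d) == 4
  if (!has_ch && length(d) != 3) stop("volume must be (3,D,H,W) or (D,H,W)")
  params <- NULL
  if (train_mode) {
    if (is.null(rng)) stop("training-mode augmentation needs an rng_stream")
    params <- draw_augment_params(cfg, rng)
  }
  if (has_ch) {
    D <- d[2]
    # channels are identical copies; augment one channel, replicate after
    frames <- aperm(v[1, , , , drop = TRUE], c(3, 2, 1)) # (W,H,D) -> x,y,frames
    aug <- apply_augment_frames(frames, cfg, params)
    dim(aug) <- c(cfg$out_size, cfg$out_size, D)
    one <- aperm(aug, c(3, 2, 1))
    out <- array(0, dim = c(d[1], D, cfg$out_size, cfg$out_size))
    for (ch in seq_len(d[1])) out[ch, , , ] <- one
    out
  } else {
    D <- d[1]
    frames <- aperm(v, c(3, 2, 1))
    aug <- apply_augment_frames(frames, cfg, params)
    dim(aug) <- c(cfg$out_size, cfg$out_size, D)
    aperm(aug, c(3, 2, 1))
  }
}

# Single-channel preprocessing for one exam: standardize slice count and
# min-max normalize (cached per exam), then resize/augment. Channel
# replication happens at batch assembly -- the three channels are identical
# copies, so caching one channel saves two thirds of the memory.
# Returns (target_depth, out_size, out_size).
prepare_exam <- function(index, exam_id, cfg = augment_config(),
                         target_depth = 15L, rng = NULL, train_mode = FALSE) {
  key <- paste0("std/", index$plane, "/", exam_id, "/", target_depth)
  std <- index$cache[[key]]
  if (is.null(std)) {
    raw <- get_volume(index, exam_id)
    std <- standardize_slices(raw, target_depth)
    ext <- range(std)
    std <- if (ext[2] > ext[1]) (std - ext[1]) / (ext[2] - ext[1]) else
      array(0, dim(std))
    index$cache[[key]] <- std
    # drop the raw volume from the cache; only the standardized form is reused
    rkey <- paste0(index$plane, "/", exam_id)
    if (!is.null(index$cache[[rkey]])) rm(list = rkey, envir = index$cache)
  }
  if (!train_mode) {
    ekey <- paste0("eval/", index$plane, "/", exam_id, "/", target_depth, "/",
                   cfg$out_size)
    out <- index$cache[[ekey]]
    if (is.null(out)) {
      out <- augment_volume(std, cfg, train_mode = FALSE)
      index$cache[[ekey]] <- out
    }
    return(out)
  }
  augment_volume(std, cfg, rng = rng, train_mode = TRUE)
}

# Stack exams into a batch array (N, 3, depth, S, S); the grayscale channel
# is replicated here.
prepare_batch <- function(index, exam_ids, cfg = augment_config(),
                          target_depth = 15L, rng = NULL, train_mode = FALSE) {
  n <- length(exam_ids)
  first <- prepare_exam(index, exam_ids[1], cfg, target_depth, rng, train_mode)
  out <- array(0, dim = c(n, 3L, dim(first)))
  out[1, 1, , , ] <- first
  if (n > 1) {
    for (i in 2:n) {
      out[i, 1, , , ] <- prepare_exam(index, exam_ids[i], cfg, target_depth,
                                      rng, train_mode)
    }
  }
  out[, 2, , , ] <- out[, 1, , , ]
  out[, 3, , , ] <- out[, 1, , , ]
  out
}
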