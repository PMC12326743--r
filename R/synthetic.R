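# Synthetic MRNet-layout generator.
#
# Emulates the dataset's shape without any anatomical realism: per-exam
# variable-depth grayscale volumes (one per plane), Gaussian background
# noise, and class-conditional signal made of additive 3-D Gaussian blobs
# whose number, position and amplitude are a fixed function of the class
# id. The blob table is constructed so that the class pairs used as
# held-out test pairs separate cleanly from class 0, while classes 3 and 4
# share their main blob and differ only through half-amplitude satellites
# -- mimicking the observed hardness ordering in which (3, 4) is the most
# confusable test pair.

# blob table: rows (d, h, w) fractional centers, amp = amplitude factor,
# sig = width as a fraction of each dimension
.CLASS_BLOBS <- list(
  `0` = NULL,
  `1` = data.frame(d = 0.30, h = 0.30, w = 0.30, amp = 1.0, sig = 0.12),
  `2` = data.frame(d = 0.70, h = 0.70, w = 0.70, amp = 1.0, sig = 0.12),
  `3` = data.frame(d = c(0.50, 0.35), h = c(0.35, 0.65), w = c(0.65, 0.30),
                   amp = c(1.0, 0.5), sig = c(0.12, 0.10)),
  `4` = data.frame(d = c(0.50, 0.65), h = c(0.35, 0.30), w = c(0.65, 0.60),
                   amp = c(1.0, 0.5), sig = c(0.12, 0.10))
)

# Deterministic class signal template (no noise), dimension (D, H, W).
signal_template <- function(class_id, D, H, W, signal_strength) {
  out <- array(0, dim = c(D, H, W))
  blobs <- .CLASS_BLOBS[[as.character(class_id)]]
  if (is.null(blobs) || signal_strength == 0) {
    return(out)
  }
  for (i in seq_len(nrow(blobs))) {
    gd <- exp(-((seq_len(D) / D - blobs$d[i])^2) / (2 * blobs$sig[i]^2))
    gh <- exp(-((seq_len(H) / H - blobs$h[i])^2) / (2 * blobs$sig[i]^2))
    gw <- exp(-((seq_len(W) / W - blobs$w[i])^2) / (2 * blobs$sig[i]^2))
    out <- out + signal_strength * blobs$amp[i] *
      outer(outer(gd, gh), gw)
  }
  out
}

#' Synthetic dataset configuration
#'
#' The defaults define the benchmark conditions the package is exercised
#' under: imbalanced class proportions (class 1 most frequent, class 3
#' rarest, qualitatively matching the real label distribution), raw depths
#' uniform over 17..61 slices, 64-pixel slices, and a signal-to-noise ratio
#' of 5 (blob amplitude 5 against unit-variance Gaussian background).
#'
#' @param n_exams Number of exams to generate.
#' @param class_proportions Length-5 non-negative vector summing to 1.
#' @param depth_range Inclusive raw slice-count range.
#' @param image_size Slice side in pixels (64 by default; 256 reproduces
#'   the real layout's geometry).
#' @param signal_strength Blob amplitude in intensity units.
#' @param noise_sd Gaussian background standard deviation.
#' @param valid_frac Fraction of exams assigned (per class) to the valid
#'   split.
#' @param seed Integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_exams = 100L,
                         class_proportions = c(0.20, 0.30, 0.22, 0.08, 0.20),
                         depth_range = c(17L, 61L), image_size = 64L,
                         signal_strength = 5, noise_sd = 1,
                         valid_frac = 0.2, seed = 0L) {
  if (length(class_proportions) != 5 || any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class_proportions must be 5 non-negative values summing to 1")
  }
  depth_range <- as.integer(depth_range)
  if (depth_range[1] < 2 || depth_range[2] > 61 ||
      depth_range[1] > depth_range[2]) {
    stop("depth_range must lie within [2, 61] and be ordered")
  }
  structure(
    list(n_exams = as.integer(n_exams), class_proportions = class_proportions,
         depth_range = depth_range, image_size = as.integer(image_size),
         signal_strength = signal_strength, noise_sd = noise_sd,
         valid_frac = valid_frac, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate one synthetic exam
#'
#' Each requested plane gets an independent noise realization and depth
#' draw; the class signal template is shared. The exam's label triple is
#' the decoding of `class_id` (see [class_to_triple()]).
#'
#' @param class_id Class id 0..4.
#' @param cfg A [synth_config()].
#' @param rng An [rng_stream()].
#' @param exam_id Exam id string (default `"0000"`).
#' @param planes Planes to generate (default all three).
#' @return An `exam_record` with in-memory volumes.
#' @export
generate_exam <- function(class_id, cfg, rng, exam_id = "0000",
                          planes = c("axial", "coronal", "sagittal")) {
  S <- cfg$image_size
  vols <- with_rng(rng, {
    out <- list()
    depths <- seq.int(cfg$depth_range[1], cfg$depth_range[2])
    for (p in planes) {
      D <- depths[sample.int(length(depths), 1)] # robust to a collapsed range
      v <- array(stats::rnorm(D * S * S, sd = cfg$noise_sd), dim = c(D, S, S))
      out[[p]] <- v + signal_template(class_id, D, S, S, cfg$signal_strength)
    }
    out
  })
  exam_record(exam_id, vols, class_to_triple(class_id))
}

draw_classes_and_split <- function(cfg, rng) {
  with_rng(rng, {
    cls <- sample(0:4, cfg$n_exams, replace = TRUE,
                  prob = cfg$class_proportions)
    split <- character(cfg$n_exams)
    for (k in unique(cls)) {
      rows <- which(cls == k)
      nv <- round(cfg$valid_frac * length(rows))
      vrows <- if (nv > 0) sample(rows, nv) else integer(0)
      split[rows] <- "train"
      split[vrows] <- "valid"
    }
    list(classes = cls, split = split)
  })
}

#' Generate an in-memory synthetic dataset
#'
#' Draws exam classes from the configured proportions, assigns a per-class
#' `valid_frac` of exams to the valid split, and generates volumes for the
#' requested plane(s) only, keeping them in memory. Use
#' [generate_dataset()] to additionally write the on-disk MRNet layout.
#'
#' @param cfg A [synth_config()].
#' @param planes Planes to generate (default `"axial"` only).
#' @return List with dataset indices `train` and `valid` (for `planes[1]`).
#' @export
generate_index <- function(cfg, planes = "axial") {
  rng_cls <- rng_stream(derive_seed(cfg$seed, "synth/classes"))
  cs <- draw_classes_and_split(cfg, rng_cls)
  records <- vector("list", cfg$n_exams)
  for (i in seq_len(cfg$n_exams)) {
    rng_ex <- rng_stream(derive_seed(cfg$seed, paste0("synth/exam/", i)))
    records[[i]] <- generate_exam(cs$classes[i], cfg, rng_ex,
                                  exam_id = sprintf("%04d", i),
                                  planes = planes)
  }
  list(
    train = dataset_index(records[cs$split == "train"], "train", planes[1]),
    valid = dataset_index(records[cs$split == "valid"], "valid", planes[1])
  )
}

#' Generate and write a synthetic MRNet-layout dataset
#'
#' Writes `<root>/<split>/<plane>/<exam_id>.npy` float32 volume stacks for
#' all three planes plus the three two-column label CSVs per split, then
#' loads the result back with [load_dataset()].
#'
#' @param cfg A [synth_config()].
#' @param root Output directory (created if needed).
#' @param plane Plane of the returned indices.
#' @return List with dataset indices `train` and `valid` read back from
#'   disk.
#' @export
generate_dataset <- function(cfg, root, plane = "axial") {
  planes <- c("axial", "coronal", "sagittal")
  rng_cls <- rng_stream(derive_seed(cfg$seed, "synth/classes"))
  cs <- draw_classes_and_split(cfg, rng_cls)
  for (sp in c("train", "valid")) {
    for (p in planes) {
      dir.create(file.path(root, sp, p), recursive = TRUE,
                 showWarnings = FALSE)
    }
  }
  labels <- list(train = NULL, valid = NULL)
  for (i in seq_len(cfg$n_exams)) {
    rng_ex <- rng_stream(derive_seed(cfg$seed, paste0("synth/exam/", i)))
    rec <- generate_exam(cs$classes[i], cfg, rng_ex,
                         exam_id = sprintf("%04d", i), planes = planes)
    sp <- cs$split[i]
    for (p in planes) {
      write_npy(rec$volumes[[p]],
                file.path(root, sp, p, paste0(rec$exam_id, ".npy")),
                dtype = "float32")
    }
    labels[[sp]] <- rbind(labels[[sp]],
                          data.frame(exam_id = rec$exam_id,
                                     abnormal = rec$triple[["abnormal"]],
                                     acl = rec$triple[["acl"]],
                                     meniscus = rec$triple[["meniscus"]]))
  }
  for (sp in c("train", "valid")) {
    lab <- labels[[sp]]
    if (is.null(lab)) {
      lab <- data.frame(exam_id = character(0), abnormal = integer(0),
                        acl = integer(0), meniscus = integer(0))
    }
    for (fnd in c("abnormal", "acl", "meniscus")) {
      utils::write.table(lab[, c("exam_id", fnd)],
                         file.path(root, paste0(sp, "-", fnd, ".csv")),
                         sep = ",", row.names = FALSE, col.names = FALSE,
                         quote = FALSE)
    }
  }
  list(train = load_dataset(root, "train", plane),
       valid = load_dataset(root, "valid", plane))
}
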