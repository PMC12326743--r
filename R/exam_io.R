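# MRNet-layout dataset I/O and label-powerset encoding.
#
# An exam carries three binary findings (general abnormality, ACL tear,
# meniscus tear). Only five of the eight conceivable triples occur -- a tear
# implies the abnormality flag -- and these five combinations are encoded as
# a single categorical class id 0..4 (label powerset).

.VALID_TRIPLES <- matrix(
  c(0L, 0L, 0L,
    1L, 0L, 0L,
    1L, 0L, 1L,
    1L, 1L, 0L,
    1L, 1L, 1L),
  ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("abnormal", "acl", "meniscus"))
)

#' Encode a label triple as a class id
#'
#' Maps the binary (abnormal, ACL tear, meniscus tear) triple to the
#' five-class powerset scheme: (0,0,0) -> 0, (1,0,0) -> 1, (1,0,1) -> 2,
#' (1,1,0) -> 3, (1,1,1) -> 4. Any other combination (a tear without the
#' abnormality flag, e.g. (0,1,0)) is rejected rather than silently mapped:
#' only these five combinations occur in the labeling scheme.
#'
#' @param triple Integer vector of length 3: `c(abnormal, acl, meniscus)`,
#'   each 0 or 1.
#' @return Integer class id in 0..4.
#' @examples
#' combine_labels(c(1, 1, 1)) # 4
#' combine_labels(c(1, 0, 1)) # 2
#' @export
combine_labels <- function(triple) {
  triple <- as.integer(triple)
  if (length(triple) != 3 || anyNA(triple) || !all(triple %in% c(0L, 1L))) {
    stop("label triple must be three binary values")
  }
  hit <- which(.VALID_TRIPLES[, 1] == triple[1] &
               .VALID_TRIPLES[, 2] == triple[2] &
               .VALID_TRIPLES[, 3] == triple[3])
  if (length(hit) == 0) {
    stop(sprintf("invalid label combination (%d, %d, %d): not one of the five observed triples",
                 triple[1], triple[2], triple[3]))
  }
  hit - 1L
}

#' Decode a class id back to its label triple
#'
#' Inverse of [combine_labels()].
#'
#' @param class_id Integer in 0..4.
#' @return Named integer vector `c(abnormal, acl, meniscus)`.
#' @export
class_to_triple <- function(class_id) {
  class_id <- as.integer(class_id)
  if (length(class_id) != 1 || is.na(class_id) || class_id < 0 || class_id > 4) {
    stop("class_id must be a single integer in 0..4")
  }
  .VALID_TRIPLES[class_id + 1L, ]
}

read_label_table <- function(path) {
  if (!file.exists(path)) stop("label table not found: ", path)
  if (length(readLines(path, n = 1L)) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  df <- utils::read.csv(path, header = FALSE, colClasses = "character",
                        strip.white = TRUE)
  if (ncol(df) != 2) stop("label table must have two columns: ", path)
  # optional header row c("exam","label")
  if (nrow(df) > 0 && tolower(df[1, 1]) %in% c("exam", "exam_id", "id") &&
      tolower(df[1, 2]) == "label") {
    df <- df[-1, , drop = FALSE]
  }
  if (nrow(df) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  if (!all(df[[2]] %in% c("0", "1"))) {
    bad <- df[[2]][!df[[2]] %in% c("0", "1")][1]
    stop(sprintf("non-binary label value '%s' in %s", bad, path))
  }
  if (anyDuplicated(df[[1]])) stop("duplicated exam ids in ", path)
  stats::setNames(as.integer(df[[2]]), df[[1]])
}

#' Read the three per-finding label tables
#'
#' Each table is a two-column CSV (exam id, 0/1 label), one file per finding;
#' a header row `exam,label` is accepted but not required. Exam ids are kept
#' as opaque text (zero padding preserved). All three tables must cover the
#' same id set.
#'
#' @param abnormal_table,acl_table,meniscus_table Paths to the three CSVs.
#' @return A data frame with character column `exam_id` and integer columns
#'   `abnormal`, `acl`, `meniscus`, one row per exam, in the abnormal table's
#'   order.
#' @export
read_label_tables <- function(abnormal_table, acl_table, meniscus_table) {
  ab <- read_label_table(abnormal_table)
  ac <- read_label_table(acl_table)
  me <- read_label_table(meniscus_table)
  ids <- names(ab)
  all_ids <- union(union(ids, names(ac)), names(me))
  for (tab in list(abnormal = ab, acl = ac, meniscus = me)) {
    miss <- setdiff(all_ids, names(tab))
    if (length(miss) > 0) {
      stop("missing label for exam(s) ", paste(utils::head(miss, 5), collapse = ", "),
           " in one of the label tables")
    }
  }
  data.frame(
    exam_id = ids,
    abnormal = unname(ab[ids]),
    acl = unname(ac[ids]),
    meniscus = unname(me[ids]),
    stringsAsFactors = FALSE
  )
}

exam_record <- function(exam_id, volumes, triple, class_id = NULL) {
  triple <- as.integer(triple)
  cid <- combine_labels(triple)
  if (!is.null(class_id) && as.integer(class_id) != cid) {
    stop("class_id inconsistent with label triple for exam ", exam_id)
  }
  structure(
    list(exam_id = as.character(exam_id), volumes = volumes,
         triple = stats::setNames(triple, c("abnormal", "acl", "meniscus")),
         class_id = cid),
    class = "exam_record"
  )
}

dataset_index <- function(records, split, plane, root = NULL) {
  ids <- vapply(records, function(r) r$exam_id, character(1))
  if (anyDuplicated(ids)) stop("duplicated exam ids in dataset index")
  cls <- vapply(records, function(r) r$class_id, integer(1))
  counts <- stats::setNames(integer(5), as.character(0:4))
  tab <- table(factor(cls, levels = 0:4))
  counts[names(tab)] <- as.integer(tab)
  structure(
    list(records = records, split = split, plane = plane,
         class_counts = counts, root = root,
         id_map = stats::setNames(seq_along(records), ids),
         cache = new.env(parent = emptyenv())),
    class = "dataset_index"
  )
}

#' @export
print.dataset_index <- function(x, ...) {
  cat(sprintf("<dataset_index> split=%s plane=%s n=%d\n", x$split, x$plane,
              length(x$records)))
  cat("  class counts:", paste(sprintf("%s:%d", names(x$class_counts),
                                       x$class_counts), collapse = " "), "\n")
  invisible(x)
}

#' Number of exams in a dataset index
#' @param index A dataset index.
#' @return Integer count.
#' @export
n_exams <- function(index) length(index$records)

#' Class ids present in a dataset index
#' @param index A dataset index.
#' @return Sorted integer vector of class ids with at least one exam.
#' @export
index_classes <- function(index) {
  sort(as.integer(names(index$class_counts)[index$class_counts > 0]))
}

#' Load an MRNet-layout dataset split
#'
#' Expects `<root>/<split>-abnormal.csv`, `<root>/<split>-acl.csv`,
#' `<root>/<split>-meniscus.csv` and one volume file
#' `<root>/<split>/<plane>/<exam_id>.npy` per labeled exam. Volumes are
#' loaded lazily (and cached) on first access through [get_volume()].
#'
#' @param root Dataset root directory.
#' @param split `"train"` or `"valid"`.
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @return A dataset index holding one record per labeled exam, with class
#'   counts derived through [combine_labels()].
#' @export
load_dataset <- function(root, split = c("train", "valid"),
                         plane = c("axial", "coronal", "sagittal")) {
  split <- match.arg(split)
  plane <- match.arg(plane)
  labels <- read_label_tables(
    file.path(root, paste0(split, "-abnormal.csv")),
    file.path(root, paste0(split, "-acl.csv")),
    file.path(root, paste0(split, "-meniscus.csv"))
  )
  records <- vector("list", nrow(labels))
  for (i in seq_len(nrow(labels))) {
    id <- labels$exam_id[i]
    path <- file.path(root, split, plane, paste0(id, ".npy"))
    if (!file.exists(path)) {
      stop(sprintf("missing volume for labeled exam %s: %s", id, path))
    }
    records[[i]] <- exam_record(
      id, stats::setNames(list(path), plane),
      c(labels$abnormal[i], labels$acl[i], labels$meniscus[i])
    )
  }
  dataset_index(records, split, plane, root = root)
}

#' Restrict a dataset index to a set of classes
#'
#' Used to realize the class-split experiment grammar (train on one subset of
#' the five classes, fine-tune/test on the disjoint remainder).
#'
#' @param index A dataset index.
#' @param classes Integer vector of class ids (subset of 0..4).
#' @param strict If `TRUE`, a requested class with no exams in `index` is an
#'   error; default is a warning.
#' @return A dataset index containing only the matching records, with class
#'   counts re-derived.
#' @export
subset_by_class <- function(index, classes, strict = FALSE) {
  classes <- as.integer(classes)
  if (!all(classes %in% 0:4)) stop("classes must be within 0..4")
  absent <- setdiff(classes, index_classes(index))
  if (length(absent) > 0) {
    msg <- paste("requested class(es) with no exams in index:",
                 paste(absent, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  keep <- vapply(index$records, function(r) r$class_id %in% classes, logical(1))
  out <- dataset_index(index$records[keep], index$split, index$plane,
                       root = index$root)
  out$cache <- index$cache # share the volume cache
  out
}

#' Fetch one exam's raw volume from an index
#'
#' Resolves the record's volume (file path or in-memory array) for the
#' index's plane, reading `.npy` files on first access and caching them.
#'
#' @param index A dataset index.
#' @param exam_id Exam id string.
#' @return A numeric array `(depth, height, width)`.
#' @export
get_volume <- function(index, exam_id) {
  pos <- unname(index$id_map[exam_id])
  if (is.na(pos)) stop("exam not in index: ", exam_id)
  rec <- index$records[[pos]]
  v <- rec$volumes[[index$plane]]
  if (is.null(v)) stop("no volume for plane ", index$plane, " in exam ", exam_id)
  if (is.character(v)) {
    key <- paste0(index$plane, "/", exam_id)
    if (!is.null(index$cache[[key]])) return(index$cache[[key]])
    arr <- read_npy(v)
    index$cache[[key]] <- arr
    return(arr)
  }
  v
}
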