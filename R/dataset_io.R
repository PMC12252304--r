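# ---------------------------------------------------------------------------
# YOLO-format annotation I/O, dataset manifests and the 7:2:1 split.
# ---------------------------------------------------------------------------

#' Read a YOLO-format label file
#'
#' Each non-blank line is `class cx cy w h` with normalized center
#' coordinates. Parsing is strict: a malformed line, an out-of-range
#' coordinate or an unknown class index raises an error naming the line.
#'
#' @param path label file path (may be empty).
#' @param n_classes number of valid classes (indices `0:(n_classes-1)`).
#' @return data.frame with columns class/cx/cy/w/h (zero rows for an empty
#'   file).
#' @export
read_yolo_labels <- function(path, n_classes = 2L) {
  if (!file.exists(path)) stop("label file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  out <- empty_labels()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\\s+")[[1]]
    if (length(f) != 5)
      stop("parse error at ", path, ":", i, ": expected 5 fields, got ",
           length(f))
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v)))
      stop("parse error at ", path, ":", i, ": non-numeric field")
    cls <- as.integer(v[1])
    if (cls < 0 || cls >= n_classes || v[1] != cls)
      stop("parse error at ", path, ":", i, ": unknown class index ", f[1])
    if (any(v[2:5] < 0) || any(v[2:5] > 1))
      stop("parse error at ", path, ":", i,
           ": coordinate out of range [0,1]")
    out <- rbind(out, data.frame(class = cls, cx = v[2], cy = v[3],
                                 w = v[4], h = v[5]))
  }
  out
}

#' Write labels in YOLO format
#'
#' One object per line, `class cx cy w h`, 6-decimal fixed point.
#'
#' @param labels data.frame class/cx/cy/w/h.
#' @param path output path.
#' @export
write_yolo_labels <- function(labels, path) {
  lines <- if (nrow(labels))
    sprintf("%d %.6f %.6f %.6f %.6f", labels$class, labels$cx, labels$cy,
            labels$w, labels$h)
  else character(0)
  writeLines(lines, path)
  invisible(path)
}

IMG_EXTS <- c("png", "tif", "tiff", "jpg")

#' Build a dataset manifest from a directory
#'
#' Discovers images by extension (png/tif/tiff/jpg) and pairs each with the
#' label file of the same basename. Every image must have exactly one label
#' file (an empty file is a valid annotation of "no objects").
#'
#' @param dir directory containing images and YOLO label files.
#' @param classes class-name table (index i-1 -> name i).
#' @return object of class `dataset_manifest`: list with `items` (data.frame
#'   image/label/split) and `classes`.
#' @export
build_manifest <- function(dir, classes = c("outer", "inner")) {
  files <- list.files(dir, full.names = TRUE)
  imgs <- files[tolower(tools::file_ext(files)) %in% IMG_EXTS]
  imgs <- sort(imgs)
  if (!length(imgs)) stop("no images found in ", dir)
  lbls <- paste0(tools::file_path_sans_ext(imgs), ".txt")
  missing <- !file.exists(lbls)
  if (any(missing))
    stop("missing label file(s): ", paste(basename(lbls[missing]), collapse = ", "))
  structure(list(items = data.frame(image = imgs, label = lbls,
                                    split = NA_character_,
                                    stringsAsFactors = FALSE),
                 classes = classes),
            class = "dataset_manifest")
}

#' Split a manifest into train/val/test
#'
#' Assigns items to splits by a seeded permutation with sizes apportioned by
#' the largest-remainder rule (ties broken train > val > test), so the sizes
#' always sum to the number of items. The default 7:2:1 follows the
#' conventional partition for this problem.
#'
#' @param manifest a [build_manifest()] result (or one returned here).
#' @param ratios positive weights for (train, val, test).
#' @param seed permutation seed.
#' @return the manifest with `items$split` filled in.
#' @export
split_dataset <- function(manifest, ratios = c(7, 2, 1), seed = 0L) {
  stopifnot(inherits(manifest, "dataset_manifest"), length(ratios) == 3,
            all(ratios > 0))
  n <- nrow(manifest$items)
  if (n < 3) stop("cannot split ", n, " items into three non-empty splits")
  sizes <- apportion(n, ratios)
  perm <- local_seed(seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(sizes[1])]] <- "train"
  split[perm[sizes[1] + seq_len(sizes[2])]] <- "val"
  split[perm[sizes[1] + sizes[2] + seq_len(sizes[3])]] <- "test"
  manifest$items$split <- split
  manifest
}

# largest-remainder apportionment; ties broken in order train > val > test;
# every split gets at least one item (possible whenever n >= 3)
apportion <- function(n, ratios) {
  q <- n * ratios / sum(ratios)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- q - base
    ord <- order(-frac, seq_along(frac))   # stable: earlier split wins ties
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  while (any(base == 0) && n >= length(ratios)) {
    base[which.max(base)] <- max(base) - 1
    base[which(base == 0)[1]] <- 1
  }
  as.integer(base)
}

#' Save / load a manifest as YAML
#' @param manifest a `dataset_manifest`.
#' @param path YAML file path.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(list(classes = as.list(manifest$classes),
                        items = lapply(seq_len(nrow(manifest$items)), function(i)
                          as.list(manifest$items[i, ]))), path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  y <- yaml::read_yaml(path)
  items <- do.call(rbind, lapply(y$items, function(it)
    data.frame(image = it$image, label = it$label,
               split = it$split %||% NA_character_, stringsAsFactors = FALSE)))
  structure(list(items = items, classes = unlist(y$classes)),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat("<dataset_manifest>", nrow(x$items), "items; classes:",
      paste(x$classes, collapse = ", "), "\n")
  if (!all(is.na(x$items$split)))
    print(table(x$items$split))
  invisible(x)
}

manifest_subset <- function(manifest, splits) {
  manifest$items <- manifest$items[manifest$items$split %in% splits, , drop = FALSE]
  manifest
}
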