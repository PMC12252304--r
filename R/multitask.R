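# ---------------------------------------------------------------------------
# Mask-driven multi-task supervision.
#
# The auxiliary task exploits the nesting of the two classes: stomata (inner)
# sit inside much larger epidermal cells (outer). Training happens in two
# phases: (1) pretraining on a half-sized subset whose labels keep only the
# outer class, teaching the network to localize the regions that contain
# stomata; (2) formal training on the full two-class annotations where a
# binary mask over supervised positions restricts optimization to the inner
# class, so gradient flow comes only from stomatal targets.
# ---------------------------------------------------------------------------

#' Binary class mask over supervised positions
#'
#' The mask is 1 exactly where the assigned label is `"inner"`, 0 at
#' `"outer"` and `"background"` positions.
#'
#' @param assigned_labels character matrix (or vector) of position tags, each
#'   one of `"inner"`, `"outer"`, `"background"`.
#' @return integer 0/1 mask with the same shape.
#' @export
build_class_mask <- function(assigned_labels) {
  known <- assigned_labels %in% c("inner", "outer", "background")
  if (!all(known))
    stop("unknown position tag(s): ",
         paste(unique(assigned_labels[!known]), collapse = ", "))
  m <- ifelse(assigned_labels == "inner", 1L, 0L)
  if (!is.null(dim(assigned_labels))) dim(m) <- dim(assigned_labels)
  m
}

#' Mean binary cross-entropy over all positions
#'
#' `-(1/N) * sum(y log p + (1-y) log(1-p))` with p clamped to
#' `[eps, 1-eps]`, `eps = 1e-7`.
#'
#' @param p predicted probabilities (any shape).
#' @param y ground-truth labels in \{0, 1\}, same shape.
#' @return non-negative scalar.
#' @export
bce_total <- function(p, y) {
  if (anyNA(p) || anyNA(y)) stop("NaN/NA in supervision grid")
  stopifnot(length(p) == length(y))
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Masked stomatal loss
#'
#' The per-position BCE is multiplied by the class mask and averaged over
#' masked positions, with the denominator guarded:
#' `sum(BCE * M) / max(sum(M), 1)`. An all-zero mask therefore gives exactly
#' 0 rather than a division failure.
#'
#' @param p,y as in [bce_total()].
#' @param mask 0/1 mask of the same shape (see [build_class_mask()]).
#' @return non-negative scalar.
#' @export
stoma_masked_loss <- function(p, y, mask) {
  if (length(p) != length(mask)) stop("mask shape does not match grid")
  if (anyNA(p) || anyNA(y)) stop("NaN/NA in supervision grid")
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  bce <- -(y * log(p) + (1 - y) * log(1 - p))
  sum(bce * mask) / max(sum(mask), 1)
}

#' Build the outer-only pretraining dataset
#'
#' Randomly selects `fraction` of the train and val items (per split,
#' seeded), strips all inner-class lines from their label files and writes
#' the stripped labels to `out_dir`. Images are referenced in place, not
#' copied.
#'
#' @param manifest a split [build_manifest()] manifest.
#' @param fraction fraction of each of train/val to sample (default 0.5).
#' @param seed sampling seed.
#' @param out_dir directory for the stripped label files.
#' @return a new `dataset_manifest` for the pretraining subset.
#' @export
make_pretrain_dataset <- function(manifest, fraction = 0.5, seed = 0L,
                                  out_dir = tempfile("pretrain")) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  items <- manifest$items
  keep <- list()
  for (sp in c("train", "val")) {
    idx <- which(items$split == sp)
    if (!length(idx)) stop("manifest has no '", sp, "' split")
    k <- max(1L, round(length(idx) * fraction))
    keep[[sp]] <- local_seed(sub_seed(seed, match(sp, c("train", "val"))),
                             sort(sample(idx, k)))
  }
  sel <- items[c(keep$train, keep$val), , drop = FALSE]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(sel))) {
    lb <- read_yolo_labels(sel$label[i])
    lb <- lb[lb$class == 0L, , drop = FALSE]
    new_path <- file.path(out_dir, basename(sel$label[i]))
    write_yolo_labels(lb, new_path)
    sel$label[i] <- new_path
  }
  structure(list(items = sel, classes = manifest$classes[1]),
            class = "dataset_manifest")
}

#' Multi-task detection loss
#'
#' The training loss over a batch with label assignment already performed:
#' classification BCE over all head positions plus IoU and distribution-focal
#' box terms at supervised positions. With `mask_inner_only = TRUE` (the
#' formal-training default) the positive classification targets and the box
#' terms are restricted by the inner-class mask: outer-assigned positions
#' carry the background (all-zero) classification target and contribute no
#' box loss, so only stomatal targets drive optimization. With
#' `mask_inner_only = FALSE` the standard both-class loss is recovered.
#'
#' @param model a [build_detector()] model.
#' @param fw a [graph_forward()] result for the batch.
#' @param assigned result of the label assigner for the batch targets.
#' @param mask_inner_only logical.
#' @return list: `loss` (scalar), `components`, `npos`, and `grad_out`
#'   (gradients on the head buffers, for backpropagation).
#' @export
multitask_loss <- function(model, fw, assigned, mask_inner_only = TRUE) {
  detection_loss_grad(model, fw, assigned, mask_inner_only = mask_inner_only)
}
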