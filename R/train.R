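# ---------------------------------------------------------------------------
# Training engine: in-memory dataset, seeded augmentation, SGD with momentum
# and cosine decay, the two-phase multi-task schedule, optional distillation,
# evaluation and checkpointing.
# ---------------------------------------------------------------------------

# Load one split into memory as letterboxed matrices + input-space labels.
load_split <- function(manifest, split, input_size) {
  items <- manifest$items[manifest$items$split == split, , drop = FALSE]
  lapply(seq_len(nrow(items)), function(i) {
    img <- read_micrograph(items$image[i])
    lb <- letterbox(img, input_size)
    labels <- read_yolo_labels(items$label[i])
    list(im = lb$x[, , 1, 1], labels = labels_to_input(labels, lb, input_size),
         lbinfo = lb)
  })
}

# seeded per-image flip/quarter-turn augmentation on a square letterboxed
# record; returns im matrix + labels
augment_record <- function(rec, seed) {
  draws <- local_runif(3, 0, 1, seed = seed)
  im <- rec$im; lb <- rec$labels
  if (draws[1] < 0.5) {  # horizontal flip
    im <- im[, rev(seq_len(ncol(im))), drop = FALSE]
    if (nrow(lb)) lb$cx <- 1 - lb$cx
  }
  if (draws[2] < 0.5) {  # vertical flip
    im <- im[rev(seq_len(nrow(im))), , drop = FALSE]
    if (nrow(lb)) lb$cy <- 1 - lb$cy
  }
  if (draws[3] < 0.25) { # quarter turn
    im <- t(im)[rev(seq_len(ncol(im))), , drop = FALSE]
    if (nrow(lb)) {
      new <- lb; new$cx <- lb$cy; new$cy <- 1 - lb$cx
      new$w <- lb$h; new$h <- lb$w
      lb <- new
    }
  }
  list(im = im, labels = lb)
}

make_batch <- function(records, idx, input_size, augment_seed = NULL) {
  B <- length(idx)
  x <- array(0, c(input_size, input_size, 3, B))
  targets <- vector("list", B)
  for (j in seq_len(B)) {
    rec <- records[[idx[j]]]
    if (!is.null(augment_seed)) rec <- augment_record(rec, sub_seed(augment_seed, j))
    x[, , 1, j] <- rec$im; x[, , 2, j] <- rec$im; x[, , 3, j] <- rec$im
    targets[[j]] <- rec$labels
  }
  list(x = x, targets = targets)
}

# SGD with momentum; weight decay applied to convolution kernels only
sgd_step <- function(params, grads, state, lr, momentum = 0.937,
                     weight_decay = 5e-4) {
  for (nm in ls(grads)) {
    g <- grads[[nm]]
    if (weight_decay > 0 && grepl("\\.(w|bank)$", nm))
      g <- g + weight_decay * params[[nm]]
    v <- state[[nm]]
    v <- if (is.null(v)) -lr * g else momentum * v - lr * g
    state[[nm]] <- v
    params[[nm]] <- params[[nm]] + v
  }
}

# cosine schedule with linear warmup (fractions of lr0)
lr_at <- function(step, total_steps, warmup_steps, lr0, lr_final_frac = 0.01) {
  if (step <= warmup_steps && warmup_steps > 0) return(lr0 * step / warmup_steps)
  t <- (step - warmup_steps) / max(total_steps - warmup_steps, 1)
  lr0 * (lr_final_frac + (1 - lr_final_frac) * 0.5 * (1 + cos(pi * min(t, 1))))
}

#' Train a detector on an in-memory dataset
#'
#' One training phase (used for outer-only pretraining, formal multi-task
#' training, plain training and distillation alike). Deterministic for fixed
#' (model seed, data, seed).
#'
#' @param model a [build_detector()] model (updated in place).
#' @param records list from the internal split loader.
#' @param epochs number of epochs.
#' @param batch_size batch size.
#' @param lr0 peak learning rate.
#' @param mask_inner_only restrict supervised positives to the inner class.
#' @param teacher optional frozen teacher model for distillation.
#' @param distill optional [distill_config()].
#' @param seed phase seed (shuffling, augmentation, distillation masks).
#' @param phase label written to the log rows.
#' @param log_file optional JSON-lines log path (appended).
#' @param epoch_offset epoch numbering offset for the log.
#' @param warmup_epochs warmup length in epochs.
#' @param augment apply seeded flip/rotation augmentation.
#' @param teacher_feats optional precomputed per-record teacher neck
#'   features (list parallel to `records`); computed on the fly when `NULL`.
#' @return list of per-epoch log rows (also appended to `log_file`).
#' @export
train_detector <- function(model, records, epochs, batch_size = 8L,
                           lr0 = 0.01, mask_inner_only = FALSE,
                           teacher = NULL, distill = NULL, seed = 0L,
                           phase = "train", log_file = NULL,
                           epoch_offset = 0L, warmup_epochs = 1L,
                           augment = TRUE, teacher_feats = NULL) {
  P <- model$graph$params
  n <- length(records)
  stopifnot(n > 0, epochs >= 0)
  input_size <- model$config$input_size
  state <- new.env(parent = emptyenv())
  steps_per_epoch <- ceiling(n / batch_size)
  total_steps <- epochs * steps_per_epoch
  warmup <- warmup_epochs * steps_per_epoch
  step <- 0L
  logs <- list()

  distiller <- NULL
  if (!is.null(teacher)) {
    stopifnot(inherits(distill, "distill_config"))
    # teacher features are cached per image, so the distillation phase runs
    # without geometric augmentation to keep student/teacher maps aligned
    augment <- FALSE
    scs <- names(model$neck_out)
    if (!identical(scs, names(teacher$neck_out)))
      stop("teacher/student scale sets differ: ",
           paste(names(teacher$neck_out), collapse = ","), " vs ",
           paste(scs, collapse = ","))
    # cache the frozen teacher's neck features per image (no augmentation),
    # unless a precomputed cache was supplied
    if (is.null(teacher_feats)) {
      teacher_feats <- vector("list", n)
      for (i in seq_len(n)) {
        b <- make_batch(records, i, input_size, augment_seed = NULL)
        tf <- graph_forward(teacher, b$x, train = FALSE)
        teacher_feats[[i]] <- lapply(scs, function(sc) tf$vals[[teacher$neck_out[[sc]]]])
        names(teacher_feats[[i]]) <- scs
      }
    }
    cs <- vapply(scs, function(sc) dim(teacher_feats[[1]][[sc]])[3], integer(1))
    # student channels from a shape probe
    b <- make_batch(records, 1L, input_size)
    sf <- graph_forward(model, b$x, train = FALSE)
    cs_student <- vapply(scs, function(sc) dim(sf$vals[[model$neck_out[[sc]]]])[3],
                         integer(1))
    distiller <- make_distiller(cs_student, cs, seed = sub_seed(distill$seed, 99L))
  }

  # without augmentation the targets are static, so label assignment can be
  # computed once per image and merged per batch (a pure reindexing)
  assign_cache <- NULL
  if (!augment)
    assign_cache <- lapply(records, function(r)
      assign_targets(model, list(r$labels), input_size))

  for (ep in seq_len(epochs)) {
    perm <- local_seed(sub_seed(seed, ep), sample.int(n))
    ep_loss <- 0; ep_dloss <- 0; nb <- 0
    for (bi in seq_len(steps_per_epoch)) {
      idx <- perm[((bi - 1L) * batch_size + 1L):min(bi * batch_size, n)]
      b <- make_batch(records, idx, input_size,
                      augment_seed = if (augment) sub_seed(seed, ep, bi) else NULL)
      fw <- graph_forward(model, b$x, train = TRUE)
      assigned <- if (is.null(assign_cache))
        assign_targets(model, b$targets, input_size)
      else merge_assignments(assign_cache[idx])
      lo <- detection_loss_grad(model, fw, assigned, mask_inner_only)
      loss <- lo$loss
      grad_out <- lo$grad_out
      dloss <- 0
      if (!is.null(distiller) && distill$alpha > 0) {
        scs <- names(model$neck_out)
        S <- lapply(scs, function(sc) fw$vals[[model$neck_out[[sc]]]])
        T <- lapply(seq_along(scs), function(k)
          abind_batch(lapply(idx, function(i) teacher_feats[[i]][[scs[k]]])))
        masks <- lapply(seq_along(scs), function(k)
          random_feature_mask(dim(S[[k]])[1:2], distill$lambda,
                              seed = sub_seed(distill$seed, ep, bi, k)))
        mg <- mgd_loss(S, T, masks, distiller, need_grad = TRUE)
        dloss <- mg$loss
        # inject alpha-weighted distillation gradients at the neck buffers so
        # one backward pass serves both loss terms
        for (k in seq_along(scs)) {
          nb_id <- as.character(model$neck_out[[scs[k]]])
          grad_out[[nb_id]] <- accum(grad_out[[nb_id]],
                                     mg$gs[[k]] * distill$alpha)
        }
        # update distiller parameters with plain SGD on the same schedule
        for (nm in names(mg$pg))
          distiller$params[[nm]] <- distiller$params[[nm]] -
            lr_at(step + 1L, total_steps, warmup, lr0) * distill$alpha * mg$pg[[nm]]
      }
      pg <- graph_backward(model, fw, grad_out)
      if (!is.finite(loss + dloss))
        stop("training diverged (non-finite loss) at epoch ",
             ep + epoch_offset, ", batch ", bi)
      step <- step + 1L
      lr <- lr_at(step, total_steps, warmup, lr0)
      sgd_step(P, pg, state, lr)
      ep_loss <- ep_loss + loss; ep_dloss <- ep_dloss + dloss; nb <- nb + 1
    }
    row <- list(phase = phase, epoch = ep + epoch_offset,
                loss = ep_loss / nb,
                distill_loss = if (is.null(distiller)) NULL else ep_dloss / nb,
                lr = lr_at(step, total_steps, warmup, lr0))
    logs[[ep]] <- row
    if (!is.null(log_file))
      cat(jsonlite::toJSON(row, auto_unbox = TRUE), "\n",
          file = log_file, append = TRUE)
  }
  logs
}

# merge per-image (single-sample) assignment results into one batch
# assignment; positions and targets are untouched, only the batch index is
# rewritten
merge_assignments <- function(per_image) {
  out <- per_image[[1]]
  for (sc in names(out)) {
    parts <- list()
    for (j in seq_along(per_image)) {
      p <- per_image[[j]][[sc]]$pos
      if (!is.null(p) && nrow(p)) { p$n <- j; parts[[length(parts) + 1L]] <- p }
    }
    out[[sc]]$pos <- if (length(parts)) do.call(rbind, parts) else NULL
  }
  out
}

# stack per-image (H,W,C,1) arrays along the batch dim
abind_batch <- function(lst) {
  d <- dim(lst[[1]])
  out <- array(0, c(d[1:3], length(lst)))
  for (i in seq_along(lst)) out[, , , i] <- lst[[i]]
  out
}

#' Evaluate a detector on an in-memory split
#'
#' Runs inference (evaluation confidence floor 0.001, class-wise NMS) on
#' every record and computes AP per class, mAP@0.5 and best-F1
#' precision/recall for the headline (inner) class.
#'
#' @param model a detector.
#' @param records list from the internal split loader.
#' @param iou_threshold matching threshold (default 0.5).
#' @param conf_threshold evaluation confidence floor.
#' @param nms_iou NMS threshold.
#' @return as [evaluate_detections()].
#' @export
evaluate_records <- function(model, records, iou_threshold = 0.5,
                             conf_threshold = 0.001, nms_iou = 0.7) {
  input_size <- model$config$input_size
  dets <- list(); gts <- list()
  bs <- 8L
  n <- length(records)
  for (b0 in seq(1, n, by = bs)) {
    idx <- b0:min(b0 + bs - 1L, n)
    b <- make_batch(records, idx, input_size)
    fw <- graph_forward(model, b$x, train = FALSE)
    for (j in seq_along(idx)) {
      det <- decode_heads(model, fw, j, conf_threshold, input_size)
      det <- nms(det, nms_iou)
      dets[[idx[j]]] <- det
      gts[[idx[j]]] <- b$targets[[j]]
    }
  }
  evaluate_detections(dets, gts, classes = seq_len(model$config$nc) - 1L,
                      iou_threshold = iou_threshold)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file embedding the configuration, all trainable
#' parameters and all buffers; loading rebuilds the graph and restores state
#' exactly.
#'
#' @param model a detector.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  P <- model$graph$params; B <- model$graph$buffers
  saveRDS(list(config = model$config,
               params = mget(ls(P), envir = P),
               buffers = mget(ls(B), envir = B)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_detector(ck$config)
  for (nm in names(ck$params)) model$graph$params[[nm]] <- ck$params[[nm]]
  for (nm in names(ck$buffers)) model$graph$buffers[[nm]] <- ck$buffers[[nm]]
  model
}
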