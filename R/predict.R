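# ---------------------------------------------------------------------------
# Inference: letterboxing, distribution-based box decoding, non-maximum
# suppression.
# ---------------------------------------------------------------------------

#' Letterbox an image to the square network input
#'
#' Aspect-preserving nearest-neighbour resize onto a gray canvas. Grayscale
#' input is replicated to three channels (the detector's input contract).
#'
#' @param image H x W matrix in [0,1].
#' @param size target side in pixels.
#' @return list: `x` array (size, size, 3, 1), `scale` (input px per image
#'   px), `pad` c(top, left) in input px.
#' @export
letterbox <- function(image, size) {
  H <- nrow(image); W <- ncol(image)
  s <- size / max(H, W)
  nh <- max(1L, round(H * s)); nw <- max(1L, round(W * s))
  sy <- pmin(H, pmax(1, round(seq(0.5, H - 0.5, length.out = nh) + 0.5)))
  sx <- pmin(W, pmax(1, round(seq(0.5, W - 0.5, length.out = nw) + 0.5)))
  canvas <- matrix(0.5, size, size)
  top <- (size - nh) %/% 2L; left <- (size - nw) %/% 2L
  canvas[top + seq_len(nh), left + seq_len(nw)] <- image[sy, sx]
  x <- array(0, c(size, size, 3, 1))
  x[, , 1, 1] <- canvas; x[, , 2, 1] <- canvas; x[, , 3, 1] <- canvas
  list(x = x, scale = s, pad = c(top, left), orig = c(H, W))
}

# map labels (normalized to the original image) into letterboxed input coords
labels_to_input <- function(labels, lb, size) {
  if (!nrow(labels)) return(labels)
  H <- lb$orig[1]; W <- lb$orig[2]
  out <- labels
  out$cx <- (labels$cx * W * lb$scale + lb$pad[2]) / size
  out$cy <- (labels$cy * H * lb$scale + lb$pad[1]) / size
  out$w <- labels$w * W * lb$scale / size
  out$h <- labels$h * H * lb$scale / size
  out
}

# inverse: detections in input coords -> normalized original-image coords
detections_to_image <- function(det, lb, size) {
  if (!nrow(det)) return(det)
  H <- lb$orig[1]; W <- lb$orig[2]
  det$cx <- (det$cx * size - lb$pad[2]) / (W * lb$scale)
  det$cy <- (det$cy * size - lb$pad[1]) / (H * lb$scale)
  det$w <- det$w * size / (W * lb$scale)
  det$h <- det$h * size / (H * lb$scale)
  clamp_det(det)
}

clamp_det <- function(det) {
  if (!nrow(det)) return(det)
  x0 <- pmax(det$cx - det$w / 2, 0); x1 <- pmin(det$cx + det$w / 2, 1)
  y0 <- pmax(det$cy - det$h / 2, 0); y1 <- pmin(det$cy + det$h / 2, 1)
  keep <- x1 > x0 & y1 > y0
  det <- det[keep, , drop = FALSE]
  if (nrow(det)) {
    det$cx <- (x0[keep] + x1[keep]) / 2; det$cy <- (y0[keep] + y1[keep]) / 2
    det$w <- x1[keep] - x0[keep]; det$h <- y1[keep] - y0[keep]
  }
  det
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# decode one sample's head maps into candidate detections (input-normalized)
decode_heads <- function(model, fw, n = 1L, conf_threshold = 0.25,
                         input_size = NULL) {
  if (is.null(input_size)) input_size <- model$config$input_size
  nc <- model$config$nc
  out <- list()
  for (sc in names(model$heads)) {
    stride <- SCALE_STRIDES[[sc]]
    bm <- fw$vals[[model$heads[[sc]]$box]]
    cm <- fw$vals[[model$heads[[sc]]$cls]]
    Hm <- dim(bm)[1]; Wm <- dim(bm)[2]
    P <- Hm * Wm
    box <- matrix(bm[, , , n], P, 4L * REG_MAX)
    cls <- matrix(sigmoid(cm[, , , n]), P, nc)
    best <- max.col(cls, ties.method = "first")
    conf <- cls[cbind(seq_len(P), best)]
    keep <- which(conf >= conf_threshold)
    if (!length(keep)) next
    # DFL expectation per side, in stride units
    d <- matrix(0, length(keep), 4)
    bins <- 0:(REG_MAX - 1L)
    for (s4 in 1:4) {
      z <- box[keep, (s4 - 1L) * REG_MAX + seq_len(REG_MAX), drop = FALSE]
      z <- exp(z - apply(z, 1, max))
      z <- z / rowSums(z)
      d[, s4] <- as.numeric(z %*% bins)
    }
    iy <- (keep - 1L) %% Hm; ix <- (keep - 1L) %/% Hm
    acx <- (ix + 0.5) * stride; acy <- (iy + 0.5) * stride
    x0 <- acx - d[, 1] * stride; y0 <- acy - d[, 2] * stride
    x1 <- acx + d[, 3] * stride; y1 <- acy + d[, 4] * stride
    out[[sc]] <- data.frame(class = best[keep] - 1L, conf = conf[keep],
                            cx = (x0 + x1) / 2 / input_size,
                            cy = (y0 + y1) / 2 / input_size,
                            w = (x1 - x0) / input_size,
                            h = (y1 - y0) / input_size)
  }
  det <- if (length(out)) do.call(rbind, out) else
    data.frame(class = integer(0), conf = numeric(0), cx = numeric(0),
               cy = numeric(0), w = numeric(0), h = numeric(0))
  rownames(det) <- NULL
  det[order(-det$conf), , drop = FALSE]
}

#' Class-wise non-maximum suppression
#'
#' Greedy suppression in confidence order; no retained pair of same-class
#' boxes overlaps above `iou_threshold`.
#'
#' @param det data.frame class/conf/cx/cy/w/h, any coordinate system.
#' @param iou_threshold suppression threshold.
#' @return the retained subset, sorted by confidence.
#' @export
nms <- function(det, iou_threshold = 0.7) {
  if (!nrow(det)) return(det)
  det <- det[order(-det$conf), , drop = FALSE]
  keep <- logical(nrow(det))
  for (cl in unique(det$class)) {
    idx <- which(det$class == cl)
    sub <- det[idx, , drop = FALSE]
    iou <- box_iou(sub, sub)
    alive <- rep(TRUE, length(idx))
    for (i in seq_along(idx)) {
      if (!alive[i]) next
      keep[idx[i]] <- TRUE
      if (i < length(idx)) {
        kill <- which(alive & iou[i, ] > iou_threshold)
        kill <- kill[kill > i]
        alive[kill] <- FALSE
      }
    }
  }
  out <- det[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the detector on one image
#'
#' Letterboxes the image, runs a forward pass, decodes the distribution-based
#' box regression, applies class-wise NMS and maps boxes back to coordinates
#' normalized to the original image.
#'
#' @param model a [build_detector()] model.
#' @param image H x W matrix in [0,1], or a path readable by
#'   [read_micrograph()].
#' @param conf_threshold minimum confidence (0.25 deployment default; use
#'   0.001 for evaluation sweeps).
#' @param nms_iou NMS IoU threshold (default 0.7).
#' @return data.frame class/conf/cx/cy/w/h sorted by confidence, boxes inside
#'   the unit square.
#' @export
predict_image <- function(model, image, conf_threshold = 0.25, nms_iou = 0.7) {
  stopifnot(conf_threshold >= 0, conf_threshold <= 1,
            nms_iou >= 0, nms_iou <= 1)
  if (is.character(image)) image <- read_micrograph(image)
  size <- model$config$input_size
  lb <- letterbox(image, size)
  fw <- graph_forward(model, lb$x, train = FALSE)
  det <- decode_heads(model, fw, 1L, conf_threshold, size)
  det <- nms(det, nms_iou)
  detections_to_image(det, lb, size)
}

#' @export
#' @rdname predict_image
predict.detection_model <- function(object, image, conf_threshold = 0.25,
                                    nms_iou = 0.7, ...) {
  predict_image(object, image, conf_threshold, nms_iou)
}
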