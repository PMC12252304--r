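# ---------------------------------------------------------------------------
# Label assignment and the detection loss (classification BCE + IoU +
# distribution-focal box regression), with analytic gradients onto the head
# maps. The mask-driven multi-task mode restricts the supervised positive
# terms to inner-class (stomatal) positions; background negatives are kept,
# and positions claimed by outer-class boxes carry the same all-zero
# classification target as background, so adding or moving outer-class boxes
# leaves the training loss unchanged.
# ---------------------------------------------------------------------------

LOSS_W <- c(box = 7.5, cls = 0.5, dfl = 1.5)

# Assign ground-truth boxes to head cells (static center-prior rule).
#
# A cell is a candidate for a box at a given scale when the cell center lies
# inside the box and within 2.5 strides of the box center, and the box fits
# the scale's regression range (half-extent under 15.5 strides). Each cell
# takes the smallest-area candidate box. Returns, per scale, the positive
# cells with class tags and LTRB distances in stride units.
assign_targets <- function(model, targets, input_size = NULL) {
  if (is.null(input_size)) input_size <- model$config$input_size
  out <- list()
  for (sc in names(model$heads)) {
    st <- SCALE_STRIDES[[sc]]
    Hm <- input_size %/% st; Wm <- input_size %/% st
    pos <- list()
    for (n in seq_along(targets)) {
      tb <- targets[[n]]
      if (is.null(tb) || !nrow(tb)) next
      px <- tb$cx * input_size; py <- tb$cy * input_size
      pw <- tb$w * input_size; ph <- tb$h * input_size
      fits <- pmax(pw, ph) / 2 <= 15.5 * st & pmax(pw, ph) >= 0.75 * st
      cand <- which(fits)
      if (!length(cand)) next
      rows <- vector("list", length(cand))
      for (j in seq_along(cand)) {
        gi <- cand[j]
        x0 <- max(px[gi] - pw[gi] / 2, px[gi] - 2.5 * st)
        x1 <- min(px[gi] + pw[gi] / 2, px[gi] + 2.5 * st)
        y0 <- max(py[gi] - ph[gi] / 2, py[gi] - 2.5 * st)
        y1 <- min(py[gi] + ph[gi] / 2, py[gi] + 2.5 * st)
        # cells whose center (ix + 0.5) * st falls strictly inside [x0, x1]
        ix <- seq.int(max(0L, floor(x0 / st - 0.5) + 1L),
                      min(Wm - 1L, ceiling(x1 / st - 0.5) - 1L))
        iy <- seq.int(max(0L, floor(y0 / st - 0.5) + 1L),
                      min(Hm - 1L, ceiling(y1 / st - 0.5) - 1L))
        ix <- ix[(ix + 0.5) * st > x0 & (ix + 0.5) * st < x1]
        iy <- iy[(iy + 0.5) * st > y0 & (iy + 0.5) * st < y1]
        if (!length(ix) || !length(iy)) next
        cells <- as.integer(outer(iy + 1L, ix * Hm, "+"))
        rows[[j]] <- data.frame(p = cells, gi = gi, area = pw[gi] * ph[gi])
      }
      rows <- do.call(rbind, rows)
      if (is.null(rows) || !nrow(rows)) next
      # each cell takes the smallest-area candidate box
      rows <- rows[order(rows$area), , drop = FALSE]
      rows <- rows[!duplicated(rows$p), , drop = FALSE]
      gi <- rows$gi; hit <- rows$p
      iy <- (hit - 1L) %% Hm; ix <- (hit - 1L) %/% Hm
      acx <- (ix + 0.5) * st; acy <- (iy + 0.5) * st
      pos[[length(pos) + 1L]] <- data.frame(
        n = n, p = hit, cls = tb$class[gi],
        l = pmin(pmax((acx - (px[gi] - pw[gi] / 2)) / st, 0), REG_MAX - 1.01),
        t = pmin(pmax((acy - (py[gi] - ph[gi] / 2)) / st, 0), REG_MAX - 1.01),
        r = pmin(pmax(((px[gi] + pw[gi] / 2) - acx) / st, 0), REG_MAX - 1.01),
        b = pmin(pmax(((py[gi] + ph[gi] / 2) - acy) / st, 0), REG_MAX - 1.01))
    }
    out[[sc]] <- list(Hm = Hm, Wm = Wm, stride = st,
                      pos = if (length(pos)) do.call(rbind, pos) else NULL)
  }
  out
}

# Full detection loss and its gradients on the head output buffers.
#
# mask_inner_only: positive terms restricted to inner-class (class 1) cells;
# outer-class cells carry the background (all-zero) classification target and
# no box loss.
detection_loss_grad <- function(model, fw, assigned, mask_inner_only = FALSE,
                                weights = LOSS_W, need_grad = TRUE) {
  nc <- model$config$nc
  grad_out <- list()
  L_cls <- 0; L_box <- 0; L_dfl <- 0
  # positive count for normalization (inner-only in masked mode), Eq-3 guard
  npos <- 0L
  for (sc in names(model$heads)) {
    a <- assigned[[sc]]
    if (!is.null(a$pos)) {
      sel <- if (mask_inner_only) a$pos$cls == 1L else rep(TRUE, nrow(a$pos))
      npos <- npos + sum(sel)
    }
  }
  norm <- max(npos, 1L)
  bins <- 0:(REG_MAX - 1L)
  for (sc in names(model$heads)) {
    a <- assigned[[sc]]
    cm <- fw$vals[[model$heads[[sc]]$cls]]
    bm <- fw$vals[[model$heads[[sc]]$box]]
    d <- dim(cm); P <- d[1] * d[2]; N <- d[4]
    # rows indexed p + P*(n-1), columns = class
    zc <- matrix(aperm(cm, c(1, 2, 4, 3)), P * N, nc)
    tc <- matrix(0, P * N, nc)
    pos <- a$pos
    use <- NULL
    if (!is.null(pos)) {
      use <- if (mask_inner_only) which(pos$cls == 1L) else seq_len(nrow(pos))
      if (length(use)) {
        rows <- pos$p[use] + P * (pos$n[use] - 1L)
        tc[cbind(rows, pos$cls[use] + 1L)] <- 1
      }
    }
    s <- 1 / (1 + exp(-zc))
    eps <- 1e-9
    L_cls <- L_cls + sum(-(tc * log(s + eps) + (1 - tc) * log(1 - s + eps)))
    if (need_grad) {
      gz <- (s - tc) * weights[["cls"]] / norm
      gcm <- aperm(array(gz, c(d[1], d[2], d[4], nc)), c(1, 2, 4, 3))
      grad_out[[as.character(model$heads[[sc]]$cls)]] <- gcm
    }
    # box terms
    gbm <- if (need_grad) array(0, dim(bm)) else NULL
    if (!is.null(pos) && length(use)) {
      pu <- pos[use, , drop = FALSE]
      tmat <- as.matrix(pu[, c("l", "t", "r", "b")])
      np <- nrow(pu)
      dpred <- matrix(0, np, 4)
      pk <- vector("list", 4)
      zb <- matrix(aperm(bm, c(1, 2, 4, 3)), P * N, 4L * REG_MAX)
      rows <- pu$p + P * (pu$n - 1L)
      for (s4 in 1:4) {
        zz <- zb[rows, (s4 - 1L) * REG_MAX + seq_len(REG_MAX), drop = FALSE]
        zz <- zz - apply(zz, 1, max)
        pp <- exp(zz); pp <- pp / rowSums(pp)
        pk[[s4]] <- pp
        dpred[, s4] <- as.numeric(pp %*% bins)
      }
      # IoU of predicted vs target LTRB (shared anchor)
      iw <- pmin(dpred[, 1], tmat[, 1]) + pmin(dpred[, 3], tmat[, 3])
      ih <- pmin(dpred[, 2], tmat[, 2]) + pmin(dpred[, 4], tmat[, 4])
      I <- pmax(iw, 0) * pmax(ih, 0)
      Ap <- (dpred[, 1] + dpred[, 3]) * (dpred[, 2] + dpred[, 4])
      Ag <- (tmat[, 1] + tmat[, 3]) * (tmat[, 2] + tmat[, 4])
      U <- Ap + Ag - I
      iou <- ifelse(U > 0, I / U, 0)
      L_box <- L_box + sum(1 - iou)
      # DFL: cross-entropy against the two adjacent bins
      li <- pmin(floor(tmat), REG_MAX - 2)
      wr <- tmat - li
      for (s4 in 1:4) {
        pp <- pk[[s4]]
        p_lo <- pp[cbind(seq_len(np), li[, s4] + 1L)]
        p_hi <- pp[cbind(seq_len(np), li[, s4] + 2L)]
        L_dfl <- L_dfl + sum(-((1 - wr[, s4]) * log(p_lo + 1e-9) +
                               wr[, s4] * log(p_hi + 1e-9)))
      }
      if (need_grad) {
        # dIoU/dd for each side
        dI <- cbind(ifelse(dpred[, 1] < tmat[, 1], ih, 0),
                    ifelse(dpred[, 2] < tmat[, 2], iw, 0),
                    ifelse(dpred[, 3] < tmat[, 3], ih, 0),
                    ifelse(dpred[, 4] < tmat[, 4], iw, 0))
        dAp <- cbind(dpred[, 2] + dpred[, 4], dpred[, 1] + dpred[, 3],
                     dpred[, 2] + dpred[, 4], dpred[, 1] + dpred[, 3])
        dU <- dAp - dI
        diou_dd <- (dI * U - I * dU) / pmax(U^2, 1e-9)
        gd <- -diou_dd * weights[["box"]] / norm      # d(1-IoU)/dd
        gzb_rows <- matrix(0, np, 4L * REG_MAX)
        for (s4 in 1:4) {
          pp <- pk[[s4]]
          # IoU loss through the softmax expectation
          gz_iou <- pp * (matrix(bins, np, REG_MAX, byrow = TRUE) - dpred[, s4]) *
            gd[, s4]
          # DFL cross-entropy: softmax minus soft target
          ysoft <- matrix(0, np, REG_MAX)
          ysoft[cbind(seq_len(np), li[, s4] + 1L)] <- 1 - wr[, s4]
          ysoft[cbind(seq_len(np), li[, s4] + 2L)] <-
            ysoft[cbind(seq_len(np), li[, s4] + 2L)] + wr[, s4]
          gz_dfl <- (pp - ysoft) * weights[["dfl"]] / norm
          gzb_rows[, (s4 - 1L) * REG_MAX + seq_len(REG_MAX)] <- gz_iou + gz_dfl
        }
        gzb <- matrix(0, P * N, 4L * REG_MAX)
        gzb[rows, ] <- gzb_rows
        gbm <- aperm(array(gzb, c(d[1], d[2], N, 4L * REG_MAX)), c(1, 2, 4, 3))
      }
    }
    if (need_grad)
      grad_out[[as.character(model$heads[[sc]]$box)]] <-
        if (is.null(gbm)) array(0, dim(bm)) else gbm
  }
  total <- weights[["cls"]] * L_cls / norm + weights[["box"]] * L_box / norm +
    weights[["dfl"]] * L_dfl / norm
  list(loss = total,
       components = c(cls = L_cls / norm, box = L_box / norm,
                      dfl = L_dfl / norm),
       npos = npos, grad_out = grad_out)
}
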