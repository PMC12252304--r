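# ---------------------------------------------------------------------------
# Synthetic epidermis micrographs.
#
# Emulates the structure of grayscale FE-SEM leaf-surface imagery: large
# low-contrast epidermal (pavement) cells tiling the field of view, each
# containing a small number of stomatal complexes rendered as a pair of
# bright guard cells around a dark central slit. Every stoma is strictly
# nested inside one epidermal cell, giving the two-class annotation
# (outer = 0 epidermal cell, inner = 1 stomatal complex) with the inner class
# firmly in the small-object regime.
# ---------------------------------------------------------------------------

#' Scene specification for the synthetic generator
#'
#' @param width,height canvas size in pixels (reference 1360 x 1024).
#' @param n_cells number of epidermal (outer) cells; 0 gives pure background.
#' @param stomata_per_cell integer range (min, max) of stomata per cell.
#' @param stoma_frac range (min, max) of the stoma major diameter as a
#'   fraction of the image minimum dimension. Default 0.02-0.08: small
#'   objects, 2-8% of the short side.
#' @param bg_level background gray level in [0, 1].
#' @param texture_amp amplitude of the low-frequency background texture.
#' @param noise_sd standard deviation of the additive sensor noise.
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(width = 1360L, height = 1024L, n_cells = 12L,
                       stomata_per_cell = c(1L, 3L),
                       stoma_frac = c(0.02, 0.08),
                       bg_level = 0.35, texture_amp = 0.06,
                       noise_sd = 0.03, seed = 0L) {
  stopifnot(width >= 8, height >= 8, n_cells >= 0,
            length(stomata_per_cell) == 2, all(stomata_per_cell >= 0),
            stomata_per_cell[1] <= stomata_per_cell[2],
            length(stoma_frac) == 2, all(stoma_frac > 0), all(stoma_frac < 1),
            stoma_frac[1] <= stoma_frac[2],
            bg_level >= 0, bg_level <= 1, texture_amp >= 0, noise_sd >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_cells = as.integer(n_cells),
                 stomata_per_cell = as.integer(stomata_per_cell),
                 stoma_frac = stoma_frac, bg_level = bg_level,
                 texture_amp = texture_amp, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

empty_labels <- function() {
  data.frame(class = integer(0), cx = numeric(0), cy = numeric(0),
             w = numeric(0), h = numeric(0))
}

#' Generate one synthetic micrograph with nested two-class labels
#'
#' Epidermal cells are laid out on a jittered grid (so they tile the canvas
#' without mutual containment); each cell receives its stomata strictly
#' inside its interior, so every inner box passes a point-in-box containment
#' test against exactly one outer box.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (H x W matrix in [0,1], row = y, origin top-left)
#'   and `labels` (data.frame class/cx/cy/w/h, normalized center format).
#' @export
generate_micrograph <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  local_seed(spec$seed, .generate_micrograph_impl(spec))
}

.generate_micrograph_impl <- function(spec) {
  W <- spec$width; H <- spec$height
  mind <- min(W, H)
  img <- matrix(spec$bg_level, H, W)

  # low-frequency texture: bilinear upsample of a coarse random field
  if (spec$texture_amp > 0) {
    gh <- 8L; gw <- 8L
    coarse <- matrix(stats::runif(gh * gw, -1, 1), gh, gw)
    fy <- seq(1, gh, length.out = H); fx <- seq(1, gw, length.out = W)
    y0 <- pmin(floor(fy), gh - 1); x0 <- pmin(floor(fx), gw - 1)
    ty <- fy - y0; tx <- fx - x0
    tex <- (1 - ty) * coarse[y0, x0] + ty * coarse[y0 + 1, x0]
    tex2 <- (1 - ty) * coarse[y0, x0 + 1] + ty * coarse[y0 + 1, x0 + 1]
    img <- img + spec$texture_amp * ((1 - outer(rep(1, H), tx)) * tex +
                                     outer(rep(1, H), tx) * tex2)
  }

  labels <- empty_labels()
  if (spec$n_cells > 0) {
    # jittered grid layout for the epidermal cells
    nc <- spec$n_cells
    ncol_g <- max(1L, round(sqrt(nc * W / H)))
    nrow_g <- ceiling(nc / ncol_g)
    slots <- expand.grid(r = seq_len(nrow_g), c = seq_len(ncol_g))
    slots <- slots[seq_len(min(nc, nrow(slots))), , drop = FALSE]
    if (nrow(slots) < nc)
      stop("generation failure: cannot lay out ", nc, " cells on the canvas")
    cw <- W / ncol_g; ch <- H / nrow_g
    smax <- spec$stoma_frac[2] * mind
    if (smax * 1.6 >= min(cw, ch))
      stop("generation failure: requested stoma size (", round(smax),
           " px) does not fit inside a ", round(cw), "x", round(ch),
           " px epidermal cell; reduce stoma_frac or n_cells")
    for (i in seq_len(nrow(slots))) {
      x0 <- (slots$c[i] - 1) * cw; y0 <- (slots$r[i] - 1) * ch
      # jitter the cell rectangle inside its slot (cells never overlap)
      jx <- stats::runif(2, 0.008, 0.05) * cw
      jy <- stats::runif(2, 0.008, 0.05) * ch
      cx0 <- x0 + jx[1]; cx1 <- x0 + cw - jx[2]
      cy0 <- y0 + jy[1]; cy1 <- y0 + ch - jy[2]
      img <- draw_cell(img, cx0, cy0, cx1, cy1)
      labels <- rbind(labels, data.frame(
        class = 0L, cx = (cx0 + cx1) / 2 / W, cy = (cy0 + cy1) / 2 / H,
        w = (cx1 - cx0) / W, h = (cy1 - cy0) / H))
      ns <- if (spec$stomata_per_cell[2] > spec$stomata_per_cell[1])
        sample(spec$stomata_per_cell[1]:spec$stomata_per_cell[2], 1)
      else spec$stomata_per_cell[1]
      placed <- empty_labels()
      for (s in seq_len(ns)) {
        for (attempt in 1:25) {
          diam <- stats::runif(1, spec$stoma_frac[1], spec$stoma_frac[2]) * mind
          a <- diam / 2                      # major semi-axis
          b <- a * stats::runif(1, 0.55, 0.8)  # minor semi-axis
          th <- stats::runif(1, 0, pi)
          hx <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
          hy <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
          margin <- 3
          if (cx1 - cx0 < 2 * (hx + margin) || cy1 - cy0 < 2 * (hy + margin)) next
          scx <- stats::runif(1, cx0 + hx + margin, cx1 - hx - margin)
          scy <- stats::runif(1, cy0 + hy + margin, cy1 - hy - margin)
          cand <- data.frame(class = 1L, cx = scx / W, cy = scy / H,
                             w = 2 * hx / W, h = 2 * hy / H)
          # avoid overlapping stomata within the cell
          if (nrow(placed) == 0 ||
              all(box_iou_mat(cand, placed) < 0.05)) {
            img <- draw_stoma(img, scx, scy, a, b, th)
            placed <- rbind(placed, cand)
            break
          }
        }
      }
      labels <- rbind(labels, placed)
    }
  }

  if (spec$noise_sd > 0)
    img <- img + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, labels = labels)
}

# a low-contrast rounded rectangle with a darker border
draw_cell <- function(img, x0, y0, x1, y1) {
  H <- nrow(img); W <- ncol(img)
  xs <- max(1, floor(x0)):min(W, ceiling(x1))
  ys <- max(1, floor(y0)):min(H, ceiling(y1))
  cx <- (x0 + x1) / 2; cy <- (y0 + y1) / 2
  ax <- (x1 - x0) / 2; ay <- (y1 - y0) / 2
  u <- abs((xs - cx) / ax); v <- abs((ys - cy) / ay)
  d <- sqrt(outer(v^4, u^4, "+"))          # superellipse radius^4 metric
  inside <- d <= 1
  border <- d > 0.86 & d <= 1
  block <- img[ys, xs, drop = FALSE]
  block[inside] <- block[inside] + 0.07
  block[border] <- block[border] - 0.18
  img[ys, xs] <- block
  img
}

# paired bright guard cells around a dark central slit
draw_stoma <- function(img, cx, cy, a, b, th) {
  H <- nrow(img); W <- ncol(img)
  hx <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  hy <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  xs <- max(1, floor(cx - hx - 1)):min(W, ceiling(cx + hx + 1))
  ys <- max(1, floor(cy - hy - 1)):min(H, ceiling(cy + hy + 1))
  X <- outer(rep(1, length(ys)), xs - cx)
  Y <- outer(ys - cy, rep(1, length(xs)))
  U <- (cos(th) * X + sin(th) * Y) / a     # along the pore axis
  V <- (-sin(th) * X + cos(th) * Y) / b
  r2 <- U^2 + V^2
  body <- r2 <= 1
  rim <- r2 > 0.78 & r2 <= 1
  slit <- abs(V) < 0.16 & abs(U) < 0.82
  block <- img[ys, xs, drop = FALSE]
  block[body] <- block[body] + 0.38 * (1 - r2[body] * 0.35)
  block[rim] <- block[rim] - 0.10
  block[body & slit] <- block[body & slit] - 0.45
  img[ys, xs] <- block
  img
}

#' Mosaic several micrographs into one image
#'
#' Splices a k x k grid of equally sized tiles into a single image of the
#' same size (each tile is downscaled by 1/k), rescaling and offsetting every
#' box label into its grid cell. This emulates lower-magnification fields of
#' view built from single-cell captures.
#'
#' @param tiles list of `list(image=, labels=)` records, all the same size;
#'   length must be `k^2` (tiles are placed row-major).
#' @param k grid side (k >= 1).
#' @return a `list(image=, labels=)` record.
#' @export
mosaic <- function(tiles, k) {
  stopifnot(k >= 1, length(tiles) == k * k)
  dims <- vapply(tiles, function(t) dim(t$image), integer(2))
  if (any(dims != dims[, 1]))
    stop("dimension mismatch: all mosaic tiles must have identical size")
  if (k == 1) return(tiles[[1]])
  H <- dims[1, 1]; W <- dims[2, 1]
  th <- H %/% k; tw <- W %/% k
  out <- matrix(0, th * k, tw * k)
  labels <- empty_labels()
  for (r in seq_len(k)) for (cc in seq_len(k)) {
    t <- tiles[[(r - 1) * k + cc]]
    # nearest-neighbour 1/k downscale
    sy <- round(seq(1, H, length.out = th)); sx <- round(seq(1, W, length.out = tw))
    out[(r - 1) * th + seq_len(th), (cc - 1) * tw + seq_len(tw)] <-
      t$image[sy, sx]
    if (nrow(t$labels)) {
      lb <- t$labels
      lb$cx <- (lb$cx + cc - 1) / k
      lb$cy <- (lb$cy + r - 1) / k
      lb$w <- lb$w / k
      lb$h <- lb$h / k
      labels <- rbind(labels, lb)
    }
  }
  list(image = out, labels = labels)
}

AUGMENT_OPS <- c("rotate90k", "rotate", "brightness", "gaussian_noise",
                 "hflip", "vflip")

#' Apply one augmentation to an image and its labels
#'
#' Pixel and label transforms are kept consistent; boxes are clamped to the
#' unit square and boxes that fall fully outside the frame are removed (the
#' number removed is reported in the `"dropped"` attribute).
#'
#' @param image H x W matrix in [0,1].
#' @param labels data.frame class/cx/cy/w/h.
#' @param op_spec list with `op` (one of rotate90k, rotate, brightness,
#'   gaussian_noise, hflip, vflip) and its parameter: `k` (quarter-turns,
#'   counter-clockwise), `angle` (degrees, free rotation; boxes are refit
#'   axis-aligned and so may grow), `factor` (brightness), `sd` (noise).
#' @param seed seed for the stochastic ops.
#' @return `list(image=, labels=)`, labels carrying attribute `"dropped"`.
#' @export
augment <- function(image, labels, op_spec, seed = 0L) {
  if (!is.list(op_spec) || is.null(op_spec$op) || !op_spec$op %in% AUGMENT_OPS)
    stop("unknown augmentation op: supported ops are ",
         paste(AUGMENT_OPS, collapse = ", "))
  dropped <- 0L
  out <- switch(op_spec$op,
    rotate90k = {
      k <- (op_spec$k %||% 1L) %% 4L
      im <- image; lb <- labels
      for (i in seq_len(k)) {
        # 90 degrees counter-clockwise: (x, y) -> (y, 1 - x)
        im <- t(im)[rev(seq_len(ncol(im))), , drop = FALSE]
        if (nrow(lb)) {
          new <- lb
          new$cx <- lb$cy; new$cy <- 1 - lb$cx
          new$w <- lb$h; new$h <- lb$w
          lb <- new
        }
      }
      list(image = im, labels = lb)
    },
    rotate = {
      ang <- (op_spec$angle %||% 0) * pi / 180
      H <- nrow(image); W <- ncol(image)
      cyc <- (H + 1) / 2; cxc <- (W + 1) / 2
      # inverse map (nearest neighbour), rotation about the image center
      xg <- outer(rep(1, H), seq_len(W)) - cxc
      yg <- outer(seq_len(H), rep(1, W)) - cyc
      xs <- round(cos(ang) * xg - sin(ang) * yg + cxc)
      ys <- round(sin(ang) * xg + cos(ang) * yg + cyc)
      ok <- xs >= 1 & xs <= W & ys >= 1 & ys <= H
      im <- matrix(mean(image), H, W)
      im[ok] <- image[cbind(as.integer(ys[ok]), as.integer(xs[ok]))]
      lb <- labels
      if (nrow(lb)) {
        # forward-rotate the four corners (in pixel coords, y down) and refit
        for (i in seq_len(nrow(lb))) {
          xs4 <- (lb$cx[i] + c(-1, 1, 1, -1) / 2 * lb$w[i]) * W - cxc
          ys4 <- (lb$cy[i] + c(-1, -1, 1, 1) / 2 * lb$h[i]) * H - cyc
          # screen coords rotate clockwise for a CCW visual rotation (y down)
          xr <- cos(ang) * xs4 + sin(ang) * ys4 + cxc
          yr <- -sin(ang) * xs4 + cos(ang) * ys4 + cyc
          lb$cx[i] <- (min(xr) + max(xr)) / 2 / W
          lb$cy[i] <- (min(yr) + max(yr)) / 2 / H
          lb$w[i] <- (max(xr) - min(xr)) / W
          lb$h[i] <- (max(yr) - min(yr)) / H
        }
      }
      list(image = im, labels = lb)
    },
    brightness = {
      f <- op_spec$factor %||% 1
      list(image = pmin(pmax(image * f, 0), 1), labels = labels)
    },
    gaussian_noise = {
      sd <- op_spec$sd %||% 0.02
      im <- local_seed(seed,
        image + matrix(stats::rnorm(length(image), 0, sd), nrow(image)))
      list(image = pmin(pmax(im, 0), 1), labels = labels)
    },
    hflip = {
      lb <- labels
      if (nrow(lb)) lb$cx <- 1 - lb$cx
      list(image = image[, rev(seq_len(ncol(image))), drop = FALSE], labels = lb)
    },
    vflip = {
      lb <- labels
      if (nrow(lb)) lb$cy <- 1 - lb$cy
      list(image = image[rev(seq_len(nrow(image))), , drop = FALSE], labels = lb)
    })
  out$labels <- clamp_labels(out$labels)
  out
}

# clamp boxes to the unit square; drop boxes that left the frame entirely
clamp_labels <- function(labels) {
  if (!nrow(labels)) { attr(labels, "dropped") <- 0L; return(labels) }
  x0 <- pmax(labels$cx - labels$w / 2, 0); x1 <- pmin(labels$cx + labels$w / 2, 1)
  y0 <- pmax(labels$cy - labels$h / 2, 0); y1 <- pmin(labels$cy + labels$h / 2, 1)
  keep <- x1 - x0 > 1e-6 & y1 - y0 > 1e-6
  out <- data.frame(class = labels$class[keep],
                    cx = (x0 + x1)[keep] / 2, cy = (y0 + y1)[keep] / 2,
                    w = (x1 - x0)[keep], h = (y1 - y0)[keep])
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Write a synthetic dataset to disk
#'
#' Generates `n` scenes (optionally spliced into mosaics), writing 8-bit PNG
#' images plus YOLO-format label files with matching basenames.
#'
#' @param dir output directory (created if missing).
#' @param n number of images.
#' @param seed base seed; image i uses a sub-seed of (seed, i).
#' @param preset `"single"` (one field of view), `"mosaic2"` (2 x 2 splice)
#'   or `"mosaic4"` (4 x 4 splice).
#' @param spec template [scene_spec()]; its seed field is ignored.
#' @param format `"png"` (8-bit) or `"tiff"` (16-bit).
#' @return invisibly, the data.frame of image/label paths.
#' @export
synth_dataset <- function(dir, n, seed = 0L, preset = "single",
                          spec = scene_spec(), format = "png") {
  preset <- match.arg(preset, c("single", "mosaic2", "mosaic4"))
  format <- match.arg(format, c("png", "tiff"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  k <- switch(preset, single = 1L, mosaic2 = 2L, mosaic4 = 4L)
  paths <- data.frame(image = character(n), label = character(n))
  for (i in seq_len(n)) {
    if (k == 1L) {
      sp <- spec; sp$seed <- sub_seed(seed, i)
      rec <- generate_micrograph(sp)
    } else {
      tiles <- lapply(seq_len(k * k), function(j) {
        sp <- spec; sp$seed <- sub_seed(seed, i, j)
        generate_micrograph(sp)
      })
      rec <- mosaic(tiles, k)
    }
    base <- file.path(dir, sprintf("scene_%04d", i))
    img_path <- paste0(base, ".", if (format == "png") "png" else "tif")
    write_micrograph(rec$image, img_path)
    write_yolo_labels(rec$labels, paste0(base, ".txt"))
    paths$image[i] <- img_path
    paths$label[i] <- paste0(base, ".txt")
  }
  invisible(paths)
}

#' Write a grayscale image to PNG (8-bit) or TIFF (16-bit)
#' @param image H x W matrix in [0,1].
#' @param path output path; format chosen by extension.
#' @export
write_micrograph <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image, path, bits.per.sample = 16L)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Read a grayscale micrograph
#' @param path PNG/TIFF/JPEG path.
#' @return H x W matrix in [0,1] (multi-channel images are averaged).
#' @export
read_micrograph <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  img
}

# IoU between one box (data.frame row) and a set of boxes, normalized coords
box_iou_mat <- function(a, b) {
  ax0 <- a$cx - a$w / 2; ax1 <- a$cx + a$w / 2
  ay0 <- a$cy - a$h / 2; ay1 <- a$cy + a$h / 2
  bx0 <- b$cx - b$w / 2; bx1 <- b$cx + b$w / 2
  by0 <- b$cy - b$h / 2; by1 <- b$cy + b$h / 2
  iw <- pmax(0, pmin(ax1, bx1) - pmax(ax0, bx0))
  ih <- pmax(0, pmin(ay1, by1) - pmax(ay0, by0))
  inter <- iw * ih
  inter / (a$w * a$h + b$w * b$h - inter)
}
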