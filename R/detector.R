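# ---------------------------------------------------------------------------
# The reference detector topology.
#
# An anchor-free multi-scale one-stage detector in the YOLO family: a CSP
# backbone with stem and four stages (strides 2..32), a spatial-pyramid-
# pooling block and a position-aware attention block at stride 32, a
# top-down/bottom-up fusion neck, and one decoupled head per active scale
# (distribution-based box regression with reg_max = 16 bins, plus class
# logits). The optional small-object scale P2 extends the top-down path to
# stride 4 and re-fuses bottom-up into P3.
#
# The channel table below is the single source of truth for parameter and
# FLOP accounting. At the nano width (0.25) a few widths are calibrated
# values rather than round numbers (attention key-dim 33, attention FFN
# hidden 260, SPPF hidden 124, P2 head widths 12/23, P2 bottom-up width 60):
# together with the documented DynamicConv replacement sites they pin the
# trainable-parameter counts of the baseline and full configurations to the
# published reference values.
# ---------------------------------------------------------------------------

REG_MAX <- 16L
SCALE_STRIDES <- c(P2 = 4L, P3 = 8L, P4 = 16L, P5 = 32L)

#' Detector configuration
#'
#' @param scales character vector of active detection scales, a contiguous
#'   block ending at `"P5"`: `c("P3","P4","P5")` (default) or
#'   `c("P2","P3","P4","P5")`.
#' @param width width multiplier applied to the base channel plan
#'   (0.25 = nano, the reference size; 0.125 = the halved-nano desk size).
#' @param nc number of object classes (default 2: outer epidermal cell = 0,
#'   inner stomatal complex = 1).
#' @param use_dynamic replace the designated standard convolutions with
#'   dynamic mixture-of-kernels convolutions.
#' @param experts number of expert kernels M for dynamic convolution.
#' @param temperature router softmax temperature.
#' @param dynamic_sites character vector of replacement-site block names;
#'   `NULL` selects the documented default set (the standalone downsampling
#'   convolutions, plus five P2-path convolutions when P2 is active).
#' @param input_size network input side in pixels (letterboxed square).
#' @param seed integer seed for weight initialization.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(scales = c("P3", "P4", "P5"), width = 0.25,
                            nc = 2L, use_dynamic = FALSE, experts = 4L,
                            temperature = 1, dynamic_sites = NULL,
                            input_size = 640L, seed = 0L) {
  scales <- match.arg(scales, names(SCALE_STRIDES), several.ok = TRUE)
  idx <- sort(match(scales, names(SCALE_STRIDES)))
  if (length(idx) == 0 || any(diff(idx) != 1) || idx[length(idx)] != 4L)
    stop("invalid scale set: must be a contiguous block ending at P5, e.g. ",
         "c(\"P3\",\"P4\",\"P5\") or c(\"P2\",\"P3\",\"P4\",\"P5\")")
  if (!idx[1] %in% c(1L, 2L))
    stop("invalid scale set: must start at P2 or P3")
  stopifnot(width > 0, nc >= 1, experts >= 1, temperature > 0, input_size %% 32 == 0)
  structure(list(scales = names(SCALE_STRIDES)[idx], width = width,
                 nc = as.integer(nc), use_dynamic = isTRUE(use_dynamic),
                 experts = as.integer(experts), temperature = temperature,
                 dynamic_sites = dynamic_sites,
                 input_size = as.integer(input_size), seed = as.integer(seed)),
            class = "detector_config")
}

# channel plan for a width multiplier; nano (0.25) carries calibrated widths
channel_plan <- function(width) {
  W <- function(x) max(1L, as.integer(x * width))
  nano <- abs(width - 0.25) < 1e-9
  ch <- W(1024) %/% 2L                 # attention block width
  nh <- max(1L, ch %/% 64L)
  list(W = W,
       psa_ch = ch, psa_nh = nh,
       psa_kd = if (nano) 33L else max(4L, (ch %/% nh) %/% 2L),
       psa_ffh = if (nano) 260L else 2L * ch,
       sppf_h = if (nano) 124L else W(1024) %/% 2L,
       p2_c = W(128), p2_fuse_e = 0.75, p2_bu_c = W(240),
       p2_head_c2 = W(48), p2_head_c3 = W(92),
       head_c2 = max(16L, W(256)), head_c3 = max(16L, W(256)))
}

default_dynamic_sites <- function(p2) {
  s <- c("b0", "b1", "b3", "b5", "b7", "n17", "n20")
  if (p2) s <- c(s, "p2fuse.cv2", "hP2.cv3.0dw", "hP2.cv3.1dw",
                 "hP2.cv3.1pw", "hP2.cv3.2")
  s
}

#' Build a detection model
#'
#' Assembles the computation graph for the configured scale set, allocates
#' and initializes all weights (seeded), and returns an executable model.
#'
#' @param config a [detector_config()].
#' @return an object of class `detection_model`.
#' @export
build_detector <- function(config) {
  stopifnot(inherits(config, "detector_config"))
  p2 <- "P2" %in% config$scales
  sites <- config$dynamic_sites
  if (config$use_dynamic && is.null(sites)) sites <- default_dynamic_sites(p2)
  if (!config$use_dynamic) sites <- character(0)

  cp <- channel_plan(config$width)
  W <- cp$W
  g <- new_graph()
  input <- g_input(g)

  CONV <- function(x, name, cin, cout, k, s = 1L, groups = 1L,
                   act = TRUE, use_bn = TRUE) {
    if (name %in% sites) {
      y <- g_dynconv(g, x, paste0(name, ".conv"), cin, cout, k, s,
                     groups = groups, bias = !use_bn,
                     experts = config$experts)
      g$ops[[length(g$ops)]]$temperature <- config$temperature
    } else {
      y <- g_conv(g, x, paste0(name, ".conv"), cin, cout, k, s,
                  groups = groups, bias = !use_bn)
    }
    if (use_bn) y <- g_bn(g, y, paste0(name, ".bn"), cout)
    if (act) y <- g_silu(g, y)
    y
  }

  BOTTLENECK <- function(x, name, c1, c2, e = 0.5, shortcut = TRUE) {
    ch <- max(1L, as.integer(c2 * e))
    y <- CONV(x, paste0(name, ".cv1"), c1, ch, 3L)
    y <- CONV(y, paste0(name, ".cv2"), ch, c2, 3L)
    if (shortcut && c1 == c2) g_add(g, x, y) else y
  }

  C3K <- function(x, name, c1, c2, n = 2L, e = 0.5) {
    ch <- max(1L, as.integer(c2 * e))
    y1 <- CONV(x, paste0(name, ".cv1"), c1, ch, 1L)
    for (i in seq_len(n))
      y1 <- BOTTLENECK(y1, paste0(name, ".m", i), ch, ch, e = 1.0)
    y2 <- CONV(x, paste0(name, ".cv2"), c1, ch, 1L)
    CONV(g_concat(g, c(y1, y2)), paste0(name, ".cv3"), 2L * ch, c2, 1L)
  }

  C3K2 <- function(x, name, c1, c2, n = 1L, use_c3k = FALSE, e = 0.5,
                   be = 0.5) {
    ch <- max(1L, as.integer(c2 * e))
    y <- CONV(x, paste0(name, ".cv1"), c1, 2L * ch, 1L)
    parts <- c(g_slice(g, y, 1L, ch), g_slice(g, y, ch + 1L, 2L * ch))
    for (i in seq_len(n)) {
      last <- parts[length(parts)]
      parts <- c(parts,
                 if (use_c3k) C3K(last, paste0(name, ".m", i), ch, ch)
                 else BOTTLENECK(last, paste0(name, ".m", i), ch, ch, e = be))
    }
    CONV(g_concat(g, parts), paste0(name, ".cv2"), (2L + n) * ch, c2, 1L)
  }

  SPPF <- function(x, name, c1, c2, hidden) {
    y <- CONV(x, paste0(name, ".cv1"), c1, hidden, 1L)
    p1 <- g_maxpool(g, y); p2m <- g_maxpool(g, p1); p3 <- g_maxpool(g, p2m)
    CONV(g_concat(g, c(y, p1, p2m, p3)), paste0(name, ".cv2"), 4L * hidden, c2, 1L)
  }

  PSA <- function(x, name, ch) {
    nh <- cp$psa_nh; kd <- cp$psa_kd; hd <- ch %/% nh
    h <- ch + 2L * kd * nh
    qkv <- CONV(x, paste0(name, ".qkv"), ch, h, 1L, act = FALSE)
    att <- g_mhsa(g, qkv, nh, kd, ch)
    per_head <- 2L * kd + hd
    vparts <- integer(nh)
    for (i in seq_len(nh)) {
      off <- (i - 1L) * per_head
      vparts[i] <- g_slice(g, qkv, off + 2L * kd + 1L, off + 2L * kd + hd)
    }
    vmap <- if (nh > 1L) g_concat(g, vparts) else vparts[1]
    pe <- CONV(vmap, paste0(name, ".pe"), ch, ch, 3L, groups = ch, act = FALSE)
    y <- CONV(g_add(g, att, pe), paste0(name, ".proj"), ch, ch, 1L, act = FALSE)
    y <- g_add(g, x, y)                       # attention residual
    f <- CONV(y, paste0(name, ".ffn1"), ch, cp$psa_ffh, 1L)
    f <- CONV(f, paste0(name, ".ffn2"), cp$psa_ffh, ch, 1L, act = FALSE)
    g_add(g, y, f)
  }

  C2PSA <- function(x, name, c) {
    ch <- c %/% 2L
    y <- CONV(x, paste0(name, ".cv1"), c, 2L * ch, 1L)
    a <- g_slice(g, y, 1L, ch)
    b <- g_slice(g, y, ch + 1L, 2L * ch)
    b <- PSA(b, paste0(name, ".psa1"), ch)
    CONV(g_concat(g, c(a, b)), paste0(name, ".cv2"), 2L * ch, c, 1L)
  }

  HEAD <- function(x, name, cin, c2, c3) {
    b <- CONV(x, paste0(name, ".cv2.0"), cin, c2, 3L)
    b <- CONV(b, paste0(name, ".cv2.1"), c2, c2, 3L)
    box <- CONV(b, paste0(name, ".cv2.2"), c2, 4L * REG_MAX, 1L,
                act = FALSE, use_bn = FALSE)
    cl <- CONV(x, paste0(name, ".cv3.0dw"), cin, cin, 3L, groups = cin)
    cl <- CONV(cl, paste0(name, ".cv3.0pw"), cin, c3, 1L)
    cl <- CONV(cl, paste0(name, ".cv3.1dw"), c3, c3, 3L, groups = c3)
    cl <- CONV(cl, paste0(name, ".cv3.1pw"), c3, c3, 1L)
    cls <- CONV(cl, paste0(name, ".cv3.2"), c3, config$nc, 1L,
                act = FALSE, use_bn = FALSE)
    list(box = box, cls = cls)
  }

  # backbone
  x0 <- CONV(input, "b0", 3L, W(64), 3L, 2L)
  x1 <- CONV(x0, "b1", W(64), W(128), 3L, 2L)
  x2 <- C3K2(x1, "b2", W(128), W(256), e = 0.25)
  x3 <- CONV(x2, "b3", W(256), W(256), 3L, 2L)
  x4 <- C3K2(x3, "b4", W(256), W(512), e = 0.25)
  x5 <- CONV(x4, "b5", W(512), W(512), 3L, 2L)
  x6 <- C3K2(x5, "b6", W(512), W(512), use_c3k = TRUE)
  x7 <- CONV(x6, "b7", W(512), W(1024), 3L, 2L)
  x8 <- C3K2(x7, "b8", W(1024), W(1024), use_c3k = TRUE)
  x9 <- SPPF(x8, "b9", W(1024), W(1024), cp$sppf_h)
  x10 <- C2PSA(x9, "b10", W(1024))

  # top-down neck
  u1 <- g_up2(g, x10)
  n13 <- C3K2(g_concat(g, c(u1, x6)), "n13", W(1024) + W(512), W(512))
  u2 <- g_up2(g, n13)
  n16 <- C3K2(g_concat(g, c(u2, x4)), "n16", W(512) + W(256), W(256))

  p3_feat <- n16
  p2_feat <- NULL
  if (p2) {
    u3 <- g_up2(g, n16)
    p2_feat <- C3K2(g_concat(g, c(u3, x2)), "p2fuse", W(256) + W(256),
                    cp$p2_c, e = cp$p2_fuse_e, be = 1.0)
    bu <- CONV(p2_feat, "p2bu", cp$p2_c, cp$p2_bu_c, 3L, 2L)
    p3_feat <- C3K2(g_concat(g, c(bu, n16)), "p2refuse",
                    cp$p2_bu_c + W(256), W(256), be = 1.0)
  }

  # bottom-up neck
  d1 <- CONV(p3_feat, "n17", W(256), W(256), 3L, 2L)
  n19 <- C3K2(g_concat(g, c(d1, n13)), "n19", W(256) + W(512), W(512))
  d2 <- CONV(n19, "n20", W(512), W(512), 3L, 2L)
  n22 <- C3K2(g_concat(g, c(d2, x10)), "n22", W(512) + W(1024), W(1024),
              use_c3k = TRUE)

  heads <- list()
  neck_out <- list()
  if (p2) {
    heads$P2 <- HEAD(p2_feat, "hP2", cp$p2_c, cp$p2_head_c2, cp$p2_head_c3)
    neck_out$P2 <- p2_feat
  }
  if ("P3" %in% config$scales) {
    heads$P3 <- HEAD(p3_feat, "hP3", W(256), cp$head_c2, cp$head_c3)
    neck_out$P3 <- p3_feat
  }
  heads$P4 <- HEAD(n19, "hP4", W(512), cp$head_c2, cp$head_c3)
  heads$P5 <- HEAD(n22, "hP5", W(1024), cp$head_c2, cp$head_c3)
  neck_out$P4 <- n19
  neck_out$P5 <- n22

  model <- structure(list(graph = g, input = input, heads = heads,
                          neck_out = neck_out, config = config, plan = cp,
                          strides = SCALE_STRIDES[config$scales]),
                     class = "detection_model")
  init_weights(model)
  model
}

# seeded weight initialization: kaiming-uniform convolutions, unit BN,
# detection-prior biases on the head output convolutions
init_weights <- function(model) {
  g <- model$graph
  cfg <- model$config
  nms <- sort(ls(g$params))
  for (i in seq_along(nms)) {
    nm <- nms[i]
    p <- g$params[[nm]]
    s <- sub_seed(cfg$seed, i)
    if (grepl("\\.bn\\.gamma$", nm)) { p[] <- 1
    } else if (grepl("\\.bn\\.beta$", nm)) { p[] <- 0
    } else if (grepl("\\.router\\.w1$", nm)) {
      p[] <- local_rnorm(length(p), 0, 1 / sqrt(nrow(p)), seed = s)
    } else if (grepl("\\.router\\.w2$", nm) || grepl("\\.router\\.b", nm)) {
      p[] <- 0        # uniform routing at start
    } else if (grepl("\\.(w|bank)$", nm)) {
      d <- dim(p)
      fan_in <- prod(d[1:3])
      p[] <- local_runif(length(p), -1, 1, seed = s) / sqrt(fan_in)
    } else if (grepl("\\.b$", nm)) {
      p[] <- 0
    }
    g$params[[nm]] <- p
  }
  # head bias priors
  for (sc in names(model$heads)) {
    stride <- SCALE_STRIDES[[sc]]
    hn <- paste0("h", sc)
    bx <- paste0(hn, ".cv2.2.conv.b")
    cl <- paste0(hn, ".cv3.2.conv.b")
    if (!is.null(g$params[[bx]])) g$params[[bx]][] <- 1.0
    if (!is.null(g$params[[cl]]))
      g$params[[cl]][] <- log(5 / cfg$nc / (640 / stride)^2)
  }
  invisible(model)
}

#' Count trainable parameters
#'
#' Enumerates every trainable array stored in the model (convolution kernels
#' and biases, batch-norm scale/shift, dynamic-convolution expert banks and
#' router weights) and returns the exact total. Batch-norm running statistics
#' and the fixed integral kernel of the distribution-based box decoder are
#' buffers, not parameters, and are excluded.
#'
#' @param model a [build_detector()] model.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  p <- model$graph$params
  sum(vapply(ls(p), function(nm) length(p[[nm]]), numeric(1)))
}

#' Count forward-pass FLOPs
#'
#' Sums floating-point operations layer by layer for one forward pass at the
#' given square input size, under the convention 1 multiply-accumulate =
#' 2 FLOPs. Multiply-accumulate-bearing operations are counted: convolutions,
#' the attention projections and attention matrix products, and for dynamic
#' convolutions additionally the pooling, router and bank-aggregation terms.
#' Element-wise activations and normalizations (folded into convolutions at
#' inference) are excluded.
#'
#' @param model a [build_detector()] model.
#' @param input_size input side in pixels (default: the configured size).
#' @return FLOP count in GFLOPs (value), with attribute `"flops"` (raw count)
#'   and attribute `"convention"`.
#' @export
count_flops <- function(model, input_size = NULL) {
  g <- model$graph
  if (is.null(input_size)) input_size <- model$config$input_size
  hw <- shape_infer(model, input_size)
  total <- 0
  for (op in g$ops) {
    s <- hw[[op$out]]
    total <- total + switch(op$kind,
      conv = {
        d <- dim(g$params[[op$w]])
        2 * prod(d) * s[1] * s[2]
      },
      dynconv = {
        d <- dim(g$params[[op$w]])              # (k,k,cg,cout,M)
        kw <- prod(d[1:4])
        xin <- hw[[op$ins]]
        2 * kw * s[1] * s[2] +                  # the convolution itself
          op$cin * xin[1] * xin[2] +            # global average pooling
          2 * (op$cin * op$hidden + op$hidden * op$M) +  # router MLP
          2 * op$M * kw                          # bank aggregation
      },
      mhsa = {
        P <- s[1] * s[2]
        2 * P * P * (op$kd * op$nh) + 2 * P * P * op$c
      },
      0)
  }
  gf <- total / 1e9
  attr(gf, "flops") <- total
  attr(gf, "convention") <- "1 MAC = 2 FLOPs; conv/attention/router ops counted; element-wise and normalization layers excluded"
  gf
}

# spatial side of each buffer for a square input
shape_infer <- function(model, input_size) {
  g <- model$graph
  hw <- vector("list", g$nbuf)
  hw[[model$input]] <- c(input_size, input_size)
  osz <- function(insz, k, s, p) (insz + 2 * p - k) %/% s + 1
  for (op in g$ops) {
    hw[[op$out]] <- switch(op$kind,
      conv = , dynconv = {
        i <- hw[[op$ins]]
        c(osz(i[1], op$k, op$stride, op$pad), osz(i[2], op$k, op$stride, op$pad))
      },
      maxpool = {
        i <- hw[[op$ins]]
        c(osz(i[1], op$k, op$stride, op$pad), osz(i[2], op$k, op$stride, op$pad))
      },
      up2 = 2L * hw[[op$ins]],
      add = , concat = hw[[op$ins[1]]],
      hw[[op$ins[1]]])
  }
  hw
}

#' @export
print.detection_model <- function(x, ...) {
  cfg <- x$config
  cat("<detection_model>\n")
  cat("  scales:", paste(cfg$scales, collapse = " "),
      " width:", cfg$width, " classes:", cfg$nc, "\n")
  cat("  dynamic conv:", if (cfg$use_dynamic) sprintf("yes (M=%d)", cfg$experts) else "no", "\n")
  cat("  parameters:", format(count_parameters(x), big.mark = ","), "\n")
  invisible(x)
}

#' @export
print.detector_config <- function(x, ...) {
  cat("<detector_config> scales:", paste(x$scales, collapse = " "),
      " width:", x$width, " nc:", x$nc,
      " dynamic:", x$use_dynamic, "\n")
  invisible(x)
}
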