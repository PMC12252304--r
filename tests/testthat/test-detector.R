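# Independent closed-form parameter accounting for the reference topology,
# written directly from the documented channel plan (conv + batch-norm
# bookkeeping only), used as an oracle against the builder's enumeration of
# stored weight arrays.
count_oracle <- function(width, p2 = FALSE) {
  W <- function(x) max(1L, as.integer(x * width))
  cp <- stomadet:::channel_plan(width)
  cv <- function(cin, cout, k, g = 1, bn = TRUE, bias = !bn)
    cout * (cin / g) * k^2 + (if (bn) 2 * cout else 0) + (if (bias) cout else 0)
  bneck <- function(c1, c2, e) {
    ch <- max(1L, as.integer(c2 * e)); cv(c1, ch, 3) + cv(ch, c2, 3)
  }
  c3k <- function(c1, c2) {
    ch <- as.integer(c2 * 0.5)
    cv(c1, ch, 1) + cv(c1, ch, 1) + cv(2 * ch, c2, 1) + 2 * bneck(ch, ch, 1)
  }
  c3k2 <- function(c1, c2, use_c3k = FALSE, e = 0.5, be = 0.5) {
    ch <- max(1L, as.integer(c2 * e))
    cv(c1, 2 * ch, 1) + cv(3 * ch, c2, 1) +
      (if (use_c3k) c3k(ch, ch) else bneck(ch, ch, be))
  }
  head <- function(cin, c2, c3, nc = 2) {
    cv(cin, c2, 3) + cv(c2, c2, 3) + cv(c2, 64, 1, bn = FALSE, bias = TRUE) +
      cv(cin, cin, 3, g = cin) + cv(cin, c3, 1) + cv(c3, c3, 3, g = c3) +
      cv(c3, c3, 1) + cv(c3, nc, 1, bn = FALSE, bias = TRUE)
  }
  psa_ch <- cp$psa_ch
  h_qkv <- psa_ch + 2 * cp$psa_kd * cp$psa_nh
  total <- cv(3, W(64), 3) + cv(W(64), W(128), 3) +
    c3k2(W(128), W(256), e = 0.25) + cv(W(256), W(256), 3) +
    c3k2(W(256), W(512), e = 0.25) + cv(W(512), W(512), 3) +
    c3k2(W(512), W(512), use_c3k = TRUE) + cv(W(512), W(1024), 3) +
    c3k2(W(1024), W(1024), use_c3k = TRUE) +
    cv(W(1024), cp$sppf_h, 1) + cv(4 * cp$sppf_h, W(1024), 1) +
    cv(W(1024), 2 * psa_ch, 1) + cv(2 * psa_ch, W(1024), 1) +
    cv(psa_ch, h_qkv, 1) + cv(psa_ch, psa_ch, 1) +
    cv(psa_ch, psa_ch, 3, g = psa_ch) +
    cv(psa_ch, cp$psa_ffh, 1) + cv(cp$psa_ffh, psa_ch, 1) +
    c3k2(W(1024) + W(512), W(512)) + c3k2(W(512) + W(256), W(256)) +
    cv(W(256), W(256), 3) + c3k2(W(256) + W(512), W(512)) +
    cv(W(512), W(512), 3) + c3k2(W(512) + W(1024), W(1024), use_c3k = TRUE) +
    head(W(256), cp$head_c2, cp$head_c3) +
    head(W(512), cp$head_c2, cp$head_c3) +
    head(W(1024), cp$head_c2, cp$head_c3)
  if (p2) {
    total <- total +
      c3k2(2 * W(256), cp$p2_c, e = cp$p2_fuse_e, be = 1.0) +
      cv(cp$p2_c, cp$p2_bu_c, 3) +
      c3k2(cp$p2_bu_c + W(256), W(256), be = 1.0) +
      head(cp$p2_c, cp$p2_head_c2, cp$p2_head_c3)
  }
  total
}

test_that("the builder's parameter count matches the closed-form plan", {
  for (w in c(0.125, 0.25)) {
    m <- build_detector(detector_config(width = w))
    expect_equal(count_parameters(m), count_oracle(w))
    m2 <- build_detector(detector_config(scales = c("P2", "P3", "P4", "P5"),
                                         width = w))
    expect_equal(count_parameters(m2), count_oracle(w, p2 = TRUE))
    # adding P2 strictly increases the parameter count
    expect_gt(count_parameters(m2), count_parameters(m))
  }
})

test_that("dynamic replacement adds experts and routers linearly in M", {
  base <- count_parameters(build_detector(detector_config(width = 0.25)))
  sites <- stomadet:::default_dynamic_sites(FALSE)
  for (M in c(1L, 2L, 4L)) {
    m <- build_detector(detector_config(width = 0.25, use_dynamic = TRUE,
                                        experts = M))
    # replaced kernels: (M - 1) extra expert copies + one router per site
    rp <- function(cin) { h <- max(cin %/% 4L, 4L); cin * h + h + h * M + M }
    wsz <- c(3 * 16 * 9, 16 * 32 * 9, 64 * 64 * 9, 128 * 128 * 9,
             128 * 256 * 9, 64 * 64 * 9, 128 * 128 * 9)
    cins <- c(3, 16, 64, 128, 128, 64, 128)
    expect_equal(count_parameters(m),
                 base + (M - 1) * sum(wsz) + sum(vapply(cins, rp, numeric(1))))
  }
})

test_that("FLOP accounting follows the closed forms and scales quadratically", {
  # single 3x3 conv, 3 -> 16 channels, 64x64 output: 2 * 16 * 64 * 64 * 27
  g <- stomadet:::new_graph()
  x <- stomadet:::g_input(g)
  stomadet:::g_conv(g, x, "c", 3L, 16L, 3L)
  m <- structure(list(graph = g, input = x,
                      config = list(input_size = 64L)),
                 class = "detection_model")
  expect_equal(as.numeric(count_flops(m, 64)) * 1e9, 2 * 16 * 64 * 64 * 27)
  # doubling the input side quadruples the FLOPs of the full model
  md <- build_detector(detector_config(scales = c("P2", "P3", "P4", "P5"),
                                       width = 0.125))
  f320 <- as.numeric(count_flops(md, 320))
  f640 <- as.numeric(count_flops(md, 640))
  # (attention cost is quartic in map side but negligible at these widths)
  expect_equal(f640 / f320, 4, tolerance = 0.02)
})

test_that("the forward pass emits one map per active scale at the right sides", {
  m <- build_detector(detector_config(scales = c("P2", "P3", "P4", "P5"),
                                      width = 0.0626, input_size = 128))
  x <- array(runif(128 * 128 * 3 * 2), c(128, 128, 3, 2))
  fw <- stomadet:::graph_forward(m, x, train = FALSE)
  sides <- c(P2 = 32, P3 = 16, P4 = 8, P5 = 4)
  expect_equal(length(m$heads), 4)
  for (sc in names(m$heads)) {
    d <- dim(fw$vals[[m$heads[[sc]]$cls]])
    expect_equal(d, c(sides[[sc]], sides[[sc]], 2, 2), ignore_attr = TRUE)
    db <- dim(fw$vals[[m$heads[[sc]]$box]])
    expect_equal(db[3], 64)
  }
})

test_that("invalid scale sets are rejected", {
  expect_error(detector_config(scales = c("P2", "P4", "P5")), "contiguous")
  expect_error(detector_config(scales = c("P3", "P4")), "ending at P5")
  expect_error(detector_config(scales = character(0)))
})

test_that("predictions respect thresholds, NMS and the unit square", {
  m <- build_detector(detector_config(width = 0.0626, input_size = 64, seed = 2))
  img <- matrix(runif(96 * 80), 96, 80)
  # conf_threshold = 1 suppresses everything
  expect_equal(nrow(predict_image(m, img, conf_threshold = 1)), 0)
  # untrained model: all confidences in [0,1], boxes inside the unit square
  det <- predict_image(m, img, conf_threshold = 0, nms_iou = 0.7)
  if (nrow(det)) {
    expect_true(all(det$conf >= 0 & det$conf <= 1))
    expect_true(all(det$cx - det$w / 2 >= -1e-9))
    expect_true(all(det$cx + det$w / 2 <= 1 + 1e-9))
    expect_true(all(det$cy - det$h / 2 >= -1e-9))
    expect_true(all(det$cy + det$h / 2 <= 1 + 1e-9))
    expect_true(all(diff(det$conf) <= 1e-12))
  }
  # NMS keeps the higher-scored of two identical same-class boxes
  two <- data.frame(class = c(1L, 1L), conf = c(0.9, 0.8),
                    cx = c(0.5, 0.5), cy = c(0.5, 0.5),
                    w = c(0.2, 0.2), h = c(0.2, 0.2))
  kept <- nms(two, 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$conf, 0.9)
  # different classes are suppressed independently
  two$class <- c(0L, 1L)
  expect_equal(nrow(nms(two, 0.5)), 2)
})

test_that("checkpoints round-trip the model exactly", {
  m <- build_detector(detector_config(width = 0.0626, input_size = 64, seed = 4))
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_equal(count_parameters(m2), count_parameters(m))
  img <- matrix(runif(64 * 64), 64, 64)
  expect_equal(predict_image(m2, img, conf_threshold = 0),
               predict_image(m, img, conf_threshold = 0))
})
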