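test_that("the class mask is 1 exactly at inner-tagged positions", {
  expect_equal(build_class_mask(rep("inner", 4)), rep(1L, 4))
  expect_equal(build_class_mask(rep("outer", 4)), rep(0L, 4))
  tags <- matrix(c("inner", "background", "outer", "inner"), 2, 2)
  expect_equal(build_class_mask(tags), matrix(c(1L, 0L, 0L, 1L), 2, 2))
  expect_error(build_class_mask(c("inner", "stoma")), "unknown position tag")
})

test_that("total BCE matches its closed forms", {
  expect_lt(bce_total(c(1, 0, 1), c(1, 0, 1)), 1e-5)      # perfect (clamped)
  expect_equal(bce_total(rep(0.5, 10), rep(c(0, 1), 5)), log(2),
               tolerance = 1e-9)
  expect_equal(bce_total(0.9, 1), -log(0.9), tolerance = 1e-9)
  expect_error(bce_total(c(0.5, NA), c(1, 0)), "NaN")
})

test_that("the masked stomatal loss averages BCE over masked positions only", {
  # all-zero mask: the max(sum(M), 1) guard gives exactly 0
  expect_identical(stoma_masked_loss(c(0.9, 0.2), c(1, 0), c(0, 0)), 0)
  # a single masked position reduces to its scalar BCE
  expect_equal(stoma_masked_loss(c(0.9, 0.2), c(1, 1), c(1, 0)), -log(0.9),
               tolerance = 1e-9)
  # brute-force oracle over random grids and masks
  set.seed(4)
  for (trial in 1:40) {
    n <- sample(4:40, 1)
    p <- runif(n, 0.01, 0.99)
    y <- rbinom(n, 1, 0.5)
    m <- rbinom(n, 1, 0.4)
    acc <- 0
    for (i in seq_len(n))
      acc <- acc + (-(y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i]))) * m[i]
    expect_equal(stoma_masked_loss(p, y, m), acc / max(sum(m), 1),
                 tolerance = 1e-6)
  }
})

make_split_dataset <- function(n_train, n_val, with_inner = TRUE) {
  d <- tempfile(); dir.create(d)
  n <- n_train + n_val
  for (i in seq_len(n)) {
    write_micrograph(matrix(runif(256), 16, 16),
                     file.path(d, sprintf("im%03d.png", i)))
    lb <- data.frame(class = 0L, cx = .5, cy = .5, w = .6, h = .6)
    if (with_inner)
      lb <- rbind(lb, data.frame(class = 1L, cx = .5, cy = .5, w = .15, h = .15))
    write_yolo_labels(lb, file.path(d, sprintf("im%03d.txt", i)))
  }
  m <- build_manifest(d)
  m$items$split <- rep(c("train", "val"), c(n_train, n_val))
  m
}

test_that("the pretraining subset samples half and strips inner labels", {
  m <- make_split_dataset(100, 20)
  pm <- make_pretrain_dataset(m, fraction = 0.5, seed = 7)
  expect_equal(sum(m$items$split[match(pm$items$image, m$items$image)] == "train"), 50)
  expect_equal(sum(m$items$split[match(pm$items$image, m$items$image)] == "val"), 10)
  for (f in pm$items$label) {
    lb <- read_yolo_labels(f)
    expect_true(all(lb$class == 0L))
    expect_gt(nrow(lb), 0)
  }
  # determinism of the sampling
  pm2 <- make_pretrain_dataset(m, fraction = 0.5, seed = 7)
  expect_identical(pm$items$image, pm2$items$image)
  pm3 <- make_pretrain_dataset(m, fraction = 0.5, seed = 8)
  expect_false(identical(pm$items$image, pm3$items$image))
})

tiny_model <- function(seed = 5, input = 64) {
  build_detector(detector_config(scales = c("P3", "P4", "P5"), width = 0.0626,
                                 input_size = input, seed = seed))
}

targets_with <- function(outer_shift = 0, inner_shift = 0, extra_outer = FALSE) {
  t1 <- data.frame(class = c(0L, 1L),
                   cx = c(0.5 + outer_shift, 0.45 + inner_shift),
                   cy = c(0.5, 0.48), w = c(0.7, 0.22), h = c(0.7, 0.2))
  if (extra_outer)
    t1 <- rbind(t1, data.frame(class = 0L, cx = 0.52, cy = 0.55,
                               w = 0.65, h = 0.6))
  list(t1)
}

masked_loss_of <- function(model, x, targets) {
  fw <- stomadet:::graph_forward(model, x, train = FALSE)
  assigned <- stomadet:::assign_targets(model, targets)
  multitask_loss(model, fw, assigned, mask_inner_only = TRUE)$loss
}

test_that("gradients are isolated to the stomatal class", {
  model <- tiny_model()
  set.seed(8)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  base <- masked_loss_of(model, x, targets_with())
  # perturbing the outer-class target box leaves the masked loss unchanged
  eps <- 1e-4
  l_outer <- masked_loss_of(model, x, targets_with(outer_shift = eps))
  expect_lt(abs(l_outer - base), 1e-8)
  # doubling the outer-class targets leaves it unchanged too
  l_extra <- masked_loss_of(model, x, targets_with(extra_outer = TRUE))
  expect_lt(abs(l_extra - base), 1e-8)
  # perturbing the inner-class target changes it measurably
  l_inner <- masked_loss_of(model, x, targets_with(inner_shift = 5 * eps))
  expect_gt(abs(l_inner - base), 1e-9)
  # an image with no inner objects contributes no positive terms: the same
  # loss as an empty target list (background everywhere)
  l_outer_only <- masked_loss_of(model, x,
                                 list(targets_with()[[1]][1, , drop = FALSE]))
  l_empty <- masked_loss_of(model, x, list(data.frame(class = integer(0),
                                                      cx = numeric(0), cy = numeric(0),
                                                      w = numeric(0), h = numeric(0))))
  expect_equal(l_outer_only, l_empty, tolerance = 1e-12)
})

test_that("removing the mask recovers the standard both-class loss", {
  model <- tiny_model()
  set.seed(9)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  # inner-only targets: masked and unmasked losses coincide
  tgt <- list(data.frame(class = 1L, cx = .5, cy = .5, w = .25, h = .25))
  fw <- stomadet:::graph_forward(model, x, train = FALSE)
  a <- stomadet:::assign_targets(model, tgt)
  lm <- multitask_loss(model, fw, a, mask_inner_only = TRUE)$loss
  lu <- multitask_loss(model, fw, a, mask_inner_only = FALSE)$loss
  expect_equal(lm, lu, tolerance = 1e-12)
  # with outer targets present the unmasked loss sees them, the masked not
  a2 <- stomadet:::assign_targets(model, targets_with())
  l2m <- multitask_loss(model, fw, a2, mask_inner_only = TRUE)
  l2u <- multitask_loss(model, fw, a2, mask_inner_only = FALSE)
  expect_gt(l2u$npos, l2m$npos)
})

test_that("the pretraining protocol runs its full epoch count before formal training", {
  d <- tempfile(); dir.create(d)
  for (i in 1:6) {
    rec <- generate_micrograph(scene_spec(width = 64, height = 64, n_cells = 1,
                                          stoma_frac = c(0.1, 0.2), seed = i))
    write_micrograph(rec$image, file.path(d, sprintf("s%02d.png", i)))
    write_yolo_labels(rec$labels, file.path(d, sprintf("s%02d.txt", i)))
  }
  cfg <- run_config(out_dir = tempfile(), data_dir = d, input_size = 64,
                    width = 0.0626, pretrain = TRUE, pretrain_epochs = 50,
                    epochs = 2, batch_size = 4, seed = 3, use_dynamic = FALSE,
                    scales = c("P3", "P4", "P5"))
  res <- train_pipeline(cfg)
  log <- readLines(file.path(cfg$out_dir, "train_log.jsonl"))
  rows <- lapply(log, jsonlite::fromJSON)
  phases <- vapply(rows, function(r) r$phase, character(1))
  epochs <- vapply(rows, function(r)
    if (is.null(r$epoch)) NA_real_ else as.numeric(r$epoch), numeric(1))
  expect_equal(sum(phases == "pretrain"), 50)
  expect_equal(epochs[phases == "pretrain"], 1:50)
  # formal training starts numbering after the pretraining block
  expect_equal(epochs[phases == "formal"], 51:52)
  expect_equal(phases[length(phases)], "eval")
})
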