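test_that("the random feature mask hits its ratio and boundaries", {
  expect_equal(random_feature_mask(c(8, 8), 0), matrix(1, 8, 8))
  expect_equal(random_feature_mask(c(8, 8), 1), matrix(0, 8, 8))
  expect_error(random_feature_mask(c(8, 8), 1.2), "lambda")
  expect_identical(random_feature_mask(c(16, 16), 0.5, seed = 3),
                   random_feature_mask(c(16, 16), 0.5, seed = 3))
  # zero-fraction concentration: for lambda = 0.5 on a 100x100 mask the
  # fraction of zeros stays within +-0.05 for at least 99% of seeds
  # (binomial sd = 0.005, so 0.05 is a 10-sigma band)
  # (the acceptance suite runs the full 1000-seed version)
  frac0 <- vapply(1:300, function(s)
    mean(random_feature_mask(c(100, 100), 0.5, seed = s) == 0), numeric(1))
  expect_gte(mean(frac0 >= 0.45 & frac0 <= 0.55), 0.99)
  expect_equal(mean(frac0), 0.5, tolerance = 0.01)
})

test_that("the generation network composes conv -> ReLU -> conv", {
  # zero-initialized convolutions produce zero output
  x <- array(rnorm(5 * 5 * 2), c(5, 5, 2, 1))
  w0 <- array(0, c(3, 3, 2, 2))
  expect_equal(generation_network(x, w0, w0), array(0, c(5, 5, 2, 1)),
               ignore_attr = TRUE)
  # 1x1 scalar chain: w1 = 2, w2 = 3 gives 6x for positive x, 0 otherwise
  w1 <- array(2, c(1, 1, 1, 1)); w2 <- array(3, c(1, 1, 1, 1))
  xs <- array(c(1, -1, 0.5, -2), c(2, 2, 1, 1))
  y <- generation_network(xs, w1, w2)
  expect_equal(as.numeric(y), c(6, 0, 3, 0))
  # 3x3 with padding 1 preserves the spatial size
  wa <- array(rnorm(9 * 4), c(3, 3, 2, 2))
  expect_equal(dim(generation_network(x, wa, wa))[1:2], c(5, 5))
})

test_that("the masked generative loss matches its brute-force definition", {
  # identity regeneration of identical maps is exactly zero
  ds <- stomadet:::make_distiller(1, 1, seed = 1)
  ds$params$dl1.g1.w <- array(1, c(1, 1, 1, 1))  # k=1 identity chain
  ds$params$dl1.g2.w <- array(1, c(1, 1, 1, 1))
  Tm <- array(abs(rnorm(16)), c(4, 4, 1, 1))
  r0 <- mgd_loss(list(Tm), list(Tm), list(matrix(1, 4, 4)), ds)
  expect_equal(r0$loss, 0, tolerance = 1e-12)
  # scalar case: teacher 3, generated 1 -> (3 - 1)^2 = 4
  S1 <- array(1, c(1, 1, 1, 1)); T1 <- array(3, c(1, 1, 1, 1))
  r1 <- mgd_loss(list(S1), list(T1), list(matrix(1, 1, 1)), ds)
  expect_equal(r1$loss, 4)
  # random pair vs a four-level loop oracle
  set.seed(12)
  cs <- 2L; ct <- 3L
  dd <- stomadet:::make_distiller(cs, ct, seed = 5)
  S <- array(rnorm(6 * 6 * cs * 2), c(6, 6, cs, 2))
  T <- array(rnorm(6 * 6 * ct * 2), c(6, 6, ct, 2))
  m <- random_feature_mask(c(6, 6), 0.4, seed = 8)
  r <- mgd_loss(list(S), list(T), list(m), dd)
  # oracle: explicit sum over layers, channels, positions and batch
  P <- dd$params
  mm <- array(rep(as.numeric(m), cs * 2), dim(S))
  A <- stomadet:::.conv2d_fw(S * mm, dim(S), P$dl1.align.w,
                             dim(P$dl1.align.w), NULL, 1L, 0L, 1L)
  G <- generation_network(A, P$dl1.g1.w, P$dl1.g2.w)
  acc <- 0
  for (n in 1:2) for (k in 1:ct) for (i in 1:6) for (j in 1:6)
    acc <- acc + (T[i, j, k, n] - G[i, j, k, n])^2
  expect_equal(r$loss, acc, tolerance = 1e-5)
  expect_error(mgd_loss(list(S), list(T), list(matrix(1, 3, 3)), dd),
               "shape mismatch")
})

test_that("distillation gradients match finite differences", {
  set.seed(21)
  cs <- 2L; ct <- 2L
  dd <- stomadet:::make_distiller(cs, ct, seed = 9)
  S <- array(rnorm(4 * 4 * cs), c(4, 4, cs, 1))
  T <- array(rnorm(4 * 4 * ct), c(4, 4, ct, 1))
  m <- random_feature_mask(c(4, 4), 0.3, seed = 2)
  r <- mgd_loss(list(S), list(T), list(m), dd, need_grad = TRUE)
  # single-precision conv internals: use a larger step and band
  eps <- 1e-3
  for (probe in 1:5) {
    i <- sample(length(S), 1)
    Sp <- S; Sp[i] <- S[i] + eps
    Sm <- S; Sm[i] <- S[i] - eps
    num <- (mgd_loss(list(Sp), list(T), list(m), dd)$loss -
            mgd_loss(list(Sm), list(T), list(m), dd)$loss) / (2 * eps)
    expect_equal(r$gs[[1]][i], num, tolerance = 0.02)
  }
  i <- sample(length(dd$params$dl1.g1.w), 1)
  w0 <- dd$params$dl1.g1.w[i]
  dd$params$dl1.g1.w[i] <- w0 + eps
  lp <- mgd_loss(list(S), list(T), list(m), dd)$loss
  dd$params$dl1.g1.w[i] <- w0 - eps
  lm <- mgd_loss(list(S), list(T), list(m), dd)$loss
  dd$params$dl1.g1.w[i] <- w0
  expect_equal(r$pg$dl1.g1.w[i], (lp - lm) / (2 * eps), tolerance = 0.02)
})

test_that("the blended loss is linear in alpha", {
  expect_equal(total_loss(1.7, 123, 0), 1.7)
  expect_equal(total_loss(1, 1, 1), 2)
  v <- vapply(c(0.1, 0.2, 0.3), function(a) total_loss(2, 5, a), numeric(1))
  expect_equal(diff(v), rep(0.5, 2))
  expect_error(total_loss(NaN, 1, 1))
})

micro_records <- function(n = 6, size = 64) {
  lapply(seq_len(n), function(i) {
    rec <- generate_micrograph(scene_spec(width = size, height = size,
                                          n_cells = 1,
                                          stoma_frac = c(0.12, 0.2), seed = i))
    lb <- letterbox(rec$image, size)
    list(im = lb$x[, , 1, 1],
         labels = stomadet:::labels_to_input(rec$labels, lb, size),
         lbinfo = lb)
  })
}

test_that("the teacher stays frozen and alpha = 0 reproduces plain training", {
  rec <- micro_records()
  cfgd <- detector_config(scales = c("P3", "P4", "P5"), width = 0.0626,
                          input_size = 64, seed = 6)
  teacher <- build_detector(detector_config(scales = c("P3", "P4", "P5"),
                                            width = 0.125, input_size = 64,
                                            seed = 7))
  ck0 <- stomadet:::param_checksum(teacher)

  s1 <- build_detector(cfgd)
  log1 <- train_detector(s1, rec, epochs = 2, batch_size = 3, seed = 5,
                         teacher = teacher, distill = distill_config(alpha = 0),
                         augment = FALSE)
  expect_equal(stomadet:::param_checksum(teacher), ck0)

  s2 <- build_detector(cfgd)
  log2 <- train_detector(s2, rec, epochs = 2, batch_size = 3, seed = 5,
                         augment = FALSE)
  # bit-for-bit identical trajectories and final parameters
  expect_identical(vapply(log1, `[[`, numeric(1), "loss"),
                   vapply(log2, `[[`, numeric(1), "loss"))
  P1 <- s1$graph$params; P2 <- s2$graph$params
  for (nm in ls(P1)) expect_identical(P1[[nm]], P2[[nm]])

  # with alpha > 0 the trajectory differs and the teacher is still frozen
  s3 <- build_detector(cfgd)
  log3 <- train_detector(s3, rec, epochs = 2, batch_size = 3, seed = 5,
                         teacher = teacher,
                         distill = distill_config(alpha = 1e-4),
                         augment = FALSE)
  expect_false(identical(vapply(log3, `[[`, numeric(1), "loss"),
                         vapply(log2, `[[`, numeric(1), "loss")))
  expect_equal(stomadet:::param_checksum(teacher), ck0)
  # scale-set mismatch is rejected
  tmis <- build_detector(detector_config(scales = c("P2", "P3", "P4", "P5"),
                                         width = 0.0626, input_size = 64))
  expect_error(train_detector(build_detector(cfgd), rec, 1, 3,
                              teacher = tmis, distill = distill_config()),
               "scale sets differ")
})
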