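test_that("a spec with zero cells yields pure background and no labels", {
  sp <- scene_spec(width = 128, height = 96, n_cells = 0, seed = 3)
  rec <- generate_micrograph(sp)
  expect_equal(dim(rec$image), c(96, 128))
  expect_equal(nrow(rec$labels), 0)
  expect_true(all(rec$image >= 0 & rec$image <= 1))
})

test_that("every stoma center lies inside exactly one epidermal-cell box", {
  sp <- scene_spec(width = 256, height = 192, n_cells = 4,
                   stomata_per_cell = c(1, 1), seed = 9)
  rec <- generate_micrograph(sp)
  lb <- rec$labels
  expect_equal(sum(lb$class == 0), 4)
  expect_equal(sum(lb$class == 1), 4)
  outer <- lb[lb$class == 0, ]
  inner <- lb[lb$class == 1, ]
  # brute-force pairwise point-in-box check
  for (i in seq_len(nrow(inner))) {
    hits <- sum(inner$cx[i] > outer$cx - outer$w / 2 &
                inner$cx[i] < outer$cx + outer$w / 2 &
                inner$cy[i] > outer$cy - outer$h / 2 &
                inner$cy[i] < outer$cy + outer$h / 2)
    expect_equal(hits, 1)
  }
})

test_that("containment and the small-object regime hold across seeds", {
  areas <- c()
  for (seed in 1:5) {
    rec <- generate_micrograph(scene_spec(width = 320, height = 320,
                                          n_cells = 4, seed = seed))
    lb <- rec$labels
    outer <- lb[lb$class == 0, ]
    inner <- lb[lb$class == 1, ]
    for (i in seq_len(nrow(inner))) {
      # full box containment of the inner box in at least one outer box
      contained <- any(
        inner$cx[i] - inner$w[i] / 2 >= outer$cx - outer$w / 2 - 1e-9 &
        inner$cx[i] + inner$w[i] / 2 <= outer$cx + outer$w / 2 + 1e-9 &
        inner$cy[i] - inner$h[i] / 2 >= outer$cy - outer$h / 2 - 1e-9 &
        inner$cy[i] + inner$h[i] / 2 <= outer$cy + outer$h / 2 + 1e-9)
      expect_true(contained)
    }
    areas <- c(areas, inner$w * inner$h)
  }
  expect_lt(median(areas), 0.01)
})

test_that("generation is a pure function of spec and seed", {
  sp <- scene_spec(width = 160, height = 128, n_cells = 2, seed = 77)
  a <- generate_micrograph(sp)
  b <- generate_micrograph(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  c <- generate_micrograph(scene_spec(width = 160, height = 128, n_cells = 2,
                                      seed = 78))
  expect_false(identical(a$image, c$image))
})

test_that("infeasible cell/stoma geometry raises a generation failure", {
  sp <- scene_spec(width = 64, height = 64, n_cells = 16,
                   stoma_frac = c(0.4, 0.6), seed = 1)
  expect_error(generate_micrograph(sp), "generation failure")
})

test_that("mosaic with k = 1 is the identity", {
  rec <- generate_micrograph(scene_spec(width = 64, height = 64, n_cells = 1,
                                        seed = 5))
  out <- mosaic(list(rec), 1)
  expect_identical(out$image, rec$image)
  expect_identical(out$labels, rec$labels)
})

test_that("mosaic rescales and offsets boxes into their grid cells", {
  im <- matrix(0.5, 64, 64)
  lb <- data.frame(class = 1L, cx = 0.5, cy = 0.5, w = 0.2, h = 0.2)
  tile <- list(image = im, labels = lb)
  out <- mosaic(list(tile, tile, tile, tile), 2)
  expect_equal(dim(out$image), c(64, 64))
  expect_equal(nrow(out$labels), 4)
  got <- out$labels[order(out$labels$cy, out$labels$cx), ]
  expect_equal(got$cx, c(0.25, 0.75, 0.25, 0.75))
  expect_equal(got$cy, c(0.25, 0.25, 0.75, 0.75))
  expect_equal(got$w, rep(0.1, 4))
  expect_equal(got$h, rep(0.1, 4))
})

test_that("mosaic conserves the total label count for any k", {
  for (k in c(2, 3)) {
    tiles <- lapply(seq_len(k * k), function(i)
      generate_micrograph(scene_spec(width = 96, height = 96, n_cells = 1,
                                     seed = i)))
    out <- mosaic(tiles, k)
    expect_equal(nrow(out$labels), sum(vapply(tiles, function(t)
      nrow(t$labels), integer(1))))
  }
  expect_error(mosaic(list(list(image = matrix(0, 4, 4), labels = empty <- data.frame()),
                           list(image = matrix(0, 8, 8), labels = empty),
                           list(image = matrix(0, 4, 4), labels = empty),
                           list(image = matrix(0, 4, 4), labels = empty)), 2),
               "dimension mismatch")
})

test_that("augmentations transform labels consistently with pixels", {
  rec <- generate_micrograph(scene_spec(width = 96, height = 96, n_cells = 1,
                                        seed = 2))
  # zero-op identities
  r0 <- augment(rec$image, rec$labels, list(op = "rotate90k", k = 0))
  expect_identical(r0$image, rec$image)
  expect_equal(r0$labels$cx, rec$labels$cx)
  rb <- augment(rec$image, rec$labels, list(op = "brightness", factor = 1))
  expect_identical(rb$image, rec$image)
  # quarter-turn (counter-clockwise) box map: (cx,cy,w,h) -> (cy, 1-cx, h, w)
  r1 <- augment(rec$image, rec$labels, list(op = "rotate90k", k = 1))
  expect_equal(r1$labels$cx, rec$labels$cy, tolerance = 1e-9)
  expect_equal(r1$labels$cy, 1 - rec$labels$cx, tolerance = 1e-9)
  expect_equal(r1$labels$w, rec$labels$h)
  expect_equal(r1$labels$h, rec$labels$w)
  # four quarter turns restore the input
  r4 <- rec
  for (i in 1:4) r4 <- augment(r4$image, r4$labels, list(op = "rotate90k", k = 1))
  expect_equal(r4$image, rec$image)
  expect_equal(r4$labels$cx, rec$labels$cx, tolerance = 1e-9)
  # flips
  rh <- augment(rec$image, rec$labels, list(op = "hflip"))
  expect_equal(rh$labels$cx, 1 - rec$labels$cx)
  expect_equal(rh$image[, 1], rec$image[, ncol(rec$image)])
  # label conservation + bounds for all ops
  for (op in list(list(op = "rotate90k", k = 3), list(op = "hflip"),
                  list(op = "vflip"), list(op = "brightness", factor = 1.2),
                  list(op = "gaussian_noise", sd = 0.05),
                  list(op = "rotate", angle = 17))) {
    r <- augment(rec$image, rec$labels, op, seed = 4)
    expect_equal(nrow(r$labels) + attr(r$labels, "dropped"), nrow(rec$labels))
    if (nrow(r$labels)) {
      expect_true(all(r$labels$cx - r$labels$w / 2 >= -1e-9))
      expect_true(all(r$labels$cx + r$labels$w / 2 <= 1 + 1e-9))
      expect_true(all(r$labels$cy - r$labels$h / 2 >= -1e-9))
      expect_true(all(r$labels$cy + r$labels$h / 2 <= 1 + 1e-9))
    }
  }
  expect_error(augment(rec$image, rec$labels, list(op = "solarize")),
               "supported ops")
})

test_that("image round trip through PNG and 16-bit TIFF is faithful", {
  rec <- generate_micrograph(scene_spec(width = 64, height = 48, n_cells = 1,
                                        seed = 6))
  p1 <- file.path(tempdir(), "t.png")
  p2 <- file.path(tempdir(), "t.tif")
  write_micrograph(rec$image, p1)
  write_micrograph(rec$image, p2)
  expect_equal(read_micrograph(p1), rec$image, tolerance = 1 / 255)
  expect_equal(read_micrograph(p2), rec$image, tolerance = 1e-4,
               ignore_attr = TRUE)
})
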