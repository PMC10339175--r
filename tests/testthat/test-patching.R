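test_that("downsample factor and effective mpp track magnification", {
  expect_equal(downsample_factor(20, 5), 4)
  expect_equal(effective_mpp(0.5, downsample_factor(20, 5)), 2.0)
  expect_equal(downsample_factor(40, 5), 8)
  expect_equal(effective_mpp(0.25, downsample_factor(40, 5)), 2.0)
  for (x in c(1, 5, 20, 40)) expect_equal(downsample_factor(x, x), 1)
  expect_error(downsample_factor(5, 20), "upsampling")
})

test_that("Lanczos slide resize honours dimension and constancy contracts", {
  img <- rand_image(96, 96, seed = 11)
  out <- resize_slide(img, 2)
  expect_equal(dim(out), c(48, 48, 3))
  # floor() of non-integer ratios
  expect_equal(dim(resize_slide(img, 2.5))[1:2], c(floor(96 / 2.5),
                                                   floor(96 / 2.5)))
  # factor 1 is pixel-identical
  expect_identical(resize_slide(img, 1), img)
  # kernel weights sum to one: constant images stay constant
  const <- array(0.37, c(64, 80, 3))
  down <- resize_slide(const, 3)
  expect_equal(as.numeric(down), rep(0.37, length(down)), tolerance = 1e-12)
  expect_error(resize_slide(img, 0.5), "factor")
  expect_error(resize_slide(matrix(0, 4, 4), 2), "RGB")
})

test_that("grid coordinates enumerate strides plus edge alignment", {
  spec <- patch_grid_spec(224, 112)
  g <- grid_coordinates(448, 448, spec)
  expect_equal(nrow(g), 9)
  expect_setequal(unique(g$x), c(0, 112, 224))
  expect_setequal(unique(g$y), c(0, 112, 224))

  g1 <- grid_coordinates(224, 224, patch_grid_spec(224, 37))
  expect_equal(g1, data.frame(x = 0, y = 0))

  g2 <- grid_coordinates(336, 224, spec)
  expect_equal(g2, data.frame(x = c(0, 112), y = c(0, 0)))

  expect_error(grid_coordinates(200, 448, spec), "smaller than patch")
})

test_that("grid coordinate counts match brute-force enumeration", {
  # independent oracle: walk the axis by stride, then add the edge patch
  brute_axis <- function(extent, ps, stride) {
    xs <- c()
    x <- 0
    while (x + ps <= extent) {
      xs <- c(xs, x)
      x <- x + stride
    }
    if (xs[length(xs)] + ps < extent) xs <- c(xs, extent - ps)
    xs
  }
  set.seed(42)
  for (ov in c(0, 56, 112)) {
    spec <- patch_grid_spec(224, ov)
    for (k in 1:20) {
      w <- sample(224:600, 1)
      h <- sample(224:600, 1)
      g <- grid_coordinates(w, h, spec)
      nx <- length(brute_axis(w, 224, 224 - ov))
      ny <- length(brute_axis(h, 224, 224 - ov))
      expect_equal(nrow(g), nx * ny)
      expect_true(all(g$x + 224 <= w & g$y + 224 <= h))
    }
  }
})

test_that("training overlap solver finds the smallest sufficient overlap", {
  # brute-force oracle: actual grid sizes for every overlap. Note the
  # edge-aligned extra patch makes small overlaps productive: a 448x448
  # slide jumps from 4 patches (o = 0, aligned) to 9 at o = 1, because
  # stride 223 leaves a remainder that appends the edge patch per axis.
  counts <- vapply(0:223, function(o) {
    nrow(grid_coordinates(448, 448, patch_grid_spec(224, o)))
  }, integer(1))
  expect_equal(counts[1], 4L)
  # patch count is non-decreasing in overlap
  expect_true(all(diff(counts) >= 0))
  for (target in c(9, 25, 100)) {
    sol <- solve_training_overlap(448, 448, 224, target)
    expect_equal(sol$overlap, min(which(counts >= target)) - 1L)
    expect_gte(sol$count, target)
    expect_false(sol$shortfall)
    # minimality: one pixel less overlap falls short
    if (sol$overlap > 0) expect_lt(counts[sol$overlap], target)
  }

  # already enough patches at zero overlap
  expect_equal(solve_training_overlap(c(448, 448), c(448, 448), 224,
                                      5)$overlap, 0)
  # unreachable budget flags a shortfall at maximum overlap
  big <- solve_training_overlap(256, 256, 224, 10000)
  expect_equal(big$overlap, 223)
  expect_true(big$shortfall)
  expect_error(solve_training_overlap(integer(0), integer(0), 224, 10),
               "no slides")
})

test_that("patchify produces labeled in-bounds manifests deterministically", {
  img <- rand_image(112, 112, seed = 5)
  rec <- slide_record("s1", img, 20, 0.5, "tumor")
  spec <- patch_grid_spec(56, 28, 5) # factor 4 -> 28x28 slide? no: 112/4 = 28
  # 112 at 20x downsampled to 5x -> 28x28; patch 56 would not fit, use 14
  spec <- patch_grid_spec(14, 7, 5)
  p <- patchify(list(rec), spec, split = "train")
  expect_equal(dim(p$images[["s1"]]), c(28, 28, 3))
  expect_equal(nrow(p$manifest), 9)
  expect_true(all(p$manifest$label == "tumor"))
  expect_true(all(p$manifest$split == "train"))
  expect_true(all(p$manifest$x + 14 <= 28 & p$manifest$y + 14 <= 28))

  # additivity over identical slides
  rec2 <- slide_record("s2", img, 20, 0.5, "tumor")
  p2 <- patchify(list(rec, rec2), spec)
  expect_equal(nrow(p2$manifest), 2 * nrow(p$manifest))

  # per-class overlap override touches only that class
  recb <- slide_record("s3", rand_image(112, 112, seed = 6), 20, 0.5,
                       "normal")
  p3 <- patchify(list(rec, recb), spec,
                 class_overlaps = c(normal = 0L))
  n_normal <- sum(p3$manifest$label == "normal")
  expect_equal(n_normal, nrow(grid_coordinates(28, 28,
                                               patch_grid_spec(14, 0, 5))))
  expect_equal(sum(p3$manifest$label == "tumor"), 9)
})

test_that("manifest CSV round-trips losslessly", {
  ds <- tiny_patch_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(ds$manifest, path)
  back <- read_manifest(path)
  expect_equal(back, ds$manifest, ignore_attr = TRUE)
})

test_that("manifest boxes stay inside slide bounds on random slide sizes", {
  set.seed(7)
  for (k in 1:10) {
    h <- sample(40:90, 1)
    w <- sample(40:90, 1)
    rec <- slide_record(paste0("r", k), rand_image(h, w, seed = k), 5, 2,
                        "c")
    spec <- patch_grid_spec(32, sample(0:31, 1), 5)
    if (h < 32 || w < 32) {
      expect_error(patchify(list(rec), spec))
    } else {
      m <- patchify(list(rec), spec, keep_images = FALSE)$manifest
      expect_true(all(m$x >= 0 & m$y >= 0 &
                        m$x + m$patch_size <= w &
                        m$y + m$patch_size <= h))
    }
  }
})

test_that("tissue filter scores saturation, not brightness", {
  white <- array(1, c(16, 16, 3))
  expect_equal(tissue_fraction(white), 0)
  pink <- array(rep(c(0.9, 0.5, 0.6), each = 256), c(16, 16, 3))
  expect_equal(tissue_fraction(pink), 1)
  half <- white
  half[, 1:8, 1] <- 0.9
  half[, 1:8, 2] <- 0.4
  half[, 1:8, 3] <- 0.6
  expect_equal(tissue_fraction(half), 0.5)
})
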