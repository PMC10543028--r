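test_that("gradient map is zero on constant images and matches hand convolution on a step edge", {
  expect_equal(compute_gradient_map(gray_slide(8, 8)), matrix(0, 8, 8))

  sl <- step_slide(8, 8, at = 4)
  gm <- compute_gradient_map(sl)
  # nonzero magnitude only in the two columns adjacent to the step
  expect_true(all(gm[, c(4, 5)] > 0))
  expect_equal(gm[, c(1:3, 6:8)], matrix(0, 8, 6))
  # and the map agrees with the brute-force per-pixel convolution
  gray <- 0.299 * sl$pixels[, , 1] + 0.587 * sl$pixels[, , 2] + 0.114 * sl$pixels[, , 3]
  expect_equal(gm, sobel_oracle(gray))
})

test_that("gradient map agrees with the brute-force oracle on random slides", {
  for (seed in 1:3) {
    sl <- noise_slide(9, 11, seed = seed)
    gray <- 0.299 * sl$pixels[, , 1] + 0.587 * sl$pixels[, , 2] + 0.114 * sl$pixels[, , 3]
    expect_equal(compute_gradient_map(sl), sobel_oracle(gray))
  }
})

test_that("gradient magnitudes of an image and its 180-degree rotation are rotations of each other", {
  sl <- noise_slide(12, 10, seed = 4)
  rot <- rotate_slide(rotate_slide(sl, 90), 90)
  g1 <- compute_gradient_map(sl)
  g2 <- compute_gradient_map(rot)
  expect_equal(g2, g1[nrow(g1):1, ncol(g1):1])
})

test_that("gradient map rejects images smaller than the kernel", {
  expect_error(compute_gradient_map(gray_slide(2, 5)), "Sobel")
})

test_that("tiling produces the exact floor-arithmetic grid and discards remainders", {
  ts <- tile_slide(gray_slide(1024, 1024), 512)
  expect_length(ts, 4)
  man <- tile_manifest(ts)
  expect_setequal(paste(man$grid_row, man$grid_col), c("0 0", "0 1", "1 0", "1 1"))

  ts2 <- tile_slide(gray_slide(1280, 1030), 512)
  expect_length(ts2, 4)

  # property: count equals floor(H/e) * floor(W/e) on random dims
  set.seed(7)
  for (i in 1:5) {
    h <- sample(8:40, 1); w <- sample(8:40, 1); e <- sample(3:9, 1)
    expect_length(tile_slide(gray_slide(h, w), e), (h %/% e) * (w %/% e))
  }
})

test_that("a slide holding the stated per-slide maximum yields 8,000 tiles", {
  # 51,200 x 40,960 at edge 512 -> 100 x 80 grid; checked on the grid
  # arithmetic (materializing the pixels is pointless)
  expect_identical((51200L %/% 512L) * (40960L %/% 512L), 8000L)
  # and the tiler agrees at a downscaled slide with the same aspect
  expect_length(tile_slide(gray_slide(100, 80), 1), 8000)
})

test_that("tiling a slide smaller than one tile warns and returns an empty set", {
  expect_warning(ts <- tile_slide(gray_slide(8, 8), 16), "smaller")
  expect_length(ts, 0)
})

test_that("low-gradient filtering removes background and keeps the half-below boundary", {
  # uniform slide: every pixel below threshold -> removed
  sl <- gray_slide(16, 16)
  ts <- filter_tiles(tile_slide(sl, 16), compute_gradient_map(sl), 10)
  expect_false(tile_manifest(ts)$retained)
  expect_equal(tile_manifest(ts)$frac_low_gradient, 1)

  # checkerboard (2-px squares): high contrast off-border -> retained at 20,
  # and the brute-force magnitudes confirm every interior pixel exceeds it
  cb <- checker_slide(16, 16, sq = 2)
  gcb <- compute_gradient_map(cb)
  expect_true(all(gcb[2:15, 2:15] > 20))
  tcb <- filter_tiles(tile_slide(cb, 16), gcb, 20)
  expect_true(tile_manifest(tcb)$retained)

  # exactly half the pixels below threshold -> retained ("more than half" rule)
  gm <- matrix(c(rep(0, 128), rep(99, 128)), 16, 16)
  ts2 <- filter_tiles(tile_slide(gray_slide(16, 16), 16), gm, 10)
  expect_equal(tile_manifest(ts2)$frac_low_gradient, 0.5)
  expect_true(tile_manifest(ts2)$retained)
})

test_that("filtering decisions match a per-pixel brute-force count on toy tiles", {
  sl <- noise_slide(32, 32, seed = 9)
  gm <- compute_gradient_map(sl)
  thr <- 150
  ts <- filter_tiles(tile_slide(sl, 16), gm, thr)
  man <- tile_manifest(ts)
  for (k in seq_len(nrow(man))) {
    rows <- man$grid_row[k] * 16 + 1:16
    cols <- man$grid_col[k] * 16 + 1:16
    frac <- sum(gm[rows, cols] < thr) / 256
    expect_equal(man$frac_low_gradient[k], frac)
    expect_identical(man$retained[k], frac <= 0.5)
  }
})

test_that("filtering rejects a misaligned gradient map", {
  sl <- gray_slide(32, 32)
  expect_error(filter_tiles(tile_slide(sl, 16), matrix(0, 8, 8), 10), "aligned")
})

test_that("the tiler is deterministic end to end", {
  sl <- noise_slide(32, 32, seed = 5)
  run <- function() {
    ts <- filter_tiles(tile_slide(sl, 16), compute_gradient_map(sl), 15)
    resize_tiles(retained_tiles(ts), 8)
  }
  expect_identical(run(), run())
})

test_that("resize preserves constants, decimates aligned blocks exactly, and is idempotent", {
  # constant tile stays constant
  ts <- resize_tiles(tile_slide(gray_slide(16, 16, value = 77), 16), 8)
  expect_equal(as.vector(ts$tiles[[1]]$pixels), rep(77, 8 * 8 * 3))

  # 2x2 constant blocks survive exact 2x decimation
  set.seed(3)
  blocks <- matrix(sample(0:255, 16), 4, 4)
  big <- blocks[rep(1:4, each = 2), rep(1:4, each = 2)]
  sl <- slide_image(array(rep(big, 3), c(8, 8, 3)), "S1")
  ts2 <- resize_tiles(tile_slide(sl, 8), 4)
  expect_equal(ts2$tiles[[1]]$pixels[, , 1], blocks, tolerance = 1e-6)

  # resizing an already-sized tile is the identity
  ts3 <- resize_tiles(ts2, 4)
  expect_identical(ts3$tiles[[1]]$pixels, ts2$tiles[[1]]$pixels)
})

test_that("Reinhard normalization matches reference statistics and is deterministic", {
  sl <- noise_slide(16, 16, seed = 11)
  ts <- tile_slide(sl, 16)
  ref <- reinhard_reference()
  out1 <- normalize_color(ts, ref, method = "reinhard")
  out2 <- normalize_color(ts, ref, method = "reinhard")
  expect_identical(out1, out2)

  # closed-form contract: output Lab channel means/sds equal the reference
  lab <- pathtx:::tile_lab(out1$tiles[[1]]$pixels)
  expect_equal(unname(colMeans(lab)), ref$mean, tolerance = 0.1)
  expect_equal(unname(apply(lab, 2, sd)), ref$sd, tolerance = 0.1)

  # normalizing a tile to its own statistics is the identity up to rounding
  own <- list(mean = colMeans(pathtx:::tile_lab(ts$tiles[[1]]$pixels)),
              sd = apply(pathtx:::tile_lab(ts$tiles[[1]]$pixels), 2, sd))
  self_norm <- normalize_color(ts, own, method = "reinhard")
  expect_lt(max(abs(self_norm$tiles[[1]]$pixels - ts$tiles[[1]]$pixels)), 2)
})

test_that("degenerate tiles pass through color normalization unchanged with a warning", {
  ts <- tile_slide(gray_slide(8, 8), 8)
  expect_warning(out <- normalize_color(ts, method = "reinhard"), "degenerate")
  expect_equal(out$tiles[[1]]$pixels, ts$tiles[[1]]$pixels)
})

test_that("identity normalization and Macenko are available and deterministic", {
  sl <- noise_slide(16, 16, seed = 13)
  ts <- tile_slide(sl, 16)
  expect_identical(normalize_color(ts, method = "identity"), ts)
  m1 <- normalize_color(ts, method = "macenko")
  m2 <- normalize_color(ts, method = "macenko")
  expect_identical(m1, m2)
  expect_true(all(m1$tiles[[1]]$pixels >= 0 & m1$tiles[[1]]$pixels <= 255))
})
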