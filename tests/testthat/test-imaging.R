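test_that("contrast enhancement spreads intensities and keeps range bounds", {
  # smooth low-contrast image: spread and dynamic range both increase
  img <- outer(seq(0, 2 * pi, length.out = 64), seq(0, 2 * pi, length.out = 64),
               function(a, b) 120 + 15 * sin(a) * cos(b))
  out <- enhance_contrast(img)
  expect_equal(dim(out), dim(img))
  expect_gt(sd(out), sd(img))
  expect_gt(diff(range(out)), diff(range(img)))
  # two-level image with a generous clip limit: the bright level is pushed
  # to the top of the range and the separation widens
  two <- matrix(c(rep(40, 3000), rep(220, 1096)), 64, 64)
  out2 <- enhance_contrast(two, detect_config(clahe_clip = 50))
  expect_gte(max(out2), 254)
  expect_gt(diff(range(out2)), diff(range(two)))
  expect_true(all(out2 >= 0 & out2 <= 255))
  # constant image unchanged
  expect_equal(enhance_contrast(matrix(128, 32, 32)), matrix(128, 32, 32))
  # random images stay in range
  set.seed(4)
  r <- matrix(runif(32 * 32, 0, 255), 32)
  out2 <- enhance_contrast(r)
  expect_true(all(out2 >= 0 & out2 <= 255))
})

test_that("sharpening follows the documented 3x3 weighted-sum convention", {
  # zero-sum kernel on a constant image: constant regions vanish
  k0 <- matrix(-1, 3, 3); k0[2, 2] <- 8
  out <- sharpen(matrix(77, 20, 20), detect_config(sharpen_kernel = k0))
  expect_equal(max(abs(out)), 0, tolerance = 1e-6)
  # the kernel stage matches a hand-computed weighted sum at an interior pixel
  set.seed(11)
  x <- matrix(runif(49, 0, 255), 7, 7)
  k <- matrix(c(1, -2, 0, 3, 5, -1, 0, 2, -4), 3, 3, byrow = TRUE)
  o <- strainspeech:::conv3x3_replicate(x, k)
  expect_equal(o[4, 4], sum(k * x[3:5, 3:5]), tolerance = 1e-10)
  # edge replication: top-left corner uses replicated border rows/cols
  xp <- x[c(1, 1:7), ]; xp <- xp[, c(1, 1:7)]
  expect_equal(o[1, 1], sum(k * xp[1:3, 1:3]), tolerance = 1e-10)
})

test_that("sharpening increases the gradient magnitude at a step edge", {
  img <- matrix(60, 40, 40)
  img[, 21:40] <- 200
  out <- sharpen(img, detect_config())
  grad_in <- max(abs(diff(t(img))))
  grad_out <- max(abs(diff(t(out))))
  expect_gt(grad_out, grad_in)
  expect_error(sharpen(img, detect_config(sharpen_kernel = matrix(1, 2, 2))),
               "3x3")
})

test_that("border removal blanks exactly the margin frame", {
  img <- matrix(0, 30, 40)
  expect_identical(remove_border(img, 0), img)
  out <- remove_border(img, 10)
  expect_true(all(out[1:10, ] == 255))
  expect_true(all(out[, 1:10] == 255))
  expect_true(all(out[11:20, 11:30] == 0))
  expect_error(remove_border(img, 15), "margin")
})

test_that("Otsu matches the exhaustive between-class-variance sweep", {
  set.seed(7)
  # bimodal image
  img <- matrix(c(rnorm(600, 40, 6), rnorm(400, 220, 8)), 40, 25)
  t_pkg <- otsu_threshold(img)
  expect_gt(t_pkg, 40)
  expect_lt(t_pkg, 220)
  expect_identical(t_pkg, brute_otsu(img))
  # assorted random images, exact agreement every time
  for (i in 1:5) {
    r <- matrix(runif(400, 0, 255), 20)
    expect_identical(otsu_threshold(r), brute_otsu(r))
  }
  # independent cross-check against the EBImage implementation on an
  # overlapping-population image (a well-separated one has a plateau of
  # equally optimal thresholds where tie-break conventions legitimately
  # differ); bin conventions allow a few gray levels of slack
  imo <- matrix(pmin(pmax(c(rnorm(600, 90, 30), rnorm(400, 170, 30)), 0), 255),
                40, 25)
  eb <- EBImage::otsu(EBImage::Image(t(imo) / 255), range = c(0, 1)) * 255
  expect_lt(abs(otsu_threshold(imo) - eb), 3)
})

test_that("binarization keeps dark markers as foreground and respects symmetry", {
  img <- matrix(220, 20, 20)
  img[8:12, 8:12] <- 40
  b <- binarize(img)
  expect_true(all(b[8:12, 8:12]))
  expect_false(any(b[1:5, 1:5]))
  # already-binary image: classes preserved
  bin01 <- matrix(c(0, 255), 10, 10)
  expect_equal(unname(binarize(bin01)), bin01 == 0, ignore_attr = TRUE)
  # inverting intensities swaps the classes exactly
  b_inv <- binarize(255 - img)
  expect_equal(unname(b_inv), !unname(b), ignore_attr = TRUE)
  # constant image falls back to all background with a warning
  expect_warning(bc <- binarize(matrix(100, 5, 5)), "constant")
  expect_false(any(bc))
})

test_that("component extraction filters by area and tolerates empty images", {
  cfg <- detect_config(min_area_px = 20, max_area_px = 500)
  expect_equal(nrow(extract_markers(matrix(FALSE, 20, 20), cfg)), 0)
  spec <- small_spec()
  img <- render_marker_image(spec, deformation_field())
  b <- binarize(img)
  mk <- extract_markers(b, cfg)
  expect_equal(nrow(mk), spec$rows * spec$cols)
  # add a 4-px speck: filtered out by min_area
  b2 <- b
  b2[3, 60:61] <- TRUE; b2[4, 60:61] <- TRUE
  expect_equal(nrow(extract_markers(b2, cfg)), spec$rows * spec$cols)
  # with the filter off the speck appears
  expect_equal(nrow(extract_markers(b2, detect_config(min_area_px = 1))),
               spec$rows * spec$cols + 1)
})

test_that("connected components merge across diagonal touches (8-connectivity)", {
  b <- matrix(FALSE, 10, 10)
  b[3, 3] <- TRUE; b[4, 4] <- TRUE; b[5, 5] <- TRUE
  mk <- extract_markers(b, detect_config(min_area_px = 1, max_area_px = 50))
  expect_equal(nrow(mk), 1)
  expect_equal(mk$area, 3)
})

test_that("size filter is monotone: raising min_area never increases the count", {
  spec <- small_spec()
  img <- render_marker_image(spec, deformation_field(), noise_sd = 10, seed = 2)
  b <- suppressWarnings(binarize(sharpen(enhance_contrast(img))))
  counts <- vapply(c(1, 10, 30, 60, 90), function(mn)
    nrow(extract_markers(b, detect_config(min_area_px = mn))), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("full detection: blank frames, exact recovery, noisy recall", {
  cfg <- detect_config(min_area_px = 15)
  expect_equal(nrow(detect_markers(matrix(255, 100, 120), cfg)), 0)
  spec <- small_spec()
  truth <- marker_lattice(spec)
  img <- render_marker_image(spec, deformation_field())
  mk <- detect_markers(img, cfg)
  expect_equal(nrow(mk), nrow(truth))   # 100% recall, noiseless
  err <- centroid_errors(mk, truth)
  expect_lt(sqrt(mean(err^2)), 0.5)
  expect_true(all(err < 1))
  # determinism
  expect_identical(detect_markers(img, cfg), mk)
  # Gaussian noise sigma = 8: at least 90% of markers recovered
  imgn <- render_marker_image(spec, deformation_field(), noise_sd = 8, seed = 9)
  mkn <- detect_markers(imgn, cfg)
  hits <- sum(centroid_errors(mkn, truth) < 2)
  expect_gte(hits / nrow(truth), 0.9)
})

test_that("a dark vignette ring is removed before extraction", {
  spec <- small_spec()
  img <- render_marker_image(spec, deformation_field())
  h <- nrow(img); w <- ncol(img)
  img[c(1:3, (h - 2):h), ] <- 10     # dark frame border
  img[, c(1:3, (w - 2):w)] <- 10
  mk <- detect_markers(img, detect_config(min_area_px = 15, border_margin_px = 4))
  expect_equal(nrow(mk), spec$rows * spec$cols)
  expect_true(all(mk$x > 3 & mk$y > 3))
})

test_that("frames round-trip through 8-bit PNG", {
  img <- render_marker_image(small_spec(), deformation_field())
  f <- tempfile(fileext = ".png")
  write_frame(img, f)
  back <- read_frame(f)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - unclass(img))), 0.51)   # 8-bit quantization
  unlink(f)
})
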