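test_that("MOI selection takes the k markers nearest the image centre", {
  set.seed(3)
  mk <- data.frame(cx = runif(25, 0, 319), cy = runif(25, 0, 239))
  mois <- select_mois(mk, c(320, 240), k = 16)
  expect_equal(nrow(mois), 16)
  # brute-force full sort oracle
  d <- sqrt((mk$cx - 159.5)^2 + (mk$cy - 119.5)^2)
  expect_setequal(round(mois$dist, 9), round(sort(d)[1:16], 9))
  # a marker exactly at the centre is always selected with distance 0
  mk2 <- rbind(mk, data.frame(cx = 159.5, cy = 119.5))
  mois2 <- select_mois(mk2, c(320, 240), k = 16)
  expect_equal(min(mois2$dist), 0)
  expect_error(select_mois(mk[1:10, ], c(320, 240), k = 16), "insufficient")
})

test_that("marker matching is one-to-one with analytic displacements", {
  # well-spread layout (lattice + jitter) so nearest-neighbour pairing is
  # unambiguous at the tested displacements
  set.seed(5)
  lat <- marker_lattice(small_spec())
  a <- data.frame(cx = lat[1:12, 1] + runif(12, -2, 2),
                  cy = lat[1:12, 2] + runif(12, -2, 2))
  # identical sets: identity matching at distance 0
  m <- match_markers(a, a, 5)
  expect_equal(nrow(m$pairs), 12)
  expect_equal(m$pairs$dist, rep(0, 12))
  expect_equal(m$pairs$i, m$pairs$j)
  # uniform displacement (2, 1): all pair distances sqrt(5)
  b <- data.frame(cx = a$cx + 2, cy = a$cy + 1)
  m2 <- match_markers(a, b, 10)
  expect_equal(nrow(m2$pairs), 12)
  expect_equal(m2$pairs$dist, rep(sqrt(5), 12))
  # removing one current marker leaves exactly that initial marker unmatched
  m3 <- match_markers(a, b[-4, ], 10)
  expect_equal(nrow(m3$pairs), 11)
  expect_equal(m3$unmatched_initial, 4L)
})

test_that("homography estimation recovers exact and outlier-laden transforms", {
  H <- centered_homography(c(320, 240), rbind(c(1.05, 0.03), c(-0.02, 0.96)),
                           c(3, -2))
  set.seed(8)
  src <- cbind(runif(15, 10, 300), runif(15, 10, 230))
  dst <- apply_homography(H, src)
  p <- data.frame(x0 = src[, 1], y0 = src[, 2], x1 = dst[, 1], y1 = dst[, 2])
  est <- estimate_homography(p, seed = 2)
  expect_lt(max(abs(est$H - H)), 1e-6)
  # identity correspondences give the identity matrix
  pid <- data.frame(x0 = src[, 1], y0 = src[, 2], x1 = src[, 1], y1 = src[, 2])
  expect_lt(max(abs(estimate_homography(pid, seed = 1)$H - diag(3))), 1e-6)
  # translation (3, 4) puts the shift in the last column
  pt <- data.frame(x0 = src[, 1], y0 = src[, 2],
                   x1 = src[, 1] + 3, y1 = src[, 2] + 4)
  et <- estimate_homography(pt, seed = 1)
  expect_equal(et$H[1, 3], 3, tolerance = 1e-6)
  expect_equal(et$H[2, 3], 4, tolerance = 1e-6)
  # 20% gross outliers: inlier reprojection error < 0.5 px vs the true H
  p_out <- p
  p_out$x1[1:3] <- p_out$x1[1:3] + 40
  eo <- estimate_homography(p_out, seed = 6)
  pred <- apply_homography(eo$H, src[4:15, ])
  expect_lt(max(sqrt(rowSums((pred - dst[4:15, ])^2))), 0.5)
  expect_error(estimate_homography(p[1:3, ]), "underdetermined")
})

test_that("random invertible homographies are recovered to 1e-6 from exact points", {
  set.seed(42)
  for (rep in 1:8) {
    M2 <- diag(2) + matrix(rnorm(4, 0, 0.05), 2)
    H <- centered_homography(c(320, 240), M2, rnorm(2, 0, 4))
    H[3, 1:2] <- rnorm(2, 0, 1e-4)       # mild projective component
    H <- H / H[3, 3]
    src <- cbind(runif(10, 5, 310), runif(10, 5, 230))
    dst <- apply_homography(H, src)
    p <- data.frame(x0 = src[, 1], y0 = src[, 2], x1 = dst[, 1], y1 = dst[, 2])
    est <- estimate_homography(p, seed = rep)
    expect_lt(max(abs(est$H - H)), 1e-6)
  }
})

test_that("strain maps follow the closed-form amplitude and direction", {
  lat <- strain_lattice(c(320, 240), rows = 6, cols = 8)
  # identity: zero amplitude
  sm0 <- compute_strain_map(diag(3), lat)
  expect_true(all(sm0$amplitude == 0))
  # translation (3, 4): amplitude 5, direction atan2(4, 3) everywhere
  Ht <- diag(3); Ht[1, 3] <- 3; Ht[2, 3] <- 4
  smt <- compute_strain_map(Ht, lat)
  expect_equal(as.numeric(smt$amplitude), rep(5, 48), tolerance = 1e-12)
  expect_equal(as.numeric(smt$direction), rep(atan2(4, 3), 48),
               tolerance = 1e-12)
  # uniform scaling s about the centre: amplitude |s-1| * r pointwise
  s <- 1.07
  Hs <- centered_homography(c(320, 240), s * diag(2))
  sms <- compute_strain_map(Hs, lat)
  ctr <- c(159.5, 119.5)
  r <- sqrt((lat$points[, 1] - ctr[1])^2 + (lat$points[, 2] - ctr[2])^2)
  expect_equal(as.numeric(t(sms$amplitude)), abs(s - 1) * r, tolerance = 1e-9)
})

test_that("amplitude at shared points is lattice-resolution invariant for affine H", {
  H <- centered_homography(c(320, 240), rbind(c(1.03, 0.01), c(0, 0.98)), c(1, 2))
  coarse <- strain_lattice(c(320, 240), rows = 3, cols = 5)
  fine <- strain_lattice(c(320, 240), rows = 5, cols = 9)   # supersets coarse
  smc <- compute_strain_map(H, coarse)
  smf <- compute_strain_map(H, fine)
  expect_equal(smc$amplitude[2, 3], smf$amplitude[3, 5], tolerance = 1e-12)
  expect_equal(smc$amplitude[1, 1], smf$amplitude[1, 1], tolerance = 1e-12)
})

test_that("residual stress maps are exactly translation invariant", {
  spec <- small_spec()
  designed <- marker_lattice(spec)
  # captured = designed: all deviations zero
  r0 <- compute_residual_stress_map(designed, designed)
  expect_equal(r0$deviation, rep(0, nrow(designed)))
  # uniform translation absorbed by centroid alignment, exactly
  rt <- compute_residual_stress_map(designed, sweep(designed, 2, c(7, -3), `+`))
  expect_equal(rt$deviation, rep(0, nrow(designed)))
  # arbitrary perturbed layout: deviations invariant under global shifts
  set.seed(12)
  captured <- designed + matrix(rnorm(length(designed), 0, 1.5), ncol = 2)
  ra <- compute_residual_stress_map(designed, captured)
  rb <- compute_residual_stress_map(designed,
                                    sweep(captured, 2, c(-11.3, 40.02), `+`))
  expect_equal(ra$deviation, rb$deviation, tolerance = 1e-10)
  expect_identical(ra$pairing, rb$pairing)
})

test_that("a single perturbed marker leaks 1/m into every deviation via the centroid", {
  spec <- small_spec()
  designed <- marker_lattice(spec)
  m <- nrow(designed)
  captured <- designed
  captured[5, ] <- captured[5, ] + c(1, 1)
  res <- compute_residual_stress_map(designed, captured)
  # brute-force recomputation
  shift <- colMeans(captured) - colMeans(designed)
  adj <- sweep(designed, 2, shift, `+`)
  brute <- vapply(seq_len(m), function(i)
    min(sqrt(rowSums(sweep(adj, 2, captured[i, ])^2))), numeric(1))
  expect_equal(res$deviation, brute, tolerance = 1e-12)
  # unperturbed markers still feel the centroid shift of magnitude sqrt(2)/m
  expect_equal(res$deviation[1], sqrt(2) / m, tolerance = 1e-12)
})

test_that("relative pixel change follows the 3-4-5 arithmetic and homogeneity", {
  ctr <- c(160, 120)
  p0 <- ctr + c(30, 40)
  expect_equal(relative_pixel_change(p0, p0, center = ctr), 0)
  expect_equal(relative_pixel_change(p0, p0 + c(3, 4), center = ctr), 0.1)
  expect_equal(relative_pixel_change(p0, p0 + c(6, 8), center = ctr), 0.2)
  expect_error(relative_pixel_change(ctr, ctr + c(1, 1), center = ctr),
               "undefined ratio")
  # origin reference option
  expect_equal(relative_pixel_change(c(30, 40), c(33, 44), reference = "origin"),
               0.1)
})

test_that("MAPE matches hand-computed percentages and its scaling law", {
  s <- c(1, 2, 4)
  expect_equal(mape(s, s), 0)
  expect_equal(mape(s, 1.05 * s), 5, tolerance = 1e-12)
  expect_equal(mape(c(1, 2, 4), c(1.1, 1.8, 4.4)), 10, tolerance = 1e-12)
  for (c_ in c(0.5, 0.9, 1.3)) {
    expect_equal(mape(s, c_ * s), 100 * abs(1 - c_), tolerance = 1e-12)
  }
  expect_error(mape(c(1, 0, 2), c(1, 1, 1)), "zero")
  expect_error(mape(1:3, 1:4), "lengths")
})

test_that("end-to-end: render -> detect -> match -> RANSAC reproduces analytic strain", {
  spec <- substrate_spec()
  cfg <- detect_config()
  img0 <- render_marker_image(spec, deformation_field())
  m0 <- detect_markers(img0, cfg)
  lat <- strain_lattice(spec$image_size)
  set.seed(31)
  for (rep in 1:2) {
    M2 <- diag(2) + matrix(rnorm(4, 0, 0.03), 2)
    H <- centered_homography(spec$image_size, M2, rnorm(2, 0, 2))
    m1 <- detect_markers(render_marker_image(spec, deformation_field(H)), cfg)
    mt <- match_markers(m0, m1, max_disp_px = spec$pitch_px / 2)
    est <- estimate_homography(mt$pairs, seed = rep)
    sm <- compute_strain_map(est, lat)
    truth <- compute_strain_map(H, lat)
    expect_lt(max(abs(sm$amplitude - truth$amplitude)), 0.5)
  }
})
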