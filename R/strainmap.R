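# From marker detections to strain: markers-of-interest selection, frame-to-
# frame marker matching, robust homography estimation (RANSAC + normalized
# DLT), multiaxial strain amplitude/direction maps, residual-stress baseline
# maps, and the scalar sensor metrics (relative pixel change, MAPE).

#' Select markers of interest (MOIs)
#'
#' The `k` detected markers with the smallest Euclidean distance to the
#' image centre, assigned stable ids. Ties are broken deterministically by
#' (distance, x, y).
#'
#' @param markers a `marker_set` from [detect_markers()].
#' @param image_size `c(width, height)` px.
#' @param k number of MOIs (default 16).
#' @return a `moi_set`: data.frame with columns `id`, `x0`, `y0`, `dist`,
#'   plus attributes `center` and `k`.
#' @export
select_mois <- function(markers, image_size, k = 16) {
  abort_if(nrow(markers) < k, "insufficient markers in FOV")
  ctr <- image_center(image_size[1], image_size[2])
  d <- sqrt((markers$cx - ctr["x"])^2 + (markers$cy - ctr["y"])^2)
  ord <- order(d, markers$cx, markers$cy)
  sel <- ord[seq_len(k)]
  out <- data.frame(id = seq_len(k), x0 = markers$cx[sel], y0 = markers$cy[sel],
                    dist = d[sel])
  attr(out, "center") <- unname(ctr)
  attr(out, "k") <- as.integer(k)
  class(out) <- c("moi_set", "data.frame")
  out
}

#' Match markers between frames
#'
#' Greedy one-to-one nearest-neighbour matching on centroid positions:
#' candidate pairs within `max_disp_px` are accepted in ascending distance
#' order, each marker used at most once. All micromarkers look identical, so
#' matching is purely positional; keep `max_disp_px` below half the marker
#' pitch to prevent identity swaps.
#'
#' @param initial,current `marker_set`s (or data.frames with `cx`, `cy`).
#' @param max_disp_px maximum allowed displacement (px).
#' @return list with `pairs` (data.frame: `i`, `j`, `dist`, and the four
#'   coordinates), `unmatched_initial`, `unmatched_current` (index vectors).
#' @export
match_markers <- function(initial, current, max_disp_px = 12) {
  abort_if(nrow(initial) == 0 || nrow(current) == 0, "empty marker set")
  dx <- outer(initial$cx, current$cx, `-`)
  dy <- outer(initial$cy, current$cy, `-`)
  d <- sqrt(dx^2 + dy^2)
  cand <- which(d <= max_disp_px, arr.ind = TRUE)
  used_i <- logical(nrow(initial)); used_j <- logical(nrow(current))
  pairs <- list()
  if (nrow(cand)) {
    cand <- cand[order(d[cand]), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (used_i[i] || used_j[j]) next
      used_i[i] <- TRUE; used_j[j] <- TRUE
      pairs[[length(pairs) + 1]] <- c(i, j, d[i, j])
    }
  }
  if (length(pairs)) {
    m <- do.call(rbind, pairs)
    pairs <- data.frame(i = m[, 1], j = m[, 2], dist = m[, 3],
                        x0 = initial$cx[m[, 1]], y0 = initial$cy[m[, 1]],
                        x1 = current$cx[m[, 2]], y1 = current$cy[m[, 2]])
    pairs <- pairs[order(pairs$i), ]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(i = integer(), j = integer(), dist = numeric(),
                        x0 = numeric(), y0 = numeric(), x1 = numeric(),
                        y1 = numeric())
  }
  list(pairs = pairs,
       unmatched_initial = which(!used_i),
       unmatched_current = which(!used_j))
}

# Normalized direct linear transform: least-squares homography from >= 4
# point correspondences (Hartley normalization for conditioning).
dlt_homography <- function(src, dst) {
  norm_pts <- function(p) {
    mu <- colMeans(p)
    sc <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, mu)^2)) + 1e-12)
    Tm <- rbind(c(sc, 0, -sc * mu[1]), c(0, sc, -sc * mu[2]), c(0, 0, 1))
    list(p = cbind(p[, 1] * sc - sc * mu[1], p[, 2] * sc - sc * mu[2]), T = Tm)
  }
  ns <- norm_pts(src); nd <- norm_pts(dst)
  s <- ns$p; d <- nd$p
  n <- nrow(s)
  A <- matrix(0, 2 * n, 9)
  for (r in seq_len(n)) {
    x <- s[r, 1]; y <- s[r, 2]; u <- d[r, 1]; v <- d[r, 2]
    A[2 * r - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * r, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  hvec <- eigen(crossprod(A), symmetric = TRUE)$vectors[, 9]
  H <- matrix(hvec, 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  abort_if(abs(H[3, 3]) < 1e-12, "degenerate homography")
  H / H[3, 3]
}

#' Robust homography from correspondences (RANSAC)
#'
#' Fits the 3x3 homography mapping initial to current coordinates: random
#' 4-point minimal samples, inlier counting at a reprojection threshold,
#' then a least-squares (normalized DLT) refit on the best inlier set.
#'
#' @param correspondences the `pairs` data.frame from [match_markers()] (or
#'   any data.frame with `x0`, `y0`, `x1`, `y1`).
#' @param ransac_threshold_px inlier reprojection threshold (px).
#' @param seed integer seed for the minimal-sample draws.
#' @param max_iter maximum RANSAC iterations.
#' @return list of class `homography`: `H` (3x3, `H[3,3] = 1`), `inliers`
#'   (row indices), `rmse` (inlier reprojection RMSE, px).
#' @export
estimate_homography <- function(correspondences, ransac_threshold_px = 1.0,
                                seed = 1, max_iter = 1000) {
  p <- if (is.data.frame(correspondences)) correspondences else correspondences$pairs
  n <- nrow(p)
  abort_if(n < 4, "underdetermined homography")
  src <- cbind(p$x0, p$y0); dst <- cbind(p$x1, p$y1)
  reproj_err <- function(H) {
    pred <- apply_homography(H, src)
    sqrt(rowSums((pred - dst)^2))
  }
  best_inl <- NULL
  with_seed(seed, {
    for (it in seq_len(max_iter)) {
      s <- sample.int(n, 4)
      H <- tryCatch(dlt_homography(src[s, , drop = FALSE], dst[s, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(H)) next
      err <- tryCatch(reproj_err(H), error = function(e) NULL)
      if (is.null(err)) next
      inl <- which(err <= ransac_threshold_px)
      if (length(inl) > length(best_inl)) best_inl <- inl
      if (length(best_inl) == n) break
    }
  })
  abort_if(length(best_inl) < 4, "RANSAC failed to find a 4-point consensus")
  H <- dlt_homography(src[best_inl, , drop = FALSE], dst[best_inl, , drop = FALSE])
  err <- reproj_err(H)
  inl <- which(err <= ransac_threshold_px)
  if (length(inl) >= 4 && length(inl) > length(best_inl)) {
    H <- dlt_homography(src[inl, , drop = FALSE], dst[inl, , drop = FALSE])
    err <- reproj_err(H)
    inl <- which(err <= ransac_threshold_px)
  } else inl <- best_inl
  structure(list(H = H, inliers = inl, rmse = sqrt(mean(err[inl]^2))),
            class = "homography")
}

#' Lattice of strain-map evaluation points
#'
#' Regular grid over the frame interior at which the strain map is sampled.
#'
#' @param image_size `c(width, height)` px.
#' @param rows,cols lattice shape (default 12 x 16 over a 320x240 frame).
#' @return list with `points` (n x 2 matrix), `rows`, `cols`.
#' @export
strain_lattice <- function(image_size, rows = 12, cols = 16) {
  xs <- seq(0, image_size[1] - 1, length.out = cols)
  ys <- seq(0, image_size[2] - 1, length.out = rows)
  g <- expand.grid(x = xs, y = ys)
  list(points = cbind(x = g$x, y = g$y), rows = as.integer(rows),
       cols = as.integer(cols))
}

#' Compute the multiaxial strain map
#'
#' Each lattice point `p` is mapped to `p' = H p` (homogeneous,
#' dehomogenised). The amplitude map is the Euclidean distance
#' `||p' - p||` in pixels; the direction map is `atan2(dy, dx)` in radians,
#' range `(-pi, pi]`, with y growing downwards (image convention).
#'
#' @param H a `homography` (or bare 3x3 matrix).
#' @param lattice a [strain_lattice()].
#' @return a `strain_map`: list with `amplitude` and `direction`
#'   (rows x cols matrices), `lattice`.
#' @export
compute_strain_map <- function(H, lattice) {
  if (inherits(H, "homography")) H <- H$H
  p <- lattice$points
  q <- apply_homography(H, p)
  d <- q - p
  amp <- sqrt(rowSums(d^2))
  dir <- atan2(d[, 2], d[, 1])
  dir[amp == 0] <- 0
  structure(list(
    amplitude = matrix(amp, nrow = lattice$rows, ncol = lattice$cols, byrow = TRUE),
    direction = matrix(dir, nrow = lattice$rows, ncol = lattice$cols, byrow = TRUE),
    lattice = lattice), class = "strain_map")
}

#' Residual-stress baseline map
#'
#' Quantifies the attachment state of the worn sensor: the designed marker
#' layout is translated so its centroid coincides with the centroid of the
#' captured markers, each captured marker is paired with its nearest
#' translated designed point, and the per-marker Euclidean deviations form
#' the map. Exactly invariant to any global translation of the captured set.
#'
#' @param designed m x 2 matrix of designed marker positions (px), e.g.
#'   [marker_lattice()].
#' @param captured a `marker_set` or n x 2 matrix of captured centroids.
#' @return a `residual_stress_map`: list with `deviation` (per captured
#'   marker, px), `pairing` (designed index per captured marker), `shift`
#'   (the alignment translation applied to the designed layout).
#' @export
compute_residual_stress_map <- function(designed, captured) {
  designed <- as.matrix(designed)
  if (is.data.frame(captured)) captured <- cbind(captured$cx, captured$cy)
  captured <- as.matrix(captured)
  abort_if(nrow(designed) == 0 || nrow(captured) == 0, "empty layout")
  shift <- colMeans(captured) - colMeans(designed)
  adj <- sweep(designed, 2, shift, `+`)
  d2 <- outer(captured[, 1], adj[, 1], `-`)^2 + outer(captured[, 2], adj[, 2], `-`)^2
  pairing <- apply(d2, 1, which.min)
  deviation <- sqrt(d2[cbind(seq_len(nrow(captured)), pairing)])
  structure(list(deviation = deviation, pairing = pairing, shift = shift),
            class = "residual_stress_map")
}

#' Relative pixel change of an MOI
#'
#' `||current - initial|| / ||initial||`, with coordinates expressed in the
#' configured reference frame. The default measures the initial coordinate
#' norm from the image centre so that sensitivity does not depend on where
#' the coordinate origin happens to sit; `reference = "origin"` uses raw
#' coordinates.
#'
#' @param moi_initial,moi_current `(x, y)` MOI centre coordinates.
#' @param center image centre `(x, y)`; required for the default reference.
#' @param reference `"center"` or `"origin"`.
#' @return the dimensionless ratio.
#' @export
relative_pixel_change <- function(moi_initial, moi_current,
                                  center = NULL, reference = c("center", "origin")) {
  reference <- match.arg(reference)
  p0 <- as.numeric(moi_initial); p1 <- as.numeric(moi_current)
  if (reference == "center") {
    abort_if(is.null(center), "center required for reference = 'center'")
    p0 <- p0 - as.numeric(center)
    p1 <- p1 - as.numeric(center)
  }
  denom <- sqrt(sum(p0^2))
  abort_if(denom < 1e-12, "undefined ratio: initial MOI at the reference origin")
  sqrt(sum((p1 - p0)^2)) / denom
}

#' Mean absolute percentage error between two response series
#'
#' `100/n * sum(|1 - A_t / S_t|)`, the uniformity metric comparing one
#' sensor's response series `A` against a reference series `S`.
#'
#' @param series_s reference response series (no zero entries).
#' @param series_a comparison response series, same length.
#' @return MAPE in percent.
#' @export
mape <- function(series_s, series_a) {
  abort_if(length(series_s) != length(series_a), "series lengths differ")
  abort_if(any(series_s == 0), "reference series contains zero entries")
  100 * mean(abs(1 - series_a / series_s))
}

#' Serialize a strain map
#'
#' Writes paired CSV grids (`<stem>_amplitude.csv`, `<stem>_direction.csv`)
#' and a JSON sidecar with the lattice metadata.
#'
#' @param sm a `strain_map`.
#' @param stem output path stem.
#' @return the stem, invisibly.
#' @export
write_strain_map <- function(sm, stem) {
  write.csv(sm$amplitude, paste0(stem, "_amplitude.csv"), row.names = FALSE)
  write.csv(sm$direction, paste0(stem, "_direction.csv"), row.names = FALSE)
  jsonlite::write_json(list(rows = sm$lattice$rows, cols = sm$lattice$cols),
                       paste0(stem, "_lattice.json"), auto_unbox = TRUE)
  invisible(stem)
}
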