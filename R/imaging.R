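# Micromarker detection: CLAHE -> unsharp masking + Gaussian blur + 3x3
# sharpening convolution -> border removal -> Otsu binarization -> size-
# filtered connected components. Images are height x width matrices in
# 0-255; EBImage carries the standard image operations.

#' Detection configuration
#'
#' Parameters of the micromarker detection pipeline. The sharpening kernel
#' defaults to the standard 3x3 kernel with -1 in the eight neighbours and a
#' configurable centre weight (9 preserves local mean against the -8
#' surround; 11 gives stronger edge gain).
#'
#' @param clahe_clip CLAHE clip limit.
#' @param clahe_tiles CLAHE tile grid (tiles per axis).
#' @param gaussian_sigma Gaussian blur sigma (px) applied before sharpening.
#' @param sharpen_center centre weight of the 3x3 sharpening kernel.
#' @param sharpen_kernel optional explicit 3x3 kernel (overrides
#'   `sharpen_center`).
#' @param border_margin_px frame border width blanked to background (px).
#' @param min_area_px,max_area_px inclusive component area window (px^2);
#'   components outside it are discarded.
#' @return an object of class `detect_config`.
#' @export
detect_config <- function(clahe_clip = 2.0, clahe_tiles = 8,
                          gaussian_sigma = 1.0, sharpen_center = 9,
                          sharpen_kernel = NULL, border_margin_px = 4,
                          min_area_px = 20, max_area_px = 500) {
  if (is.null(sharpen_kernel)) {
    sharpen_kernel <- matrix(-1, 3, 3)
    sharpen_kernel[2, 2] <- sharpen_center
  }
  sharpen_kernel <- as.matrix(sharpen_kernel)
  abort_if(!all(dim(sharpen_kernel) == c(3, 3)), "sharpen_kernel must be 3x3")
  abort_if(min_area_px >= max_area_px, "min_area_px must be < max_area_px")
  abort_if(border_margin_px < 0, "border_margin_px must be >= 0")
  structure(list(clahe_clip = clahe_clip, clahe_tiles = as.integer(clahe_tiles),
                 gaussian_sigma = gaussian_sigma,
                 sharpen_kernel = sharpen_kernel,
                 border_margin_px = as.integer(border_margin_px),
                 min_area_px = min_area_px, max_area_px = max_area_px),
            class = "detect_config")
}

as_gray_image <- function(img) {
  img <- unclass(as.matrix(img))
  abort_if(nrow(img) < 1 || ncol(img) < 1, "image must be at least 1x1")
  img
}

# matrix (h x w, row = y) <-> EBImage Image (x, y)
to_eb <- function(img) EBImage::Image(t(img) / 255)
from_eb <- function(e) clip255(t(EBImage::imageData(e)) * 255)

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise CLAHE to boost global contrast and marker edge definition;
#' output keeps the 0-255 range and image shape.
#'
#' @param img gray image matrix (0-255).
#' @param cfg a [detect_config()].
#' @return enhanced gray image matrix.
#' @export
enhance_contrast <- function(img, cfg = detect_config()) {
  img <- as_gray_image(img)
  if (diff(range(img)) < 1e-9) return(img)   # constant image: nothing to equalize
  nt <- max(2L, min(cfg$clahe_tiles, floor(dim(img) / 2)))
  # CLAHE needs dimensions divisible by the tile grid: replicate-pad, crop back
  h <- nrow(img); w <- ncol(img)
  hp <- ceiling(h / nt) * nt; wp <- ceiling(w / nt) * nt
  padded <- img[c(seq_len(h), rep(h, hp - h)), c(seq_len(w), rep(w, wp - w)),
                drop = FALSE]
  out <- EBImage::clahe(to_eb(padded), nx = nt, ny = nt,
                        limit = cfg$clahe_clip)
  from_eb(out)[seq_len(h), seq_len(w), drop = FALSE]
}

# 3x3 sliding-window weighted sum with edge replication; out[i, j] =
# sum_{a,b} k[a, b] * x[i + a - 2, j + b - 2] (correlation convention;
# identical to convolution for the symmetric default kernel).
conv3x3_replicate <- function(x, k) {
  h <- nrow(x); w <- ncol(x)
  xp <- rbind(x[1, , drop = FALSE], x, x[h, , drop = FALSE])
  xp <- cbind(xp[, 1, drop = FALSE], xp, xp[, w, drop = FALSE])
  out <- matrix(0, h, w)
  for (a in 1:3) for (b in 1:3) {
    out <- out + k[a, b] * xp[a:(a + h - 1), b:(b + w - 1)]
  }
  out
}

#' Sharpen marker edges
#'
#' Unsharp masking, then a Gaussian blur of `cfg$gaussian_sigma`, then the
#' 3x3 sharpening kernel applied as a sliding weighted sum (`out[i, j] =
#' sum k[a, b] * img[i + a - 2, j + b - 2]`). Borders are edge-replicated;
#' output clipped to 0-255.
#'
#' @inheritParams enhance_contrast
#' @return sharpened gray image matrix.
#' @export
sharpen <- function(img, cfg = detect_config()) {
  img <- as_gray_image(img)
  abort_if(!all(dim(cfg$sharpen_kernel) == c(3, 3)), "sharpen_kernel must be 3x3")
  e <- to_eb(img)
  # unsharp mask: x + (x - blur(x))
  blurred <- EBImage::gblur(e, sigma = max(cfg$gaussian_sigma, 0.5))
  e <- e + (e - blurred)
  e <- EBImage::gblur(e, sigma = max(cfg$gaussian_sigma, 0.5))
  stage <- from_eb(e)
  clip255(conv3x3_replicate(stage, cfg$sharpen_kernel))
}

#' Blank the frame border
#'
#' Sets all pixels within `margin` px of any image edge to white background,
#' removing the dark vignette ring the optics leave at the frame edge before
#' component extraction.
#'
#' @param img gray image matrix (0-255).
#' @param margin border width in px; `2 * margin` must be smaller than the
#'   shorter image side.
#' @param background fill intensity (default 255).
#' @return gray image matrix with blanked border.
#' @export
remove_border <- function(img, margin, background = 255) {
  img <- as_gray_image(img)
  abort_if(2 * margin >= min(dim(img)), "margin too large for image")
  if (margin == 0) return(img)
  h <- nrow(img); w <- ncol(img)
  img[c(seq_len(margin), h - seq_len(margin) + 1), ] <- background
  img[, c(seq_len(margin), w - seq_len(margin) + 1)] <- background
  img
}

#' Otsu threshold of an 8-bit histogram
#'
#' Exhaustive maximization of between-class variance over the 256 integer
#' gray levels; ties resolved to the lowest threshold. Returned threshold
#' `t` splits pixels into `x <= t` and `x > t`.
#'
#' @param img gray image matrix (0-255).
#' @return integer threshold in 0-255, or `NA` for a constant image.
#' @export
otsu_threshold <- function(img) {
  v <- floor(clip255(as.numeric(img)))
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)                     # class-0 mass for t = 0..255
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  if (all(sb == -Inf)) return(NA_integer_)
  which.max(sb) - 1L
}

#' Binarize an image with Otsu's method
#'
#' Threshold chosen to maximize between-class variance of the intensity
#' histogram; the dark class (markers) becomes foreground (`TRUE`). A
#' constant image yields all background with a warning.
#'
#' @param img gray image matrix (0-255).
#' @return logical matrix, `TRUE` = marker foreground; the threshold is
#'   attached as attribute `"threshold"`.
#' @export
binarize <- function(img) {
  img <- as_gray_image(img)
  t <- otsu_threshold(img)
  if (is.na(t)) {
    warning("constant image: binarization falls back to all background")
    out <- matrix(FALSE, nrow(img), ncol(img))
    attr(out, "threshold") <- NA_integer_
    return(out)
  }
  out <- img <= t
  attr(out, "threshold") <- t
  out
}

# 8-connected labeling: EBImage::bwlabel is 4-connected; merge labels that
# touch diagonally with a union-find pass over the label pairs.
label_components8 <- function(bin) {
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(bin * 1)))))
  n <- max(lab)
  if (n < 2) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-h, -1]), as.vector(lab[-1, -w]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relabel[lab[lab > 0]]
  out
}

#' Extract size-filtered markers from a binary image
#'
#' Connected foreground components (8-connectivity) become candidate
#' markers; components with pixel area outside
#' `[min_area_px, max_area_px]` are discarded. Centroids are
#' intensity-weighted when a `weights` image is supplied (darkness-weighted
#' sub-pixel centroid), otherwise the unweighted pixel centroid.
#'
#' @param bin logical matrix from [binarize()].
#' @param cfg a [detect_config()].
#' @param weights optional gray image; weight of a pixel is
#'   `255 - weights[i, j]` (darker = heavier).
#' @return a `marker_set`: data.frame with columns `id`, `cx`, `cy`
#'   (0-based sub-pixel centroid), `x`, `y`, `w`, `h` (bounding box,
#'   0-based top-left corner) and `area` (px^2).
#' @export
extract_markers <- function(bin, cfg = detect_config(), weights = NULL) {
  lab <- label_components8(bin)
  empty <- data.frame(id = integer(), cx = numeric(), cy = numeric(),
                      x = numeric(), y = numeric(), w = numeric(),
                      h = numeric(), area = numeric())
  class(empty) <- c("marker_set", "data.frame")
  if (max(lab) == 0) return(empty)
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[lab > 0]
  px <- idx[, 2] - 1   # x (0-based)
  py <- idx[, 1] - 1   # y
  wt <- if (is.null(weights)) rep(1, length(comp)) else
    pmax(255 - weights[idx], 1e-6)
  area <- tapply(rep(1, length(comp)), comp, sum)
  keep <- names(area)[area >= cfg$min_area_px & area <= cfg$max_area_px]
  if (!length(keep)) return(empty)
  sel <- comp %in% as.integer(keep)
  comp <- comp[sel]; px <- px[sel]; py <- py[sel]; wt <- wt[sel]
  sw <- tapply(wt, comp, sum)
  cx <- tapply(wt * px, comp, sum) / sw
  cy <- tapply(wt * py, comp, sum) / sw
  x0 <- tapply(px, comp, min); x1 <- tapply(px, comp, max)
  y0 <- tapply(py, comp, min); y1 <- tapply(py, comp, max)
  out <- data.frame(id = seq_along(sw), cx = as.numeric(cx), cy = as.numeric(cy),
                    x = as.numeric(x0), y = as.numeric(y0),
                    w = as.numeric(x1 - x0 + 1), h = as.numeric(y1 - y0 + 1),
                    area = as.numeric(tapply(rep(1, length(comp)), comp, sum)))
  out <- out[order(out$cy, out$cx), ]
  out$id <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("marker_set", "data.frame")
  out
}

#' Detect micromarkers in a frame
#'
#' Full pipeline composition: [enhance_contrast()] -> [sharpen()] ->
#' [remove_border()] -> [binarize()] -> [extract_markers()], in that order.
#' Deterministic: identical input and config give identical output.
#'
#' @param img gray image matrix (0-255).
#' @param cfg a [detect_config()].
#' @return a `marker_set` (see [extract_markers()]).
#' @export
detect_markers <- function(img, cfg = detect_config()) {
  img <- as_gray_image(img)
  stage <- enhance_contrast(img, cfg)
  stage <- sharpen(stage, cfg)
  stage <- remove_border(stage, cfg$border_margin_px)
  bin <- suppressWarnings(binarize(stage))
  extract_markers(bin, cfg, weights = stage)
}

#' Read / write marker frames and marker sets
#'
#' Frames are 8-bit grayscale PNG; marker sets are CSV with columns
#' `id, cx, cy, x, y, w, h, area`.
#'
#' @param img gray image matrix; `path` file path.
#' @return `read_frame` returns a gray image matrix; writers return the path
#'   invisibly.
#' @export
write_frame <- function(img, path) {
  png::writePNG(clip01(as_gray_image(img) / 255), path)
  invisible(path)
}

#' @rdname write_frame
#' @param path file path.
#' @export
read_frame <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a * 255
}

#' @rdname write_frame
#' @param markers a `marker_set`.
#' @export
write_marker_set <- function(markers, path) {
  write.csv(as.data.frame(markers), path, row.names = FALSE)
  invisible(path)
}
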