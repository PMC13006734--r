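# Independent oracles and small fixture builders shared across the suite.

# Exhaustive Otsu: sweep all 256 thresholds, maximize between-class
# variance of the integer histogram (class 0 = x <= t); lowest-t tie-break.
brute_otsu <- function(img) {
  v <- floor(pmin(pmax(as.numeric(img), 0), 255))
  best_t <- NA_integer_; best_sb <- -Inf
  n <- length(v)
  for (t in 0:255) {
    c0 <- v <= t
    w0 <- sum(c0) / n
    if (w0 == 0 || w0 == 1) next
    sb <- w0 * (1 - w0) * (mean(v[c0]) - mean(v[!c0]))^2
    if (sb > best_sb + 1e-12) { best_sb <- sb; best_t <- t }
  }
  best_t
}

# Exhaustive DTW: recursively enumerate every monotone boundary-matched
# warping path and take the minimal cumulative squared-difference cost.
# Only feasible for tiny sequences.
brute_dtw <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  ca <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  n <- nrow(ca); m <- ncol(ca)
  rec <- function(i, j) {
    if (i == n && j == m) return(ca[i, j])
    opts <- c()
    if (i < n) opts <- c(opts, rec(i + 1, j))
    if (j < m) opts <- c(opts, rec(i, j + 1))
    if (i < n && j < m) opts <- c(opts, rec(i + 1, j + 1))
    ca[i, j] + min(opts)
  }
  rec(1, 1)
}

# Small substrate that renders and detects quickly.
small_spec <- function() substrate_spec(rows = 4, cols = 4, pitch_px = 20,
                                        marker_radius_px = 5,
                                        image_size = c(120, 100))

# Centroid-matching error between a detected marker set and analytic
# positions: returns per-marker nearest distances.
centroid_errors <- function(markers, truth) {
  d2 <- outer(markers$cx, truth[, 1], `-`)^2 +
        outer(markers$cy, truth[, 2], `-`)^2
  sqrt(apply(d2, 1, min))
}

# Homography about the centre of a frame from an affine 2x2 + translation.
centered_homography <- function(image_size, M2, tvec = c(0, 0)) {
  ctr <- c((image_size[1] - 1) / 2, (image_size[2] - 1) / 2)
  Tc <- diag(3); Tc[1:2, 3] <- ctr
  Ti <- diag(3); Ti[1:2, 3] <- -ctr
  M <- diag(3); M[1:2, 1:2] <- M2; M[1:2, 3] <- tvec
  Tc %*% M %*% Ti
}

# Tiny separable dataset for fast decoder checks.
tiny_dataset <- function(n_classes = 6, samples_per_class = 6, n_subjects = 3,
                         seed = 5, noise = 0.02) {
  generate_word_dataset(seq_gen_config(
    n_classes = n_classes, samples_per_class = samples_per_class,
    n_subjects = n_subjects, template_noise_sd = noise,
    channel_noise_sd = noise / 2, attachment_states = 2, seed = seed))
}

# Small classifier config for fast tests.
tiny_classifier_config <- function(n_classes = 6, in_channels = 4) {
  classifier_config(in_channels = in_channels, n_classes = n_classes,
                    conv_filters = c(8, 16), conv_kernels = c(5, 5),
                    conv_strides = c(3, 3), n_layers = 1, n_heads = 2,
                    d_ff = 24, fusion_dim = 8, resid_dim = 16, fc_dim = 24,
                    dropout = 0)
}
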