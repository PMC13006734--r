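# Utterance-level signal conditioning for strain time series sampled at
# 50 Hz: moving-average smoothing, length validation, centre zero-padding,
# global z-score normalization, the three stochastic training augmentations
# (local time warping, random cropping, amplitude scaling), and energy-based
# voice activity detection.

as_sequence <- function(seq) {
  if (is.null(dim(seq))) seq <- matrix(seq, ncol = 1)
  as.matrix(seq)
}

#' Moving-average smoothing
#'
#' Per-channel centred moving average of odd width (default 5); edges use a
#' shrinking window so the output keeps the input shape.
#'
#' @param seq T x C strain sequence (vector treated as one channel).
#' @param window odd window width, `<=` T.
#' @return smoothed T x C matrix.
#' @export
smooth_sequence <- function(seq, window = 5) {
  seq <- as_sequence(seq)
  T_ <- nrow(seq)
  abort_if(window > T_, "window larger than sequence length")
  abort_if(window %% 2 == 0, "window must be odd")
  half <- (window - 1) / 2
  cs <- apply(seq, 2, function(col) cumsum(c(0, col)))
  lo <- pmax(seq_len(T_) - half, 1)
  hi <- pmin(seq_len(T_) + half, T_)
  out <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  dimnames(out) <- NULL
  out
}

#' Validate utterance length
#'
#' A segment is a valid utterance iff its length lies in the inclusive
#' window (default 100-220 time steps at 50 Hz).
#'
#' @param seq T x C sequence, or an integer length.
#' @param bounds inclusive `(min, max)` length.
#' @return logical.
#' @export
validate_length <- function(seq, bounds = c(100, 220)) {
  T_ <- if (is.numeric(seq) && length(seq) == 1) seq else nrow(as_sequence(seq))
  T_ >= bounds[1] && T_ <= bounds[2]
}

#' Centre zero-padding to a unified length
#'
#' Symmetric zero padding to `target` steps (default 220): the original
#' values stay contiguous and centred; an odd remainder puts the extra zero
#' on the trailing side. Conserves each channel's sum exactly.
#'
#' @param seq T x C sequence with `T <= target`.
#' @param target output length.
#' @return target x C matrix.
#' @export
center_pad <- function(seq, target = 220) {
  seq <- as_sequence(seq)
  T_ <- nrow(seq)
  abort_if(T_ > target, "sequence longer than pad target")
  if (T_ == target) return(seq)
  lead <- (target - T_) %/% 2
  rbind(matrix(0, lead, ncol(seq)), seq,
        matrix(0, target - T_ - lead, ncol(seq)))
}

#' Global normalization statistics from a training corpus
#'
#' Computes the scalar mean and SD over every value of the training corpus
#' (the default), or per-channel vectors with `per_channel = TRUE`.
#' [apply_norm()] applies `(x - mu) / sigma`.
#'
#' @param corpus a `word_dataset`, list of T x C matrices, or one matrix.
#' @param per_channel compute per-channel statistics instead of global
#'   scalars.
#' @param eps guard added to a vanishing SD; with `eps = 0` a constant
#'   corpus is an error.
#' @return a `norm_stats` list with `mu`, `sigma`, `per_channel`.
#' @export
fit_norm <- function(corpus, per_channel = FALSE, eps = 0) {
  seqs <- if (inherits(corpus, "word_dataset")) corpus$sequences
          else if (is.list(corpus)) corpus else list(as_sequence(corpus))
  abort_if(length(seqs) == 0, "empty corpus")
  all_vals <- do.call(rbind, lapply(seqs, as_sequence))
  if (per_channel) {
    mu <- colMeans(all_vals)
    sigma <- apply(all_vals, 2, sd)
  } else {
    mu <- mean(all_vals)
    sigma <- sd(as.numeric(all_vals))
  }
  abort_if(any(sigma <= 0) && eps == 0,
           "constant corpus: sigma is zero (set eps to guard)")
  sigma <- pmax(sigma, eps)
  structure(list(mu = mu, sigma = sigma, per_channel = per_channel),
            class = "norm_stats")
}

#' @rdname fit_norm
#' @param seq T x C sequence.
#' @param stats a `norm_stats`.
#' @export
apply_norm <- function(seq, stats) {
  seq <- as_sequence(seq)
  if (stats$per_channel) {
    sweep(sweep(seq, 2, stats$mu), 2, stats$sigma, `/`)
  } else {
    (seq - stats$mu) / stats$sigma
  }
}

#' Augmentation: local time warping by duplication
#'
#' Randomly selects `n_dup` distinct time indices inside the active signal
#' range (default indices 20-200, 1-based half-open `[21, 200]` interior in
#' 0-based terms) and duplicates the rows at those steps in place, locally
#' stretching the time axis. Output length is `T + n_dup`.
#'
#' @param seq T x C sequence with `T >= active_range[2]`.
#' @param n_dup number of duplicated steps (default 20).
#' @param active_range 0-based `(lo, hi)` index window the duplicated steps
#'   are drawn from (`[lo, hi)`).
#' @return (T + n_dup) x C matrix.
#' @export
augment_time_warp <- function(seq, n_dup = 20, active_range = c(20, 200)) {
  seq <- as_sequence(seq)
  T_ <- nrow(seq)
  abort_if(T_ < active_range[2], "sequence shorter than the active range")
  pick <- sort(sample(seq.int(active_range[1] + 1L, active_range[2]), n_dup))
  idx <- sort(c(seq_len(T_), pick))
  seq[idx, , drop = FALSE]
}

#' Augmentation: random temporal crop
#'
#' Contiguous window of `out_len` steps (default 200) at a uniformly random
#' start, teaching shift invariance.
#'
#' @param seq T x C sequence with `T >= out_len`.
#' @param out_len crop length.
#' @return out_len x C matrix.
#' @export
augment_crop <- function(seq, out_len = 200) {
  seq <- as_sequence(seq)
  T_ <- nrow(seq)
  abort_if(T_ < out_len, "sequence shorter than crop length")
  start <- sample.int(T_ - out_len + 1L, 1L)
  seq[start:(start + out_len - 1L), , drop = FALSE]
}

#' Augmentation: random amplitude scaling
#'
#' Multiplies the whole sequence by one factor `alpha` drawn uniformly from
#' `bounds` (default U(0.9, 1.1)), emulating sensitivity fluctuations.
#'
#' @param seq T x C sequence.
#' @param bounds `(lo, hi)` of the uniform scale distribution.
#' @return scaled T x C matrix with attribute `"alpha"`.
#' @export
augment_scale <- function(seq, bounds = c(0.9, 1.1)) {
  abort_if(bounds[1] >= bounds[2], "bounds must be increasing")
  seq <- as_sequence(seq)
  alpha <- runif(1, bounds[1], bounds[2])
  out <- seq * alpha
  attr(out, "alpha") <- alpha
  out
}

#' Training augmentation chain
#'
#' The stochastic chain applied to a padded sequence during training:
#' time warp (+`n_dup` steps) -> random crop to `crop_len` -> amplitude
#' scale. Deterministic given the RNG state.
#'
#' @param seq padded sequence (length >= 200).
#' @param n_dup,crop_len,scale_bounds stage parameters.
#' @return crop_len x C matrix.
#' @export
augment_chain <- function(seq, n_dup = 20, crop_len = 200,
                          scale_bounds = c(0.9, 1.1)) {
  out <- augment_time_warp(seq, n_dup = n_dup)
  out <- augment_crop(out, out_len = crop_len)
  augment_scale(out, bounds = scale_bounds)
}

#' Energy-based voice activity detection
#'
#' Running energy is the trailing boxcar sum (default 200 most recent
#' samples) of the per-step squared channel norm. Energy rising above the
#' threshold opens a segment at the current index; falling below closes it.
#' Segments whose length falls outside `length_bounds` are discarded. When
#' `threshold = NULL` it is calibrated per stream as `mu + 4 sd` of the
#' energy over the leading `calib_span` samples.
#'
#' @param stream T x C strain stream.
#' @param window boxcar length in samples.
#' @param threshold energy threshold (> 0), or `NULL` to auto-calibrate.
#' @param length_bounds valid utterance length window.
#' @param calib_span leading samples used for auto-calibration.
#' @return data.frame of class `vad_segments` with `start`, `end` (0-based,
#'   half-open `[start, end)`) and `peak_energy`; zero rows when nothing is
#'   detected.
#' @export
detect_voice_activity <- function(stream, window = 200, threshold = NULL,
                                  length_bounds = c(100, 220),
                                  calib_span = 250) {
  stream <- as_sequence(stream)
  power <- rowSums(stream^2)
  T_ <- length(power)
  cs <- cumsum(c(0, power))
  lo <- pmax(seq_len(T_) - window + 1L, 1L)
  energy <- cs[seq_len(T_) + 1L] - cs[lo]       # trailing boxcar sum
  if (is.null(threshold)) {
    span <- seq_len(min(calib_span, T_))
    threshold <- mean(energy[span]) + 4 * sd(energy[span])
    if (!is.finite(threshold) || threshold <= 0) threshold <- 1e-8
  }
  abort_if(threshold <= 0, "threshold must be > 0")
  active <- energy > threshold
  edges <- diff(c(FALSE, active))
  starts <- which(edges == 1) - 1L              # 0-based
  ends <- which(edges == -1) - 1L
  if (length(ends) < length(starts)) ends <- c(ends, T_)
  # the trailing window keeps the energy high for ~window samples past the
  # activity; pull the end index back so the segment spans the burst itself
  peaks <- vapply(seq_along(starts), function(s) {
    max(energy[(starts[s] + 1L):ends[s]])
  }, numeric(1))
  ends <- pmax(starts + 1L, ends - as.integer(window))
  keep <- (ends - starts) >= length_bounds[1] & (ends - starts) <= length_bounds[2]
  out <- data.frame(start = starts[keep], end = ends[keep],
                    peak_energy = peaks[keep])
  attr(out, "threshold") <- threshold
  class(out) <- c("vad_segments", "data.frame")
  out
}

#' Deterministic evaluation-time preprocessing
#'
#' The deployment path for one segment: smoothing, length validation,
#' centre padding to 220, centre crop to the model input length (200).
#'
#' @param seq raw T x C segment.
#' @param stats optional `norm_stats` applied after padding.
#' @param pad_to,crop_to pipeline lengths.
#' @return crop_to x C matrix, or `NULL` when the segment fails length
#'   validation.
#' @export
preprocess_segment <- function(seq, stats = NULL, pad_to = 220, crop_to = 200) {
  seq <- smooth_sequence(as_sequence(seq))
  if (!validate_length(seq)) return(NULL)
  out <- center_pad(seq, pad_to)
  if (!is.null(stats)) out <- apply_norm(out, stats)
  off <- (pad_to - crop_to) %/% 2
  out[(off + 1):(off + crop_to), , drop = FALSE]
}
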