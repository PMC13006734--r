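# Synthetic fabrication: rendered micromarker frames under known deformations,
# throat-motion deformation sequences, and labeled 26-class strain-sequence
# datasets with subject / attachment-state structure. Everything downstream
# (detection, strain mapping, decoding) is exercised against these grounds.

#' NATO phonetic alphabet vocabulary
#'
#' The 26 spelling words (Alpha..Zulu) used as the decoder's class labels.
#' @export
nato_alphabet <- c(
  "Alpha", "Bravo", "Charlie", "Delta", "Echo", "Foxtrot", "Golf", "Hotel",
  "India", "Juliett", "Kilo", "Lima", "Mike", "November", "Oscar", "Papa",
  "Quebec", "Romeo", "Sierra", "Tango", "Uniform", "Victor", "Whiskey",
  "Xray", "Yankee", "Zulu"
)

#' Substrate specification for micromarker rendering
#'
#' Describes the designed marker layout: a regular `rows x cols` grid of dark
#' circular markers centred in the frame, on a light substrate. Defaults put
#' ~20-30 markers in a 320x240 frame so that the 16 markers of interest are
#' surrounded by spares, as on the physical sensor.
#'
#' @param rows,cols marker grid counts (>= 1).
#' @param pitch_px inter-marker spacing in pixels.
#' @param marker_radius_px circle radius in pixels; must be < pitch_px / 2.
#' @param image_size `c(width, height)` of the rendered frame in pixels.
#' @param fg_intensity,bg_intensity marker / substrate gray levels in 0-255;
#'   markers are dark on light (`fg < bg`).
#' @return an object of class `substrate_spec`.
#' @export
substrate_spec <- function(rows = 5, cols = 5, pitch_px = 24,
                           marker_radius_px = 6, image_size = c(320, 240),
                           fg_intensity = 20, bg_intensity = 235) {
  abort_if(!is_count(rows) || !is_count(cols), "rows and cols must be counts >= 1")
  abort_if(!(fg_intensity >= 0 && fg_intensity < bg_intensity && bg_intensity <= 255),
           "need 0 <= fg_intensity < bg_intensity <= 255 (dark markers on light substrate)")
  abort_if(!(marker_radius_px > 0 && marker_radius_px < pitch_px / 2),
           "marker_radius_px must be positive and < pitch_px / 2")
  abort_if(length(image_size) != 2 || any(image_size < 1),
           "image_size must be c(width, height)")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pitch_px = pitch_px, marker_radius_px = marker_radius_px,
                 image_size = as.integer(image_size),
                 fg_intensity = fg_intensity, bg_intensity = bg_intensity),
            class = "substrate_spec")
}

#' Designed marker lattice positions
#'
#' Undeformed marker centres of a substrate, in 0-based pixel coordinates
#' (x right, y down, origin at the top-left pixel centre), grid centred on
#' the image centre.
#'
#' @param spec a [substrate_spec()].
#' @return numeric matrix with columns `x`, `y`, one row per marker
#'   (row-major over the grid).
#' @export
marker_lattice <- function(spec) {
  stopifnot(inherits(spec, "substrate_spec"))
  ctr <- image_center(spec$image_size[1], spec$image_size[2])
  xs <- (seq_len(spec$cols) - 1 - (spec$cols - 1) / 2) * spec$pitch_px + ctr["x"]
  ys <- (seq_len(spec$rows) - 1 - (spec$rows - 1) / 2) * spec$pitch_px + ctr["y"]
  g <- expand.grid(x = xs, y = ys)
  m <- cbind(x = g$x, y = g$y)
  rownames(m) <- NULL
  m
}

#' Deformation field applied to substrate coordinates
#'
#' A plane homography (3x3 matrix, `H[3,3] = 1`) optionally composed with
#' per-marker additive local displacements. The identity field leaves all
#' marker centres fixed.
#'
#' @param H 3x3 invertible homography matrix.
#' @param local_displacements optional m x 2 matrix of per-marker `(dx, dy)`
#'   pixel offsets, added after the homography.
#' @return an object of class `deformation_field`.
#' @export
deformation_field <- function(H = diag(3), local_displacements = NULL) {
  H <- as.matrix(H)
  abort_if(!all(dim(H) == c(3, 3)), "H must be a 3x3 matrix")
  abort_if(abs(det(H)) < 1e-12, "H must be invertible")
  H <- H / H[3, 3]
  if (!is.null(local_displacements)) {
    local_displacements <- as.matrix(local_displacements)
    abort_if(ncol(local_displacements) != 2,
             "local_displacements must have two columns (dx, dy)")
  }
  structure(list(H = H, local_displacements = local_displacements),
            class = "deformation_field")
}

#' Apply a homography to 2-D points
#'
#' Homogeneous transform followed by dehomogenisation.
#'
#' @param H 3x3 homography.
#' @param pts n x 2 matrix of `(x, y)` points.
#' @return n x 2 matrix of transformed points.
#' @export
apply_homography <- function(H, pts) {
  pts <- rbind(t(as.matrix(pts)), 1)
  q <- H %*% pts
  w <- q[3, ]
  abort_if(any(abs(w) < 1e-12), "point mapped to infinity (vanishing denominator)")
  out <- t(q[1:2, , drop = FALSE] / rep(w, each = 2))
  colnames(out) <- c("x", "y")
  out
}

# Deformed marker centres for a field over a spec's lattice.
deformed_lattice <- function(spec, field) {
  pts <- apply_homography(field$H, marker_lattice(spec))
  if (!is.null(field$local_displacements)) {
    d <- field$local_displacements
    abort_if(nrow(d) != nrow(pts),
             "local_displacements rows must match marker count")
    pts <- pts + d
  }
  pts
}

#' Render a micromarker frame
#'
#' Draws anti-aliased dark circles at the deformed marker centres on a light
#' substrate, using 4x4 supersampled coverage per pixel so that centroiding
#' the rendered discs recovers the analytic centres to sub-pixel accuracy.
#' Optional additive Gaussian intensity noise emulates sensor noise.
#'
#' @param spec a [substrate_spec()].
#' @param field a [deformation_field()].
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (gray levels); 0 for a noiseless render.
#' @param seed optional integer seed for the noise draw.
#' @return a `height x width` numeric matrix (`gray_image`), values 0-255.
#' @export
render_marker_image <- function(spec, field, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(spec, "substrate_spec"), inherits(field, "deformation_field"))
  w <- spec$image_size[1]; h <- spec$image_size[2]
  centers <- deformed_lattice(spec, field)
  r <- spec$marker_radius_px
  in_fov <- centers[, 1] > -r & centers[, 1] < w - 1 + r &
            centers[, 2] > -r & centers[, 2] < h - 1 + r
  abort_if(!any(in_fov), "empty field of view")

  img <- matrix(spec$bg_intensity, nrow = h, ncol = w)
  # 4x supersampling offsets around each pixel centre
  off <- (seq_len(4) - 0.5) / 4 - 0.5
  for (k in which(in_fov)) {
    cx <- centers[k, 1]; cy <- centers[k, 2]
    js <- max(0, floor(cx - r - 1)):min(w - 1, ceiling(cx + r + 1))
    is <- max(0, floor(cy - r - 1)):min(h - 1, ceiling(cy + r + 1))
    if (!length(js) || !length(is)) next
    # coverage fraction per sub-sample axis, combined over the 16 sub-samples
    sx <- outer(js, off, "+") - cx      # |js| x 4 sub-sample x-offsets
    sy <- outer(is, off, "+") - cy
    r2 <- r^2
    cov <- matrix(0, nrow = length(is), ncol = length(js))
    for (a in 1:4) for (b in 1:4) {
      cov <- cov + (outer(sy[, a]^2, sx[, b]^2, "+") <= r2)
    }
    cov <- matrix(as.numeric(cov), nrow = length(is)) / 16
    patch <- img[is + 1, js + 1, drop = FALSE]
    img[is + 1, js + 1] <- pmin(patch,
      spec$bg_intensity + (spec$fg_intensity - spec$bg_intensity) * cov)
  }
  if (noise_sd > 0) {
    img <- with_seed(seed, img + matrix(rnorm(h * w, 0, noise_sd), h, w))
    img <- clip255(img)
  }
  structure(img, class = c("gray_image", class(img)))
}

#' Generate a deformation sequence emulating throat motion
#'
#' Produces `n_frames` deformation fields. Pattern `"expand_contract"`
#' emulates the expansion/contraction phases of throat muscle movement:
#' anisotropic scaling about the frame centre that contracts one axis while
#' elongating the other, then reverses over the sequence. Patterns
#' `"translate"` (linear drift) and `"shear"` are also available. Frame 1 is
#' always the identity; the seed fully determines the output.
#'
#' @param spec a [substrate_spec()] (provides the frame centre).
#' @param pattern one of `"expand_contract"`, `"translate"`, `"shear"`.
#' @param n_frames number of frames (>= 1).
#' @param seed integer seed for the per-frame jitter.
#' @param amplitude peak scale deviation (unitless) or drift (px/frame).
#' @param jitter_sd per-frame jitter on the scale factors.
#' @return list of [deformation_field()]s of length `n_frames`.
#' @export
generate_motion_sequence <- function(spec, pattern = "expand_contract",
                                     n_frames = 40, seed = 1,
                                     amplitude = 0.05, jitter_sd = 0) {
  abort_if(!is_count(n_frames), "n_frames must be >= 1")
  abort_if(!pattern %in% c("expand_contract", "translate", "shear"),
           paste0("unknown motion pattern: ", pattern))
  ctr <- image_center(spec$image_size[1], spec$image_size[2])
  Tc <- diag(3); Tc[1, 3] <- ctr["x"]; Tc[2, 3] <- ctr["y"]
  Ti <- diag(3); Ti[1, 3] <- -ctr["x"]; Ti[2, 3] <- -ctr["y"]
  with_seed(seed, {
    jit <- if (jitter_sd > 0) rnorm(n_frames, 0, jitter_sd) else numeric(n_frames)
    lapply(seq_len(n_frames), function(t) {
      if (t == 1) return(deformation_field(diag(3)))
      phase <- sin(2 * pi * (t - 1) / max(n_frames - 1, 1))
      M <- diag(3)
      if (pattern == "expand_contract") {
        s <- amplitude * phase + jit[t]
        M[1, 1] <- 1 + s      # x elongates while ...
        M[2, 2] <- 1 - s      # ... y contracts, then reverses
      } else if (pattern == "shear") {
        M[1, 2] <- amplitude * phase + jit[t]
      } else {                # translate: linear drift
        M[1, 3] <- amplitude * (t - 1) + jit[t]
        M[2, 3] <- 0.5 * amplitude * (t - 1)
      }
      deformation_field(Tc %*% M %*% Ti)
    })
  })
}

#' Configuration for synthetic word-dataset generation
#'
#' Defines the study conditions emulated by [generate_word_dataset()]:
#' class count, per-class sample count, subject and attachment-state
#' structure, channel count, valid length window and noise amplitudes.
#'
#' @param n_classes number of word classes (default 26, the NATO alphabet).
#' @param samples_per_class samples per class (exact class balance).
#' @param n_subjects number of emulated subjects.
#' @param n_channels strain feature channels per time step.
#' @param length_range inclusive `(min, max)` valid utterance length in time
#'   steps at 50 Hz; must lie within `[100, 220]`.
#' @param template_noise_sd per-sample additive noise on the class template.
#' @param channel_noise_sd per-entry white measurement noise.
#' @param attachment_states number of residual-map clusters (wearing states).
#' @param seed integer; fully determines the dataset.
#' @return an object of class `seq_gen_config`.
#' @export
seq_gen_config <- function(n_classes = 26, samples_per_class = 10,
                           n_subjects = 6, n_channels = 4,
                           length_range = c(100, 220),
                           template_noise_sd = 0.05, channel_noise_sd = 0.02,
                           attachment_states = 3, seed = 1) {
  abort_if(n_classes < 2, "n_classes must be >= 2")
  abort_if(samples_per_class < 1, "samples_per_class must be >= 1")
  abort_if(length_range[1] < 100 || length_range[2] > 220 ||
             length_range[1] > length_range[2],
           "length_range must be within [100, 220]")
  structure(list(n_classes = as.integer(n_classes),
                 samples_per_class = as.integer(samples_per_class),
                 n_subjects = as.integer(n_subjects),
                 n_channels = as.integer(n_channels),
                 length_range = as.integer(length_range),
                 template_noise_sd = template_noise_sd,
                 channel_noise_sd = channel_noise_sd,
                 attachment_states = as.integer(attachment_states),
                 seed = as.integer(seed)),
            class = "seq_gen_config")
}

# Smooth per-class template: sum of enveloped sinusoids, one curve per
# channel, evaluated at `len` points on [0, 1]. Deterministic given the RNG
# state at call time.
make_template <- function(n_channels, len = 220L, n_harmonics = 4L) {
  tt <- seq(0, 1, length.out = len)
  env <- sin(pi * tt)^2        # utterance-like burst: quiet ends, active middle
  sapply(seq_len(n_channels), function(ch) {
    amp <- rnorm(n_harmonics, 0, 1)
    freq <- sample(1:6, n_harmonics, replace = TRUE)
    phase <- runif(n_harmonics, 0, 2 * pi)
    env * colSums(amp * sin(outer(freq * 2 * pi, tt) + phase))
  })
}

# Linear-interpolation resampling of a T x C matrix to a new length.
resample_sequence <- function(x, new_len) {
  old <- seq(0, 1, length.out = nrow(x))
  new <- seq(0, 1, length.out = new_len)
  apply(x, 2, function(col) stats::approx(old, col, xout = new)$y)
}

#' Generate a labeled synthetic word dataset
#'
#' Builds a balanced multi-class dataset of strain sequences. Each class has
#' a smooth random template shared across subjects; a sample is the template
#' resampled at the subject's speaking-speed factor, scaled by the subject's
#' per-channel gains, shifted by its attachment-state offset, plus noise.
#' Each sample carries a residual-stress map drawn from its attachment
#' state's smooth per-marker deviation field (tighter states expose fewer
#' markers).
#'
#' @param config a [seq_gen_config()].
#' @return an object of class `word_dataset`: a list with `sequences`
#'   (list of T x C matrices), `labels` (integer 1..n_classes, named with
#'   NATO words when n_classes == 26), `subjects`, `states` (integer
#'   vectors), `residuals` (list of per-marker deviation vectors, px) and
#'   `config`.
#' @export
generate_word_dataset <- function(config) {
  stopifnot(inherits(config, "seq_gen_config"))
  abort_if(config$samples_per_class < 1, "samples_per_class must be >= 1")
  cf <- config
  with_seed(cf$seed, {
    lo <- cf$length_range[1]; hi <- cf$length_range[2]
    # class-level structure
    templates <- lapply(seq_len(cf$n_classes), function(k)
      make_template(cf$n_channels))
    base_len <- round(runif(cf$n_classes, lo + 0.15 * (hi - lo),
                            hi - 0.15 * (hi - lo)))
    # subject-level structure: per-channel gain + speaking-speed factor
    gains <- matrix(rnorm(cf$n_subjects * cf$n_channels, 1, 0.08),
                    nrow = cf$n_subjects)
    speeds <- runif(cf$n_subjects, 0.9, 1.1)
    # attachment-state structure: channel offsets + residual deviation field
    state_offset <- matrix(rnorm(cf$attachment_states * cf$n_channels, 0, 0.15),
                           nrow = cf$attachment_states)
    state_markers <- pmax(8L, 16L + 2L * (seq_len(cf$attachment_states) -
                                            ceiling(cf$attachment_states / 2)))
    state_field <- lapply(seq_len(cf$attachment_states), function(s) {
      m <- state_markers[s]
      raw <- abs(stats::filter(rnorm(m + 4, 1.5, 0.6), rep(1 / 3, 3),
                               sides = 2))
      as.numeric(raw[3:(m + 2)])
    })

    n_total <- cf$n_classes * cf$samples_per_class
    sequences <- vector("list", n_total)
    residuals <- vector("list", n_total)
    labels <- integer(n_total); subjects <- integer(n_total)
    states <- integer(n_total)
    i <- 0L
    for (k in seq_len(cf$n_classes)) {
      subj_of <- rep_len(seq_len(cf$n_subjects), cf$samples_per_class)
      for (j in seq_len(cf$samples_per_class)) {
        i <- i + 1L
        s <- subj_of[j]
        st <- sample.int(cf$attachment_states, 1L)
        len <- max(lo, min(hi, round(base_len[k] * speeds[s])))
        x <- resample_sequence(templates[[k]], len)
        x <- sweep(x, 2, gains[s, ], `*`)
        x <- sweep(x, 2, state_offset[st, ], `+`)
        if (cf$template_noise_sd > 0) {
          drift <- resample_sequence(
            matrix(rnorm(24 * cf$n_channels, 0, cf$template_noise_sd), 24), len)
          x <- x + drift
        }
        if (cf$channel_noise_sd > 0) {
          x <- x + matrix(rnorm(length(x), 0, cf$channel_noise_sd), nrow = len)
        }
        dev <- state_field[[st]]
        if (cf$template_noise_sd > 0) {
          dev <- pmax(0, dev + rnorm(length(dev), 0, 0.1 * cf$template_noise_sd * 20))
        }
        sequences[[i]] <- x
        residuals[[i]] <- dev
        labels[i] <- k; subjects[i] <- s; states[i] <- st
      }
    }
    if (cf$n_classes == 26L) names(labels) <- nato_alphabet[labels]
    structure(list(sequences = sequences, labels = labels,
                   subjects = subjects, states = states,
                   residuals = residuals, config = cf),
              class = "word_dataset")
  })
}

#' @export
print.word_dataset <- function(x, ...) {
  cat(sprintf("word_dataset: %d samples, %d classes, %d subjects, %d states, %d channels\n",
              length(x$sequences), x$config$n_classes, x$config$n_subjects,
              x$config$attachment_states, x$config$n_channels))
  invisible(x)
}

#' Write / read a word dataset as plain-text files
#'
#' Serialises each sample as a CSV table of its T x C values plus a JSON
#' manifest (label, subject, state, length, residual map, seed).
#'
#' @param dataset a `word_dataset`.
#' @param dir output directory (created if needed).
#' @return `write_word_dataset` returns `dir` invisibly;
#'   `read_word_dataset` returns a `word_dataset`.
#' @export
write_word_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset$sequences)
  manifest <- list(
    n_samples = n, config = unclass(dataset$config),
    samples = lapply(seq_len(n), function(i) list(
      file = sprintf("sample_%04d.csv", i),
      label = unname(dataset$labels[i]),
      word = if (!is.null(names(dataset$labels))) names(dataset$labels)[i] else NA,
      subject = dataset$subjects[i], state = dataset$states[i],
      length = nrow(dataset$sequences[[i]]),
      residual = dataset$residuals[[i]])))
  for (i in seq_len(n)) {
    write.csv(as.data.frame(dataset$sequences[[i]]),
              file.path(dir, sprintf("sample_%04d.csv", i)), row.names = FALSE)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_word_dataset
#' @export
read_word_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE, simplifyDataFrame = FALSE)
  n <- man$n_samples
  sequences <- vector("list", n); residuals <- vector("list", n)
  labels <- integer(n); subjects <- integer(n); states <- integer(n)
  for (i in seq_len(n)) {
    s <- man$samples[[i]]
    sequences[[i]] <- as.matrix(read.csv(file.path(dir, s$file)))
    dimnames(sequences[[i]]) <- NULL
    residuals[[i]] <- as.numeric(unlist(s$residual))
    labels[i] <- s$label; subjects[i] <- s$subject; states[i] <- s$state
  }
  cfgl <- man$config
  cfg <- seq_gen_config(cfgl$n_classes, cfgl$samples_per_class, cfgl$n_subjects,
                        cfgl$n_channels, unlist(cfgl$length_range),
                        cfgl$template_noise_sd, cfgl$channel_noise_sd,
                        cfgl$attachment_states, cfgl$seed)
  if (cfg$n_classes == 26L) names(labels) <- nato_alphabet[labels]
  structure(list(sequences = sequences, labels = labels, subjects = subjects,
                 states = states, residuals = residuals, config = cfg),
            class = "word_dataset")
}
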