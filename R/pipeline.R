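# End-to-end orchestration: each run_* function is a thin, logged
# composition of module operations that writes its outputs plus a JSON
# manifest (resolved config + seed) so every artifact is reproducible.
# inst/cli/strainspeech.R wraps these functions as shell subcommands.

pipe_log <- function(verbose, ...) {
  if (verbose) message(sprintf(...))
  invisible(NULL)
}

write_manifest <- function(out_dir, command, config, seed, extra = list()) {
  # no timestamps: manifests for the same seed must be byte-identical
  man <- c(list(command = command, seed = seed, config = config), extra)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(man)
}

#' Simulate a marker-frame sequence and a word dataset
#'
#' Renders PNG frames of the micromarker substrate under a seeded motion
#' pattern and writes a labeled synthetic word dataset, with a manifest
#' capturing the resolved configuration. Deterministic given the seed.
#'
#' @param out_dir output directory.
#' @param seed global seed.
#' @param n_frames rendered frames of the motion sequence.
#' @param pattern motion pattern id.
#' @param spec a [substrate_spec()].
#' @param seq_config a [seq_gen_config()]; its seed is overridden by
#'   `seed`.
#' @param noise_sd render noise (gray levels).
#' @param verbose log progress to stderr.
#' @return the manifest list, invisibly.
#' @export
run_simulate <- function(out_dir, seed = 1, n_frames = 8,
                         pattern = "expand_contract",
                         spec = substrate_spec(),
                         seq_config = seq_gen_config(samples_per_class = 6),
                         noise_sd = 0, verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fields <- generate_motion_sequence(spec, pattern, n_frames, seed = seed)
  pipe_log(verbose, "rendering %d frames (%dx%d)", n_frames,
           spec$image_size[1], spec$image_size[2])
  frame_files <- character(n_frames)
  for (t in seq_len(n_frames)) {
    img <- render_marker_image(spec, fields[[t]], noise_sd = noise_sd,
                               seed = seed + t)
    frame_files[t] <- sprintf("frame_%03d.png", t)
    write_frame(img, file.path(out_dir, frame_files[t]))
  }
  hs <- lapply(fields, `[[`, "H")
  utils::write.csv(do.call(rbind, lapply(seq_along(hs), function(t)
    data.frame(frame = t, t(as.vector(hs[[t]]))))),
    file.path(out_dir, "true_homographies.csv"), row.names = FALSE)
  seq_config$seed <- as.integer(seed)
  ds <- generate_word_dataset(seq_config)
  write_word_dataset(ds, file.path(out_dir, "dataset"))
  pipe_log(verbose, "wrote %d dataset samples", length(ds$sequences))
  invisible(write_manifest(out_dir, "simulate",
                           list(spec = unclass(spec),
                                seq_config = unclass(seq_config),
                                pattern = pattern, n_frames = n_frames,
                                noise_sd = noise_sd),
                           seed,
                           extra = list(frames = frame_files,
                                        n_markers = spec$rows * spec$cols)))
}

#' Detect markers in a directory of frames
#'
#' Runs [detect_markers()] on every `frame_*.png` in `in_dir` and writes one
#' marker CSV per frame.
#'
#' @param in_dir directory holding PNG frames.
#' @param out_dir output directory for marker CSVs.
#' @param cfg a [detect_config()].
#' @param verbose log progress.
#' @return data.frame summarising per-frame marker counts, invisibly.
#' @export
run_detect <- function(in_dir, out_dir, cfg = detect_config(), verbose = TRUE) {
  frames <- sort(list.files(in_dir, pattern = "^frame_.*\\.png$"))
  abort_if(length(frames) == 0, paste0("no frames found in ", in_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- integer(length(frames))
  for (i in seq_along(frames)) {
    mk <- detect_markers(read_frame(file.path(in_dir, frames[i])), cfg)
    counts[i] <- nrow(mk)
    write_marker_set(mk, file.path(out_dir, sub("\\.png$", "_markers.csv",
                                                frames[i])))
  }
  pipe_log(verbose, "detected %s markers across %d frames",
           paste(range(counts), collapse = "-"), length(frames))
  summary <- data.frame(frame = frames, n_markers = counts)
  utils::write.csv(summary, file.path(out_dir, "detection_summary.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, "detect", list(detect = unclass(cfg)), NA,
                 extra = list(n_frames = length(frames)))
  invisible(summary)
}

#' Strain maps from detected marker tracks
#'
#' For each frame after the first: match markers to the initial frame,
#' estimate the homography by RANSAC, and write the strain
#' amplitude/direction maps. Also writes the MOI set and the residual
#' stress map of the first frame against the designed layout.
#'
#' @param markers_dir directory of per-frame marker CSVs from
#'   [run_detect()].
#' @param out_dir output directory.
#' @param spec the [substrate_spec()] used at simulation time (designed
#'   layout + frame size).
#' @param lattice_rows,lattice_cols strain-map lattice shape.
#' @param seed RANSAC seed.
#' @param verbose log progress.
#' @return list of `strain_map`s, invisibly.
#' @export
run_strainmap <- function(markers_dir, out_dir, spec = substrate_spec(),
                          lattice_rows = 12, lattice_cols = 16, seed = 1,
                          verbose = TRUE) {
  files <- sort(list.files(markers_dir, pattern = "_markers\\.csv$"))
  abort_if(length(files) < 2, "need at least two marker frames")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sets <- lapply(files, function(f) read.csv(file.path(markers_dir, f)))
  init <- sets[[1]]
  mois <- select_mois(init, spec$image_size,
                      k = min(16, nrow(init)))
  utils::write.csv(as.data.frame(mois), file.path(out_dir, "mois.csv"),
                   row.names = FALSE)
  rsm <- compute_residual_stress_map(marker_lattice(spec), init)
  utils::write.csv(data.frame(marker = seq_along(rsm$deviation),
                              deviation = rsm$deviation),
                   file.path(out_dir, "residual_stress_map.csv"),
                   row.names = FALSE)
  lattice <- strain_lattice(spec$image_size, lattice_rows, lattice_cols)
  maps <- vector("list", length(files) - 1)
  for (t in 2:length(files)) {
    mt <- match_markers(init, sets[[t]], max_disp_px = spec$pitch_px / 2)
    hom <- estimate_homography(mt$pairs, seed = seed + t)
    maps[[t - 1]] <- compute_strain_map(hom, lattice)
    write_strain_map(maps[[t - 1]],
                     file.path(out_dir, sprintf("strain_%03d", t)))
  }
  pipe_log(verbose, "wrote %d strain maps on a %dx%d lattice",
           length(maps), lattice_rows, lattice_cols)
  write_manifest(out_dir, "strainmap",
                 list(lattice = c(lattice_rows, lattice_cols),
                      k_moi = attr(mois, "k")), seed)
  invisible(maps)
}

#' Train the word decoder on a simulated dataset
#'
#' Loads a serialized word dataset, makes a subject-independent split,
#' fits global normalization statistics on the training side only, trains
#' the CNN-Transformer and writes the checkpoint, history and confusion
#' matrix.
#'
#' @param dataset_dir directory from [write_word_dataset()].
#' @param out_dir output directory.
#' @param seed global seed.
#' @param model_cfg a [classifier_config()].
#' @param tcfg a [train_config()].
#' @param test_fold which fold of a [make_folds()] plan to hold out.
#' @param verbose log progress.
#' @return list with `model`, `history`, `test_accuracy`, `stats`,
#'   invisibly.
#' @export
run_train_pipeline <- function(dataset_dir, out_dir, seed = 1,
                               model_cfg = NULL, tcfg = NULL,
                               test_fold = 1, verbose = TRUE) {
  ds <- read_word_dataset(dataset_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(model_cfg))
    model_cfg <- classifier_config(in_channels = ds$config$n_channels,
                                   n_classes = ds$config$n_classes)
  if (is.null(tcfg)) tcfg <- train_config(seed = seed)
  plan <- make_folds(ds, k = min(5, ds$config$n_subjects), seed = seed)
  test_idx <- which(plan$assignments == test_fold)
  train_idx <- which(plan$assignments != test_fold)
  # carve a validation share out of the training subjects
  val_take <- with_seed(seed, sample(train_idx, max(1, round(0.15 * length(train_idx)))))
  fit_idx <- setdiff(train_idx, val_take)
  stats <- fit_norm(ds$sequences[fit_idx])
  train_set <- prepare_model_inputs(ds, fit_idx, stats,
                                    resid_dim = model_cfg$resid_dim)
  val_set <- prepare_model_inputs(ds, val_take, stats,
                                  resid_dim = model_cfg$resid_dim)
  test_set <- prepare_model_inputs(ds, test_idx, stats,
                                   resid_dim = model_cfg$resid_dim)
  model <- build_classifier(model_cfg, seed = seed)
  pipe_log(verbose, "training on %d samples, validating on %d, testing on %d",
           length(fit_idx), length(val_take), length(test_idx))
  fit <- train_classifier(model, train_set, val_set, tcfg)
  ev <- evaluate_classifier(fit$model, test_set)
  pipe_log(verbose, "held-out fold accuracy: %.3f", ev$accuracy)
  export_model(fit$model, file.path(out_dir, "model.json"))
  utils::write.csv(fit$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)
  utils::write.csv(ev$confusion, file.path(out_dir, "confusion.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(mu = stats$mu, sigma = stats$sigma,
                            per_channel = stats$per_channel),
                       file.path(out_dir, "norm_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(out_dir, "train",
                 list(model = unclass(model_cfg), train = unclass(tcfg),
                      test_fold = test_fold), seed,
                 extra = list(test_accuracy = ev$accuracy,
                              best_epoch = fit$best_epoch))
  invisible(list(model = fit$model, history = fit$history,
                 test_accuracy = ev$accuracy, stats = stats))
}

#' Voice-activity-gated streaming inference
#'
#' Streams a long strain recording, segments it with energy-based VAD,
#' preprocesses each valid segment (smooth -> centre pad -> normalize ->
#' centre crop) and emits the decoded word with its probability.
#'
#' @param model an `ssi_classifier` (or path to an exported checkpoint).
#' @param stream T x C matrix, or path to a CSV of it.
#' @param stats `norm_stats` used at training time (or path to the
#'   `norm_stats.json` written by [run_train_pipeline()]).
#' @param residual optional residual-map feature vector for the current
#'   attachment state.
#' @param window,threshold VAD parameters (see [detect_voice_activity()]).
#' @param out_csv optional path for the per-segment prediction table.
#' @param verbose log progress.
#' @return data.frame with `start`, `end`, `label`, `word`, `probability`.
#' @export
run_vad_infer <- function(model, stream, stats = NULL, residual = NULL,
                          window = 200, threshold = NULL, out_csv = NULL,
                          verbose = TRUE) {
  if (is.character(model)) model <- import_model(model)
  if (is.character(stream)) {
    stream <- as.matrix(utils::read.csv(stream))
    dimnames(stream) <- NULL
  }
  if (is.character(stats)) {
    sl <- jsonlite::read_json(stats, simplifyVector = TRUE)
    stats <- structure(list(mu = sl$mu, sigma = sl$sigma,
                            per_channel = isTRUE(sl$per_channel)),
                       class = "norm_stats")
  }
  segs <- detect_voice_activity(stream, window = window, threshold = threshold)
  res <- data.frame(start = integer(), end = integer(), label = integer(),
                    word = character(), probability = numeric())
  rfeat <- if (is.null(residual)) NULL else
    residual_feature(residual, model$config$resid_dim)
  for (i in seq_len(nrow(segs))) {
    seg <- stream[(segs$start[i] + 1):segs$end[i], , drop = FALSE]
    x <- preprocess_segment(seg, stats, crop_to = model$config$seq_len)
    if (is.null(x)) next
    pr <- predict_proba(model, x, rfeat)
    lab <- which.max(pr)
    word <- if (model$config$n_classes == 26) nato_alphabet[lab]
            else as.character(lab)
    res <- rbind(res, data.frame(start = segs$start[i], end = segs$end[i],
                                 label = lab, word = word,
                                 probability = max(pr)))
    pipe_log(verbose, "[%d, %d) -> %s (p = %.3f)", segs$start[i],
             segs$end[i], word, max(pr))
  }
  if (!is.null(out_csv)) utils::write.csv(res, out_csv, row.names = FALSE)
  res
}
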