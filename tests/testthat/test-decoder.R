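test_that("forward pass yields valid probabilities and head symmetry", {
  cfg <- tiny_classifier_config(n_classes = 26)
  m <- build_classifier(cfg, seed = 1)
  x <- matrix(0, 200, 4)
  p <- predict_proba(m, x)
  expect_length(p, 26)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p > 0))
  # permuting the output head permutes the probabilities identically
  perm <- sample(26)
  m2 <- m
  m2$params$out_W <- m$params$out_W[, perm]
  m2$params$out_b <- m$params$out_b[perm]
  set.seed(2)
  xr <- matrix(rnorm(200 * 4), 200, 4)
  rr <- rnorm(16)
  expect_equal(predict_proba(m2, xr, rr), predict_proba(m, xr, rr)[, perm, drop = FALSE],
               tolerance = 1e-12)
})

test_that("parameter count matches the analytic layer-size formula", {
  cfg <- classifier_config(in_channels = 4, n_classes = 26,
                           conv_filters = c(16, 32), conv_kernels = c(5, 5),
                           conv_strides = c(2, 2), n_layers = 1, n_heads = 4,
                           d_ff = 64, fusion_dim = 16, resid_dim = 16,
                           fc_dim = 64)
  m <- build_classifier(cfg)
  d <- 32
  t_tokens <- ((200 - 5) %/% 2 + 1 - 5) %/% 2 + 1   # 47 tokens after two convs
  expect_equal(cfg$t_tokens, t_tokens)
  analytic <-
    (5 * 4) * 16 + 16 +                 # conv1
    (5 * 16) * 32 + 32 +                # conv2
    t_tokens * d +                      # positional embedding
    4 * (d * d + d) +                   # q, k, v, o projections
    2 * (2 * d) +                       # two layer norms
    d * 64 + 64 + 64 * d + d +          # feed-forward
    16 * 16 + 16 +                      # residual-map branch
    (d + 16) * 64 + 64 +                # fused fc
    64 * 26 + 26                        # head
  expect_equal(count_params(m), analytic)
  expect_error(classifier_config(conv_filters = c(16, 30), n_heads = 4),
               "divisible")
})

test_that("fold plans partition the data with subject disjointness and 1/k shares", {
  ds <- generate_word_dataset(seq_gen_config(
    n_classes = 26, samples_per_class = 50, n_subjects = 5, seed = 13))
  plan <- make_folds(ds, k = 5, seed = 1)
  # partition: union = everything, pairwise disjoint
  expect_setequal(unlist(lapply(1:5, function(f) which(plan$assignments == f))),
                  seq_along(ds$labels))
  expect_equal(sum(table(plan$assignments)), 1300)
  for (f in 1:5) {
    test_idx <- which(plan$assignments == f)
    train_idx <- which(plan$assignments != f)
    expect_length(intersect(unique(ds$subjects[test_idx]),
                            unique(ds$subjects[train_idx])), 0)
    # stratification: each test fold holds 10 of the 50 samples per class
    expect_true(all(table(ds$labels[test_idx]) == 10))
  }
  expect_error(make_folds(list(subjects = c(1, 1, 2, 2), labels = 1:4), k = 5),
               "fewer subjects")
})

test_that("a single sample is memorised within the epoch budget", {
  ds <- tiny_dataset(n_classes = 2, samples_per_class = 1, n_subjects = 1)
  st <- fit_norm(ds$sequences, eps = 1e-6)
  set.seed(1)
  one <- prepare_model_inputs(ds, 1, st)
  m <- build_classifier(tiny_classifier_config(n_classes = 2), seed = 1)
  fit <- train_classifier(m, one, one,
                          train_config(max_epochs = 30, patience = 30, seed = 1))
  ev <- evaluate_classifier(fit$model, one)
  expect_equal(ev$accuracy, 1)
})

test_that("seeded training is reproducible and honours the early-stop contract", {
  ds <- tiny_dataset(n_classes = 4, samples_per_class = 6, n_subjects = 2)
  st <- fit_norm(ds$sequences)
  set.seed(3)
  idx <- sample(seq_along(ds$labels))
  tr <- prepare_model_inputs(ds, idx[1:16], st)
  va <- prepare_model_inputs(ds, idx[17:24], st)
  cfg <- train_config(max_epochs = 12, patience = 3, seed = 7)
  m <- build_classifier(tiny_classifier_config(n_classes = 4), seed = 2)
  f1 <- train_classifier(m, tr, va, cfg)
  f2 <- train_classifier(m, tr, va, cfg)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history, f2$history)
  expect_lte(nrow(f1$history), f1$best_epoch + cfg$patience)
})

test_that("evaluation accuracy and confusion bookkeeping are conserved", {
  ds <- tiny_dataset(n_classes = 5, samples_per_class = 6, n_subjects = 2)
  st <- fit_norm(ds$sequences)
  te <- prepare_model_inputs(ds, NULL, st)
  m <- build_classifier(tiny_classifier_config(n_classes = 5), seed = 4)
  ev <- evaluate_classifier(m, te)
  expect_equal(sum(ev$confusion), length(te$y))
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / length(te$y))
  # an untrained model on balanced classes scores near chance
  expect_lt(abs(ev$accuracy - 1 / 5), 3 * sqrt(0.2 * 0.8 / length(te$y)) + 0.05)
  # label outside the model's space errors
  bad <- te; bad$y[1] <- 99L
  expect_error(evaluate_classifier(m, bad), "class space")
})

test_that("distillation with lambda = 0 reduces to plain training, same seed", {
  ds <- tiny_dataset(n_classes = 3, samples_per_class = 4, n_subjects = 2)
  st <- fit_norm(ds$sequences)
  set.seed(5)
  idx <- sample(seq_along(ds$labels))
  tr <- prepare_model_inputs(ds, idx[1:8], st)
  va <- prepare_model_inputs(ds, idx[9:12], st)
  scfg <- classifier_config(in_channels = 4, n_classes = 3,
                            conv_filters = c(4, 8), conv_kernels = c(5, 5),
                            conv_strides = c(3, 3), n_layers = 1, n_heads = 2,
                            d_ff = 12, fusion_dim = 4, resid_dim = 16,
                            fc_dim = 12, dropout = 0)
  teacher <- build_classifier(tiny_classifier_config(n_classes = 3), seed = 6)
  tcfg <- train_config(max_epochs = 4, patience = 4, seed = 11)
  d0 <- distill(teacher, distill_config(lambda = 0, student_config = scfg),
                tr, va, tcfg, seed = 8)
  plain <- train_classifier(build_classifier(scfg, seed = 8), tr, va, tcfg)
  expect_identical(d0$model$params, plain$model$params)
  # invalid lambda rejected; student must be smaller
  expect_error(distill_config(lambda = 1.5), "lambda")
  big <- distill_config(student_config = tiny_classifier_config(n_classes = 3))
  expect_error(distill(build_classifier(scfg, seed = 1), big, tr, va, tcfg),
               "smaller")
})

test_that("LoRA attaches as an exact identity and freezes the base weights", {
  m <- build_classifier(tiny_classifier_config(), seed = 9)
  set.seed(10)
  x <- matrix(rnorm(200 * 4), 200, 4); r <- rnorm(16)
  p0 <- predict_proba(m, x, r)
  ml <- attach_lora(m, lora_config(rank = 4), seed = 3)
  expect_equal(predict_proba(ml, x, r), p0, tolerance = 1e-12)
  # adaptation trains only the adapters; base weights bit-identical
  ds <- tiny_dataset(n_classes = 6, samples_per_class = 4, n_subjects = 1,
                     seed = 30)
  st <- fit_norm(ds$sequences)
  user <- prepare_model_inputs(ds, NULL, st)
  la <- lora_adapt(m, user, lora_config(rank = 4),
                   train_config(max_epochs = 3, patience = 3, seed = 2))
  expect_identical(la$model$params, m$params)
  # analytic trainable fraction: r (d_in + d_out) per adapted projection
  d <- m$config$d_model
  n_lora <- 4 * (d + d) * 2 * m$config$n_layers
  expect_equal(la$report$trainable_params, n_lora)
  expect_equal(la$report$trainable_fraction,
               n_lora / (count_params(m) + n_lora))
  expect_lt(la$report$trainable_fraction, 0.1)
  expect_error(lora_config(targets = "Wx"), "unknown target")
})

test_that("checkpoints round-trip through the portable JSON export", {
  m <- build_classifier(tiny_classifier_config(), seed = 12)
  f <- file.path(tempdir(), "model_roundtrip.json")
  export_model(m, f)
  m2 <- import_model(f)
  set.seed(13)
  x <- lapply(1:3, function(i) matrix(rnorm(200 * 4), 200, 4))
  r <- matrix(rnorm(3 * 16), 3, 16)
  expect_lt(max(abs(predict_proba(m, x, r) - predict_proba(m2, x, r))), 1e-5)
  expect_equal(count_params(m2), count_params(m))
  # a LoRA-carrying model round-trips too
  ml <- attach_lora(m, lora_config(rank = 2), seed = 1)
  ml$lora$layers[[1]]$Wq$B[] <- 0.01    # non-trivial adapter state
  export_model(ml, f)
  ml2 <- import_model(f)
  expect_lt(max(abs(predict_proba(ml, x, r) - predict_proba(ml2, x, r))), 1e-5)
  unlink(f)
})

test_that("residual-map fusion helps when classes shift with attachment state", {
  # two attachment states displace the class patterns; the residual feature
  # identifies the state, so the fused model should not do worse than one
  # trained with the residual branch silenced (directional, fixed seed)
  ds <- generate_word_dataset(seq_gen_config(
    n_classes = 4, samples_per_class = 12, n_subjects = 2,
    template_noise_sd = 0.02, channel_noise_sd = 0.02,
    attachment_states = 2, seed = 44))
  st <- fit_norm(ds$sequences)
  set.seed(15)
  idx <- sample(seq_along(ds$labels))
  n <- length(idx)
  tr_i <- idx[1:round(0.6 * n)]
  va_i <- idx[(round(0.6 * n) + 1):round(0.8 * n)]
  te_i <- idx[(round(0.8 * n) + 1):n]
  tr <- prepare_model_inputs(ds, tr_i, st)
  va <- prepare_model_inputs(ds, va_i, st)
  te <- prepare_model_inputs(ds, te_i, st)
  cfg <- tiny_classifier_config(n_classes = 4)
  tcfg <- train_config(max_epochs = 25, patience = 8, seed = 3)
  fused <- train_classifier(build_classifier(cfg, seed = 5), tr, va, tcfg)
  acc_fused <- evaluate_classifier(fused$model, te)$accuracy
  # silenced residual branch: identical pipeline, zeroed residual features
  zero_r <- function(s) { s$r[] <- 0; s }
  blind <- train_classifier(build_classifier(cfg, seed = 5),
                            zero_r(tr), zero_r(va), tcfg)
  acc_blind <- evaluate_classifier(blind$model, zero_r(te))$accuracy
  expect_gte(acc_fused, acc_blind)
})
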