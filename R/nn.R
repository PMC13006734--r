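# Neural-network engine for the hybrid CNN-Transformer word classifier.
# Implemented directly in base R matrix code: strided 1-D convolutions
# (im2col), learned positional embeddings, multi-head self-attention with
# post-norm residual blocks, a position-wise feed-forward net, mean pooling,
# a residual-stress-map fusion branch at the fully connected stage, and a
# softmax head. Batches are lists of T x C matrices; time-stacked matrices
# ((B*T) x d) keep the large multiplies in BLAS; only the attention score
# products loop over sample x head.

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- parameter initialisation -------------------------------------------

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

conv_out_len <- function(T_in, kernel, stride) (T_in - kernel) %/% stride + 1L

# Initialise all parameters for a classifier config. Consumes the RNG.
nn_init_params <- function(cfg) {
  p <- list()
  c_in <- cfg$in_channels
  for (l in seq_along(cfg$conv_filters)) {
    k <- cfg$conv_kernels[l]; c_out <- cfg$conv_filters[l]
    p[[paste0("conv", l, "_W")]] <- glorot(k * c_in, c_out)
    p[[paste0("conv", l, "_b")]] <- numeric(c_out)
    c_in <- c_out
  }
  d <- cfg$d_model
  p$pos <- matrix(rnorm(cfg$t_tokens * d, 0, 0.02), cfg$t_tokens, d)
  for (l in seq_len(cfg$n_layers)) {
    for (nm in c("Wq", "Wk", "Wv", "Wo"))
      p[[paste0("att", l, "_", nm)]] <- glorot(d, d)
    for (nm in c("bq", "bk", "bv", "bo"))
      p[[paste0("att", l, "_", nm)]] <- numeric(d)
    p[[paste0("ln1_", l, "_g")]] <- rep(1, d)
    p[[paste0("ln1_", l, "_b")]] <- numeric(d)
    p[[paste0("ffn", l, "_W1")]] <- glorot(d, cfg$d_ff)
    p[[paste0("ffn", l, "_b1")]] <- numeric(cfg$d_ff)
    p[[paste0("ffn", l, "_W2")]] <- glorot(cfg$d_ff, d)
    p[[paste0("ffn", l, "_b2")]] <- numeric(d)
    p[[paste0("ln2_", l, "_g")]] <- rep(1, d)
    p[[paste0("ln2_", l, "_b")]] <- numeric(d)
  }
  p$resid_W <- glorot(cfg$resid_dim, cfg$fusion_dim)
  p$resid_b <- numeric(cfg$fusion_dim)
  p$fc1_W <- glorot(d + cfg$fusion_dim, cfg$fc_dim)
  p$fc1_b <- numeric(cfg$fc_dim)
  p$out_W <- glorot(cfg$fc_dim, cfg$n_classes)
  p$out_b <- numeric(cfg$n_classes)
  p
}

# Effective attention projection: base weight plus LoRA low-rank update
# when adapters are attached.
eff_weight <- function(model, l, nm) {
  W <- model$params[[paste0("att", l, "_", nm)]]
  lo <- model$lora
  if (!is.null(lo) && nm %in% lo$targets) {
    ab <- lo$layers[[l]][[nm]]
    W <- W + (lo$alpha / lo$rank) * (ab$A %*% ab$B)
  }
  W
}

# ---- layer normalisation -------------------------------------------------

ln_forward <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  list(y = sweep(sweep(xhat, 2, g, `*`), 2, b, `+`),
       xhat = xhat, inv = inv)
}

ln_backward <- function(dy, cache, g) {
  dxhat <- sweep(dy, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- (dxhat - m1 - cache$xhat * m2) * cache$inv
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

# ---- im2col 1-D convolution ---------------------------------------------

# Unfold one T x C sequence into T_out x (k*C) with tap-fastest columns.
unfold1d <- function(x, kernel, stride) {
  T_out <- conv_out_len(nrow(x), kernel, stride)
  idx <- outer(seq_len(T_out) * stride - stride, seq_len(kernel), `+`)
  matrix(array(x[as.vector(idx), , drop = FALSE],
               c(T_out, kernel, ncol(x))), T_out)
}

# Scatter the unfolded-gradient back onto the input sequence.
fold1d_grad <- function(dU, T_in, kernel, stride, c_in) {
  T_out <- nrow(dU)
  arr <- array(dU, c(T_out, kernel, c_in))
  dx <- matrix(0, T_in, c_in)
  base <- seq_len(T_out) * stride - stride
  for (tap in seq_len(kernel)) {
    rows <- base + tap
    dx[rows, ] <- dx[rows, ] + matrix(arr[, tap, ], nrow = T_out)
  }
  dx
}

# ---- forward pass --------------------------------------------------------

# X: list of B sequences (seq_len x C); R: B x resid_dim matrix.
# Returns probs and, when train = TRUE, the caches needed for backward.
nn_forward <- function(model, X, R, train = FALSE, drop_masks = NULL) {
  cfg <- model$config; p <- model$params
  B <- length(X)
  cache <- list(B = B)

  # convolution stack
  T_cur <- cfg$seq_len; c_in <- cfg$in_channels
  M <- NULL
  conv_caches <- list()
  for (l in seq_along(cfg$conv_filters)) {
    k <- cfg$conv_kernels[l]; s <- cfg$conv_strides[l]
    T_out <- conv_out_len(T_cur, k, s)
    U <- vector("list", B)
    if (l == 1) {
      for (b in seq_len(B)) U[[b]] <- unfold1d(X[[b]], k, s)
    } else {
      for (b in seq_len(B))
        U[[b]] <- unfold1d(M[((b - 1) * T_cur + 1):(b * T_cur), , drop = FALSE], k, s)
    }
    U_all <- do.call(rbind, U)
    Z <- sweep(U_all %*% p[[paste0("conv", l, "_W")]], 2,
               p[[paste0("conv", l, "_b")]], `+`)
    M <- relu(Z)
    conv_caches[[l]] <- list(U = U_all, mask = Z > 0, T_in = T_cur,
                             T_out = T_out, c_in = c_in)
    T_cur <- T_out; c_in <- cfg$conv_filters[l]
  }
  Tt <- T_cur; d <- cfg$d_model
  cache$conv <- conv_caches; cache$Tt <- Tt

  # positional embedding
  pos_rep <- p$pos[rep(seq_len(Tt), times = B), , drop = FALSE]
  M <- M + pos_rep
  cache$layer_in <- vector("list", cfg$n_layers)
  cache$att <- vector("list", cfg$n_layers)
  cache$ln1 <- vector("list", cfg$n_layers)
  cache$ffn <- vector("list", cfg$n_layers)
  cache$ln2 <- vector("list", cfg$n_layers)

  H <- cfg$n_heads; dk <- d %/% H
  head_cols <- lapply(seq_len(H), function(h) ((h - 1) * dk + 1):(h * dk))
  rows_of <- function(b) ((b - 1) * Tt + 1):(b * Tt)

  for (l in seq_len(cfg$n_layers)) {
    cache$layer_in[[l]] <- M
    Wq <- eff_weight(model, l, "Wq"); Wk <- eff_weight(model, l, "Wk")
    Wv <- eff_weight(model, l, "Wv")
    Q <- sweep(M %*% Wq, 2, p[[paste0("att", l, "_bq")]], `+`)
    K <- sweep(M %*% Wk, 2, p[[paste0("att", l, "_bk")]], `+`)
    V <- sweep(M %*% Wv, 2, p[[paste0("att", l, "_bv")]], `+`)
    O <- matrix(0, B * Tt, d)
    Pmats <- vector("list", B * H)
    for (b in seq_len(B)) {
      rb <- rows_of(b)
      for (h in seq_len(H)) {
        hc <- head_cols[[h]]
        S <- tcrossprod(Q[rb, hc, drop = FALSE], K[rb, hc, drop = FALSE]) / sqrt(dk)
        Pm <- softmax_rows(S)
        O[rb, hc] <- Pm %*% V[rb, hc, drop = FALSE]
        Pmats[[(b - 1) * H + h]] <- Pm
      }
    }
    A_out <- sweep(O %*% p[[paste0("att", l, "_Wo")]], 2,
                   p[[paste0("att", l, "_bo")]], `+`)
    cache$att[[l]] <- list(Q = Q, K = K, V = V, O = O, P = Pmats)
    S1 <- M + A_out
    l1 <- ln_forward(S1, p[[paste0("ln1_", l, "_g")]], p[[paste0("ln1_", l, "_b")]])
    cache$ln1[[l]] <- l1
    N1 <- l1$y
    Zf <- sweep(N1 %*% p[[paste0("ffn", l, "_W1")]], 2,
                p[[paste0("ffn", l, "_b1")]], `+`)
    Af <- relu(Zf)
    Fo <- sweep(Af %*% p[[paste0("ffn", l, "_W2")]], 2,
                p[[paste0("ffn", l, "_b2")]], `+`)
    cache$ffn[[l]] <- list(N1 = N1, mask = Zf > 0, Af = Af)
    S2 <- N1 + Fo
    l2 <- ln_forward(S2, p[[paste0("ln2_", l, "_g")]], p[[paste0("ln2_", l, "_b")]])
    cache$ln2[[l]] <- l2
    M <- l2$y
  }

  # mean pooling over time
  grp <- rep(seq_len(B), each = Tt)
  Hp <- rowsum(M, grp) / Tt
  cache$pooled <- Hp

  # dropout (training only, inverted)
  dp <- cfg$dropout
  if (train && dp > 0) {
    if (is.null(drop_masks)) {
      m1 <- matrix(stats::rbinom(length(Hp), 1, 1 - dp), nrow(Hp)) / (1 - dp)
    } else m1 <- drop_masks$m1
    Hp_d <- Hp * m1
  } else { m1 <- NULL; Hp_d <- Hp }

  # residual-stress-map fusion branch
  Zr <- sweep(R %*% p$resid_W, 2, p$resid_b, `+`)
  Rf <- relu(Zr)
  cache$resid_mask <- Zr > 0

  Zc <- cbind(Hp_d, Rf)
  Z1 <- sweep(Zc %*% p$fc1_W, 2, p$fc1_b, `+`)
  F1 <- relu(Z1)
  if (train && dp > 0) {
    if (is.null(drop_masks)) {
      m2 <- matrix(stats::rbinom(length(F1), 1, 1 - dp), nrow(F1)) / (1 - dp)
    } else m2 <- drop_masks$m2
    F1_d <- F1 * m2
  } else { m2 <- NULL; F1_d <- F1 }
  logits <- sweep(F1_d %*% p$out_W, 2, p$out_b, `+`)
  probs <- softmax_rows(logits)

  cache$Zc <- Zc; cache$fc1_mask <- Z1 > 0; cache$F1_d <- F1_d
  cache$m1 <- m1; cache$m2 <- m2; cache$Hp_d <- Hp_d; cache$R <- R
  list(probs = probs, logits = logits, cache = cache)
}

# ---- backward pass -------------------------------------------------------

# dlogits: B x n_classes gradient of the loss at the logits.
# Returns a named list of gradients matching model$params (plus lora grads
# under $lora when adapters are attached).
nn_backward <- function(model, fw, dlogits) {
  cfg <- model$config; p <- model$params; ca <- fw$cache
  B <- ca$B; Tt <- ca$Tt; d <- cfg$d_model
  g <- list()

  g$out_W <- crossprod(ca$F1_d, dlogits)
  g$out_b <- colSums(dlogits)
  dF1 <- dlogits %*% t(p$out_W)
  if (!is.null(ca$m2)) dF1 <- dF1 * ca$m2
  dZ1 <- dF1 * ca$fc1_mask
  g$fc1_W <- crossprod(ca$Zc, dZ1)
  g$fc1_b <- colSums(dZ1)
  dZc <- dZ1 %*% t(p$fc1_W)
  dHp_d <- dZc[, seq_len(d), drop = FALSE]
  dRf <- dZc[, (d + 1):ncol(dZc), drop = FALSE]
  dZr <- dRf * ca$resid_mask
  g$resid_W <- crossprod(ca$R, dZr)
  g$resid_b <- colSums(dZr)
  dHp <- if (!is.null(ca$m1)) dHp_d * ca$m1 else dHp_d

  # un-pool
  dM <- dHp[rep(seq_len(B), each = Tt), , drop = FALSE] / Tt

  H <- cfg$n_heads; dk <- d %/% H
  head_cols <- lapply(seq_len(H), function(h) ((h - 1) * dk + 1):(h * dk))
  rows_of <- function(b) ((b - 1) * Tt + 1):(b * Tt)
  lora <- model$lora
  if (!is.null(lora)) g$lora <- list()

  for (l in rev(seq_len(cfg$n_layers))) {
    l2 <- ln_backward(dM, ca$ln2[[l]], p[[paste0("ln2_", l, "_g")]])
    g[[paste0("ln2_", l, "_g")]] <- l2$dg
    g[[paste0("ln2_", l, "_b")]] <- l2$db
    dS2 <- l2$dx
    # FFN
    fc <- ca$ffn[[l]]
    dFo <- dS2
    g[[paste0("ffn", l, "_W2")]] <- crossprod(fc$Af, dFo)
    g[[paste0("ffn", l, "_b2")]] <- colSums(dFo)
    dAf <- dFo %*% t(p[[paste0("ffn", l, "_W2")]])
    dZf <- dAf * fc$mask
    g[[paste0("ffn", l, "_W1")]] <- crossprod(fc$N1, dZf)
    g[[paste0("ffn", l, "_b1")]] <- colSums(dZf)
    dN1 <- dS2 + dZf %*% t(p[[paste0("ffn", l, "_W1")]])
    l1 <- ln_backward(dN1, ca$ln1[[l]], p[[paste0("ln1_", l, "_g")]])
    g[[paste0("ln1_", l, "_g")]] <- l1$dg
    g[[paste0("ln1_", l, "_b")]] <- l1$db
    dS1 <- l1$dx
    # attention
    at <- ca$att[[l]]
    dA_out <- dS1
    g[[paste0("att", l, "_Wo")]] <- crossprod(at$O, dA_out)
    g[[paste0("att", l, "_bo")]] <- colSums(dA_out)
    dO <- dA_out %*% t(p[[paste0("att", l, "_Wo")]])
    dQ <- matrix(0, B * Tt, d); dK <- dQ; dV <- dQ
    for (b in seq_len(B)) {
      rb <- rows_of(b)
      for (h in seq_len(H)) {
        hc <- head_cols[[h]]
        Pm <- at$P[[(b - 1) * H + h]]
        dObh <- dO[rb, hc, drop = FALSE]
        Vbh <- at$V[rb, hc, drop = FALSE]
        dPm <- tcrossprod(dObh, Vbh)
        dV[rb, hc] <- crossprod(Pm, dObh)
        dS <- Pm * (dPm - rowSums(dPm * Pm))
        dQ[rb, hc] <- (dS %*% at$K[rb, hc, drop = FALSE]) / sqrt(dk)
        dK[rb, hc] <- (crossprod(dS, at$Q[rb, hc, drop = FALSE])) / sqrt(dk)
      }
    }
    M0 <- ca$layer_in[[l]]
    GWq <- crossprod(M0, dQ); GWk <- crossprod(M0, dK); GWv <- crossprod(M0, dV)
    g[[paste0("att", l, "_Wq")]] <- GWq
    g[[paste0("att", l, "_Wk")]] <- GWk
    g[[paste0("att", l, "_Wv")]] <- GWv
    g[[paste0("att", l, "_bq")]] <- colSums(dQ)
    g[[paste0("att", l, "_bk")]] <- colSums(dK)
    g[[paste0("att", l, "_bv")]] <- colSums(dV)
    if (!is.null(lora)) {
      sc <- lora$alpha / lora$rank
      g$lora[[l]] <- list()
      for (nm in lora$targets) {
        Gw <- switch(nm, Wq = GWq, Wk = GWk, Wv = GWv)
        ab <- lora$layers[[l]][[nm]]
        g$lora[[l]][[nm]] <- list(A = sc * Gw %*% t(ab$B),
                                  B = sc * crossprod(ab$A, Gw))
      }
    }
    # residual path contributes dS1; projections add their pullbacks
    dM <- dQ %*% t(eff_weight(model, l, "Wq")) +
          dK %*% t(eff_weight(model, l, "Wk")) +
          dV %*% t(eff_weight(model, l, "Wv")) + dS1
  }

  # positional embedding
  g$pos <- rowsum(dM, rep(seq_len(Tt), times = B))

  # convolution stack (reverse)
  for (l in rev(seq_along(cfg$conv_filters))) {
    cc <- ca$conv[[l]]
    dZ <- dM * cc$mask
    g[[paste0("conv", l, "_W")]] <- crossprod(cc$U, dZ)
    g[[paste0("conv", l, "_b")]] <- colSums(dZ)
    if (l > 1) {
      dU <- dZ %*% t(p[[paste0("conv", l, "_W")]])
      k <- cfg$conv_kernels[l]; s <- cfg$conv_strides[l]
      dM <- matrix(0, B * cc$T_in, cc$c_in)
      for (b in seq_len(B)) {
        rows_out <- ((b - 1) * cc$T_out + 1):(b * cc$T_out)
        rows_in <- ((b - 1) * cc$T_in + 1):(b * cc$T_in)
        dM[rows_in, ] <- fold1d_grad(dU[rows_out, , drop = FALSE],
                                     cc$T_in, k, s, cc$c_in)
      }
    }
  }
  g
}

# ---- Adam ----------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, trainable = names(params)) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in trainable) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
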