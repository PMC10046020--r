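# Minimal neural-network engine for the 9-mer window classifiers.
#
# Architectures are stacks of: symbol embedding -> optional 1-D convolution
# (kernel 3, ReLU) -> zero or more LSTM layers (hidden width 8) -> one or
# more additive self-attention layers -> global average pooling -> sigmoid.
#
# Sequence activations are kept "stacked": a (B*T) x d matrix whose rows
# are grouped by position (rows (t-1)*B+1 .. t*B hold position t for the
# whole mini-batch). Embedding, convolution and attention then reduce to a
# handful of large matrix products per layer; only the LSTM iterates over
# positions. Gradients are hand-derived and verified against numerical
# differentiation in the test suite. Training is Adam on binary
# cross-entropy.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# Sum the T position blocks of a stacked (B*T) x d matrix -> B x d.
block_sum <- function(M, B, Tn) {
  if (Tn == 1L) return(M)
  out <- M[seq_len(B), , drop = FALSE]
  for (t in 2:Tn) {
    out <- out + M[(t - 1L) * B + seq_len(B), , drop = FALSE]
  }
  out
}

# Architecture geometry implied by a model spec.
nn_arch <- function(spec, width = 9L, d_hidden = 8L, d_attn = 8L) {
  E <- spec$embedding_dim
  C <- spec$conv_units
  R <- spec$lstm_layers
  A <- spec$attention_layers
  kernel <- 3L
  T_seq <- if (C > 0) width - kernel + 1L else width
  d <- if (R > 0) d_hidden else if (C > 0) C else E
  list(E = E, C = C, R = R, A = A, kernel = kernel, width = width,
       T_seq = T_seq, d_hidden = d_hidden, d_attn = d_attn, d_out = d)
}

# Seeded parameter initialization. LSTM forget-gate biases start at 1.
nn_init_params <- function(arch, seed) {
  withr::local_seed(seed)
  p <- list()
  p$emb <- matrix(stats::runif(21L * arch$E, -0.1, 0.1), 21L, arch$E)
  d <- arch$E
  if (arch$C > 0) {
    p$conv_W <- glorot(arch$kernel * arch$E, arch$C)
    p$conv_b <- numeric(arch$C)
    d <- arch$C
  }
  h <- arch$d_hidden
  if (arch$R > 0) {
    for (r in seq_len(arch$R)) {
      d_in <- if (r == 1) d else h
      p[[paste0("lstm", r, "_Wx")]] <- glorot(d_in, 4L * h)
      p[[paste0("lstm", r, "_Wh")]] <- glorot(h, 4L * h)
      b <- numeric(4L * h)
      b[(h + 1L):(2L * h)] <- 1  # forget gate bias
      p[[paste0("lstm", r, "_b")]] <- b
    }
    d <- h
  }
  for (a in seq_len(arch$A)) {
    p[[paste0("attn", a, "_Wa")]] <- glorot(d, arch$d_attn)
    p[[paste0("attn", a, "_ba")]] <- numeric(arch$d_attn)
    p[[paste0("attn", a, "_va")]] <- stats::runif(arch$d_attn, -0.1, 0.1)
    p[[paste0("attn", a, "_Uh")]] <- glorot(d, d)
    p[[paste0("attn", a, "_Uc")]] <- glorot(d, d)
    p[[paste0("attn", a, "_bo")]] <- numeric(d)
  }
  p$head_w <- matrix(stats::runif(d, -0.1, 0.1), d, 1L)
  p$head_b <- 0
  p
}

# Forward pass. X: integer matrix B x width of vocabulary indices.
# Returns list(prob = B-vector, cache); cache is NULL unless keep_cache.
nn_forward <- function(params, arch, X, keep_cache = FALSE) {
  B <- nrow(X)
  W <- arch$width
  # stacked embedding: as.vector(X) is column-major, so rows are already
  # grouped by position
  Hs <- params$emb[as.vector(X), , drop = FALSE]
  cache <- if (keep_cache) list(X = X) else NULL

  if (arch$C > 0) {
    Tn <- arch$T_seq
    n <- B * Tn
    Xcol <- cbind(Hs[seq_len(n), , drop = FALSE],
                  Hs[B + seq_len(n), , drop = FALSE],
                  Hs[2L * B + seq_len(n), , drop = FALSE])
    pre <- Xcol %*% params$conv_W
    pre <- sweep(pre, 2L, params$conv_b, "+")
    Zs <- pre * (pre > 0)
    if (keep_cache) {
      cache$conv_Xcol <- Xcol
      cache$conv_Z <- Zs
    }
    Hs <- Zs
  }
  Tn <- arch$T_seq
  h_dim <- arch$d_hidden

  if (arch$R > 0) {
    for (r in seq_len(arch$R)) {
      Wx <- params[[paste0("lstm", r, "_Wx")]]
      Wh <- params[[paste0("lstm", r, "_Wh")]]
      b <- params[[paste0("lstm", r, "_b")]]
      h_prev <- matrix(0, B, h_dim)
      c_prev <- matrix(0, B, h_dim)
      Hout <- matrix(0, B * Tn, h_dim)
      st <- if (keep_cache) vector("list", Tn) else NULL
      idx_i <- 1L:h_dim
      idx_f <- (h_dim + 1L):(2L * h_dim)
      idx_o <- (2L * h_dim + 1L):(3L * h_dim)
      idx_g <- (3L * h_dim + 1L):(4L * h_dim)
      for (t in seq_len(Tn)) {
        rows <- (t - 1L) * B + seq_len(B)
        x_t <- Hs[rows, , drop = FALSE]
        z <- x_t %*% Wx + h_prev %*% Wh
        z <- sweep(z, 2L, b, "+")
        gi <- sigmoid(z[, idx_i, drop = FALSE])
        gf <- sigmoid(z[, idx_f, drop = FALSE])
        go <- sigmoid(z[, idx_o, drop = FALSE])
        gg <- tanh(z[, idx_g, drop = FALSE])
        c_t <- gf * c_prev + gi * gg
        tc <- tanh(c_t)
        h_t <- go * tc
        if (keep_cache) {
          st[[t]] <- list(x = x_t, h_prev = h_prev, c_prev = c_prev,
                          gi = gi, gf = gf, go = go, gg = gg, tc = tc)
        }
        h_prev <- h_t
        c_prev <- c_t
        Hout[rows, ] <- h_t
      }
      if (keep_cache) cache[[paste0("lstm", r)]] <- st
      Hs <- Hout
    }
  }

  if (arch$A > 0) {
    rep_idx <- rep(seq_len(B), Tn)
    for (a in seq_len(arch$A)) {
      Wa <- params[[paste0("attn", a, "_Wa")]]
      ba <- params[[paste0("attn", a, "_ba")]]
      va <- params[[paste0("attn", a, "_va")]]
      Uh <- params[[paste0("attn", a, "_Uh")]]
      Uc <- params[[paste0("attn", a, "_Uc")]]
      bo <- params[[paste0("attn", a, "_bo")]]
      U <- tanh(sweep(Hs %*% Wa, 2L, ba, "+"))        # (B*T) x da
      E_mat <- matrix(U %*% va, B, Tn)                # scores per position
      E_mat <- E_mat - apply(E_mat, 1L, max)
      alpha <- exp(E_mat)
      alpha <- alpha / rowSums(alpha)
      alpha_vec <- as.vector(alpha)
      ctx <- block_sum(alpha_vec * Hs, B, Tn)         # B x d
      ctxU <- sweep(ctx %*% Uc, 2L, bo, "+")
      Os <- tanh(Hs %*% Uh + ctxU[rep_idx, , drop = FALSE])
      if (keep_cache) {
        cache[[paste0("attn", a)]] <-
          list(H_in = Hs, U = U, alpha = alpha, ctx = ctx, O = Os)
      }
      Hs <- Os
    }
  }

  g <- block_sum(Hs, B, Tn) / Tn
  logit <- drop(g %*% params$head_w) + params$head_b
  prob <- sigmoid(logit)
  if (keep_cache) {
    cache$g <- g
    cache$prob <- prob
  }
  list(prob = prob, cache = cache)
}

# Mean binary cross-entropy with clamped probabilities.
bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Backward pass for mean BCE. Returns gradient list parallel to params.
nn_backward <- function(params, arch, cache, y) {
  B <- length(y)
  Tn <- arch$T_seq
  rep_idx <- rep(seq_len(B), Tn)
  g <- list()

  dlogit <- (cache$prob - y) / B                 # B-vector
  g$head_w <- crossprod(cache$g, dlogit)         # d x 1
  g$head_b <- sum(dlogit)
  dg <- tcrossprod(dlogit, params$head_w[, 1L])  # B x d
  dHs <- (dg / Tn)[rep_idx, , drop = FALSE]      # stacked GAP gradient

  if (arch$A > 0) {
    for (a in rev(seq_len(arch$A))) {
      nm <- paste0("attn", a)
      cc <- cache[[nm]]
      Wa <- params[[paste0(nm, "_Wa")]]
      va <- params[[paste0(nm, "_va")]]
      Uh <- params[[paste0(nm, "_Uh")]]
      Uc <- params[[paste0(nm, "_Uc")]]
      alpha_vec <- as.vector(cc$alpha)

      dPre <- dHs * (1 - cc$O^2)                 # (B*T) x d
      g[[paste0(nm, "_Uh")]] <- crossprod(cc$H_in, dPre)
      g[[paste0(nm, "_bo")]] <- colSums(dPre)
      dH_in <- tcrossprod(dPre, Uh)
      dPre_sum <- block_sum(dPre, B, Tn)         # B x d
      g[[paste0(nm, "_Uc")]] <- crossprod(cc$ctx, dPre_sum)
      dctx <- tcrossprod(dPre_sum, Uc)           # B x d
      dctx_rep <- dctx[rep_idx, , drop = FALSE]
      dH_in <- dH_in + alpha_vec * dctx_rep
      dalpha <- matrix(rowSums(dctx_rep * cc$H_in), B, Tn)
      dE <- cc$alpha * (dalpha - rowSums(dalpha * cc$alpha))
      dU <- tcrossprod(as.vector(dE), va)        # (B*T) x da
      g[[paste0(nm, "_va")]] <- colSums(cc$U * as.vector(dE))
      dPreU <- dU * (1 - cc$U^2)
      g[[paste0(nm, "_Wa")]] <- crossprod(cc$H_in, dPreU)
      g[[paste0(nm, "_ba")]] <- colSums(dPreU)
      dHs <- dH_in + tcrossprod(dPreU, Wa)
    }
  }

  if (arch$R > 0) {
    h_dim <- arch$d_hidden
    for (r in rev(seq_len(arch$R))) {
      st <- cache[[paste0("lstm", r)]]
      Wx <- params[[paste0("lstm", r, "_Wx")]]
      Wh <- params[[paste0("lstm", r, "_Wh")]]
      dWx <- matrix(0, nrow(Wx), ncol(Wx))
      dWh <- matrix(0, h_dim, 4L * h_dim)
      db <- numeric(4L * h_dim)
      dX <- matrix(0, B * Tn, nrow(Wx))
      dh_next <- matrix(0, B, h_dim)
      dc_next <- matrix(0, B, h_dim)
      for (t in rev(seq_len(Tn))) {
        rows <- (t - 1L) * B + seq_len(B)
        s <- st[[t]]
        dh <- dHs[rows, , drop = FALSE] + dh_next
        dgo <- dh * s$tc
        dc <- dc_next + dh * s$go * (1 - s$tc^2)
        dgi <- dc * s$gg
        dgg <- dc * s$gi
        dgf <- dc * s$c_prev
        dc_next <- dc * s$gf
        dz <- cbind(dgi * s$gi * (1 - s$gi),
                    dgf * s$gf * (1 - s$gf),
                    dgo * s$go * (1 - s$go),
                    dgg * (1 - s$gg^2))
        dWx <- dWx + crossprod(s$x, dz)
        dWh <- dWh + crossprod(s$h_prev, dz)
        db <- db + colSums(dz)
        dX[rows, ] <- tcrossprod(dz, Wx)
        dh_next <- tcrossprod(dz, Wh)
      }
      g[[paste0("lstm", r, "_Wx")]] <- dWx
      g[[paste0("lstm", r, "_Wh")]] <- dWh
      g[[paste0("lstm", r, "_b")]] <- db
      dHs <- dX
    }
  }

  W <- arch$width
  if (arch$C > 0) {
    E_dim <- arch$E
    n <- B * arch$T_seq
    dZ <- dHs * (cache$conv_Z > 0)
    g$conv_W <- crossprod(cache$conv_Xcol, dZ)
    g$conv_b <- colSums(dZ)
    dXcol <- tcrossprod(dZ, params$conv_W)
    dEs <- matrix(0, B * W, E_dim)
    for (k in 0L:(arch$kernel - 1L)) {
      rows <- k * B + seq_len(n)
      cols <- k * E_dim + seq_len(E_dim)
      dEs[rows, ] <- dEs[rows, , drop = FALSE] +
        dXcol[, cols, drop = FALSE]
    }
    dHs <- dEs
  }

  dEmb <- matrix(0, 21L, arch$E)
  agg <- rowsum(dHs, group = as.vector(cache$X))
  idx <- as.integer(rownames(agg))
  dEmb[idx, ] <- agg
  g$emb <- dEmb
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.005,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Scalar loss for gradient checking.
nn_loss_at <- function(params, arch, X, y) {
  bce_loss(nn_forward(params, arch, X)$prob, y)
}
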