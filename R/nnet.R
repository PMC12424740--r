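# Internal neural-network math for the denoiser: batched forward pass with
# cache, reverse-mode backward pass, and Adam on a flattened parameter
# vector. Everything is plain base-R matrix algebra; a batch of examples is
# processed as one stacked token stream with block-diagonal attention, which
# amortizes interpreter overhead. Gradients are pinned against finite
# differences in the tests.

# GeLU in its fast sigmoid form, x * sigmoid(1.702 x)
.gelu <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  x * s
}
.gelu_grad <- function(x) {
  s <- 1 / (1 + exp(-1.702 * x))
  s * (1 + 1.702 * x * (1 - s))
}

.ln_eps <- 1e-6

# rowwise layer norm without affine parameters
.ln_forward <- function(h) {
  mu <- rowMeans(h)
  hc <- h - mu
  v <- rowMeans(hc^2)
  inv <- 1 / sqrt(v + .ln_eps)
  list(xhat = hc * inv, inv = inv)
}

.ln_backward <- function(dxhat, cache) {
  xhat <- cache$xhat
  cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
}

# rowwise RMS norm with learned scale g (used for QK-norm, per head)
.rms_forward <- function(q, g) {
  r <- sqrt(rowMeans(q^2) + .ln_eps)
  list(qn = (q / r) * rep(g, each = nrow(q)), r = r)
}

.rms_backward <- function(dqn, q, g, r) {
  n <- ncol(q)
  gq <- dqn * rep(g, each = nrow(q))
  dg <- colSums(dqn * q / r)
  dq <- gq / r - q * (rowSums(gq * q) / (n * r^3))
  list(dq = dq, dg = dg)
}

# sinusoidal features of scalar warped times in [0, 1]; returns a
# length(tp) x channels matrix
.time_features <- function(tp, channels) {
  half <- channels %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1L) / half)
  ang <- outer(1000 * tp, freqs)
  cbind(cos(ang), sin(ang))
}

# ---------------------------------------------------------------------------
# parameter shapes, initialization, counting

.denoiser_shapes <- function(cfg) {
  d <- cfg$hidden_dim
  f <- cfg$ffn_ratio * d
  tc <- cfg$time_channels
  sh <- list(
    tok_emb = c(cfg$vocab_size, d),
    pos_emb = c(cfg$max_length, d),
    struct_w = c(3L, d), struct_b = d,
    motif_w = c(3L, d), motif_b = d,
    motif_mark = d, motif_mark_cond = d,
    time_w1 = c(tc, d), time_b1 = d,
    time_w2 = c(d, d), time_b2 = d
  )
  if (cfg$n_function_terms > 0L) {
    sh$term_emb <- c(cfg$n_function_terms, d)
    sh$term_null <- d
  }
  for (b in seq_len(cfg$n_blocks)) {
    p <- sprintf("b%02d_", b)
    sh[[paste0(p, "qkv_w")]] <- c(d, 3L * d)
    sh[[paste0(p, "qkv_b")]] <- 3L * d
    sh[[paste0(p, "proj_w")]] <- c(d, d)
    sh[[paste0(p, "proj_b")]] <- d
    sh[[paste0(p, "qn")]] <- d
    sh[[paste0(p, "kn")]] <- d
    sh[[paste0(p, "ffn_w1")]] <- c(d, f)
    sh[[paste0(p, "ffn_b1")]] <- f
    sh[[paste0(p, "ffn_w2")]] <- c(f, d)
    sh[[paste0(p, "ffn_b2")]] <- d
    sh[[paste0(p, "ada_w")]] <- c(d, 6L * d)
    sh[[paste0(p, "ada_b")]] <- 6L * d
  }
  sh$final_ada_w <- c(d, 2L * d)
  sh$final_ada_b <- 2L * d
  sh$head_seq_w <- c(d, cfg$vocab_size)
  sh$head_seq_b <- cfg$vocab_size
  sh$head_struct_w <- c(d, 3L)
  sh$head_struct_b <- 3L
  sh
}

.init_params <- function(cfg, seed = NULL) {
  .maybe_seed(seed)
  sh <- .denoiser_shapes(cfg)
  params <- vector("list", length(sh))
  names(params) <- names(sh)
  for (nm in names(sh)) {
    dm <- sh[[nm]]
    params[[nm]] <-
      if (grepl("ada", nm) || grepl("head_", nm)) {
        # adaLN-Zero: modulation and output heads start at exactly zero
        if (length(dm) == 2L) matrix(0, dm[1L], dm[2L]) else numeric(dm)
      } else if (nm %in% c("tok_emb", "pos_emb", "term_emb")) {
        matrix(0.02 * stats::rnorm(prod(dm)), dm[1L], dm[2L])
      } else if (grepl("(^|_)(qn|kn)$", nm)) {
        rep(1, dm)
      } else if (length(dm) == 2L) {
        matrix(stats::rnorm(prod(dm)) * sqrt(1 / dm[1L]), dm[1L], dm[2L])
      } else {
        numeric(dm)
      }
  }
  params
}

# ---------------------------------------------------------------------------
# input stacking: a batch is a list of inputs, each
#   list(tokens, X [L x 3, centered+scaled], tp [warped struct time],
#        motif = NULL | list(positions, coords [centered+scaled], tokens),
#        term = NULL | int)

.stack_inputs <- function(inputs, cfg) {
  lens <- vapply(inputs, function(i) length(i$tokens), integer(1))
  if (any(lens > cfg$max_length)) stop("sequence longer than max_length")
  B <- length(inputs)
  N <- sum(lens)
  offsets <- cumsum(c(0L, lens[-B]))
  list(B = B, N = N, lens = lens, offsets = offsets,
       tokens = unlist(lapply(inputs, `[[`, "tokens"), use.names = FALSE),
       pos = unlist(lapply(lens, seq_len), use.names = FALSE),
       ex = rep(seq_len(B), lens),
       X = do.call(rbind, lapply(inputs, `[[`, "X")),
       tp = vapply(inputs, `[[`, numeric(1), "tp"),
       terms = lapply(inputs, `[[`, "term"),
       motifs = lapply(inputs, `[[`, "motif"))
}

# ---------------------------------------------------------------------------
# batched forward pass with optional cache for backprop

.denoiser_forward_batch <- function(params, cfg, inputs, train = FALSE,
                                    want_cache = FALSE) {
  d <- cfg$hidden_dim
  nh <- cfg$n_heads
  dh <- d %/% nh
  st <- .stack_inputs(inputs, cfg)
  N <- st$N; B <- st$B; ex <- st$ex
  drop_p <- if (train) cfg$dropout else 0

  # conditioning vectors, one per example
  E <- .time_features(st$tp, cfg$time_channels)
  H1 <- E %*% params$time_w1 + rep(params$time_b1, each = B)
  A1 <- .gelu(H1)
  CvecB <- A1 %*% params$time_w2 + rep(params$time_b2, each = B)
  for (b in seq_len(B)) {
    term <- st$terms[[b]]
    if (cfg$n_function_terms > 0L) {
      if (!is.null(term)) {
        if (term < 1L || term > cfg$n_function_terms) stop("term id out of range")
        CvecB[b, ] <- CvecB[b, ] + params$term_emb[term, ]
      } else {
        CvecB[b, ] <- CvecB[b, ] + params$term_null
      }
    } else if (!is.null(term)) {
      stop("model built without function conditioning")
    }
  }
  Mbases <- vector("list", B)
  for (b in seq_len(B)) {
    motif <- st$motifs[[b]]
    if (!is.null(motif) && length(motif$positions) > 0L) {
      nm <- length(motif$positions)
      Mbases[[b]] <- motif$coords %*% params$motif_w +
        rep(params$motif_b, each = nm) +
        params$tok_emb[motif$tokens, , drop = FALSE]
      CvecB[b, ] <- CvecB[b, ] + params$motif_mark_cond + colMeans(Mbases[[b]])
    }
  }
  caB <- .gelu(CvecB)

  # stacked input stream
  H <- params$tok_emb[st$tokens, , drop = FALSE] +
    params$pos_emb[st$pos, , drop = FALSE] +
    st$X %*% params$struct_w + rep(params$struct_b, each = N)
  for (b in seq_len(B)) {
    if (!is.null(Mbases[[b]])) {
      rows <- st$offsets[b] + st$motifs[[b]]$positions
      nm <- length(rows)
      H[rows, ] <- H[rows, , drop = FALSE] + Mbases[[b]] +
        rep(params$motif_mark, each = nm)
    }
  }

  exrows <- lapply(seq_len(B), function(b) {
    (st$offsets[b] + 1L):(st$offsets[b] + st$lens[b])
  })
  blocks <- if (want_cache) vector("list", cfg$n_blocks) else NULL
  for (b in seq_len(cfg$n_blocks)) {
    p <- sprintf("b%02d_", b)
    ModB <- caB %*% params[[paste0(p, "ada_w")]] +
      rep(params[[paste0(p, "ada_b")]], each = B)
    sc1R <- ModB[ex, (d + 1L):(2L * d), drop = FALSE]
    g1R <- ModB[ex, (2L * d + 1L):(3L * d), drop = FALSE]
    sc2R <- ModB[ex, (4L * d + 1L):(5L * d), drop = FALSE]
    g2R <- ModB[ex, (5L * d + 1L):(6L * d), drop = FALSE]

    ln1 <- .ln_forward(H)
    u1 <- ln1$xhat * (1 + sc1R) + ModB[ex, 1L:d, drop = FALSE]
    qkv <- u1 %*% params[[paste0(p, "qkv_w")]] +
      rep(params[[paste0(p, "qkv_b")]], each = N)
    Q <- qkv[, 1L:d, drop = FALSE]
    K <- qkv[, (d + 1L):(2L * d), drop = FALSE]
    V <- qkv[, (2L * d + 1L):(3L * d), drop = FALSE]
    heads <- if (want_cache) vector("list", nh) else NULL
    O <- matrix(0, N, d)
    for (hh in seq_len(nh)) {
      idx <- ((hh - 1L) * dh + 1L):(hh * dh)
      qr_ <- .rms_forward(Q[, idx, drop = FALSE], params[[paste0(p, "qn")]][idx])
      kr_ <- .rms_forward(K[, idx, drop = FALSE], params[[paste0(p, "kn")]][idx])
      Ps <- vector("list", B)
      for (bb in seq_len(B)) {
        rows <- exrows[[bb]]
        S <- tcrossprod(qr_$qn[rows, , drop = FALSE],
                        kr_$qn[rows, , drop = FALSE]) / sqrt(dh)
        P <- .softmax_rows(S)
        O[rows, idx] <- P %*% V[rows, idx, drop = FALSE]
        Ps[[bb]] <- P
      }
      if (want_cache) heads[[hh]] <- list(qr = qr_, kr = kr_, P = Ps)
    }
    A <- O %*% params[[paste0(p, "proj_w")]] +
      rep(params[[paste0(p, "proj_b")]], each = N)
    mask1 <- NULL
    if (drop_p > 0) {
      mask1 <- matrix(stats::rbinom(N * d, 1L, 1 - drop_p) / (1 - drop_p), N, d)
      A <- A * mask1
    }
    H <- H + A * g1R

    ln2 <- .ln_forward(H)
    u2 <- ln2$xhat * (1 + sc2R) + ModB[ex, (3L * d + 1L):(4L * d), drop = FALSE]
    F1 <- u2 %*% params[[paste0(p, "ffn_w1")]] +
      rep(params[[paste0(p, "ffn_b1")]], each = N)
    G <- .gelu(F1)
    F2 <- G %*% params[[paste0(p, "ffn_w2")]] +
      rep(params[[paste0(p, "ffn_b2")]], each = N)
    mask2 <- NULL
    if (drop_p > 0) {
      mask2 <- matrix(stats::rbinom(N * d, 1L, 1 - drop_p) / (1 - drop_p), N, d)
      F2 <- F2 * mask2
    }
    H <- H + F2 * g2R

    if (want_cache) {
      blocks[[b]] <- list(ln1 = ln1, u1 = u1, Q = Q, K = K, V = V,
                          heads = heads, O = O, A = A, mask1 = mask1,
                          ln2 = ln2, u2 = u2, F1 = F1, G = G, F2 = F2,
                          mask2 = mask2, ModB = ModB)
    }
  }

  lnf <- .ln_forward(H)
  ModF <- caB %*% params$final_ada_w + rep(params$final_ada_b, each = B)
  uf <- lnf$xhat * (1 + ModF[ex, (d + 1L):(2L * d), drop = FALSE]) +
    ModF[ex, 1L:d, drop = FALSE]
  logits <- uf %*% params$head_seq_w + rep(params$head_seq_b, each = N)
  struct_pred <- uf %*% params$head_struct_w + rep(params$head_struct_b, each = N)

  out <- list(logits = logits, structure_pred = struct_pred, rows = exrows)
  if (want_cache) {
    out$cache <- list(st = st, exrows = exrows, E = E, H1 = H1, A1 = A1,
                      CvecB = CvecB, caB = caB, Mbases = Mbases,
                      blocks = blocks, lnf = lnf, ModF = ModF, uf = uf)
  }
  out
}

# single-example convenience wrappers (the public denoise() path)
.denoiser_forward <- function(params, cfg, input, train = FALSE,
                              want_cache = FALSE) {
  out <- .denoiser_forward_batch(params, cfg, list(input), train, want_cache)
  list(logits = out$logits, structure_pred = out$structure_pred,
       cache = out$cache)
}

.denoiser_backward <- function(params, cfg, cache, d_logits, d_struct,
                               shapes = NULL) {
  .denoiser_backward_batch(params, cfg, cache, d_logits, d_struct, shapes)
}

# ---------------------------------------------------------------------------
# batched backward pass: d_logits / d_struct are stacked (N x 21, N x 3)

.denoiser_backward_batch <- function(params, cfg, cache, d_logits, d_struct,
                                     shapes = NULL) {
  d <- cfg$hidden_dim
  nh <- cfg$n_heads
  dh <- d %/% nh
  st <- cache$st
  N <- st$N; B <- st$B; ex <- st$ex

  g <- list()
  acc <- function(nm, val) {
    g[[nm]] <<- if (is.null(g[[nm]])) val else g[[nm]] + val
  }
  # per-example reduction of an N x d matrix to B x d
  exsum <- function(m) {
    if (B == 1L) matrix(colSums(m), 1L) else rowsum(m, ex, reorder = TRUE)
  }

  uf <- cache$uf
  acc("head_seq_w", crossprod(uf, d_logits))
  acc("head_seq_b", colSums(d_logits))
  acc("head_struct_w", crossprod(uf, d_struct))
  acc("head_struct_b", colSums(d_struct))
  d_uf <- tcrossprod(d_logits, params$head_seq_w) +
    tcrossprod(d_struct, params$head_struct_w)

  scfR <- cache$ModF[ex, (d + 1L):(2L * d), drop = FALSE]
  xhat_f <- cache$lnf$xhat
  d_lnf <- d_uf * (1 + scfR)
  d_ModF <- cbind(exsum(d_uf), exsum(d_uf * xhat_f))
  acc("final_ada_w", crossprod(cache$caB, d_ModF))
  acc("final_ada_b", colSums(d_ModF))
  d_caB <- tcrossprod(d_ModF, params$final_ada_w)
  dH <- .ln_backward(d_lnf, cache$lnf)

  for (b in rev(seq_len(cfg$n_blocks))) {
    p <- sprintf("b%02d_", b)
    bc <- cache$blocks[[b]]
    ModB <- bc$ModB
    sc1R <- ModB[ex, (d + 1L):(2L * d), drop = FALSE]
    g1R <- ModB[ex, (2L * d + 1L):(3L * d), drop = FALSE]
    sc2R <- ModB[ex, (4L * d + 1L):(5L * d), drop = FALSE]
    g2R <- ModB[ex, (5L * d + 1L):(6L * d), drop = FALSE]

    # FFN residual: H = H_mid + F2 * g2
    d_G2B <- exsum(dH * bc$F2)
    d_F2 <- dH * g2R
    if (!is.null(bc$mask2)) d_F2 <- d_F2 * bc$mask2
    acc(paste0(p, "ffn_w2"), crossprod(bc$G, d_F2))
    acc(paste0(p, "ffn_b2"), colSums(d_F2))
    d_G <- tcrossprod(d_F2, params[[paste0(p, "ffn_w2")]])
    d_F1 <- d_G * .gelu_grad(bc$F1)
    acc(paste0(p, "ffn_w1"), crossprod(bc$u2, d_F1))
    acc(paste0(p, "ffn_b1"), colSums(d_F1))
    d_u2 <- tcrossprod(d_F1, params[[paste0(p, "ffn_w1")]])
    d_ln2 <- d_u2 * (1 + sc2R)
    d_SH2B <- exsum(d_u2)
    d_SC2B <- exsum(d_u2 * bc$ln2$xhat)
    dH <- dH + .ln_backward(d_ln2, bc$ln2)

    # attention residual: H_mid = H_in + A * g1   (A post-dropout)
    d_G1B <- exsum(dH * bc$A)
    d_A <- dH * g1R
    if (!is.null(bc$mask1)) d_A <- d_A * bc$mask1
    acc(paste0(p, "proj_w"), crossprod(bc$O, d_A))
    acc(paste0(p, "proj_b"), colSums(d_A))
    d_O <- tcrossprod(d_A, params[[paste0(p, "proj_w")]])
    d_Q <- matrix(0, N, d); d_K <- matrix(0, N, d); d_V <- matrix(0, N, d)
    d_qn_scale <- numeric(d); d_kn_scale <- numeric(d)
    for (hh in seq_len(nh)) {
      idx <- ((hh - 1L) * dh + 1L):(hh * dh)
      hd <- bc$heads[[hh]]
      d_Qn <- matrix(0, N, dh); d_Kn <- matrix(0, N, dh)
      for (bb in seq_len(B)) {
        rows <- cache$exrows[[bb]]
        dOh <- d_O[rows, idx, drop = FALSE]
        P <- hd$P[[bb]]
        Vh <- bc$V[rows, idx, drop = FALSE]
        d_P <- tcrossprod(dOh, Vh)
        d_V[rows, idx] <- crossprod(P, dOh)
        d_S <- P * (d_P - rowSums(d_P * P))
        d_Qn[rows, ] <- d_S %*% hd$kr$qn[rows, , drop = FALSE] / sqrt(dh)
        d_Kn[rows, ] <- crossprod(d_S, hd$qr$qn[rows, , drop = FALSE]) / sqrt(dh)
      }
      rq <- .rms_backward(d_Qn, bc$Q[, idx, drop = FALSE],
                          params[[paste0(p, "qn")]][idx], hd$qr$r)
      rk <- .rms_backward(d_Kn, bc$K[, idx, drop = FALSE],
                          params[[paste0(p, "kn")]][idx], hd$kr$r)
      d_Q[, idx] <- rq$dq
      d_K[, idx] <- rk$dq
      d_qn_scale[idx] <- rq$dg
      d_kn_scale[idx] <- rk$dg
    }
    acc(paste0(p, "qn"), d_qn_scale)
    acc(paste0(p, "kn"), d_kn_scale)
    d_qkv <- cbind(d_Q, d_K, d_V)
    acc(paste0(p, "qkv_w"), crossprod(bc$u1, d_qkv))
    acc(paste0(p, "qkv_b"), colSums(d_qkv))
    d_u1 <- tcrossprod(d_qkv, params[[paste0(p, "qkv_w")]])
    d_ln1 <- d_u1 * (1 + sc1R)
    d_SH1B <- exsum(d_u1)
    d_SC1B <- exsum(d_u1 * bc$ln1$xhat)
    dH <- dH + .ln_backward(d_ln1, bc$ln1)

    d_ModB <- cbind(d_SH1B, d_SC1B, d_G1B, d_SH2B, d_SC2B, d_G2B)
    acc(paste0(p, "ada_w"), crossprod(cache$caB, d_ModB))
    acc(paste0(p, "ada_b"), colSums(d_ModB))
    d_caB <- d_caB + tcrossprod(d_ModB, params[[paste0(p, "ada_w")]])
  }

  # input embeddings (grouped accumulation over the stacked rows)
  tok_g <- matrix(0, cfg$vocab_size, d)
  tg <- rowsum(dH, st$tokens, reorder = TRUE)
  tok_g[as.integer(rownames(tg)), ] <- tg
  pos_g <- matrix(0, cfg$max_length, d)
  pg <- rowsum(dH, st$pos, reorder = TRUE)
  pos_g[as.integer(rownames(pg)), ] <- pg
  acc("pos_emb", pos_g)
  acc("struct_w", crossprod(st$X, dH))
  acc("struct_b", colSums(dH))

  # conditioning vectors
  d_CvecB <- d_caB * .gelu_grad(cache$CvecB)
  for (b in seq_len(B)) {
    if (!is.null(cache$Mbases[[b]])) {
      motif <- st$motifs[[b]]
      nm <- length(motif$positions)
      rows <- st$offsets[b] + motif$positions
      d_M_input <- dH[rows, , drop = FALSE]
      acc("motif_mark", colSums(d_M_input))
      acc("motif_mark_cond", d_CvecB[b, ])
      d_Mbase <- d_M_input +
        matrix(rep(d_CvecB[b, ] / nm, each = nm), nm, d)
      acc("motif_w", crossprod(motif$coords, d_Mbase))
      acc("motif_b", colSums(d_Mbase))
      for (i in seq_len(nm)) {
        tok_g[motif$tokens[i], ] <- tok_g[motif$tokens[i], ] + d_Mbase[i, ]
      }
    }
  }
  acc("tok_emb", tok_g)

  if (cfg$n_function_terms > 0L) {
    te <- matrix(0, cfg$n_function_terms, d)
    tn <- numeric(d)
    for (b in seq_len(B)) {
      term <- st$terms[[b]]
      if (!is.null(term)) te[term, ] <- te[term, ] + d_CvecB[b, ]
      else tn <- tn + d_CvecB[b, ]
    }
    acc("term_emb", te)
    acc("term_null", tn)
  }

  acc("time_w2", crossprod(cache$A1, d_CvecB))
  acc("time_b2", colSums(d_CvecB))
  d_A1 <- tcrossprod(d_CvecB, params$time_w2)
  d_H1 <- d_A1 * .gelu_grad(cache$H1)
  acc("time_w1", crossprod(cache$E, d_H1))
  acc("time_b1", colSums(d_H1))

  # fill gradients absent from this batch with zeros
  sh <- if (is.null(shapes)) .denoiser_shapes(cfg) else shapes
  for (nm in names(sh)) {
    if (is.null(g[[nm]])) {
      dm <- sh[[nm]]
      g[[nm]] <- if (length(dm) == 2L) matrix(0, dm[1L], dm[2L]) else numeric(dm)
    }
  }
  g[names(sh)]
}

# ---------------------------------------------------------------------------
# flat-vector parameter arithmetic

.flatten_params <- function(params) unlist(params, use.names = FALSE)

.unflatten_params <- function(theta, shapes) {
  out <- vector("list", length(shapes))
  names(out) <- names(shapes)
  off <- 0L
  for (nm in names(shapes)) {
    dm <- shapes[[nm]]
    n <- as.integer(prod(dm))
    v <- theta[(off + 1L):(off + n)]
    out[[nm]] <- if (length(dm) == 2L) matrix(v, dm[1L], dm[2L]) else v
    off <- off + n
  }
  out
}

.adam_init <- function(n) {
  list(m = numeric(n), v = numeric(n), step = 0L)
}

.adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$step <- state$step + 1L
  t <- state$step
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}
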