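#' Linear survival schedule for masked diffusion
#'
#' Survival probability alpha_t = 1 - t: the chance a position is still
#' unmasked at time t. Satisfies alpha_0 = 1, alpha_1 = 0, strictly
#' decreasing; the linear choice is consistent with the sequence loss
#' weight lambda(t) = 1 - t.
#'
#' @param t time(s) in [0, 1].
#' @return survival probability (same length as `t`).
#' @export
alpha_linear <- function(t) {
  if (any(t < -1e-12 | t > 1 + 1e-12)) stop("t outside [0, 1]")
  1 - pmin(pmax(t, 0), 1)
}

#' Sequence diffusion state
#'
#' @param tokens integer vector over 1..21 (21 = mask).
#' @param time discrete-diffusion time in [0, 1].
#' @return an object of class `sequence_state`.
#' @export
sequence_state <- function(tokens, time = 0) {
  tokens <- as.integer(tokens)
  stopifnot(all(tokens >= 1L, tokens <= 21L), time >= 0, time <= 1)
  structure(list(tokens = tokens, time = time), class = "sequence_state")
}

#' @export
print.sequence_state <- function(x, ...) {
  cat(sprintf("sequence_state (t = %.3f): %s\n", x$time, tokens_to_string(x$tokens)))
  invisible(x)
}

.tokens_of <- function(s) {
  if (inherits(s, "sequence_state")) s$tokens else as.integer(s)
}

#' Forward masking corruption
#'
#' Each position is independently kept with probability alpha_t and
#' otherwise replaced by the mask symbol.
#'
#' @param s0 clean sequence (`sequence_state` or integer vector, no masks).
#' @param t corruption time in [0, 1].
#' @param seed optional seed.
#' @return a `sequence_state` at time `t`.
#' @export
mask_forward <- function(s0, t, seed = NULL) {
  tok <- .tokens_of(s0)
  if (any(tok == mask_token())) stop("input sequence must be mask-free")
  .maybe_seed(seed)
  keep <- stats::runif(length(tok)) < alpha_linear(t)
  tok[!keep] <- mask_token()
  sequence_state(tok, time = t)
}

#' Exact reverse posterior of masked diffusion
#'
#' For a single position, the distribution of x_s given x_t (s < t):
#' an unmasked token is carried as a point mass; a masked token stays
#' masked with probability (1 - alpha_s) / (1 - alpha_t) and is otherwise
#' filled from the predicted clean-token distribution with total
#' probability (alpha_s - alpha_t) / (1 - alpha_t).
#'
#' @param xt_token current token (1..21).
#' @param x0_hat length-21 simplex row: predicted clean-token distribution
#'   (zero mass on the mask symbol).
#' @param alpha_s,alpha_t survival probabilities at s and t, `alpha_s >
#'   alpha_t`.
#' @return a length-21 probability vector.
#' @export
reverse_posterior <- function(xt_token, x0_hat, alpha_s, alpha_t) {
  if (alpha_s <= alpha_t) stop("requires alpha_s > alpha_t (s < t)")
  stopifnot(length(x0_hat) == 21L, abs(sum(x0_hat) - 1) < 1e-6)
  p <- numeric(21L)
  if (xt_token != mask_token()) {
    p[xt_token] <- 1
    return(p)
  }
  w_fill <- (alpha_s - alpha_t) / (1 - alpha_t)
  p <- w_fill * x0_hat
  p[mask_token()] <- p[mask_token()] + (1 - alpha_s) / (1 - alpha_t)
  p
}

#' Masked cross-entropy sequence loss
#'
#' (1 - t) times the mean, over masked positions only, of the negative
#' log-probability of the true token under the softmax of the logits
#' restricted to the 20 amino acids (the mask column carries no
#' probability mass for clean data). Unmasked positions contribute
#' nothing.
#'
#' @param logits L x 21 matrix of per-position token scores.
#' @param s0 clean sequence (integer vector or `sequence_state`).
#' @param st corrupted sequence at time `t`.
#' @param t time in [0, 1].
#' @return nonnegative scalar.
#' @export
seq_loss <- function(logits, s0, st, t) {
  s0 <- .tokens_of(s0); st <- .tokens_of(st)
  stopifnot(nrow(logits) == length(s0), length(s0) == length(st),
            t >= 0, t <= 1)
  masked <- which(st == mask_token())
  if (length(masked) == 0L) return(0)
  lp <- .log_softmax_rows(logits[masked, 1:20, drop = FALSE])
  (1 - t) * mean(-lp[cbind(seq_along(masked), s0[masked])])
}

# gradient of seq_loss with respect to the logits (zero on the mask column
# and on unmasked rows); used by the trainer.
.seq_loss_grad <- function(logits, s0, st, t) {
  s0 <- .tokens_of(s0); st <- .tokens_of(st)
  g <- matrix(0, nrow(logits), ncol(logits))
  masked <- which(st == mask_token())
  if (length(masked) == 0L) return(g)
  p <- .softmax_rows(logits[masked, 1:20, drop = FALSE])
  p[cbind(seq_along(masked), s0[masked])] <-
    p[cbind(seq_along(masked), s0[masked])] - 1
  g[masked, 1:20] <- (1 - t) * p / length(masked)
  g
}

#' One Gumbel top-k path-planning step
#'
#' Draws per-position noisy log-confidences
#' phi = logsoftmax(logits / gamma + z), z standard Gumbel, takes the
#' per-position argmax token y and its confidence u, keeps the
#' k = L_free - round(s * L_free) highest-confidence free positions
#' (half-away-from-zero rounding; ties by lowest position index), fills
#' newly unmasked positions with y, carries already-unmasked positions
#' inside the keep-set, and re-masks positions outside it. In
#' co-generation mode, positions already unmasked use their current token
#' and its model log-probability as (y, u). Clamped positions (motif
#' residues) are never masked, never resampled, and excluded from the
#' keep-set accounting.
#'
#' @param logits L x 21 matrix of model logits.
#' @param st current sequence (`sequence_state` or integer vector).
#' @param s,t target and current times, 0 <= s < t <= 1.
#' @param gamma temperature (> 0).
#' @param mode `"unconditional"` or `"cogeneration"`.
#' @param clamp optional integer vector of fixed (always unmasked)
#'   positions.
#' @param seed optional seed.
#' @param noise optional pre-drawn L x 20 Gumbel matrix (zeros give the
#'   deterministic zero-temperature-style limit used in tests).
#' @return a `sequence_state` at time `s`.
#' @export
path_planning_step <- function(logits, st, s, t, gamma = 0.5,
                               mode = c("unconditional", "cogeneration"),
                               clamp = NULL, seed = NULL, noise = NULL) {
  mode <- match.arg(mode)
  tok <- .tokens_of(st)
  L <- length(tok)
  stopifnot(nrow(logits) == L, ncol(logits) == 21L, gamma > 0)
  if (s >= t) stop("requires s < t")
  if (!is.null(clamp)) {
    clamp <- as.integer(clamp)
    stopifnot(all(clamp >= 1L), all(clamp <= L))
    if (any(tok[clamp] == mask_token())) stop("clamped positions must be unmasked")
  }
  .maybe_seed(seed)
  if (is.null(noise)) {
    u01 <- matrix(stats::runif(L * 20L), L, 20L)
    noise <- -log(-log(u01))
  }
  phi <- .log_softmax_rows(logits[, 1:20, drop = FALSE] / gamma + noise)
  y <- apply(phi, 1L, which.max)           # ties -> lowest token index
  u <- phi[cbind(seq_len(L), y)]
  if (mode == "cogeneration") {
    um <- which(tok != mask_token())
    if (length(um)) {
      y[um] <- tok[um]
      u[um] <- phi[cbind(um, tok[um])]
    }
  }
  free <- setdiff(seq_len(L), clamp)
  Lf <- length(free)
  k <- Lf - as.integer(round_half_up(s * Lf))
  keep <- if (k > 0L) free[order(-u[free], free)][seq_len(k)] else integer(0)
  new_tok <- rep(mask_token(), L)
  if (!is.null(clamp)) new_tok[clamp] <- tok[clamp]
  newly <- keep[tok[keep] == mask_token()]
  carried <- keep[tok[keep] != mask_token()]
  new_tok[newly] <- y[newly]
  new_tok[carried] <- tok[carried]
  out <- sequence_state(new_tok, time = s)
  attr(out, "keep_set") <- sort(keep)
  out
}

#' Sample a sequence by iterative unmasking
#'
#' Rollout from the all-mask state on a time grid uniform in t. The model
#' is a function `(tokens, t) -> L x 21 logits`; with `n_samples > 1` it
#' receives an `n_samples x L` token matrix and must return an
#' `n_samples x L x 21` array (batched oracle models). Modes:
#' `"path_planning"` (Gumbel top-k self-planning), `"cogeneration"`
#' (current tokens keep their model log-probability), `"ancestral"`
#' (exact per-position reverse posterior).
#'
#' @param model logits function (see Details).
#' @param L sequence length.
#' @param n_steps number of steps (default `L`).
#' @param gamma_fn temperature as a function of t (default constant 0.5;
#'   co-generation uses 0.1 + 0.4 t).
#' @param mode sampling mode.
#' @param clamp optional list with integer `positions` and `tokens`: fixed
#'   residues that are never masked and never resampled.
#' @param seed optional seed.
#' @param n_samples number of independent rollouts.
#' @return a `sequence_state` (or an `n_samples x L` integer matrix).
#' @export
sample_sequence <- function(model, L, n_steps = L,
                            gamma_fn = function(t) 0.5,
                            mode = c("path_planning", "cogeneration", "ancestral"),
                            clamp = NULL, seed = NULL, n_samples = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_steps >= 1)
  clamp_pos <- NULL
  if (!is.null(clamp)) {
    clamp_pos <- as.integer(clamp$positions)
    if (any(clamp_pos < 1L | clamp_pos > L)) stop("clamp indices out of range")
    stopifnot(length(clamp_pos) == length(clamp$tokens))
  }
  .maybe_seed(seed)
  states <- matrix(mask_token(), n_samples, L)
  if (!is.null(clamp_pos)) {
    states[, clamp_pos] <- matrix(rep(as.integer(clamp$tokens), each = n_samples),
                                  n_samples, length(clamp_pos))
  }
  tgrid <- seq(1, 0, length.out = n_steps + 1L)
  for (i in seq_len(n_steps)) {
    t <- tgrid[i]; s <- tgrid[i + 1L]
    lg <- if (n_samples == 1L) model(states[1L, ], t) else model(states, t)
    if (mode == "ancestral") {
      states <- .ancestral_update(states, lg, s, t, clamp_pos, n_samples)
    } else {
      pmode <- if (mode == "cogeneration") "cogeneration" else "unconditional"
      for (b in seq_len(n_samples)) {
        lgb <- if (n_samples == 1L) lg else matrix(lg[b, , ], L, 21L)
        st <- path_planning_step(lgb, states[b, ], s, t,
                                 gamma = gamma_fn(t), mode = pmode,
                                 clamp = clamp_pos)
        states[b, ] <- st$tokens
      }
    }
  }
  if (n_samples == 1L) sequence_state(states[1L, ], time = 0) else states
}

# vectorized exact-posterior ancestral update across a batch of states
.ancestral_update <- function(states, lg, s, t, clamp_pos, n_samples) {
  a_s <- alpha_linear(s); a_t <- alpha_linear(t)
  L <- ncol(states)
  if (n_samples == 1L) lg <- array(lg, c(1L, L, 21L))
  masked_idx <- which(states == mask_token(), arr.ind = TRUE)
  if (nrow(masked_idx) == 0L) return(states)
  w_fill <- (a_s - a_t) / (1 - a_t)
  unmask <- stats::runif(nrow(masked_idx)) < w_fill
  sel <- masked_idx[unmask, , drop = FALSE]
  if (nrow(sel) > 0L) {
    for (r in seq_len(nrow(sel))) {
      b <- sel[r, 1L]; l <- sel[r, 2L]
      lgr <- lg[b, l, 1:20]
      p <- exp(lgr - max(lgr)); p <- p / sum(p)
      states[b, l] <- sample.int(20L, 1L, prob = p)
    }
  }
  states
}

#' Inverse folding: sequence sampling at fixed structure
#'
#' Unmasks one position per step in a uniformly random order, sampling
#' each position from the model softmax at low temperature (default 0.1)
#' conditioned on the fixed structure. The model is a function
#' `(tokens, t) -> L x 21 logits` already conditioned on the structure;
#' `temperature = 0` takes the argmax.
#'
#' @param model conditioned logits function.
#' @param L sequence length (number of residues of the fixed structure).
#' @param temperature softmax temperature (>= 0).
#' @param seed optional seed.
#' @return a `sequence_state` with no masks.
#' @export
inverse_fold_sample <- function(model, L, temperature = 0.1, seed = NULL) {
  .maybe_seed(seed)
  ord <- sample.int(L)
  tok <- rep(mask_token(), L)
  for (j in seq_len(L)) {
    pos <- ord[j]
    t <- 1 - (j - 1) / L
    lg <- model(tok, t)
    lr <- lg[pos, 1:20]
    if (temperature <= 0) {
      tok[pos] <- which.max(lr)
    } else {
      p <- exp((lr - max(lr)) / temperature)
      tok[pos] <- sample.int(20L, 1L, prob = p / sum(p))
    }
  }
  sequence_state(tok, time = 0)
}
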