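#' Training policy
#'
#' Probabilities and coefficients governing the joint training loop:
#' motif conditioning is attached half the time, a function term 85% of
#' the time (drawn among the example's terms in proportion to inverse
#' global frequency), and each modality is completely dropped 5% of the
#' time (all-mask sequence / maximum-noise structure). Parameters are
#' tracked with an exponential moving average (decay 0.999); the combined
#' loss weights the sequence term by 3.
#'
#' @param motif_prob probability of attaching a training motif.
#' @param term_use_prob probability of attaching a function term when the
#'   example has any.
#' @param modality_drop_prob per-modality complete-drop probability.
#' @param ema_decay EMA decay coefficient in (0, 1).
#' @param crop_size contiguous random crop length.
#' @param seq_loss_weight weight of the sequence loss in the combined
#'   loss.
#' @return an object of class `training_policy`.
#' @export
training_policy <- function(motif_prob = 0.5, term_use_prob = 0.85,
                            modality_drop_prob = 0.05, ema_decay = 0.999,
                            crop_size = 512L, seq_loss_weight = 3) {
  stopifnot(motif_prob >= 0, motif_prob <= 1,
            term_use_prob >= 0, term_use_prob <= 1,
            modality_drop_prob >= 0, modality_drop_prob <= 1,
            ema_decay > 0, ema_decay < 1, crop_size >= 2L,
            seq_loss_weight >= 0)
  structure(list(motif_prob = motif_prob, term_use_prob = term_use_prob,
                 modality_drop_prob = modality_drop_prob,
                 ema_decay = ema_decay, crop_size = as.integer(crop_size),
                 seq_loss_weight = seq_loss_weight),
            class = "training_policy")
}

#' Combined training loss
#'
#' @param l_struct,l_seq nonnegative structure and sequence losses.
#' @param policy a [training_policy()].
#' @return `l_struct + seq_loss_weight * l_seq`.
#' @export
combined_loss <- function(l_struct, l_seq, policy = training_policy()) {
  stopifnot(l_struct >= 0, l_seq >= 0)
  l_struct + policy$seq_loss_weight * l_seq
}

#' Independent modality noise levels
#'
#' Two independent uniform draws on [0, 1]: the sequence diffusion time
#' and the warped structural time (converted to a noise level with
#' [invert_time()]).
#'
#' @param seed optional seed.
#' @return named vector `c(t_seq, t_struct_prime)`.
#' @export
sample_noise_levels <- function(seed = NULL) {
  .maybe_seed(seed)
  c(t_seq = stats::runif(1), t_struct_prime = stats::runif(1))
}

#' Sample a multi-segment training motif
#'
#' Draws 1--4 contiguous segments jointly covering 5--50% of the residues
#' (uniform segment count and coverage, segments placed uniformly at
#' random without overlap) and packages their coordinates and identities
#' as a [motif_spec()].
#'
#' @param tokens clean sequence tokens.
#' @param coords clean coordinates.
#' @param max_segments maximum number of segments.
#' @param coverage length-2 coverage range as fractions of L.
#' @param seed optional seed.
#' @return a [motif_spec()].
#' @export
sample_training_motif <- function(tokens, coords, max_segments = 4L,
                                  coverage = c(0.05, 0.5), seed = NULL) {
  .maybe_seed(seed)
  tokens <- .tokens_of(tokens); coords <- .coords_of(coords)
  L <- length(tokens)
  total <- max(1L, round_half_up(stats::runif(1, coverage[1], coverage[2]) * L))
  n_seg <- sample.int(min(max_segments, total), 1L)
  # random composition of `total` into n_seg parts >= 1
  cuts <- sort(sample.int(total - 1L, n_seg - 1L))
  lens <- diff(c(0L, cuts, total))
  # distribute the free residues among the n_seg + 1 gaps
  free <- L - total
  gap_cuts <- sort(sample.int(free + n_seg, n_seg))
  gaps <- diff(c(0L, gap_cuts, free + n_seg + 1L)) - 1L
  pos <- integer(0)
  cursor <- 0L
  for (i in seq_len(n_seg)) {
    cursor <- cursor + gaps[i]
    pos <- c(pos, (cursor + 1L):(cursor + lens[i]))
    cursor <- cursor + lens[i]
  }
  pos <- pos[pos <= L]
  motif_spec(pos, coords[pos, , drop = FALSE], tokens[pos])
}

#' Apply the conditioning policy to a training example
#'
#' Independently: with probability `motif_prob` attaches a multi-segment
#' motif; with probability `term_use_prob` attaches one of the example's
#' terms drawn in proportion to inverse frequency (none if the example
#' has no terms); with probability `modality_drop_prob` each, flags the
#' sequence or the structure for complete dropping (all-mask input /
#' maximum-noise input respectively).
#'
#' @param example list with `tokens`, `coords`, optional `terms` (integer
#'   ids).
#' @param vocab_weights named numeric vector of term frequencies (counts);
#'   names are term ids as strings.
#' @param policy a [training_policy()].
#' @param seed optional seed.
#' @return the example augmented with `motif`, `term`, `drop_seq`,
#'   `drop_struct`.
#' @export
conditioning_policy <- function(example, vocab_weights = NULL,
                                policy = training_policy(), seed = NULL) {
  .maybe_seed(seed)
  example$motif <- NULL
  if (stats::runif(1) < policy$motif_prob) {
    example$motif <- sample_training_motif(example$tokens, example$coords)
  }
  example$term <- NULL
  terms <- example$terms
  if (!is.null(terms) && length(terms) > 0L &&
      stats::runif(1) < policy$term_use_prob) {
    w <- if (is.null(vocab_weights)) rep(1, length(terms)) else {
      cnt <- vocab_weights[as.character(terms)]
      cnt[is.na(cnt)] <- max(vocab_weights)
      1 / cnt
    }
    example$term <- if (length(terms) == 1L) terms else sample(terms, 1L, prob = w)
  }
  example$drop_seq <- stats::runif(1) < policy$modality_drop_prob
  example$drop_struct <- stats::runif(1) < policy$modality_drop_prob
  example
}

#' Hierarchical cluster-then-protein sampling
#'
#' Draws uniformly over outer (structure) clusters, then uniformly over
#' inner (sequence) clusters within the chosen outer cluster, then
#' uniformly over proteins passing the quality filter; clusters with no
#' passing protein never yield.
#'
#' @param table data frame with columns `id`, `outer_cluster`,
#'   `inner_cluster`, `quality` (plus any payload columns).
#' @param quality_min strict lower quality bound (e.g. pLDDT 80).
#' @param seed optional seed.
#' @return the selected row of `table`.
#' @export
hierarchical_sample <- function(table, quality_min = 80, seed = NULL) {
  stopifnot(all(c("id", "outer_cluster", "inner_cluster", "quality") %in%
                  names(table)))
  .maybe_seed(seed)
  pass <- table[table$quality > quality_min, , drop = FALSE]
  if (nrow(pass) == 0L) stop("no protein passes the quality filter")
  outers <- unique(pass$outer_cluster)
  o <- if (length(outers) == 1L) outers else sample(outers, 1L)
  po <- pass[pass$outer_cluster == o, , drop = FALSE]
  inners <- unique(po$inner_cluster)
  i <- if (length(inners) == 1L) inners else sample(inners, 1L)
  pi_ <- po[po$inner_cluster == i, , drop = FALSE]
  pi_[if (nrow(pi_) == 1L) 1L else sample.int(nrow(pi_), 1L), , drop = FALSE]
}

#' Transitive is_a closure of term annotations
#'
#' Expands each annotation set with all implied ancestors via `is_a`
#' edges. Cycles are an error. Root terms (no parents) are retained in
#' the closed sets but flagged via the `"roots"` attribute so callers can
#' apply non-root counting conventions.
#'
#' @param annotations named list: id -> character vector of term ids.
#' @param ontology named list: term id -> character vector of parent term
#'   ids (`is_a` only), as from [read_obo()].
#' @return named list of closed term sets, with attribute `"roots"`.
#' @export
propagate_terms <- function(annotations, ontology) {
  all_terms <- union(names(ontology), unlist(ontology, use.names = FALSE))
  # cycle check by iterative ancestor expansion
  ancestors <- new.env(parent = emptyenv())
  anc <- function(term, stack = character(0)) {
    if (term %in% stack) stop("cycle detected in ontology at term ", term)
    hit <- ancestors[[term]]
    if (!is.null(hit)) return(hit)
    parents <- ontology[[term]]
    out <- character(0)
    for (p in parents) out <- union(out, c(p, anc(p, c(stack, term))))
    ancestors[[term]] <- out
    out
  }
  closed <- lapply(annotations, function(terms) {
    out <- unique(terms)
    for (tm in terms) out <- union(out, anc(tm))
    sort(out)
  })
  roots <- sort(Filter(function(tm) length(ontology[[tm]]) == 0L, all_terms))
  attr(closed, "roots") <- roots
  closed
}

#' Exponential moving average update
#'
#' `ema <- decay * ema + (1 - decay) * params`, applied tensor-wise.
#' Decay 0 copies the current parameters; decay 1 freezes the average.
#'
#' @param ema,params parameter lists of identical shapes.
#' @param decay decay coefficient in [0, 1].
#' @return updated EMA parameter list.
#' @export
ema_update <- function(ema, params, decay = 0.999) {
  stopifnot(decay >= 0, decay <= 1)
  for (nm in names(params)) {
    ema[[nm]] <- decay * ema[[nm]] + (1 - decay) * params[[nm]]
  }
  ema
}

#' Train the joint denoiser
#'
#' Standard loop: per example, apply the conditioning policy, corrupt the
#' two modalities at independently drawn noise levels, run the forward
#' pass, accumulate gradients of the combined loss (structure + 3 x
#' sequence), take an Adam step with linear warmup, and update the EMA
#' parameters. Training aborts with a diagnostic if the loss becomes
#' non-finite. `steps = 0` returns the model unchanged.
#'
#' @param model a `denoiser`.
#' @param dataset list of examples, each a list with `tokens` (clean,
#'   mask-free), `coords` (L x 3), optional `terms`.
#' @param policy a [training_policy()].
#' @param steps number of optimizer steps.
#' @param batch_size examples per step.
#' @param lr peak learning rate.
#' @param lr_decay one of `"constant"` or `"cosine"` (cosine anneals to
#'   `0.1 * lr` by the final step).
#' @param warmup linear warmup steps.
#' @param clip_norm optional global gradient-norm clip (NULL disables).
#' @param vocab_weights term frequency table for inverse-frequency term
#'   sampling.
#' @param seed optional seed.
#' @param verbose print running loss every 200 steps.
#' @return list with `model` (trained), `ema_model`, and `history`
#'   (combined loss per step).
#' @export
train_denoiser <- function(model, dataset, policy = training_policy(),
                           steps = 1000L, batch_size = 8L, lr = 1e-3,
                           lr_decay = c("constant", "cosine"),
                           warmup = 100L, clip_norm = NULL,
                           vocab_weights = NULL, seed = NULL,
                           verbose = FALSE) {
  lr_decay <- match.arg(lr_decay)
  stopifnot(inherits(model, "denoiser"), length(dataset) > 0L)
  .maybe_seed(seed)
  if (steps == 0L) {
    return(list(model = model, ema_model = model, history = numeric(0)))
  }
  cfg <- model$config
  sched <- model$sched
  shapes <- .denoiser_shapes(cfg)
  params <- model$params[names(shapes)]
  theta <- .flatten_params(params)
  ema_theta <- theta
  opt <- .adam_init(length(theta))
  history <- numeric(steps)
  for (step in seq_len(steps)) {
    idx <- sample.int(length(dataset), batch_size, replace = TRUE)
    exs <- vector("list", batch_size)
    inputs <- vector("list", batch_size)
    for (j in seq_len(batch_size)) {
      ex <- dataset[[idx[j]]]
      if (length(ex$tokens) > policy$crop_size) {
        start <- sample.int(length(ex$tokens) - policy$crop_size + 1L, 1L)
        span <- start:(start + policy$crop_size - 1L)
        ex$tokens <- ex$tokens[span]
        ex$coords <- center_coords(ex$coords[span, , drop = FALSE])
      }
      ex <- conditioning_policy(ex, vocab_weights, policy)
      nl <- sample_noise_levels()
      ex$t_seq <- nl[["t_seq"]]
      ex$t_struct <- invert_time(nl[["t_struct_prime"]], sched)
      if (ex$drop_seq) {
        ex$st <- rep(mask_token(), length(ex$tokens)); ex$t_seq <- 1
      } else {
        ex$st <- mask_forward(ex$tokens, ex$t_seq)$tokens
      }
      if (ex$drop_struct) ex$t_struct <- sched$t_max
      ex$x0 <- center_coords(ex$coords)
      ex$xt <- forward_noise(ex$x0, ex$t_struct)$coords
      exs[[j]] <- ex
      inputs[[j]] <- .prepare_input(sched, ex$st, ex$xt, ex$t_seq,
                                    ex$t_struct, ex$motif, ex$term)
    }
    out <- .denoiser_forward_batch(params, cfg, inputs, train = TRUE,
                                   want_cache = TRUE)
    d_logits <- matrix(0, nrow(out$logits), ncol(out$logits))
    d_struct <- matrix(0, nrow(out$structure_pred), 3L)
    loss_acc <- 0
    for (j in seq_len(batch_size)) {
      ex <- exs[[j]]
      rows <- out$rows[[j]]
      lg <- out$logits[rows, , drop = FALSE]
      sp <- out$structure_pred[rows, , drop = FALSE]
      l_seq <- seq_loss(lg, ex$tokens, ex$st, ex$t_seq)
      l_struct <- structure_loss(sp, ex$x0, ex$xt, ex$t_struct, sched)
      if (!is.finite(l_seq) || !is.finite(l_struct)) {
        stop(sprintf("training diverged at step %d (non-finite loss)", step))
      }
      loss_acc <- loss_acc + combined_loss(l_struct, l_seq, policy)
      d_logits[rows, ] <- policy$seq_loss_weight *
        .seq_loss_grad(lg, ex$tokens, ex$st, ex$t_seq)
      d_struct[rows, ] <- .structure_loss_grad(sp, ex$x0, ex$xt,
                                               ex$t_struct, sched)
    }
    g <- .denoiser_backward_batch(params, cfg, out$cache, d_logits, d_struct,
                                  shapes = shapes)
    grad_flat <- unlist(g, use.names = FALSE) / batch_size
    if (!is.null(clip_norm)) {
      gn <- sqrt(sum(grad_flat^2))
      if (is.finite(gn) && gn > clip_norm) {
        grad_flat <- grad_flat * (clip_norm / gn)
      }
    }
    loss <- loss_acc / batch_size
    if (!is.finite(loss)) {
      stop(sprintf("training diverged at step %d (non-finite loss)", step))
    }
    history[step] <- loss
    lr_t <- lr * min(1, step / max(1L, warmup))
    if (lr_decay == "cosine") {
      lr_t <- lr_t * (0.1 + 0.45 * (1 + cos(pi * step / steps)))
    }
    upd <- .adam_step(theta, grad_flat, opt, lr_t)
    theta <- upd$theta
    opt <- upd$state
    params <- .unflatten_params(theta, shapes)
    ema_theta <- policy$ema_decay * ema_theta + (1 - policy$ema_decay) * theta
    if (verbose && step %% 200L == 0L) {
      message(sprintf("step %d: loss %.4f", step, mean(history[max(1, step - 99):step])))
    }
  }
  trained <- structure(list(config = cfg, params = params, sched = sched),
                       class = "denoiser")
  ema_model <- structure(list(config = cfg,
                              params = .unflatten_params(ema_theta, shapes),
                              sched = sched),
                         class = "denoiser")
  list(model = trained, ema_model = ema_model, history = history)
}
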