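#' Classifier-free guidance combination
#'
#' Linear extrapolation (1 - lambda) * unconditional + lambda * conditional
#' applied to the logits and to the raw structure prediction; because the
#' score parameterization is linear in the raw prediction at fixed (x, t),
#' combining raw predictions combines the derived scores identically.
#' lambda = 1 reduces to conditional sampling, lambda = 0 to
#' unconditional; values above 1 strengthen adherence to the conditioning
#' label.
#'
#' @param uncond,cond denoiser outputs (lists with `logits` and
#'   `structure_pred`).
#' @param lambda guidance strength.
#' @return a combined denoiser output.
#' @export
cfg_combine <- function(uncond, cond, lambda) {
  stopifnot(all(dim(uncond$logits) == dim(cond$logits)),
            all(dim(uncond$structure_pred) == dim(cond$structure_pred)))
  list(logits = (1 - lambda) * uncond$logits + lambda * cond$logits,
       structure_pred = (1 - lambda) * uncond$structure_pred +
         lambda * cond$structure_pred)
}

#' Coupled sequence logits
#'
#' Product-of-experts combination for multistate sampling: the two
#' motif-conditioned branches contribute their logits and the
#' unconditional sequence branch is divided out,
#' phi_1 + phi_2 - phi_uncond.
#'
#' @param phi1,phi2 L x 21 logits of the two conditional branches.
#' @param phi_uncond L x 21 logits of the unconditional branch.
#' @return L x 21 combined logits.
#' @export
coupled_logits <- function(phi1, phi2, phi_uncond) {
  stopifnot(all(dim(phi1) == dim(phi2)), all(dim(phi1) == dim(phi_uncond)))
  phi1 + phi2 - phi_uncond
}

#' Place an effector motif on a scaffold
#'
#' Re-indexes a motif at a fixed or uniformly random contiguous location
#' of length |motif| that does not overlap `occupied` index ranges.
#'
#' @param L scaffold length.
#' @param motif a [motif_spec()] (its positions define only the motif
#'   length and internal order).
#' @param fixed_position optional fixed start (1-based).
#' @param occupied optional list of integer vectors (or a single vector)
#'   of residue indices the motif must not overlap.
#' @param seed optional seed.
#' @return a [motif_spec()] with positions `[p, p + len - 1]`.
#' @export
place_effector_motif <- function(L, motif, fixed_position = NULL,
                                 occupied = NULL, seed = NULL) {
  len <- length(motif$positions)
  if (len > L) stop("motif longer than scaffold")
  occ <- sort(unique(unlist(occupied)))
  ok_start <- function(p) {
    span <- p:(p + len - 1L)
    p >= 1L && p + len - 1L <= L && !any(span %in% occ)
  }
  if (!is.null(fixed_position)) {
    if (!ok_start(fixed_position)) stop("no legal placement at fixed position")
    p <- as.integer(fixed_position)
  } else {
    .maybe_seed(seed)
    starts <- Filter(ok_start, seq_len(L - len + 1L))
    if (length(starts) == 0L) stop("no legal placement available")
    p <- if (length(starts) == 1L) starts else sample(starts, 1L)
  }
  motif_spec(positions = p:(p + len - 1L), coords = motif$coords,
             identities = motif$identities)
}

# clamp spec (positions + tokens) from one or more motifs, with identity
# conflict detection at shared positions
.motif_clamp <- function(..., L) {
  motifs <- Filter(Negate(is.null), list(...))
  pos <- integer(0); tok <- integer(0)
  for (m in motifs) {
    if (any(m$positions > L)) stop("motif positions out of range")
    for (i in seq_along(m$positions)) {
      j <- match(m$positions[i], pos)
      if (is.na(j)) {
        pos <- c(pos, m$positions[i]); tok <- c(tok, m$identities[i])
      } else if (tok[j] != m$identities[i]) {
        stop("motif identity conflict at shared clamped position ", pos[j])
      }
    }
  }
  if (length(pos) == 0L) return(NULL)
  o <- order(pos)
  list(positions = pos[o], tokens = tok[o])
}

#' Sequence--structure co-generation
#'
#' Joint rollout denoising both modalities on linear schedules: at each of
#' `n_steps` steps the model is evaluated once (twice under classifier-free
#' guidance), the sequence advances by a co-generation path-planning step
#' (temperature 0.1 + 0.4 t) and the structure by an annealed reverse SDE
#' step. Motif residues are clamped in the sequence for the entire
#' trajectory.
#'
#' @param model a `denoiser`.
#' @param L design length.
#' @param n_steps steps (default `L`).
#' @param motif optional [motif_spec()].
#' @param term optional function-term id.
#' @param guidance_strength classifier-free guidance strength (default 1 =
#'   plain conditional; needs `term` or `motif`).
#' @param ann [annealing_params()]; conditional sampling uses nu = 1.
#' @param gamma_fn sequence sampling temperature schedule.
#' @param seed optional seed.
#' @return list with `sequence` (a `sequence_state`) and `structure`
#'   (a `structure_state`).
#' @export
cogenerate <- function(model, L, n_steps = L, motif = NULL, term = NULL,
                       guidance_strength = 1,
                       ann = annealing_params(gamma = 0.5,
                                              nu = if (is.null(motif) && is.null(term)) 0.5 else 1),
                       gamma_fn = function(t) 0.1 + 0.4 * t,
                       seed = NULL) {
  stopifnot(inherits(model, "denoiser"), n_steps >= 1)
  .maybe_seed(seed)
  sched <- model$sched
  clamp <- .motif_clamp(motif, L = L)
  tok <- rep(mask_token(), L)
  if (!is.null(clamp)) tok[clamp$positions] <- clamp$tokens
  x <- sched$t_max * matrix(stats::rnorm(3 * L), L, 3L)
  grid <- seq(1, 0, length.out = n_steps + 1L)
  use_cfg <- !is.null(guidance_strength) && guidance_strength != 1 &&
    (!is.null(term) || !is.null(motif))
  for (i in seq_len(n_steps)) {
    t <- grid[i]; s <- grid[i + 1L]
    t_struct <- invert_time(t, sched)
    dt <- t_struct - invert_time(s, sched)
    out <- denoise(model, tok, x, t_seq = t, t_struct = t_struct,
                   motif = motif, term = term)
    if (use_cfg) {
      out_u <- denoise(model, tok, x, t_seq = t, t_struct = t_struct)
      out <- cfg_combine(out_u, out, guidance_strength)
    }
    st <- path_planning_step(out$logits, tok, s, t, gamma = gamma_fn(t),
                             mode = "cogeneration",
                             clamp = clamp$positions)
    tok <- st$tokens
    sc <- score_from_raw(out$structure_pred, x, t_struct, sched)$score
    x <- reverse_step(x, sc, t_struct, dt, ann,
                      deterministic = (i == n_steps))$coords
  }
  list(sequence = sequence_state(tok, time = 0),
       structure = structure_state(center_coords(x), noise_level = sched$t_min))
}

#' Coupled structure diffusion for multistate design
#'
#' Samples one sequence tied to two structure trajectories, each
#' conditioned on its own motif. Per step, three model evaluations are
#' made -- (s, x1 | m1), (s, x2 | m2) and an unconditional sequence branch
#' (s | no motif, structure input held at maximum noise) -- the sequence
#' advances by a co-generation path-planning step on
#' [coupled_logits()] with all motif residues clamped, and each structure
#' advances on its own branch score. The branches share only the sequence,
#' never each other's coordinates.
#'
#' @param model a `denoiser`.
#' @param m1,m2 the two [motif_spec()]s (their positions may overlap in
#'   sequence; identity conflicts at shared positions are an error).
#' @param L design length.
#' @param n_steps steps (default `L`).
#' @param ann [annealing_params()]; defaults to the conditional setting
#'   (gamma 0.5, nu 1).
#' @param gamma_fn sequence temperature schedule (co-generation default).
#' @param seed optional seed.
#' @param share_structure_noise share the initial draw and the per-step
#'   Gaussian between the two branches (diagnostic for the degenerate
#'   m1 = m2 case and for label-symmetry checks).
#' @return list with `sequence`, `structure1`, `structure2`.
#' @export
coupled_sample <- function(model, m1, m2, L, n_steps = L,
                           ann = annealing_params(gamma = 0.5, nu = 1),
                           gamma_fn = function(t) 0.1 + 0.4 * t,
                           seed = NULL, share_structure_noise = FALSE) {
  stopifnot(inherits(model, "denoiser"), inherits(m1, "motif_spec"),
            inherits(m2, "motif_spec"), n_steps >= 1)
  .maybe_seed(seed)
  sched <- model$sched
  clamp <- .motif_clamp(m1, m2, L = L)
  tok <- rep(mask_token(), L)
  tok[clamp$positions] <- clamp$tokens
  x1 <- sched$t_max * matrix(stats::rnorm(3 * L), L, 3L)
  x2 <- if (share_structure_noise) x1 else
    sched$t_max * matrix(stats::rnorm(3 * L), L, 3L)
  x_null <- sched$t_max * matrix(stats::rnorm(3 * L), L, 3L)
  grid <- seq(1, 0, length.out = n_steps + 1L)
  for (i in seq_len(n_steps)) {
    t <- grid[i]; s <- grid[i + 1L]
    t_struct <- invert_time(t, sched)
    dt <- t_struct - invert_time(s, sched)
    out1 <- denoise(model, tok, x1, t_seq = t, t_struct = t_struct, motif = m1)
    out2 <- denoise(model, tok, x2, t_seq = t, t_struct = t_struct, motif = m2)
    out0 <- denoise(model, tok, x_null, t_seq = t, t_struct = sched$t_max)
    phi <- coupled_logits(out1$logits, out2$logits, out0$logits)
    st <- path_planning_step(phi, tok, s, t, gamma = gamma_fn(t),
                             mode = "cogeneration", clamp = clamp$positions)
    tok <- st$tokens
    noise1 <- matrix(stats::rnorm(3 * L), L, 3L)
    noise2 <- if (share_structure_noise) noise1 else matrix(stats::rnorm(3 * L), L, 3L)
    s1 <- score_from_raw(out1$structure_pred, x1, t_struct, sched)$score
    s2 <- score_from_raw(out2$structure_pred, x2, t_struct, sched)$score
    last <- (i == n_steps)
    x1 <- reverse_step(x1, s1, t_struct, dt, ann, noise = noise1,
                       deterministic = last)$coords
    x2 <- reverse_step(x2, s2, t_struct, dt, ann, noise = noise2,
                       deterministic = last)$coords
  }
  list(sequence = sequence_state(tok, time = 0),
       structure1 = structure_state(center_coords(x1), noise_level = sched$t_min),
       structure2 = structure_state(center_coords(x2), noise_level = sched$t_min))
}

#' Unconditional generation protocols
#'
#' `generate_sequence()` fixes a maximum-noise structure input and
#' iteratively unmasks the sequence with the path-planning sampler
#' (temperature 0.5). `generate_structure()` fixes the all-mask sequence
#' and integrates the structure reverse SDE. `inverse_fold()` samples a
#' sequence for a fixed clean structure at temperature 0.1 in a random
#' unmasking order. All use L model forward passes by default.
#'
#' @param model a `denoiser`.
#' @param L design length.
#' @param n_steps number of steps (default `L`).
#' @param term optional function-term id.
#' @param ann annealing parameters for the structure branch.
#' @param seed optional seed.
#' @return `generate_sequence()` / `inverse_fold()` a `sequence_state`;
#'   `generate_structure()` a `structure_state`.
#' @export
generate_sequence <- function(model, L, n_steps = L, term = NULL, seed = NULL) {
  .maybe_seed(seed)
  sched <- model$sched
  x_fix <- sched$t_max * matrix(stats::rnorm(3 * L), L, 3L)
  fn <- function(tokens, t) {
    denoise(model, tokens, x_fix, t_seq = t, t_struct = sched$t_max,
            term = term)$logits
  }
  sample_sequence(fn, L, n_steps, gamma_fn = function(t) 0.5,
                  mode = "path_planning")
}

#' @rdname generate_sequence
#' @export
generate_structure <- function(model, L, n_steps = L, term = NULL,
                               ann = annealing_params(), seed = NULL) {
  .maybe_seed(seed)
  sched <- model$sched
  tok_fix <- rep(mask_token(), L)
  fn <- function(x, t, conditioning) {
    out <- denoise(model, tok_fix, x, t_seq = 1, t_struct = t, term = term)
    score_from_raw(out$structure_pred, x, t, sched)$score
  }
  sample_structure(fn, L, n_steps, ann, sched)
}

#' @rdname generate_sequence
#' @param structure a clean `structure_state` (or L x 3 matrix).
#' @param temperature inverse-folding softmax temperature.
#' @export
inverse_fold <- function(model, structure, temperature = 0.1, seed = NULL) {
  coords <- .coords_of(structure)
  sched <- model$sched
  fn <- function(tokens, t) {
    denoise(model, tokens, coords, t_seq = t, t_struct = sched$t_min)$logits
  }
  inverse_fold_sample(fn, nrow(coords), temperature = temperature, seed = seed)
}
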