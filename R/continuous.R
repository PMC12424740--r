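#' Construct a structure diffusion state
#'
#' @param coords L x 3 matrix of C-alpha coordinates (Angstrom).
#' @param noise_level the current noise level t (Angstrom); 0 for clean data.
#' @return an object of class `structure_state`.
#' @export
structure_state <- function(coords, noise_level = 0) {
  stopifnot(is.matrix(coords), ncol(coords) == 3L, is.numeric(coords),
            noise_level >= 0)
  structure(list(coords = coords, noise_level = noise_level),
            class = "structure_state")
}

#' @export
print.structure_state <- function(x, ...) {
  cat(sprintf("structure_state: L = %d residues, noise level %g A\n",
              nrow(x$coords), x$noise_level))
  invisible(x)
}

.coords_of <- function(x) {
  if (inherits(x, "structure_state")) x$coords else x
}

#' Forward Gaussian corruption of coordinates
#'
#' Draws from the perturbation kernel N(x_t; x_0, t^2 I): independent
#' isotropic Gaussian noise of standard deviation t Angstrom per coordinate.
#'
#' @param x0 clean coordinates (`structure_state` or L x 3 matrix).
#' @param t noise level (Angstrom), >= 0.
#' @param seed optional integer seed for reproducibility.
#' @return a `structure_state` at noise level `t`.
#' @export
forward_noise <- function(x0, t, seed = NULL) {
  if (t < 0) stop("negative noise level")
  .maybe_seed(seed)
  x <- .coords_of(x0)
  xt <- x + t * matrix(stats::rnorm(length(x)), nrow(x), ncol(x))
  structure_state(xt, noise_level = t)
}

#' Score estimate from the raw network output
#'
#' Post-conditioned score parameterization (EDM style): with data scale
#' `t_data`,
#' s(x, t) = (1/t^2) * ( t * t_data / sqrt(t_data^2 + t^2) * f
#'                      - t^2 / (t_data^2 + t^2) * x ),
#' so that s ~ f / t as t -> 0 and s ~ (t_data f - x) / t^2 as t -> Inf:
#' the network interpolates between predicting the score and predicting the
#' clean data.
#'
#' @param raw L x 3 raw network prediction f(x, t).
#' @param x L x 3 current (noisy) coordinates.
#' @param t noise level (> 0).
#' @param sched a [sigma_schedule()] providing `t_data`.
#' @return list with fields `raw_prediction` and `score` (Angstrom^-1).
#' @export
score_from_raw <- function(raw, x, t, sched = sigma_schedule()) {
  if (t <= 0) stop("score undefined at t = 0")
  stopifnot(all(dim(raw) == dim(x)))
  td <- sched$t_data
  c_out <- t * td / sqrt(td^2 + t^2)
  c_x <- t^2 / (td^2 + t^2)
  score <- (c_out * raw - c_x * x) / t^2
  list(raw_prediction = raw, score = score)
}

#' Denoising score-matching loss for the structure branch
#'
#' Weighted squared error between the parameterized score and the analytic
#' conditional score (x_0 - x_t) / t^2, with time weighting
#' w(t) = t^2 (t^2 + t_data^2) / t_data^2 (the EDM weighting carried to
#' score space). The squared error is averaged over the 3L coordinates.
#'
#' @param raw L x 3 raw network prediction.
#' @param x0 clean coordinates (matrix or `structure_state`).
#' @param xt noisy coordinates at level `t`.
#' @param t noise level inside `[t_min, t_max]`.
#' @param sched a [sigma_schedule()].
#' @return nonnegative scalar; zero iff the derived score equals the target.
#' @export
structure_loss <- function(raw, x0, xt, t, sched = sigma_schedule()) {
  x0 <- .coords_of(x0); xt <- .coords_of(xt)
  if (!all(dim(raw) == dim(x0)) || !all(dim(raw) == dim(xt))) {
    stop("shape mismatch between prediction and coordinates")
  }
  if (t < sched$t_min - 1e-12 || t > sched$t_max + 1e-12) {
    stop("t outside schedule support")
  }
  s <- score_from_raw(raw, xt, t, sched)$score
  target <- (x0 - xt) / t^2
  w <- t^2 * (t^2 + sched$t_data^2) / sched$t_data^2
  w * mean((s - target)^2)
}

# gradient of structure_loss with respect to `raw`; used by the trainer.
.structure_loss_grad <- function(raw, x0, xt, t, sched = sigma_schedule()) {
  td <- sched$t_data
  s <- score_from_raw(raw, xt, t, sched)$score
  target <- (x0 - xt) / t^2
  w <- t^2 * (t^2 + td^2) / td^2
  c_out <- t * td / sqrt(td^2 + t^2)
  w * 2 * (s - target) * (c_out / t^2) / length(raw)
}

#' One annealed Euler--Maruyama reverse step
#'
#' Integrates dx = (g^2/2)(1 + beta(t)) s dt + g sqrt(beta(t) gamma) dw
#' backwards in t with g(t) = sqrt(2 t): a step of size `dt` toward smaller
#' noise. With beta = gamma = 1 this is the standard reverse SDE for the
#' variance-exploding process.
#'
#' @param x current coordinates (`structure_state` or matrix).
#' @param score score estimate at (x, t), same shape as the coordinates.
#' @param t current noise level (Angstrom).
#' @param dt step size in t (> 0, toward smaller t).
#' @param ann an [annealing_params()].
#' @param seed optional seed.
#' @param noise optional pre-drawn standard-normal matrix (shared-noise
#'   protocols); overrides the internal draw.
#' @param deterministic if TRUE no noise is injected (used for the final
#'   integration step).
#' @return a `structure_state` at noise level `t - dt`.
#' @export
reverse_step <- function(x, score, t, dt, ann = annealing_params(),
                         seed = NULL, noise = NULL, deterministic = FALSE) {
  xm <- .coords_of(x)
  if (!all(dim(score) == dim(xm))) stop("score shape mismatch")
  stopifnot(dt > 0)
  .maybe_seed(seed)
  g2 <- 2 * t
  beta <- ann$beta_fn(t)
  xn <- xm + (g2 / 2) * (1 + beta) * score * dt
  if (!deterministic) {
    if (is.null(noise)) {
      noise <- matrix(stats::rnorm(length(xm)), nrow(xm), ncol(xm))
    }
    xn <- xn + sqrt(g2 * beta * ann$gamma * dt) * noise
  }
  structure_state(xn, noise_level = max(t - dt, 0))
}

#' Sample coordinates by reverse SDE integration
#'
#' Full rollout: initialize x ~ N(0, t_max^2 I), then take `n_steps`
#' Euler--Maruyama steps on a grid uniform in warped time t' from 1 to 0
#' (one model call per step; the final step is deterministic). The model is
#' a function `(x, t, conditioning) -> L x 3 score`.
#'
#' @param model score function.
#' @param L number of residues.
#' @param n_steps number of integration steps (default `L`, i.e. L model
#'   forward passes).
#' @param ann an [annealing_params()].
#' @param sched a [sigma_schedule()].
#' @param conditioning opaque conditioning object passed to the model.
#' @param seed optional seed.
#' @param center_output re-center the terminal coordinates (default TRUE;
#'   analytic-oracle models on raw coordinates should disable this).
#' @param trajectory if TRUE also return the list of intermediate states.
#' @return a `structure_state` at `t_min`, with attribute `"n_model_calls"`;
#'   if `trajectory`, a list with fields `final` and `states`.
#' @export
sample_structure <- function(model, L, n_steps = L, ann = annealing_params(),
                             sched = sigma_schedule(), conditioning = NULL,
                             seed = NULL, center_output = TRUE,
                             trajectory = FALSE) {
  stopifnot(n_steps >= 1)
  .maybe_seed(seed)
  x <- sched$t_max * matrix(stats::rnorm(3 * L), L, 3L)
  tp <- seq(1, 0, length.out = n_steps + 1L)
  tt <- invert_time(tp, sched)
  states <- if (trajectory) vector("list", n_steps) else NULL
  calls <- 0L
  for (i in seq_len(n_steps)) {
    t_i <- tt[i]
    dt <- t_i - tt[i + 1L]
    s <- model(x, t_i, conditioning)
    calls <- calls + 1L
    if (!all(dim(s) == dim(x))) stop("model output shape mismatch")
    st <- reverse_step(x, s, t_i, dt, ann, deterministic = (i == n_steps))
    x <- st$coords
    if (trajectory) states[[i]] <- st
  }
  if (center_output) x <- center_coords(x)
  out <- structure_state(x, noise_level = sched$t_min)
  attr(out, "n_model_calls") <- calls
  if (trajectory) list(final = out, states = states) else out
}
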