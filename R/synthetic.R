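#' Toy sequence--structure family
#'
#' A deterministic sequence-to-structure map small models can learn in
#' minutes on a CPU while preserving the property every end-to-end test
#' needs: the sequence determines the structure, and an exact decoder is
#' available as an oracle. The chain follows a fixed helical direction
#' template (per-residue twist and pitch), and each residue class sets the
#' ideal local geometry of its step: the rise (step length, Angstrom) and a
#' class twist (azimuthal offset on the template direction) -- helix-like
#' short rises, strand-like long straight rises, coil in between. Every
#' step is therefore one of a few fixed per-position vectors, so the
#' sequence-to-structure map is linear in the one-hot sequence (learnable
#' by a tiny model in minutes on a CPU) while distinct classes displace the
#' chain by several Angstrom (the structure determines the sequence; an
#' exact geometric inverse is available). In `two_state` mode a second
#' conformer differing by a rigid hinge rotation of the C-terminal half is
#' also emitted.
#'
#' @param length number of residues.
#' @param noise_sd isotropic coordinate noise added to emitted structures
#'   (Angstrom).
#' @param two_state also emit the hinge-rotated conformer.
#' @param hinge_residue hinge position (default middle residue).
#' @param hinge_angle hinge rotation angle (radians), applied about an
#'   axis perpendicular to the template's helical axis.
#' @param template_twist per-residue in-plane rotation of the template
#'   direction (radians).
#' @param template_pitch out-of-plane pitch of the template (radians).
#' @param classes data frame with columns `class`, `letter`, `rise`,
#'   `twist` (azimuthal offset, radians) defining the segment alphabet.
#' @return an object of class `toy_family_spec`.
#' @export
toy_family_spec <- function(length = 32L, noise_sd = 0.05, two_state = FALSE,
                            hinge_residue = NULL, hinge_angle = 1.5,
                            template_twist = 0.35, template_pitch = 0.26,
                            classes = NULL) {
  if (is.null(classes)) {
    classes <- data.frame(
      class = c("helix", "strand", "coil"),
      letter = c("A", "V", "G"),
      rise = c(1.5, 3.4, 2.5),
      twist = c(2, 0, 4) * pi / 3,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(length >= 2L, noise_sd >= 0,
            all(c("class", "letter", "rise", "twist") %in% names(classes)),
            !anyDuplicated(classes$rise), !anyDuplicated(classes$letter))
  classes$token <- match(classes$letter, aa_alphabet())
  if (anyNA(classes$token)) stop("class letters must be standard amino acids")
  if (is.null(hinge_residue)) hinge_residue <- as.integer(floor(length / 2))
  stopifnot(hinge_residue >= 2L, hinge_residue <= length - 1L)
  structure(list(length = as.integer(length), noise_sd = noise_sd,
                 two_state = two_state, hinge_residue = hinge_residue,
                 hinge_angle = hinge_angle,
                 template_twist = template_twist,
                 template_pitch = template_pitch,
                 classes = classes),
            class = "toy_family_spec")
}

# candidate step vector for class k at the step into residue i (i >= 2):
# rise_k times the unit template direction rotated by the class twist
.toy_step <- function(spec, i, k) {
  theta <- spec$template_twist * (i - 1L) + spec$classes$twist[k]
  phi <- spec$template_pitch
  spec$classes$rise[k] *
    c(cos(phi) * cos(theta), cos(phi) * sin(theta), sin(phi))
}

# all candidate step vectors: (L-1) x n_classes x 3 array
.toy_step_table <- function(spec, L) {
  nc <- nrow(spec$classes)
  out <- array(0, c(L - 1L, nc, 3L))
  for (i in 2:L) for (k in seq_len(nc)) out[i - 1L, k, ] <- .toy_step(spec, i, k)
  out
}

#' Exact decoder of the toy family
#'
#' Replays the deterministic chain growth for a token sequence: the oracle
#' against which generated sequence--structure pairs are scored. Errors if
#' the sequence contains letters outside the family alphabet.
#'
#' @param tokens integer token vector (family letters only).
#' @param spec a [toy_family_spec()].
#' @param conformer 1 for the base conformation, 2 for the hinge-rotated
#'   one (requires `two_state`).
#' @return centered L x 3 coordinate matrix.
#' @export
decode_structure <- function(tokens, spec, conformer = 1L) {
  tokens <- .tokens_of(tokens)
  cls <- match(tokens, spec$classes$token)
  if (anyNA(cls)) stop("sequence contains letters outside the toy family alphabet")
  L <- length(tokens)
  tab <- .toy_step_table(spec, L)
  steps <- t(vapply(2:L, function(i) tab[i - 1L, cls[i], ], numeric(3)))
  x <- rbind(0, apply(steps, 2L, cumsum))
  if (conformer == 2L) {
    if (!spec$two_state) stop("conformer 2 requires a two_state spec")
    x <- .hinge_rotate(x, spec$hinge_residue, spec$hinge_angle)
  }
  center_coords(x)
}

# rigid rotation of residues beyond the hinge about the x axis through the
# hinge C-alpha (perpendicular to the template's helical axis, so the two
# conformers separate substantially)
.hinge_rotate <- function(x, hinge, angle) {
  R <- matrix(c(1, 0, 0,
                0, cos(angle), sin(angle),
                0, -sin(angle), cos(angle)), 3L, 3L)
  pivot <- x[hinge, ]
  idx <- (hinge + 1L):nrow(x)
  x[idx, ] <- sweep(sweep(x[idx, , drop = FALSE], 2L, pivot) %*% R, 2L, pivot, `+`)
  x
}

#' Draw a toy protein from the family
#'
#' A uniformly random class sequence plus its decoded structure with
#' isotropic coordinate noise; in `two_state` mode the hinge-rotated
#' conformer (same sequence) is also returned.
#'
#' @param spec a [toy_family_spec()].
#' @param seed optional seed.
#' @return list with `sequence` (a `sequence_state`), `structure`
#'   (a `structure_state`), and optionally `structure2`.
#' @export
make_toy_protein <- function(spec, seed = NULL) {
  .maybe_seed(seed)
  L <- spec$length
  tokens <- sample(spec$classes$token, L, replace = TRUE)
  # residue 1 has no incoming step, so its class cannot be read off the
  # geometry; the family pins it to the first class to keep the
  # sequence <-> structure map a bijection
  tokens[1L] <- spec$classes$token[1L]
  noisy <- function(conf) {
    x <- decode_structure(tokens, spec, conformer = conf)
    if (spec$noise_sd > 0) x <- x + spec$noise_sd * matrix(stats::rnorm(3 * L), L, 3L)
    structure_state(center_coords(x), noise_level = 0)
  }
  out <- list(sequence = sequence_state(tokens), structure = noisy(1L))
  if (spec$two_state) out$structure2 <- noisy(2L)
  out
}

#' Nearest-class inverse of the toy geometry
#'
#' Reads the class of each residue off its incoming C-alpha step by nearest
#' candidate step vector (classes have distinct rises and twist offsets);
#' the geometric inverse-folding oracle, exact in the family's canonical
#' frame. The first residue, which has no incoming step, is the family's
#' pinned first class.
#'
#' @param coords L x 3 coordinate matrix (canonical frame, centered or not).
#' @param spec a [toy_family_spec()].
#' @return integer token vector.
#' @export
toy_inverse_fold <- function(coords, spec) {
  coords <- .coords_of(coords)
  L <- nrow(coords)
  tab <- .toy_step_table(spec, L)
  steps <- coords[-1L, , drop = FALSE] - coords[-L, , drop = FALSE]
  k <- vapply(2:L, function(i) {
    d2 <- colSums((t(tab[i - 1L, , ]) - steps[i - 1L, ])^2)
    which.min(d2)
  }, integer(1))
  c(spec$classes$token[1L], spec$classes$token[k])
}

#' Co-generation self-consistency against the family oracle
#'
#' A generated (sequence, structure) pair is self-consistent when the
#' sequence lies in the family alphabet and the structure decoded from it
#' superposes onto the emitted structure below `threshold` (aligned
#' C-alpha RMSD, Angstrom).
#'
#' @param tokens emitted sequence.
#' @param coords emitted structure.
#' @param spec a [toy_family_spec()].
#' @param threshold RMSD cutoff in Angstrom (default 2).
#' @return logical, with the RMSD as attribute `"rmsd"` (NA when the
#'   sequence leaves the alphabet).
#' @export
toy_self_consistency <- function(tokens, coords, spec, threshold = 2.0) {
  tokens <- .tokens_of(tokens)
  if (!all(tokens %in% spec$classes$token)) {
    return(structure(FALSE, rmsd = NA_real_))
  }
  dec <- decode_structure(tokens, spec)
  r <- kabsch_superpose(dec, center_coords(.coords_of(coords)))$backbone_rmsd
  structure(r < threshold, rmsd = r)
}

#' Isotropic Gaussian mixture with analytic score
#'
#' Fixture for testing the reverse integrator: the score of the mixture
#' convolved with the diffusion kernel is available in closed form (each
#' component variance inflated by t^2).
#'
#' @param means list of 3-vectors (component means).
#' @param weights mixture weights (sum to 1).
#' @param component_sd common component standard deviation (Angstrom).
#' @return an object of class `mixture_spec`.
#' @export
mixture_spec <- function(means, weights, component_sd = 1) {
  stopifnot(length(means) == length(weights),
            abs(sum(weights) - 1) < 1e-8, component_sd > 0)
  structure(list(means = lapply(means, as.numeric), weights = weights,
                 component_sd = component_sd),
            class = "mixture_spec")
}

#' Exact score of a Gaussian-convolved mixture
#'
#' Gradient of log of the mixture density after convolution with
#' N(0, t^2 I). Accepts a single 3-vector or an n x 3 matrix of points
#' (rows treated independently).
#'
#' @param x point(s).
#' @param t noise level (>= 0).
#' @param spec a [mixture_spec()].
#' @return score with the same shape as `x`.
#' @export
mixture_score <- function(x, t, spec) {
  stopifnot(t >= 0)
  single <- is.null(dim(x))
  xm <- if (single) matrix(x, 1L) else x
  v <- spec$component_sd^2 + t^2
  K <- length(spec$means)
  n <- nrow(xm)
  loglik <- matrix(0, n, K)
  for (k in seq_len(K)) {
    d2 <- rowSums(sweep(xm, 2L, spec$means[[k]])^2)
    loglik[, k] <- log(spec$weights[k]) - d2 / (2 * v)
  }
  m <- apply(loglik, 1L, max)
  r <- exp(loglik - m)
  r <- r / rowSums(r)
  sc <- matrix(0, n, ncol(xm))
  for (k in seq_len(K)) {
    sc <- sc + r[, k] * sweep(-xm, 2L, spec$means[[k]], `+`) / v
  }
  if (single) drop(sc) else sc
}

#' Enumerable discrete joint with exact posterior oracle
#'
#' An explicit probability table over all sequences of a small alphabet
#' (tokens 1..n_letters), with the exact clean-token posterior for any
#' partially masked state computed by Bayesian summation over compatible
#' completions. Serves as the independent oracle for reverse-posterior and
#' ancestral-sampling tests.
#'
#' @param n_letters alphabet size (<= 6).
#' @param length sequence length (<= 4).
#' @param probs optional probability vector over the `n_letters^length`
#'   sequences (rows of the table, lexicographic); random if omitted.
#' @param seed optional seed for the random table.
#' @return list with `sequences` (table of all sequences), `probs`,
#'   `posterior(tokens)` returning an L x 21 matrix, and `model` (a
#'   batched logits function usable with [sample_sequence()]).
#' @export
enumerate_discrete_joint <- function(n_letters = 4L, length = 3L,
                                     probs = NULL, seed = NULL) {
  Lq <- as.integer(length)
  if (n_letters > 6L || Lq > 4L) stop("table too large for enumeration")
  .maybe_seed(seed)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_letters)), Lq)))[, Lq:1, drop = FALSE]
  dimnames(grid) <- NULL
  n_seq <- nrow(grid)
  if (is.null(probs)) {
    probs <- stats::rexp(n_seq)
    probs <- probs / sum(probs)
  }
  stopifnot(base::length(probs) == n_seq, abs(sum(probs) - 1) < 1e-8)

  posterior <- function(tokens) {
    tokens <- .tokens_of(tokens)
    stopifnot(base::length(tokens) == Lq)
    known <- which(tokens != mask_token())
    compat <- rep(TRUE, n_seq)
    for (j in known) compat <- compat & (grid[, j] == tokens[j])
    w <- probs * compat
    if (sum(w) == 0) w <- probs   # impossible evidence: fall back to prior
    w <- w / sum(w)
    out <- matrix(0, Lq, 21L)
    for (j in seq_len(Lq)) {
      if (j %in% known) {
        out[j, tokens[j]] <- 1
      } else {
        for (a in seq_len(n_letters)) out[j, a] <- sum(w[grid[, j] == a])
      }
    }
    out
  }

  cache <- new.env(parent = emptyenv())
  post_logits <- function(tokens) {
    key <- paste(tokens, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    p <- posterior(tokens)
    lg <- log(pmax(p, 1e-30))
    cache[[key]] <- lg
    lg
  }
  model <- function(states, t) {
    if (is.null(dim(states))) return(post_logits(states))
    out <- array(0, c(nrow(states), Lq, 21L))
    for (b in seq_len(nrow(states))) out[b, , ] <- post_logits(states[b, ])
    out
  }
  list(sequences = grid, probs = probs, posterior = posterior, model = model)
}

#' Decoy structures for the alignment pipeline
#'
#' Builds a synthetic reference with annotated active-site residues plus
#' two decoys under a random rigid transform: a positive decoy sharing the
#' site identities with local geometry perturbed by a known magnitude on a
#' scaffold with randomized identities and mildly perturbed coordinates,
#' and a negative decoy whose first site residue is mutated to an
#' amino-acid type absent from the whole decoy.
#'
#' @param seed optional seed.
#' @param L number of residues.
#' @param site_idx indices of annotated site residues (>= 2).
#' @param perturbation exact displacement magnitude applied to each site
#'   C-alpha of the positive decoy (Angstrom).
#' @param scaffold_sd coordinate noise applied to non-site residues
#'   (Angstrom).
#' @return list with `reference`, `positive`, `negative` (each a list of
#'   `coords` and `tokens`), `site` indices, and the injected
#'   `perturbation`.
#' @export
make_alignment_decoy <- function(seed = NULL, L = 80L,
                                 site_idx = c(20L, 40L, 60L),
                                 perturbation = 0.25, scaffold_sd = 0.08) {
  stopifnot(length(site_idx) >= 2L, all(site_idx <= L))
  .maybe_seed(seed)
  # self-avoiding-ish random chain, 3.8 A steps
  steps <- matrix(stats::rnorm(3 * (L - 1L)), L - 1L, 3L)
  steps <- 3.8 * steps / sqrt(rowSums(steps^2))
  ref_coords <- center_coords(rbind(0, apply(steps, 2L, cumsum)))
  trp <- match("W", aa_alphabet())
  site_types <- c(trp, sample(setdiff(1:20, trp), length(site_idx) - 1L, replace = TRUE))
  scaffold_pool <- setdiff(1:20, site_types)
  ref_tokens <- sample(scaffold_pool, L, replace = TRUE)
  ref_tokens[site_idx] <- site_types

  perturb <- function(mutate_site = FALSE) {
    x <- ref_coords + scaffold_sd * matrix(stats::rnorm(3 * L), L, 3L)
    for (i in site_idx) {
      d <- stats::rnorm(3)
      x[i, ] <- ref_coords[i, ] + perturbation * d / sqrt(sum(d^2))
    }
    tok <- sample(scaffold_pool, L, replace = TRUE)
    tok[site_idx] <- site_types
    if (mutate_site) tok[site_idx[1L]] <- scaffold_pool[1L]
    xf <- .random_rigid(x)
    list(coords = xf, tokens = tok)
  }
  list(reference = list(coords = ref_coords, tokens = ref_tokens),
       positive = perturb(FALSE),
       negative = perturb(TRUE),
       site = site_idx,
       perturbation = perturbation)
}

#' Fixture with site-conserved, distance-decaying identity
#'
#' A reference and a decoy with identical geometry whose residue
#' identities match only within a conservation radius of the site
#' centroid: the shell identity profile is non-increasing in radius by
#' construction.
#'
#' @param seed optional seed.
#' @param L number of residues.
#' @param site_idx annotated site indices.
#' @param keep_radius radius (Angstrom) within which identities are
#'   conserved.
#' @return list with `reference`, `decoy`, `site`.
#' @export
make_shell_fixture <- function(seed = NULL, L = 80L, site_idx = c(30L, 34L),
                               keep_radius = 8) {
  .maybe_seed(seed)
  steps <- matrix(stats::rnorm(3 * (L - 1L)), L - 1L, 3L)
  steps <- 3.8 * steps / sqrt(rowSums(steps^2))
  coords <- center_coords(rbind(0, apply(steps, 2L, cumsum)))
  tokens <- sample.int(20L, L, replace = TRUE)
  center <- colMeans(coords[site_idx, , drop = FALSE])
  d <- sqrt(rowSums(sweep(coords, 2L, center)^2))
  dec_tokens <- tokens
  far <- which(d > keep_radius)
  dec_tokens[far] <- ((tokens[far]) %% 20L) + 1L   # guaranteed different
  list(reference = list(coords = coords, tokens = tokens),
       decoy = list(coords = coords, tokens = dec_tokens),
       site = site_idx)
}

# random proper rotation + translation
.random_rigid <- function(x, translation_sd = 20) {
  M <- matrix(stats::rnorm(9), 3L, 3L)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  tr <- stats::rnorm(3, sd = translation_sd)
  sweep(x %*% R, 2L, tr, `+`)
}
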