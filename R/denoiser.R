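#' Denoiser configuration
#'
#' The joint denoiser is a diffusion-transformer: pre-norm attention + FFN
#' blocks with QK-norm and GeLU, adaLN-Zero conditioning (six modulation
#' vectors per block, two for the final layer) on a sinusoidal embedding
#' of the structural diffusion time, learned absolute position embeddings,
#' a learned 21-token sequence embedding, linear structure and motif
#' embeddings (no equivariance), an optional learned function-term table,
#' and two linear output heads (21-way logits and a 3-d clean-structure
#' prediction). Reference-scale configurations: 30 blocks with hidden
#' dimension 768 (unconditional) or 1024 plus an 8220-term table
#' (conditional), dropout 0.2, FFN expansion 4, heads of width 64.
#'
#' @param n_blocks number of transformer blocks.
#' @param hidden_dim model width d (divisible by `n_heads`).
#' @param ffn_ratio FFN expansion ratio.
#' @param n_heads attention heads (default d / 64, minimum 1).
#' @param dropout dropout rate applied to both residual branches during
#'   training.
#' @param vocab_size token vocabulary (21: 20 amino acids + mask).
#' @param n_function_terms size of the function-term embedding table; 0
#'   disables function conditioning.
#' @param max_length maximum sequence length (learned positions).
#' @param time_channels sinusoidal frequency channels of the time
#'   embedding MLP.
#' @return an object of class `denoiser_config`.
#' @export
denoiser_config <- function(n_blocks = 30L, hidden_dim = 768L, ffn_ratio = 4L,
                            n_heads = max(1L, hidden_dim %/% 64L),
                            dropout = 0.2, vocab_size = 21L,
                            n_function_terms = 0L, max_length = 512L,
                            time_channels = 256L) {
  stopifnot(n_blocks >= 1L, hidden_dim >= 8L, ffn_ratio >= 1L,
            hidden_dim %% n_heads == 0L, dropout >= 0, dropout < 1,
            vocab_size == 21L, n_function_terms >= 0L, max_length >= 1L,
            time_channels %% 2L == 0L)
  structure(list(n_blocks = as.integer(n_blocks),
                 hidden_dim = as.integer(hidden_dim),
                 ffn_ratio = as.integer(ffn_ratio),
                 n_heads = as.integer(n_heads),
                 dropout = dropout,
                 vocab_size = as.integer(vocab_size),
                 n_function_terms = as.integer(n_function_terms),
                 max_length = as.integer(max_length),
                 time_channels = as.integer(time_channels)),
            class = "denoiser_config")
}

#' @export
print.denoiser_config <- function(x, ...) {
  cat(sprintf(paste0("denoiser_config: %d blocks, d = %d, %d heads, ffn x%d, ",
                     "dropout %.2f, %d function terms, max length %d\n"),
              x$n_blocks, x$hidden_dim, x$n_heads, x$ffn_ratio, x$dropout,
              x$n_function_terms, x$max_length))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Build a denoiser model
#'
#' Allocates and initializes all trainable tensors. adaLN-Zero modulation
#' linears and both output heads start at exactly zero, so every block is
#' an identity residual at initialization.
#'
#' @param config a [denoiser_config()].
#' @param seed optional seed for the random initialization.
#' @param sched the [sigma_schedule()] the model is trained/sampled under
#'   (provides the data scale for input preconditioning).
#' @return an object of class `denoiser` (fields `config`, `params`,
#'   `sched`).
#' @export
build_denoiser <- function(config, seed = NULL, sched = sigma_schedule()) {
  stopifnot(inherits(config, "denoiser_config"))
  structure(list(config = config,
                 params = .init_params(config, seed),
                 sched = sched),
            class = "denoiser")
}

#' @export
print.denoiser <- function(x, ...) {
  cat("denoiser model\n")
  print(x$config)
  invisible(x)
}

#' Count trainable parameters
#'
#' Works on a built model (sums tensor sizes) or directly on a
#' configuration (sums the shape table the builder allocates from); the
#' two agree by construction.
#'
#' @param x a `denoiser` or `denoiser_config`.
#' @return total number of trainable scalar parameters.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "denoiser")) {
    return(sum(vapply(x$params, length, numeric(1))))
  }
  if (inherits(x, "denoiser_config")) {
    sh <- .denoiser_shapes(x)
    return(sum(vapply(sh, prod, numeric(1))))
  }
  stop("expected a denoiser or denoiser_config")
}

#' Motif specification for conditional scaffolding
#'
#' A set of residue positions with target C-alpha coordinates and
#' amino-acid identities. Coordinates are centered at embedding time, so
#' only the motif's internal geometry conditions the model.
#'
#' @param positions strictly increasing 1-based residue indices.
#' @param coords |positions| x 3 coordinates (Angstrom).
#' @param identities amino-acid tokens (1..20), same length as
#'   `positions`.
#' @return an object of class `motif_spec`.
#' @export
motif_spec <- function(positions, coords, identities) {
  positions <- as.integer(positions)
  identities <- as.integer(identities)
  coords <- as.matrix(coords)
  stopifnot(length(positions) == nrow(coords), ncol(coords) == 3L,
            length(identities) == length(positions),
            all(identities >= 1L, identities <= 20L))
  if (length(positions) > 1L && any(diff(positions) <= 0L)) {
    stop("motif positions must be strictly increasing")
  }
  structure(list(positions = positions, coords = coords,
                 identities = identities),
            class = "motif_spec")
}

#' Single denoiser forward pass
#'
#' Joint evaluation on a (possibly masked) sequence and (possibly noisy)
#' structure. Coordinates are re-centered and preconditioned by
#' 1/sqrt(t_struct^2 + t_data^2) before the linear embedding, so the call
#' is invariant to rigid translations of the input. Absent motif or term
#' use the null conditioning (required by classifier-free guidance and by
#' the unconditional branch of coupled sampling). The sequence noise level
#' is implicit in the mask pattern; only the structural time is embedded.
#'
#' @param model a `denoiser`.
#' @param tokens length-L token vector (21 = mask) or `sequence_state`.
#' @param coords L x 3 coordinates or `structure_state`.
#' @param t_seq sequence diffusion time in [0, 1] (carried for protocol
#'   bookkeeping).
#' @param t_struct structural noise level (Angstrom).
#' @param motif optional [motif_spec()].
#' @param term optional function-term id.
#' @param train enable dropout (training mode).
#' @param want_cache keep the activation cache for backprop (internal).
#' @return list with `logits` (L x 21) and `structure_pred` (L x 3 raw
#'   prediction).
#' @export
denoise <- function(model, tokens, coords, t_seq, t_struct, motif = NULL,
                    term = NULL, train = FALSE, want_cache = FALSE) {
  stopifnot(inherits(model, "denoiser"))
  input <- .prepare_input(model$sched, tokens, coords, t_seq, t_struct,
                          motif, term)
  .denoiser_forward(model$params, model$config, input, train = train,
                    want_cache = want_cache)
}

# preprocessing shared by denoise() and the trainer: centering, EDM input
# preconditioning, warped-time computation, motif normalization
.prepare_input <- function(sched, tokens, coords, t_seq, t_struct,
                           motif = NULL, term = NULL) {
  tokens <- .tokens_of(tokens)
  coords <- .coords_of(coords)
  if (nrow(coords) != length(tokens)) stop("sequence/structure length mismatch")
  t_struct <- min(max(t_struct, sched$t_min), sched$t_max)
  c_in <- 1 / sqrt(t_struct^2 + sched$t_data^2)
  m <- NULL
  if (!is.null(motif) && length(motif$positions) > 0L) {
    if (any(motif$positions > length(tokens))) stop("motif positions out of range")
    m <- list(positions = motif$positions,
              coords = center_coords(motif$coords) / sched$t_data,
              tokens = motif$identities)
  }
  list(tokens = tokens, X = center_coords(coords) * c_in,
       tp = rescale_time(t_struct, sched),
       motif = m, term = term, t_seq = t_seq)
}

#' Save / load a denoiser checkpoint
#'
#' Single-file archive (RDS) with a version field and the configuration
#' embedded, so a checkpoint is self-describing.
#'
#' @param model a `denoiser`.
#' @param path file path.
#' @return `load_denoiser()` returns the restored `denoiser`.
#' @export
save_denoiser <- function(model, path) {
  stopifnot(inherits(model, "denoiser"))
  saveRDS(list(format = "codiffuse-denoiser", version = 1L,
               config = unclass(model$config), sched = unclass(model$sched),
               params = model$params),
          path)
  invisible(path)
}

#' @rdname save_denoiser
#' @export
load_denoiser <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "codiffuse-denoiser")) {
    stop("not a denoiser checkpoint")
  }
  structure(list(config = do.call(denoiser_config, obj$config[
                   setdiff(names(obj$config), character(0))]),
                 params = obj$params,
                 sched = do.call(sigma_schedule, obj$sched)),
            class = "denoiser")
}
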