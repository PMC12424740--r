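# Lazily trained toy model shared across test files. Training happens at
# most once per test run; the trained fit (model, EMA model, loss history)
# and the family spec are cached in the package namespace session.

.toy_cache <- new.env(parent = emptyenv())

toy_family <- function() {
  toy_family_spec(length = 32, noise_sd = 0.05, two_state = TRUE)
}

# self-consistency against either conformer of the two-state family
toy_self_consistency2 <- function(tokens, coords, spec, threshold = 2.0) {
  tokens <- if (inherits(tokens, "sequence_state")) tokens$tokens else tokens
  if (!all(tokens %in% spec$classes$token)) {
    return(structure(FALSE, rmsd = NA_real_))
  }
  cc <- if (inherits(coords, "structure_state")) coords$coords else coords
  cc <- sweep(cc, 2, colMeans(cc))
  r <- min(
    kabsch_superpose(decode_structure(tokens, spec, 1), cc)$backbone_rmsd,
    kabsch_superpose(decode_structure(tokens, spec, 2), cc)$backbone_rmsd)
  structure(r < threshold, rmsd = r)
}

get_toy_fit <- function() {
  if (!is.null(.toy_cache$fit)) return(.toy_cache$fit)
  spec <- toy_family()
  set.seed(41)
  seqs <- lapply(1:256, function(i) make_toy_protein(spec))
  dataset <- unlist(lapply(seqs, function(p) list(
    list(tokens = p$sequence$tokens, coords = p$structure$coords),
    list(tokens = p$sequence$tokens, coords = p$structure2$coords))),
    recursive = FALSE)
  model <- build_denoiser(denoiser_config(n_blocks = 4L, hidden_dim = 64L,
                                          n_heads = 4L, dropout = 0,
                                          max_length = 64L), seed = 42)
  fit <- train_denoiser(model, dataset, steps = 2500L, batch_size = 16L,
                        lr = 4e-3, lr_decay = "cosine", clip_norm = 1,
                        seed = 43)
  .toy_cache$fit <- fit
  fit
}

# sampling uses the trained weights: at this horizon the EMA window spans
# half the run (see the methods vignette)
get_toy_model <- function() get_toy_fit()$model

# aligned RMSD of a structure's residues at the motif positions against the
# motif's own (centred) geometry
motif_region_rmsd <- function(coords, motif) {
  cc <- if (inherits(coords, "structure_state")) coords$coords else coords
  kabsch_superpose(sweep(cc, 2, colMeans(cc))[motif$positions, , drop = FALSE],
                   sweep(motif$coords, 2, colMeans(motif$coords)))$backbone_rmsd
}
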