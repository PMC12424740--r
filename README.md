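# codiffuse

Joint generative modelling of protein sequence and C-alpha backbone
structure with two coupled diffusion processes and one transformer
denoiser, in pure R.

Protein designers usually pick one modality: structure diffusion models
generate backbones but need a separate inverse-folding step and hand-crafted
functional specifications, while protein language models generate sequences
but cannot natively reason about geometry. `codiffuse` implements the
multimodal alternative: Gaussian score-based diffusion acting directly on
zero-centred C-alpha coordinates together with masked (absorbing-state)
discrete diffusion on the amino-acid string, denoised jointly by a single
diffusion-transformer whose two noise levels move independently. One model
then supports sequence generation, structure generation, sequence-structure
co-generation, inverse folding, motif scaffolding, classifier-free guidance
on categorical function labels, and a coupled two-trajectory sampling
protocol for designing multistate (e.g. allosterically switchable) proteins.

## The model in brief

**Continuous branch.** Forward kernel `N(x_t; x_0, t^2 I)` with
`t in [0.05, 160]` Angstrom, warped time
`t' = (t^(1/p) - t_min^(1/p)) / (t_max^(1/p) - t_min^(1/p))`, `p = 7`.
The network output `f(x, t)` is post-conditioned into a score
(`t_data = 15` Angstrom):

    s(x, t) = [ t t_data / sqrt(t_data^2 + t^2) f - t^2 / (t_data^2 + t^2) x ] / t^2

and generation integrates the reverse SDE
`dx = (g^2/2)(1 + beta(t)) s dt + g sqrt(beta(t) gamma) dw` with
`g = sqrt(2 t)`, `beta(t) = 1 / (1 + (t / t_data)^nu)`, `gamma = 0.5`.

**Discrete branch.** Linear survival `alpha_t = 1 - t`; the exact reverse
posterior fills masked positions from the predicted clean-token
distribution; unconditional sampling uses Gumbel top-k path planning
(unmask the `k = L - round(sL)` most confident positions, allow re-masking)
and inverse folding unmasks one position per step at temperature 0.1.

**Denoiser.** A DiT-style transformer: pre-norm blocks, QK-norm, GeLU,
adaLN-Zero conditioning on the sinusoidal embedding of the structural time,
learned token/position embeddings, linear structure and motif embeddings,
an optional function-term table, and two linear heads (21-way logits,
3-d structure prediction). At reference scale the conventions give 321M
trainable parameters (30 blocks, d = 768) and 579M (d = 1024 plus an
8220-term table).

**Multistate design.** Two structure trajectories, each conditioned on its
own motif, share one sequence trajectory advanced with product-of-experts
logits `phi_1 + phi_2 - phi_uncond`; motif residues are clamped verbatim.

There is no deep-learning framework underneath: the forward pass,
reverse-mode backprop, and Adam are implemented in base-R matrix algebra
and verified against finite differences, which keeps the whole stack
installable from this package alone and trainable at toy scale on a CPU.

## Worked example

Train a tiny denoiser on the built-in toy sequence-structure family (a
deterministic class-geometry code with an exact decoder; here the
two-conformation variant), then co-generate a sequence-structure pair and
score it against the decoder oracle (about 13 minutes on one CPU):

```r
library(codiffuse)

spec <- toy_family_spec(length = 32, noise_sd = 0.05, two_state = TRUE)
set.seed(41)
seqs <- lapply(1:256, function(i) make_toy_protein(spec))
dataset <- unlist(lapply(seqs, function(p) list(
  list(tokens = p$sequence$tokens, coords = p$structure$coords),
  list(tokens = p$sequence$tokens, coords = p$structure2$coords))),
  recursive = FALSE)

model <- build_denoiser(
  denoiser_config(n_blocks = 4, hidden_dim = 64, n_heads = 4,
                  dropout = 0, max_length = 64), seed = 42)
fit <- train_denoiser(model, dataset, steps = 2500, batch_size = 16,
                      lr = 4e-3, lr_decay = "cosine", clip_norm = 1,
                      seed = 43)
round(c(first = mean(fit$history[1:100]),
        last = mean(tail(fit$history, 100))), 3)
#> first  last
#> 2.652 1.231

g <- cogenerate(fit$model, L = 32, n_steps = 64, seed = 7)
tokens_to_string(g$sequence$tokens)
#> [1] "AVGAGAGVAAVGAGGVAGVGAAVAVGAVGVGA"
ok <- toy_self_consistency(g$sequence$tokens, g$structure$coords, spec)
round(attr(ok, "rmsd"), 2)  # aligned C-alpha RMSD to the decoded sequence
#> [1] 2.59

s <- inverse_fold(fit$model, decode_structure(dataset[[1]]$tokens, spec),
                  seed = 8)
mean(s$tokens == dataset[[1]]$tokens)   # inverse-folding token accuracy
#> [1] 0.9375
```

The combined loss halves; the emitted sequence stays inside the family
alphabet; and the inverse-folding pathway recovers ~94% of residues from
geometry alone. The co-generation self-consistency RMSD compares the
emitted backbone with the structure decoded from the emitted sequence:
below the 2 Angstrom toy threshold the pair is fully coherent. At this
13-minute training scale typical draws land at 2-3.5 Angstrom with a few
percent fully coherent (a random sequence paired with the same backbone
sits at 4-5 Angstrom and never passes); the methods vignette discusses
what desk-scale training does and does not establish.
Sampling-protocol wrappers (`generate_sequence()`, `generate_structure()`,
`inverse_fold()`, `coupled_sample()`), the evaluation pipeline
(`active_site_align()`, `shell_metrics()`), PDB/FASTA/OBO I/O, and a thin
command-line interface (`inst/scripts/codiffuse`) round out the package;
see the methods vignette (`vignettes/codiffuse-methods.Rmd`) for the full
account of the model and the design decisions.

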