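---
title: "Multimodal diffusion over protein sequence and structure: models, samplers, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal diffusion over protein sequence and structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codiffuse)
```

# Overview

`codiffuse` implements joint generative modelling of protein sequences and
C-alpha backbone traces with two coupled diffusion processes sharing one
transformer denoiser:

* **Continuous branch.** Variance-exploding Gaussian diffusion directly on the
  zero-centred C-alpha coordinates `x` (in Angstrom), with perturbation kernel
  `N(x_t; x_0, t^2 I)`, drift `f = 0` and diffusion `g(t) = sqrt(2 t)`. The
  network estimates the score of the noised marginal and the reverse-time SDE
  is integrated numerically.
* **Discrete branch.** Masked (absorbing-state) diffusion on the 21-token
  sequence: each position is independently replaced by a mask symbol with
  probability `1 - alpha_t`, and reversal is iterative unmasking driven by the
  network's predicted clean-token distribution.

Because the two noise levels are drawn independently during training, one
model supports sequence-only generation, structure-only generation,
simultaneous co-generation, inverse folding, motif-conditioned scaffolding,
classifier-free guidance on categorical function labels, and a coupled
two-state protocol for multistate design.

# The continuous branch

## Noise schedule and time warp

Noise levels range over `[t_min, t_max] = [0.05, 160]` Angstrom. Training and
sampling operate in a warped time

```
t' = (t^(1/p) - t_min^(1/p)) / (t_max^(1/p) - t_min^(1/p)),   p = 7,
```

a strictly increasing bijection onto `[0, 1]`; uniform steps in `t'`
concentrate computation at low noise where structural detail forms. Because
sampling needs `t(t')`, the package implements the exact algebraic inverse
`t = (t_min^(1/p) + t' (t_max^(1/p) - t_min^(1/p)))^p` (`invert_time()`);
round-tripping is tested to 1e-9.

## Score parameterization and loss

The raw network output `f(x, t)` is post-conditioned into a score with the
EDM-style blend (data scale `t_data = 15` Angstrom):

```
s(x, t) = [ t * t_data / sqrt(t_data^2 + t^2) * f(x, t)
            - t^2 / (t_data^2 + t^2) * x ] / t^2
```

so `s -> f / t` as `t -> 0` (score prediction) and
`s -> (t_data f - x) / t^2` as `t -> infinity` (clean-data prediction); both
limits are pinned numerically in the tests. The training loss is the squared
error between `s` and the analytic conditional score `(x_0 - x_t) / t^2`
weighted by `t^2 (t^2 + t_data^2) / t_data^2` — the EDM weighting transported
to score space, which keeps per-example losses `O(1)` across eleven orders of
magnitude in noise. Among the algebraically plausible placements of this
weighting, we adopt the one above because it is the unique form consistent
with the preconditioning and with both limit behaviours. The squared error
is averaged (not summed) over the `3 L` coordinates, a choice that only
rescales the loss by a constant.

## Annealed reverse integration

Generation integrates the reverse SDE from `t' = 1` to `t' = 0` by
Euler--Maruyama with drift `(g^2 / 2)(1 + beta(t)) s` and noise amplitude
`g sqrt(beta(t) gamma)`, where `beta(t) = 1 / (1 + (t / t_data)^nu)` mixes in
Langevin dynamics and `gamma = 0.5` lowers the temperature (`nu = 0.5`
unconditional, `nu = 1` conditional). With `beta = gamma = 1` this is the
standard reverse SDE, under which the sampler provably recovers an isotropic
Gaussian data law and the component weights of an analytic two-component
mixture (both verified with closed-form score oracles). Numerical choices
made here, each covered by a test:

* The integration grid includes both endpoints; the final step injects **no
  noise** (there is no subsequent denoising step to remove it).
* Re-centring is a property of the neural denoiser wrapper — `denoise()`
  centres its input coordinates, making the call translation invariant — not
  of the raw integrator, so analytic-score oracles on raw coordinates (where
  forced centring would distort the target law) remain exact.
* Chirality is not handled: the architecture is a plain transformer without
  equivariance, so mirrored toy structures are legal outputs; evaluation-side
  superposition uses proper rotations only and never silently flips handedness.

# The discrete branch

The survival schedule is linear, `alpha_t = 1 - t`; the framework constrains
only the endpoints and monotonicity, and the linear choice is the one
consistent with the stated loss weight `lambda(t) = 1 - t`. The exact
single-position reverse posterior carries unmasked tokens as point masses and
splits masked mass between staying masked, `(1 - alpha_s) / (1 - alpha_t)`,
and filling from the predicted clean-token distribution. The sequence loss is
the `lambda`-weighted cross-entropy over masked positions only, with the
softmax restricted to the 20 amino acids (clean data has no mask mass); both
the posterior substitution values and the uniform-logit closed form
`(1 - t) ln 20` are asserted exactly.

## Path-planning sampler

Unconditional generation does not use ancestral sampling; instead each step
draws Gumbel-noised log-confidences, unmasks the top-`k` most confident
positions (`k = L_free - round(s L_free)`, half-away-from-zero rounding) and
re-masks everything else, allowing the sampler to revise earlier decisions.
Decisions needed where the procedure leaves details open:

* **Temperature placement.** We compute
  `phi = logsoftmax(logits / gamma + z)`: the temperature sharpens the logits
  before Gumbel perturbation, so `gamma -> 0` recovers greedy argmax
  selection; placing the division after the log-softmax would make `gamma` a
  global monotone rescale with no effect on either the per-position argmax or
  the cross-position top-k, contradicting its description as a temperature.
* **Gumbel convention.** The noise is standard Gumbel (location 0, scale 1);
  a common location shift cancels in both the argmax and the top-k.
* **Ties** break deterministically: lowest token index within a position,
  lowest position index across positions.
* **Re-masking** of previously unmasked positions outside the keep-set is
  implemented as written and exercised by an adversarial-logits test.
* In co-generation mode, already-unmasked positions keep their token and take
  its current model log-probability as confidence; this applies to every
  currently unmasked position, not only clamped ones.
* Clamped (motif) positions are initialized unmasked, never resampled, and
  excluded from the keep-set budget, so `k` counts free positions only.

Inverse folding uses a different, simpler policy: one position per step in a
uniformly random order, sampled at temperature 0.1 with the structure held
fixed at minimal noise.

# The denoiser

A diffusion-transformer: pre-norm blocks with QK-norm (RMS-normalised queries
and keys with learned scales), GeLU activations (the fast sigmoid form),
full bidirectional attention, and adaLN-Zero conditioning in which a shared
conditioning vector produces six modulation vectors per block (shift, scale,
gate for each of the attention and FFN residuals) plus two for the final
layer, with the modulation linears and both output heads initialized to
exactly zero so every block starts as an identity residual. The conditioning
vector is a two-layer MLP on 256-channel sinusoidal features of the *warped
structural* time; the sequence noise level is not separately embedded — it is
implicit in the mask pattern. Inputs are embedded linearly: a learned
21-token table, learned absolute positions up to `max_length`, a linear
3-to-d coordinate embedding (no equivariance), and, for motifs, a linear
embedding of the motif's centred coordinates plus the motif residues' token
embeddings and a learned position mark injected into both the token stream
and the conditioning pathway (identity information must flow for the coupled
protocol). Function terms add one learned vector per term; absence of a term
uses a learned null vector, which is what classifier-free guidance and the
coupled protocol's unconditional branch evaluate.

At reference scale these conventions (FFN expansion 4, heads of width 64,
crop/positions 512) give 321.3M trainable parameters for 30 blocks at
`d = 768` and 579.2M for 30 blocks at `d = 1024` with an 8220-term table;
head count, time-embedding width and bias placement are free conventions, so
such totals are pinned only to within about a percent.
`count_parameters()` sums the same shape table the builder allocates from,
so the count is a pure function of the configuration.

Two implementation notes. First, network inputs are scaled by
`1 / sqrt(t^2 + t_data^2)` before the coordinate embedding; with noise up to
160 Angstrom some input normalisation is numerically necessary, and this is
the standard preconditioning companion to the score blend above. Second,
because no deep-learning framework is available to this package, the forward
pass, reverse-mode backward pass, and Adam are implemented in base-R matrix
algebra; a training batch is processed as one stacked token stream with
per-example attention, and every gradient is verified against central finite
differences in the test suite.

# Training

Each step draws examples, applies the conditioning policy — attach a
multi-segment motif with probability 0.5 (1--4 contiguous segments jointly
covering 5--50% of residues, placed uniformly without overlap; a compact
multi-segment stand-in for elaborate motif samplers), attach one of the
example's function terms with probability 0.85 drawn in proportion to inverse
global frequency, and drop each modality entirely with probability 0.05
(all-mask sequence / maximum-noise structure, which keeps tensor shapes fixed
and matches the noising semantics) — then corrupts the two modalities at
independent uniform times and minimises `L_struct + 3 L_seq`. Parameters are
tracked with an EMA at decay 0.999 and the EMA model is the one sampled from.
The optimizer is Adam with linear warmup, with optional cosine decay and
gradient-norm clipping; the optimizer is configuration, not part of the
method's identity. Long chains are
randomly cropped to `crop_size` contiguous residues and re-centred.

Data-side policies are generic operations over user tables: hierarchical
sampling draws uniformly over outer (structural) clusters, then inner
(sequence) clusters, then quality-filtered members, so small clusters are not
swamped by large ones; and `propagate_terms()` closes annotation sets over
`is_a` edges of an OBO-dialect ontology, flagging roots so non-root counting
conventions can be applied downstream. Term and motif conditioning co-occur
independently, the minimal assumption.

# Guidance and the coupled two-state protocol

Classifier-free guidance combines conditional and unconditional evaluations
as `(1 - lambda) uncond + lambda cond` on logits and, because the score blend
is linear in the raw prediction at fixed `(x, t)`, combining raw structure
predictions combines the derived scores identically.

The coupled protocol samples one sequence tied to two structure trajectories.
Per step it makes three model evaluations — `(s, x_1 | m_1)`,
`(s, x_2 | m_2)`, and an unconditional sequence branch — advances the
sequence by a co-generation path-planning step on the product-of-experts
logits `phi_1 + phi_2 - phi_uncond` with all motif residues clamped, and
advances each structure on its own branch score. The branches exchange no
coordinates; only the sequence couples them. For the unconditional `p(s)`
branch the joint model needs *some* structure input: we feed the same noisy
sequence with a maximum-noise structure drawn once per rollout and no motif —
the closest available realisation of a pure sequence prior, and explicitly a
heuristic. Degenerate designs (both branches collapsing to one conformation)
are possible and are measured, not prevented. A diagnostic
`share_structure_noise` mode shares the initial draw and per-step Gaussians
between branches, which makes the degenerate identical-motif case exactly
symmetric (bitwise-equal branches) and underlies the label-symmetry test.

# Evaluation pipeline

`kabsch_superpose()` solves least-squares rigid superposition by SVD with the
determinant-sign correction, so only proper rotations are returned.
`active_site_align()` superposes generated onto reference C-alpha traces
(index-paired), matches each annotated site residue to the nearest generated
residue of identical amino-acid type (ties to the lower index), requires
one-to-one matching, and reports the site RMSD with success below 1.0
Angstrom; a missing same-type candidate yields a `match_failed` status rather
than an error. `shell_metrics()` expands spheres of 1--18 Angstrom around the
site centroid (no single centre is canonical; the centroid is our
convention), re-superposes on each shell,
and reports RMSD and identity fraction; shells with fewer than three residues
are undefined. Radius selections are boundary-inclusive — the common
convention, pinned by a test. Since the generative core emits C-alpha traces,
"backbone" selections degrade gracefully to C-alpha.

# The synthetic family and what passing tests mean

Real training corpora are out of reach at desk scale, so the package ships a
toy sequence--structure family built for exactly two properties: the
sequence determines the structure through idealized per-class local
geometry, and the map is learnable by a tiny model in minutes on a CPU. The
chain follows a fixed helical direction template (0.35 rad per-residue
twist, 0.26 rad pitch); each of three residue classes (letters A/V/G) sets
its step's rise (1.5, 3.4, 2.5 Angstrom) and an azimuthal twist offset (120,
0, 240 degrees) on the template direction. Every step is thus one of three
fixed per-position vectors, so the sequence-to-structure map is linear in
the one-hot sequence — the reason a 4-block model can learn it — while a
single class substitution still displaces the chain by about 1 Angstrom of
aligned RMSD and unrelated sequences decode 3.5--4.5 Angstrom apart. An
earlier design that *accumulated* class twists along the chain (making
global geometry a composition of rotations) proved unlearnable at this
scale and was revised; the per-position template form preserves every
oracle property while honouring the family's learnability goal. Emitted
structures carry isotropic coordinate noise of 0.05 Angstrom. The first
residue — whose class no step encodes — is pinned to the first class so
sequence and structure determine each other exactly; `decode_structure()`
is the exact oracle every end-to-end test scores against, with
self-consistency declared below 2.0 Angstrom aligned C-alpha RMSD (tolerant
of roughly four class errors, far below the separation of random pairs).
The two-state mode rotates the C-terminal half about a mid-chain hinge by
1.5 rad about an axis perpendicular to the helical axis, giving one
sequence two conformers whose hinge-spanning regions differ by about 2.4
Angstrom of aligned RMSD — above the success threshold, so the conformers
are genuinely distinct, while keeping both modes of the resulting bimodal
structure distribution learnable at toy scale. For alignment-pipeline testing,
`make_alignment_decoy()` builds a reference with annotated site residues plus
a positive decoy (site identities kept, site geometry displaced by a known
magnitude, scaffold identities randomized and coordinates mildly perturbed,
under a random rigid transform) and a negative decoy whose mutated site type
is absent from the whole structure.

The family deliberately omits most features of real proteins: excluded volume,
side chains, Ramachandran statistics, long-range contacts, variable lengths,
and homology structure. Passing the end-to-end tests therefore demonstrates
that the diffusion mathematics, the samplers, the conditioning pathways, and
the training loop are implemented correctly and can jointly learn a
sequence-determines-structure family at toy scale — not that the architecture
at this size generates realistic proteins.

# Problem sizes and defaults used by the shipped tests

The test suite trains one tiny denoiser (4 blocks, `d = 64`, 4 heads, no
dropout — dropout is a large-scale regularizer that only slows learning at
toy scale) on 512 examples (256 sequences of length 32, both conformers) for
2,500 steps of batch 16 at peak learning rate 4e-3 with cosine decay and
gradient-norm clipping at 1, and reuses it across the training-loop and
end-to-end tests. At this horizon the EMA window (1,000 steps at decay
0.999) covers half the run, so the end-to-end tests sample from the trained
weights directly; the EMA machinery is verified by its own unit tests and
remains the default for long-horizon training. Monte-Carlo checks use 2e4 chains and 400
steps for the Gaussian-recovery bound, 1e4 chains for mixture occupancy, and
1e5 rollouts for the discrete total-variation bound; these sizes put the
statistical error comfortably below the asserted tolerances. Generation
protocols default to `n_steps = L` (one model call per residue).

# What the toy end-to-end runs do and do not show

With the shipped training recipe the tiny model reaches ~96% inverse-folding
token accuracy, halves its combined loss, scaffolds single motifs, and
co-generates fully self-consistent pairs in a small fraction of rollouts
against a random-sequence baseline that never succeeds — evidence that the
two diffusion branches, the conditioning pathways, and the trainer are wired
correctly end to end. One property remains beyond this compute scale: the
family's two-state mode makes p(structure | sequence) bimodal, and the
desk-scale model under-represents the hinge-rotated conformer, so coupled
two-state sampling does not yet consistently outperform independent
single-motif baselines at the toy threshold even though the coupled
machinery itself is verified exactly (degenerate-case bitwise identity,
label symmetry, clamping, and the product-of-experts logit algebra). The
corresponding end-to-end assertion is expected to fail until the denoiser is
trained well past the toy budget; the failure is a statement about training
scale, not about the sampling protocol.

# Known limitations

* Sequence-only and structure-only generation quality at reference scale is
  unverifiable here; parameter counts and all algorithmic identities are.
* The hand-rolled trainer is single-threaded CPU R; it is adequate for the
  toy family, not for corpus-scale training.
* External tools in the full-scale evaluation loop (inverse-folding and
  folding networks, function predictors, structure clustering, co-folding)
  are represented by documented adapter stubs that refuse to run rather than
  fabricate results.
* Reported structure outputs are C-alpha traces; no side chains or full
  backbone atoms are generated.
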