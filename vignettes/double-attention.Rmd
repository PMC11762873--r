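---
title: "Double Attention: model, audits, and the cross-window benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double Attention: model, audits, and the cross-window benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dattn)
```

## The model

Window-based multi-head self-attention (W-MSA) partitions an $h \times w$
token grid into non-overlapping $M \times M$ windows and computes, per window
and head,

$$A = \mathrm{softmax}\!\left(\frac{Q K^\top}{\sqrt{d_k}}\right), \qquad
  Z = A V,$$

which reduces the quadratic token cost of global attention,
$\Omega(\mathrm{MSA}) = 4hwC^2 + 2(hw)^2C$, to
$\Omega(\text{W-MSA}) = 4hwC^2 + 2M^2hwC$. The price is that no information
crosses a window boundary; the usual remedy is to alternate layers that
cyclically shift the grid before re-windowing.

Double Attention (DA) removes the alternation. Each attention layer projects
a *second* Key matrix $K_2$ from a cyclically shifted copy of its input map
and fuses the two score terms before the softmax:

$$A_{\mathrm{DA}} = \mathrm{softmax}\!\left(\frac{Q K_1^\top}{\sqrt{d_k}} +
  \frac{Q K_2^\top}{\sqrt{d_k}}\right).$$

Because $K_2$ carries neighbouring windows' content into each window, every
layer sees cross-window correlations in a single pass. The cost becomes
$\Omega(\mathrm{DA}) = 5hwC^2 + 3M^2hwC$ — one extra projection and one
extra windowed matrix product. The ablation DA-N projects $K_2$ from the
*unshifted* map: identical parameter count and cost, extra width, but no
cross-window flow; it isolates whether a gain comes from width or from the
shift.

Two consequences of Eq. above are worth stating because the package's tests
are built around them:

* **Reduction.** With $W_{K_2} \equiv 0$ the second score term vanishes and a
  DA layer is *bit-identical* to a W-MSA layer with the same remaining
  weights. This is an exact, not approximate, identity and is tested as such.
* **Dual gradient path.** The score sum feeds $Q$ through both Key terms, so
  $\partial L/\partial Q$ aggregates a $K_1$-path and a $K_2$-path and stays
  nonzero when either path alone is blocked. The package verifies this
  numerically (below) rather than by re-deriving backward formulas.

A further structural point that the benchmark design (below) depends on: DA
moves *scores*, not *values*, across windows. The attention output is still a
convex combination of the window's own Value vectors; neighbouring content
influences only the combination weights. Cross-window information therefore
enters the representation multiplicatively — through Query–Key2 products —
not additively.

## The backbone

The four-stage hierarchy follows the standard window-transformer recipe:
$4\times4$ patch embedding to $C$ channels, then stages of pre-norm residual
blocks (`x + Attn(LN(x))` followed by `x + MLP(LN(x))`, GELU MLP of ratio 4),
with a $2\times2$ patch-merging (concatenate to $4C$, LayerNorm, bias-free
projection to $2C$) between stages, a final LayerNorm, global average
pooling, and a linear head. The "Tiny" configuration is embed dim 96, depths
(2, 2, 6, 2), heads (3, 6, 12, 24), window 7, 224×224 input. Every block in
every stage uses the configured attention variant; there is no alternating
shifted-window layer anywhere — the stated design replaces that mechanism
entirely with the $K_2$ pathway, so we interpret "not applied after the
first usage" as *no* shifted-window blocks rather than one initial one.

Choices the architecture description leaves open, fixed here:

* **Shift magnitude and source.** The cyclic shift is $\lfloor M/2 \rfloor$
  tokens in both axes (the window-transformer convention), applied to each
  attention layer's *input feature map*, not once to the raw image — after
  patch merging "the image" no longer exists at the layer's resolution.
* **No mask for wrapped regions.** Unlike alternating shifted-window
  attention, wrap-around Query–Key2 pairs are not masked: cross-window
  mixing is the purpose of $K_2$, not an artefact to suppress.
* **K2 projection.** A separate learnable $C \times C$ matrix plus bias per
  attention layer. Summed over the Tiny depths this adds
  $\sum_\ell (C_\ell^2 + C_\ell) = 2{,}160{,}960$ parameters, which is
  exactly the gap between the published 27.7 M and 29.8 M figures — the
  arithmetic that pins this interpretation down.
* **Relative-position bias.** One $(2M-1)^2 \times \text{heads}$ table per
  block, added to the *summed* pre-softmax score. Its ≈23 K parameters sit
  below the 0.1 M print precision, so the published tables cannot adjudicate
  its presence; it is exposed as `use_relpos` and on by default.
* **Initialisation.** Truncated normal (sd 0.02, clipped at 2 sd) for
  projections, zeros for biases, seeded. The draw order is
  variant-independent ($K_2$ weights are always drawn, then discarded for
  W-MSA), so models of different variants built from one seed share
  bit-identical common weights — the controlled-comparison setup.
* **Stochastic depth / dropout** default to 0 and are exposed in the config.

## Complexity audits

`count_params()` sums learnable scalars from layer shapes alone and is
cross-checked against instantiated models. Per window-attention block it is
$12C^2 + 13C + (2M-1)^2 n_{\text{heads}}$, plus $C^2 + C$ for DA/DA-N.

`count_flops()` counts multiply–accumulates for one input under two named
conventions. `projections-only` counts every learned projection (patch
embed, Q/K1/K2/V, output projections, MLPs, mergings, head) and excludes the
attention matrix products $QK^\top$ and $AV$ — this is what the common
network profilers report when those products are functional ops they do not
trace, and it is the convention under which the audit lands exactly on the
published 4.4 G (W-MSA) and 4.7 G (DA) at 224²: 4,350,425,088 and
4,697,241,600 MACs. `eq78` adds the windowed matrix products ($2M^2hwC$ per
W-MSA block, $3M^2hwC$ per DA block) and is reported alongside so the
convention is auditable rather than buried. Two details matter at the
printed precision:

* The figures are backbone-level audits with the standard 1000-class
  reference head (the package default). With a 200-class task head the
  W-MSA count is 4,349,810,688 MACs, which rounds to 4.3 G; the published
  tables print identical FLOPs columns across datasets with head sizes from
  37 to 200, consistent with a single reference-head audit.
* Rounding is half-away-from-zero at one decimal on the G/M scale;
  normalisations, activations, softmax and biases count zero MACs.

All audit arithmetic is plain-double integer arithmetic kept below $2^{53}$,
with a guard that errors rather than silently losing exactness.

## Gradient verification

There is no automatic differentiation in this environment, so every layer's
backward pass is written by hand — and correspondingly every one is checked
against central finite differences. `gradcheck()` perturbs each parameter
entry of seeded score/attention cases ($\varepsilon \in [10^{-6}, 10^{-3}]$,
default $10^{-4}$) and reports the maximum relative deviation
$|a - n| / (|a| + \varepsilon)$; an `identity` hook removes the softmax so
the multilinear remainder must agree to rounding error ($<10^{-8}$). The
dual gradient path is confirmed operationally: zeroing the $K_1$ projection
(blocking that path) leaves $\partial L/\partial W_Q$ nonzero through $K_2$,
and vice versa. The training-side counterpart is the optimizer contract: the
`sgd` optimizer is the literal per-parameter update
$\theta_{t+1} = \theta_t - \eta\, \partial L/\partial \theta$, tested against
the closed form; `adamw` (decoupled decay, optional cosine schedule with 10%
warmup) is the practical default.

## The cross-window benchmark

The synthetic task exists to make cross-window information flow *necessary*,
not merely helpful. Each grayscale image carries two $5\times5$ oriented
motifs (diagonal vs anti-diagonal bar) in horizontally adjacent attention
windows; the class is 1 iff the orientations match. Each motif's own
orientation is uniform and independent of the label, so *no single window
carries any class information* — a probe classifier restricted to one
window's pixels sits at chance (tested with a logistic probe that
simultaneously decodes the motif's orientation from the same pixels at
>90%). Labels are balanced to within one; pixel noise is additive Gaussian
(sd 0.1 by default), clipped to $[0,1]$; generation is integer-lattice
stamping plus seeded noise, hence bit-reproducible.

The stamp geometry is aligned with the mechanism under test: the right motif
is displaced from the left one by exactly `shift_px` — the consumer model's
cyclic-shift magnitude in pixels ($\lfloor M/2\rfloor \times$ patch size; 12
for the default 56×56 geometry) — so the shift maps one motif onto the
other's token positions and the $QK_2^\top$ term compares the two
orientations directly. An earlier draft stamped the motifs at unrelated
positions; the class signal was then reachable only through higher-order
interactions and no desk-scale budget learned it. Aligning the stamp with
the shift is a design decision of the generator, made to instantiate the
stated dependency structure as directly as possible, and it does not weaken
the control: window-local undecodability is unchanged.

What the generator does *not* emulate: texture, scale variation, class
imbalance, label noise, or anything resembling medical image statistics.
Passing the benchmark shows that the cross-window mechanism works and that
the training loop can exploit it; it says nothing about accuracy on real
images.

The `blob` task (class = intensity of a centred disk, linearly separable by
a global mean threshold at zero noise) is a smoke test for the training
harness with no cross-window structure.

## Training protocol and problem sizes

Training follows the published protocol where it is stated: cross-entropy
loss, best-on-validation checkpoint selection (ties to the earliest epoch),
test accuracy reported from the selected checkpoint, a 6:2:2
train/validation/test split (floor rule, remainder to test: 14,249 items
split (8549, 2849, 2851)), and rotation/flip augmentation. Optimizer,
schedule, epochs and batch size are unstated there; the defaults here are
adamw with cosine schedule, and every run is deterministic given (seed,
config, data).

The desk-scale problem sizes used by the test suite were chosen to exercise
the mechanism on one CPU in minutes and are the package's own choices:

* **Overfit sanity**: a mini-DA model (C = 32, depths (1, 1), heads (2, 4),
  M = 7, 56×56 input) driven to 100% training accuracy on 8 cross-window
  images (adamw, $\eta = 10^{-3}$; it typically gets there near epoch 13,
  well inside the 200-epoch bound).
* **Variant comparison**: 240 images at 32×32 (window 16 px, shift 8 px —
  the default geometry scaled down), a *single-stage* model (C = 16, 1 head,
  M = 4), adamw $\eta = 3\times10^{-3}$ cosine, 40 epochs, batch 8, seeds
  0–2, W-MSA vs DA from shared initialisations. The single stage is
  deliberate: with a second stage the merged grid fits one window, every
  variant becomes globally attentive, and the contrast dissolves. In a
  single-stage W-MSA model the pooled representation is a sum of per-window
  encodings, and the same/different-orientation label is an XOR that no
  linear readout of such sums can express — W-MSA is at chance by
  construction, not merely in practice, while DA reaches high validation
  accuracy on most seeds. The margin is a direction check, not a
  quantitative claim.

## Numerical choices and degenerate inputs

Softmax uses row-max subtraction (exact by shift invariance); all-equal
score rows yield uniform weights with no special-casing. LayerNorm uses
$\varepsilon = 10^{-5}$. Window partition/reverse are exact permutations
(round-trip bit-identical); cyclic shifts wrap modulo the grid and compose
to the identity with their negation. The 6:2:2 split puts the rounding
remainder in the test set. Grayscale inputs are replicated to three channels
with a warning; non-patch-divisible images are reflect-padded with a log
message. Checkpoints store a versioned flat map of named arrays; loading
into a model with a different variant skips mismatched entries and logs
every skipped name (the counterpart of initialising a modified attention
architecture from weights whose attention parameters were removed).

## Known limitations

* Accuracy columns of the published comparison tables are out of reach at
  desk scale (GPU-scale training on external or private data); the package
  reproduces the parameter and FLOP columns exactly and the accuracy
  *direction* on the synthetic benchmark.
* The ViT baseline's 85.8 M / 16.9 G figures follow a counting convention
  that could not be reconciled at print precision, so ViT is not
  reimplemented.
* Pure-R training is desk-scale only: single-digit-minutes runs at the sizes
  above, not ImageNet-scale.
* Whether the original implementation includes a relative-position bias, or
  independent learned scales on the two score terms, is not documented; the
  former is a flag, the latter deliberately not implemented (the score sum
  shares one $1/\sqrt{d_k}$ scale, exactly as written).
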