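---
title: "Motion-direction detection with dendritic neurons: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-direction detection with dendritic neurons: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avsmotion)
```

## The problem and the model

`avsmotion` classifies the direction of single-pixel object motion between
two RGB frames into one of eight unit displacements. The architecture is a
deliberately small, biologically structured alternative to a CNN: every
stage corresponds to a cell class of the early visual pathway, and the whole
learnable state is 432 numbers whose roles can be read off individually.

**Retinal front end.** Cone cells split the frame into R/G/B intensity
planes. For each channel, a bipolar cell at pixel $(a,b)$ emits
$B_5 = \mathbf{1}[\,|x_5(t) - x_5(t+\Delta t)| > \epsilon_V\,]$ (temporal
change), and a horizontal cell emits, for each slot $i$ of the 3×3
receptive field, $H_i = \mathbf{1}[\,|x_5(t) - x'_i(t+\Delta t)| <
\epsilon_H\,]$ — the centre's old value reappearing at neighbour $i$. The
binary 9-vector feeding the next stage takes slot 5 from the bipolar map
and the other slots from the horizontal maps. Motion in direction $m$
therefore shows up, on an object's trailing edge, as the conjunction
"centre changed AND the neighbour in direction $m$ matches".

**Dendritic ganglion neuron.** One neuron per direction $m$ and channel
$c$: synapses $S_i = \sigma((w_i x_i - q_i)/d)$, a branch
$b = \prod_i S_i$, a membrane $u = \sum_j v_j b_j$, a soma
$O = \sigma(\lambda_s(u - \theta_s))$. The multiplicative branch makes the
neuron an AND-gate over its synapses: a single synapse near zero silences
the branch. Each synapse's qualitative role is its *connection state*,
classified by its outputs at $x \in \{0, 1\}$ (excitatory, inhibitory,
constant-1, constant-0).

**LGN stage.** Non-learnable by construction:
$M_m(a,b) = \sigma(\lambda_\ell(O^R O^G O^B - \theta_\ell))$ fires only
when all three channels agree. Global sums $D_m = \sum_{a,b} M_m(a,b)$ over
the interior pixels feed an argmax readout; ties break to the smallest
direction index.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| $\epsilon_V$ | 0 | intensity levels | any integer change fires the bipolar cell; equality with the threshold is "off" (the strict inequalities leave equality undefined, so it is assigned to the off branch) |
| $\epsilon_H$ | 1 | intensity levels | exact integer match between centre and neighbour |
| $d$ | 0.2 | — | synaptic sigmoid slope $1/d = 5$; steep enough that binary inputs produce near-binary synapse outputs |
| $v$ | 1 | — | fixed branch weight; with $J = 1$ the membrane is the branch |
| $J$ | 1 | branches | one branch suffices for the AND-gate semantics and gives the 432-parameter count $I \times 2 \times M \times C$; configurable |
| $\lambda_s, \theta_s$ | 5, 0.5 | — | soma responds around half-activation of the branch product |
| $\lambda_\ell, \theta_\ell$ | 5, 0.5 | — | LGN responds around half-activation of the channel product |
| $\eta$ | 0.05 | — | stable across 0.02–0.1 in our convergence runs |
| batch | 32 | pairs | epochs 100 max, early stop patience 10 |

All are exposed in `avs_params()` / `train_config()`.

## The training objective, and why it is shaped this way

The loss is the cross-entropy $E = -\sum_m T_m \log \bar D_m$ with one-hot
teacher $T$. Two readings of the "normalised output" $\bar D$ exist, and the
choice matters enormously in practice:

* **Ratio normalisation** $\bar D_m = D_m / \sum_{m'} D_{m'}$ is what
  `normalize_outputs()` reports. As a *training* objective it is nearly
  degenerate here: every $D_m$ is dominated by the direction-independent
  background response (the LGN floor $\sigma(-\lambda_\ell \theta_\ell)
  \approx 0.076$ times ~900 interior pixels), so $\bar D$ is pinned near
  $1/8$, gradients scale like $1/\sum D \sim 10^{-3}$, and the background
  saturation ($M \to 1$, where $M(1-M)$ annihilates all downstream
  gradients) is an absorbing state. In our experiments no learning-rate,
  batch or slope setting made this objective move off chance accuracy.
* **Softmax normalisation** $\bar D = \mathrm{softmax}(D)$, the default
  used by `train_model()` in `gradient_mode = "exact"`. Softmax is
  shift-invariant, so the background common mode cancels *exactly* in the
  gradient $\partial E/\partial D = \bar D - T$, and the learning signal
  concentrates on the few boundary pixels that actually distinguish
  directions. Training then converges to 100% train accuracy within ~30
  epochs on high-contrast data.

The readout (`argmax D`) is identical under both; only the training signal
differs. `gradient_mode = "simplified"` retains, for comparison, a shortcut
backward rule in which the normalisation Jacobian is the constant
$1/(AB)$, the LGN derivative is evaluated per channel at
$(O^c - \theta_m)$ rather than at the channel product, and the soma
derivative at the set-point $(v - \theta)$ rather than the running membrane
potential. These shortcuts are *not* the derivative of any single scalar
objective; the exact mode is the default and is the one verified against
finite differences.

## Initialisation

Two facts shape the initialisation. First, a product of nine sigmoids with
$w, q \sim U(-1,1)$ at $d = 0.2$ is almost surely $\sim e^{-11}$: the soma
sits on its floor and every gradient inherits the factor $b \approx 0$ —
the network is born dead. Second, the solution the task demands is known in
shape: centre synapse excitatory, one direction-specific surround synapse
excitatory, the rest permissive. The default `init = "change_gated"`
therefore starts all surround synapses *permissive* (near constant-1:
$w \sim U(-0.25, 0.25)$, $q \sim U(-0.7, -0.5)$) and the centre synapse
*excitatory* ($w = 1.5$, $q = 0.75$) for every direction and channel.
Gating on temporal change is direction-agnostic — no direction is
privileged — but it (i) silences the static background from the start and
(ii) places every branch product in the responsive band of the soma.
From there, seeded SGD reliably carves out the direction-selective surround
synapse; after training, every excitatory surround synapse sits exactly on
the slot its direction moves toward (a property the test suite asserts).
`init = "uniform"` is kept for comparison.

Early stopping tracks the *running training accuracy* (best-epoch restore,
patience 10): under softmax cross-entropy the loss can drift upward on a
few hard samples while accuracy still improves, so loss is the wrong
plateau signal for this classifier.

## The synthetic benchmark

`generate_dataset()` emulates controlled single-object motion: a
4-connected object of a given pixel count grown by random accretion
(strictest reading of "connected"; the flood-fill oracle in the tests is
then unambiguous), placed with a one-pixel margin so every direction is
legal, coloured by one of three categories (dark = 0; light = one constant
random RGB triplet with channels uniform on 1..255; random = i.i.d. uniform
per pixel and channel), on a *static* background of the same palette. The
object translates by exactly one pixel. Eight object–background
configurations (DL … RR) exercise contrast and clutter; DD is rejected
(invisible object, undefined label), and an LL draw whose background
triplet equals the object triplet is redrawn for the same reason.

What the generator does *not* emulate: multi-pixel or sub-pixel motion,
moving backgrounds, lighting change, occlusion, multiple objects, sensor
noise. Passing tests therefore demonstrate correct mechanics and learnable
direction selectivity under controlled conditions, not performance on
natural video.

## Numerical choices

* Branch products and their leave-one-out companions are computed in log
  space (`log b = X \log S_1 + (1-X) \log S_0`, one matrix product per
  neuron), which is exact for binary inputs and avoids underflow; pixels
  sharing one of the $2^{27}$ possible binary input patterns are grouped
  with multiplicities, an exact regrouping verified against the per-pixel
  composition in the tests.
* The gradient check compares every coordinate against central finite
  differences, scaled by the gradient's largest magnitude. The plain
  central difference at step $10^{-5}$ carries cancellation noise
  $\sim 10^{-11}$ (loss of magnitude $\ln 8$ in binary64), which a
  coordinate-wise relative comparison of near-zero gradients cannot
  survive; the test oracle therefore uses Richardson-extrapolated central
  differences (base step $10^{-3}$), which measured $\le 2.4\times10^{-7}$
  scaled error across random instances at the $10^{-6}$ tolerance.
* Cross-entropy clamps probabilities at $10^{-12}$ with a warning;
  `normalize_outputs()` raises an error on an all-zero field rather than
  fabricating a uniform readout.
* Checkpoints serialise doubles as `%.17g` strings inside JSON — 17
  significant digits round-trip IEEE binary64 exactly, where JSON number
  emitters may not.
* Only centres with a full 3×3 neighbourhood contribute (no padding is
  invented at the border); horizontal maps carry `NA` there and the
  direction sums run over the interior.

## Experiment protocols and problem sizes

`run_ratio_experiment()` pools a balanced mixture of all eight
configurations (the benchmark read as a whole) and splits it
train:test at 75:25, 50:50, 10:90, 5:95, stratified jointly by
configuration, object size and direction (balance within one pair,
asserted in tests). `run_cross_config_experiment()` trains on one
configuration — 75% of it, stratified, so that a same-configuration test
column exists — and evaluates on the held-out 25% plus the full datasets of
the other seven. Repetition seeds vary the split and training; datasets are
fixed by their own seed.

Defaults run at a reduced desk scale chosen to keep the full protocol in
the minutes range on one CPU: object sizes {8, 16, 32}, 100 pairs per
direction per configuration, 3 repetition seeds. The full benchmark scale
(sizes 1–128, 500 pairs per direction) remains available behind
`paper_scale = TRUE` on both protocols and `--paper-scale` on the CLI.

At this scale the package's own runs give: 75:25 mean test accuracy
≈ 99.9%, 5:95 ≈ 99.9%, DL-trained transfer to LL ≈ 99.5% and to RL ≈ 100%
(the acceptance script recomputes these from scratch).

## Known limitations

* **Transfer is more uniform than selective.** Trained networks here
  converge to the background-invariant conjunction (centre change AND
  direction match), which transfers at ≈ 100% to *every* other
  configuration, including random backgrounds. A trained system whose
  selectivity leans on constant-background context would instead collapse
  on random backgrounds; our optimizer simply does not produce such
  solutions, so cross-configuration accuracy tables from this package show
  little of that asymmetry.
* The exact-mode objective differs from the reported readout normalisation
  (softmax vs ratio) for the reasons above; both are exposed, and the
  discrepancy is surfaced here rather than silently resolved.
* Single-branch neurons ($J = 1$) are the default; multi-branch training is
  supported but not exercised by the shipped experiments.
* The model assumes 8-bit integer intensities; $\epsilon_H = 1$ (exact
  match) is brittle under any intensity noise, which the benchmark does not
  include.
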