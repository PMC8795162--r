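---
title: "Multi-site split learning: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-site split learning: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Split learning cuts a deep network into a client part and a server part.
In the multi-site variant simulated here, *K* end-systems (hospitals) each
hold exactly one hidden layer and a disjoint shard of the training data;
the server holds every remaining layer. For image tasks the client hidden
layer is a Conv2D + 2×2 MaxPool group with a ReLU nonlinearity (the
transmitted map is post-activation, post-pool, so its spatial dimensions
are half the input's and its channel count equals the client filter
count); for the tabular task it is a dense layer with leaky-ReLU.

Per round, every client forwards a local mini-batch through its layer and
sends the feature map and the batch labels to the server. The server
concatenates the maps **along the sample axis** in ascending client order
— each client contributes its own patients, so the server input shape
never depends on the client count — computes the batch-mean loss, updates
its own parameters, and returns each client the gradient slice of the
loss with respect to that client's activations, taken at the recorded
concatenation boundaries. The client finishes backpropagation locally.
Because each client's samples touch only its own slice of the joined
batch, the slice-wise gradients are exact, not an approximation.

Three architectures are provided. `custom_cnn`: client Conv2D(8, 3×3,
same padding) + pool, server Conv2D(16)/Conv2D(32)/Conv2D(64) each with
pool, then flatten + dense(1, sigmoid) — four server hidden layers.
`vgg19_split`: client Conv2D(64) + pool, server the standard VGG19 stack
of 19 weight layers (16 convolutions in five blocks, then 4096/4096/1
dense with a sigmoid head), 20 weight layers in total; pooling floors odd
spatial dimensions, and no pretrained weights exist for single-channel
input. `custom_mlp`: client dense(32, leaky-ReLU), server dense(16,
leaky-ReLU) + dense(1, linear). Filter and unit counts are not fixed by
the protocol; these are the smallest configurations consistent with the
stated layer counts, and the client width is configurable
(`client_filters`, `client_units`).

## Weight handling: independent vs synchronised clients

Whether collaborating hospitals share their first-layer weights is an
open design question; both modes are implemented.

* **Independent (default).** Each client owns its parameters and its own
  Adam state. Sites drift toward different embeddings of the shared
  server representation. Held-out evaluation embeds each test sample
  through *every* client and averages the server's predictions — a
  deterministic convention; a real deployment would route each patient
  through their own hospital's layer.
* **Synchronised (`sync = TRUE`).** One shared client parameter set; the
  per-client gradient slices are summed into a single Adam state each
  round. Summing slice gradients reconstructs the full-batch gradient
  exactly, so this mode is *mathematically identical* to training the
  monolithic network (client layer + server layers) centrally on the
  pooled data. The test suite exploits this as an oracle: a 3-client
  synchronised run's per-round losses are compared to
  `train_centralized()` replaying the identical batch composition, and
  agree to floating-point accuracy (the tolerance asserted is 1e-5; the
  observed gap is ~1e-16). Note that *averaging parameters after
  independent Adam updates* would not have this property — Adam is
  nonlinear in the gradient — which is why synchronisation is implemented
  at the gradient, not the parameter, level. A standalone
  `sync_client_weights()` (mean or broadcast averaging) is still provided
  for manual federation experiments.

## Partitioning and batching

Split ratios (`"8:1:1"`) are colon-separated positive integers in client
order. Counts are apportioned by the largest-remainder method computed in
exact integer arithmetic (remainders compared as `(n·share) mod Σshares`,
ties to the lower client index), with a minimum of one sample per client
enforced by taking units from the clients with the largest excess over
their ideal quota. This allocation is optimal in L1 distance to the ideal
quotas — a brute-force enumeration over all count vectors confirms it in
the tests — and reproduces printed ratios exactly (1000 at 8:1:1 →
800/100/100). The "largest-count donor" repair one might first reach for
is *not* L1-optimal (e.g. 5 samples at ratio 5:4:4:1), which is why the
excess-based donor is used.

A global 20% test set is carved out (stratified, seeded) *before*
partitioning, so all sites share one benchmark; the ratios apply to the
training set only. Stratified partitioning gives every client the global
class mix within ±1 sample per class; classes with fewer members than
clients are dealt round-robin into remaining capacity with a warning.

One epoch is `ceil(n_train / global_batch)` rounds. Every round uses a
full global batch, apportioned across clients proportionally to shard
size by default (so an epoch traverses each shard about once) or equally
(`batch_policy = "equal"`); each client samples via its own seeded,
cyclically reshuffled cursor, so there is no ragged final batch. All
randomness — initialisation, the test split, the partition, every
client's shuffling — derives from one integer seed through independent
streams; two runs with the same seed are identical.

## Optimisation and numerical choices

Adam (lr 1e-3 default, β₁ 0.9, β₂ 0.999, ε 1e-8) with separate states per
client and for the server. Glorot-uniform initialisation from the run
seed. Leaky-ReLU slope 0.01. Binary cross-entropy clips probabilities to
[1e-7, 1−1e-7]; max-pooling breaks ties toward the first (top-left)
element of each window; convolutions are stride-1 'same' zero padding,
realised as k² shifted BLAS multiplications. `build_split_model()`
rejects input shapes the architecture cannot pool down (e.g. 8×8 through
the four-pool `custom_cnn`). For regression, features and target are
z-scored on training statistics; predictions are mapped back and floored
at zero (the target is a concentration) before RMSLE.

## Synthetic data: what it emulates, and what it does not

`make_image_set()` emulates two-class grayscale medical imaging: a
smoothed Gaussian texture with per-image mean fixed at 0.30 (amplitude
0.08), to which positive-class images add 1–3 bright elliptical blobs
(default peak contrast 0.5, radii size/10–size/5), then white pixel noise
(default sd 0.1) and clipping to [0, 1]; classes balanced to within one.
Fixing the background mean makes the noise-free set perfectly separable
by a pixel-mean threshold — a designed oracle: a classifier that fails it
is broken. Real CT/X-ray data have anatomy, acquisition artifacts,
class-dependent texture and much weaker separability; passing tests here
show protocol correctness and learnability of a planted signal, not
clinical performance.

`make_cholesterol_set()` draws age ~ U(20, 80) y, sex ~ Bernoulli(0.5),
height ~ N(165, 10) cm, weight ~ N(70, 15) kg, TC ~ N(190, 35) mg/dL,
HDL-C ~ N(55, 12) truncated into (0, TC), TG ~ LogNormal(ln 120, 0.4),
and sets LDL-C = TC − HDL-C − TG/5 + N(0, noise_sd), floored at zero. The
Friedewald identity is the natural planted truth over exactly these
attributes: it makes the regression target recoverable in closed form
(OLS on the noise-free table returns 1, −1, −0.2 to 1e-6), while age,
sex, height and weight are nuisance covariates the model must ignore.
Note two deliberate consequences: about 0.4% of LDL-C draws fall near
zero, and RMSLE is dominated by that tail — the irreducible RMSLE of even
the exact Friedewald predictor against noisy observations is roughly
0.07–0.12 at noise sd 5 mg/dL depending on the test split. The
recoverability check (RMSLE < 0.10 after 50 epochs on 5000 rows) is
therefore run in synchronised mode with lr 3e-3 and global batch 128, the
setting at which optimisation reliably reaches the noise floor;
independent-client ensembles land a little higher (≈0.09–0.13 across
seeds) because averaging diverged local optima costs accuracy, and are
reported descriptively rather than asserted.

## The leakage audit

The privacy claim of split learning is qualitative — the feature map
"looks distorted". `audit_leakage()` makes it quantitative with two
scores. (1) Each feature-map channel is bilinearly upsampled to the input
size; the per-channel maximum absolute Pearson correlation with the input
is reported (a zero-variance channel scores 0). (2) The image is
regressed pixel-wise on the upsampled channels plus an intercept; the
report's nRMSE is the residual RMS divided by the RMS around the mean
image, so an uninformative map scores exactly 1 and perfect linear
inversion 0. The regression is on upsampled channels (HW observations,
C+1 coefficients) rather than the raw flattened map, which would be a
one-observation, hwc-unknown problem with no defined least-squares
answer. No pass/fail threshold is asserted — the protocol makes no
quantitative privacy guarantee, and the audit's role is to *report*; on
trained one-conv clients the first channels typically correlate strongly
(≈0.6–0.9) with the input, which is exactly the kind of finding the audit
exists to surface. A side-by-side original/first-channel PNG and a JSON
report can be exported.

## The experiment grid

`grid_spec()` defaults to the nine-cell imbalance design: 3, 4, 5
end-systems with equal (1:1:1…), imbalanced (7:2:1, 4:3:2:1, 4:2:2:1:1)
and extreme (8:1:1, 7:1:1:1, 6:1:1:1:1) ratios. `run_grid()` trains each
(count, ratio, seed) cell, records the final held-out metric, writes
per-cell histories plus a tidy and a wide CSV (numbers formatted to 12
significant digits so reruns are byte-identical; wall-clock times are
kept in memory, not in the CSVs), and leaves JSON markers so interrupted
grids resume without retraining. Failures are recorded per cell and do
not stop the grid. `summarize_grid()` ranks by mean metric with ties
broken toward more clients, then more imbalance (max share / total) —
the preference for inclusive configurations — and adds a delta-to-best
column so near-ties are visible. Whether accuracy *actually* rises with
imbalance on real hospital data is an empirical claim about those
datasets; on the synthetic IID images the grid is a structural and
reproducibility harness, and no trend is asserted.

## Problem sizes

The shipped checks run at desk scale by choice: equivalence on 240
samples (8×8 flattened for the dense path, 16×16 for the convolutional
path — the smallest input the four-pool CNN admits), five epochs;
gradient checks on an 8×8×1, 2-filter instance; the grid on 400 images of
32×32 for 10 epochs; regression on 5000 rows for 50 epochs. The
`vgg19_split` architecture is validated by shape propagation and layer
accounting rather than by training — at 224×224 it holds ~60M parameters
and is not exercised in simulation.

## Known limitations

* In-process simulation only: no transport, serialisation, TLS, or
  asynchronous/stale-gradient behaviour.
* Labels travel with the feature map (vanilla split learning); label
  privacy would need the U-shaped variant, which is out of scope.
* "Privacy" here is representational distortion measured by a linear
  adversary; there is no differential privacy or formal guarantee, and
  nonlinear reconstruction attacks are not modelled.
* Binary outputs only (one sigmoid/linear unit); no pretrained weights,
  no augmentation.
* Determinism is per platform: BLAS summation order may differ across
  builds, so byte-reproducibility claims hold within one machine.
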