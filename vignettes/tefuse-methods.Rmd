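---
title: "Multi-modal temporal fusion for preclinical glioblastoma: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal temporal fusion for preclinical glioblastoma: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Longitudinal preclinical glioblastoma (GBM) studies in patient-derived
xenograft (PDX) mice produce several weakly-aligned data streams per animal:
segmented T2-weighted anatomical MRI in three plane orientations on imaging
days, dynamic hyperpolarized ¹³C pyruvate spectroscopy (HPMRS) capturing
real-time pyruvate→lactate conversion, scalar tumor-volume measurements, and
a single ex vivo NMR metabolite panel obtained at euthanasia. Because
euthanasia is terminal and scanner time is scarce, most animals are missing
most modality-day combinations. `tefuse` implements a multi-modal temporal
classifier over these streams, the label rules that define its three
prediction tasks, the repeated cross-validation protocol that evaluates it,
and a seeded synthetic cohort simulator so the entire pipeline runs without
animal data.

## Model

### Plane encoders

Each imaging day contributes three single-channel volumes with fixed
geometries: sagittal $(7, 107, 147)$, axial $(6, 107, 147)$ and coronal
$(9, 107, 147)$ voxels. A plane encoder is three stacked stages, each a
valid (unpadded, stride-1) 3D convolution

$$Z^{(l)}_{ijkm} = \sum_{c}\sum_{u,v,w} W^{(l)}_{uvwcm}\,X^{(l-1)}_{i+u,\,j+v,\,k+w,\,c} + B^{(l)}_m,$$

a rectifier $\max(0, Z)$, and a non-overlapping max-pool whose stride equals
its kernel. The kernels are $(2,3,3), (1,3,3), (1,3,3)$ with output channels
$64, 128, 256$ at full width; the final map is flattened to a per-day vector
(9216 / 6144 / 12288 wide for sagittal / axial / coronal). Valid convolution
with floor-division pooling is the only convention that reproduces the
reference layer census (e.g. width 145 → 48); `model_shapes()` exposes the
whole chain and the test-suite pins every stage.

### Temporal aggregation and time-elapsed attention

Per plane, the day-ordered vectors pass through a single-layer Elman
recurrence

$$h_t = \tanh(W x_t + U h_{t-1} + b), \qquad h_0 = 0,$$

whose hidden states (width 256 at full width) form the plane representation
matrix $M \in \mathbb{R}^{D \times \ell}$. Days without a scan propagate the
previous hidden state unchanged, so row $t$ depends only on observed days
$\le t$. The linear output head $y_t = \sigma_y(W_y h_t + b_y)$ that
sometimes accompanies this recurrence is omitted: the hidden states are the
emitted representation, and the census counts
$\ell\cdot d_{in} + \ell^2 + 2\ell$ parameters per recurrence accordingly.

Cross-view fusion uses scaled dot-product attention,

$$\mathrm{Attention}(Q, K, V) = \mathrm{softmax}\!\left(\frac{QK^\top}{\sqrt{d_k}}\right)V,$$

with two heads and bias-free square projections for query, key, value and
output ($4d^2 = 262{,}144$ parameters per unit at $d = 256$; the absence of
projection biases is forced by that count). One *time-elapsed attention
block* anchors one plane: the anchor attends to itself over days
(self-attention), then the self-attended anchor queries each of the two
other planes (cross-view attention). The last-day rows of the three attended
matrices are concatenated and rectified into a 768-vector. Three blocks —
anchored at the axial, coronal and sagittal planes respectively — are
concatenated into the fused 2304-wide MRI representation. The exact
composition of "self-attention then cross-view attention" admits several
wirings; the package fixes the one above, keeps the anchor order
configurable via `role_order`, and pins the choice with parameter-count
conformance (786,432 per block).

### HPMRS and tabular branches

A dynamic spectrum is an $18 \times 2532$ intensity matrix (spectral bins ×
acquisition time points; the row/column convention is a package choice,
documented here because the data layout alone does not determine it). Two
2D convolution/ReLU/max-pool stages (kernels $(3,3)$, channels 8 then 16)
reduce it to $(16, 1, 280)$; the mean over channels yields the width-280
per-day vector — forced by the HPMRS recurrence's 52,480-parameter census
($128\cdot280 + 128^2 + 2\cdot128$), which rules out flattening to
$16\cdot280$. The mean (rather than max) is chosen for smoothness. Each
encoder stage centers its input first: on the raw spectrum this is standard
baseline/DC-offset removal, and between stages it is a lightweight
normalization that keeps the narrow scaled-down encoder (1–2 channels at
width-scale 1/8) responsive to spectral structure rather than rectified into
silence by a large positive offset. Conv biases are initialized at zero for
the same reason. A 280→128 Elman recurrence over HPMRS days returns its
final hidden state.

The NMR branch is a 9→9 Elman recurrence (180 parameters) over the
nine-metabolite panel sequence; the tumor-volume branch passes the up-to-3
most recent volume measurements in mm³, zero-padded with an availability
mask.

### Missing values

Panels missing on a day are imputed with the same-cohort same-day mean of
*observed* values (nearest observed day as fallback — needed because a
synthetic cohort can lack any observation for a given cohort-day), flagged,
and *masked*: masked coordinates are zeroed before the input-to-hidden
product, so their numeric values provably cannot reach the output. The
test-suite asserts this end-to-end: perturbing any imputed-and-masked value
leaves the predicted probability bit-identical. Whole missing scan days
propagate the recurrent state, as above.

### Classifier and loss

Layer 1 maps the fused 2304-vector through an affine 2304→768 map and a
ReLU; layer 2 concatenates the result with the HPMRS (128), NMR (9) and
volume (3) representations — 908 inputs, forced by the 1818-parameter census
of the output layer — into two logits and softmax probabilities. Training
minimizes the weighted cross-entropy

$$\ell = -w\,[\,y \log x + (1 - y)\log(1 - x)\,],$$

with $x$ clamped to $[10^{-7}, 1-10^{-7}]$; $w$ is applied per sample, equal
to the inverse positive-class prevalence of the training fold for positives
and 1 for negatives, so rare positives are not drowned.

## Training regime

No automatic-differentiation framework is involved: the forward passes are
explicit matrix code, and training uses the random-feature (reservoir)
regime — encoder, recurrence and attention weights stay at their seeded
scaled-uniform fan-in initialization, while the two classification layers
are trained per fold by full-batch Adam (default: learning rate 0.01, 300
epochs, weight decay $10^{-3}$, per-column standardization learned on the
training fold). Fixed random convolutional and recurrent features preserve
the monotone tumor-burden and kinetic-rate information the planted tasks
carry, the trained head is where class geometry is decided, and the whole
5×3 repeated cross-validation runs in minutes on one CPU core at width-scale
1/8. The regime is a package design choice; `fit_head()`/`predict_head()`
isolate it so a full-backprop trainer could be substituted without touching
the evaluation protocol.

`model_config(width_scale = s)` scales every channel and embedding width by
`s` (integers, floor 1; the NMR recurrence stays 9→9 because the panel width
is data, not capacity). Width-scale 1 reproduces the reference census
exactly; the default working scale is 1/8 (~238k parameters).

## Synthetic cohort simulator

The simulator emulates the *statistical and structural* properties the model
and labels assume — not MR physics.

* **Growth** — exponential in expectation from the first scheduled
  measurement day, $v(t) = v_0 e^{r (t - t_0)}$, with additive Gaussian
  measurement noise, clamped at zero; treated mice follow the untreated
  trajectory until the first radiotherapy day (day 25; 2 × 5 Gy on days 25
  and 27) and then shrink exponentially. Defaults: $v_0 \sim \mathcal N(1.59,
  0.5^2)$ mm³ (the first-measurement mean reported for untreated PDX
  cohorts), growth rate $0.08 \pm 0.06$ /day so that typical untreated
  volumes stay below ~10 mm³ through day 28 while a minority cross the
  progression threshold, regression rate $0.03 \pm 0.05$ /day so that most
  but not all treated mice respond. Per-mouse rate heterogeneity is what
  makes outcome labels vary within a cohort; a growth law with shared rates
  would give every mouse the same label.
* **HPMRS** — the two-site exchange model: $P(t) = p_0 e^{-(k_{PL}+\rho_P)t}$
  and $dL/dt = k_{PL} P - \rho_L L$ with $L(0)=0$, solved in closed form
  (including the degenerate equal-rate case $L = p_0 k_{PL} t e^{-at}$) and
  rendered as truncated unit-sum Gaussian lines (pyruvate at bin 5, lactate
  at bin 14, disjoint supports) over 2532 time points spanning 90 s, plus
  seeded noise. Unit-sum lines make the column sums recover $P(t)+L(t)$
  exactly, giving a machine-precision conservation check in the no-decay
  limit; the closed form is verified against independent ODE integration to
  $10^{-6}$. $k_{PL}$ rises with instantaneous tumor burden (0.002 s⁻¹
  baseline, +6×10⁻⁴ per mm³, capped at 0.05 s⁻¹), planting an in vivo
  kinetic signal correlated with disease state.
* **Plane volumes** — zero background plus a centered hyperintense ellipsoid
  whose voxel count is proportional to tumor volume (100 voxels/mm³), with
  Gaussian background noise: pre-segmented input, as the model consumes.
* **NMR panels** — nine metabolites in three groups (amino-acid metabolism:
  valine, alanine, glycine, glutamate; membrane: glycerophosphocholine,
  phosphocholine, phosphoethanolamine; reactive-oxygen: glutathione, NAD).
  Controls draw from configured normal distributions; tumor cohorts add
  per-group mean shifts (+2 / +1.5 / −1.5 SD) ramping linearly to day 21.
* **Missingness** — each mouse draws a terminal (euthanasia) day — untreated
  and control between days 14 and 35, treated between 28 and 48, weighted
  toward later days — after which nothing is measured and at which the only
  NMR panel is taken; independent per-day modality dropout (defaults 25%
  MRI, 35% HPMRS) removes further scan days, under the hard guarantee that
  every mouse keeps at least one MRI day or one HPMRS day.

What the simulator does **not** emulate: coil profiles, B0 inhomogeneity,
chemical-shift structure, segmentation error, realistic metabolite
covariance, or treatment-time confounding. Tests passing on this simulator
therefore demonstrate that the pipeline recovers the signals it plants under
realistic missingness — not performance on real animals.

## Label rules

* **Progression** — volume strictly greater than 25 mm³; the cohort label
  takes measured volumes from day 21 onward (window 21–35). Features for
  the progression task come from days 1–24 only (defaults 8/11/14).
* **Treatment effect** — over the regression window days 25–48 (day 28 =
  post-radiotherapy day 1): with ≥2 measurements, effective iff day and
  volume are negatively Pearson-correlated (zero or undefined correlation
  counts as not effective — the effect must be affirmative); with exactly
  one, effective iff the volume falls below the untreated reference lower
  bound, an ordinary least-squares line (the Gaussian identity-link reading
  of a generalized linear model) minus one SD of its residuals (the sample,
  $n-1$, SD; the alternative reading — SD of the predicted mean — is noted
  and not used).
* **Biomarker abnormality** — outside mean ± SD of the control cohort,
  boundary inclusive (a value exactly at mean ± SD is normal).

## Evaluation protocol

Repeated stratified k-fold cross-validation, read as 5 independent repeats
of 3-fold CV (15 train/test cycles); stratification keeps 3 folds viable at
small n. Metrics: AUROC (Mann–Whitney with ties at ½ — tested exhaustively
against a brute-force pairwise-concordance oracle), average-precision
AUPRC, and per-cohort TPR/FNR/FPR/TNR at threshold 0.5, with the convention
that a cohort with no positive animals (tumor-free controls) reports
TPR = FNR = 0. The null control re-permutes labels independently per repeat:
a single fixed permutation would let fold-level overfitting anticorrelate
with it systematically (small-sample "anti-learning"), biasing the null
below chance. Modality ablations (e.g. HPMRS-only) zero the excluded
branch representations. Each day-window configuration retrains from scratch.

## Benchmark study conditions

`benchmark_cohort()` freezes the learnability study: 20 controls + 40
untreated PDX mice, all followed to a uniform day-35 endpoint with no
modality dropout, growth $0.10 \pm 0.06$ /day — so the progression label is
a function of the planted growth trajectory (roughly balanced), not of
unobservable censoring. Early euthanasia is deliberately absent here: it
would add label noise unrelated to the planted signal, and missingness
handling has its own contracts. On this cohort (width-scale 1/8, 5×3 CV)
the acceptance checks verify planted-signal AUROC, a chance-level permuted
null, and that three time points do at least as well as one. Problem sizes
(n = 60 mice, 3 feature days, width-scale 1/8) are the package's chosen
desk-scale study conditions.

## Numerical choices and degenerate inputs

* Probability clamp $10^{-7}$ in the loss; softmax computed with row-max
  subtraction.
* Equal-rate exchange kinetics switch to the $t e^{-at}$ limit when
  $|a - \rho_L| < 10^{-12}$.
* Zero-correlation (tied) treated series → not effective; single-day
  reference fits are rejected (slope undefined).
* Shape underflow in any conv stage is rejected naming the offending axis;
  empty sequences are rejected by every recurrence.
* Seeds: every stochastic function takes a `seed` and restores the caller's
  RNG state; derived sub-seeds stay below 2³¹.

## Limitations

The random-feature training regime is weaker than end-to-end
backpropagation on tasks whose signal is not linearly recoverable from
random encodings; the simulator's planted signals are deliberately
recoverable. Real-data performance claims are out of scope. The attention
wiring and the HPMRS row/column convention are fixed package choices among
several readings consistent with the layer census; both are isolated behind
configuration should evidence favor another reading.
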