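---
title: "gEUD-weighted GRU models for organ-at-risk DVH prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gEUD-weighted GRU models for organ-at-risk DVH prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modelling problem

A cumulative dose-volume histogram (DVH) summarises, for one organ, the
fraction of its volume receiving at least each dose level. Resampled on a
percent-volume grid — `D_v` = dose at volume fraction `v`, for
`v = 1%, …, 100%` in 1% steps — a DVH becomes a length-100, non-negative,
monotone non-increasing dose sequence. This package predicts the
clinical-plan DVH of an organ at risk (OAR) from the nine DVHs that
nonmodulated conformal beams (gantry angles 160–120° in 40° steps)
deposit in that organ. Those nine curves are a dosimetric fingerprint of
the patient's geometry: how much of the organ each beam direction
traverses, and at what depth. The predictor is a recurrent network
because a DVH is intrinsically sequential — dose at neighbouring volume
fractions is strongly coupled and the curve is monotone — and because
recurrent models are parameter-frugal, which matters when a clinic can
supply only tens of training plans.

## Model

At volume step `j` (ascending, `v = j%`), the model consumes the nine
beam doses at that bin, each divided by the prescription dose
(`dose_norm`, default 70 Gy), updates a GRU hidden state `h_v`, and emits
the predicted plan dose through a one-unit affine head. A dropout layer
(`p = 0.5`) sits between the recurrent output and the head, active only
during training. Defaults: one recurrent layer, hidden size 64 (about
14.5k parameters — small enough to fit from 50 sequences, large enough
for the synthetic mapping below; exposed in `model_spec()`).

Predictions are post-processed deterministically: rescaled to Gy, clipped
at zero, and made monotone by a running maximum taken from the
100%-volume tail. The tail-side running maximum is deliberate: it can
only raise interior bins toward the high-dose head, never lower the
head itself, so the clinically critical maximum-dose region is preserved.
The loss does not enforce monotonicity; post-processing does.

Two decisions here were genuinely open and are worth recording. First,
the per-step feature vector: we use the nine beam doses at the *current*
bin only, keeping the model free of autoregression on its own output and
of any dependence on the target at inference time (no teacher forcing —
the clinical-plan dose does not exist when the prediction is needed).
Second, the sweep direction: ascending volume puts the high-dose head
first; the GRU still sees the entire curve, and the direction is a
`model_spec(reverse = TRUE)` flag for anyone who wants the opposite
convention.

## The gEUD-weighted loss

The generalized equivalent uniform dose of an equal-volume-sampled DVH is
the power mean

$$\mathrm{gEUD}_a = \Big(\sum_j \Delta v\, D_j^a\Big)^{1/a},
\qquad \Delta v = 0.01 .$$

We read the volume weight as the fractional bin volume 0.01, which makes
the weights sum to one and the gEUD an ordinary power mean: `a = 1` is
the mean dose, `a → ∞` approaches the maximum. `a = 8` is used for serial
organs and `a = 1` for parallel organs at evaluation time. The
sensitivity of the gEUD to bin `j` scales with `D_j^{a-1}`; normalised,

$$s(D_j, k) = \frac{D_j^{k-1}}{\sum_i D_i^{k-1}},$$

and the training loss is the sensitivity-weighted squared error

$$f = \frac{1}{n}\sum_{p=1}^{n} \sum_j s(D_{pj}, k)\,(D'_{pj} - D_{pj})^2 ,$$

with `n` the number of patients in the batch and the weights computed
from the *target* (plan) doses and treated as constants — no gradient
flows through `s`, which keeps `f` a proper weighted least-squares
objective. With `k = 1` the weights collapse to `1/100` and `f` is the
per-patient-averaged MSE; for `k > 1` the per-bin weights no longer carry
a `1/n_bins` factor — the loss is implemented exactly in this form. The
derivative of the gEUD with respect to each bin dose, which motivates the
weighting, is never needed explicitly: it is recovered implicitly by the
backpropagated gradients (which the test suite checks against central
finite differences).

`k` is organ-specific and selected by grid search: one model per
candidate, scored on a held-out validation split by
`|μ_EUD| + σ_EUD`, plus `|μ_Dmax| + σ_Dmax` for serial organs. The
composite mirrors the reporting statistics (below): it asks for both
small bias and small spread on exactly the endpoints the organ's
radiobiology prioritises. Ties break toward the smaller `k`. Defaults
shipped in `default_oar_configs()`: brainstem 8, spinal cord 15, optic
nerves 3 and 2, chiasm 1, and 1 for all parallel organs. A caution on
the optic-nerve values: left and right optic nerves are anatomically and
radiobiologically interchangeable, so different selected exponents for
the two sides are best read as small-sample noise in the grid search,
not organ biology — re-run `grid_search_k()` on your own cohort rather
than trusting any published pair.

## Training

Full-batch Adam (learning rate 1e-3, 500 epochs by default): 50
sequences of 100 steps fit trivially in one batch, so mini-batching would
only add noise. The compiled training loop records the loss under each
epoch's dropout mask and, separately, the dropout-free loss of the
returned parameters (`final_loss`). Optional early stopping monitors a
validation loss with a patience counter and returns the best-scoring
parameters. Everything is deterministic given the three seeds involved:
model-spec seed (initialisation, uniform on ±1/√h), training seed
(dropout masks), and cohort seed. A non-finite loss aborts immediately
with the epoch and learning rate in the message.

The comparison arm, `train_previous_baseline()`, approximates the older
multi-organ approach: a single 3-layer GRU trained jointly on all organs
with `k = 1` and a one-hot organ-identity feature appended to the nine
beam doses. It is an honest stand-in for that class of model — the
original's exact features and conditioning are not public — and is
labelled as such wherever it appears.

## Evaluation protocol

Per organ and endpoint (gEUD always; maximum dose, defined as the dose at
the 1% bin without extrapolation toward 0% volume, for serial organs
only), the per-patient errors are `δ_i = predicted − planned`, summarised
as

$$\mu = \tfrac{1}{n}\sum_i \delta_i, \qquad
  \sigma = \sqrt{\tfrac{1}{n}\sum_i (\delta_i - \mu)^2},$$

with the **population** denominator `n` — not `n − 1`. This differs from
`stats::sd()` and from most library defaults; `mu_sigma()` implements it
as printed above. Two methods are compared by a paired two-sided Wilcoxon
signed-rank test on the signed `δ` values (an `absolute = TRUE` flag
pairs `|δ|` instead): zero differences are dropped, midranks handle ties,
the null distribution is enumerated exactly over all `2^n` sign
assignments for `n ≤ 15`, and a normal approximation with tie and
continuity corrections takes over above that. Agreement across organs is
summarised by ordinary least squares of predicted on planned endpoint
values with the Pearson `r`; pooling across organs and endpoints is the
default (per-organ regressions are one `subset()` away). Boxplot
summaries use linear-interpolation (type-7) quantiles with whiskers at
the most extreme points within 1.5 × IQR.

## The synthetic cohort

Clinical DVH databases are private, so the generator substitutes a
parametric family with the statistical structure the method assumes.
Patient `p` draws a latent anatomy factor `x_p ~ U(0.5, 1.5)`; organ `o`,
beam `b` deposits

$$D_b(v) = x_p \, M_o \, w_b \, (1 - v/100)^{\gamma_b}$$

and the plan DVH is the mixture `Σ_b c_b D_b(v)` plus i.i.d. Gaussian
noise (sd `η`, default 1 Gy — the order of bin-level DVH variability a
planner would call realistic), repaired to be monotone by the same
tail-side running maximum and clipped at zero. Defaults: ten organs
matching `default_oar_configs()`, with base scales `M_o` of 24–58 Gy
(highest for temporal lobes and brainstem, lowest for the larynx),
per-beam weights tilted by gantry angle and organ laterality, and 80
patients split 50/30 into train/test. `serial_scenario()` is a stress
variant: one beam with a much faster volumetric falloff (γ = 10) and full
weight creates a small-volume hot spot, so the maximum dose is the hard
part of the prediction — the regime where `k ≫ 1` should beat `k = 1`.

What the generator does and does not emulate: the beam-to-plan mapping is
per-bin linear given the beams, fully learnable, with retained ground
truth (`x_p`, mixture weights) — so noiseless recovery tests are sharp
and parameter recovery is checkable. It does **not** model anatomy, PTV
coverage or beam physics, and real plan-to-beam relationships are
nonlinear in ways this family cannot represent. Passing tests therefore
demonstrate that the machinery (model, loss, selection, statistics)
behaves as designed, not that any particular clinical accuracy would be
achieved.

## Numerical choices and degenerate inputs

- Doses are doubles in Gy throughout; equality tolerance 1e-9 Gy.
- Power means and sensitivity weights factor out the maximum dose before
  exponentiation, so `a` or `k` up to a few hundred stay finite.
- Resampling onto the grid interpolates linearly in the
  (volume → dose) direction; vertical steps (several doses at one volume)
  resolve to the maximum dose at that volume — conservative for serial
  organs. Inputs must cover the 1–100% grid and be monotone; violations
  are rejected naming the offending pair.
- `sensitivity_weights()` rejects the undefined all-zero/`k > 1` case;
  `k = 1` returns uniform weights for any input.
- Wilcoxon with all-zero differences warns and returns `p = 1`.
- Checkpoints are single-file R serialisations plus a JSON metadata
  sidecar; reloads reproduce predictions bit-identically.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run the full 80-patient cohort
(50/30) for the ten default organs at the default 500 epochs, the
serial-organ scenario over grids `k ∈ {1, 8, 15}` across five seeds, and
smaller cohorts (6–40 patients, 8–64 hidden units, 10–40 epochs) for
format, determinism and CLI checks. These sizes were chosen as the
smallest that exercise each property convincingly; all are set in code
and scale up by changing one argument.

## Known limitations

- The baseline arm approximates, not reproduces, earlier multi-organ
  models; comparisons against it are qualitative.
- Differential DVHs, absolute-volume (cc) DVHs, and biological indices
  beyond the gEUD (NTCP/TCP) are out of scope, as are DICOM-RT parsing
  and treatment-planning-system integration; the interface is the
  long-format CSV of sampled DVHs.
- Selected `k` values are data-dependent; treat the shipped defaults as
  starting points for `grid_search_k()`, not as transferable constants.
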