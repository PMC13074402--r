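---
title: "Designing k-space coverage and averaging for MRI denoising"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing k-space coverage and averaging for MRI denoising}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kcoverage)
```

## The design problem

MRI trades SNR against spatial resolution. A Cartesian acquisition that
measures an $N \times N$ k-space grid with $\tilde w_m$ averages of
phase-encode line $m$ spends $\sum_m \tilde w_m$ repetitions (TRs). Holding
the total experiment duration and the readout duration fixed, a
lower-resolution acquisition ($N < N_0$) frees time for extra averaging, and
the reduced acquisition bandwidth gives a further SNR gain of $N_0/N$. Both
effects are absorbed into *effective averages*
$w_m = \tilde w_m \, N_0 / N$, under which the averaged noise is circular
complex Gaussian with per-line variance $\sigma^2 / w_m$ and the fixed
scan-time budget reads $\sum_m w_m = \tilde w_0 N_0^2 / N$.

`kcoverage` asks: given a modern computational denoiser, what grid size $N$
and averaging pattern $w$ should the acquisition use? The answer is obtained
by a bilevel optimization. For each candidate $N$, the *inner* problem
jointly trains the reconstruction parameters $p$ and (optionally) the
pattern $w$ by projected stochastic gradient descent on the mean-squared
error against matched-resolution noise-free references $r^N$ — a pure
denoising task. The *outer* problem then scores each trained design against
the high-resolution references $r^{N_0}$ and keeps the best $N$ by
brute-force search. Training against $r^N$ rather than $r^{N_0}$ avoids
turning the inner problem into super-resolution; scoring against $r^{N_0}$
keeps the final selection honest about resolution loss.

Two reconstructor families are trained end to end:

* **Apodized reconstruction** — multiply the data by a real positive
  $N \times N$ window $h$, zero-pad, inverse Fourier transform, SENSE coil
  combination. Linear in the data; the gradients of the training loss with
  respect to $h$ and $w$ are closed-form.
* **SENSE-TV** — $\hat x = \arg\min_x \|\sqrt{w} \odot (Ex - d)\|_2^2 +
  \lambda \|Dx\|_1$, where $E$ is sensitivity encoding, Fourier transform,
  and cropping to the acquired band; $D$ is the periodic first-difference
  operator. Solved by ADMM with a fixed iteration count (default 50).

A plugin interface (`recon_cnn()`) accepts learned reconstructors honoring
the $2L$-in / 2-out channel contract on zero-padded per-channel images; the
package ships a weight-free coil-combination stub that exercises the
contract, and leaves deep-network training to the plugin provider.

## Noise model and simulation

Noise is i.i.d. circular complex Gaussian, prewhitened across channels, with
variance $\sigma^2$ per unaveraged sample. One master unit-variance
realization is drawn per (seed, dataset) pair *on the full $N_0$ grid* and
cropped for each candidate $N$, so the outer search compares candidates
under identical noise. The printed data model scales this realization by
$1/\sqrt{w_m}$ per line, which is the scale consistent with the stated
variance $\sigma^2/w_m$; the package treats the variance statement as
authoritative. By default a dataset's realization is fixed for all of
training (matching the formulation in which the noise vectors are fixed
quantities); `inner_schedule(..., redraw_noise = TRUE)` redraws per epoch.

In the SENSE-TV data term the per-line weight is $\sqrt{w_m}$ inside the
squared norm, so the quadratic term equals the negative log-likelihood under
variance $\sigma^2/w_m$. The literal elementwise-$w$ weighting is available
via `literal_w = TRUE` for comparison.

## The synthetic study suite

Because every stage must be testable at desk scale, the package generates
multicoil brain-like phantoms: nested perturbed-ellipse anatomy (CSF rim and
ventricles, cortical gray-matter ribbon, white-matter interior), thin bright
vessel-like random-walk curves one to two voxels wide (the fine structure
that reduced resolution sacrifices), a smooth low-order polynomial phase,
and Gaussian-lobed complex coil sensitivities with strictly positive summed
energy. Defaults are $N_0 = 64$, $L = 4$, $T = 32$ phantoms split
80/10/10 — chosen so a full SENSE-TV design run completes in minutes on one
CPU while preserving the structure of a full-scale study
($320$-grid, 16 channels, thousands of slices). Grid sizes, channel counts
and dataset counts remain configurable.

What the generator does *not* emulate: relaxation and off-resonance effects,
eddy currents, readout oversampling chains, hidden noise in the references,
and anatomical realism beyond piecewise-smooth tissue plus fine bright
structure. Passing tests therefore demonstrate correctness of the noise
model, the pattern algebra, the solvers, and the qualitative design trends —
not clinical image quality on real anatomy.

The SNR convention is calibrated in a central white-matter ROI of the
conventional reconstruction (inverse Fourier transform plus SENSE
combination) of the reference acquisition ($N = N_0$, uniform
$\tilde w_0 = 8$ averaging): signal is the mean ROI magnitude of the
noiseless reconstruction, noise is the Monte-Carlo standard deviation of
noise-only reconstructions. Because the noise measure is exactly
proportional to $\sigma$, calibration reduces to one Monte-Carlo estimate at
a reference $\sigma$ followed by linear rescaling — no bisection is needed,
and $\sigma(\mathrm{SNR})$ is exactly inverse-proportional by construction.
The ROI is a fixed central disk intersected with the white-matter label; it
is a property of the synthetic suite, not a claim about any particular real
protocol.

## Numerical choices

* **Transforms.** All grids are even and stored in centered order (DC at
  index $N/2+1$). Transforms are unitary, so Parseval identities and
  crop/pad adjointness are exact and scale-free. In compiled code the
  centered transform uses the checkerboard-sign identity instead of four
  circular shifts.
* **ADMM.** Splitting $z = Dx$ with scaled dual; the $x$-update is solved by
  conjugate gradients (10 inner iterations, tolerance $10^{-8}$, warm
  started); the $z$-update is complex soft-thresholding; iteration count
  fixed at 50. The penalty $\rho$ is an algorithmic parameter tuned on a
  coarse logarithmic grid against NRMSE on one representative slice per
  (noise level, $N$), then frozen. A divergence flag (objective increasing
  for 10 consecutive iterations) is recorded, not fatal.
* **Gradients.** The apodized reconstructor is linear, so window and
  averaging gradients are closed-form. For SENSE-TV the package implements a
  hand-derived reverse-mode sweep through the unrolled ADMM iterations,
  treating each CG solve as an exact linear solve (the backward pass solves
  the same normal equations once more per iteration). Both routes are
  cross-checked against central finite differences, which are also exposed
  (`fd_gradient()`) for plugin reconstructors.
* **Projection and rounding.** The budget projection $w \mapsto w + \beta/N$
  is the exact Euclidean projection onto the budget hyperplane; entries
  falling below a positivity floor of $10^{-3}$ effective averages are
  clipped and the deficit redistributed over the free set, iterated. The
  floor preserves the no-undersampling regime (zeros never emerged in
  practice) while keeping the solver defined. Integer rounding minimizes the
  $\ell_1$ distance to the scaled continuous pattern subject to the exact TR
  budget; nearest-integer rounding followed by greedy unit corrections is
  globally optimal by separability and piecewise linearity. Ties prefer
  preserving averages nearest the k-space center; for even grids the center
  distance is $|m + 1/2|$ (the two central lines are equidistant), and
  remaining ties resolve toward the smaller row index on addition and the
  larger on removal.
* **$\lambda$.** Optimized in log-space so SGD preserves positivity, and
  initialized by a coarse NRMSE grid search on the same representative slice
  used for $\rho$ tuning (its initialization is otherwise unspecified).

## Training schedules at desk scale

The full-scale schedules (SGD batch 8; SENSE-TV uniform: lr 0.01, decay 0.9,
10 epochs; nonuniform: 45 joint + 5 refinement epochs with lr 0.001/0.01;
apodized: 50 or 45+5 epochs with pattern lr 0.1; pattern gradients
normalized to unit norm before the projected step) are kept, with two
deliberate adaptations, both consequences of training on 26 slices instead
of thousands:

1. **Mean reduction.** Minibatch gradients use the mean-squared-error
   reduction (averaged over batch and voxels). Under batch-summed losses the
   printed learning rates diverge immediately at any scale; under the mean
   reduction they are well-scaled, consistent with the loss being described
   as mean-squared error.
2. **Adam for the window.** The apodized window's per-entry loss curvature
   spans roughly four orders of magnitude between the k-space center
   ($\propto |s|^2$) and the edges ($\propto \sigma^2/w$). With only ~200
   SGD steps available at desk scale, a single SGD step size either stalls
   or diverges; the window is therefore trained with Adam (lr 0.02), an
   optimizer the schedule structure already provides. SENSE-TV keeps plain
   SGD for its scalar log-$\lambda$.

The per-epoch loss trace records the mean per-sample sum-norm loss. After
the joint epochs the pattern is rounded, frozen as exact effective averages
$q \, N_0/N$, and the reconstruction parameters adapt for the refinement
epochs.

The tests and the acceptance script run the design study at the generator's
desk-scale defaults with the full candidate set
$\{20, 32, 44, 64\}$ for the apodized family; the SENSE-TV searches use a
reduced candidate set $\{24, 64\}$ and 3 training epochs, problem sizes at
which a full run completes in a few minutes — sufficient because $\lambda$
is grid-initialized and the selection of $N$ is driven by the
noise/resolution tradeoff rather than by fine $\lambda$ adaptation.

## What the scaled-down study reproduces

On the synthetic suite with fixed seeds the package reproduces the
qualitative findings of the full-scale design study:

* the selected grid size $\hat N$ decreases as SNR decreases, for both
  reconstructor families (at SNR 2 the apodized design selects 31% of full
  resolution);
* optimized nonuniform patterns allocate more averages to central (low
  spatial frequency) k-space lines than to the outermost lines;
* nonuniform averaging trains to an inner loss at least as good as uniform
  averaging at every candidate $N$ (uniform is in its feasible set);
* with zero noise the search keeps full resolution — reduced coverage only
  pays when there is noise to suppress.

These are trend-level statements computed by `tests/testthat/` and
`scripts/acceptance.R`; the package makes no numeric claims about real
clinical data.

## Known limitations

* NRMSE is implemented exactly as printed in the field convention adopted
  here — normalized by the *estimate* norm — with the conventional
  reference-normalized variant available but off by default. SSIM is
  computed on magnitude images with an 11×11 Gaussian window (σ = 1.5),
  constants $K_1 = 0.01$, $K_2 = 0.03$, and dynamic range equal to the
  reference's maximum magnitude; the range convention makes it asymmetric.
  Both metrics are known to be weakly sensitive to resolution loss, which is
  precisely why the outer selection compares against high-resolution
  references.
* The inner problem is nonconvex; trained patterns are local minima and no
  global-optimality claim is made over sampling strategies. Undersampling
  (zero-average lines) is excluded by the positivity floor.
* The ADMM gradient treats the CG solve as exact; with very loose CG budgets
  the analytic gradient degrades away from the finite-difference reference.
* Dataset serialization uses RDS plus a plain-text CSV mirror.
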