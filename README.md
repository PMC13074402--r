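# kcoverage

Joint optimization of MRI k-space coverage, signal averaging, and
reconstruction under a fixed scan-time budget.

## The problem

Modern computational MRI denoisers are usually trained and deployed for a
fixed acquisition. But k-space coverage is itself a design variable: a
Cartesian scan that measures an `N × N` grid (instead of the nominal
`N0 × N0`) with `w̃_m` averages of phase-encode line `m` can reinvest the
saved repetitions into extra averaging, and the narrower readout bandwidth
adds a further SNR gain of `N0/N`. Writing the *effective* averages as
`w_m = w̃_m · N0/N`, the averaged noise on line `m` has variance
`σ²/w_m` and the scan-time budget is

```
Σ_m w_m = w̃0 · N0² / N          (budget of the reference scan: w̃0 · N0 TRs)
```

`kcoverage` finds the grid size `N̂`, the averaging pattern `ŵ`, and the
reconstruction parameters `p̂` that minimize the reconstruction error of a
chosen denoising method, via a bilevel search:

* **inner** (per candidate `N`): projected minibatch SGD jointly trains `p`
  and, in nonuniform mode, `w` against matched-resolution noise-free
  references `r^N` — with an exact Euclidean projection of `w` onto the
  budget hyperplane (`w ← w + β/N`) after every step, unit-norm gradient
  normalization for `w`, and globally optimal greedy `ℓ₁` rounding of the
  final pattern to integer averages;
* **outer**: brute-force search over candidate `N`, scoring each trained
  design against the high-resolution references `r^{N0}` with shared noise
  realizations.

Reconstructors implemented behind one interface `g_{p,N,w}(d) → N0 × N0`
image: **apodized** (trainable positive k-space window, closed-form
gradients), **SENSE-TV**
(`argmin_x ‖√w ⊙ (Ex − d)‖₂² + λ‖Dx‖₁`, 50-iteration ADMM in compiled
code with a hand-derived reverse-mode gradient through the unrolled
iterations), and a **CNN plugin** contract with a weight-free
coil-combination stub. A synthetic multicoil brain-phantom generator with
white-matter-ROI SNR calibration makes the whole pipeline testable at desk
scale (64-grid, 4 coils, 32 phantoms by default).

Who is this for: MRI acquisition/reconstruction researchers studying the
SNR-resolution tradeoff, and anyone needing a compact, fully testable
reference implementation of budget-constrained averaging design.

## Worked example

```r
library(kcoverage)

spec  <- phantom_spec()                       # N0 = 64, L = 4, T = 32
train <- assemble_training_set(spec)
train <- set_noise(train, target_snr = 2)     # sigma calibrated in a WM ROI

res <- outer_select_N(train, kind = "apodized", mode = "uniform",
                      candidates = c(20, 32, 44, 64), seed = 11)
print(res)
#> <design_result: apodized / uniform averaging>
#>   candidates N = {20, 32, 44, 64}
#>   selected N_hat = 20 (outer losses: 1239, 1459, 1716, 2225)
```

At SNR 2 the search selects `N̂ = 20` — 31% of full resolution — because
reinvesting scan time into averaging beats acquiring noisy high-frequency
samples. Repeating at SNR 10 selects `N̂ = 44`: as SNR improves, resolution
is worth keeping. With `mode = "nonuniform"` the trained integer pattern
concentrates averages at the center of k-space (e.g. 18 averages on the
central lines versus 15 at the edges for `N = 32` at SNR 2), and

```r
rep <- evaluate_design(res, train, split = "test")
#> <eval_report: apodized / uniform averaging, N_hat = 20>
#>   mean NRMSE 0.1470 | mean SSIM 0.6484 over 3 datasets
```

reports test-split NRMSE/SSIM against the high-resolution references.
With zero noise (`train$noise <- noise_model(0, 1)`) the same search keeps
full resolution, `N̂ = N0` — reduced coverage only pays when there is noise
to suppress.

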