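# t2moco

Retrospective motion correction for quantitative T2\* mapping from
multi-echo 2D gradient-echo (GRE) brain MRI, with self-supervised,
physics-informed detection of motion-corrupted k-space lines.

## Who this is for

Quantitative MRI groups doing T2\* relaxometry from Cartesian multi-echo
GRE: the acquisition is slow (one phase-encode line per TR per slice
package), so brief head movements corrupt contiguous blocks of PE lines
and bias the fitted maps. `t2moco` detects those lines *after* the scan,
without motion tracking hardware, navigators, or labelled training data,
and reconstructs the down-weighted data with a data-consistent unrolled
scheme.

## The method in brief

The signal model is mono-exponential decay, `s_n = s0 * exp(-TE_n / T2*)`.
The corrupted acquisition follows the rigid-motion multicoil forward model
`y = sum_t S_t F C U_t x`, where `U_t` combines in-plane rigid resampling
with the echo-time-dependent phase `exp(-2i * omega_t * TE_n)` of the
pose-dependent field perturbation.

Correction splits into two sub-problems:

1. **Line detection.** One continuous exclusion mask `Omega in [0,1]^Y`
   per interleaved slice package (Even/Odd; 2 × 92 = 184 parameters) is
   optimized with Adam through the frozen reconstruction so that
   `L_phys + L_reg` is minimal. `L_phys` is one minus the per-voxel
   correlation across echoes between reconstructed magnitudes and their own
   mono-exponential least-squares fit — motion-induced field changes break
   mono-exponentiality and raise it. `L_reg` penalizes exclusion, with
   stronger weight on the ten central lines. The central 2×2 k-space block
   is always kept (*KeepCenter*) to preserve the mean image intensity.
2. **Reconstruction.** An unrolled scheme alternates a denoiser with
   gradient-descent data-consistency steps,
   `x <- x - eta * A^H W (A x - y)`, where the soft mask enters both the
   k-space multiplication and the DC weight `W`.

All gradients (through the reconstruction, the magnitude, and the
differentiable log-linear fit inside the loss) are hand-derived
reverse-mode and verified against finite differences in the test suite.
Baselines (bootstrap-aggregation over random masks; weighted combination of
full/half/quarter-resolution reacquisitions), the digital multi-echo brain
phantom, rigid-motion + B0 simulation, and line/map quality metrics are
included. See `vignettes/methods.Rmd` for the full account.

## Worked example

A deterministic phantom, one 6 mm motion event corrupting 12 known PE
lines, detection, and evaluation:

```r
library(t2moco)

ph  <- make_digital_phantom(seed = 0)          # 92 x 64, 8 slices, 12 echoes
sch <- acquisition_times(92, ph$tr_ms)          # interleaved Even/Odd timing
cv  <- event_motion_curve(list(c(20.6, 47.38)), amplitude_mm = 6,
                          scan_duration_s = sch$scan_duration_s, seed = 7)
sim <- simulate_corrupted_kspace(ph$images, ph$csm, cv, sch, ph$te_ms)

opt <- optimize_exclusion_masks(sim$kspace, ph$csm, unrolled_config(),
                                ph$brain_mask, ph$sg_map,
                                detect_config(seed = 1))
opt
#> <mask_optimization> 100 epochs; final total loss 0.0025
#>   even mask: mean 0.842, 9 lines < 0.5
#>   odd  mask: mean 0.832, 14 lines < 0.5

mask_metrics(opt$mask_odd, sim$ref_mask$odd)
#> <mask_metrics> MAE 0.140 | accuracy 0.946 | precision 0.714 | recall 0.909
```

The detected masks flag the corrupted block (reference: lines 11–21 odd /
10–21 even). Reconstructing under them lowers the T2\* error relative to
ignoring the corruption:

```r
nz     <- normalize_volume(sim$kspace, ph$csm)
x_corr <- reconstruct_with_masks(nz$data, opt$mask_even, opt$mask_odd, ph$csm)
x_naive <- unrolled_reconstruct(nz$data$data, matrix(1, 92, 64), ph$csm,
                                unrolled_config())
fit  <- t2star_from_images(x_corr, ph$te_ms, mask = ph$brain_mask)
t2star_map_metrics(fit$t2star_ms, ph$t2star_map, ph$brain_mask, ph$sg_map)
```

reports the per-slice mean absolute T2\* error (ms) and SSIM (first
slices: 9.1 / 8.2 / 8.3 ms, SSIM ≈ 0.95); averaged over slices the
corrected reconstruction reaches 10.8 ms versus 14.4 ms uncorrected.
`physics_loss(Mod(x_naive), ph$te_ms, ph$brain_mask)` is 0.019 for the
corrupted data and ~0 for motion-free input — the signal the detection
optimizes.

## Command line

A thin wrapper over the same functions is installed as `exec/t2moco`:

```sh
t2moco phantom  --seed 0 --out ph/
t2moco simulate --input ph/ --out sim/ --n-events 2 --amplitude-mm 6
t2moco detect   --input sim/ --out masks.csv
t2moco reconstruct --input sim/ --masks masks.csv --out recon/
t2moco fit      --input recon/ --out maps/
t2moco evaluate --masks masks.csv --ref-masks sim/reference_masks.csv \
                --out metrics.json
```

Every subcommand accepts `--config <yaml>`, rejects unknown keys, and
writes a JSON manifest (resolved configuration, seed, input hashes) next to
its outputs.

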