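---
title: "Physics-informed detection of motion-corrupted k-space lines for T2* mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-informed detection of motion-corrupted k-space lines for T2* mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(t2moco)
```

## The problem

Quantitative T2\* mapping acquires a series of gradient-echo images at
increasing echo times and fits the mono-exponential magnitude decay

$$ s_n = s_0 \, e^{-\mathrm{TE}_n / T_2^*} $$

per voxel. In a Cartesian 2D multi-slice acquisition every phase-encode
(PE) line of every slice is measured at a distinct time, so a brief head
movement corrupts a contiguous block of PE lines in every echo. Those lines
leave ringing and wave-like artifacts in the images and systematic errors
in the fitted T2\* maps.

`t2moco` implements a retrospective, self-supervised correction that needs
no motion tracking and no paired training data:

1. **Forward model.** The corrupted acquisition is
   $\hat{y} = \sum_t S_t \mathcal{F} C\, U_t x$, where $S_t$ samples the
   line(s) acquired at time $t$, $C$ are coil sensitivities, $\mathcal{F}$
   is the centered unitary 2D Fourier transform, and
   $U_t = e^{-2 i \omega_t \mathrm{TE}_n}\, T_t R_t$ combines rigid
   resampling with the phase of the pose-dependent in-plane field
   perturbation $\omega_t$ (rad/s), which grows with echo time.
2. **Line exclusion.** If the subject is still most of the time, a per-line
   weight vector $\Omega \in [0,1]^Y$ (1 = keep) multiplied into k-space
   removes the corrupted lines: $\Omega \hat y \simeq \Omega y$.
   Reconstruction of the down-weighted data is a data-consistent unrolled
   scheme that alternates a denoiser with gradient-descent data-consistency
   steps.
3. **Self-supervised detection.** The weights are found by minimizing a
   physics-informed loss through the frozen reconstruction: per voxel, one
   minus the empirical correlation across echoes between the reconstructed
   magnitudes and their own mono-exponential least-squares fit, averaged
   over the brain mask. Motion-induced field changes break
   mono-exponentiality, so corrupted lines raise the loss and the optimizer
   learns to suppress them.

## The detection objective

One mask is optimized per interleaved slice package ("Even/Odd"): even and
odd slices are excited in separate passes with distinct timing, so lines of
the two packages are corrupted independently, while all slices within a
package share the same corruption pattern. For $Y = 92$ PE lines this gives
a parameter vector of length $2Y = 184$.

The total objective is $L_\mathrm{phys} + L_\mathrm{reg}$ with

$$ L_\mathrm{reg} = \lambda_\mathrm{reg}\Big[\big(1 - \tfrac1Y \textstyle\sum_y
\Omega_y\big) + \lambda_\mathrm{center} \big(1 - \tfrac1{10}
\textstyle\sum_{y \in \mathrm{ctr}} \Omega_y\big)\Big], $$

which penalizes unnecessary exclusion, with extra weight
($\lambda_\mathrm{center} = 2$) on the ten central lines whose loss would
destroy the image contrast. The central window is the half-open 0-based
range $[Y/2-5,\, Y/2+5)$, which contains exactly ten lines including DC;
the closed form of the printed bounds would contain eleven, contradicting
the stated count, so the half-open reading is used.

**KeepCenter.** The 2×2 k-space block around DC (the smallest symmetric
group containing the DC sample on an even grid) is forced to weight 1 both
during reconstruction training and at inference. The mean image intensity
changes little under small motion, while excluding it falsifies every
fitted $s_0$ and T2\*; keeping it is the cheaper error.

**Parametrization.** Weights are squashed through a gain-logistic,
$\Omega = \sigma(g\,p)$ with $g = 6$, initialized at $\Omega \approx 0.95$.
The gain follows from a budget argument rather than tuning: Adam's
sign-normalized steps move each parameter by at most $\approx$
epochs × lr = 1.0 under the fixed budget (learning rate 0.01, 100 epochs),
and with a plain logistic the initialization near 1 could never even cross
the 0.5 decision boundary within that budget. Requiring the budget to span
the usable mask range — from the 0.95 initialization down to a deep
exclusion of 0.05, a logit span of $2\,\mathrm{logit}(0.95) \approx 5.9$ —
gives $g \approx 6$.

**Slice selection.** The loss is vulnerable to strong static susceptibility
gradients (they also break mono-exponentiality), so optimization uses only
the most inferior eight slices with more than 20% brain voxels and mean
susceptibility gradient below 80 µT/m; each step samples a batch of 20
slices with replacement from that set (the batch size intentionally exceeds
the selected count). The resulting two masks are applied to all slices.

**Gradients.** No autodiff framework is used: the whole chain — k-space
multiplication, data-consistency weights, unrolled reconstruction,
magnitude, and the closed-form log-linear fit inside the loss — is
differentiated by hand in reverse mode. The fit is recomputed from the
current magnitudes at every step and differentiated through (its hat matrix
is constant, which keeps this cheap). The test suite checks every gradient
path against central finite differences.

## Reconstruction

`unrolled_reconstruct()` starts from the zero-filled adjoint and alternates
a denoiser with the DC step $x \leftarrow x - \eta A^H W (A x - y)$ five
times. With unit-RSS coil maps the operator norm of $A^H A$ is at most 1,
so $\eta = 1$ is stable. The soft mask enters both the initial k-space
multiplication and the DC weight $W$, keeping the operator consistent.

The default denoiser is the identity (or a small Gaussian smoother): the
reconstruction is then a plain data-consistency iteration, fully testable
on CPU with no training, and under full sampling it recovers the reference
image exactly. A compact learnable denoiser (two 3×3 conv layers, 16
features, ReLU, residual connection, independent weights per iteration,
real/imaginary echo channels stacked) is provided with hand-written
backpropagation and can be trained on randomly undersampled motion-free
data with an MSE loss (`train_unrolled()`); it is a deliberately small
stand-in at phantom scale, not a re-creation of any particular trained
network.

## Motion simulation and the digital phantom

Because scanner data cannot ship with the package, `make_digital_phantom()`
builds a deterministic piecewise-elliptical brain: WM/GM/CSF compartments
with T2\* around 45/60/250 ms (design values in plausible tissue ranges)
and smooth within-compartment variation, smooth unit-RSS coil profiles, a
smooth B0 field whose finite-difference gradient magnitude provides the
susceptibility-gradient map, and mono-exponential echoes with a static
off-resonance phase. The default geometry is 92 PE × 64 readout × 8 slices,
12 echoes (TE 5…60 ms), TR 2300 ms, 4 coils, 2 mm in-plane voxels: the
protocol's PE count, echo timing and TR at a slice/readout/coil count that
keeps the full detection loop in CPU minutes. The two most superior slices
carry deliberately strong field gradients so that susceptibility-based
slice selection has something to reject. Full protocol geometry (36 slices,
larger readout, more coils) is reachable through the arguments.

`synthetic_motion_curve()` emulates an instructed-motion protocol: a still
baseline with a few events of 5–10 s whose rigid pose is scaled so the
average displacement of points in a 64 mm sphere (the severity metric,
evaluated on a fixed 4096-point Halton set for determinism) matches the
requested amplitude. Curves are median-centered: every state is composed
with the inverse of the state of median displacement, aligning the
reconstruction with the dominant pose so full-reference metrics need no
registration. `simulate_corrupted_kspace()` applies the motion forward
model only to lines whose displacement exceeds 2 mm (one voxel); corrupted
lines additionally receive the phase of a smooth random field perturbation
(Gaussian-filtered white noise, rescaled to a peak amplitude, default
5 rad/s) scaled linearly by `displacement / threshold`. The scaling is
deliberately uncapped: a larger pose change plausibly produces a larger
susceptibility-field change, and capping it at the threshold would make
3 mm and 6 mm events equally corrupting, destroying the intended monotone
relation between motion amplitude and corruption severity. The default
peak amplitude corresponds to a sub-hertz to few-hertz pose-dependent
frequency shift (roughly the magnitude reported for moderate head
movements away from air-tissue interfaces) and keeps the accumulated
phase `2 omega TE` well below a cycle across the echo train even at 6 mm
displacement; at tens of rad/s the phase wraps within the echo train and
the corruption severity saturates instead of growing with amplitude.
A PCA model over
motion curves (`pca_augment()`) reproduces the augmentation scheme used to
enlarge motion-curve training sets: the mean curve plus the top 20% of
components weighted by normal scores with the training score variances.

What the phantom does *not* emulate: anatomical detail, through-plane
motion resampling (a 2D multi-slice model cannot re-slice; through-plane
components still count toward displacement), parallel-imaging artifacts,
physiological noise, and the true statistics of the field change that
accompanies head motion. Passing tests therefore demonstrate the mechanics
and self-consistency of the method, not clinical performance.

## Numerical choices

* FFTs are centered and unitary; DC sits at index $N/2$ (0-based), the
  KeepCenter block is $\{N/2-1, N/2\}$ in both axes. Adjoint = inverse.
* Eq.-style phase factor implemented as printed, $e^{-2 i \omega \mathrm{TE}}$,
  with `phase_gain = 1` available for the conventional single factor; the
  factor only rescales the simulated $\omega$ amplitude, so no result in
  the package depends on the choice.
* Rigid in-plane resampling is bilinear with zero fill outside the FOV;
  differentiability with respect to motion is never needed.
* The log-linear fit floors its log argument at $10^{-6}\times$ the volume
  maximum; voxels with non-negative decay slope are flagged invalid and
  clamped to the 1–1000 ms export range (the fit itself is unclamped).
* Zero-variance voxels are excluded from the physics-loss average rather
  than scored zero, so wiping out signal is never rewarded.
* Variable-density masks exclude line $k$ with probability proportional to
  $|k|/(Y/2)$ (exact exclusion count enforced); DC is never excluded.
* The half-TR offset between the two slice packages is a modeling choice;
  the intra-TR ordering is not observable by any package computation.
* 0-based slice parity defines the Even package; a flag flips the
  convention.

## Problem sizes

Module tests run on a 48×32×4-slice phantom (6 echoes, 2 coils); the
end-to-end checks use the default 92×64×8 geometry with the full
100-epoch detection, chosen so the complete suite runs in minutes on one
CPU core. The variance-bound and rate-calibration properties use 300–1000
seeded draws.

## Limitations

* Detection shares one mask per package; isolated per-slice corruption
  (e.g. swallowing affecting a single slice's excitation) is averaged out.
* With the identity denoiser, excluded lines are zero-filled rather than
  inpainted, so aggressive exclusion trades motion artifacts for
  undersampling artifacts; the regularizer balances this.
* The simulated field perturbation is a stationary smooth field scaled by
  displacement; real pose-dependent susceptibility changes are spatially
  structured around air-tissue interfaces.
* The conv denoiser is trained at phantom scale only and is not expected
  to transfer to real acquisitions.
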