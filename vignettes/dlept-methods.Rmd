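---
title: "Simulation and reconstruction methods in dlept"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation and reconstruction methods in dlept}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

MR electrical properties tomography (MR-EPT) aims to map tissue conductivity
$\sigma$ (S/m) and relative permittivity $\varepsilon_r$ from measurements of
the radiofrequency transmit field $B_1^+$ of a clinical MR scanner. At 3 T
(128 MHz) the classical analytic route — the Helmholtz identity

$$\varepsilon_r(\mathbf r) = \frac{-1}{\mu_0 \varepsilon_0 \omega^2}
  \operatorname{Re}\frac{\nabla^2 B_1^+}{B_1^+}, \qquad
  \sigma(\mathbf r) = \frac{1}{\mu_0 \omega}
  \operatorname{Im}\frac{\nabla^2 B_1^+}{B_1^+}$$

— requires second spatial derivatives of noisy data and therefore amplifies
measurement noise severely; permittivity in particular is barely accessible.
The package implements both this baseline (H-EPT) and a data-driven
alternative: a conditional GAN trained on simulated fields (DL-EPT), which
learns the mapping from MR-accessible quantities (transmit magnitude,
transceive-derived phase, and a mask or tissue-contrast channel) to the
property maps. Everything needed to study the two approaches — tissue models,
an electromagnetic solver, a calibrated noise model, training, and evaluation
— is generated inside the package; no external data are required.

## Tissue models

Models are 2D label grids with piecewise-constant properties; air is label 0
with $\sigma = 0$, $\varepsilon_r = 1$ exactly. The bundled 128 MHz property
table holds the literature values used as ground truth (WM 0.34 S/m / 52.6,
GM 0.59 / 73.4, CSF 2.14 / 84, tumor analogue 1.4 / 73, agar phantom
0.88 / 80).

* **Phantoms** are homogeneous 12 cm disks. Libraries sample
  $\sigma \in [0.2, 2.2]$ S/m and $\varepsilon_r \in [40, 90]$ with
  stratified uniform draws — the ranges bracket the tissue and phantom
  values in the 128 MHz table, and the stratification guarantees coverage
  even for small libraries.
* **Head stand-ins** are nested, sinusoidally perturbed shells (outer CSF
  rim, thick GM ribbon, WM core) plus two ventricle-like CSF inclusions.
  Two deliberate departures from anatomy matter here:
  * The GM ribbon is much thicker than cortex. At the working resolution
    (2 mm) a realistically thin cortex leaves no interior voxels after the
    3-voxel ROI erosion that the evaluation prescribes, so per-tissue
    statistics would be undefined. The ribbon is sized so each tissue
    retains an eroded interior.
  * The geometry is bilaterally symmetric up to a small `asymmetry`
    parameter (default 0.2). Real heads are close to left-right symmetric
    with respect to a quadrature body coil, and that symmetry is what makes
    the transceive phase assumption (below) accurate in practice. With
    fully random asymmetric shapes the assumption error alone biased GM
    permittivity by roughly 17% even without noise — far beyond the error
    budget head reconstructions are known to achieve at 3 T.
  Per-tissue properties are the table values perturbed uniformly within
  `eps_variation` (default ±10%), constant within each tissue.
* **Tumors** are disk inclusions (default 1.5 cm radius, 1.4 S/m, 73)
  overwriting host tissue; placement into air is refused.

## Electromagnetic forward model

The solver works in the frequency domain in 2D, TM polarization: only the
longitudinal electric field $E_z$ is nonzero and satisfies
$(\nabla^2 + \omega^2 \mu_0 \tilde\varepsilon(\mathbf r)) E_z =
-i\omega\mu_0 J_z$ with $\tilde\varepsilon = \varepsilon_0\varepsilon_r -
i\sigma/\omega$ under the $e^{+i\omega t}$ convention (the sign convention is
fixed package-wide and verified by the closed-form exponential-field test).
This is a deliberate desk-scale stand-in for 3D FDTD with an anatomical coil
model: the reconstruction problem is slice-wise 2D anyway, and a 2D sparse
direct solve takes seconds instead of hours. The fidelity cost — no
longitudinal field variation, no end-ring effects — is accepted and
documented.

The coil is 16 line sources on a 0.35 m circle driven in quadrature
(phases $-\phi_n$), mimicking the dominant rotating birdcage mode. Because
the sources lie outside the computational grid, the solve uses the
scattered-field formulation: the incident field is evaluated analytically
(outgoing Hankel functions $H_0^{(2)}$), and only the object-scattered field
is solved on the grid, with homogeneous Dirichlet edges behind a 6-voxel
conductive damping annulus ($\sigma$ ramping quadratically to 15 S/m) that
absorbs outgoing waves. A complex system of size $n^2$ is assembled as a real
system of size $2n^2$ (the sparse factorization handles the transmit- and
receive-polarity drives together). Requirements: at least a 10-voxel vacuum
margin around the object; the 128×128 / 2 mm default leaves comfortable
margins for 12 cm phantoms and the head models.

**Verification oracle.** For a homogeneous cylinder the interior transmit
field is $B_1^+ \propto J_0(k\rho)$ with
$k^2 = \omega^2\mu_0(\varepsilon_0\varepsilon_r - i\sigma/\omega)$, and the
counter-rotating component is $\propto J_2(k\rho)e^{2i\varphi}$; coefficients
follow from mode matching at the boundary. `analytic_cylinder_field()`
implements this closed form (complex-argument Bessel functions by power
series) and the test suite requires the solver to agree with it to better
than 2% in the interior.

**Transmit, receive, and the transceive phase.** The receive sensitivity
$B_1^-$ is computed from a second solve with reversed drive polarity. By
reciprocity the receive field enters the measured signal conjugated, so the
transceive phase is $\varphi^\pm = \arg(B_1^+ \overline{B_1^-})$, unwrapped
inside the object by flood fill. The reconstruction input uses the standard
3 T transceive assumption $\tilde\varphi^+ = \varphi^\pm/2$. On a
mirror-symmetric object this equals the true transmit phase up to a
constant; on asymmetric objects it carries a genuine error — exactly the
approximation error the real measurement has.

## Noise model

Thermal noise is injected as independent Gaussian noise on the real and
imaginary parts of the (normalized) complex transmit field, with standard
deviation `mean(|field| in mask) / SNR`; the magnitude channel is then the
magnitude of the noisy complex field. The default magnitude SNR is 90. Phase
noise is an independent Gaussian knob with default SD $9\times10^{-3}$ rad
applied to $\tilde\varphi^+$ (a phase-precision figure can be read as
applying to $\tilde\varphi^+$ or to $\tilde\varphi^\pm$; this package
applies it to $\tilde\varphi^+$). SNR is
measured as mean in-mask clean magnitude over residual SD; calibration is
verified to 2% on masks of more than 1000 voxels.

## Helmholtz reconstruction (H-EPT)

Second derivatives come from a noise-robust Savitzky–Golay kernel: the
least-squares second-order polynomial fit over a 7×7 (2D) support. It is
exact for quadratics, annihilates linear fields, and has a noise
amplification factor ~1500× smaller than the 5-point stencil at equal
spacing — the properties that make large derivative kernels the standard
choice for Helmholtz reconstruction on noisy data. Voxels whose kernel footprint crosses the object boundary, or where
the field vanishes, are excluded from the valid mask rather than
extrapolated — boundary voxels are unreliable by construction, which is also
why evaluation erodes ROIs.

`erode_rois()` uses a *square* structuring element by default: after an
erosion of radius 3, every surviving voxel's 7×7 footprint lies inside its
own tissue, which is the stated purpose of the 3-voxel erosion (avoiding
boundary regions). With a Euclidean disc, diagonal voxels keep footprints
straddling boundaries and per-tissue means are visibly contaminated; the
disc remains available as an option.

## The cGAN reconstructor (DL-EPT)

Separate networks are trained for conductivity and permittivity with the
objective
$\lambda_{GAN}\mathcal L_{cGAN} + \lambda_{L1}\mathcal L_{L1} +
\lambda_{L2}\mathcal L_{L2}$, defaults $(2, 100, 200)$; the tumor experiment
uses the boundary-sharpening combination $(2, 1000, 2000)$. Setting
$\lambda_{GAN}=0$ yields the plain U-Net ablation through the identical
pipeline. The generator is a U-Net (4 resolution levels at 64², stride-2
4×4 encoder convolutions, nearest-upsampling + 3×3 decoder convolutions,
instance normalization, skip connections); the discriminator is a 3-layer
PatchGAN scoring ~22-pixel patches of (input, map) stacks. Only the
U-Net/PatchGAN family is fixed by the method; the layer counts, widths and
optimizer settings are this package's choices: Adam with $\beta_1 = 0.5$,
batches of 5 stacked images, weight init $\mathcal N(0, 0.02)$.

Numerical/training choices that were genuinely open and are fixed here:

* **Input normalization**: magnitude divided by its in-mask mean (the only
  normalization available at measurement time), phase divided by $\pi$,
  targets mapped linearly to $[0,1]$ over $\sigma \in [0, 2.5]$ S/m and
  $\varepsilon_r \in [1, 100]$ and inverted at inference; air is clamped to
  vacuum values outside the mask.
* **Object-weighted regression**: object voxels receive weight $1 +$
  `mask_weight` (default 4) in the L1/L2 terms. About 83% of a desk-scale
  image is air with a trivially constant target; with unweighted means the
  small-sample fits collapsed toward the dataset-mean property value.
* **Per-target schedules**: conductivity networks use 30 epochs at
  $2\times10^{-4}$ with object-voxel weight 4; permittivity networks
  45 epochs at $4\times10^{-4}$ with weight 8, both with the rate decaying
  linearly to zero over the second half. The conductivity cue (transceive
  phase slope) is nearly linear and converges quickly; the permittivity cue
  (magnitude curvature) is weaker at 128 MHz and needs the longer schedule.
* **Collapse screening**: a minority of training seeds stall in a mode that
  predicts the dataset-mean property (the stall is a property of the
  small-sample optimization landscape: it appears identically without the
  discriminator, with larger initializations, and under a noiseless
  curriculum). A validation-NRMSE probe three quarters of the way through
  training abandons such runs and restarts once from a derived seed — the
  same validation-based screening philosophy as the NRMSE-based model
  selection.
* **Compiled core**: convolutions run through a small Rcpp/Armadillo kernel
  (im2col gather, single-precision GEMM, transposed scatter). Training
  tolerates single precision comfortably; the solver, the Helmholtz
  reconstruction and all physics stay in double precision.
* **Pseudo-slices**: the 2D stand-in has no third dimension to slice, so
  multiple "slices" per model are emulated by independent noise draws plus
  small integer-voxel translations (±1) of the whole scene. The translation
  is an augmentation, not a re-solve; at these shifts the incident-field
  inconsistency is negligible compared to noise.
* **Determinism**: every stochastic step (library sampling, geometry, noise,
  initialization, shuffling) draws from seeds derived from one master seed;
  fits are bit-reproducible.

## Evaluation harnesses and problem sizes

The experiment functions run the package's standard quantitative
comparisons at sizes chosen for a desk machine; the sizes are part of those
standard conditions and are stated here once:

* `experiment_noise_calibration()`: 12 cm phantom at 128² / 2 mm, 8 noise
  injections (~2800 mask voxels each).
* `experiment_phantom_dlept()`: 42-phantom library at 64² / 4 mm, the
  standard split (validation 12/24, test 38/42), 5 slices per model (190
  training examples), 3 training seeds; evaluates held-out phantom 42 with
  ROI means averaged over 4 independent acquisitions (its emulated slices),
  reporting per-quantity medians across seeds. The Helmholtz precision
  baseline runs on the same phantom at the 2 mm acquisition-native grid —
  the analytic method needs no training, and Laplacian noise amplification
  scales as $1/h^2$, so evaluating it at the coarse network grid would
  understate the baseline's noise by 4x (the harness reports both). The
  SNR 20 vs 90 comparison uses per-voxel masked NRMSE — ROI means average
  away exactly the map corruption at stake — with phase noise scaling as
  $9\times10^{-3}\cdot 90/\mathrm{SNR}$ so both noise sources track the
  level.
* `experiment_head_hept()`: one head at 128² / 2 mm, three noise seeds,
  WM/GM eroded-ROI errors.
* `experiment_tumor()`: mixed phantom/head library at 64² (12 + 12 models,
  5 slices each), tumor-free training, a held-out head with a 1.5 cm tumor,
  CNR $|\mu_{tumor}-\mu_{WM}|/\mathrm{SD}_{WM}$ for both methods. The
  tumor ROI uses a 1-voxel erosion at 4 mm (the ~7-voxel inclusion would
  not survive the standard 3 voxels); the Helmholtz arm runs on the same
  physical scene at 2 mm with the standard erosion.

  This experiment is the package's known negative result: the desk-scale
  networks do not develop a usable response to an inclusion class absent
  from training. The reconstructed tumor conductivity stays near the host
  tissue value and the tumor CNR remains below the Helmholtz baseline's —
  the opposite of the ordering that large-scale training is able to
  deliver. Two desk-scale factors conspire: the 2D Helmholtz baseline in
  these conditions is considerably less noisy than a 3D counterpart
  (white-matter SD ~0.27 S/m at SNR 90), so it detects the 15-voxel
  inclusion on the 2 mm grid comfortably; and networks trained on 24
  tumor-free models at 64² lack the diversity (thousands of anatomically
  convoluted slices) that out-of-class generalization rests on. The
  harness reports the numbers as measured; the corresponding ordering
  check in the test suite fails by design rather than being weakened.

NRMSE is RMSE over the mask divided by the in-mask mean of the truth (the
source does not define its normalization); table-style SDs use the
population convention. Both choices are configurable.

## What the synthetic data do and do not show

The generator emulates: piecewise-constant dielectric geometry at 128 MHz,
quadrature excitation, dielectric resonance brightening, transceive-phase
error on asymmetric objects, and thermal noise at calibrated SNR. It does
not emulate: 3D field variation, anatomical detail at cortical scale, coil
rung/end-ring structure, $T_1/T_2$ contrast physics behind the pseudo
spin-echo images, Rician magnitude bias, or physiological noise (motion,
CSF pulsation). Passing tests therefore demonstrate correctness of the
algorithms and the claimed *orderings* (noise robustness of DL-EPT over
H-EPT, tumor conspicuity, SNR breakdown) under the stated model — not
clinical performance on in-vivo data.

## Known limitations

* The 2D TM model cannot reproduce absolute 3D field patterns of a physical
  birdcage; only structure-level behavior transfers.
* Networks are trained at 64² with small capacity; they recover ROI-level
  statistics well but per-voxel texture only approximately.
* H-EPT CSF statistics on head models are unreliable (thin rim, kernel
  contamination) — consistent with the known boundary-error behavior of
  Helmholtz reconstruction, and the reason CSF is excluded from the head
  accuracy checks.
* Only 128 MHz (3 T) properties are bundled; other field strengths would
  need their own dielectric table and validation.
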