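---
title: "Quantifying nuclear mechanics and chromatin dynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear mechanics and chromatin dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucmech)
```

# Scope

`nucmech` implements four quantitative pipelines used to characterise how DNA
damage changes the biophysical state of the cell nucleus, together with the
group statistics that tie them together:

1. **AFM nanoindentation** — from raw z-sensor/deflection records to effective
   Young's moduli via a pyramidal-tip Hertz model, with thermal-noise
   spring-constant calibration and per-cell averaging.
2. **Multifocal 3D single-particle tracking** — from nine-plane tiled camera
   movies to 3D trajectories and anomalous-diffusion coefficients.
3. **EM chromatin condensation** — dark/light pixel fractions inside a nuclear
   mask as a measure of condensed vs decondensed chromatin.
4. **High-content γH2AX screening** — nuclei segmented from the Hoechst
   channel, damage scored per nucleus, damage percentages per field.

Because raw data of this kind are rarely shared, every pipeline is paired with
a seeded generator that simulates its input with known ground truth. The
package's validation strategy is *parameter recovery*: data generated at a
known truth must be recovered by the corresponding analysis stage within a
stochastic tolerance. The test suite additionally pins each estimator to an
independent oracle (exhaustive grid search for the Hertz fit, the O(N²)
definition for the MSD, brute-force assignment for the linker, numeric
integration of the t density for p-values).

# AFM force-curve analysis

## Model

A rigid four-sided pyramid indenting an elastic half-space produces

$$F = C_{\mathrm{pyr}}\,\frac{E}{1-\nu^2}\,\tan\theta\,\delta^2,
\qquad C_{\mathrm{pyr}} = 0.7453,$$

with indentation depth $\delta$, effective Young's modulus $E$, Poisson ratio
$\nu$ and face half-angle $\theta$ (Bilodeau's result for a regular four-sided
pyramid). A flag switches to the Sneddon cone prefactor ($0.5\tan\theta$) for
users whose "modified Hertz" convention is conical. The raw observables are
the z-piezo position $z$ and the cantilever deflection $d$; force is
$F = k(d-d_0)$ and the true indentation subtracts cantilever bending,
$\delta = (z - z_0) - (d - d_0)$, where $d_0$ is the baseline deflection
(median of the first 20% of samples) and $z_0$ the contact point.

Parameter conventions and defaults:

* `theta` — the probe is specified by vendors through its *opening* angle; a
  35° opening angle means a 17.5° face half-angle, which is what enters
  $\tan\theta$. Default 17.5°, configurable.
* `nu = 0.5` — cells treated as incompressible; configurable.
* `F_max = 1.5` nN — the fit window runs from contact to the first sample
  exceeding this force, matching force-capped indentation protocols.
  Approach segments only; no adhesion, viscoelastic or finite-thickness
  corrections (explicit non-goals).
* `k` in pN/nm; all lengths in nm; moduli in Pa.

## Contact-point detection

The contact point is found by piecewise model selection rather than
derivative thresholding: every candidate $z_0$ induces a two-part model
(flat baseline before, Hertzian rise after, with $E$ refit in closed form —
the model is linear in $E/(1-\nu^2)$), and the candidate minimising the total
squared deflection residual wins. A coarse stride-8 scan is refined by an
exhaustive local scan and then golden-section search between neighbouring
samples. The procedure is deterministic, translation-equivariant, and errors
out (`no_contact`) when no candidate beats the baseline-only model. On
noiseless synthetic curves it recovers $z_0$ to better than one sample
spacing and $E$ to <0.1%; at 1 nm RMS deflection noise the median fitted
modulus stays within 5% of truth across 0.5–10 kPa.

## Spring-constant calibration

The thermal method equates the deflection variance of a free cantilever with
$k_BT/k$. The implementation removes DC and linear drift, integrates the
power spectrum (DC bin excluded) and applies the first-flexural-mode
correction $k = \beta\,k_BT/\langle d^2\rangle$ with $\beta = 0.817$. The
matching generator simulates the *measured* first-mode deflection — a simple
harmonic oscillator spectrum whose apparent variance is $\beta\,k_BT/k$ — so
that generator and calibrator form a consistent round trip; setting
`beta = 1` in the generator yields an ideal displacement record obeying
equipartition exactly ($\langle d^2\rangle = k_BT/k$, i.e. 0.1358 nm² for
k = 30 pN/nm at 295 K). This measurement convention is a package design
choice: the two conventions differ by 18% and cannot both round-trip, so the
calibrator's form was taken as primary.

# Multifocal 3D single-particle tracking

## Geometry and calibration

An aberration-corrected multifocal microscope forms nine simultaneous images
of successive focal planes as a 3×3 tile on one camera. The package's tile
convention is row-major with plane 1 (shallowest) top-left; the calibration
file records this order. Reconstruction needs three calibrations: (i) the
inter-plane spacing (nominal 400 nm; fiducials at a shared depth carry no
spacing information, so it is taken from configuration), (ii) a 2×3 affine
transform per plane mapping observed tile coordinates to the reference plane
(plane 5, the central one), and (iii) per-plane relative detection
efficiencies, which in practice scatter within ±5–15% of their mean.
`calibrate_planes()` estimates (ii) by least squares on matched fiducial
centroids and (iii) from mean fiducial intensities; recovery on simulated
bead fields is better than 0.1 px and 2% respectively.

## Reassembly, detection, linking

Each frame is split into tiles, each tile is warped into the reference frame
(bilinear interpolation), divided by its efficiency and stacked along z.
Preprocessing is deterministic and order-fixed: percentile background
subtraction (median by default; negative residuals are *kept* so robust
noise estimates downstream remain meaningful), optional Richardson–Lucy
deconvolution (3–5 iterations, Gaussian PSF), optional Gaussian denoising.
Detection takes 3D local maxima above median + 8·MAD and refines x, y, z by
log-quadratic interpolation — exact for Gaussian lateral spots and a
Gaussian axial response (σ_z default 350 nm, a configurable stand-in for the
unknown axial PSF). At the default spot SNR (~10) localization errors are
~20 nm laterally and ~100 nm axially.

Linking is frame-to-frame with a hard displacement gate (default 400 nm) and
no gap closing; a missed detection terminates the track, and tracks shorter
than 10 frames are discarded. Within each conflict component the assignment
maximising the number of links and minimising total squared displacement is
found exactly by enumeration when the component is small (≤8 nodes), with
greedy nearest-neighbour as the large-component fallback; on ≤3 particles
the output provably equals the brute-force global optimum.

## MSD analysis

Per track, the time-averaged 3D MSD is
$\mathrm{msd}(n\,\Delta t) = \langle |r_{i+n} - r_i|^2 \rangle_i$ for lags up
to a quarter of the track length, and the anomalous-diffusion model

$$\mathrm{msd}(\tau) = 6D\tau^{\alpha} + 6\sigma_{\mathrm{loc}}^2$$

is fitted by weighted least squares on the first 10 lags, with
inverse-variance weights from the standard Qian approximation
$\mathrm{var}(\mathrm{msd}_n) \approx \mathrm{msd}_n^2\,(2n^2+1)/(3n(N-n+1))$.
The localization floor is co-fitted with a lower bound of zero by default, or
fixed when σ_loc is known. Because α is free, the generalized coefficient D
has units μm²/s^α; an apparent coefficient
$D_{\mathrm{app}} = \mathrm{msd}(\tau_1)/(6\tau_1)$ in plain μm²/s is also
reported for comparability. Condition summaries pool per-track D (mean ±
SEM); an ensemble-MSD fit is available through the same functions by
averaging MSD curves first.

## Synthetic trajectories

Each axis is an independent fractional Brownian motion with Hurst exponent
$H = \alpha/2$, synthesised through the exact Cholesky factor of the
fractional-Gaussian-noise covariance, so
$\mathrm{MSD}(\tau) = 6D\tau^\alpha$ holds exactly in expectation at every
lag — a deliberate choice over approximate spectral schemes, because
parameter recovery is the package's acceptance surface. Defaults follow the
acquisition being emulated: 32 ms frames, 30 s movies, 400 nm plane spacing,
±15% efficiency jitter, ~20 nm localization noise.

## A physical limitation worth knowing

Freely diffusing nuclear proteins (D ≈ 0.8–1.2 μm²/s) have RMS frame steps
of $\sqrt{6D\Delta t} \approx$ 390–480 nm at 32 ms — at or beyond the 400 nm
linking gate — and cross the whole 3.2 μm nine-plane axial span in about a
second. Tracks surviving the gate are therefore conditioned on small steps,
which biases per-track D estimates low by roughly a factor of two, and long
uninterrupted tracks of such molecules simply do not exist in this geometry.
This is a property of the acquisition physics, not of the implementation.
Consequently the rendered-movie chain is validated end to end at
diffusivities where steps sit well inside the gate (e.g. D = 0.02 μm²/s,
recovering D within 15% and α within 0.1), while recovery of fast printed
coefficients is demonstrated at the MSD-analysis stage on simulated
trajectories with realistic localization noise. Users tracking fast species
should shorten the frame interval or widen the gate, and treat per-track D
from gated linking with caution.

# EM chromatin condensation

Condensed chromatin stains densely in transmission EM, so the condensed area
fraction inside a nuclear mask is measured by thresholding: per-image Otsu
computed *within the mask* (staining intensity varies between sections, so a
global threshold across images would confound condition with exposure), or a
fixed threshold for auditability. Dark fraction + light fraction = 1 by
construction; pixels outside the mask never influence the result. Masks are
caller-supplied inputs — nucleus segmentation from EM, texture features and
heterochromatin subclassification are non-goals.

One guard was added to plain Otsu: a unimodal in-mask histogram (no
condensed phase at all) would otherwise be split near its middle, reporting
~50% condensation for a uniformly decondensed nucleus. The split is
therefore accepted only when the two class means separate by more than 4
pooled within-class SDs; otherwise the mask is read as single-phase
nucleoplasm (dark fraction 0, flagged `bimodal = FALSE`). The symmetric
failure mode — a nucleus so condensed that *no* light phase remains — would
also read as decondensed; that regime is outside the assay's working range
and flagged as a known limitation.

The matching generator thresholds a smoothed Gaussian random field at the
quantile that makes dark blobs cover exactly the requested fraction of the
mask (to one pixel), with configurable blob scale, two-phase contrast and
additive noise. It makes no attempt at realistic chromatin texture beyond a
two-phase blob field.

# High-content γH2AX screening

## Segmentation and measurement

Nuclei are segmented from the Hoechst channel by Gaussian smoothing → Otsu →
hole filling → watershed on the distance map (to split touching nuclei) →
area filter in μm². Per nucleus, the pipeline reports the area
(pixel count × pixel size²), the background-corrected mean γH2AX intensity
(field background = median of non-nucleus pixels — robust and deterministic),
and the γH2AX focus count (local maxima of the mildly smoothed channel inside
the mask whose prominence over the nucleus median exceeds a threshold,
default 0.2 intensity units).

## Damage classification and replication unit

"Displaying γH2AX signalling" is operationalised with explicit, reported
thresholds: a nucleus is damaged when it has ≥ `min_foci` foci (default 3)
**or** its mean intensity exceeds the robust centre of the undamaged
population by `intensity_z` MADs (default 3; the reference population is the
below-foci-threshold nuclei, pooled across fields; if that population has
zero spread the intensity criterion is undefined and only the foci rule
applies). Both parameters are echoed in the output. The replication unit for
damage percentages is the field/well — matching how such screens report n —
while per-nucleus rows are retained for area and intensity analyses.

## Generator

Fields contain non-overlapping ellipses with areas drawn from a truncated
normal distribution, placed by rejection sampling (bounded retries, then an
error — the generator refuses rather than silently overlapping). Exactly
`round(fraction × n)` nuclei per field are damaged; R's `round()` is IEEE
round-half-even, which is the documented convention. Damaged nuclei receive
3–8 bright foci with at least 4.5 px mutual separation — closer pairs merge
into one physical blob that no detector could count as two, which would make
the planted count unrecoverable by construction rather than by defect.
Defaults (180 ± 40 μm² nuclei, 0.454 μm pixels) describe a 20× high-content
scan of HeLa-like cells; both are configurable, and the area-recovery
studies use 456 μm² nuclei at 0.227 μm pixels. What the generator does *not*
emulate: out-of-focus light, vignetting, cell-cycle area structure,
overlapping/clumped nuclei beyond tangency, and cytoplasmic γH2AX — passing
tests therefore certify the measurement chain, not robustness to every
real-world artefact.

# Group statistics

All pipelines report group dispersion as mean ± SEM (sample SD/√n, flagged
undefined at n = 1) and compare conditions with two-tailed Student's t-tests
assuming equal variance (pooled variance, df = n₁+n₂−2), annotated
`ns > 0.05`, `* ≤ 0.05`, `** ≤ 0.01`, `*** ≤ 0.001`, `**** ≤ 0.0001`. Exact
boundary values are classed into the more significant bin, because the
legends' "ns > 0.05" makes the upper boundary strict. Zero pooled variance is
handled explicitly (p = 1 for equal means, p = 0 otherwise, flagged
degenerate). No multiple-testing correction is applied by default — raw
pairwise tests are the reporting convention this mirrors. The closed form is
implemented directly (not delegated) so the degenerate contracts hold;
`stats::t.test(var.equal = TRUE)` and numeric integration of the t density
serve as independent cross-checks in the test suite.

# Numerical choices and degenerate inputs

* Hertz fits are closed-form (linear in $E/(1-\nu^2)$); degenerate
  indentation ranges raise `singular_fit`, flat curves `empty_contact`.
* The fGn Cholesky factor is computed once per generator call and shared
  across particles and axes.
* `nlsLM` starts from a log–log regression; a start landing numerically on
  the optimum can trip the Levenberg–Marquardt gradient check, so fits retry
  from mildly perturbed starts before being flagged non-converged.
* Watershed tolerance (default 2 px on the distance map) trades
  over-splitting of rough masks against merging of tangent nuclei.
* Reproducibility: all generators take explicit seeds and restore the
  caller's RNG state; identical seeds give bit-identical outputs.

# Problem sizes used in the recovery studies

The recovery studies (test suite and `scripts/acceptance.R`) use the full
published designs where they are cheap — 29–40 cells × 10 curves for AFM,
200 tracks × ~940 frames for SPT, 20 fields × 100 nuclei per condition for
HCS, 139 nuclei at 0.227 μm/px for the area study — and scaled-down designs
for the rendered-movie end-to-end test (12 particles × 150 frames), chosen
as the smallest ensembles at which the stochastic tolerances are
statistically meaningful.
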