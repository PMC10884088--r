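---
title: "Inverse calibration of aortic root material parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse calibration of aortic root material parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootcalib)
```

## The problem

Patients who receive a transcatheter aortic valve are typically 75 years or
older, and their aortic tissue cannot be harvested for ex-vivo mechanical
testing. Simulation of the implantation therefore has to run on material
parameters that are, at best, borrowed from much younger or non-human
tissue. `rootcalib` implements a non-invasive alternative: the
patient-specific Young's moduli of the aortic root wall and the stenotic
valve leaflets are identified by matching forward-model predictions to
image-derived measurements available from routine two-phase (end-diastolic
and peak-systolic) gated CT.

Two observables drive the identification:

* the regional diameter strain of the wall,
  $\varepsilon_r = (D_{sys} - D_{dias})/D_{dias}$, evaluated at the
  annulus, the sinus of Valsalva and the sinotubular junction (STJ), and
* the valve orifice area at peak systole, measured in the valve plane from
  the leaflet free edges.

## The identification procedure

Both tissues are treated as linear elastic with Poisson ratio
$\nu = 0.475$, so a single unknown modulus $E$ remains per tissue. For
each observable the procedure is:

1. **Design.** Draw $n = 15$ modulus samples uniformly at random from
   0.8–15 MPa (seeded; a Latin-hypercube option exists). The range spans
   compliant to stiff aged tissue.
2. **Forward evaluation.** Run the forward model at every sample and
   record the observable.
3. **Response surface.** Fit the quadratic surrogate
   $f(E) = \beta_1 + \beta_2 E + \beta_3 E^2$ by ordinary least squares.
4. **Cost solution.** Solve $F(E) = f(E) - \text{measured} = 0$. A
   quadratic can cross the target twice; both roots reproduce the
   measurement, so the solver keeps the root on the physically meaningful
   branch where the response decreases with stiffness ($f'(E) < 0$),
   breaks remaining ties toward the smaller modulus, and always raises a
   `multiple_roots` flag for audit. Without a real or in-range root the
   squared cost is minimised over the range instead and the result is
   flagged (`no_real_root`, `boundary_solution`).
5. **Aggregation.** The three regional wall cost functions are combined
   into one patient-level modulus as the argmin of
   $\sum_r (f_r(E) - \varepsilon_r)^2$ over the design range. The
   independent per-region roots are preserved and exported as the
   identified min–max range, which feeds the deployment sensitivity
   analysis. The leaflet modulus is calibrated separately against the
   orifice area on its own design.
6. **Verification.** The forward model is re-run at the optimum and the
   per-observable discrepancies are reported; when predicted and reference
   systolic shapes are available their volumetric Jaccard index is
   appended.

### Why the combined least-squares aggregation

A single modulus per patient has to reconcile three regional targets. The
options were a mean of the regional roots, an annulus-only solution, or a
joint least-squares fit. We chose the joint fit: it is the maximum
likelihood combination under independent homoscedastic strain errors, it
degrades gracefully when one region is noisy, and it reduces exactly to
the per-region root when the regions agree. The per-region roots remain
available in the result for inspection.

### Why windowed refinement after the surrogate

The physical response of a pressurised linear-elastic shell is
$\varepsilon \propto 1/E$, which a single quadratic cannot represent over
a 19-fold modulus range: we measured root errors of several percent
mid-range, growing toward the edges, for a one-shot fit. The calibrator
therefore repeats the design–fit–solve cycle on a window centred on the
current estimate, shrinking the window by 0.3 per converged step (and
holding its width while the minimiser sits on a window edge, so the
iteration can walk toward an out-of-window optimum). A quadratic is an
excellent local model of any smooth monotone response, so a handful of
iterations (default cap 8) recovers noise-free ground truth to well below
0.1%. All designs derive their seeds from the configuration seed, so the
whole procedure is deterministic.

## The reference forward model

The package defines a forward-model contract (`forward_model()`): any
deterministic function `run(E, target)` returning regional strains (%) or
an orifice area (mm²) over a declared modulus range can drive the
calibration, so finite-element backends can be plugged in unchanged. The
shipped reference model is deliberately desk-scale:

* **Wall.** Each region is an independent thin-walled cylinder with
  longitudinally constrained ends, loaded by the systolic-minus-diastolic
  pressure increment (the reference configuration is end-diastole, the
  segmentation phase): $\Delta\sigma_\theta = \Delta P\, r / t$ and
  $\varepsilon_\theta = \Delta\sigma_\theta (1 - \nu^2)/E$. This is the
  same Laplace closed form used as the analytical benchmark for shell
  models of the aortic wall, and the implementation is tested against it
  to $10^{-12}$ relative error. Wall thickness defaults to 2 mm and
  leaflet thickness to 0.5 mm, the usual uniform-thickness assumptions
  when neither is resolvable in CT.
* **Leaflets.** A plate-bending-motivated opening law: the free edge moves
  radially from its closed position toward the maximal-orifice circle by
  the fraction $\varphi = \min(1,\, c\, \Delta p\, L^4 / (\kappa E t^3
  L_{ref}))$, where $L$ is the mean free-edge-to-annulus distance,
  $\kappa \ge 1$ a calcification stiffening factor and $\Delta p$ the
  peak transvalvular gradient. The constant $c$ is anchored so that
  $\varphi = 0.5$ at $E = 5$ MPa, $\Delta p = 40$ mmHg, $\kappa = 1$ on
  the default geometry, which centres the default cohort in the
  identifiable range. The orifice area then comes from the same spline
  observable used on real measurements.

The leaflet model saturates: below some modulus the valve is fully open
and the area carries no information about $E$. The calibrator detects the
flat response (zero-variance design window, degenerate surrogate) and
flags the leaflet solution rather than failing, and a saturated leaflet
never voids the wall solution.

Pressure waveforms are provided (`pressure_waveform()`) as a fixed
normalized beat shape scaled affinely to the cuff pressures with period
$60/\mathrm{HR}$; the shape is cosmetic, because the identification uses
only the peak values.

## Observables and validation metrics

* `diameter_strain()` — the two-phase strain in percent, sign preserved;
  negative values are flagged as non-physiological, not rejected.
* `orifice_area()` — free-edge points are projected to the valve plane,
  ordered by polar angle about their projected centroid (points within
  1e-9 rad are averaged; the ordering rule is ours, the upstream
  extraction convention not being standardised), interpolated by a closed
  periodic cubic spline parameterised by chord length, sampled at 512
  points and integrated by the shoelace formula. A winding-number guard
  rejects grossly self-intersecting interpolants. Accuracy on analytic
  circles and ellipses with 24 points is ~0.005%.
* `voxelize_surface()` / `jaccard_index()` — shape agreement is computed
  as volumetric intersection-over-union on occupancy grids at the CT
  resolution (0.488 × 0.488 × 0.625 mm), the natural representation for
  segmentation-derived shapes. Interior fill is by ray parity with a
  fixed sub-voxel ray offset (1e-4 voxel) so rays cannot graze shared
  triangle edges; the induced bias is orders of magnitude below the 2%
  volume tolerance.
* `device_diameters()` — stent-frame point clouds are sliced in 1-mm
  bands at 10/50/90% of the axial extent (inflow/mid/outflow) and the
  maximal and minimal chords through the convex-hull centroid are
  reported. Band thickness and level fractions are fixed defaults; the
  imaging protocol marks the levels only pictorially.

## The constitutive catalog

`material_catalog()` serves the parameter sets used around the
calibration: the linear-elastic wall/leaflet entries (modulus left unset
for calibration), neo-Hookean calcification ($C_{10} = 67.7$ MPa), skirt
and balloon, second-order Ogden pericardium ($\mu_1 = 0.96$ MPa,
$\alpha_1 = -56.5$, $\mu_2 = 3.57$ MPa, $\alpha_2 = 1.87$) and the
cobalt-chromium stent frame (elastic 238.54 GPa plus Johnson–Cook
hardening $\sigma_y = A + B\,\varepsilon_p^n$ with $A = 465$ MPa,
$B = 2140$ MPa, $n = 0.73$; rate and thermal terms are dropped because
deployment is simulated quasi-statically). Hyperelastic stresses are
evaluated in incompressible uniaxial closed form — the tensorial FE
context is out of scope — so the volumetric $D_1$ parameters are stored
and reported verbatim but do not enter the stress; whether the Ogden
$D_1 = 0.027$ is a compressibility parameter or its inverse is not
resolvable from the source and it is treated as opaque metadata. The
Ogden stress uses the convention consistent with the strain energy
$W = \sum_i 2\mu_i/\alpha_i^2\,(\lambda_1^{\alpha_i} + \lambda_2^{\alpha_i}
+ \lambda_3^{\alpha_i} - 3)$, i.e.
$\sigma = \sum_i (2\mu_i/\alpha_i)(\lambda^{\alpha_i} -
\lambda^{-\alpha_i/2})$; every evaluator is tested against a
central-difference derivative of its energy.

## The virtual cohort and what it does (not) show

`generate_virtual_patient()` draws hemodynamics from truncated normals
matching the study cohort summary (systolic 129.4 ± 18.3 mmHg, diastolic
61.2 ± 11.2 mmHg, heart rate 70.6 ± 10.9 bpm; ±3 SD truncation,
diastolic floor 30 mmHg, resampling until systolic exceeds diastolic).
The peak gradient is not tabulated in the source cohort; we fixed
40 ± 10 mmHg truncated to 15–80 mmHg once, centred on the leaflet
anchor point and within the clinical range for significant stenosis.
Ground-truth moduli are uniform on 1.5–13 MPa, the interior of the design
range where the method is identifiable. Geometry is a perturbed template
(annulus 23 ± 1.5 mm, sinus/STJ scaled from it, a 12-point tri-lobed
stenotic free edge). The noisy measurement set adds Gaussian diameter
noise with SD 0.244 mm (half the in-plane voxel) and 3% multiplicative
area noise — measurement-limited observables at CT resolution.

`recovery_experiment()` instead parameterises noise as a relative SD
applied multiplicatively to the strain and area observables (0, 2%, 5% by
default), with a single standard-normal draw per patient scaled by the
level, so error is non-decreasing in noise by construction and runs are
comparable across levels. At the default sizes (50 patients, 3 levels,
~150 calibrations) the experiment runs in about a minute; those sizes are
our choice of a cohort large enough for stable medians and RMSEs.

What passing recovery shows: the identification machinery — design,
surrogate, root selection, aggregation, refinement — inverts a monotone
forward model correctly and degrades gracefully with noise. What it does
not show: fidelity of the reference forward model to a real aortic root.
The Laplace wall strains at realistic moduli are several-fold smaller
than the printed clinical strains, which include heart-motion effects and
geometric nonlinearity that only the original finite-element models
capture; reproducing the per-patient moduli of the study table from its
strains is therefore explicitly not claimed. The table ships as a fixture
for summary statistics and interface examples, and its printed
correlations are not asserted because the exact strain aggregation behind
them is not stated.

## Deployment sensitivity

`sensitivity_analysis()` propagates the identified modulus range to the
deployed device diameter through a spring-equilibrium surrogate:
$R = (k_s R_0 + k_t R_a)/(k_s + k_t)$ with the frame radial stiffness
$k_s = 79.89$ N/mm, free radius $R_0 = 11.5$ mm, and tissue stiffness
$k_t = c_t E t$ with $c_t = 2\pi/(1-\nu^2)$ per unit thickness (the hoop
stiffness of a unit-length ring, configurable). This is explicitly not a
finite-element deployment — it reproduces the correct limits (free
expansion at $k_t = 0$, annulus-constrained at $k_t \to \infty$) and the
monotone stiffer-wall/smaller-diameter trend used for sensitivity
reporting, nothing more.

## Numerical choices and degenerate inputs

* mmHg → MPa conversion fixed at 133.322 Pa/mmHg; millimetres and MPa
  internally everywhere; GPa accepted at the catalog boundary.
* Quadratic solver: linear fallback at $|\beta_3| < 10^{-12}$; a flat
  surrogate matching the measurement returns `NA` with `poor_fit` (zero
  sensitivity), and errors only when it cannot match.
* Combined minimiser: 2001-point grid scan bracketing a golden-section
  polish (`optimize`, tol 1e-10); verified against a $10^5$-point
  exhaustive scan.
* Equal systolic and diastolic pressures are treated as zero load (zero
  strain) by the wall model, while the hemodynamic-record constructor
  rejects non-increasing pressure pairs at the data boundary.
* Voxel grids are comparable only with identical origin/spacing/shape;
  Jaccard of two empty grids is an error, not 100%.
* All randomness flows from user-supplied seeds through one
  deterministic child-seed derivation; repeated runs are byte-identical.

## Known limitations

The reference forward model is a verification vehicle, not a substitute
for patient-specific FE; regional moduli are reduced to one global value
per tissue; the leaflet model has an unidentifiable fully-open plateau
(flagged); co-registration of the two cardiac phases is assumed; and the
deployment surrogate ignores calcification contact, crimping history and
frame plasticity.
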