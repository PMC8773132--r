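---
title: "From CT attenuation to bone stress: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From CT attenuation to bone stress: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxbone)
```

`voxbone` builds subject-specific long-bone models from CT volumes and
compares four constitutive representations of bone under gait loading.
This vignette explains the model, its assumptions, the tunable parameters,
what the synthetic generators do and do not emulate, and the numerical
choices made where the design was genuinely open.

## 1. From Hounsfield units to density

CT attenuation in Hounsfield units (water = 0, air ≈ −1000) is a proxy for
bone mineral content. The package uses a single linear calibration,

$$\rho = 0.0000464\,\mathrm{HU} + 1 \quad [\mathrm{g/cm^3}],$$

applied voxelwise inside the bone mask (`huToDensity()`). Both
coefficients are configurable; no scanner-specific phantom calibration
(K₂HPO₄ rods) is attempted. Note the small slope: across the full clinical
HU range the calibrated densities stay within roughly 0.95–1.2 g/cm³, so
this calibration compresses the cortical–trabecular density contrast far
below what ash-density calibrations produce. It is used as printed; the
sensitivity of every downstream modulus to the calibration is one reason
the package exposes it as a parameter rather than a constant.

## 2. Segmentation: compartments, segments, groups

Real workflows segment bone interactively; here thresholds stand in, and
all of them are configurable in `segmentationConfig()`:

* `boneHuThreshold` (default 200 HU) — bone vs background, followed by a
  largest-6-connected-component filter to drop specks;
* `corticalHuThreshold` (default 700 HU) — cortical (label 1) vs
  trabecular (label 2) inside the mask. Both defaults are common CT bone
  practice values, not derived quantities.

The bone is then cut into `nSegments` (default 8) longitudinal segments of
equal extent along the **principal axis** of the masked voxel cloud — not
the image z-axis — so tilted specimens segment correctly; for an aligned
bone the two coincide. Whether the original eight segments were
equal-length or anatomical is unknowable from the source; equal extent is
the implemented reading.

Within each segment × compartment stratum, voxel densities are binned into
`nGroupsPerSegment` (default 10) material groups, equal-width over the
stratum's density range (quantile binning optional). Cortical and
trabecular voxels never share bins because they use different property
equations, so a full model carries up to 8 × 2 × 10 material cards. Each
group's representative density is the **mean of its member voxels**, and
the property equations are applied to that mean (the convention of
HU-based material assignment tools), not averaged over per-voxel
properties.

## 3. The four material representations

All four laws derive from the same density field.

**Isotropic elastic.** E = 2314 ρ^1.57 (cortical) or 1157 ρ^1.78
(trabecular) MPa, ν = 0.25.

**Elastic–perfectly-plastic.** Same elastic branch; rate-independent
return mapping with yield at the ultimate strength (100 MPa cortical,
10 MPa trabecular, used for tension and compression alike), no hardening —
no hardening curve exists in the source material, and the tabulated
Vickers hardness is carried as metadata only. A failure flag latches when
|total strain| exceeds the fracture strain (3% / 7%, overridable within
the tabulated ranges).

**Hyper-elastic (Mooney–Rivlin, three parameters).** Incompressible
uniaxial nominal stress

$$P(\lambda) = 2(\lambda - \lambda^{-2})\left[C_{10} + \frac{C_{01}}{\lambda}
  + C_{11}\Big((I_2 - 3) + \frac{I_1 - 3}{\lambda}\Big)\right],$$

with $I_1 = \lambda^2 + 2/\lambda$, $I_2 = 2\lambda + 1/\lambda^2$. P is
linear in $(C_{10}, C_{01}, C_{11})$, so `fitMooneyRivlin()` is exact
closed-form least squares; the volumetric parameter is set for
near-incompressibility ($d = 2/K$, $K = 1000 \cdot 6(C_{10}+C_{01})$) and
unused at the material point. Density dependence of the fitted constants
is not specified by any source, so cards scale the compartment fit by
$(\rho_{group}/\rho_{fit})^{b}$ with $b$ the compartment's elastic
exponent (1.57 / 1.78), keeping the small-strain tangent
$6(C_{10}+C_{01})$ consistent with the elastic power law. When no measured
test data are supplied, `mooneyRivlinReferenceCard()` provides a synthetic
stand-in whose tangent matches the elastic modulus at the reference
density (split 3:1 between C10 and C01, C11 = 0.05 C10).

**Transversely isotropic.** E1 = E2 and E3 as in the table above,
ν12 = 0.4, ν23 = ν31 = 0.25, and quadratic shear scaling
$G_{ij} = G_{ij,\max}(\rho/\rho_{\max})^2$.

Two open questions are resolved as follows:

* **Shear units.** The printed maxima 5.71/7.11/6.58 are labelled MPa,
  three orders below the Young's moduli — physically implausible for bone
  (plausible values are GPa-scale). `shearScaling()` defaults to the
  verbatim MPa reading *with a loud warning*, and offers
  `units = "GPa"`. The pipeline runner and the four-law comparison default
  to the GPa reading, because the comparison's narrow stress spread
  presupposes plausible stiffness; the verbatim reading remains one
  configuration switch away.
* **ρ_max** is undefined in the source. Default: the maximum masked
  density of the current model, so $G(\rho_{\max}) = G_{\max}$ is
  attainable within each model. Overridable.

Stiffness assembly (`assembleStiffness()`) builds the orthotropic
compliance with $S_{12} = -\nu_{12}/E_1$, $S_{23} = -\nu_{23}/E_2$,
$S_{31} = -\nu_{31}/E_3$; the conjugate ratios follow from compliance
symmetry $\nu_{ij}/E_i = \nu_{ji}/E_j$, which only three printed ratios
leave undetermined. Voigt order is (11, 22, 33, 23, 31, 12) with
engineering shear strain and axis 3 longitudinal. Positive definiteness is
verified by an eigenvalue check and violations are errors, not warnings.

## 4. The finite-element stage

The mesh is one trilinear 8-node hexahedron per masked voxel, nodes
deduplicated across faces, in a consistent mm–N–MPa system. A voxel mesh
was chosen over body-fitted tetrahedra deliberately: the CT voxel grid is
the natural discretization for HU-driven material assignment, every
element is perfectly shaped, and one stiffness per material group serves
all its elements. The price is a stair-stepped surface, acceptable for
interior stress fields at the voxel sizes used here. Near-isotropic
spacing (max/min ≤ 1.5) is required; anisotropic acquisitions are
resampled first (`resampleVolume()`, trilinear for HU,
nearest-neighbour for labels).

Element stiffness uses 2×2×2 Gauss quadrature of $B^\top C B$; element
stress is recovered at the centroid as the Gauss average of $CBu$.
Boundary conditions mirror a femur fixed at the condyles: the distal face
is fully clamped by default, with a `rollers` option (axial fixity plus
minimal lateral pinning) that admits the textbook uniform-stress state
used by the verification suite. The axial load is distributed over the
proximal face by tributary area — equivalent to a uniform surface
traction; per-node equal weights are available but do *not* reproduce the
analytic F/A state on a regular grid, which is why tributary is the
default.

Gait loading is quasi-static: walking-frequency load variation is slow
relative to bone's stiffness, so inertia is neglected and one spatial
pattern is factorized once (supernodal sparse Cholesky below a
configurable DOF threshold, Jacobi-preconditioned conjugate gradient with
relative residual ≤ 1e-8 above it) and scaled per time step. The bundled
gait curve is a parametric double peak — 2.38 and 2.20 × body weight at
15% and 48% of the cycle, raised-cosine bumps, zero through the swing
tail — standing in for proprietary instrumented-hip datasets.

The plastic and hyper-elastic laws are **material-point models** here:
requesting them from the assembler is an error. The four-law comparison
(`fourLawComparison()`) therefore solves elastic and transversely
isotropic models exactly, reuses the elastic field with a per-element
yield cap for the plastic law, and linearizes the Mooney–Rivlin cards to
their small-strain tangent for the hyper-elastic law. Because the
reference hyper-elastic cards are tangent-matched to the elastic law, the
elastic/plastic/hyper-elastic triplet coincides on phantoms that stay
below yield — a consequence of the stand-in test data, not a property of
measured bone.

## 5. Damage

The damage indicator is binary by definition — 0 intact, 1 failed — which
is untestable for monotonicity and uninformative below failure. The
package therefore computes the continuous utilization
$u = \sigma_{vM}/\sigma_{ult}$ clamped to [0, 1] as the interpolant and
preserves the binary flag as $u = 1$, latched across load steps. Strengths
come from the plastic card (or the compartment defaults 100/10 MPa for the
other laws). The per-subject summary used in cohort cumulative-damage
plots is the maximum element utilization over the gait cycle (a
failed-fraction summary is the alternative); empirical CDFs are computed
per demographic group. No fatigue accumulation or crack propagation is
modelled.

## 6. Synthetic data: what it emulates, what it does not

`makePhantom()` produces a tube — cortical shell (default HU 1500) around
a trabecular core (HU 300) in air-like background (−1000), optional tilt,
Gaussian HU noise per region, deterministic per seed. Default cortical
thickness is 45% of the outer radius, a typical adult mid-diaphysis
proportion. Two preset sizes: 16×16×48 voxels at 0.5 mm for tests and the
default pipeline (solves in seconds on one CPU) and 40×40×120 for demos.
The phantom exercises every pipeline contract — thresholding, axis
finding, binning, meshing, load paths — but has no femoral neck,
trochanter, curvature, or cortical thinning, so passing tests demonstrate
correctness of the machinery, not anatomical realism.

`makeCohort()` generates demographic tables whose density column follows
one configurable generating relation: the published bivariate fits
(density on age, BMI, weight, height, or maximum von Mises stress) plus
Gaussian noise; per-gender normal densities at the published means and
SDs; or race-mean offsets constructed so the Black > Mixed > Caucasian >
Asian ordering and contrast magnitudes are reproduced (group means are not
published, only percentage contrasts, so ordering is the testable
property). Ages are uniform within the published per-gender ranges
(23–95 / 26–92); BMI uniform on [18, 45]; the stress column either derives
statistically from the inverted density–stress relation (default — keeps
cohort tests in seconds) or could come from per-subject FE runs. Noise
SDs default to 0.05 g/cm³ (0.02 for the stress relation). Each relation is
univariate by construction: the generator does not model the
cross-correlations (age with BMI, gender with height) a real cohort
would show, so only one covariate at a time carries signal.

## 7. Numerical choices

* Solver tolerance 1e-8 (relative residual); direct/iterative crossover at
  150 000 free DOFs; both solvers agree to 1e-6 on shared systems.
* Degenerate inputs: empty masks, constant-density strata (one group),
  all-cortical volumes (valid, warned), λ = 1 test points (zero
  information, harmless), rank-deficient Mooney–Rivlin designs (error).
* Equal-width binning uses right-open intervals with the maximum clamped
  into the last bin; quantile binning uses rank-and-split, which balances
  group sizes to ±1.
* Tie-breaks: the principal axis sign is fixed by its largest component;
  the segment of the axial maximum joins the last segment.
* Voxel convention: 0-based indices, voxel-center positions
  `origin + index · spacing`; internal axis order (x, y, z), z
  longitudinal; all readers permute to it.
* Problem sizes in the shipped tests: 10³-element bars for analytic
  oracles, 3³ patch tests, the 16×16×48 phantom (≈ 6 000 elements,
  ≈ 22 000 DOF) for end-to-end runs, n = 313 cohorts (the study size) for
  parameter recovery, 100-seed Monte Carlo for fit recovery under noise.

## 8. Known limitations

* Linear kinematics only; no contact, implants, or dynamics. The plastic
  and hyper-elastic laws never feed back into the stiffness.
* The verbatim MPa shear reading produces a valid (positive-definite) but
  implausibly shear-compliant material; results under it should be read
  as a sensitivity exercise.
* The calibration-vs-printed-density inconsistency noted in §1 means the
  printed compartment densities (1.15802 / 0.93508 g/cm³) are not
  reachable from realistic HU through the printed calibration; the
  material-mapping tests therefore exercise the printed densities
  directly.
* Cohort statistics are simple bivariate OLS and Welch tests (with
  Bonferroni-corrected pairwise extensions); no multivariable or
  mixed-effects modelling.
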