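# voxbone

Subject-specific bone finite-element models from CT imaging, in R.

Orthopaedic damage prediction needs bone models whose material properties
come from the patient's own imaging rather than from textbook constants.
`voxbone` implements that workflow end to end for long bones: it calibrates
CT attenuation (Hounsfield units, HU) to apparent density, maps density to
material parameters under four constitutive representations, runs a voxel
finite-element stress analysis under gait loading, evaluates a binary
damage indicator, and analyses how bone density and stress vary with
demography across a cohort. Synthetic generators (CT phantoms, gait
curves, uniaxial test data, demographic cohorts) make the whole pipeline
runnable and testable with no external data.

It is intended for biomechanics researchers and engineers who want a
transparent, scriptable reference implementation of the CT-to-FE
material-mapping chain — not a clinical tool.

## The model

**Calibration.** Apparent density (g/cm³) is linear in HU:

    rho = 0.0000464 · HU + 1

**Density–modulus laws** (moduli in MPa, rho in g/cm³). Axis 3 is the bone
longitudinal axis; transverse isotropy means E1 = E2.

| | cortical | trabecular |
|---|---|---|
| E1 = E2 | 2314 ρ^1.57 | 1157 ρ^1.78 |
| E3 | 2065 ρ^3.09 | 1904 ρ^1.64 |
| G12, G23, G31 | G_max (ρ/ρ_max)² | same |
| ν12, ν23, ν31 | 0.4, 0.25, 0.25 | same |

with shear maxima G12/G23/G31 = 5.71/7.11/6.58 (taken as MPa verbatim, with
a loud warning — that reading gives G ≪ E; a GPa reading is one switch
away and is the default inside the pipeline runner).

**Four constitutive representations** share those densities: isotropic
elastic (E from the compartment law, ν = 0.25); elastic–perfectly-plastic
(yield at the ultimate strength, 100 MPa cortical / 10 MPa trabecular,
fracture strain 3% / 7%); three-parameter incompressible Mooney–Rivlin
hyper-elasticity, P(λ) = 2(λ − λ⁻²)[C10 + C01/λ + C11((I2−3) + (I1−3)/λ)],
fitted by closed-form least squares to uniaxial test data; and the
transversely isotropic law above, assembled into a 6×6 Voigt stiffness and
verified positive definite.

**Mechanics.** One 8-node hexahedral element per masked voxel (2×2×2 Gauss
quadrature, mm–N–MPa units), distal face fixed, axial gait load on the
proximal face as a double-peak body-weight curve, quasi-static sweep with
one factorization. Damage per element is the clamped utilization
u = σ_vM / σ_ult ∈ [0, 1]; u = 1 is "failed" and latches across load steps.

## Worked example

```r
library(voxbone)

vol  <- makePhantom(phantomSpec("test"))      # 16 x 16 x 48 voxel tube
mask <- boneMask(vol)
rho  <- huToDensity(vol, mask)
rho
#> DensityVolume: 5952 voxels in mask, rho in [1.0139, 1.0696] g/cm^3
#>   calibration: rho = 4.64e-05 * HU + 1

cfg    <- segmentationConfig()                 # 8 segments x 10 groups
comp   <- splitCompartments(vol, mask, cfg)
seg    <- longitudinalSegments(mask, cfg)
groups <- materialGroups(rho, comp, seg, cfg)
cards  <- buildMaterialCards(rho, groups, "anisotropic",
            scaling = shearScaling(rhoMax = max(voxelValues(rho)),
                                   units = "GPa"))
cards
#> MaterialCardSet: 16 anisotropic cards (8 cortical, 8 trabecular)

mesh <- buildMesh(mask, groups, vol)
gait <- makeGaitCurve(700)                     # 700 N body weight
sys  <- assembleSystem(mesh, cards)
res  <- gaitSweep(sys, gait, loadCase(mesh, totalForce = -max(gait$force_N)))
res
#> FEResult: 101 steps, 5952 elements; global max von Mises 71.9 MPa
#>   (element 118, step 16)

dmg <- computeDamage(res, buildMaterialCards(rho, groups, "plastic"))
dmg
#> DamageField: 5952 elements, 101 steps; final failed fraction 0.2581

cohort <- makeCohort(cohortSpec(313, "age", seed = 1))
bivariateFit(cohort, "age", "density")
#> BivariateFit: density = 1.530728 -0.009897935 * age  (R^2 = 0.9370, n = 313)
```

The peak stress (71.9 MPa) occurs at the first gait peak (step 16 of 101,
2.38 × body weight); the failed fraction counts trabecular elements whose
von Mises stress exceeded their 10 MPa strength at any step. The cohort fit
recovers the generating age relation (intercept 1.5404, slope −0.010025)
within sampling error.

`fourLawComparison()` runs the same phantom under all four material
representations and reports the four maximum von Mises stresses.

A command-line driver wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "voxbone.R", package = "voxbone"))')" all --seed 1 --out out/
```

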