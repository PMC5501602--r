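---
title: "Flow, shear stress and mineralization mapping in a perfusion bioreactor: methods"
author: "perfusim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow, shear stress and mineralization mapping in a perfusion bioreactor: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`perfusim` models the mechanical micro-environment of human mesenchymal
stromal cells cultured on a porous silk-fibroin scaffold disc inside an
axially perfused bioreactor, and quantifies how well the simulated wall shear
stress (SS) predicts where mineralized extracellular matrix forms. It covers
four computational stages:

1. steady culture-medium flow through the coupled free/porous domains
   (Stokes--Brinkman), with a mesh-refinement convergence criterion;
2. the scalar SS field and its revolution onto a 3-D voxel lattice aligned
   with micro-CT volumes;
3. the micro-CT processing chain (Gaussian filtration, density thresholding,
   particle-size filtering) and time-lapsed BV/TV morphometry;
4. voxel-wise ROC analysis of SS against mineralization, with the
   least-random (Youden) operating point.

A synthetic-data module generates scaffold phantoms, SS-driven weekly
mineralization series and micro-CT-like acquisitions, so every stage is
testable without any external data.

# Flow model

## Governing equations

The chamber is treated as axisymmetric: an inlet tube, a lower plenum, the
scaffold disc, an upper plenum and an outlet tube, all coaxial. In the
free-media region the steady incompressible Navier--Stokes equations hold; in
the scaffold the volume-averaged (Brinkman) momentum equation adds a Darcy
drag:

$$\rho\,(\mathbf{u}\cdot\nabla)\mathbf{u}
  = -\nabla p + \mu \nabla^2 \mathbf{u} - \frac{\mu}{k}\,\mathbf{u}\,\chi_s,
  \qquad \nabla\cdot\mathbf{u} = 0,$$

where $\chi_s$ is the scaffold indicator, $k = 1.76\times10^{-11}\,
\mathrm{m^2}$ the scaffold permeability and $\mu$ the dynamic viscosity. This
single-field penalization form avoids explicit interface conditions between
the two domains: one momentum equation holds everywhere and the drag term is
switched on in porous cells. The effective viscosity in the porous region is
$\mu$ itself (not $\mu/\varepsilon$); the choice only affects a boundary
layer of thickness $\sqrt{k}\approx 4\,\mu\mathrm{m}$, far below any
practical grid resolution, and plain $\mu$ is the most common Brinkman
closure.

The fluid is water at 37 °C: $\rho = 993\ \mathrm{kg/m^3}$,
$\mu = 6.91\times10^{-4}\ \mathrm{Pa\,s}$ (standard property tables); both
are config-overridable. The porosity (default 0.55) does not enter the
momentum equation in this closure; it parameterizes the synthetic phantom.

## Geometry defaults

The scaffold disc is 8 mm in diameter and 3 mm high. The device drawing is
not part of the model, so the remaining dimensions are canonical
reconstructions, all overridable:

| parameter | default | rationale |
|---|---|---|
| chamber radius | 4.0 mm | scaffold press-fit (the highest SS appears at the chamber wall, which requires no bypass gap) |
| tube radius | 1.025 mm | consistency of the pump settings with the stated mean inlet velocities: $Q/v = \pi r^2$ gives $d \approx 2.05$ mm from both the 0.2 ml/min / 0.001 m/s and the 12 ml/min / 0.061 m/s pairs |
| tube length | 10 mm | several entrance lengths at the low flow rate |
| plenum heights | 5 mm above and below | enough room for the inlet jet to spread before the scaffold |

Boundary conditions: plug inflow at the tube inlet (mean velocity
$v = Q/\pi r^2$), zero reference pressure with zero-gradient velocity at the
outlet, no-slip on all walls.

## Discretization

The solver uses a staggered (MAC) finite-volume scheme on a uniform
axisymmetric $(r, z)$ grid: radial velocity on radial faces, axial velocity
on axial faces, pressure at cell centres. This layout is inf--sup stable, so
the coupled momentum + continuity system is solved monolithically by a
sparse direct factorization (Matrix package). The Brinkman drag
($\mu/k \approx 4\times10^{7}\,\mathrm{s^{-1}\,kg/m^3}$) is treated
implicitly on the diagonal; explicit treatment would be unconditionally
unstable at any useful time step.

Walls that do not coincide with a velocity face are enforced by ghost
reflection ($v_\text{ghost} = -v$), second order for walls lying midway
between faces. Cell labels come from a cell-centre point-in-region test with
half-open intervals; a centre exactly on the scaffold interface is porous.

One discretization choice matters quantitatively: the radial spacing is
snapped so the inlet-tube radius is an integer number of cells, and the
chamber radius is then rounded to the nearest cell. The tube cross-section
sets the pump flow rate; rasterizing it a half-cell small at a 100 µm
nominal spacing would bias every downstream velocity by 5–10%, an error that
does not vanish under refinement at fixed rounding. With the tube fitted,
the inlet flux matches $Q$ to machine precision.

Convective inertia is included by default (first-order upwind, Picard
iteration with under-relaxation 0.8); at the low flow rate it changes the
scaffold velocities by well under 2% (interstitial Reynolds number « 1), and
a Stokes-only flag exists for linearity checks, where scaling the inlet
velocity by any factor scales the whole field exactly.

## Mesh refinement criterion

`refine_until_converged()` re-solves on successively halved spacings until
the relative change of the mean velocity between two consecutive levels is
below 2% in both the free and the porous domain. "Mean velocity" is taken as
the volume-weighted mean of the velocity magnitude over revolved cell
volumes — the natural reading for an axisymmetric model. Starting from
200 µm, the canonical geometry converges at the third level (51 µm radial
spacing, ≈ 84 000 unknowns) for both pump settings; that sweep is the
problem size used by the tests and the acceptance script.

# Shear stress

The scalar SS is $\tau = \mu\dot\gamma$ with shear rate
$\dot\gamma = \sqrt{2\,\mathbf{D}:\mathbf{D}}$, where $\mathbf{D}$ is the
strain-rate tensor in axisymmetric coordinates including the hoop term
$u_r/r$. This matches the standard CFD "shear rate × viscosity" output. The
normal components are evaluated at cell centres (where the staggered layout
makes them exact differences), the cross term at cell corners with one-sided
ghost treatment at the outer wall, then averaged back to centres.

**Grid sensitivity of SS maxima.** The velocity maxima are
mass-conservation-dominated and converge cleanly under refinement. The SS
*maxima* do not: the true Brinkman boundary layer at the scaffold wall has
thickness $\sqrt{k}\approx4\,\mu$m, so the wall-cell velocity gradient — and
with it the maximum SS — grows like $1/\Delta r$ as the grid is refined and
would only saturate at micron resolution. Reported SS maxima are therefore
model outputs at a stated resolution, not physical constants; the ROC
analysis is insensitive to this because it depends only on the SS ranking,
which a monotone rescaling of near-wall values barely perturbs.

`revolve_to_voxels()` samples the axisymmetric field at every voxel centre
by bilinear interpolation between cell centres (nearest-neighbour fallback
within half a cell of boundaries); voxels outside the fluid are flagged
invalid, never zero-filled. The pose convention is: volume third axis along
the bioreactor axis, 1-based voxel $(i,j,k)$ centred at
$\mathbf{o} + (\mathbf{i}-\tfrac12)\,h$.

# Micro-CT processing chain

The chain mirrors standard scanner-side bone morphometry:

* **Gaussian filtration**, filter width (σ) 1.2 voxels with support 1,
  interpreted in the scanner-vendor convention: the kernel is truncated at a
  1-voxel radius ($3^3$ taps) and renormalized to unit sum; applied
  separably with mirror boundaries.
* **Segmentation** at 97.5 mg HA/cm³ (equivalently 12.7% of grey full
  scale; the calibration is linear through the origin). The comparison is
  `>=`: a voxel exactly at the threshold is mineralized. The convention had
  to be fixed one way; it is documented and only moves measure-zero voxels.
* **Particle filtering**: unconnected components *strictly smaller* than 50
  voxels are removed — a 49-voxel particle goes, a 50-voxel one stays.
  Foreground connectivity defaults to the 26-neighbourhood (corner-touching
  voxels connect), with 6-neighbourhood available by config. Labeling runs
  over the voxel adjacency graph via `igraph`; the test suite checks it
  against an independent brute-force flood fill.
* **Morphometry**: BV is the mineralized volume inside the total-volume (TV)
  region; TV is the nominal scaffold cylinder (8 mm Ø × 3 mm) mapped into
  image coordinates. The scaffold itself is invisible at this threshold, so
  the envelope is the only self-consistent TV choice; using the full scan
  field of view instead would rescale BV/TV by a constant.

Weekly volumes are assumed pre-registered on a common lattice (the generator
emits them that way); no registration is implemented.

# ROC analysis

Every analysis-region voxel with a valid simulated SS is paired with its
mineralization label; scaffolds are pooled into one analysis. The prediction
rule is "mineralized if $\tau \ge t$", swept over the *exact sorted unique*
SS values (all voxels tied at a threshold switch together), plus a sentinel
for $(0,0)$; an optional log-spaced grid exists for very large inputs. AUC
is the trapezoidal integral, which equals the Mann–Whitney statistic
$\Pr(\tau_+ > \tau_-) + \tfrac12\Pr(\text{tie})$ exactly — the suite asserts
this identity against a double-loop oracle.

The least-random operating point is the sweep point furthest from the
45° diagonal. Since that distance is $(TPR - FPR)/\sqrt2$, it is the Youden
maximum. Ties are broken toward the **larger TPR** (the more sensitive,
lower-threshold point): on the worked 6-voxel example
($\tau = 1\ldots6$ mPa, labels 0,0,1,0,1,1) the maximum $J = 2/3$ occurs at
both 3 mPa (TPR 1, FPR 1/3) and 5 mPa (TPR 2/3, FPR 0), and the
high-sensitivity end is the one consistent with reporting an operating point
at FPR 0.50 — an operating regime chosen to miss little mineralization.

The analysis region is the full scaffold envelope *including*
scaffold-material voxels. This mirrors a known limitation of the
experimental analysis (the wet scaffold cannot be segmented out of the
medium), and inflates the negative count by roughly the scaffold's solid
fraction; an erosion option exists but is off by default.

# Synthetic data generator

The generator's role is to produce inputs with the statistical structure the
analysis assumes — not to calibrate biology. Defaults are the study
conditions:

* **Phantom**: a 8 mm × 3 mm cylinder at 36 µm voxels with spherical pores
  of diameter drawn uniformly from 315–400 µm (the salt-granule range),
  centres uniform in the cylinder, overlap allowed (packed granules touch).
  Spheres are added until the measured pore fraction is within ±2 percentage
  points of the target porosity, default 0.55 — the value used by the flow
  model. (The material itself is described as ~90% porous; the parameter is
  exposed, and the 0.55 default keeps phantom and flow model consistent.)
  Scaffold material gets a sub-threshold density of 30 mg HA/cm³, consistent
  with being indistinguishable from medium.
* **Mineralization**: per listed week, an unmineralized pore voxel
  mineralizes with probability
  $p = \text{rate}\cdot \text{link}(\tau) + \text{bonus}\cdot f_{\text{nb}}$,
  clipped to $[0,1]$, where $f_{\text{nb}}$ is its mineralized
  6-neighbour fraction. The default link is the band
  $[0.55, 24]$ mPa — the SS range observed to support mineralization under
  flow; `uniform` reproduces the static-culture condition. Masks are nested
  (no demineralization). Edge-to-centre growth under flow is *emergent*:
  the band selects the peripheral high-SS shell and the neighbourhood bonus
  (default 0.25/week) sharpens the front; nothing hard-codes the pattern.
  The default rate, 0.15/week, is a stand-in chosen to produce sub-percent
  BV/TV over a 5-week series — the regime the real cultures occupy; no
  quantitative growth law exists to calibrate against, and none is claimed.
* **Scan model**: mineral density 200 mg HA/cm³ on the mask (comfortably
  above the 97.5 threshold), Gaussian PSF of 0.8 voxels, additive Gaussian
  noise with SD 25 mg HA/cm³ (≈ 4 SD below threshold — visible noise that
  the vendor filter must actually remove). All generators are pure
  functions of their seed and parameters.

What passing tests on these data do **not** show: that real mineralization
follows a hard SS band, that real noise is Gaussian and stationary, or that
real scans are registered. The generator exists to verify the *pipeline*,
and the recovered quantities (band edge, AUC behaviour, BV/TV monotonicity)
are properties the construction guarantees — their recovery validates the
measurement chain, not the biology.

# Numerical choices and degenerate inputs

* Sparse direct solve; Picard stops when the relative velocity update falls
  below $10^{-6}$ (max 40 iterations); an update growing over five
  consecutive checks raises a non-convergence error carrying diagnostics.
* Zero inflow returns the exact zero field with constant pressure and a
  defined mass imbalance of 0.
* ROC requires at least one positive and one negative voxel; degenerate
  label sets raise an undefined-ROC error rather than returning NaN.
* Gaussian support 0 is the identity; kernels renormalize to unit sum to
  $10^{-12}$.
* Component labeling of an empty mask returns an all-zero label array.
* MetaImage headers are written at full double precision; NIfTI stores
  spacing as float32, so only MetaImage round-trips the 36 µm spacing
  exactly.

# Problem sizes

The test suite and the acceptance script run the refinement sweep from
200 µm, converging at 51 µm (~84 000 unknowns, ~10–20 Picard iterations at
the high flow rate); voxel analyses use 100–130 µm lattices
(~150 000–190 000 voxels) and reduced phantoms (3 mm Ø) for generator unit
tests. These sizes were chosen so the full pipeline and its verification
complete in minutes on a single core while still exercising every code path
at non-trivial scale; all of them are parameters, and the full-resolution
36 µm / 8 mm configuration runs unchanged when more time is available.

# Known limitations

* No pore-scale CFD: SS is a volume-averaged field; pore-level SS on strut
  surfaces is known to be higher than the averaged value.
* SS maxima are resolution-dependent (see above); only SS *rankings* and
  velocity/flux quantities should be compared across grids.
* No ECM-growth feedback on permeability over the culture period, no
  transient dynamics, no turbulence (Reynolds numbers stay laminar), no
  fluid--structure interaction.
* No scanner raw formats, no beam hardening or scatter, no inter-week
  registration.
* The axisymmetric assumption cannot reproduce quantities dominated by
  non-axisymmetric device details (e.g. the exact developing-jet maximum in
  the outlet tube region).
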