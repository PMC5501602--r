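# perfusim

Flow simulation, micro-CT morphometry and shear-stress-to-mineralization
mapping for perfusion bone-tissue-engineering cultures.

## The problem

In perfusion bioreactor cultures, human mesenchymal stromal cells seeded on a
porous scaffold are mechanically stimulated by the wall shear stress (SS) of
the medium flowing through the pore space. Weekly micro-CT monitoring shows
*where* mineralized extracellular matrix forms; computational fluid dynamics
shows *where* the shear stress is. `perfusim` implements the full
computational arm needed to connect the two, for researchers who want to
relate local mechanical stimuli to local tissue formation:

1. **Flow**: steady culture-medium flow through the coupled free/porous
   domains of an axially perfused chamber holding a scaffold disc
   (8 mm diameter x 3 mm, porosity 0.55, permeability 1.76e-11 m^2), solved
   with a single-field Stokes–Brinkman model on a staggered axisymmetric
   finite-volume grid,

   rho (u . grad) u = -grad p + mu lap(u) - (mu/k) u * chi_scaffold,
   div u = 0,

   with plug inflow at the pump-driven inlet (0.2 or 12 ml/min, i.e. mean
   inlet velocities of 0.001 and 0.061 m/s), a zero-pressure outlet, no-slip
   walls, and a mesh-refinement sweep that stops when the mean velocity per
   domain changes by less than 2% between levels.
2. **Shear stress**: tau = mu * sqrt(2 D:D) (full strain-rate second
   invariant, including the axisymmetric hoop term), revolved onto a 3-D
   voxel lattice aligned with the micro-CT volumes.
3. **Micro-CT chain**: Gaussian filtration (sigma 1.2 voxels, support 1),
   segmentation at 97.5 mg HA/cm^3 (12.7% grey), removal of unconnected
   particles smaller than 50 voxels, and time-lapsed BV/TV morphometry at
   36 um resolution.
4. **ROC mapping**: voxel-wise pairing of SS with mineralization pooled over
   scaffolds, incremental-threshold ROC with trapezoidal AUC (equal to the
   Mann–Whitney statistic), and the least-random operating point — the sweep
   point furthest from the 45-degree diagonal, i.e. the Youden maximum of
   TPR - FPR.

A synthetic-data module generates salt-leached scaffold phantoms
(315–400 um pores), SS-band-driven weekly mineralization series
(default band 0.55–24 mPa) and micro-CT-like acquisitions, so the whole
pipeline runs and is tested without any external data.

## Worked example

Solve the low-flow case on a 100 um grid and report the quantities of
interest:

```r
library(perfusim)

geom <- build_geometry()                       # canonical chamber + scaffold
bc   <- flow_bc(Q = ml_per_min(0.2), tube_radius = geom$tube_radius)
grid <- rasterize(geom, 100e-6)
sol  <- solve_flow(grid, bc = bc)
sol
#> Steady axisymmetric flow solution
#>   grid: 39 x 330 cells (dr = 102.5 um)
#>   inlet velocity: 0.00101 m/s; inertia: TRUE (10 Picard iterations)
#>   max velocity magnitude: 0.002 m/s; normalized max divergence: 4.1e-11

stress <- shear_stress(sol)
max_velocity(sol, "porous")        # 6.643e-05 m/s
max_in_region(stress, "porous")    # 4.83e-04 Pa (0.483 mPa)
mass_balance(sol)$imbalance        # 4.6e-12
```

The maximum velocity (0.002 m/s) is the developed parabolic peak in the
inlet tube — twice the mean inlet velocity. Inside the scaffold the Brinkman
drag flattens the profile to a near-uniform 0.066 mm/s, the pump flow rate
divided by the scaffold cross-section; shear stress peaks at the chamber
wall. The discrete inlet flux equals the pump setting to machine precision.

The full pipeline — simulation, synthetic weekly scans, morphometry, ROC —
runs from a config file:

```r
m <- run_pipeline(system.file("extdata", "smoke.toml", package = "perfusim"),
                  out_dir = "run1")
m
#> perfusim run manifest (seed 7)
#>   max velocity: 0.1134 m/s (scaffold 0.004212 m/s)
#>   max scaffold shear stress: 113.2 mPa
#>   ROC AUC 0.816, tau* = 0.7189 mPa; final BV/TV 0.156%
#>   outputs:  fields.vtk, scan_week2.nii.gz, scan_week3.nii.gz,
#>   scan_week4.nii.gz, morphometry.csv, mineral_week4.nii.gz,
#>   roc_curve.csv, roc_summary.json
```

Here the AUC well above 0.5 reflects the generator's shear-stress band
driving mineralization, and the recovered least-random threshold tau*
(0.72 mPa) sits near the 0.55 mPa lower band edge — blurred upward by the
simulated scan noise and segmentation. BV/TV grows monotonically over the
weekly series by construction. Identical config + seed reproduces
bit-identical artifacts (checksums are recorded in `manifest.json`).

A thin command-line wrapper with `simulate` / `run` subcommands is installed
at `inst/cli/perfusim.R`.

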