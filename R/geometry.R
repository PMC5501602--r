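#' Canonical perfusion bioreactor geometry
#'
#' Builds the parametric axisymmetric description of the perfusion chamber:
#' an inlet tube, a lower plenum, the porous scaffold disc, an upper plenum
#' and an outlet tube, all coaxial. Defaults describe a disc-shaped
#' salt-leached silk-fibroin scaffold (8 mm diameter, 3 mm height) press-fit
#' into the culture chamber; the tube radius is chosen so that the pump flow
#' rates 0.2 and 12 ml/min map onto mean inlet velocities of 0.001 and
#' 0.061 m/s.
#'
#' @param chamber_radius chamber radius (m)
#' @param scaffold_radius scaffold radius (m); must not exceed `chamber_radius`
#' @param scaffold_height scaffold height (m)
#' @param plenum_height_top,plenum_height_bottom free-media gaps above and
#'   below the scaffold (m)
#' @param tube_radius inlet/outlet tube radius (m); must be smaller than the
#'   chamber radius
#' @param tube_length inlet/outlet tube length (m)
#' @return an object of class `bioreactor_geometry`
#' @export
build_geometry <- function(chamber_radius = 4.0e-3,
                           scaffold_radius = 4.0e-3,
                           scaffold_height = 3.0e-3,
                           plenum_height_top = 5.0e-3,
                           plenum_height_bottom = 5.0e-3,
                           tube_radius = 1.025e-3,
                           tube_length = 10.0e-3) {
  vals <- c(chamber_radius = chamber_radius, scaffold_radius = scaffold_radius,
            scaffold_height = scaffold_height,
            plenum_height_top = plenum_height_top,
            plenum_height_bottom = plenum_height_bottom,
            tube_radius = tube_radius, tube_length = tube_length)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all geometry lengths must be finite and positive")
  if (scaffold_radius > chamber_radius)
    stop("invalid geometry: scaffold_radius (", scaffold_radius,
         ") exceeds chamber_radius (", chamber_radius, ")")
  if (tube_radius >= chamber_radius)
    stop("invalid geometry: tube_radius must be smaller than chamber_radius")
  g <- as.list(vals)
  # axial section boundaries, inlet tube starts at z = 0
  g$z_sections <- cumsum(c(0, tube_length, plenum_height_bottom,
                           scaffold_height, plenum_height_top, tube_length))
  names(g$z_sections) <- c("inlet", "plenum_bottom", "scaffold",
                           "plenum_top", "outlet", "top")
  class(g) <- "bioreactor_geometry"
  g
}

#' @export
print.bioreactor_geometry <- function(x, ...) {
  cat("Axisymmetric perfusion bioreactor geometry\n")
  cat(sprintf("  chamber radius : %.3f mm\n", x$chamber_radius * 1e3))
  cat(sprintf("  scaffold       : %.3f mm radius x %.3f mm height (porous)\n",
              x$scaffold_radius * 1e3, x$scaffold_height * 1e3))
  cat(sprintf("  plenums        : %.3f mm below, %.3f mm above\n",
              x$plenum_height_bottom * 1e3, x$plenum_height_top * 1e3))
  cat(sprintf("  tubes          : %.3f mm radius x %.3f mm length\n",
              x$tube_radius * 1e3, x$tube_length * 1e3))
  cat(sprintf("  total axial extent: %.3f mm\n", x$z_sections[["top"]] * 1e3))
  invisible(x)
}

#' Mean inlet velocity from a pump flow rate
#'
#' Plug-flow conversion `v = Q / (pi r^2)` between the volumetric flow rate
#' set at the pump and the mean velocity in the inlet tube.
#'
#' @param Q volumetric flow rate (m^3/s); use [ml_per_min()] to convert
#' @param tube_radius tube radius (m)
#' @return mean velocity (m/s)
#' @export
inlet_velocity_from_flow_rate <- function(Q, tube_radius) {
  if (!is.finite(Q) || Q < 0) stop("flow rate Q must be non-negative")
  if (!is.finite(tube_radius) || tube_radius <= 0)
    stop("tube_radius must be positive")
  Q / (pi * tube_radius^2)
}

#' Convert ml/min to m^3/s
#' @param x flow rate in millilitres per minute
#' @return flow rate in m^3/s
#' @export
ml_per_min <- function(x) x * 1e-6 / 60

#' Flow boundary condition
#'
#' Inlet plug velocity (derived from the pump flow rate if `v` is missing),
#' zero reference pressure at the outlet, no-slip on all walls.
#'
#' @param v mean inlet velocity (m/s); if missing, derived from `Q`
#' @param Q pump flow rate (m^3/s); if missing, derived from `v`
#' @param tube_radius tube radius (m) used for the Q/v conversion
#' @return an object of class `flow_bc`
#' @export
flow_bc <- function(v = NULL, Q = NULL, tube_radius = 1.025e-3) {
  if (is.null(v) && is.null(Q)) stop("provide inlet velocity v or flow rate Q")
  if (is.null(v)) v <- inlet_velocity_from_flow_rate(Q, tube_radius)
  if (is.null(Q)) Q <- v * pi * tube_radius^2
  if (v < 0) stop("inlet velocity must be non-negative")
  structure(list(v_inlet = v, Q = Q, tube_radius = tube_radius,
                 outlet = "zero-pressure", walls = "no-slip"),
            class = "flow_bc")
}

# domain labels used throughout the solver
LBL_OUTSIDE <- 0L
LBL_FREE    <- 1L
LBL_POROUS  <- 2L

#' Rasterize the bioreactor geometry onto an axisymmetric grid
#'
#' Labels every (r, z) cell of a uniform staggered grid as free fluid, porous
#' scaffold, or outside the flow region, by a cell-centre point-in-region test
#' (half-open at interfaces; a centre exactly on the scaffold interface counts
#' as porous). The radial spacing is snapped so the inlet tube radius is an
#' integer number of cells -- the tube cross-section controls the pump flow
#' rate and is the feature most sensitive to rasterization error; the chamber
#' radius is then rounded to the nearest cell.
#'
#' @param geom a [build_geometry()] object
#' @param spacing requested grid spacing (m); must resolve the tube radius
#' @param fit_tube snap the radial spacing to the tube radius (default TRUE)
#' @return an object of class `domain_grid` with fields `dr`, `dz`, `nr`,
#'   `nz`, the integer `label` matrix (nr x nz), cell-centre coordinates and
#'   the source geometry
#' @export
rasterize <- function(geom, spacing, fit_tube = TRUE) {
  stopifnot(inherits(geom, "bioreactor_geometry"))
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be positive")
  if (spacing > geom$tube_radius)
    stop("spacing (", spacing, " m) exceeds the tube radius; grid cannot ",
         "resolve the inlet")
  if (fit_tube) {
    n_tube <- max(2L, as.integer(round(geom$tube_radius / spacing)))
    dr <- geom$tube_radius / n_tube
  } else {
    dr <- spacing
    n_tube <- as.integer(round(geom$tube_radius / dr))
  }
  dz <- spacing
  nr <- max(as.integer(round(geom$chamber_radius / dr)), n_tube + 1L)
  nz <- as.integer(round(geom$z_sections[["top"]] / dz))
  r_c <- (seq_len(nr) - 0.5) * dr
  z_c <- (seq_len(nz) - 0.5) * dz
  zs <- geom$z_sections
  label <- matrix(LBL_OUTSIDE, nr, nz)
  in_tube_z <- (z_c < zs[["plenum_bottom"]]) | (z_c >= zs[["outlet"]])
  in_chamber_z <- !in_tube_z & z_c < zs[["top"]]
  # centre exactly on a scaffold interface counts as porous
  in_scaffold_z <- (z_c >= zs[["scaffold"]]) & (z_c <= zs[["plenum_top"]])
  for (j in seq_len(nz)) {
    if (in_tube_z[j]) {
      label[r_c < geom$tube_radius, j] <- LBL_FREE
    } else if (in_chamber_z[j]) {
      if (in_scaffold_z[j]) {
        label[r_c <= geom$scaffold_radius, j] <- LBL_POROUS
        label[r_c > geom$scaffold_radius & r_c < geom$chamber_radius, j] <- LBL_FREE
      } else {
        label[r_c < geom$chamber_radius, j] <- LBL_FREE
      }
    }
  }
  grid <- structure(list(dr = dr, dz = dz, nr = nr, nz = nz,
                         r_centers = r_c, z_centers = z_c,
                         label = label, geom = geom,
                         n_tube = n_tube),
                    class = "domain_grid")
  grid
}

#' @export
print.domain_grid <- function(x, ...) {
  cat(sprintf("Axisymmetric domain grid: %d x %d cells (dr = %.1f um, dz = %.1f um)\n",
              x$nr, x$nz, x$dr * 1e6, x$dz * 1e6))
  cat(sprintf("  free: %d, porous: %d, outside: %d cells\n",
              sum(x$label == LBL_FREE), sum(x$label == LBL_POROUS),
              sum(x$label == LBL_OUTSIDE)))
  cat(sprintf("  revolved porous volume: %.2f mm^3 (analytic %.2f mm^3)\n",
              revolved_volume(x, LBL_POROUS) * 1e9,
              pi * x$geom$scaffold_radius^2 * x$geom$scaffold_height * 1e9))
  invisible(x)
}

#' Revolved volume of a labelled region
#'
#' Sums `2 pi r dr dz` over all cells carrying the given label, i.e. the
#' volume swept when the axisymmetric cell is revolved about the axis.
#'
#' @param grid a [rasterize()] grid
#' @param label one of `label_free()`, `label_porous()`, `label_outside()`
#' @return volume (m^3)
#' @export
revolved_volume <- function(grid, label) {
  sel <- grid$label == label
  sum(2 * pi * grid$r_centers[row(sel)[sel]] * grid$dr * grid$dz)
}

#' @rdname revolved_volume
#' @export
label_free <- function() LBL_FREE
#' @rdname revolved_volume
#' @export
label_porous <- function() LBL_POROUS
#' @rdname revolved_volume
#' @export
label_outside <- function() LBL_OUTSIDE

#' Simple tube / porous-column grids for validation
#'
#' Builds a straight-tube domain grid (optionally entirely porous) on the
#' same staggered-grid conventions as [rasterize()]. Used for the analytic
#' flow limits: Poiseuille flow in an empty tube and Darcy flow through a
#' porous column.
#'
#' @param radius tube radius (m)
#' @param length tube length (m)
#' @param spacing grid spacing (m)
#' @param porous if TRUE all fluid cells are porous
#' @return a `domain_grid`
#' @export
tube_grid <- function(radius, length, spacing, porous = FALSE) {
  n_r <- max(2L, as.integer(round(radius / spacing)))
  dr <- radius / n_r
  nz <- max(2L, as.integer(round(length / spacing)))
  dz <- length / nz
  label <- matrix(if (porous) LBL_POROUS else LBL_FREE, n_r, nz)
  geom <- structure(list(chamber_radius = radius, scaffold_radius = radius,
                         scaffold_height = if (porous) length else 0,
                         tube_radius = radius, tube_length = length,
                         z_sections = c(inlet = 0, plenum_bottom = 0,
                                        scaffold = 0,
                                        plenum_top = if (porous) length else 0,
                                        outlet = length, top = length)),
                    class = "bioreactor_geometry")
  structure(list(dr = dr, dz = dz, nr = n_r, nz = nz,
                 r_centers = (seq_len(n_r) - 0.5) * dr,
                 z_centers = (seq_len(nz) - 0.5) * dz,
                 label = label, geom = geom, n_tube = n_r),
            class = "domain_grid")
}
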