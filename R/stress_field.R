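#' Shear-stress field of a flow solution
#'
#' Computes the scalar shear stress `tau = mu * gamma_dot` with shear rate
#' `gamma_dot = sqrt(2 D:D)`, the second invariant of the strain-rate tensor
#' in axisymmetric coordinates (including the hoop term `u/r`). This matches
#' the standard CFD "shear rate times viscosity" output; absolute maxima are
#' grid-sensitive model outputs because the Brinkman boundary layer
#' (~sqrt(k) = 4 um) is far below any practical grid resolution.
#'
#' Derivatives are evaluated where the staggered layout makes them natural:
#' the normal components at cell centres, the cross term at cell corners
#' (one-sided with ghost reflection at the outer wall and the inlet plane),
#' then corner values are averaged back to centres.
#'
#' @param sol a converged [solve_flow()] solution
#' @param mu dynamic viscosity (Pa s); defaults to the solution's fluid
#' @return an object of class `shear_stress_field`: matrix `tau` (Pa, NA
#'   outside the fluid), the grid and provenance
#' @export
shear_stress <- function(sol, mu = NULL) {
  stopifnot(inherits(sol, "flow_solution"))
  if (!isTRUE(sol$converged)) stop("flow solution is not converged")
  if (is.null(mu)) mu <- sol$fluid$viscosity
  grid <- sol$grid
  nr <- grid$nr; nz <- grid$nz; dr <- grid$dr; dz <- grid$dz
  U <- sol$U; W <- sol$W
  r_c <- grid$r_centers

  d_rr <- (U[2:(nr + 1L), , drop = FALSE] - U[1:nr, , drop = FALSE]) / dr
  d_zz <- (W[, 2:(nz + 1L), drop = FALSE] - W[, 1:nz, drop = FALSE]) / dz
  u_c <- (U[1:nr, , drop = FALSE] + U[2:(nr + 1L), , drop = FALSE]) / 2
  d_tt <- sweep(u_c, 1L, r_c, "/")

  # cross term at corners (i = 0..nr, j = 0..nz)
  dwdr <- matrix(0, nr + 1L, nz + 1L)
  dwdr[2:nr, ] <- (W[2:nr, , drop = FALSE] - W[1:(nr - 1L), , drop = FALSE]) / dr
  dwdr[nr + 1L, ] <- -2 * W[nr, ] / dr            # wall on the outer face
  dudz <- matrix(0, nr + 1L, nz + 1L)
  dudz[, 2:nz] <- (U[, 2:nz, drop = FALSE] - U[, 1:(nz - 1L), drop = FALSE]) / dz
  dudz[, 1L] <- 2 * U[, 1L] / dz                  # u = 0 on the inlet plane
  d_rz_c <- 0.5 * (dwdr + dudz)
  d_rz <- (d_rz_c[1:nr, 1:nz] + d_rz_c[2:(nr + 1L), 1:nz] +
           d_rz_c[1:nr, 2:(nz + 1L)] + d_rz_c[2:(nr + 1L), 2:(nz + 1L)]) / 4

  gdot <- sqrt(2 * (d_rr^2 + d_tt^2 + d_zz^2) + 4 * d_rz^2)
  tau <- mu * gdot
  tau[grid$label == LBL_OUTSIDE] <- NA_real_
  structure(list(tau = tau, grid = grid,
                 provenance = list(v_inlet = sol$bc$v_inlet,
                                   spacing = c(dr = dr, dz = dz),
                                   mu = mu)),
            class = "shear_stress_field")
}

#' @export
print.shear_stress_field <- function(x, ...) {
  cat("Shear-stress field (Pa) on the simulation grid\n")
  cat(sprintf("  grid: %d x %d, inlet velocity %.4g m/s\n",
              nrow(x$tau), ncol(x$tau), x$provenance$v_inlet))
  cat(sprintf("  range: %.4g .. %.4g mPa\n",
              min(x$tau, na.rm = TRUE) * 1e3, max(x$tau, na.rm = TRUE) * 1e3))
  invisible(x)
}

#' Maximum shear stress in a region
#'
#' Maximum of tau over a labelled domain, optionally restricted to the
#' mid-scaffold horizontal cross-section (a single axial cell row) or the
#' vertical mid-plane (in an axisymmetric field this is the whole (r, z)
#' plane).
#'
#' @param field a [shear_stress()] field
#' @param region `"porous"`, `"free"` or `"all"`
#' @param cross_section NULL, `"horizontal-mid"` or `"vertical-mid"`
#' @return maximum shear stress (Pa)
#' @export
max_in_region <- function(field, region = c("porous", "free", "all"),
                          cross_section = NULL) {
  stopifnot(inherits(field, "shear_stress_field"))
  region <- match.arg(region)
  grid <- field$grid
  sel <- switch(region,
                all = grid$label > 0L,
                porous = grid$label == LBL_POROUS,
                free = grid$label == LBL_FREE)
  if (!is.null(cross_section)) {
    cross_section <- match.arg(cross_section,
                               c("horizontal-mid", "vertical-mid"))
    if (cross_section == "horizontal-mid") {
      zs <- grid$geom$z_sections
      z_mid <- (zs[["scaffold"]] + zs[["plenum_top"]]) / 2
      j_mid <- which.min(abs(grid$z_centers - z_mid))
      keep <- matrix(FALSE, grid$nr, grid$nz)
      keep[, j_mid] <- TRUE
      sel <- sel & keep
    } # vertical-mid: the full (r, z) plane, i.e. no further restriction
  }
  if (!any(sel)) stop("region '", region, "' is empty")
  max(field$tau[sel], na.rm = TRUE)
}

#' Revolve an axisymmetric field onto a 3-D voxel lattice
#'
#' Maps every voxel centre to (r, z) about the bioreactor axis and samples
#' tau by bilinear interpolation between cell centres, with nearest-neighbour
#' fallback within half a cell of domain boundaries. Voxels whose centres fall
#' outside the fluid domain are flagged invalid (NA in the array, FALSE in the
#' validity mask), never silently zero-filled.
#'
#' Pose convention: the volume's third axis is the bioreactor axis; 1-based
#' voxel (i,j,k) has its centre at `origin + (c(i,j,k) - 0.5) * voxel_size`.
#' `axis_xy` gives the (x, y) position of the rotation axis and `z_offset`
#' the world z of the simulation origin (inlet plane).
#'
#' @param field a [shear_stress()] field
#' @param voxel_size voxel edge length (m)
#' @param dim integer length-3 volume dimensions
#' @param origin world coordinates (m) of the volume corner (length 3)
#' @param axis_xy (x, y) of the symmetry axis (m)
#' @param z_offset world z of the simulation inlet plane (m)
#' @return an object of class `voxel_field_sample` with fields `tau` (3-D
#'   array, Pa), `valid` (logical array), `voxel_size`, `origin`
#' @export
revolve_to_voxels <- function(field, voxel_size, dim, origin = c(0, 0, 0),
                              axis_xy = c(0, 0), z_offset = 0) {
  stopifnot(inherits(field, "shear_stress_field"), length(dim) == 3L)
  grid <- field$grid
  cx <- (seq_len(dim[1]) - 0.5) * voxel_size + origin[1]
  cy <- (seq_len(dim[2]) - 0.5) * voxel_size + origin[2]
  cz <- (seq_len(dim[3]) - 0.5) * voxel_size + origin[3]
  r <- sqrt(outer((cx - axis_xy[1])^2, (cy - axis_xy[2])^2, "+"))
  rv <- rep(as.vector(r), times = dim[3])
  zv <- rep(cz - z_offset, each = dim[1] * dim[2])
  tau <- interp_rz(field$tau, grid, rv, zv)
  if (all(is.na(tau))) stop("voxel lattice lies entirely outside the fluid domain")
  arr <- array(tau, dim = dim)
  structure(list(tau = arr, valid = !is.na(arr),
                 voxel_size = voxel_size, origin = origin,
                 provenance = field$provenance),
            class = "voxel_field_sample")
}

# bilinear interpolation of a cell-centred (r, z) matrix at arbitrary points,
# nearest-neighbour fallback near boundaries, NA outside the fluid
interp_rz <- function(vals, grid, r, z) {
  dr <- grid$dr; dz <- grid$dz; nr <- grid$nr; nz <- grid$nz
  out <- rep(NA_real_, length(r))
  # nearest cell (for validity and fallback)
  ci <- pmin(pmax(ceiling(r / dr), 1L), nr)
  cj <- pmin(pmax(ceiling(z / dz), 1L), nz)
  inside <- r >= 0 & r <= nr * dr & z >= 0 & z <= nz * dz
  valid <- inside & grid$label[cbind(ci, cj)] != LBL_OUTSIDE
  if (!any(valid)) return(out)
  # fractional position among cell centres
  fi <- r / dr + 0.5; fj <- z / dz + 0.5
  i0 <- floor(fi); j0 <- floor(fj)
  wi <- fi - i0; wj <- fj - j0
  can_bl <- valid & i0 >= 1 & i0 <= nr - 1 & j0 >= 1 & j0 <= nz - 1
  idx <- which(can_bl)
  if (length(idx)) {
    i0i <- as.integer(i0[idx]); j0i <- as.integer(j0[idx])
    v00 <- vals[cbind(i0i, j0i)];       v10 <- vals[cbind(i0i + 1L, j0i)]
    v01 <- vals[cbind(i0i, j0i + 1L)];  v11 <- vals[cbind(i0i + 1L, j0i + 1L)]
    ok <- is.finite(v00) & is.finite(v10) & is.finite(v01) & is.finite(v11)
    wii <- wi[idx]; wjj <- wj[idx]
    est <- (1 - wii) * (1 - wjj) * v00 + wii * (1 - wjj) * v10 +
      (1 - wii) * wjj * v01 + wii * wjj * v11
    out[idx[ok]] <- est[ok]
  }
  # nearest-neighbour fallback where bilinear was unavailable
  need <- valid & is.na(out)
  if (any(need)) {
    nnv <- vals[cbind(ci[need], cj[need])]
    out[which(need)[is.finite(nnv)]] <- nnv[is.finite(nnv)]
  }
  out
}
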