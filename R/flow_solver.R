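#' Fluid properties
#'
#' Defaults are water at 37 degrees C from standard property tables:
#' density 993 kg/m^3, dynamic viscosity 6.91e-4 Pa s.
#'
#' @param density fluid density (kg/m^3)
#' @param viscosity dynamic viscosity (Pa s)
#' @return an object of class `fluid_props`
#' @export
fluid_props <- function(density = 993, viscosity = 6.91e-4) {
  if (density <= 0 || viscosity <= 0)
    stop("density and viscosity must be positive")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_props")
}

#' Porous scaffold properties
#'
#' Defaults: porosity 0.55 and permeability 1.76e-11 m^2, the values used for
#' the salt-leached silk-fibroin scaffold in the flow model.
#'
#' @param porosity pore volume fraction, in (0, 1)
#' @param permeability Darcy permeability (m^2)
#' @return an object of class `porous_props`
#' @export
porous_props <- function(porosity = 0.55, permeability = 1.76e-11) {
  if (porosity <= 0 || porosity >= 1) stop("porosity must be in (0, 1)")
  if (permeability <= 0) stop("permeability must be positive")
  structure(list(porosity = porosity, permeability = permeability),
            class = "porous_props")
}

# Staggered-grid layout
# ---------------------
# u (radial velocity) lives on radial faces r = i*dr, i = 0..nr; u = 0 on the
# axis (i = 0) and the outer wall (i = nr), and on any face touching a solid
# cell. w (axial velocity) lives on axial faces z = j*dz, j = 0..nz; j = 0 is
# the inlet (Dirichlet plug profile), j = nz the pressure outlet. p lives at
# cell centres. Solid walls that do not coincide with a face are enforced by
# ghost reflection (value -v across the wall), second-order at mid-cell walls.

build_index_maps <- function(grid, bc) {
  nr <- grid$nr; nz <- grid$nz
  L <- grid$label
  fluid <- L > 0L

  uid <- matrix(0L, nr - 1L, nz)
  u_act <- fluid[1:(nr - 1L), , drop = FALSE] & fluid[2:nr, , drop = FALSE]
  uid[u_act] <- seq_len(sum(u_act))
  n_u <- sum(u_act)

  # wid columns jj = j + 1 for face index j = 0..nz
  wid <- matrix(0L, nr, nz + 1L)
  w_act <- matrix(FALSE, nr, nz + 1L)
  if (nz > 1L)
    w_act[, 2:nz] <- fluid[, 1:(nz - 1L), drop = FALSE] & fluid[, 2:nz, drop = FALSE]
  w_act[, nz + 1L] <- fluid[, nz]            # pressure outlet
  wid[w_act] <- n_u + seq_len(sum(w_act))
  n_w <- sum(w_act)

  w_known <- matrix(0, nr, nz + 1L)          # inlet Dirichlet values
  w_known[fluid[, 1L], 1L] <- bc$v_inlet

  pid <- matrix(0L, nr, nz)
  pid[fluid] <- n_u + n_w + seq_len(sum(fluid))
  n_p <- sum(fluid)

  list(uid = uid, wid = wid, pid = pid, w_known = w_known,
       n_u = n_u, n_w = n_w, n_p = n_p, n = n_u + n_w + n_p, fluid = fluid)
}

# Assemble the linear (Stokes-Brinkman + pressure + continuity) part.
# Returns triplets and the RHS contributions from the inlet Dirichlet data.
assemble_stokes <- function(grid, fluid, porous, bc, idx) {
  nr <- grid$nr; nz <- grid$nz; dr <- grid$dr; dz <- grid$dz
  mu <- fluid$viscosity
  drag <- mu / porous$permeability
  por <- (grid$label == LBL_POROUS) * 1
  solid <- grid$label == LBL_OUTSIDE
  uid <- idx$uid; wid <- idx$wid; pid <- idx$pid
  rhs <- numeric(idx$n)

  ti <- vector("list", 40L); tj <- ti; tx <- ti; nt <- 0L
  push <- function(i, j, x) {
    keep <- j != 0L
    nt <<- nt + 1L
    ti[[nt]] <<- i[keep]; tj[[nt]] <<- j[keep]; tx[[nt]] <<- x[keep]
  }

  ## ---- u momentum ----
  act <- which(uid > 0L, arr.ind = TRUE)
  iu <- act[, 1L]; ju <- act[, 2L]
  ru <- uid[act]
  r_f <- iu * dr
  chi <- (por[cbind(iu, ju)] + por[cbind(iu + 1L, ju)]) / 2
  diag_u <- mu * (2 / dr^2 + 2 / dz^2 + 1 / r_f^2) + drag * chi

  # radial neighbours (walls coincide with u faces; value 0 when inactive)
  c_rp <- -mu * (1 / dr^2 + 1 / (2 * r_f * dr))
  c_rm <- -mu * (1 / dr^2 - 1 / (2 * r_f * dr))
  has_p <- iu + 1L <= nr - 1L
  nb <- integer(length(iu)); nb[has_p] <- uid[cbind(iu[has_p] + 1L, ju[has_p])]
  push(ru, nb, c_rp)
  has_m <- iu - 1L >= 1L
  nb <- integer(length(iu)); nb[has_m] <- uid[cbind(iu[has_m] - 1L, ju[has_m])]
  push(ru, nb, c_rm)

  # axial (tangential) neighbours: ghost reflection across walls, zero-gradient
  # at the outlet plane, reflection at the inlet plane (plug inflow has u = 0)
  c_z <- -mu / dz^2
  for (s in c(-1L, 1L)) {
    jn <- ju + s
    inside <- jn >= 1L & jn <= nz
    nb <- integer(length(iu))
    nb[inside] <- uid[cbind(iu[inside], jn[inside])]
    push(ru, nb, rep(c_z, length(ru)))
    # ghost handling where no unknown neighbour exists
    ghost_wall <- inside & nb == 0L &
      solid[cbind(iu, pmax(pmin(jn, nz), 1L))] &
      solid[cbind(iu + 1L, pmax(pmin(jn, nz), 1L))]
    ghost_wall <- ghost_wall | (!inside & s == -1L)          # inlet plane
    ghost_out  <- !inside & s == 1L                          # outlet plane
    diag_u[ghost_wall] <- diag_u[ghost_wall] + mu / dz^2     # v_ghost = -v
    diag_u[ghost_out]  <- diag_u[ghost_out]  - mu / dz^2     # v_ghost = +v
  }
  push(ru, ru, diag_u)

  # pressure gradient
  push(ru, pid[cbind(iu + 1L, ju)],  rep(1 / dr, length(ru)))
  push(ru, pid[cbind(iu, ju)],      rep(-1 / dr, length(ru)))

  ## ---- w momentum ----
  actw <- which(wid > 0L, arr.ind = TRUE)
  iw <- actw[, 1L]; jw <- actw[, 2L] - 1L     # face index j = 1..nz
  rw <- wid[actw]
  r_c <- (iw - 0.5) * dr
  r_p <- iw * dr; r_m <- (iw - 1L) * dr
  c_rp <- mu * r_p / (r_c * dr^2)
  c_rm <- mu * r_m / (r_c * dr^2)
  is_out <- jw == nz
  chi_w <- ifelse(is_out, por[cbind(iw, pmin(jw, nz))],
                  (por[cbind(iw, pmax(jw, 1L))] +
                   por[cbind(iw, pmin(jw + 1L, nz))]) / 2)
  diag_w <- c_rp + c_rm + 2 * mu / dz^2 + drag * chi_w
  diag_w[is_out] <- diag_w[is_out] - mu / dz^2   # zero-gradient ghost above

  # radial neighbours with ghost reflection across solid columns / outer wall
  nbp <- integer(length(iw)); ghp <- logical(length(iw))
  inp <- iw + 1L <= nr
  nbp[inp] <- wid[cbind(iw[inp] + 1L, jw[inp] + 1L)]
  cell_hi <- solid[cbind(pmin(iw + 1L, nr), pmin(jw + 1L, nz))]
  cell_lo <- solid[cbind(pmin(iw + 1L, nr), pmax(jw, 1L))]
  ghp[inp] <- nbp[inp] == 0L & cell_lo[inp] &
    (ifelse(is_out[inp], TRUE, cell_hi[inp]))
  ghp[!inp] <- TRUE                              # beyond the outer wall
  push(rw, nbp, -c_rp)
  diag_w[ghp] <- diag_w[ghp] + c_rp[ghp]

  nbm <- integer(length(iw)); ghm <- logical(length(iw))
  inm <- iw - 1L >= 1L
  nbm[inm] <- wid[cbind(iw[inm] - 1L, jw[inm] + 1L)]
  cell_hi <- solid[cbind(pmax(iw - 1L, 1L), pmin(jw + 1L, nz))]
  cell_lo <- solid[cbind(pmax(iw - 1L, 1L), pmax(jw, 1L))]
  ghm[inm] <- nbm[inm] == 0L & cell_lo[inm] &
    (ifelse(is_out[inm], TRUE, cell_hi[inm]))
  push(rw, nbm, -c_rm)
  diag_w[ghm] <- diag_w[ghm] + c_rm[ghm]         # r_m = 0 on axis: no-op

  # axial neighbours
  below_inlet <- jw - 1L == 0L
  nbb <- integer(length(iw))
  nbb[!below_inlet] <- wid[cbind(iw[!below_inlet], jw[!below_inlet])]
  push(rw, nbb, rep(-mu / dz^2, length(rw)))
  rhs[rw[below_inlet]] <- rhs[rw[below_inlet]] +
    (mu / dz^2) * idx$w_known[cbind(iw[below_inlet], rep(1L, sum(below_inlet)))]
  nba <- integer(length(iw))
  nba[!is_out] <- wid[cbind(iw[!is_out], jw[!is_out] + 2L)]
  push(rw, nba, rep(-mu / dz^2, length(rw)))
  push(rw, rw, diag_w)

  # pressure gradient; outlet faces see a mirrored ghost cell with p = 0
  pin <- pid[cbind(iw, pmax(jw, 1L))]
  coef_in <- ifelse(is_out, -2 / dz, -1 / dz)
  push(rw, pin, coef_in)
  pup <- integer(length(iw))
  pup[!is_out] <- pid[cbind(iw[!is_out], jw[!is_out] + 1L)]
  push(rw, pup, rep(1 / dz, length(rw)))

  ## ---- continuity ----
  cells <- which(idx$fluid, arr.ind = TRUE)
  ic <- cells[, 1L]; jc <- cells[, 2L]
  rp_ <- pid[cells]
  r_c <- (ic - 0.5) * dr
  r_p <- ic * dr; r_m <- (ic - 1L) * dr
  nbu <- integer(length(ic))
  okp <- ic <= nr - 1L
  nbu[okp] <- uid[cbind(ic[okp], jc[okp])]
  push(rp_, nbu, r_p / (r_c * dr))
  nbu <- integer(length(ic))
  okm <- ic - 1L >= 1L
  nbu[okm] <- uid[cbind(ic[okm] - 1L, jc[okm])]
  push(rp_, nbu, -r_m / (r_c * dr))
  push(rp_, wid[cbind(ic, jc + 1L)], rep(1 / dz, length(ic)))
  at_in <- jc == 1L
  nbw <- integer(length(ic))
  nbw[!at_in] <- wid[cbind(ic[!at_in], jc[!at_in])]
  push(rp_, nbw, rep(-1 / dz, length(ic)))
  rhs[rp_[at_in]] <- rhs[rp_[at_in]] +
    idx$w_known[cbind(ic[at_in], rep(1L, sum(at_in)))] / dz

  list(i = unlist(ti[seq_len(nt)]), j = unlist(tj[seq_len(nt)]),
       x = unlist(tx[seq_len(nt)]), rhs = rhs,
       u_faces = cbind(iu, ju, ru), w_faces = cbind(iw, jw, rw))
}

# First-order upwind convection triplets, linearized about (U0, W0) (Picard).
# U0: (nr+1) x nz full radial-face array; W0: nr x (nz+1) full axial-face array.
assemble_convection <- function(grid, fluid, idx, st, U0, W0) {
  nr <- grid$nr; nz <- grid$nz; dr <- grid$dr; dz <- grid$dz
  rho <- fluid$density
  uid <- idx$uid; wid <- idx$wid
  rhs <- numeric(idx$n)
  ti <- vector("list", 16L); tj <- ti; tx <- ti; nt <- 0L
  push <- function(i, j, x) {
    keep <- j != 0L & x != 0
    nt <<- nt + 1L
    ti[[nt]] <<- i[keep]; tj[[nt]] <<- j[keep]; tx[[nt]] <<- x[keep]
  }

  ## u faces
  iu <- st$u_faces[, 1L]; ju <- st$u_faces[, 2L]; ru <- st$u_faces[, 3L]
  u0 <- U0[cbind(iu + 1L, ju)]
  wa <- W0[cbind(iu, ju)] + W0[cbind(iu, ju + 1L)]
  ip1 <- pmin(iu + 1L, nr)
  wb <- W0[cbind(ip1, ju)] + W0[cbind(ip1, ju + 1L)]
  wb[iu + 1L > nr] <- 0
  w0 <- (wa + wb) / 4
  # radial upwind
  pos <- u0 > 0
  diag_c <- rho * abs(u0) / dr
  nb <- integer(length(iu))
  sel <- pos & iu - 1L >= 1L
  nb[sel] <- uid[cbind(iu[sel] - 1L, ju[sel])]
  sel2 <- !pos & iu + 1L <= nr - 1L
  nb[sel2] <- uid[cbind(iu[sel2] + 1L, ju[sel2])]
  push(ru, nb, -rho * abs(u0) / dr)
  # axial upwind
  posz <- w0 > 0
  diag_c <- diag_c + rho * abs(w0) / dz
  nb <- integer(length(iu))
  sel <- posz & ju - 1L >= 1L
  nb[sel] <- uid[cbind(iu[sel], ju[sel] - 1L)]
  sel2 <- !posz & ju + 1L <= nz
  nb[sel2] <- uid[cbind(iu[sel2], ju[sel2] + 1L)]
  push(ru, nb, -rho * abs(w0) / dz)
  push(ru, ru, diag_c)

  ## w faces
  iw <- st$w_faces[, 1L]; jw <- st$w_faces[, 2L]; rw <- st$w_faces[, 3L]
  w0 <- W0[cbind(iw, jw + 1L)]
  jhi <- pmin(jw + 1L, nz)
  u0 <- (U0[cbind(iw, jw)] + U0[cbind(iw + 1L, jw)] +
         U0[cbind(iw, jhi)] + U0[cbind(iw + 1L, jhi)]) / 4
  posz <- w0 > 0
  is_out <- jw == nz
  diag_c <- numeric(length(iw))
  # axial: downwind ghost at the outlet has zero gradient -> no term
  sel_in <- posz & jw - 1L == 0L
  rhs[rw[sel_in]] <- rhs[rw[sel_in]] +
    rho * abs(w0[sel_in]) / dz * idx$w_known[cbind(iw[sel_in], rep(1L, sum(sel_in)))]
  diag_c <- diag_c + ifelse(!posz & is_out, 0, rho * abs(w0) / dz)
  nb <- integer(length(iw))
  sel <- posz & jw - 1L >= 1L
  nb[sel] <- wid[cbind(iw[sel], jw[sel])]
  sel2 <- !posz & !is_out
  nb[sel2] <- wid[cbind(iw[sel2], jw[sel2] + 2L)]
  push(rw, nb, -ifelse(!posz & is_out, 0, rho * abs(w0) / dz))
  # radial
  posr <- u0 > 0
  diag_c <- diag_c + rho * abs(u0) / dr
  nb <- integer(length(iw))
  sel <- posr & iw - 1L >= 1L
  nb[sel] <- wid[cbind(iw[sel] - 1L, jw[sel] + 1L)]
  sel2 <- !posr & iw + 1L <= nr
  nb[sel2] <- wid[cbind(iw[sel2] + 1L, jw[sel2] + 1L)]
  push(rw, nb, -rho * abs(u0) / dr)
  push(rw, rw, diag_c)

  list(i = unlist(ti[seq_len(nt)]), j = unlist(tj[seq_len(nt)]),
       x = unlist(tx[seq_len(nt)]), rhs = rhs)
}

fields_from_solution <- function(x, grid, idx) {
  nr <- grid$nr; nz <- grid$nz
  U <- matrix(0, nr + 1L, nz)                 # rows i+1 <-> face i = 0..nr
  act <- idx$uid > 0L
  U[2:nr, ][act] <- x[idx$uid[act]]
  W <- idx$w_known                            # nr x (nz+1), inlet included
  actw <- idx$wid > 0L
  W[actw] <- x[idx$wid[actw]]
  P <- matrix(NA_real_, nr, nz)
  P[idx$fluid] <- x[idx$pid[idx$fluid]]
  list(U = U, W = W, P = P)
}

#' Solve steady flow through the coupled free/porous domains
#'
#' Finite-volume solution of steady incompressible flow on the staggered
#' axisymmetric grid: Navier-Stokes in the free-media region with a Brinkman
#' drag term `-(mu/k) u` added in porous cells (single-field penalization; one
#' momentum equation everywhere). With `include_inertia = FALSE` the operator
#' is linear (Stokes-Brinkman) and a single sparse direct solve is performed;
#' otherwise first-order-upwind convection is iterated by Picard with
#' under-relaxation. Inlet: plug velocity; outlet: zero reference pressure
#' with zero-gradient velocity; all walls no-slip (ghost reflection for walls
#' not coincident with a velocity face).
#'
#' @param grid a [rasterize()] or [tube_grid()] domain grid
#' @param fluid a [fluid_props()] object
#' @param porous a [porous_props()] object
#' @param bc a [flow_bc()] boundary condition
#' @param include_inertia include convective inertia via Picard iteration
#' @param tol relative nonlinear-update tolerance for the Picard loop
#' @param max_iter maximum Picard iterations
#' @param relax Picard under-relaxation factor in (0, 1]
#' @return an object of class `flow_solution` carrying the staggered face
#'   velocities `U` ((nr+1) x nz) and `W` (nr x (nz+1)), cell pressures `P`,
#'   the grid, and solver diagnostics
#' @export
solve_flow <- function(grid, fluid = fluid_props(), porous = porous_props(),
                       bc, include_inertia = TRUE, tol = 1e-6,
                       max_iter = 40L, relax = 0.8) {
  stopifnot(inherits(grid, "domain_grid"), inherits(bc, "flow_bc"))
  idx <- build_index_maps(grid, bc)
  if (idx$n_p == 0L) stop("grid contains no fluid cells")
  st <- assemble_stokes(grid, fluid, porous, bc, idx)
  A0 <- Matrix::sparseMatrix(i = st$i, j = st$j, x = st$x,
                             dims = c(idx$n, idx$n))
  x <- as.numeric(Matrix::solve(A0, st$rhs))
  iters <- 0L
  change <- 0
  if (include_inertia && bc$v_inlet > 0) {
    vref <- max(bc$v_inlet, 1e-30)
    prev_change <- Inf; grow <- 0L
    for (it in seq_len(max_iter)) {
      f <- fields_from_solution(x, grid, idx)
      cv <- assemble_convection(grid, fluid, idx, st, f$U, f$W)
      A <- Matrix::sparseMatrix(i = c(st$i, cv$i), j = c(st$j, cv$j),
                                x = c(st$x, cv$x), dims = c(idx$n, idx$n))
      xn <- as.numeric(Matrix::solve(A, st$rhs + cv$rhs))
      xn <- relax * xn + (1 - relax) * x
      nv <- idx$n_u + idx$n_w
      change <- max(abs(xn[seq_len(nv)] - x[seq_len(nv)])) / vref
      x <- xn
      iters <- it
      if (change < tol) break
      if (change > prev_change * 1.2) grow <- grow + 1L else grow <- 0L
      if (grow >= 5L)
        stop("flow solver diverged: Picard update grew over 5 consecutive ",
             "checks (last relative change ", signif(change, 3), ")")
      prev_change <- change
    }
    if (change >= tol)
      warning("Picard iteration stopped at max_iter = ", max_iter,
              " with relative change ", signif(change, 3))
  }
  f <- fields_from_solution(x, grid, idx)
  div <- max_divergence(f, grid, idx)
  structure(list(U = f$U, W = f$W, P = f$P, grid = grid, bc = bc,
                 fluid = fluid, porous = porous,
                 diagnostics = list(picard_iterations = iters,
                                    include_inertia = include_inertia,
                                    nonlinear_change = change,
                                    max_divergence = div,
                                    n_unknowns = idx$n),
                 converged = TRUE),
            class = "flow_solution")
}

# max |div u| over fluid cells, normalized by v_inlet/dz
max_divergence <- function(f, grid, idx) {
  nr <- grid$nr; nz <- grid$nz; dr <- grid$dr; dz <- grid$dz
  r_c <- (seq_len(nr) - 0.5) * dr
  r_p <- seq_len(nr) * dr; r_m <- (seq_len(nr) - 1L) * dr
  divr <- (f$U[2:(nr + 1L), , drop = FALSE] * r_p -
           f$U[1:nr, , drop = FALSE] * r_m) / (r_c * dr)
  divz <- (f$W[, 2:(nz + 1L), drop = FALSE] - f$W[, 1:nz, drop = FALSE]) / dz
  d <- abs(divr + divz)
  d[!idx$fluid] <- 0
  scale <- max(abs(f$W), abs(f$U), 1e-300) / dz
  max(d) / scale
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("Steady axisymmetric flow solution\n")
  cat(sprintf("  grid: %d x %d cells (dr = %.1f um)\n",
              x$grid$nr, x$grid$nz, x$grid$dr * 1e6))
  cat(sprintf("  inlet velocity: %.4g m/s; inertia: %s (%d Picard iterations)\n",
              x$bc$v_inlet, x$diagnostics$include_inertia,
              x$diagnostics$picard_iterations))
  cat(sprintf("  max velocity magnitude: %.4g m/s; normalized max divergence: %.2g\n",
              max(velocity_magnitude(x), na.rm = TRUE),
              x$diagnostics$max_divergence))
  invisible(x)
}

#' Cell-centred velocity magnitude
#'
#' Averages the staggered face velocities to cell centres and returns the
#' magnitude, NA outside the fluid.
#'
#' @param sol a [solve_flow()] solution
#' @return an nr x nz matrix (m/s)
#' @export
velocity_magnitude <- function(sol) {
  nr <- sol$grid$nr; nz <- sol$grid$nz
  uc <- (sol$U[1:nr, , drop = FALSE] + sol$U[2:(nr + 1L), , drop = FALSE]) / 2
  wc <- (sol$W[, 1:nz, drop = FALSE] + sol$W[, 2:(nz + 1L), drop = FALSE]) / 2
  v <- sqrt(uc^2 + wc^2)
  v[sol$grid$label == LBL_OUTSIDE] <- NA_real_
  v
}

#' Maximum velocity magnitude over a labelled domain
#' @param sol a [solve_flow()] solution
#' @param region `"porous"`, `"free"` or `"all"` (all fluid)
#' @return maximum cell-centred velocity magnitude (m/s)
#' @export
max_velocity <- function(sol, region = c("all", "porous", "free")) {
  region <- match.arg(region)
  v <- velocity_magnitude(sol)
  sel <- switch(region,
                all = sol$grid$label > 0L,
                porous = sol$grid$label == LBL_POROUS,
                free = sol$grid$label == LBL_FREE)
  if (!any(sel)) stop("region '", region, "' is empty on this grid")
  max(v[sel])
}

# volume-weighted mean velocity magnitude per domain (weights 2 pi r dr dz)
mean_velocity_by_domain <- function(sol) {
  v <- velocity_magnitude(sol)
  r_w <- sol$grid$r_centers[row(sol$grid$label)]
  out <- c(free = NA_real_, porous = NA_real_)
  for (lab in c(free = LBL_FREE, porous = LBL_POROUS)) {
    sel <- sol$grid$label == lab
    nm <- if (lab == LBL_FREE) "free" else "porous"
    if (any(sel)) out[nm] <- sum(v[sel] * r_w[sel]) / sum(r_w[sel])
  }
  out
}

#' Mesh refinement until the mean-velocity criterion is met
#'
#' Re-solves the flow on successively halved grid spacings until the relative
#' change of the volume-weighted mean velocity magnitude between two
#' consecutive levels is below `criterion` in both the free and the porous
#' domain (the porous domain is skipped if the geometry has none).
#'
#' @param geom a [build_geometry()] geometry
#' @param fluid,porous,bc physics and boundary condition, as in [solve_flow()]
#' @param initial_spacing coarsest grid spacing (m)
#' @param criterion relative-change convergence criterion (default 0.02)
#' @param max_levels maximum number of refinement levels (default 8)
#' @param ... further arguments passed to [solve_flow()]
#' @return a list with `solution` (the finest-level [solve_flow()] result) and
#'   `report`, a data frame with one row per level: spacing, mean velocity per
#'   domain and relative changes
#' @export
refine_until_converged <- function(geom, fluid = fluid_props(),
                                   porous = porous_props(), bc,
                                   initial_spacing, criterion = 0.02,
                                   max_levels = 8L, ...) {
  rows <- list(); sol <- NULL; prev <- NULL
  spacing <- initial_spacing
  for (lev in seq_len(max_levels)) {
    grid <- rasterize(geom, spacing)
    sol <- solve_flow(grid, fluid, porous, bc, ...)
    m <- mean_velocity_by_domain(sol)
    rel <- c(free = NA_real_, porous = NA_real_)
    if (!is.null(prev)) {
      rel <- abs(m - prev) / abs(prev)
      rel[is.nan(rel)] <- 0
    }
    rows[[lev]] <- data.frame(level = lev, spacing = spacing,
                              mean_v_free = m[["free"]],
                              mean_v_porous = m[["porous"]],
                              rel_change_free = rel[["free"]],
                              rel_change_porous = rel[["porous"]])
    done <- !is.null(prev) &&
      all(rel[!is.na(m)] < criterion, na.rm = FALSE) &&
      !any(is.na(rel[!is.na(m)]))
    if (isTRUE(done)) {
      report <- do.call(rbind, rows)
      return(list(solution = sol, report = report))
    }
    prev <- m
    spacing <- spacing / 2
  }
  report <- do.call(rbind, rows)
  cond <- structure(class = c("refinement_not_converged", "error", "condition"),
                    list(message = paste0("mean-velocity criterion ", criterion,
                                          " not met after ", max_levels,
                                          " levels"),
                         call = sys.call(-1), report = report))
  stop(cond)
}

#' Global mass balance of a flow solution
#'
#' Integrates the axial velocity over the revolved inlet and outlet faces and
#' reports the relative imbalance `|flux_in - flux_out| / flux_in` (defined as
#' 0 for a zero-flow solution) together with the inlet flux for comparison
#' against the pump flow rate.
#'
#' @param sol a [solve_flow()] solution
#' @return a list with `imbalance`, `flux_in`, `flux_out` (m^3/s)
#' @export
mass_balance <- function(sol) {
  nr <- sol$grid$nr; nz <- sol$grid$nz
  dr <- sol$grid$dr
  r_c <- sol$grid$r_centers
  area <- 2 * pi * r_c * dr
  flux_in <- sum(area * sol$W[, 1L])
  flux_out <- sum(area * sol$W[, nz + 1L])
  if (flux_in == 0) {
    if (max(abs(sol$W), abs(sol$U)) > 0)
      stop("zero inlet flux but non-zero velocity field")
    return(list(imbalance = 0, flux_in = 0, flux_out = flux_out))
  }
  list(imbalance = abs(flux_in - flux_out) / abs(flux_in),
       flux_in = flux_in, flux_out = flux_out)
}
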