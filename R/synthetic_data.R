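#' Salt-leached scaffold phantom parameters
#'
#' Defaults emulate the disc-shaped silk-fibroin scaffold: 8 mm diameter x
#' 3 mm height, pore-forming granules of 315-400 um diameter, target porosity
#' 0.55 (the value used in the flow model; the material itself is described
#' as highly porous, ~90%, so the porosity is a parameter, not a constant).
#'
#' @param radius scaffold radius (m)
#' @param height scaffold height (m)
#' @param porosity target pore volume fraction, in (0, 1)
#' @param pore_diameter_range granule diameter range (m)
#' @param voxel_size voxel edge length (m); default 36 um
#' @param scaffold_density density assigned to scaffold material
#'   (mg HA/cm^3); sub-threshold, because the wet scaffold is invisible at
#'   the mineralization threshold
#' @param seed RNG seed
#' @return an object of class `phantom_params`
#' @export
phantom_params <- function(radius = 4e-3, height = 3e-3, porosity = 0.55,
                           pore_diameter_range = c(315e-6, 400e-6),
                           voxel_size = 36e-6, scaffold_density = 30,
                           seed = 1L) {
  if (porosity <= 0 || porosity >= 1) stop("porosity must be in (0, 1)")
  if (any(pore_diameter_range <= 0) || diff(pore_diameter_range) < 0)
    stop("pore diameter range must be positive and ordered")
  structure(list(radius = radius, height = height, porosity = porosity,
                 pore_diameter_range = pore_diameter_range,
                 voxel_size = voxel_size, scaffold_density = scaffold_density,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

#' Generate a salt-leached porous scaffold phantom
#'
#' Rasterizes a scaffold cylinder and carves spherical pores with diameters
#' drawn uniformly from the granule range, at uniform random centres inside
#' the cylinder (spheres may overlap, as packed salt granules touch), until
#' the measured pore fraction is within +/- 2 percentage points of the
#' target. Reproducible from the seed.
#'
#' @param params a [phantom_params()] object
#' @param max_spheres safety cap on the number of pore spheres
#' @return list with `volume` (a [voxel_volume()] of scaffold density),
#'   `pores` (a [binary_mask()] of pore space inside the cylinder),
#'   `envelope` (the cylinder mask), `porosity` (measured), `n_spheres`
#' @export
gen_scaffold_phantom <- function(params = phantom_params(),
                                 max_spheres = 200000L) {
  vs <- params$voxel_size
  nx <- as.integer(ceiling(2 * params$radius / vs))
  nz <- as.integer(ceiling(params$height / vs))
  dims <- c(nx, nx, nz)
  cxy <- nx / 2
  env <- scaffold_tv_region(dims, vs, params$radius, params$height,
                            center_xy = c(cxy, cxy))$mask
  n_env <- sum(env)
  if (n_env == 0L) stop("degenerate phantom geometry: empty envelope")
  set.seed(params$seed)
  pores <- array(FALSE, dims)
  mean_d <- mean(params$pore_diameter_range)
  vol_sphere <- pi / 6 * mean_d^3
  vol_cyl <- pi * params$radius^2 * params$height
  n <- 0L
  zmid <- nz * vs / 2
  repeat {
    frac <- sum(pores & env) / n_env
    if (frac >= params$porosity) break
    if (n >= max_spheres)
      stop("target porosity ", params$porosity, " unreachable within ",
           max_spheres, " pore spheres (reached ", signif(frac, 3), ")")
    deficit <- (params$porosity - frac) * vol_cyl
    batch <- max(1L, min(as.integer(floor(0.5 * deficit / vol_sphere)), 500L))
    for (b in seq_len(batch)) {
      # uniform centre inside the cylinder (rejection-free in r via sqrt)
      rr <- params$radius * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      cx <- cxy * vs + rr * cos(th)
      cy <- cxy * vs + rr * sin(th)
      cz <- zmid + stats::runif(1, -params$height / 2, params$height / 2)
      d <- stats::runif(1, params$pore_diameter_range[1],
                        params$pore_diameter_range[2])
      pores <- carve_sphere(pores, c(cx, cy, cz), d / 2, vs)
      n <- n + 1L
    }
  }
  pores <- pores & env
  dens <- array(0, dims)
  dens[env & !pores] <- params$scaffold_density
  list(volume = voxel_volume(dens, vs),
       pores = binary_mask(pores, vs),
       envelope = binary_mask(env, vs),
       porosity = sum(pores) / n_env,
       n_spheres = n)
}

# set voxels within radius of centre (world m) to TRUE, bounding-box local
carve_sphere <- function(arr, centre, radius, vs) {
  d <- dim(arr)
  lo <- pmax(floor((centre - radius) / vs), c(0, 0, 0))
  hi <- pmin(ceiling((centre + radius) / vs), d - 1)
  if (any(lo > hi)) return(arr)
  ix <- (lo[1]:hi[1]) + 1L; iy <- (lo[2]:hi[2]) + 1L; iz <- (lo[3]:hi[3]) + 1L
  px <- (ix - 0.5) * vs - centre[1]
  py <- (iy - 0.5) * vs - centre[2]
  pz <- (iz - 0.5) * vs - centre[3]
  d2 <- outer(outer(px^2, py^2, "+"), pz^2, "+")
  arr[ix, iy, iz] <- arr[ix, iy, iz] | (d2 <= radius^2)
  arr
}

#' Shear-stress to mineralization link
#'
#' The per-week probability that an unmineralized pore voxel mineralizes is
#' `rate * link(tau) + bonus * (fraction of mineralized 6-neighbours)`,
#' clipped to [0, 1]. Link types: `"band"` (1 inside [lo, hi], 0 outside --
#' the default, with edges at 0.55 and 24 mPa, the stress range observed to
#' support mineralization under flow), `"logistic"` (smooth log-stress band)
#' and `"uniform"` (link identically 1: the static-culture condition, where
#' mineralization is uniform rather than edge-to-centre).
#'
#' @param type `"band"`, `"logistic"` or `"uniform"`
#' @param lo,hi band edges (Pa); defaults 0.55e-3 and 24e-3
#' @param rate per-week baseline mineralization probability inside the band
#' @param bonus neighbourhood-growth bonus weight
#' @param noise lognormal perturbation SD applied to tau before the link
#'   (emulates registration/field uncertainty); 0 disables
#' @return an object of class `mineralization_link`
#' @export
mineralization_link <- function(type = c("band", "logistic", "uniform"),
                                lo = 0.55e-3, hi = 24e-3, rate = 0.15,
                                bonus = 0.25, noise = 0) {
  type <- match.arg(type)
  if (lo >= hi) stop("band edges must satisfy lo < hi")
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (noise < 0) stop("noise must be >= 0")
  structure(list(type = type, lo = lo, hi = hi, rate = rate, bonus = bonus,
                 noise = noise),
            class = "mineralization_link")
}

link_prob <- function(link, tau) {
  switch(link$type,
         uniform = rep(1, length(tau)),
         band = as.numeric(tau >= link$lo & tau <= link$hi),
         logistic = stats::plogis((log(tau) - log(link$lo)) / 0.25) *
           stats::plogis((log(link$hi) - log(tau)) / 0.25))
}

# fraction of mineralized 6-neighbours per voxel (zero padding at edges)
neighbour_fraction <- function(mask) {
  d <- dim(mask)
  acc <- array(0, d)
  m <- mask * 1
  acc[-d[1], , ] <- acc[-d[1], , ] + m[-1, , ]
  acc[-1, , ]    <- acc[-1, , ]    + m[-d[1], , ]
  acc[, -d[2], ] <- acc[, -d[2], ] + m[, -1, ]
  acc[, -1, ]    <- acc[, -1, ]    + m[, -d[2], ]
  acc[, , -d[3]] <- acc[, , -d[3]] + m[, , -1]
  acc[, , -1]    <- acc[, , -1]    + m[, , -d[3]]
  acc / 6
}

#' Generate a weekly mineralization series driven by shear stress
#'
#' Per listed week, each not-yet-mineralized pore voxel mineralizes with
#' probability `rate * link(tau) + bonus * neighbour_fraction`, clipped to
#' [0, 1]; masks are nested over weeks (no demineralization). Under the band
#' link on a perfused field, growth emerges from the scaffold edge (where
#' shear stress is highest) toward the centre; with the uniform link the
#' pattern is spatially uniform, as in static culture. Voxels without a
#' valid simulated stress participate only under the uniform link.
#'
#' @param ss a [revolve_to_voxels()] sample on the phantom lattice
#' @param pores a [binary_mask()] of pore space (candidate voxels)
#' @param link a [mineralization_link()]
#' @param weeks strictly increasing integer week labels
#' @param seed RNG seed
#' @return named list of nested [binary_mask()] objects, one per week
#' @export
gen_mineralization <- function(ss, pores, link = mineralization_link(),
                               weeks = 2:6, seed = 1L) {
  stopifnot(inherits(pores, "binary_mask"),
            inherits(link, "mineralization_link"))
  if (length(weeks) == 0L || any(diff(weeks) <= 0))
    stop("weeks must be strictly increasing")
  if (link$type != "uniform") {
    stopifnot(inherits(ss, "voxel_field_sample"))
    if (!identical(dim(ss$tau), dim(pores$mask)))
      stop("shear-stress sample and pore mask lattices differ")
    tau <- ss$tau
    candidate <- pores$mask & ss$valid
  } else {
    tau <- array(0, dim(pores$mask))
    candidate <- pores$mask
  }
  set.seed(seed)
  if (link$noise > 0)
    tau <- tau * exp(stats::rnorm(length(tau), 0, link$noise))
  base_p <- array(0, dim(pores$mask))
  base_p[candidate] <- link$rate * link_prob(link, tau[candidate])
  mineral <- array(FALSE, dim(pores$mask))
  out <- vector("list", length(weeks))
  names(out) <- paste0("week", weeks)
  for (wi in seq_along(weeks)) {
    p <- base_p + link$bonus * neighbour_fraction(mineral)
    p[!candidate | mineral] <- 0
    p <- pmin(pmax(p, 0), 1)
    draw <- array(stats::runif(length(p)) < p, dim(p))
    mineral <- mineral | draw
    out[[wi]] <- binary_mask(mineral, pores$voxel_size, pores$origin)
  }
  out
}

#' Micro-CT acquisition parameters for the forward scan model
#'
#' @param psf_sigma Gaussian point-spread-function SD (voxels)
#' @param noise_sd additive Gaussian noise SD (mg HA/cm^3)
#' @param mineral_density density assigned to mineralized ECM (mg HA/cm^3);
#'   default 200, comfortably above the 97.5 segmentation threshold
#' @return an object of class `scan_params`
#' @export
scan_params <- function(psf_sigma = 0.8, noise_sd = 25, mineral_density = 200) {
  if (psf_sigma < 0) stop("psf_sigma must be >= 0")
  if (noise_sd < 0) stop("noise SD must be >= 0")
  if (mineral_density <= 0) stop("mineral density must be positive")
  structure(list(psf_sigma = psf_sigma, noise_sd = noise_sd,
                 mineral_density = mineral_density),
            class = "scan_params")
}

#' Simulate a micro-CT acquisition of a mineralization mask
#'
#' Forward model: mineral density on the mask (scaffold material keeps its
#' sub-threshold density, as the wet scaffold cannot be distinguished from
#' culture medium), blurred by a Gaussian point-spread function, plus
#' additive Gaussian noise. Seeded and reproducible.
#'
#' @param mineral a [binary_mask()] of mineralized tissue
#' @param scan a [scan_params()] object
#' @param scaffold_volume optional [voxel_volume()] of scaffold density to
#'   superimpose (from [gen_scaffold_phantom()])
#' @param week week label stamped on the output
#' @param seed RNG seed
#' @return a [voxel_volume()]
#' @export
simulate_uct_scan <- function(mineral, scan = scan_params(),
                              scaffold_volume = NULL, week = NA_integer_,
                              seed = 1L) {
  stopifnot(inherits(mineral, "binary_mask"), inherits(scan, "scan_params"))
  dens <- array(0, dim(mineral$mask))
  if (!is.null(scaffold_volume)) {
    stopifnot(inherits(scaffold_volume, "voxel_volume"))
    if (!same_lattice(scaffold_volume, mineral))
      stop("scaffold volume and mineral mask lattices differ")
    dens <- scaffold_volume$data
  }
  dens[mineral$mask] <- scan$mineral_density
  vol <- voxel_volume(dens, mineral$voxel_size, mineral$origin, week)
  if (scan$psf_sigma > 0)
    vol <- gaussian_filter_vol(vol, scan$psf_sigma,
                               support = max(1L, ceiling(3 * scan$psf_sigma)))
  set.seed(seed)
  if (scan$noise_sd > 0)
    vol$data <- vol$data + stats::rnorm(length(vol$data), 0, scan$noise_sd)
  vol
}
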