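#' Density-calibrated voxel volume
#'
#' 3-D scalar image in mg hydroxyapatite per cm^3 on an isotropic lattice.
#'
#' @param data 3-D numeric array (mg HA/cm^3)
#' @param voxel_size voxel edge length (m); default 36 um
#' @param origin world coordinates of the volume corner (m)
#' @param week acquisition week label (optional)
#' @return an object of class `voxel_volume`
#' @export
voxel_volume <- function(data, voxel_size = 36e-6, origin = c(0, 0, 0),
                         week = NA_integer_) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (any(!is.finite(data))) stop("densities must be finite")
  if (!is.finite(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be positive")
  structure(list(data = data, voxel_size = voxel_size, origin = origin,
                 week = week),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("voxel_volume: %s voxels at %.1f um%s, density %.1f..%.1f mg HA/cm^3\n",
              paste(dim(x$data), collapse = " x "), x$voxel_size * 1e6,
              if (is.na(x$week)) "" else sprintf(" (week %d)", x$week),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Binary segmentation mask
#' @param mask 3-D logical array
#' @param voxel_size voxel edge length (m)
#' @param origin world coordinates of the volume corner (m)
#' @return an object of class `binary_mask`
#' @export
binary_mask <- function(mask, voxel_size = 36e-6, origin = c(0, 0, 0)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, is.logical(mask))
  structure(list(mask = mask, voxel_size = voxel_size, origin = origin),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %s voxels at %.1f um, %d foreground\n",
              paste(dim(x$mask), collapse = " x "), x$voxel_size * 1e6,
              sum(x$mask)))
  invisible(x)
}

same_lattice <- function(a, b) {
  arr_a <- if (!is.null(a$data)) a$data else a$mask
  arr_b <- if (!is.null(b$data)) b$data else b$mask
  identical(dim(arr_a), dim(arr_b)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Micro-CT processing parameters
#'
#' Defaults follow the scanner-vendor convention for this scanner family:
#' Gaussian filter width (sigma) 1.2 voxels truncated at a support of 1 voxel
#' (3^3 taps, renormalized), segmentation threshold 97.5 mg HA/cm^3, removal
#' of unconnected particles smaller than 50 voxels (strict), 26-neighbourhood
#' connectivity.
#'
#' @param sigma Gaussian standard deviation in voxels
#' @param support truncation radius in voxels (integer)
#' @param threshold segmentation threshold (mg HA/cm^3)
#' @param min_size minimum particle size kept (voxels); components with fewer
#'   voxels are removed, components of exactly `min_size` are kept
#' @param connectivity 26 (default) or 6
#' @return an object of class `filter_params`
#' @export
filter_params <- function(sigma = 1.2, support = 1L, threshold = 97.5,
                          min_size = 50L, connectivity = 26L) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (support != round(support) || support < 0)
    stop("support must be a non-negative integer")
  if (threshold <= 0) stop("threshold must be positive")
  if (min_size < 1) stop("min_size must be >= 1")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  structure(list(sigma = sigma, support = as.integer(support),
                 threshold = threshold, min_size = as.integer(min_size),
                 connectivity = as.integer(connectivity)),
            class = "filter_params")
}

# 1-D truncated, renormalized Gaussian taps for offsets -support..support
gaussian_taps <- function(sigma, support) {
  off <- seq(-support, support)
  w <- if (sigma == 0) as.numeric(off == 0) else exp(-off^2 / (2 * sigma^2))
  w / sum(w)
}

# shift a 3-D array by s along axis, symmetric (mirror) boundary
shift_mirror <- function(x, s, axis) {
  n <- dim(x)[axis]
  src <- seq_len(n) + s
  src[src < 1L] <- 1L - src[src < 1L]
  src[src > n] <- 2L * n + 1L - src[src > n]
  switch(axis, x[src, , , drop = FALSE], x[, src, , drop = FALSE],
         x[, , src, drop = FALSE])
}

#' Gaussian filtration of a voxel volume
#'
#' Convolution with a 3-D Gaussian kernel of standard deviation `sigma`
#' voxels, truncated to a radius of `support` voxels ((2*support+1)^3 taps)
#' and renormalized to unit sum; mirror boundary handling. The 3-D truncated
#' kernel is the outer product of the renormalized 1-D kernels, so the filter
#' is applied separably.
#'
#' @param vol a [voxel_volume()]
#' @param sigma filter width (standard deviation) in voxels; default 1.2
#' @param support truncation radius in voxels (integer); default 1;
#'   `support = 0` is the identity
#' @return the filtered [voxel_volume()]
#' @export
gaussian_filter_vol <- function(vol, sigma = 1.2, support = 1L) {
  stopifnot(inherits(vol, "voxel_volume"))
  if (support != round(support) || support < 0)
    stop("support must be a non-negative integer")
  support <- as.integer(support)
  if (support == 0L || sigma == 0) {
    if (support > 0L) {
      # sigma 0 with positive support: delta kernel, still identity
    }
    return(vol)
  }
  taps <- gaussian_taps(sigma, support)
  x <- vol$data
  for (axis in 1:3) {
    acc <- taps[support + 1L] * x
    for (s in seq_len(support)) {
      acc <- acc + taps[support + 1L + s] *
        (shift_mirror(x, s, axis) + shift_mirror(x, -s, axis))
    }
    x <- acc
  }
  voxel_volume(x, vol$voxel_size, vol$origin, vol$week)
}

#' Grey-scale / density calibration
#'
#' Linear map through the origin calibrated so that a grey value of 12.7%
#' of full scale corresponds to 97.5 mg HA/cm^3.
#'
#' @param percent grey value in percent of full scale (0..100)
#' @return density in mg HA/cm^3
#' @export
grey_to_density <- function(percent) {
  if (any(percent < 0 | percent > 100)) stop("grey percent must be in [0, 100]")
  percent * (97.5 / 12.7)
}

#' @rdname grey_to_density
#' @param density density in mg HA/cm^3
#' @return grey value in percent of full scale
#' @export
density_to_grey <- function(density) {
  density / (97.5 / 12.7)
}

#' Segment mineralized tissue by density thresholding
#'
#' A voxel is mineralized when its density is greater than or equal to the
#' threshold (a voxel at exactly 97.5 mg HA/cm^3 is included).
#'
#' @param vol a calibrated [voxel_volume()]
#' @param threshold density threshold (mg HA/cm^3); default 97.5
#' @return a [binary_mask()]
#' @export
segment <- function(vol, threshold = 97.5) {
  stopifnot(inherits(vol, "voxel_volume"))
  binary_mask(vol$data >= threshold, vol$voxel_size, vol$origin)
}

# half-neighbourhood offsets (each undirected adjacency counted once)
connectivity_offsets <- function(connectivity) {
  if (connectivity == 6L) {
    matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), ncol = 3, byrow = TRUE)
  } else {
    off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
    keep <- off[, 3] > 0 | (off[, 3] == 0 & off[, 2] > 0) |
      (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0)
    off[keep, , drop = FALSE]
  }
}

#' Label connected components of a 3-D mask
#'
#' Builds the voxel adjacency graph (26- or 6-neighbourhood) and labels its
#' connected components.
#'
#' @param mask a [binary_mask()] or 3-D logical array
#' @param connectivity 26 (default, corner-touching voxels connect) or 6
#' @return integer array of component labels, 0 = background
#' @export
label_components <- function(mask, connectivity = 26L) {
  arr <- if (inherits(mask, "binary_mask")) mask$mask else mask
  stopifnot(is.logical(arr), length(dim(arr)) == 3L)
  d <- dim(arr)
  fg <- which(arr)
  labels <- array(0L, d)
  if (length(fg) == 0L) return(labels)
  compact <- integer(length(arr))
  compact[fg] <- seq_along(fg)
  co <- arrayInd(fg, d)
  offs <- connectivity_offsets(as.integer(connectivity))
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- co + matrix(offs[k, ], nrow(co), 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    hit <- arr[lin]
    edges[[k]] <- cbind(compact[fg[ok][hit]], compact[lin[hit]])
  }
  el <- do.call(rbind, edges)
  if (is.null(el) || nrow(el) == 0L) {
    labels[fg] <- seq_along(fg)
    return(labels)
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, length(fg) - igraph::vcount(g))
  memb <- igraph::components(g)$membership
  labels[fg] <- as.integer(memb)
  labels
}

#' Remove small unconnected particles
#'
#' Deletes connected components with strictly fewer than `min_size` voxels
#' (a component of exactly `min_size` voxels is kept).
#'
#' @param mask a [binary_mask()]
#' @param min_size size cutoff in voxels; default 50
#' @param connectivity 26 (default) or 6
#' @return the filtered [binary_mask()]
#' @export
filter_components <- function(mask, min_size = 50L, connectivity = 26L) {
  stopifnot(inherits(mask, "binary_mask"))
  labels <- label_components(mask$mask, connectivity)
  if (max(labels) == 0L) return(mask)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= min_size)
  binary_mask(array(labels %in% keep, dim(mask$mask)),
              mask$voxel_size, mask$origin)
}

#' Cylindrical total-volume (TV) region
#'
#' Voxel mask of the nominal scaffold envelope (a cylinder aligned with the
#' volume's third axis) used as the TV reference for BV/TV.
#'
#' @param dim integer length-3 volume dimensions
#' @param voxel_size voxel edge length (m)
#' @param radius cylinder radius (m); default the 4 mm scaffold radius
#' @param height cylinder height (m); default 3 mm; the cylinder is centred
#'   axially in the volume
#' @param center_xy (x, y) of the cylinder axis in voxel units; defaults to
#'   the volume centre
#' @param origin world coordinates of the volume corner (m)
#' @return a [binary_mask()]
#' @export
scaffold_tv_region <- function(dim, voxel_size, radius = 4e-3, height = 3e-3,
                               center_xy = NULL, origin = c(0, 0, 0)) {
  if (is.null(center_xy)) center_xy <- dim[1:2] / 2
  xi <- (seq_len(dim[1]) - 0.5 - center_xy[1]) * voxel_size
  yi <- (seq_len(dim[2]) - 0.5 - center_xy[2]) * voxel_size
  r2 <- outer(xi^2, yi^2, "+")
  disc <- r2 <= radius^2
  zc <- (seq_len(dim[3]) - 0.5) * voxel_size
  z_mid <- dim[3] * voxel_size / 2
  in_z <- abs(zc - z_mid) <= height / 2
  mask <- array(FALSE, dim)
  mask[, , in_z] <- disc
  binary_mask(mask, voxel_size, origin)
}

#' Bone morphometry of a mineralization mask
#'
#' BV is the mineralized volume inside the TV region, TV the region volume,
#' BV/TV their percentage ratio.
#'
#' @param mask a [binary_mask()] of mineralized tissue
#' @param tv_region a [binary_mask()] of the total-volume region, on the same
#'   lattice
#' @return a one-row data frame with `BV_mm3`, `TV_mm3`, `BVTV_percent`
#' @export
morphometry <- function(mask, tv_region) {
  stopifnot(inherits(mask, "binary_mask"), inherits(tv_region, "binary_mask"))
  if (!same_lattice(mask, tv_region))
    stop("mask and TV region are not on the same lattice")
  n_tv <- sum(tv_region$mask)
  if (n_tv == 0L) stop("TV region is empty")
  vx_mm3 <- (mask$voxel_size * 1e3)^3
  bv <- sum(mask$mask & tv_region$mask) * vx_mm3
  tv <- n_tv * vx_mm3
  data.frame(BV_mm3 = bv, TV_mm3 = tv, BVTV_percent = 100 * bv / tv)
}

#' Time-lapsed BV/TV morphometry
#'
#' Applies the full processing chain -- Gaussian filtration, density
#' thresholding, particle-size filtering, morphometry -- to each weekly
#' volume and returns the ordered morphometry table.
#'
#' @param volumes list of [voxel_volume()] objects on a common lattice
#'   (time-lapse scans are assumed pre-registered)
#' @param tv_region the TV reference region ([scaffold_tv_region()])
#' @param params a [filter_params()] object
#' @return data frame with columns `week`, `BV_mm3`, `TV_mm3`, `BVTV_percent`
#' @export
timelapse_bvtv <- function(volumes, tv_region, params = filter_params()) {
  if (length(volumes) == 0L) stop("empty volume series")
  stopifnot(all(vapply(volumes, inherits, TRUE, "voxel_volume")))
  for (v in volumes[-1])
    if (!same_lattice(volumes[[1]], v)) stop("inconsistent volume lattices")
  rows <- lapply(seq_along(volumes), function(i) {
    v <- volumes[[i]]
    m <- process_volume(v, params)
    cbind(week = if (is.na(v$week)) i else v$week, morphometry(m, tv_region))
  })
  out <- do.call(rbind, rows)
  out[order(out$week), , drop = FALSE]
}

#' Full single-volume segmentation chain
#'
#' Gaussian filtration, thresholding and particle-size filtering with the
#' given parameters.
#'
#' @param vol a [voxel_volume()]
#' @param params a [filter_params()]
#' @return a [binary_mask()]
#' @export
process_volume <- function(vol, params = filter_params()) {
  f <- gaussian_filter_vol(vol, params$sigma, params$support)
  m <- segment(f, params$threshold)
  filter_components(m, params$min_size, params$connectivity)
}
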