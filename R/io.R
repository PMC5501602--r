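#' Read a voxel volume from disk
#'
#' Supported formats by extension: NIfTI (`.nii`, `.nii.gz`) and MetaImage
#' (`.mha` single-file, `.mhd` + `.raw`). The round trip through
#' [write_volume()] preserves the array, the voxel spacing and the origin
#' losslessly. Spatial units on disk follow the imaging convention (mm);
#' in-memory units are metres.
#'
#' @param path file path
#' @return a [voxel_volume()]
#' @export
read_volume <- function(path) {
  ext <- volume_format(path)
  if (ext == "nifti") {
    img <- RNifti::readNifti(path)
    hdr <- RNifti::niftiHeader(img)
    vs <- RNifti::pixdim(img)[1] / 1e3   # NIfTI stores pixdim as float32
    origin <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z) / 1e3
    voxel_volume(array(as.numeric(img), dim(img)), vs, origin)
  } else {
    read_metaimage(path)
  }
}

#' Write a voxel volume (or mask) to disk
#'
#' @param vol a [voxel_volume()] or [binary_mask()] (masks are written as
#'   8-bit volumes)
#' @param path output path; format chosen by extension (`.nii`, `.nii.gz`,
#'   `.mha`, `.mhd`)
#' @param type element type: `"auto"` (double for volumes, uint8 for masks),
#'   `"double"`, `"float"`, `"short"` or `"uchar"`
#' @return invisibly, `path`
#' @export
write_volume <- function(vol, path, type = "auto") {
  is_mask <- inherits(vol, "binary_mask")
  if (is_mask)
    vol <- voxel_volume(array(as.numeric(vol$mask), dim(vol$mask)),
                        vol$voxel_size, vol$origin)
  stopifnot(inherits(vol, "voxel_volume"))
  if (type == "auto") type <- if (is_mask) "uchar" else "double"
  ext <- volume_format(path)
  if (ext == "nifti") {
    d <- dim(vol$data)
    hdr <- RNifti::niftiHeader(list(
      dim = c(3L, d, 1L, 1L, 1L, 1L),
      pixdim = c(1, rep(vol$voxel_size * 1e3, 3), 0, 0, 0, 0),
      qform_code = 1L, quatern_b = 0, quatern_c = 0, quatern_d = 0,
      qoffset_x = vol$origin[1] * 1e3, qoffset_y = vol$origin[2] * 1e3,
      qoffset_z = vol$origin[3] * 1e3))
    dt <- c(double = "double", float = "float", short = "int16",
            uchar = "uint8")[[type]]
    img <- RNifti::asNifti(vol$data, reference = hdr, datatype = dt)
    RNifti::writeNifti(img, path, datatype = dt)
  } else {
    write_metaimage(vol, path, type)
  }
  invisible(path)
}

#' Read a binary mask from disk
#'
#' Reads an 8-bit (or any numeric) volume and interprets non-zero as
#' foreground.
#'
#' @param path file path
#' @return a [binary_mask()]
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(v$data != 0, v$voxel_size, v$origin)
}

volume_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.mhd?a?$", path, ignore.case = TRUE) &&
      grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) return("metaimage")
  stop("unsupported volume format: ", basename(path),
       " (use .nii, .nii.gz, .mha or .mhd)")
}

met_types <- c(double = "MET_DOUBLE", float = "MET_FLOAT",
               short = "MET_SHORT", uchar = "MET_UCHAR")
met_sizes <- c(MET_DOUBLE = 8L, MET_FLOAT = 4L, MET_SHORT = 2L, MET_UCHAR = 1L)

write_metaimage <- function(vol, path, type = "double") {
  met <- met_types[[type]]
  d <- dim(vol$data)
  local_data <- grepl("\\.mha$", path, ignore.case = TRUE)
  raw_name <- paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE),
                     ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           "TransformMatrix = 1 0 0 0 1 0 0 0 1",
           paste("Offset =", paste(formatC(vol$origin * 1e3, format = "g",
                                           digits = 17), collapse = " ")),
           "CenterOfRotation = 0 0 0",
           paste("ElementSpacing =",
                 paste(rep(formatC(vol$voxel_size * 1e3, format = "g",
                                   digits = 17), 3), collapse = " ")),
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementType =", met),
           paste("ElementDataFile =", if (local_data) "LOCAL" else raw_name))
  payload <- switch(type,
                    double = writeBin(as.vector(vol$data), raw(),
                                      size = 8, endian = "little"),
                    float = writeBin(as.vector(vol$data), raw(),
                                     size = 4, endian = "little"),
                    short = writeBin(as.integer(round(vol$data)), raw(),
                                     size = 2, endian = "little"),
                    uchar = writeBin(as.integer(round(vol$data)), raw(),
                                     size = 1, endian = "little"))
  if (local_data) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
    writeBin(payload, con)
  } else {
    writeLines(hdr, path)
    writeBin(payload, file.path(dirname(path), raw_name))
  }
  invisible(path)
}

read_metaimage <- function(path) {
  raw_all <- readBin(path, raw(), file.size(path))
  nl <- which(raw_all == as.raw(10L))
  hdr <- list(); data_start <- NA_integer_; prev <- 0L
  for (pos in nl) {
    line <- rawToChar(raw_all[(prev + 1L):(pos - 1L)])
    prev <- pos
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) next
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") { data_start <- pos + 1L; break }
  }
  if (is.null(hdr$ElementDataFile)) stop("corrupt MetaImage header: ", path)
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  met <- hdr$ElementType
  if (!met %in% names(met_sizes)) stop("unsupported ElementType: ", met)
  n <- prod(d)
  if (hdr$ElementDataFile == "LOCAL") {
    payload <- raw_all[data_start:length(raw_all)]
  } else {
    payload <- readBin(file.path(dirname(path), hdr$ElementDataFile),
                       raw(), n * met_sizes[[met]])
  }
  vals <- switch(met,
                 MET_DOUBLE = readBin(payload, numeric(), n, size = 8,
                                      endian = "little"),
                 MET_FLOAT = readBin(payload, numeric(), n, size = 4,
                                     endian = "little"),
                 MET_SHORT = readBin(payload, integer(), n, size = 2,
                                     endian = "little"),
                 MET_UCHAR = as.integer(readBin(payload, integer(), n,
                                                size = 1, signed = FALSE,
                                                endian = "little")))
  voxel_volume(array(as.numeric(vals), d), spacing[1] / 1e3, origin / 1e3)
}

#' Export simulation fields as a legacy-VTK structured grid
#'
#' Writes the (r, z) plane of a flow solution and/or shear-stress field as an
#' ASCII VTK structured-points file (one cell layer thick) with point data
#' `velocity_magnitude` (m/s) and, if a stress field is given, `shear_stress`
#' (Pa). Cells outside the fluid carry -1.
#'
#' @param sol a [solve_flow()] solution
#' @param path output `.vtk` path
#' @param stress optional [shear_stress()] field on the same grid
#' @return invisibly, `path`
#' @export
write_vtk <- function(sol, path, stress = NULL) {
  stopifnot(inherits(sol, "flow_solution"))
  g <- sol$grid
  vm <- velocity_magnitude(sol)
  vm[is.na(vm)] <- -1
  lines <- c("# vtk DataFile Version 3.0",
             "axisymmetric (r,z) fields", "ASCII",
             "DATASET STRUCTURED_POINTS",
             sprintf("DIMENSIONS %d %d 1", g$nr, g$nz),
             sprintf("ORIGIN %.9g %.9g 0", g$dr / 2, g$dz / 2),
             sprintf("SPACING %.9g %.9g 1", g$dr, g$dz),
             sprintf("POINT_DATA %d", g$nr * g$nz),
             "SCALARS velocity_magnitude double 1",
             "LOOKUP_TABLE default",
             formatC(as.vector(vm), format = "g", digits = 9))
  if (!is.null(stress)) {
    stopifnot(inherits(stress, "shear_stress_field"))
    tau <- stress$tau
    tau[is.na(tau)] <- -1
    lines <- c(lines, "SCALARS shear_stress double 1", "LOOKUP_TABLE default",
               formatC(as.vector(tau), format = "g", digits = 9))
  }
  writeLines(lines, path)
  invisible(path)
}

# ---- minimal TOML-subset parser -------------------------------------------
# Supports: [section] headers, key = value with string ("..."), boolean
# (true/false), number (including scientific notation) and flat arrays.
parse_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(); section <- NULL
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[[A-Za-z0-9_.-]+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: '", ln, "'")
    key <- m[2]; val <- toml_value(m[3])
    if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
  }
  out
}

toml_value <- function(s) {
  s <- trimws(s)
  if (grepl("^\\[.*\\]$", s)) {
    inner <- trimws(gsub("^\\[|\\]$", "", s))
    if (inner == "") return(list())
    parts <- trimws(strsplit(inner, ",")[[1]])
    return(unlist(lapply(parts, toml_value)))
  }
  if (grepl('^".*"$', s)) return(gsub('^"|"$', "", s))
  if (s %in% c("true", "false")) return(s == "true")
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) return(num)
  stop("cannot parse config value: '", s, "'")
}

#' Parse a flow-rate string with explicit unit suffix
#'
#' Accepts `"<x> ml/min"` or `"<x> m3/s"` (and bare numbers, taken as m^3/s).
#'
#' @param x a string like `"0.2 ml/min"` or a number (m^3/s)
#' @return flow rate in m^3/s
#' @export
parse_flow_rate <- function(x) {
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec("^\\s*([0-9.eE+-]+)\\s*(ml/min|m3/s)\\s*$", x))[[1]]
  if (length(m) != 3L)
    stop("flow rate needs an explicit unit suffix ('ml/min' or 'm3/s'): ", x)
  val <- as.numeric(m[2])
  if (m[3] == "ml/min") ml_per_min(val) else val
}

config_schema <- list(
  geometry = c("chamber_radius", "scaffold_radius", "scaffold_height",
               "plenum_height_top", "plenum_height_bottom", "tube_radius",
               "tube_length"),
  fluid = c("density", "viscosity"),
  porous = c("porosity", "permeability"),
  solver = c("flow_rate", "inlet_velocity", "spacing", "refine", "criterion",
             "max_levels", "include_inertia", "tol", "max_iter"),
  uct = c("voxel_size", "sigma", "support", "threshold", "min_size",
          "connectivity"),
  synthetic = c("porosity", "pore_diameter_min", "pore_diameter_max",
                "scaffold_density", "link_type", "band_lo", "band_hi", "rate",
                "bonus", "noise", "weeks", "psf_sigma", "noise_sd",
                "mineral_density"),
  roc = c("thresholds"),
  output = c("dir", "volume_format"),
  run = c("seed"))

#' Read and validate a pipeline configuration
#'
#' Reads a TOML-dialect config file, rejects unknown sections or keys, and
#' validates units: lengths in metres, flow rates as strings with explicit
#' unit suffix (`"0.2 ml/min"` or `"3.3e-9 m3/s"`).
#'
#' @param path path to the config file
#' @return a validated nested list of class `pipeline_config`
#' @export
read_config <- function(path) {
  cfg <- parse_toml(path)
  for (sec in names(cfg)) {
    if (!sec %in% names(config_schema))
      stop("unknown config section: [", sec, "]")
    bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(bad))
      stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "))
  }
  if (is.null(cfg$solver) ||
      (is.null(cfg$solver$flow_rate) && is.null(cfg$solver$inlet_velocity)))
    stop("missing required config key: [solver] flow_rate or inlet_velocity")
  if (is.null(cfg$solver$spacing))
    stop("missing required config key: [solver] spacing")
  if (!is.null(cfg$solver$flow_rate))
    cfg$solver$flow_rate <- parse_flow_rate(cfg$solver$flow_rate)
  structure(cfg, class = "pipeline_config")
}
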