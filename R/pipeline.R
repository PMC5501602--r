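`%||%` <- function(a, b) if (is.null(a)) b else a

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full simulation-to-ROC pipeline
#'
#' Executes, in order: flow simulation (optionally with the mesh-refinement
#' sweep), shear-stress computation and revolution onto the voxel lattice,
#' synthetic scaffold/mineralization/scan generation, the micro-CT
#' processing chain with weekly BV/TV morphometry, and the pooled voxel-wise
#' ROC analysis of simulated shear stress against mineralization. All
#' artifacts are written under the output directory together with a manifest
#' (config snapshot, package version, seed, per-stage outputs and MD5
#' checksums). Outputs contain no timestamps: re-running with an identical
#' config and seed reproduces identical files.
#'
#' @param config a [read_config()] object or path to a TOML config file
#' @param out_dir output directory (overrides the config)
#' @param seed global seed (overrides the config)
#' @param quiet suppress progress messages
#' @return the manifest, invisibly (class `run_manifest`)
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- unclass(config)
  seed <- as.integer(seed %||% cfg[["run"]][["seed"]] %||% 1L)
  out_dir <- out_dir %||% cfg[["output"]][["dir"]] %||% stop("no output directory configured")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- cfg[["output"]][["volume_format"]] %||% "nii.gz"
  vext <- paste0(".", sub("^\\.", "", fmt))
  say <- function(...) if (!quiet) message(...)
  outputs <- list()

  ## --- simulate ---
  geom <- with_stage("geometry", do.call(build_geometry, cfg[["geometry"]] %||% list()))
  fl <- with_stage("geometry", do.call(fluid_props, cfg[["fluid"]] %||% list()))
  po <- with_stage("geometry", do.call(porous_props, cfg[["porous"]] %||% list()))
  bc <- with_stage("geometry", {
    if (!is.null(cfg[["solver"]][["inlet_velocity"]]))
      flow_bc(v = cfg[["solver"]][["inlet_velocity"]], tube_radius = geom$tube_radius)
    else flow_bc(Q = cfg[["solver"]][["flow_rate"]], tube_radius = geom$tube_radius)
  })
  say("stage simulate: inlet velocity ", signif(bc$v_inlet, 4), " m/s")
  sol <- with_stage("simulate", {
    opts <- list(include_inertia = cfg[["solver"]][["include_inertia"]] %||% TRUE,
                 tol = cfg[["solver"]][["tol"]] %||% 1e-6,
                 max_iter = cfg[["solver"]][["max_iter"]] %||% 40L)
    if (isTRUE(cfg[["solver"]][["refine"]])) {
      rr <- do.call(refine_until_converged,
                    c(list(geom = geom, fluid = fl, porous = po, bc = bc,
                           initial_spacing = cfg[["solver"]][["spacing"]],
                           criterion = cfg[["solver"]][["criterion"]] %||% 0.02,
                           max_levels = cfg[["solver"]][["max_levels"]] %||% 8L), opts))
      utils::write.csv(rr$report, file.path(out_dir, "refinement_report.csv"),
                       row.names = FALSE)
      outputs$refinement_report <- "refinement_report.csv"
      rr$solution
    } else {
      grid <- rasterize(geom, cfg[["solver"]][["spacing"]])
      do.call(solve_flow, c(list(grid = grid, fluid = fl, porous = po, bc = bc),
                            opts))
    }
  })
  stress <- with_stage("simulate", shear_stress(sol))
  with_stage("simulate", write_vtk(sol, file.path(out_dir, "fields.vtk"), stress))
  outputs$fields <- "fields.vtk"

  ## --- revolve onto the voxel lattice ---
  vs <- cfg[["uct"]][["voxel_size"]] %||% 36e-6
  nxy <- as.integer(ceiling(2 * geom$scaffold_radius / vs))
  nzv <- as.integer(ceiling(geom$scaffold_height / vs))
  ssv <- with_stage("superimpose", revolve_to_voxels(
    stress, vs, dim = c(nxy, nxy, nzv),
    axis_xy = c(nxy, nxy) / 2 * vs,
    z_offset = -geom$z_sections[["scaffold"]]))

  ## --- synth ---
  say("stage synth: phantom + mineralization series")
  syn <- cfg[["synthetic"]] %||% list()
  phant <- with_stage("synth", gen_scaffold_phantom(phantom_params(
    radius = geom$scaffold_radius, height = geom$scaffold_height,
    porosity = syn[["porosity"]] %||% 0.55,
    pore_diameter_range = c(syn[["pore_diameter_min"]] %||% 315e-6,
                            syn[["pore_diameter_max"]] %||% 400e-6),
    voxel_size = vs, scaffold_density = syn[["scaffold_density"]] %||% 30,
    seed = seed)))
  link <- with_stage("synth", mineralization_link(
    type = syn[["link_type"]] %||% "band",
    lo = syn[["band_lo"]] %||% 0.55e-3, hi = syn[["band_hi"]] %||% 24e-3,
    rate = syn[["rate"]] %||% 0.15, bonus = syn[["bonus"]] %||% 0.25,
    noise = syn[["noise"]] %||% 0))
  weeks <- as.integer(syn[["weeks"]] %||% 2:6)
  minser <- with_stage("synth", gen_mineralization(ssv, phant$pores, link,
                                                   weeks, seed = seed + 1L))
  scan <- with_stage("synth", scan_params(
    psf_sigma = syn[["psf_sigma"]] %||% 0.8, noise_sd = syn[["noise_sd"]] %||% 25,
    mineral_density = syn[["mineral_density"]] %||% 200))
  scans <- with_stage("synth", lapply(seq_along(weeks), function(i)
    simulate_uct_scan(minser[[i]], scan, scaffold_volume = phant$volume,
                      week = weeks[i], seed = seed + 1000L + i)))
  for (i in seq_along(weeks)) {
    fn <- sprintf("scan_week%d%s", weeks[i], vext)
    with_stage("synth", write_volume(scans[[i]], file.path(out_dir, fn)))
    outputs[[sprintf("scan_week%d", weeks[i])]] <- fn
  }

  ## --- uct ---
  say("stage uct: filtration, segmentation, morphometry")
  fp <- with_stage("uct", filter_params(
    sigma = cfg[["uct"]][["sigma"]] %||% 1.2, support = cfg[["uct"]][["support"]] %||% 1L,
    threshold = cfg[["uct"]][["threshold"]] %||% 97.5,
    min_size = cfg[["uct"]][["min_size"]] %||% 50L,
    connectivity = cfg[["uct"]][["connectivity"]] %||% 26L))
  tv <- with_stage("uct", scaffold_tv_region(
    dim(phant$volume$data), vs, geom$scaffold_radius, geom$scaffold_height))
  bvtv <- with_stage("uct", timelapse_bvtv(scans, tv, fp))
  utils::write.csv(bvtv, file.path(out_dir, "morphometry.csv"),
                   row.names = FALSE)
  outputs$morphometry <- "morphometry.csv"

  ## --- roc ---
  say("stage roc: superimposition and ROC analysis")
  final_mask <- with_stage("roc", process_volume(scans[[length(scans)]], fp))
  fn <- sprintf("mineral_week%d%s", weeks[length(weeks)], vext)
  with_stage("roc", write_volume(final_mask, file.path(out_dir, fn)))
  outputs$final_mask <- fn
  pdat <- with_stage("roc", superimpose(ssv, final_mask, phant$envelope,
                                        sample_id = "synthetic1"))
  curve <- with_stage("roc", roc_curve(pdat))
  with_stage("roc", write_roc(curve, file.path(out_dir, "roc_curve.csv"),
                              file.path(out_dir, "roc_summary.json"),
                              excluded = pdat$excluded))
  outputs$roc_curve <- "roc_curve.csv"
  outputs$roc_summary <- "roc_summary.json"

  ## --- manifest ---
  checksums <- vapply(outputs, function(f)
    unname(tools::md5sum(file.path(out_dir, f))), "")
  manifest <- list(
    package = "perfusim",
    version = as.character(utils::packageVersion("perfusim")),
    seed = seed,
    config = cfg,
    outputs = as.list(outputs),
    checksums = as.list(checksums),
    summary = list(
      v_inlet = bc$v_inlet,
      max_velocity = max_velocity(sol, "all"),
      max_velocity_scaffold = max_velocity(sol, "porous"),
      max_ss_scaffold_Pa = max_in_region(stress, "porous"),
      auc = curve$auc,
      tau_star_Pa = curve$least_random$tau_star,
      final_bvtv_percent = bvtv$BVTV_percent[nrow(bvtv)]))
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: ", out_dir)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("perfusim run manifest (seed ", x$seed, ")\n", sep = "")
  s <- x$summary
  cat(sprintf("  max velocity: %.4g m/s (scaffold %.4g m/s)\n",
              s$max_velocity, s$max_velocity_scaffold))
  cat(sprintf("  max scaffold shear stress: %.4g mPa\n",
              s$max_ss_scaffold_Pa * 1e3))
  cat(sprintf("  ROC AUC %.3f, tau* = %.4g mPa; final BV/TV %.3f%%\n",
              s$auc, s$tau_star_Pa * 1e3, s$final_bvtv_percent))
  cat("  outputs: ", paste(unlist(x$outputs), collapse = ", "), "\n")
  invisible(x)
}
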