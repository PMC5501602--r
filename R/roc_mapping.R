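#' Superimpose a shear-stress sample on a mineralization mask
#'
#' Pairs every analysis-region voxel carrying a valid simulated shear stress
#' with its mineralization label. Voxels flagged invalid in the shear-stress
#' sample are excluded and counted in the exclusion tally.
#'
#' @param ss a [revolve_to_voxels()] sample
#' @param mineral a [binary_mask()] of mineralized tissue
#' @param region a [binary_mask()] of the analysis region (by default the
#'   scaffold envelope, including scaffold-material voxels)
#' @param sample_id identifier carried through pooling
#' @return an object of class `paired_voxel_data` with vectors `tau` (Pa) and
#'   `mineralized`, counts `P`, `N` and the exclusion tally
#' @export
superimpose <- function(ss, mineral, region, sample_id = "sample1") {
  stopifnot(inherits(ss, "voxel_field_sample"),
            inherits(mineral, "binary_mask"), inherits(region, "binary_mask"))
  if (!identical(dim(ss$tau), dim(mineral$mask)) ||
      !identical(dim(ss$tau), dim(region$mask)) ||
      !isTRUE(all.equal(ss$voxel_size, mineral$voxel_size)) ||
      !isTRUE(all.equal(mineral$voxel_size, region$voxel_size)))
    stop("shear-stress sample, mineral mask and region are not on the same lattice")
  sel <- region$mask & ss$valid
  excluded <- sum(region$mask & !ss$valid)
  if (!any(sel)) stop("no region voxels with valid shear stress")
  tau <- ss$tau[sel]
  lab <- mineral$mask[sel]
  structure(list(tau = tau, mineralized = lab,
                 sample = rep(sample_id, length(tau)),
                 P = sum(lab), N = sum(!lab), excluded = excluded),
            class = "paired_voxel_data")
}

#' @export
print.paired_voxel_data <- function(x, ...) {
  cat(sprintf("paired_voxel_data: %d voxels (P = %d mineralized, N = %d), %d excluded\n",
              length(x$tau), x$P, x$N, x$excluded))
  invisible(x)
}

#' Pool paired voxel data across scaffolds
#'
#' Concatenates per-scaffold voxel records so that all scaffolds enter a
#' single ROC analysis; `P` and `N` are summed.
#'
#' @param samples list of [superimpose()] results
#' @return a pooled `paired_voxel_data`
#' @export
pool <- function(samples) {
  if (length(samples) == 0L) stop("empty sample list")
  stopifnot(all(vapply(samples, inherits, TRUE, "paired_voxel_data")))
  structure(list(tau = unlist(lapply(samples, `[[`, "tau")),
                 mineralized = unlist(lapply(samples, `[[`, "mineralized")),
                 sample = unlist(lapply(samples, `[[`, "sample")),
                 P = sum(vapply(samples, `[[`, 0L, "P")),
                 N = sum(vapply(samples, `[[`, 0L, "N")),
                 excluded = sum(vapply(samples, `[[`, 0L, "excluded"))),
            class = "paired_voxel_data")
}

#' Construct paired voxel data from raw vectors
#'
#' Convenience constructor used for worked examples and simulation studies.
#'
#' @param tau shear stresses (Pa)
#' @param mineralized logical labels
#' @param sample_id identifier
#' @return a `paired_voxel_data`
#' @export
paired_voxels <- function(tau, mineralized, sample_id = "sample1") {
  stopifnot(length(tau) == length(mineralized))
  mineralized <- as.logical(mineralized)
  structure(list(tau = tau, mineralized = mineralized,
                 sample = rep(sample_id, length(tau)),
                 P = sum(mineralized), N = sum(!mineralized), excluded = 0L),
            class = "paired_voxel_data")
}

#' ROC curve by incremental shear-stress thresholding
#'
#' Sweeps the prediction rule "mineralized if tau >= t" over the sorted unique
#' shear-stress values (all voxels tied at a threshold change classification
#' together), plus a sentinel giving the (0, 0) point; the final threshold
#' (the minimum tau) classifies every voxel positive, giving (1, 1). AUC is
#' the trapezoidal integral of TPR over FPR, which equals the Mann-Whitney
#' statistic Pr(tau_pos > tau_neg) + 0.5 Pr(tie).
#'
#' @param data a `paired_voxel_data`
#' @param thresholds `"unique"` (exact sweep, default) or a numeric vector of
#'   descending thresholds (e.g. a log-spaced grid for huge inputs)
#' @return an object of class `roc_curve`: data frame `sweep` with columns
#'   `threshold`, `TPR`, `FPR`; `auc`; and the least-random operating point
#' @export
roc_curve <- function(data, thresholds = "unique") {
  stopifnot(inherits(data, "paired_voxel_data"))
  P <- data$P; N <- data$N
  if (P < 1L || N < 1L)
    stop("ROC undefined: need at least one mineralized (P = ", P,
         ") and one non-mineralized (N = ", N, ") voxel")
  ord <- order(data$tau, decreasing = TRUE)
  tau_s <- data$tau[ord]
  pos_s <- data$mineralized[ord]
  cum_tp <- cumsum(pos_s)
  cum_fp <- cumsum(!pos_s)
  if (identical(thresholds, "unique")) {
    runs <- rle(tau_s)
    n_ge <- cumsum(runs$lengths)      # voxels with tau >= each unique value
    t_seq <- runs$values
  } else {
    t_seq <- sort(as.numeric(thresholds), decreasing = TRUE)
    n_ge <- findInterval(-t_seq, -tau_s)   # count of tau >= t (ties included)
  }
  tp <- ifelse(n_ge > 0L, cum_tp[pmax(n_ge, 1L)], 0)
  fp <- ifelse(n_ge > 0L, cum_fp[pmax(n_ge, 1L)], 0)
  sweep_df <- data.frame(threshold = c(Inf, t_seq),
                         TPR = c(0, tp / P), FPR = c(0, fp / N))
  if (utils::tail(sweep_df$TPR, 1) != 1 || utils::tail(sweep_df$FPR, 1) != 1)
    sweep_df <- rbind(sweep_df,
                      data.frame(threshold = -Inf, TPR = 1, FPR = 1))
  n <- nrow(sweep_df)
  auc <- sum(diff(sweep_df$FPR) * (sweep_df$TPR[-1] + sweep_df$TPR[-n]) / 2)
  structure(list(sweep = sweep_df, auc = auc, P = P, N = N,
                 least_random = least_random_from_sweep(sweep_df)),
            class = "roc_curve")
}

# Youden point: maximize TPR - FPR over finite-threshold sweep points.
# The perpendicular distance to the 45-degree diagonal is (TPR - FPR)/sqrt(2),
# so the furthest-from-diagonal point is the Youden maximum. Ties break toward
# the larger TPR (the more sensitive, lower-threshold operating point).
least_random_from_sweep <- function(sweep_df) {
  fin <- is.finite(sweep_df$threshold)
  j <- sweep_df$TPR - sweep_df$FPR
  j[!fin] <- -Inf
  cand <- which(j >= max(j) - 1e-12)
  pick <- cand[order(sweep_df$TPR[cand], decreasing = TRUE)[1]]
  list(tau_star = sweep_df$threshold[pick],
       TPR = sweep_df$TPR[pick], FPR = sweep_df$FPR[pick],
       J = sweep_df$TPR[pick] - sweep_df$FPR[pick])
}

#' Least-random operating point of an ROC curve
#'
#' The sweep point furthest from the 45-degree chance diagonal, i.e. the
#' Youden maximum of TPR - FPR. Ties break toward the larger TPR.
#'
#' @param curve a [roc_curve()]
#' @return list with `tau_star` (Pa), `TPR`, `FPR`, `J`
#' @export
least_random_point <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  curve$least_random
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d sweep points, P = %d, N = %d\n",
              nrow(x$sweep), x$P, x$N))
  cat(sprintf("  AUC = %.4f\n", x$auc))
  lr <- x$least_random
  cat(sprintf("  least-random point: tau* = %.4g mPa, TPR = %.3f, FPR = %.3f\n",
              lr$tau_star * 1e3, lr$TPR, lr$FPR))
  invisible(x)
}

#' Write ROC outputs
#'
#' Writes the threshold sweep as CSV (`threshold_Pa`, `TPR`, `FPR`) and the
#' summary (AUC, operating point, counts) as JSON.
#'
#' @param curve a [roc_curve()]
#' @param csv_path,json_path output paths (either may be NULL to skip)
#' @param excluded excluded-voxel tally to record in the summary
#' @return invisibly, the summary list
#' @export
write_roc <- function(curve, csv_path = NULL, json_path = NULL, excluded = 0L) {
  stopifnot(inherits(curve, "roc_curve"))
  if (!is.null(csv_path)) {
    df <- curve$sweep
    names(df)[1] <- "threshold_Pa"
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  summary <- list(AUC = curve$auc,
                  tau_star_Pa = curve$least_random$tau_star,
                  TPR_star = curve$least_random$TPR,
                  FPR_star = curve$least_random$FPR,
                  P = curve$P, N = curve$N, excluded = excluded)
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
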