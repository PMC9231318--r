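# Full analysis pipeline: clustering, conformation metrics, free-energy
# landscape (with basins and barriers) and, when the system carries the
# needed particles, pore radius, density/PMF and permeation.  Results are
# returned as a list and optionally written out as tidy CSVs plus a JSON
# run summary.

#' Run the full analysis pipeline on a trajectory
#'
#' Stages, in order: cluster-count series, per-frame SASA/Rg, per-frame
#' order parameter of the largest cluster, the (SASA, Rg) free-energy
#' landscape with basins and the barrier between the two deepest basins,
#' the pore radius of the largest cluster in the final frame, and -- when
#' water or ion particles are present -- axial density, density-based PMF
#' and permeation counts.
#'
#' @param traj an `mp_trajectory` (e.g. from
#'   [generate_aggregation_trajectory()] or [load_trajectory()]).
#' @param config an [analysis_config()].
#' @param out_dir optional output directory; when given, each stage writes
#'   a CSV and a `summary.json` is produced.
#' @param basin_max_w basins above this W are ignored (kcal/mol).
#' @return a list with elements `clusters`, `metrics`, `order`,
#'   `landscape`, `basins`, `barrier` (or `NULL`), `pore` and, when
#'   applicable, `density`, `pmf`, `permeation`; plus `files` when
#'   `out_dir` was given.
#' @export
run_pipeline <- function(traj, config = analysis_config(), out_dir = NULL,
                         basin_max_w = Inf) {
  stopifnot(inherits(traj, "mp_trajectory"))
  res <- list()
  res$clusters <- cluster_count_series(traj, config$cluster_cutoff,
                                       config$com_weighting)
  res$metrics <- conformation_series(traj, config)
  res$order <- order_parameter_series(traj, config)
  h <- histogram2d(res$metrics$sasa_nm2, res$metrics$rg_nm,
                   bins = config$fel_bins)
  res$landscape <- boltzmann_invert(h, config$temperature)
  res$basins <- find_basins(res$landscape, max_w = basin_max_w,
                            connectivity = config$connectivity)
  res$barrier <- if (nrow(res$basins) >= 2L)
    barrier_height(res$landscape, res$basins[1, ], res$basins[2, ],
                   config$connectivity) else NULL
  last <- traj$frames[[length(traj$frames)]]
  asg <- attr(res$clusters, "assignments")
  last_asg <- asg[[length(asg)]]
  members <- last_asg$clusters[[last_asg$largest_cluster_id]]
  res$pore <- if (length(members) >= 3L)
    pore_radius(last, traj$topology, members)
  else list(radius_nm = NA_real_, area_nm2 = NA_real_,
            status = "largest cluster has fewer than 3 chains")
  roles <- traj$topology$particles$role
  for (sp in c("water", "ion")) {
    if (!any(roles == sp)) next
    dp <- axial_density(traj, sp, config$channel_z[1], config$channel_z[2],
                        cylinder_radius = config$cylinder_radius,
                        bulk_margin = config$bulk_margin,
                        bulk_cross_section = config$bulk_cross_section)
    res$density[[sp]] <- dp
    res$pmf[[sp]] <- density_pmf(dp, config$temperature)
    if (length(traj$frames) >= 2L)
      res$permeation[[sp]] <- count_permeation_events(
        traj, sp, config$channel_z[1], config$channel_z[2],
        config$cylinder_radius)
  }
  if (!is.null(out_dir)) res$files <- write_pipeline_outputs(res, out_dir)
  res
}

landscape_table <- function(ls) {
  occ <- which(ls$occupied, arr.ind = TRUE)
  data.frame(sasa_nm2 = ls$x_centers[occ[, 1]],
             rg_nm = ls$y_centers[occ[, 2]],
             P = ls$P[occ], W_kcal_mol = ls$W[occ])
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(res$clusters, "clusters.csv")
  metrics <- cbind(res$metrics, S_largest_cluster = res$order$S)
  wr(metrics, "metrics.csv")
  wr(landscape_table(res$landscape), "fel.csv")
  for (sp in names(res$density))
    wr(res$density[[sp]]$profile, sprintf("density_%s.csv", sp))
  for (sp in names(res$pmf))
    wr(res$pmf[[sp]]$profile, sprintf("pmf_%s.csv", sp))
  for (sp in names(res$permeation))
    wr(res$permeation[[sp]], sprintf("permeation_%s.csv", sp))
  summary <- list(
    n_frames = nrow(res$clusters),
    final_cluster_count = res$clusters$n_clusters[nrow(res$clusters)],
    basins = res$basins,
    barrier = if (!is.null(res$barrier))
      res$barrier[c("saddle", "forward", "backward", "connected")] else NULL,
    pore = res$pore,
    pmf_barriers = lapply(res$pmf, `[[`, "barrier")
  )
  path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  c(files, path)
}
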