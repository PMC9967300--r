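# End-to-end orchestration: simulate -> files -> analyze -> tables/figures.
# Analysis stages are pure functions of their input files; only the
# generator consumes a seed.

write_manifest <- function(out_dir, stage, config, inputs = character(),
                           stages = list(), warnings = character()) {
  manifest <- list(
    stage = stage,
    package_version = as.character(packageVersion("sqdimer")),
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
    config = config,
    input_checksums = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    stages = stages,
    warnings = as.list(warnings)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Generate a synthetic run and write it to disk
#'
#' Writes the trajectory (multi-model PDB), residue map, dye selections, dye
#' parameter table and per-frame ground truth (the latter for validation
#' only; the analysis stages never read it), plus a run manifest.
#'
#' @param cfg A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @param mock_hj Add the mock four-arm junction scaffold (default TRUE; the
#'   contact-map stage needs it).
#' @return Invisibly, the `dimer_simulation`.
#' @export
run_simulate <- function(cfg, out_dir, mock_hj = TRUE) {
  assert_that(inherits(cfg, "generator_config"), "cfg must be a generator_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_dimer_trajectory(cfg)
  if (mock_hj) sim <- generate_mock_hj(sim)
  paths <- file.path(out_dir, c("trajectory.pdb", "residue_map.csv",
                                "selections.yaml", "dye_parameters.csv",
                                "ground_truth.csv"))
  write_trajectory(sim$trajectory, paths[1], format = "pdb")
  write_residue_map(sim$residue_map, paths[2])
  write_selection_config(sim$selections, paths[3])
  write.csv(as.data.frame(dye_parameters()), paths[4], row.names = FALSE)
  write.csv(as.data.frame(sim$ground_truth), paths[5], row.names = FALSE)
  write_manifest(out_dir, "simulate", unclass(cfg)[
    !vapply(unclass(cfg), is.null, TRUE)], inputs = paths)
  invisible(sim)
}

read_run_inputs <- function(input_dir) {
  traj_path <- file.path(input_dir, "trajectory.pdb")
  assert_that(file.exists(traj_path), paste("no trajectory at", traj_path))
  list(
    trajectory = read_trajectory(traj_path, "pdb"),
    residue_map = read_residue_map(file.path(input_dir, "residue_map.csv")),
    selections = read_selection_config(file.path(input_dir, "selections.yaml")),
    params = {
      d <- read.csv(file.path(input_dir, "dye_parameters.csv"))
      tibble::as_tibble(d)
    },
    paths = file.path(input_dir, c("trajectory.pdb", "residue_map.csv",
                                   "selections.yaml", "dye_parameters.csv"))
  )
}

#' Run the full dimer analysis on a written run directory
#'
#' Reads the trajectory and configuration written by [run_simulate()] (or
#' assembled by hand in the same layout), slices off the equilibration
#' fraction and strides the frames, then computes: the per-frame geometry and
#' coupling tables, time-series and GROMOS-cluster ensemble summaries, the 2D
#' histograms of R vs kappa-squared and R vs J, and cluster assignments.
#' Every figure has a CSV twin; a manifest records configuration, input
#' checksums and collected warnings (e.g. kappa-prime sign flips
#' mid-trajectory).
#'
#' @param input_dir Directory holding `trajectory.pdb`, `residue_map.csv`,
#'   `selections.yaml`, `dye_parameters.csv`.
#' @param out_dir Output directory for tables and figures.
#' @param refractive_index,energy_unit Passed to [coupling_params()].
#' @param fold Angle folding convention.
#' @param skip_fraction,stride Passed to [slice_trajectory()]; the defaults
#'   (0.05, 50) mirror skipping 0.1 us of a 2 us run sampled every 50 steps.
#' @param rmsd_cutoff GROMOS neighbor cutoff in nm.
#' @param min_cluster_fraction Retention threshold for [filter_clusters()].
#' @param superpose Superpose frames before RMSD (fit group = the dye atoms).
#' @param bins Bins per axis for the 2D histograms.
#' @param save_figures Write PNG renderings next to the CSVs.
#' @return Invisibly, a list with `geometry`, `coupling`, `summary`,
#'   `clusters`, `gromos`, `histograms`.
#' @export
run_analyze <- function(input_dir, out_dir,
                        refractive_index = 1.33, energy_unit = "cm-1",
                        fold = "as_printed",
                        skip_fraction = 0.05, stride = 50L,
                        rmsd_cutoff = 0.05, min_cluster_fraction = 0.05,
                        superpose = TRUE, bins = 50, save_figures = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()
  stages <- list()
  tick <- function(name, expr) {
    t0 <- Sys.time()
    val <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    stages[[name]] <<- list(seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
    val
  }

  inp <- tick("load", read_run_inputs(input_dir))
  traj <- tick("slice", slice_trajectory(inp$trajectory, skip_fraction, stride))
  stages$slice$n_frames <- n_frames(traj)
  cpar <- coupling_params(refractive_index, energy_unit)

  geometry <- tick("geometry", dimer_geometry(traj, inp$selections,
                                              params = inp$params, fold = fold))
  coupling <- tick("coupling", coupling_series(traj, inp$selections,
                                               params = inp$params, p = cpar))
  if (length(unique(sign(geometry$kappa_prime[geometry$kappa_prime != 0]))) > 1)
    warnings_log <- c(warnings_log,
                      "kappa_prime changes sign mid-trajectory (packing flip)")

  ts_summary <- summarize_time_series(geometry, coupling)

  dye_res <- inp$residue_map$residue_id[inp$residue_map$label == "dye"]
  dye_atoms <- which(inp$trajectory$atoms$residue_id %in% dye_res)
  rmsd <- tick("rmsd", pairwise_rmsd(traj, dye_atoms, superpose = superpose))
  clusters <- tick("cluster", filter_clusters(gromos_cluster(rmsd, rmsd_cutoff),
                                              min_cluster_fraction))
  gromos <- tick("gromos_summary",
                 gromos_summary(clusters, traj, inp$selections,
                                params = inp$params, p = cpar, fold = fold))
  if (any(gromos$cluster_values$degenerate_mu))
    warnings_log <- c(warnings_log, "degenerate mean dipole direction in a cluster")

  h_rk <- histogram2d(geometry$R, geometry$kappa_sq, bins = bins,
                      xlab = "R (nm)", ylab = "kappa^2")
  h_rj <- histogram2d(geometry$R, coupling$J_mn, bins = bins,
                      xlab = "R (nm)",
                      ylab = sprintf("J_mn (%s)", cpar$energy_unit))

  write.csv(as.data.frame(geometry), file.path(out_dir, "metrics.csv"), row.names = FALSE)
  write.csv(as.data.frame(coupling), file.path(out_dir, "coupling.csv"), row.names = FALSE)
  write.csv(as.data.frame(dplyr::bind_rows(ts_summary, gromos$summary)),
            file.path(out_dir, "summary.csv"), row.names = FALSE)
  write.csv(data.frame(frame_index = geometry$frame_index,
                       cluster = clusters$assignment),
            file.path(out_dir, "cluster_assignments.csv"), row.names = FALSE)
  write.csv(as.data.frame(gromos$cluster_values),
            file.path(out_dir, "cluster_values.csv"), row.names = FALSE)
  write.csv(as.data.frame(tidy(h_rk)), file.path(out_dir, "hist_R_kappa_sq.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(tidy(h_rj)), file.path(out_dir, "hist_R_J.csv"),
            row.names = FALSE)
  if (save_figures) {
    ggplot2::ggsave(file.path(out_dir, "hist_R_kappa_sq.png"), autoplot(h_rk),
                    width = 5, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "hist_R_J.png"), autoplot(h_rj),
                    width = 5, height = 4, dpi = 150)
  }
  cfg_echo <- list(refractive_index = refractive_index, energy_unit = energy_unit,
                   fold = fold, skip_fraction = skip_fraction, stride = stride,
                   rmsd_cutoff = rmsd_cutoff,
                   min_cluster_fraction = min_cluster_fraction,
                   superpose = superpose, bins = bins)
  write_manifest(out_dir, "analyze", cfg_echo, inputs = inp$paths,
                 stages = stages, warnings = warnings_log)
  invisible(list(geometry = geometry, coupling = coupling,
                 summary = dplyr::bind_rows(ts_summary, gromos$summary),
                 clusters = clusters, gromos = gromos,
                 histograms = list(R_kappa_sq = h_rk, R_J = h_rj)))
}

#' Contact-map stage on a written run directory
#'
#' @inheritParams run_analyze
#' @param cutoff Contact cutoff in nm.
#' @param threshold Probability threshold for the per-dye contact summary.
#' @return Invisibly, a list with the `contact_map` and the dye summary.
#' @export
run_contact_map <- function(input_dir, out_dir, cutoff = 1.2, threshold = 0.5,
                            skip_fraction = 0.05, stride = 50L,
                            save_figures = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- read_run_inputs(input_dir)
  assert_that(any(inp$residue_map$label == "dye"),
              "residue map contains no dye residues")
  traj <- slice_trajectory(inp$trajectory, skip_fraction, stride)
  cm <- contact_probability(traj, inp$residue_map, cutoff = cutoff)
  dcs <- dye_contact_summary(cm, threshold = threshold)
  write.csv(as.data.frame(cm$P), file.path(out_dir, "contact_matrix.csv"))
  write.csv(as.data.frame(cm$residues), file.path(out_dir, "residue_labels.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(dcs[, c("dye_residue", "n_contacts")]),
            file.path(out_dir, "dye_contact_summary.csv"), row.names = FALSE)
  if (save_figures)
    ggplot2::ggsave(file.path(out_dir, "contact_map.png"), autoplot(cm),
                    width = 5, height = 4, dpi = 150)
  write_manifest(out_dir, "contact_map",
                 list(cutoff = cutoff, threshold = threshold,
                      skip_fraction = skip_fraction, stride = stride),
                 inputs = inp$paths)
  invisible(list(contact_map = cm, dye_summary = dcs))
}
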