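# End-to-end pipeline: wire descriptors, interactions, energetics and the
# rubric together from a run configuration, writing per-stage tables, the
# triage report and a reproducibility manifest.

#' Run the triage pipeline
#'
#' Two modes:
#' \describe{
#'   \item{panels-only}{`config$panels` names a delimited panel table (one
#'     row per system); the rubric runs directly on it.  This is how
#'     published panel values can be re-scored without trajectories.}
#'   \item{full}{`config` names a topology PDB, a trajectory, a site
#'     config, a ligand residue name and energy tables; descriptors,
#'     interactions and energetics are computed and assembled into a panel
#'     for the single system, then scored.}
#' }
#'
#' @param config a named list or the path to a YAML file.  Recognised
#'   fields: `panels`, `thresholds` (YAML of [triage_thresholds()]
#'   overrides), `output_dir` (required), `seed`, and for full mode
#'   `topology`, `trajectory`, `site`, `ligand_resname`, `system`,
#'   `per_residue_energies`, `mmgbsa`, `docking_score`,
#'   `docking_contacts`, `cluster_k` (default 10), `temperature`.
#' @return Named list of `triage_result` objects, invisibly; report files
#'   (`report.csv`, `report.json`, `report.md`, `manifest.json` and in
#'   full mode per-stage tables) are written to `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir)) stop("config must name an output_dir")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  th <- if (!is.null(config$thresholds)) {
    do.call(triage_thresholds, yaml::read_yaml(config$thresholds))
  } else {
    triage_thresholds()
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (!is.null(config$panels)) {
    panels <- stage("panels", read_panel_table(config$panels))
  } else {
    for (f in c("topology", "trajectory", "site", "ligand_resname",
                "per_residue_energies", "mmgbsa", "system")) {
      if (is.null(config[[f]])) {
        stop("full-mode config is missing '", f, "'")
      }
    }
    site <- stage("site", if (inherits(config$site, "site_config"))
      config$site else read_site_config(config$site))
    topo <- stage("structures", read_structure(config$topology))
    traj <- stage("structures", read_trajectory(topo, config$trajectory))
    lig <- select_atoms(topo, "ligand", resname = config$ligand_resname)
    prot_bb <- select_atoms(topo, "backbone")
    site_res <- site$pocket_residues$resno
    site_res <- site_res[site_res %in% topo$atoms$resno]

    rmsd <- stage("descriptors", rmsd_series(traj, prot_bb))
    rmsf <- stage("descriptors", rmsf_per_residue(traj, prot_bb))
    rg <- stage("descriptors", radius_of_gyration(traj))
    k <- if (is.null(config$cluster_k)) 10L else as.integer(config$cluster_k)
    clust <- stage("descriptors",
                   cluster_frames(rmsd, min(k, n_frames(traj)), seed))
    fr <- stage("interactions", interaction_fractions(traj, lig))
    mdc <- count_site_interactions(fr, site)
    per_res <- stage("energetics",
                     read_energy_table(config$per_residue_energies,
                                       "per_residue"))
    mm <- stage("energetics", read_energy_table(config$mmgbsa, "mmgbsa"))
    means <- per_residue_aggregate(per_res, config$system)
    mm_sum <- mmgbsa_summary(mm, config$system)
    viol <- sum(rmsf$resno %in% site_res &
                  rmsf$mean_rmsf > th$rmsf_cut)
    panel <- stage("rubric", build_panel(
      config$system, mmgbsa = mm_sum$overall,
      site_energy = thresholded_energy_sum(means, subset = site_res),
      total_energy = thresholded_energy_sum(means),
      md_contacts = mdc, rmsd_mean = rmsd$mean, rmsf_violations = viol,
      rg_width = rg$width,
      docking_score = if (is.null(config$docking_score)) NA_real_
      else config$docking_score,
      docking_contacts = if (is.null(config$docking_contacts)) NA_integer_
      else config$docking_contacts))
    panels <- stats::setNames(list(panel), config$system)

    utils::write.csv(
      data.frame(frame = seq_along(rmsd$values), rmsd_angstrom = rmsd$values,
                 rg_angstrom = rg$series, cluster = clust$labels),
      file.path(config$output_dir, "descriptors_per_frame.csv"),
      row.names = FALSE)
    utils::write.csv(as.data.frame(rmsf),
                     file.path(config$output_dir, "rmsf_per_residue.csv"),
                     row.names = FALSE)
    utils::write.csv(fr$table,
                     file.path(config$output_dir,
                               "interaction_fractions.csv"),
                     row.names = FALSE)
  }

  results <- stage("rubric", lapply(panels, predict_triage, thresholds = th,
                                    panel_set = panels))
  render_report(results, "delimited",
                file.path(config$output_dir, "report.csv"))
  render_report(results, "json", file.path(config$output_dir, "report.json"))
  render_report(results, "markdown",
                file.path(config$output_dir, "report.md"))
  manifest <- list(
    package = "mdtriage",
    package_version = as.character(utils::packageVersion("mdtriage")),
    seed = seed, thresholds = unclass(th),
    energy_rule = "magnitude: |E| >= 5 kcal/mol",
    config = config[setdiff(names(config), "output_dir")])
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
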