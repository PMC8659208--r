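# The seven-parameter triage rubric: assemble a parameter panel per
# system, assign traffic lights, derive the Excellent/Good/Intermediate/
# Bad label from an explicit decision tree, and rank/report compounds.

.TIERS <- c("Excellent", "Good", "Intermediate", "Bad")

#' Rubric thresholds
#'
#' Structural cuts follow the published classification rules (RMSD good
#' below 2.6 A, intermediate up to 3.0 A against an apo mean of 2.79 A; at
#' most 2 binding-site residues fluctuating above 4 A; Rg width below the
#' apo width of 0.72 A; at least 3 persistent key-residue interactions).
#' The four energy thresholds encode the qualitative ranking bullets as
#' explicit numbers, fitted once so the decision tree reproduces every
#' published label; they are parameters, not constants, and every report
#' records the set in force.
#'
#' @param apo_rmsd_mean apo-form mean backbone RMSD, A.
#' @param rmsd_good,rmsd_bad RMSD band edges, A.
#' @param rmsf_cut per-residue fluctuation threshold, A.
#' @param rmsf_max_violations maximum tolerated site residues above
#'   `rmsf_cut`.
#' @param rg_apo_width apo Rg distribution width, A.
#' @param contacts_good,contacts_strong persistent-interaction counts for a
#'   favourable / strong fingerprint.
#' @param mmgbsa_good,mmgbsa_ok MM-GBSA tier cuts, kcal/mol.
#' @param site_good binding-site energy-sum cut, kcal/mol.
#' @param total_strong,total_ok total energy-sum cuts, kcal/mol.
#' @param site_total_equality_tol tolerance for "coincident" site and total
#'   sums, kcal/mol.
#' @return Object of class `triage_thresholds`.
#' @export
triage_thresholds <- function(apo_rmsd_mean = 2.79, rmsd_good = 2.6,
                              rmsd_bad = 3.0, rmsf_cut = 4.0,
                              rmsf_max_violations = 2, rg_apo_width = 0.72,
                              contacts_good = 3, contacts_strong = 4,
                              mmgbsa_good = -70, mmgbsa_ok = -65,
                              site_good = -15, total_strong = -50,
                              total_ok = -30,
                              site_total_equality_tol = 0.01) {
  if (!(rmsd_good < rmsd_bad)) stop("rmsd_good must be < rmsd_bad")
  if (!(mmgbsa_good <= mmgbsa_ok)) stop("mmgbsa_good must be <= mmgbsa_ok")
  if (!(total_strong <= total_ok)) stop("total_strong must be <= total_ok")
  structure(list(apo_rmsd_mean = apo_rmsd_mean, rmsd_good = rmsd_good,
                 rmsd_bad = rmsd_bad, rmsf_cut = rmsf_cut,
                 rmsf_max_violations = rmsf_max_violations,
                 rg_apo_width = rg_apo_width, contacts_good = contacts_good,
                 contacts_strong = contacts_strong,
                 mmgbsa_good = mmgbsa_good, mmgbsa_ok = mmgbsa_ok,
                 site_good = site_good, total_strong = total_strong,
                 total_ok = total_ok,
                 site_total_equality_tol = site_total_equality_tol),
            class = "triage_thresholds")
}

#' Assemble a parameter panel
#'
#' Collects the seven rubric inputs (plus the two docking columns, which
#' are carried for display but never enter the decision tree) for one
#' system.  RMSF violations must already be counted over binding-site
#' residues only.
#'
#' @param system system identifier.
#' @param mmgbsa overall MM-GBSA binding free energy, kcal/mol.
#' @param site_energy thresholded per-residue energy sum over the binding
#'   site, kcal/mol.
#' @param total_energy thresholded per-residue energy sum over all
#'   residues, kcal/mol.
#' @param md_contacts number of key residues with interaction fraction
#'   above 0.5.
#' @param rmsd_mean mean backbone RMSD over the simulation, A.
#' @param rmsf_violations number of binding-site residues with mean RMSF
#'   above the fluctuation cut.
#' @param rg_width width (range) of the Rg distribution, A.
#' @param docking_score optional docking score, kcal/mol.
#' @param docking_contacts optional number of site residues contacted in
#'   the docked pose.
#' @return Object of class `parameter_panel`.
#' @export
build_panel <- function(system, mmgbsa, site_energy, total_energy,
                        md_contacts, rmsd_mean, rmsf_violations, rg_width,
                        docking_score = NA_real_,
                        docking_contacts = NA_integer_) {
  mandatory <- list(mmgbsa = mmgbsa, site_energy = site_energy,
                    total_energy = total_energy, md_contacts = md_contacts,
                    rmsd_mean = rmsd_mean,
                    rmsf_violations = rmsf_violations, rg_width = rg_width)
  for (nm in names(mandatory)) {
    v <- mandatory[[nm]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      stop("panel for '", system, "' is missing mandatory field: ", nm)
    }
  }
  if (md_contacts < 0 || rmsf_violations < 0 ||
      (!is.na(docking_contacts) && docking_contacts < 0)) {
    stop("contact and violation counts must be non-negative")
  }
  structure(list(system = as.character(system),
                 docking_score = as.numeric(docking_score),
                 docking_contacts = as.integer(docking_contacts),
                 mmgbsa = as.numeric(mmgbsa),
                 site_energy = as.numeric(site_energy),
                 total_energy = as.numeric(total_energy),
                 md_contacts = as.integer(md_contacts),
                 rmsd_mean = as.numeric(rmsd_mean),
                 rmsf_violations = as.integer(rmsf_violations),
                 rg_width = as.numeric(rg_width)),
            class = "parameter_panel")
}

#' Read parameter panels from a delimited table
#'
#' One row per system; columns as in [build_panel()] (extra columns are
#' ignored).
#'
#' @param path delimited text file (comma or tab).
#' @return Named list of [build_panel()] objects.
#' @export
read_panel_table <- function(path) {
  df <- .read_delim_auto(path)
  .require_columns(df, c("system", "mmgbsa", "site_energy", "total_energy",
                         "md_contacts", "rmsd_mean", "rmsf_violations",
                         "rg_width"), path)
  panels <- lapply(seq_len(nrow(df)), function(i) {
    build_panel(df$system[i], mmgbsa = df$mmgbsa[i],
                site_energy = df$site_energy[i],
                total_energy = df$total_energy[i],
                md_contacts = df$md_contacts[i],
                rmsd_mean = df$rmsd_mean[i],
                rmsf_violations = df$rmsf_violations[i],
                rg_width = df$rg_width[i],
                docking_score = if ("docking_score" %in% names(df))
                  df$docking_score[i] else NA_real_,
                docking_contacts = if ("docking_contacts" %in% names(df))
                  df$docking_contacts[i] else NA_integer_)
  })
  names(panels) <- as.character(df$system)
  panels
}

#' Assign traffic lights to a panel
#'
#' RMSD is good/intermediate/bad by the band edges; RMSF is good when the
#' violation count stays within the tolerance; Rg is good when the width
#' is below the apo width; the MD interaction count is good at or above
#' the favourable cut.  The four energy columns receive a 0--1 score by
#' min-max normalisation across the compared panel set (display gradient
#' only; the decision tree works on the raw values).
#'
#' @param panel a [build_panel()] object.
#' @param thresholds a [triage_thresholds()].
#' @param panel_set optional list of panels defining the normalisation
#'   range of the energy gradient.
#' @return Named list of lights; categorical entries are `"good"`,
#'   `"intermediate"` or `"bad"`, energy entries are scores in [0, 1]
#'   (1 = best, i.e. most negative in the compared set).
#' @export
assign_lights <- function(panel, thresholds = triage_thresholds(),
                          panel_set = NULL) {
  th <- thresholds
  rmsd <- if (panel$rmsd_mean < th$rmsd_good) "good"
  else if (panel$rmsd_mean <= th$rmsd_bad) "intermediate" else "bad"
  rmsf <- if (panel$rmsf_violations <= th$rmsf_max_violations) "good" else "bad"
  rg <- if (panel$rg_width < th$rg_apo_width) "good" else "bad"
  contacts <- if (panel$md_contacts >= th$contacts_good) "good" else "bad"
  grad <- function(field) {
    v <- panel[[field]]
    if (is.null(panel_set)) return(NA_real_)
    vals <- vapply(panel_set, function(p) p[[field]], numeric(1))
    vals <- vals[is.finite(vals)]
    if (length(vals) < 2L || diff(range(vals)) == 0) return(NA_real_)
    (max(vals) - v) / diff(range(vals))
  }
  list(docking_score = grad("docking_score"), mmgbsa = grad("mmgbsa"),
       site_energy = grad("site_energy"), total_energy = grad("total_energy"),
       md_contacts = contacts, rmsd = rmsd, rmsf = rmsf, rg = rg)
}

#' Predict the triage label for a panel
#'
#' Explicit decision tree over the energetic parameters and the persistent
#' interaction count (the structural lights are reported but not
#' decisive):
#' \enumerate{
#'   \item Top tier when the MM-GBSA, the binding-site energy sum and the
#'     interaction count are all favourable; within it, \emph{Excellent}
#'     when the total energy sum is strong and the interaction fingerprint
#'     dense, otherwise \emph{Good}.
#'   \item Otherwise \emph{Intermediate} when the total energy sum is
#'     acceptable, or when a favourable site sum (or site and total sums
#'     that coincide, i.e. a binding entirely carried by the pocket
#'     residues) is backed by an acceptable MM-GBSA.
#'   \item Otherwise \emph{Bad}.
#' }
#'
#' @param panel a [build_panel()] object.
#' @param thresholds a [triage_thresholds()].
#' @param panel_set optional panel list for the display gradient in the
#'   attached lights.
#' @return Object of class `triage_result`: list with `system`, `panel`,
#'   `lights`, `label`, `rationale` (ordered rule trace).
#' @export
predict_triage <- function(panel, thresholds = triage_thresholds(),
                           panel_set = NULL) {
  th <- thresholds
  trace <- character(0)
  note <- function(x) trace <<- c(trace, x)

  mm_good <- panel$mmgbsa <= th$mmgbsa_good
  site_ok <- panel$site_energy <= th$site_good
  cont_ok <- panel$md_contacts >= th$contacts_good
  note(sprintf("tier-1: mmgbsa %.2f <= %.1f is %s; site %.2f <= %.1f is %s; contacts %d >= %d is %s",
               panel$mmgbsa, th$mmgbsa_good, mm_good,
               panel$site_energy, th$site_good, site_ok,
               panel$md_contacts, th$contacts_good, cont_ok))
  if (mm_good && site_ok && cont_ok) {
    strong <- panel$total_energy <= th$total_strong &&
      panel$md_contacts >= th$contacts_strong
    note(sprintf("tier-1 met; excellent test (total %.2f <= %.1f and contacts %d >= %d) is %s",
                 panel$total_energy, th$total_strong, panel$md_contacts,
                 th$contacts_strong, strong))
    label <- if (strong) "Excellent" else "Good"
  } else {
    total_ok_ <- panel$total_energy <= th$total_ok
    mm_ok <- panel$mmgbsa <= th$mmgbsa_ok
    coincident <- abs(panel$total_energy - panel$site_energy) <=
      th$site_total_equality_tol
    inter <- total_ok_ || (site_ok && mm_ok) || (coincident && mm_ok)
    note(sprintf("tier-2: total %.2f <= %.1f is %s; (site favourable and mmgbsa <= %.1f) is %s; (coincident sums and mmgbsa <= %.1f) is %s",
                 panel$total_energy, th$total_ok, total_ok_,
                 th$mmgbsa_ok, site_ok && mm_ok,
                 th$mmgbsa_ok, coincident && mm_ok))
    label <- if (inter) "Intermediate" else "Bad"
  }
  note(paste("label:", label))
  structure(list(system = panel$system, panel = panel,
                 lights = assign_lights(panel, th, panel_set),
                 label = label, rationale = trace,
                 thresholds = th),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("%s: %s (mmgbsa %.2f, site %.2f, total %.2f, contacts %d)\n",
              x$system, x$label, x$panel$mmgbsa, x$panel$site_energy,
              x$panel$total_energy, x$panel$md_contacts))
  invisible(x)
}

#' Rank triage results
#'
#' Orders by label tier (Excellent > Good > Intermediate > Bad), ties
#' broken by ascending MM-GBSA (more negative first).
#'
#' @param results list of [predict_triage()] results.
#' @return data.frame with one row per system in ranked order: `rank`,
#'   `system`, `label` and the panel columns.
#' @export
rank_triage <- function(results) {
  if (length(results) < 1L) stop("no results to rank")
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(system = r$system, label = r$label,
               docking_score = r$panel$docking_score,
               docking_contacts = r$panel$docking_contacts,
               mmgbsa = r$panel$mmgbsa, site_energy = r$panel$site_energy,
               total_energy = r$panel$total_energy,
               md_contacts = r$panel$md_contacts,
               rmsd_mean = r$panel$rmsd_mean,
               rmsf_violations = r$panel$rmsf_violations,
               rg_width = r$panel$rg_width, stringsAsFactors = FALSE)
  }))
  tier <- match(df$label, .TIERS)
  ord <- order(tier, df$mmgbsa, df$system)
  df <- df[ord, , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' Render a triage report
#'
#' @param results list of [predict_triage()] results.
#' @param format `"delimited"`, `"json"` or `"markdown"`.
#' @param path optional output file; when `NULL` the rendered report is
#'   returned (data.frame, list, or character vector).
#' @return The rendered report (invisibly when written to `path`).
#' @export
render_report <- function(results, format = c("delimited", "json",
                                              "markdown"), path = NULL) {
  format <- match.arg(format)
  if (length(results) == 0L) stop("no results to report")
  ranked <- rank_triage(results)
  th <- results[[1L]]$thresholds
  meta <- list(thresholds = unclass(th),
               energy_rule = "magnitude: |E| >= 5 kcal/mol enters the sums",
               contact_counting = "cumulative per-residue fraction > 0.5")
  if (format == "delimited") {
    if (!is.null(path)) {
      utils::write.csv(ranked, path, row.names = FALSE)
      return(invisible(ranked))
    }
    return(ranked)
  }
  if (format == "json") {
    obj <- list(metadata = meta, ranking = ranked,
                results = lapply(results, function(r)
                  list(system = r$system, label = r$label,
                       panel = unclass(r$panel), lights = r$lights,
                       rationale = r$rationale)))
    if (!is.null(path)) {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
      return(invisible(obj))
    }
    return(obj)
  }
  ## markdown
  hdr <- c("| Rank | System | Label | MM-GBSA | Site | Total | Contacts | RMSD | RMSF | Rg width |",
           "|---|---|---|---|---|---|---|---|---|---|")
  rows <- sprintf("| %d | %s | %s | %.2f | %.2f | %.2f | %d | %.2f | %d | %.2f |",
                  ranked$rank, ranked$system, ranked$label, ranked$mmgbsa,
                  ranked$site_energy, ranked$total_energy,
                  ranked$md_contacts, ranked$rmsd_mean,
                  ranked$rmsf_violations, ranked$rg_width)
  txt <- c("# Binder triage report", "",
           sprintf("Energy rule: %s. Contact counting: %s.",
                   meta$energy_rule, meta$contact_counting),
           sprintf("Thresholds: %s.",
                   paste(names(meta$thresholds), unlist(meta$thresholds),
                         sep = "=", collapse = ", ")),
           "", hdr, rows)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Rebuild triage results from a JSON report
#'
#' Inverse of `render_report(format = "json")` for the panel, label and
#' rationale content.
#'
#' @param path JSON report file.
#' @return Named list of `triage_result` objects.
#' @export
read_report_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  th <- do.call(triage_thresholds, obj$metadata$thresholds)
  out <- lapply(obj$results, function(r) {
    p <- r$panel
    panel <- build_panel(p$system, mmgbsa = p$mmgbsa,
                         site_energy = p$site_energy,
                         total_energy = p$total_energy,
                         md_contacts = p$md_contacts,
                         rmsd_mean = p$rmsd_mean,
                         rmsf_violations = p$rmsf_violations,
                         rg_width = p$rg_width,
                         docking_score = if (is.null(p$docking_score))
                           NA_real_ else p$docking_score,
                         docking_contacts = if (is.null(p$docking_contacts))
                           NA_integer_ else p$docking_contacts)
    res <- predict_triage(panel, th)
    res
  })
  names(out) <- vapply(out, `[[`, "", "system")
  out
}
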