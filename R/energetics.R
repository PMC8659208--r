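# Ingestion and aggregation of externally computed energies: MM-GBSA
# ensemble averages, per-residue interaction-energy means, thresholded
# energy sums, Kd-to-free-energy conversion, and the experimental vs
# calculated affinity regression.

#' Gas constant in cal K^-1 mol^-1
#' @export
R_GAS_CAL <- 1.987

#' Convert a dissociation constant to a binding free energy
#'
#' \deqn{\Delta G_{exp} = R \, T \, \ln(K_D) / 1000}
#' with \eqn{K_D} in molar, \eqn{R = 1.987} cal K^-1 mol^-1 and the result
#' in kcal/mol.  Negative for sub-molar \eqn{K_D}; strictly increasing in
#' \eqn{K_D} and linear in temperature.
#'
#' @param kd_micromolar dissociation constant(s) in micromolar.
#' @param temperature temperature in Kelvin (default 298.15).
#' @return Binding free energy in kcal/mol (vectorised).
#' @export
kd_to_dg <- function(kd_micromolar, temperature = 298.15) {
  if (any(!is.finite(kd_micromolar)) || any(kd_micromolar <= 0)) {
    stop("kd must be positive and finite")
  }
  if (temperature <= 0) stop("temperature must be positive")
  R_GAS_CAL * temperature * log(kd_micromolar * 1e-6) / 1000
}

#' Read a delimited energy, affinity or panel table
#'
#' Comma or tab delimiters are autodetected.  Energy tables must carry a
#' `unit` column reading `kcal/mol`; duplicate keys and non-numeric values
#' are rejected with the offending key or row.
#'
#' @param path delimited text file with a header.
#' @param kind one of `"per_residue"` (columns `system`, `replica`,
#'   `residue`, `energy`, `unit`), `"mmgbsa"` (`system`, `replica`,
#'   `value`, `unit`; optional `cluster`), `"affinity"` (`system`,
#'   `kd_micromolar`, optionally `docking_score`).
#' @return data.frame of class `per_residue_energy`, `mmgbsa_ensemble` or
#'   `affinity_table`.
#' @export
read_energy_table <- function(path,
                              kind = c("per_residue", "mmgbsa", "affinity")) {
  kind <- match.arg(kind)
  df <- .read_delim_auto(path)
  check_numeric <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) &
                   !(trimws(df[[col]]) %in% c("", "NA", "/")))
    if (length(bad) > 0L) {
      stop("non-numeric value in column '", col, "' at data row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), " of ", path)
    }
    v
  }
  check_unit <- function() {
    .require_columns(df, "unit", path)
    bad <- unique(df$unit[tolower(df$unit) != "kcal/mol"])
    if (length(bad) > 0L) {
      stop("unexpected unit '", bad[1], "' in ", path,
           " (energies must be kcal/mol)")
    }
  }
  if (kind == "per_residue") {
    .require_columns(df, c("system", "replica", "residue", "energy"), path)
    check_unit()
    df$energy <- check_numeric("energy")
    key <- paste(df$system, df$replica, df$residue, sep = "|")
    if (anyDuplicated(key)) {
      stop("duplicate (system, replica, residue) key: ",
           key[duplicated(key)][1])
    }
    class(df) <- c("per_residue_energy", "data.frame")
  } else if (kind == "mmgbsa") {
    .require_columns(df, c("system", "replica", "value"), path)
    check_unit()
    df$value <- check_numeric("value")
    if ("cluster" %in% names(df)) {
      key <- paste(df$system, df$replica, df$cluster, sep = "|")
      if (anyDuplicated(key)) {
        stop("duplicate (system, replica, cluster) key: ",
             key[duplicated(key)][1])
      }
    }
    class(df) <- c("mmgbsa_ensemble", "data.frame")
  } else {
    .require_columns(df, c("system", "kd_micromolar"), path)
    df$kd_micromolar <- check_numeric("kd_micromolar")
    if (anyDuplicated(df$system)) {
      stop("duplicate system: ", df$system[duplicated(df$system)][1])
    }
    df$experimental_dg <- NA_real_
    ok <- !is.na(df$kd_micromolar)
    df$experimental_dg[ok] <- kd_to_dg(df$kd_micromolar[ok])
    class(df) <- c("affinity_table", "data.frame")
  }
  df
}

#' MM-GBSA replicate/cluster averaging
#'
#' Per replica, the mean over the cluster-representative values; overall,
#' the mean of the per-replica means (how published per-system averages
#' over three independent simulations are formed).
#'
#' @param ens data.frame with columns `system`, `replica`, `value`
#'   (optionally one row per cluster representative).
#' @param system system identifier to summarise.
#' @return List with `system`, `replica_means` (named by replica) and
#'   `overall` (kcal/mol).
#' @export
mmgbsa_summary <- function(ens, system) {
  rows <- ens[ens$system == system, , drop = FALSE]
  if (nrow(rows) == 0L) stop("unknown system: ", system)
  rm_ <- tapply(rows$value, rows$replica, mean)
  list(system = system, replica_means = rm_,
       overall = mean(as.numeric(rm_)))
}

#' Average a per-replica quantity for every system
#'
#' Generic replicate averaging for tables with one value per (system,
#' replica) -- e.g. per-simulation mean RMSDs or MM-GBSA replica means.
#'
#' @param df data.frame with columns `system`, `value` (and anything else).
#' @return data.frame with `system` and `average` (mean over that system's
#'   rows), in first-appearance order.
#' @export
average_replicas <- function(df) {
  .require_columns(df, c("system", "value"), "average_replicas")
  systems <- unique(df$system)
  avg <- vapply(systems, function(s) mean(df$value[df$system == s]),
                numeric(1))
  data.frame(system = systems, average = as.numeric(avg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-residue energy means over replicas
#'
#' Arithmetic mean of each residue's interaction energy across replicas.
#' Residues present in only a subset of replicas are averaged over the
#' available values and flagged.
#'
#' @param table data.frame with `system`, `replica`, `residue`, `energy`.
#' @param system system to aggregate.
#' @return data.frame with `residue`, `energy` (mean, kcal/mol),
#'   `n_replicas`, `complete`.
#' @export
per_residue_aggregate <- function(table, system) {
  rows <- table[table$system == system, , drop = FALSE]
  if (nrow(rows) == 0L) {
    return(data.frame(residue = character(0), energy = numeric(0),
                      n_replicas = integer(0), complete = logical(0)))
  }
  n_rep <- length(unique(rows$replica))
  res <- unique(rows$residue)
  out <- data.frame(
    residue = res,
    energy = vapply(res, function(r) mean(rows$energy[rows$residue == r]),
                    numeric(1)),
    n_replicas = vapply(res, function(r)
      length(unique(rows$replica[rows$residue == r])), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out$complete <- out$n_replicas == n_rep
  if (any(!out$complete)) {
    warning("residue(s) missing from some replicas: ",
            paste(out$residue[!out$complete], collapse = ", "))
  }
  out
}

#' Thresholded per-residue energy sum
#'
#' Sums the per-residue mean energies whose magnitude reaches the cutoff,
#' optionally restricted to a residue subset (e.g. the binding pocket).
#' The magnitude rule (`|E| >= cutoff`, the default) admits destabilising
#' positive contributions as well -- a pocket dominated by a repulsive
#' residue then yields a positive site sum.  A one-sided rule
#' (`E <= -cutoff`) is available via `rule = "negative"`.
#'
#' @param means data.frame from [per_residue_aggregate()] (columns
#'   `residue`, `energy`) or a named numeric vector.
#' @param subset optional residue identifiers restricting the sum; `NULL`
#'   sums over all residues.
#' @param magnitude_cutoff kcal/mol cutoff (default 5).
#' @param rule `"magnitude"` or `"negative"`.
#' @return Sum in kcal/mol (0 when no residue passes the cutoff).
#' @export
thresholded_energy_sum <- function(means, subset = NULL,
                                   magnitude_cutoff = 5,
                                   rule = c("magnitude", "negative")) {
  rule <- match.arg(rule)
  if (is.data.frame(means)) {
    e <- means$energy
    names(e) <- as.character(means$residue)
  } else {
    e <- means
  }
  if (!is.null(subset)) {
    if (inherits(subset, "site_config")) subset <- subset$pocket_residues
    res <- .parse_residues(subset)
    keys <- .parse_residues(names(e))$resno
    e <- e[keys %in% res$resno]
  }
  pass <- if (rule == "magnitude") abs(e) >= magnitude_cutoff else
    e <= -magnitude_cutoff
  if (!any(pass)) return(0)
  sum(e[pass])
}

#' Regression of calculated on experimental binding affinity
#'
#' Ordinary least squares of the calculated affinity on the experimental
#' one; the reported R-squared equals the squared Pearson correlation, so
#' the axis choice is immaterial.
#'
#' @param experimental experimental binding free energies, kcal/mol.
#' @param calculated calculated (docking) binding affinities, kcal/mol.
#' @return Object of class `affinity_regression`: list with `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @export
affinity_regression <- function(experimental, calculated) {
  ok <- is.finite(experimental) & is.finite(calculated)
  x <- experimental[ok]; y <- calculated[ok]
  if (length(x) < 2L) stop("need at least 2 complete pairs")
  if (stats::sd(x) == 0) stop("zero variance in experimental affinities")
  fit <- stats::lm(y ~ x)
  # R^2 of simple OLS equals the squared Pearson correlation; computing it
  # directly avoids summary.lm()'s perfect-fit warning on collinear input
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = stats::cor(x, y)^2, n = length(x)),
            class = "affinity_regression")
}

#' @export
print.affinity_regression <- function(x, ...) {
  cat(sprintf(
    "affinity_regression: n = %d, R^2 = %.3f (slope %.3f, intercept %.3f)\n",
    x$n, x$r_squared, x$slope, x$intercept))
  invisible(x)
}
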