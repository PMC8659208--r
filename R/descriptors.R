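# Geometric trajectory descriptors: optimal superposition, RMSD series,
# per-residue RMSF, radius of gyration, 1-D frame clustering, binding-site
# RMSD between structures, and the apo-resemblance filter.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the (weighted) RMSD
#' between two paired coordinate sets.  The returned transform maps the
#' mobile set onto the reference: `mobile %*% rotation + translation`.
#'
#' @param mobile n x 3 coordinate matrix to move.
#' @param reference n x 3 coordinate matrix to match.
#' @param weights optional non-negative per-atom weights.
#' @return List with `rotation` (3 x 3, determinant +1), `translation`
#'   (length 3) and `rmsd` (the minimised value, Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("point counts differ")
  if (n < 3L) stop("superposition needs at least 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0) {
    stop("invalid weights")
  }
  w <- weights / sum(weights)
  mc <- colSums(mobile * w)
  rc <- colSums(reference * w)
  P <- sweep(mobile, 2, mc)
  Q <- sweep(reference, 2, rc)
  # degenerate (collinear) reference cannot fix the rotation
  sv_chk <- svd(Q * sqrt(w))$d
  if (sv_chk[2] < 1e-8 * max(sv_chk[1], 1e-12)) {
    stop("degenerate (collinear) coordinates: rotation is undetermined")
  }
  C <- crossprod(P, Q * w)
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  trans <- as.numeric(rc - mc %*% R)
  resid <- P %*% R - Q
  rmsd <- sqrt(sum(w * rowSums(resid^2)))
  list(rotation = R, translation = trans, rmsd = rmsd)
}

# Apply a superposition transform to a coordinate matrix.
.apply_transform <- function(xyz, fit) {
  sweep(xyz %*% fit$rotation, 2, fit$translation, "+")
}

.rmsd_between <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Per-frame RMSD of a trajectory against a reference frame
#'
#' Each frame is superposed onto the reference frame on the `fit` atoms
#' (Kabsch), and the RMSD is then computed over the `calc` atoms.  The value
#' at the reference frame is zero by construction.
#'
#' @param traj an [md_trajectory()].
#' @param fit atom indices used for superposition (e.g. backbone).
#' @param calc atom indices the RMSD is computed over; defaults to `fit`.
#' @param reference_frame 1-based frame index of the reference (default 1,
#'   i.e. the first frame).
#' @return Object of class `rmsd_series`: list with `values` (Angstrom per
#'   frame), `mean`, `reference_frame`, `fit_label`, `calc_label`.
#' @export
rmsd_series <- function(traj, fit, calc = fit, reference_frame = 1L) {
  if (length(fit) == 0L || length(calc) == 0L) stop("empty atom selection")
  nf <- n_frames(traj)
  if (reference_frame < 1L || reference_frame > nf) {
    stop("reference_frame out of range")
  }
  ref <- traj$frames[[reference_frame]]
  vals <- vapply(seq_len(nf), function(i) {
    f <- traj$frames[[i]]
    tr <- kabsch_superpose(f[fit, , drop = FALSE], ref[fit, , drop = FALSE])
    moved <- .apply_transform(f[calc, , drop = FALSE], tr)
    .rmsd_between(moved, ref[calc, , drop = FALSE])
  }, numeric(1))
  structure(list(values = vals, mean = mean(vals),
                 reference_frame = reference_frame,
                 fit_label = attr(fit, "label"),
                 calc_label = attr(calc, "label")),
            class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("rmsd_series: %d frames, mean %.2f A (reference frame %d)\n",
              length(x$values), x$mean, x$reference_frame))
  invisible(x)
}

#' Per-residue RMSF profile
#'
#' Fluctuations about the time-average structure, using a two-pass
#' alignment: frames are first superposed onto the reference frame on the
#' `fit` atoms, the mean structure is computed, and frames are re-aligned to
#' that mean before measuring displacements.  Each atom's RMSF is the root
#' mean square displacement from its time-average position; residue values
#' average the backbone atoms (N, CA, C, O) and the heavy side-chain atoms
#' separately, and `mean_rmsf` is the mean of the two (or the defined one
#' when a residue lacks side-chain heavy atoms, e.g. glycine).
#'
#' @param traj an [md_trajectory()] with at least 2 frames.
#' @param fit atom indices used for alignment (default: protein backbone).
#' @return Object of class `rmsf_profile`: a data.frame with columns
#'   `chain`, `resno`, `resname`, `backbone_rmsf`, `side_chain_rmsf`,
#'   `mean_rmsf` (Angstrom), plus an `atom_rmsf` attribute.
#' @export
rmsf_per_residue <- function(traj, fit = NULL) {
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  topo <- traj$topology
  if (is.null(fit)) fit <- select_atoms(topo, "backbone")
  if (length(fit) < 3L) stop("fit selection too small")
  ref <- traj$frames[[1L]]
  aligned <- lapply(traj$frames, function(f) {
    tr <- kabsch_superpose(f[fit, , drop = FALSE], ref[fit, , drop = FALSE])
    .apply_transform(f, tr)
  })
  mean1 <- Reduce(`+`, aligned) / length(aligned)
  aligned2 <- lapply(traj$frames, function(f) {
    tr <- kabsch_superpose(f[fit, , drop = FALSE], mean1[fit, , drop = FALSE])
    .apply_transform(f, tr)
  })
  mean2 <- Reduce(`+`, aligned2) / length(aligned2)
  sq <- Reduce(`+`, lapply(aligned2, function(f) (f - mean2)^2)) /
    length(aligned2)
  atom_rmsf <- sqrt(rowSums(sq))

  at <- topo$atoms
  is_aa <- at$resname %in% .AA3
  key <- paste(at$chain, at$resno, sep = "|")
  res_keys <- unique(key[is_aa])
  rows <- lapply(res_keys, function(k) {
    sel <- which(key == k & is_aa)
    bb <- sel[at$name[sel] %in% .BACKBONE_NAMES]
    sc <- sel[!(at$name[sel] %in% .BACKBONE_NAMES) & !at$is_hydrogen[sel]]
    b <- if (length(bb) > 0L) mean(atom_rmsf[bb]) else NA_real_
    s <- if (length(sc) > 0L) mean(atom_rmsf[sc]) else NA_real_
    m <- mean(c(b, s), na.rm = TRUE)
    data.frame(chain = at$chain[sel[1]], resno = at$resno[sel[1]],
               resname = at$resname[sel[1]], backbone_rmsf = b,
               side_chain_rmsf = s, mean_rmsf = m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "atom_rmsf") <- atom_rmsf
  class(out) <- c("rmsf_profile", "data.frame")
  out
}

#' Radius of gyration statistics over a trajectory
#'
#' Rg per frame is the root mean square distance of the selected atoms from
#' their unweighted centroid.  The distribution width used by the triage
#' rubric is the range (maximum minus minimum).
#'
#' @param traj an [md_trajectory()].
#' @param sel atom indices (default: protein heavy atoms).
#' @return Object of class `rg_stats`: list with `series` (Angstrom per
#'   frame), `minimum`, `maximum`, `range`, `mean`, `std`, `width`
#'   (`width == range`).
#' @export
radius_of_gyration <- function(traj, sel = NULL) {
  if (is.null(sel)) {
    sel <- intersect(select_atoms(traj$topology, "protein"),
                     select_atoms(traj$topology, "heavy"))
  }
  if (length(sel) == 0L) stop("empty atom selection")
  series <- vapply(traj$frames, function(f) {
    x <- f[sel, , drop = FALSE]
    cen <- colMeans(x)
    sqrt(mean(rowSums(sweep(x, 2, cen)^2)))
  }, numeric(1))
  rng <- max(series) - min(series)
  structure(list(series = series, minimum = min(series),
                 maximum = max(series), range = rng, mean = mean(series),
                 std = stats::sd(series), width = rng),
            class = "rg_stats")
}

#' @export
print.rg_stats <- function(x, ...) {
  cat(sprintf(
    "rg_stats: mean %.2f A, range %.2f A (min %.2f, max %.2f, sd %.3f)\n",
    x$mean, x$range, x$minimum, x$maximum, x$std))
  invisible(x)
}

#' Cluster trajectory frames on a 1-D RMSD series
#'
#' One-dimensional k-means (Lloyd) on the per-frame RMSD values,
#' deterministically initialised at the k quantile midpoints of the series.
#' The representative of each cluster is the frame whose RMSD is nearest
#' the cluster mean, ties resolved to the lowest frame index.  When the
#' series has fewer distinct values than `k`, the achievable number of
#' clusters is returned and flagged.
#'
#' @param series an [rmsd_series()] or numeric vector.
#' @param k requested number of clusters (10 mirrors the per-trajectory
#'   protocol; 50 the ensemble-docking receptor extraction).
#' @param seed retained for provenance; the procedure is deterministic.
#' @return Object of class `frame_clustering`: list with `k`, `labels`
#'   (per-frame cluster id), `centers`, `representatives` (1-based frame
#'   indices, one per cluster), `reduced` (TRUE when k was lowered), `seed`.
#' @export
cluster_frames <- function(series, k, seed = 1L) {
  x <- if (inherits(series, "rmsd_series")) series$values else as.numeric(series)
  n <- length(x)
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop("k (", k, ") exceeds the number of frames (", n, ")")
  ux <- unique(x)
  reduced <- FALSE
  if (length(ux) < k) {
    k <- length(ux)
    reduced <- TRUE
    warning("fewer distinct RMSD values than clusters requested; using k = ", k)
  }
  if (k == 1L) {
    centers <- mean(x)
    labels <- rep(1L, n)
  } else {
    centers <- unname(stats::quantile(x, probs = (seq_len(k) - 0.5) / k,
                                      type = 7))
    centers <- unique(centers)
    if (length(centers) < k) {
      k <- length(centers)
      reduced <- TRUE
    }
    km <- suppressWarnings(stats::kmeans(x, centers = matrix(centers),
                                         iter.max = 200L,
                                         algorithm = "Lloyd"))
    labels <- km$cluster
    centers <- as.numeric(km$centers)
  }
  reps <- vapply(seq_len(k), function(cl) {
    members <- which(labels == cl)
    members[which.min(abs(x[members] - centers[cl]))]
  }, integer(1))
  structure(list(k = k, labels = labels, centers = centers,
                 representatives = reps, reduced = reduced, seed = seed),
            class = "frame_clustering")
}

#' @export
print.frame_clustering <- function(x, ...) {
  cat("frame_clustering: k =", x$k, "- representatives:",
      paste(x$representatives, collapse = ", "), "\n")
  invisible(x)
}

# Match the site atoms of two structures: returns list(a_idx, b_idx,
# fit_a, fit_b) with heavy site atoms paired by (resno, atom name) and the
# backbone subset used for fitting.  Errors list missing residues or
# atom-name mismatches.
.match_site_atoms <- function(a, b, site) {
  res <- .parse_residues(site)
  a_at <- a$atoms; b_at <- b$atoms
  a_idx <- integer(0); b_idx <- integer(0); offenders <- character(0)
  for (r in res$resno) {
    ia <- which(a_at$resno == r & !a_at$is_hydrogen &
                  a_at$resname %in% .AA3)
    ib <- which(b_at$resno == r & !b_at$is_hydrogen &
                  b_at$resname %in% .AA3)
    if (length(ia) == 0L || length(ib) == 0L) {
      offenders <- c(offenders, paste0("residue ", r, " missing"))
      next
    }
    na <- a_at$name[ia]; nb <- b_at$name[ib]
    if (!setequal(na, nb)) {
      offenders <- c(offenders,
                     paste0("residue ", r, ": atom names differ (",
                            paste(union(setdiff(na, nb), setdiff(nb, na)),
                                  collapse = ","), ")"))
      next
    }
    ord <- match(na, nb)
    a_idx <- c(a_idx, ia)
    b_idx <- c(b_idx, ib[ord])
  }
  if (length(offenders) > 0L) {
    stop("site mismatch between structures: ",
         paste(offenders, collapse = "; "))
  }
  bb <- a_at$name[a_idx] %in% .BACKBONE_NAMES
  list(a_idx = a_idx, b_idx = b_idx, backbone = bb)
}

#' Binding-site RMSD between two structures
#'
#' Superposes `b` onto `a` on the site backbone atoms, then computes the
#' RMSD over all site heavy atoms (backbone plus side chains) -- side-chain
#' rearrangement therefore contributes to the score while global placement
#' does not.
#'
#' @param a,b [md_structure()] objects containing all site residues with
#'   matching heavy-atom names.
#' @param site residue identifiers (labels, numbers, or a [site_config()]
#'   whose pocket residues are used).
#' @return RMSD in Angstrom.
#' @export
site_rmsd <- function(a, b, site) {
  if (inherits(site, "site_config")) site <- site$pocket_residues
  m <- .match_site_atoms(a, b, site)
  ax <- a$xyz[m$a_idx, , drop = FALSE]
  bx <- b$xyz[m$b_idx, , drop = FALSE]
  tr <- kabsch_superpose(bx[m$backbone, , drop = FALSE],
                         ax[m$backbone, , drop = FALSE])
  .rmsd_between(.apply_transform(bx, tr), ax)
}

#' Apo-resemblance arithmetic
#'
#' Given per-crystal counts of apo snapshots whose binding site lies within
#' the RMSD threshold, derives both reported percentage conventions: the
#' share of the filtered snapshot pool, and the share of all frames tested
#' (also returned as a plain fraction, since published tables have printed
#' that fraction with a percent sign).
#'
#' @param counts named integer vector (or data.frame with `system`,
#'   `count`) of matching snapshots per crystal.
#' @param filtered_total size of the filtered snapshot pool (denominator of
#'   the first convention).
#' @param total_frames number of frames tested per crystal.
#' @return data.frame with `system`, `match_count`, `percent_of_filtered`
#'   (rounded to integer percent), `percent_of_filtered_raw`,
#'   `percent_of_all_frames`, `fraction_of_all_frames`.
#' @export
apo_percentages <- function(counts, filtered_total, total_frames) {
  if (is.data.frame(counts)) {
    cnt <- counts$count
    names(cnt) <- counts$system
    counts <- cnt
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  pf_raw <- if (filtered_total > 0) 100 * counts / filtered_total else
    rep(0, length(counts))
  pa <- if (total_frames > 0) 100 * counts / total_frames else
    rep(0, length(counts))
  data.frame(system = names(counts), match_count = as.integer(counts),
             percent_of_filtered = as.integer(round(pf_raw)),
             percent_of_filtered_raw = pf_raw,
             percent_of_all_frames = pa,
             fraction_of_all_frames = counts / max(total_frames, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apo-resemblance binding-site filter
#'
#' Compares the binding site of each holo crystal structure against every
#' snapshot of an apo trajectory via [site_rmsd()]; snapshots below the
#' threshold count as resembling that crystal.  Reports per-crystal match
#' counts and both percentage conventions (see [apo_percentages()]).
#'
#' @param apo_frames an [md_trajectory()] of the apo protein, or a list of
#'   [md_structure()] snapshots.
#' @param crystals named list of [md_structure()] holo crystals.
#' @param site residue identifiers or a [site_config()].
#' @param threshold RMSD threshold in Angstrom (default 2.5).
#' @return Object of class `apo_report`: list with `table` (see
#'   [apo_percentages()]), `filtered_total` (snapshot-crystal pairs
#'   passing), `n_frames`, `threshold`, and the full `rmsd` matrix
#'   (frames x crystals).
#' @export
apo_resemblance <- function(apo_frames, crystals, site, threshold = 2.5) {
  if (inherits(apo_frames, "md_trajectory")) {
    apo_frames <- lapply(seq_len(n_frames(apo_frames)),
                         function(i) .frame_structure(apo_frames, i))
  }
  if (is.null(names(crystals)) || any(names(crystals) == "")) {
    stop("crystals must be a named list")
  }
  nf <- length(apo_frames)
  rmat <- sapply(crystals, function(cr) {
    vapply(apo_frames, function(fr) site_rmsd(cr, fr, site), numeric(1))
  })
  rmat <- matrix(rmat, nrow = nf, dimnames = list(NULL, names(crystals)))
  counts <- colSums(rmat < threshold)
  filtered_total <- sum(counts)
  structure(list(table = apo_percentages(counts, filtered_total, nf),
                 filtered_total = filtered_total, n_frames = nf,
                 threshold = threshold, rmsd = rmat),
            class = "apo_report")
}

#' @export
print.apo_report <- function(x, ...) {
  cat(sprintf("apo_report: %d frames, threshold %.1f A, %d pairs passed\n",
              x$n_frames, x$threshold, x$filtered_total))
  print(x$table)
  invisible(x)
}
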