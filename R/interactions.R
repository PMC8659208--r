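# Frame-wise protein-ligand contact detection and interaction-fraction
# fingerprints.  The geometric criteria are explicit and configurable; the
# aim is self-consistent occupancy bookkeeping, not bit-compatibility with
# any particular MD engine's analysis tool.

#' Geometric contact criteria
#'
#' @param hbond_heavy_dist donor--acceptor heavy-atom distance cutoff, A.
#' @param hbond_angle_min minimum donor-H-acceptor angle in degrees,
#'   applied only when hydrogens are present in the topology.
#' @param hydrophobic_dist carbon--carbon distance cutoff for hydrophobic
#'   contacts, A.
#' @param aromatic_centroid_dist ring-centroid distance cutoff, A.
#' @param pication_dist cation--ring-centroid cutoff, A.
#' @param ionic_dist charged-group atom distance cutoff, A.
#' @param water_bridge include water-bridged hydrogen bonds (only relevant
#'   when explicit waters are present; off by default).
#' @return Object of class `contact_criteria`.
#' @export
contact_criteria <- function(hbond_heavy_dist = 3.5, hbond_angle_min = 120,
                             hydrophobic_dist = 3.6,
                             aromatic_centroid_dist = 4.5,
                             pication_dist = 4.5, ionic_dist = 3.7,
                             water_bridge = FALSE) {
  dists <- c(hbond_heavy_dist, hydrophobic_dist, aromatic_centroid_dist,
             pication_dist, ionic_dist)
  if (any(dists <= 0)) stop("all distance cutoffs must be positive")
  if (hbond_angle_min <= 0 || hbond_angle_min > 180) {
    stop("hbond_angle_min must be in (0, 180]")
  }
  structure(list(hbond_heavy_dist = hbond_heavy_dist,
                 hbond_angle_min = hbond_angle_min,
                 hydrophobic_dist = hydrophobic_dist,
                 aromatic_centroid_dist = aromatic_centroid_dist,
                 pication_dist = pication_dist, ionic_dist = ionic_dist,
                 water_bridge = water_bridge),
            class = "contact_criteria")
}

# Bond graph of a small molecule from heavy-atom distances (< 1.75 A).
.bond_graph <- function(xyz) {
  d <- .crossdist(xyz, xyz)
  diag(d) <- Inf
  d < 1.75
}

# Enumerate 5- and 6-membered rings by bounded DFS over the bond graph.
# Returns a list of integer vectors (vertex indices); each ring reported
# once (canonical smallest-first orientation).
.find_rings <- function(adj) {
  n <- nrow(adj)
  rings <- list()
  seen <- character(0)
  dfs <- function(path) {
    last <- path[length(path)]
    for (nb in which(adj[last, ])) {
      if (nb == path[1] && length(path) >= 5L) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- path
        }
      } else if (!(nb %in% path) && length(path) < 6L && nb > path[1]) {
        dfs(c(path, nb))
      }
    }
  }
  for (v in seq_len(n)) dfs(v)
  rings
}

# Aromatic-capable rings of the ligand: 5/6-membered cycles made of C/N.
.ligand_rings <- function(structure, ligand) {
  at <- structure$atoms
  heavy <- ligand[!at$is_hydrogen[ligand]]
  if (length(heavy) < 5L) return(list())
  xyz <- structure$xyz[heavy, , drop = FALSE]
  adj <- .bond_graph(xyz)
  rings <- .find_rings(adj)
  keep <- vapply(rings, function(r) {
    all(at$element[heavy[r]] %in% c("C", "N"))
  }, logical(1))
  lapply(rings[keep], function(r) heavy[r])
}

# Hydrogens bonded to each heavy atom (indices into the structure).
.attached_hydrogens <- function(structure, heavy_idx) {
  at <- structure$atoms
  h_idx <- which(at$is_hydrogen)
  if (length(h_idx) == 0L) return(lapply(heavy_idx, function(i) integer(0)))
  d <- .crossdist(structure$xyz[heavy_idx, , drop = FALSE],
                  structure$xyz[h_idx, , drop = FALSE])
  lapply(seq_along(heavy_idx), function(i) h_idx[d[i, ] < 1.25])
}

.angle_deg <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

.empty_events <- function() {
  data.frame(resno = integer(0), resname = character(0),
             chain = character(0), type = character(0),
             channel = character(0), stringsAsFactors = FALSE)
}

#' Detect protein-ligand contacts in a single frame
#'
#' Applies the geometric [contact_criteria()] to one conformation and emits
#' one event per satisfied contact channel.  Hydrogen-bond channels are
#' identified by the (ligand atom, protein atom) heavy-atom pair, so two
#' distinct donor/acceptor pairs on the same residue count as separate
#' channels; hydrophobic contacts are residue-level; aromatic, pi-cation
#' and ionic events are keyed by the interacting groups.  When the
#' structure carries hydrogens, hydrogen bonds additionally require a
#' donor-H-acceptor angle above the criterion; on heavy-atom-only inputs
#' the distance rule alone applies.
#'
#' @param structure an [md_structure()] (a trajectory frame or a pose).
#' @param ligand atom indices of the ligand (disjoint from the protein).
#' @param criteria a [contact_criteria()].
#' @param ligand_charges optional list with character vectors `positive`
#'   and `negative` naming formally charged ligand atoms (input files carry
#'   no charges, so these must be declared).
#' @return data.frame with columns `resno`, `resname`, `chain`, `type`
#'   (`hbond`, `hydrophobic`, `aromatic`, `pication`, `ionic`), `channel`.
#' @export
detect_contacts <- function(structure, ligand,
                            criteria = contact_criteria(),
                            ligand_charges = NULL) {
  at <- structure$atoms
  xyz <- structure$xyz
  ligand <- as.integer(ligand)
  if (length(ligand) == 0L) stop("no ligand atoms")
  prot <- setdiff(which(at$resname %in% .AA3), ligand)
  if (length(intersect(prot, ligand)) > 0L) {
    stop("ligand and protein atom sets must be disjoint")
  }
  events <- list()
  add <- function(idx_prot, type, channel) {
    events[[length(events) + 1L]] <<- data.frame(
      resno = at$resno[idx_prot], resname = at$resname[idx_prot],
      chain = at$chain[idx_prot], type = type, channel = channel,
      stringsAsFactors = FALSE)
  }
  has_h <- any(at$is_hydrogen)

  ## hydrogen bonds: polar (N/O) heavy atoms within cutoff
  lig_pol <- ligand[at$element[ligand] %in% c("N", "O") &
                      !at$is_hydrogen[ligand]]
  prot_pol <- prot[at$element[prot] %in% c("N", "O") & !at$is_hydrogen[prot]]
  if (length(lig_pol) > 0L && length(prot_pol) > 0L) {
    d <- .crossdist(xyz[lig_pol, , drop = FALSE],
                    xyz[prot_pol, , drop = FALSE])
    hits <- which(d <= criteria$hbond_heavy_dist, arr.ind = TRUE)
    if (nrow(hits) > 0L && has_h) {
      lig_h <- .attached_hydrogens(structure, lig_pol)
      prot_h <- .attached_hydrogens(structure, prot_pol)
      ok <- vapply(seq_len(nrow(hits)), function(r) {
        i <- hits[r, 1]; j <- hits[r, 2]
        donors <- c(lapply(lig_h[[i]], function(h)
          c(lig_pol[i], h, prot_pol[j])),
          lapply(prot_h[[j]], function(h) c(prot_pol[j], h, lig_pol[i])))
        if (length(donors) == 0L) return(FALSE)
        any(vapply(donors, function(dha) {
          .angle_deg(xyz[dha[1], ], xyz[dha[2], ], xyz[dha[3], ]) >=
            criteria$hbond_angle_min
        }, logical(1)))
      }, logical(1))
      hits <- hits[ok, , drop = FALSE]
    }
    if (nrow(hits) > 0L) {
      for (r in seq_len(nrow(hits))) {
        i <- lig_pol[hits[r, 1]]; j <- prot_pol[hits[r, 2]]
        add(j, "hbond", paste0(at$name[i], ":", at$name[j]))
      }
    }
  }

  ## hydrophobic: ligand carbons vs carbons of hydrophobic residues
  lig_c <- ligand[at$element[ligand] == "C"]
  prot_c <- prot[at$element[prot] == "C" &
                   at$resname[prot] %in% .HYDROPHOBIC_RES]
  if (length(lig_c) > 0L && length(prot_c) > 0L) {
    d <- .crossdist(xyz[lig_c, , drop = FALSE], xyz[prot_c, , drop = FALSE])
    close_res <- unique(prot_c[colSums(d <= criteria$hydrophobic_dist) > 0])
    touched <- unique(at$resno[close_res])
    for (r in touched) {
      j <- close_res[at$resno[close_res] == r][1]
      add(j, "hydrophobic", "hydrophobic")
    }
  }

  ## ring centroids
  lig_rings <- .ligand_rings(structure, ligand)
  lig_cent <- lapply(lig_rings, function(r) colMeans(xyz[r, , drop = FALSE]))
  prot_rings <- list()
  for (rn in names(.PROTEIN_RINGS)) {
    res_idx <- prot[at$resname[prot] == rn]
    for (resno in unique(at$resno[res_idx])) {
      sel <- res_idx[at$resno[res_idx] == resno]
      for (ring_names in .PROTEIN_RINGS[[rn]]) {
        ring <- sel[match(ring_names, at$name[sel])]
        if (!anyNA(ring)) {
          prot_rings[[length(prot_rings) + 1L]] <-
            list(idx = ring, resno = resno, rep = ring[1])
        }
      }
    }
  }

  ## aromatic stacking: ligand ring centroid vs protein ring centroid
  if (length(lig_cent) > 0L && length(prot_rings) > 0L) {
    for (li in seq_along(lig_cent)) {
      for (pr in prot_rings) {
        cen <- colMeans(xyz[pr$idx, , drop = FALSE])
        if (sqrt(sum((lig_cent[[li]] - cen)^2)) <=
            criteria$aromatic_centroid_dist) {
          add(pr$rep, "aromatic", paste0("ring", li))
        }
      }
    }
  }

  ## pi-cation: protein cations vs ligand rings, ligand cations vs protein rings
  prot_cat <- prot[(at$resname[prot] == "LYS" & at$name[prot] == "NZ") |
                     (at$resname[prot] == "ARG" & at$name[prot] == "CZ")]
  if (length(lig_cent) > 0L && length(prot_cat) > 0L) {
    for (li in seq_along(lig_cent)) {
      for (pc in prot_cat) {
        if (sqrt(sum((lig_cent[[li]] - xyz[pc, ])^2)) <=
            criteria$pication_dist) {
          add(pc, "pication", paste0("ring", li, ":", at$name[pc]))
        }
      }
    }
  }
  lig_pos <- if (!is.null(ligand_charges))
    ligand[at$name[ligand] %in% ligand_charges$positive] else integer(0)
  lig_neg <- if (!is.null(ligand_charges))
    ligand[at$name[ligand] %in% ligand_charges$negative] else integer(0)
  if (length(lig_pos) > 0L && length(prot_rings) > 0L) {
    for (pr in prot_rings) {
      cen <- colMeans(xyz[pr$idx, , drop = FALSE])
      for (lp in lig_pos) {
        if (sqrt(sum((cen - xyz[lp, ])^2)) <= criteria$pication_dist) {
          add(pr$rep, "pication", paste0(at$name[lp], ":ring"))
        }
      }
    }
  }

  ## ionic: charged-group atom pairs
  prot_neg <- prot[(at$resname[prot] == "ASP" &
                      at$name[prot] %in% c("OD1", "OD2")) |
                     (at$resname[prot] == "GLU" &
                        at$name[prot] %in% c("OE1", "OE2"))]
  prot_pos <- prot[(at$resname[prot] == "LYS" & at$name[prot] == "NZ") |
                     (at$resname[prot] == "ARG" &
                        at$name[prot] %in% c("NE", "NH1", "NH2"))]
  ionic_pairs <- rbind(
    if (length(lig_pos) > 0L && length(prot_neg) > 0L)
      expand.grid(lig = lig_pos, pr = prot_neg),
    if (length(lig_neg) > 0L && length(prot_pos) > 0L)
      expand.grid(lig = lig_neg, pr = prot_pos))
  if (!is.null(ionic_pairs) && nrow(ionic_pairs) > 0L) {
    touched <- character(0)
    for (r in seq_len(nrow(ionic_pairs))) {
      i <- ionic_pairs$lig[r]; j <- ionic_pairs$pr[r]
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= criteria$ionic_dist) {
        ch <- paste0(at$name[i], ":", at$resno[j])
        if (!(ch %in% touched)) {
          touched <- c(touched, ch)
          add(j, "ionic", paste0(at$name[i], ":", at$name[j]))
        }
      }
    }
  }

  if (length(events) == 0L) return(.empty_events())
  ev <- do.call(rbind, events)
  unique(ev)
}

#' Interaction-fraction fingerprint of a trajectory
#'
#' Runs [detect_contacts()] on every frame and reports, per (residue,
#' interaction type, channel), the fraction of frames in which the channel
#' is occupied (the ratio between the contact duration and the trajectory
#' length).  The per-residue cumulative fraction sums all channels and
#' types of a residue and may exceed 1 when a residue engages the ligand
#' through multiple interaction points.
#'
#' @param traj an [md_trajectory()] with at least one frame.
#' @param ligand ligand atom indices in the topology.
#' @param criteria a [contact_criteria()].
#' @param ligand_charges see [detect_contacts()].
#' @return Object of class `interaction_fractions`: list with `table`
#'   (data.frame `resno`, `resname`, `chain`, `type`, `channel`,
#'   `fraction`), `cumulative` (data.frame `resno`, `resname`,
#'   `cumulative_fraction`), `n_frames`.
#' @export
interaction_fractions <- function(traj, ligand,
                                  criteria = contact_criteria(),
                                  ligand_charges = NULL) {
  nf <- n_frames(traj)
  if (nf < 1L) stop("trajectory has no frames")
  per_frame <- lapply(seq_len(nf), function(i) {
    ev <- detect_contacts(.frame_structure(traj, i), ligand, criteria,
                          ligand_charges)
    if (nrow(ev) > 0L) ev$frame <- i
    ev
  })
  all_ev <- do.call(rbind, per_frame[vapply(per_frame, nrow, 1L) > 0])
  if (is.null(all_ev) || nrow(all_ev) == 0L) {
    tab <- cbind(.empty_events(), fraction = numeric(0))
    cum <- data.frame(resno = integer(0), resname = character(0),
                      cumulative_fraction = numeric(0))
    return(structure(list(table = tab, cumulative = cum, n_frames = nf),
                     class = "interaction_fractions"))
  }
  key <- paste(all_ev$resno, all_ev$chain, all_ev$type, all_ev$channel,
               sep = "|")
  counts <- tapply(all_ev$frame, key, function(f) length(unique(f)))
  first <- all_ev[!duplicated(key), , drop = FALSE]
  ord <- match(names(counts), key[!duplicated(key)])
  tab <- data.frame(resno = first$resno[ord], resname = first$resname[ord],
                    chain = first$chain[ord], type = first$type[ord],
                    channel = first$channel[ord],
                    fraction = as.numeric(counts) / nf,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$resno, tab$type, tab$channel), , drop = FALSE]
  rownames(tab) <- NULL
  cum_v <- tapply(tab$fraction, tab$resno, sum)
  cum <- data.frame(resno = as.integer(names(cum_v)),
                    resname = tab$resname[match(as.integer(names(cum_v)),
                                                tab$resno)],
                    cumulative_fraction = as.numeric(cum_v),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, cumulative = cum, n_frames = nf),
            class = "interaction_fractions")
}

#' @export
print.interaction_fractions <- function(x, ...) {
  cat("interaction_fractions over", x$n_frames, "frames:",
      nrow(x$table), "channels on", nrow(x$cumulative), "residues\n")
  invisible(x)
}

#' Count persistently interacting binding-site residues
#'
#' The rubric's molecular dynamics interaction statistic: how many key
#' binding-site residues keep contact with the ligand for more than the
#' given fraction of simulation time.  The per-residue cumulative fraction
#' (all channels and types summed) is compared against the threshold.
#'
#' @param fractions an [interaction_fractions()] result.
#' @param key_residues residue numbers/labels or a [site_config()] (key set
#'   used).
#' @param threshold time-fraction threshold (default 0.5).
#' @return Integer count.
#' @export
count_site_interactions <- function(fractions, key_residues,
                                    threshold = 0.5) {
  if (inherits(key_residues, "site_config")) {
    key_residues <- key_residues$key_residues
  }
  res <- .parse_residues(key_residues)
  cum <- fractions$cumulative
  sum(cum$resno %in% res$resno & cum$cumulative_fraction > threshold)
}

#' Count site residues contacted in a static pose
#'
#' Number of distinct binding-site residues with at least one contact event
#' in a single (e.g. docked) pose.
#'
#' @param complex an [md_structure()] containing protein and ligand.
#' @param ligand_resname residue name of the ligand.
#' @param site residue identifiers or a [site_config()] (pocket set used).
#' @param criteria a [contact_criteria()].
#' @param ligand_charges see [detect_contacts()].
#' @return Integer count of distinct site residues touched.
#' @export
static_pose_contacts <- function(complex, ligand_resname, site,
                                 criteria = contact_criteria(),
                                 ligand_charges = NULL) {
  ligand <- which(complex$atoms$resname == toupper(ligand_resname))
  if (length(ligand) == 0L) {
    stop("ligand residue '", ligand_resname, "' not found")
  }
  if (inherits(site, "site_config")) site <- site$pocket_residues
  res <- .parse_residues(site)
  ev <- detect_contacts(complex, ligand, criteria, ligand_charges)
  length(unique(ev$resno[ev$resno %in% res$resno]))
}
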