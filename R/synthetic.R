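# Ground-truth fixture generation: toy structures, trajectories with known
# per-residue fluctuation amplitudes, rigid-body drift and planted contact
# schedules, and energy tables with known per-residue means.  Everything is
# deterministic under a fixed seed.

.SIDE_CHAINS <- list(
  GLY = character(0),
  ALA = c(CB = "C"),
  SER = c(CB = "C", OG = "O"),
  VAL = c(CB = "C", CG1 = "C", CG2 = "C"),
  THR = c(CB = "C", OG1 = "O", CG2 = "C"),
  ASN = c(CB = "C", CG = "C", OD1 = "O", ND2 = "N"),
  ASP = c(CB = "C", CG = "C", OD1 = "O", OD2 = "O"),
  PHE = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C"),
  ILE = c(CB = "C", CG1 = "C", CG2 = "C", CD1 = "C"),
  LYS = c(CB = "C", CG = "C", CD = "C", NZ = "N")
)

#' Generate an idealised toy structure
#'
#' A poly-residue chain on a loose helix with an N/CA/C/O backbone and 0--4
#' heavy side-chain atoms per residue (residue types cycle through a fixed
#' palette spanning hydrophobic, polar, charged and glycine).  Optionally a
#' small-molecule ligand (`LIG`, 6 heavy atoms with polar O1/N1 and carbons
#' C1--C4) is placed near the designated pocket residues.  Identical seeds
#' give identical structures.
#'
#' @param n_residues number of residues (>= 2).
#' @param seed RNG seed.
#' @param ligand place a ligand near the pocket?
#' @param pocket_residues residue numbers the ligand is centred on
#'   (default: the middle third of the chain).
#' @return An [md_structure()].
#' @export
make_toy_structure <- function(n_residues, seed = 1L, ligand = FALSE,
                               pocket_residues = NULL) {
  if (n_residues < 2L) stop("n_residues must be >= 2")
  set.seed(seed)
  palette <- names(.SIDE_CHAINS)
  rows <- list(); xyz <- list(); serial <- 0L
  add_atom <- function(name, element, resno, resname, pos) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, element = element, resno = resno,
      resname = resname, chain = "A", stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <<- pos
  }
  for (i in seq_len(n_residues)) {
    resname <- palette[((i - 1L) %% length(palette)) + 1L]
    theta <- i * 100 * pi / 180
    ca <- c(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
    add_atom("N", "N", i, resname, ca + c(-1.2, 0.4, -0.5))
    add_atom("CA", "C", i, resname, ca)
    add_atom("C", "C", i, resname, ca + c(1.2, 0.3, 0.6))
    add_atom("O", "O", i, resname, ca + c(1.9, 1.2, 0.4))
    sc <- .SIDE_CHAINS[[resname]]
    if (length(sc) > 0L) {
      dir <- ca - c(0, 0, ca[3])
      dir <- dir / max(sqrt(sum(dir^2)), 1e-9)
      for (j in seq_along(sc)) {
        add_atom(names(sc)[j], unname(sc[j]), i, resname,
                 ca + dir * (1.5 * j) + c(0, 0, 0.3 * j))
      }
    }
  }
  if (ligand) {
    if (is.null(pocket_residues)) {
      pocket_residues <- seq(floor(n_residues / 3),
                             ceiling(2 * n_residues / 3))
    }
    at_df <- do.call(rbind, rows)
    ca_idx <- which(at_df$name == "CA" & at_df$resno %in% pocket_residues)
    centre <- colMeans(do.call(rbind, xyz[ca_idx]))
    out_dir <- centre - colMeans(do.call(rbind, xyz))
    out_dir <- out_dir / max(sqrt(sum(out_dir^2)), 1e-9)
    base <- centre + out_dir * 5
    lig <- list(O1 = c("O", c(0, 0, 0)), N1 = c("N", c(1.3, 0, 0)),
                C1 = c("C", c(0.7, 1.2, 0)), C2 = c("C", c(-0.7, 1.2, 0.5)),
                C3 = c("C", c(0, -1.3, 0.3)), C4 = c("C", c(1.4, -1.0, 0.8)))
    for (nm in names(lig)) {
      add_atom(nm, lig[[nm]][1], n_residues + 1L, "LIG",
               base + as.numeric(lig[[nm]][-1]))
    }
  }
  md_structure(do.call(rbind, rows), do.call(rbind, xyz))
}

#' Simulation specification for the synthetic trajectory generator
#'
#' @param n_frames number of frames (>= 1).
#' @param sigma per-axis Gaussian jitter amplitude in Angstrom: a scalar,
#'   or a vector named by residue number for residue-specific amplitudes
#'   (unnamed residues get the `sigma_default`).
#' @param sigma_default fallback amplitude when `sigma` is named.
#' @param drift_angle rigid-body rotation per frame, degrees.
#' @param drift_axis rotation axis.
#' @param drift_translation rigid-body translation per frame (length 3).
#' @param contact_schedule data.frame with columns `resno`, `type`
#'   (`"hbond"` or `"hydrophobic"`), `fraction` in [0, 1]: the designated
#'   ligand atom is placed in contact with that residue in exactly
#'   `round(fraction * n_frames)` frames (chosen deterministically from the
#'   seed).
#' @param seed RNG seed; identical seeds give byte-identical trajectories.
#' @return Object of class `sim_spec`.
#' @export
sim_spec <- function(n_frames, sigma = 0, sigma_default = 0,
                     drift_angle = 0, drift_axis = c(0, 0, 1),
                     drift_translation = c(0, 0, 0),
                     contact_schedule = NULL, seed = 1L) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (any(sigma < 0) || sigma_default < 0) stop("sigma must be >= 0")
  if (!is.null(contact_schedule)) {
    .require_columns(contact_schedule, c("resno", "type", "fraction"),
                     "contact_schedule")
    if (any(contact_schedule$fraction < 0 | contact_schedule$fraction > 1)) {
      stop("contact fractions must be in [0, 1]")
    }
  }
  structure(list(n_frames = as.integer(n_frames), sigma = sigma,
                 sigma_default = sigma_default, drift_angle = drift_angle,
                 drift_axis = drift_axis,
                 drift_translation = drift_translation,
                 contact_schedule = contact_schedule, seed = as.integer(seed)),
            class = "sim_spec")
}

# Designated ligand atom for the s-th schedule entry of a given type.
.planted_ligand_atom <- function(type, entry_index) {
  if (type == "hbond") c("O1", "N1")[((entry_index - 1L) %% 2L) + 1L]
  else c("C1", "C2", "C3", "C4")[((entry_index - 1L) %% 4L) + 1L]
}

#' Simulate a synthetic trajectory with known statistics
#'
#' Frame t applies, to the base structure plus iid per-atom Gaussian jitter
#' (per-residue amplitude), the rigid-body drift accumulated over t-1
#' steps.  Scheduled contacts are realised by moving one designated ligand
#' atom (without jitter) to within the default contact criteria of the
#' target residue in exactly the scheduled share of frames, and well beyond
#' every cutoff otherwise, so the corresponding channel fraction is
#' recovered exactly by [interaction_fractions()].
#'
#' @param base an [md_structure()] (with a `LIG` residue when a contact
#'   schedule is given).
#' @param spec a [sim_spec()].
#' @return An [md_trajectory()].
#' @export
simulate_trajectory <- function(base, spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  at <- base$atoms
  n_at <- nrow(at)
  nf <- spec$n_frames
  # per-atom jitter amplitude
  if (!is.null(names(spec$sigma)) && length(spec$sigma) > 0) {
    sig <- rep(spec$sigma_default, n_at)
    m <- match(as.character(at$resno), names(spec$sigma))
    sig[!is.na(m)] <- as.numeric(spec$sigma[m[!is.na(m)]])
  } else {
    sig <- rep(spec$sigma[1], n_at)
  }
  # planted contacts: target protein atom, designated ligand atom, distance
  plants <- list()
  if (!is.null(spec$contact_schedule)) {
    sched <- spec$contact_schedule
    for (s in seq_len(nrow(sched))) {
      type <- sched$type[s]
      resno <- sched$resno[s]
      res_idx <- which(at$resno == resno & at$resname %in% .AA3)
      if (length(res_idx) == 0L) stop("schedule residue ", resno,
                                      " not in structure")
      target <- if (type == "hbond") {
        cand <- res_idx[at$element[res_idx] %in% c("N", "O")]
        if (length(cand) == 0L) stop("residue ", resno,
                                     " has no polar atom for an hbond plant")
        cand[length(cand)]   # prefer a side-chain polar atom
      } else {
        cand <- res_idx[at$element[res_idx] == "C"]
        cand[length(cand)]
      }
      lig_name <- .planted_ligand_atom(type, s)
      lig_idx <- which(at$resname == "LIG" & at$name == lig_name)
      if (length(lig_idx) == 0L) stop("base structure has no ligand atom ",
                                      lig_name)
      n_on <- round(sched$fraction[s] * nf)
      on_frames <- if (n_on > 0) sort(sample.int(nf, n_on)) else integer(0)
      plants[[s]] <- list(target = target, lig = lig_idx,
                          dist_on = if (type == "hbond") 2.9 else 3.2,
                          on = on_frames)
    }
  }
  centre <- colMeans(base$xyz)
  away <- function(pos) {
    u <- pos - centre
    u / max(sqrt(sum(u^2)), 1e-9)
  }
  frames <- vector("list", nf)
  for (t in seq_len(nf)) {
    f <- base$xyz + matrix(stats::rnorm(n_at * 3, sd = rep(sig, 3)),
                           ncol = 3)
    for (p in plants) {
      tgt <- f[p$target, ]
      d <- if (t %in% p$on) p$dist_on else 9.5
      f[p$lig, ] <- tgt + away(tgt) * d
    }
    if (spec$drift_angle != 0 || any(spec$drift_translation != 0)) {
      R <- .rotation_matrix(spec$drift_axis, spec$drift_angle * (t - 1))
      f <- sweep(sweep(f, 2, centre) %*% R, 2,
                 centre + spec$drift_translation * (t - 1), "+")
    }
    frames[[t]] <- f
  }
  md_trajectory(base, frames)
}

#' Synthetic per-residue energy table with known truth
#'
#' Entries are `true_mean + N(0, noise_sd)` per replica; the generating
#' means are attached as the `truth` attribute, so
#' [per_residue_aggregate()] can be validated against them.
#'
#' @param true_means named numeric vector of per-residue mean energies
#'   (kcal/mol), names are residue labels.
#' @param noise_sd Gaussian noise standard deviation.
#' @param replicas number of replicas (>= 1).
#' @param seed RNG seed.
#' @param system system label.
#' @return data.frame with columns `system`, `replica`, `residue`,
#'   `energy`, `unit` and attribute `truth`.
#' @export
synth_energy_tables <- function(true_means, noise_sd = 0, replicas = 3L,
                                seed = 1L, system = "synthetic") {
  if (replicas < 1L) stop("replicas must be >= 1")
  set.seed(seed)
  res <- names(true_means)
  if (is.null(res)) res <- as.character(seq_along(true_means))
  out <- do.call(rbind, lapply(seq_len(replicas), function(r) {
    data.frame(system = system, replica = r, residue = res,
               energy = as.numeric(true_means) +
                 stats::rnorm(length(true_means), sd = noise_sd),
               unit = "kcal/mol", stringsAsFactors = FALSE)
  }))
  attr(out, "truth") <- true_means
  class(out) <- c("per_residue_energy", "data.frame")
  out
}

#' Synthetic parameter panel with a prescribed label
#'
#' Samples a panel from the decision-tree region of the requested label
#' (jittered within the region) so that [predict_triage()] returns that
#' label under the given thresholds; errors if the region is infeasible
#' under pathological thresholds.
#'
#' @param label `"Excellent"`, `"Good"`, `"Intermediate"` or `"Bad"`.
#' @param thresholds a [triage_thresholds()].
#' @param seed RNG seed.
#' @param system system label.
#' @return A [build_panel()] object.
#' @export
synth_panel <- function(label, thresholds = triage_thresholds(), seed = 1L,
                        system = "synthetic") {
  label <- match.arg(label, .TIERS)
  th <- thresholds
  set.seed(seed)
  u <- function(a, b) stats::runif(1, a, b)
  if (label == "Excellent") {
    mmgbsa <- th$mmgbsa_good - u(1, 30)
    site <- th$site_good - u(1, 20)
    total <- th$total_strong - u(1, 30)
    mdc <- th$contacts_strong + sample.int(3L, 1L)
  } else if (label == "Good") {
    mmgbsa <- th$mmgbsa_good - u(1, 20)
    site <- th$site_good - u(1, 10)
    mdc <- th$contacts_good
    total <- if (mdc >= th$contacts_strong)
      th$total_strong + u(1, 10) else site
  } else if (label == "Intermediate") {
    mmgbsa <- th$mmgbsa_good + u(1, 10)     # tier 1 fails on MM-GBSA
    total <- th$total_ok - u(1, 10)         # tier 2 passes on the total sum
    site <- th$site_good + u(1, 5)
    mdc <- sample(0:2, 1L)
  } else {
    mmgbsa <- th$mmgbsa_ok + u(1, 20)
    total <- th$total_ok + u(1, 10)
    site <- total + 5 + u(0, 5)             # sums distinct and unfavourable
    mdc <- max(0L, th$contacts_good - sample(1:2, 1L))
  }
  panel <- build_panel(system, mmgbsa = mmgbsa, site_energy = site,
                       total_energy = total, md_contacts = mdc,
                       rmsd_mean = u(1.8, 3.4),
                       rmsf_violations = sample(0:2, 1L),
                       rg_width = u(0.4, 1.2))
  got <- predict_triage(panel, th)$label
  if (got != label) {
    stop("infeasible label region under the supplied thresholds (",
         label, " requested, tree yields ", got, ")")
  }
  panel
}
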