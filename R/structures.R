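# Structure and trajectory containers with PDB/DCD input and multi-model
# PDB output, plus atom selection primitives.
#
# A structure is a list with
#   $atoms : data.frame(serial, name, element, resno, resname, chain,
#                       is_hydrogen, het)
#   $xyz   : numeric n_atoms x 3 matrix, Angstrom
# A trajectory holds a topology structure plus a list of coordinate frames.

#' Construct a molecular structure
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resno`, `resname`, `chain` (and optionally `is_hydrogen`, `het`).
#' @param xyz numeric matrix with one row per atom and columns x, y, z, in
#'   Angstrom.
#' @return An object of class `md_structure`.
#' @export
md_structure <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  if (!is.numeric(xyz) || ncol(xyz) != 3L) {
    stop("xyz must be a numeric matrix with 3 columns")
  }
  if (nrow(xyz) != nrow(atoms)) {
    stop("coordinate rows (", nrow(xyz), ") do not match atom count (",
         nrow(atoms), ")")
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  need <- c("serial", "name", "element", "resno", "resname", "chain")
  .require_columns(atoms, need, "md_structure")
  if (anyDuplicated(atoms$serial)) stop("duplicate atom serial numbers")
  if (is.null(atoms$is_hydrogen)) {
    atoms$is_hydrogen <- .is_hydrogen(atoms$name, atoms$element)
  }
  if (is.null(atoms$het)) atoms$het <- !(atoms$resname %in% .AA3)
  rownames(atoms) <- NULL
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz), class = "md_structure")
}

#' @export
print.md_structure <- function(x, ...) {
  cat("md_structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues\n")
  invisible(x)
}

.is_hydrogen <- function(name, element) {
  el <- toupper(trimws(element))
  out <- el == "H"
  # fall back on the atom name where the element column is blank
  blank <- is.na(el) | el == ""
  if (any(blank)) {
    stripped <- sub("^[0-9]*", "", toupper(trimws(name[blank])))
    out[blank] <- substr(stripped, 1, 1) == "H"
  }
  out
}

#' Read a molecular structure from a PDB file
#'
#' Reads ATOM/HETATM records via [bio3d::read.pdb()].  When alternate
#' locations are present, one atom per (chain, residue, atom name) is kept:
#' the highest occupancy wins, ties broken in favour of altloc "A" (then
#' alphabetically).  Hydrogens are retained; selections exclude them where
#' appropriate.
#'
#' @param path path to a PDB file.
#' @param format currently only `"pdb"`.
#' @return An [md_structure()].
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop("PDB file '", path, "' contains no ATOM/HETATM records")
  }
  xyz <- cbind(at$x, at$y, at$z)
  if (!all(is.finite(xyz))) {
    bad <- which(!stats::complete.cases(xyz))
    stop("malformed coordinate record(s) at atom row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  keep <- .resolve_altloc(at)
  at <- at[keep, , drop = FALSE]
  xyz <- xyz[keep, , drop = FALSE]
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  elem <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  atoms <- data.frame(serial = at$eleno, name = trimws(at$elety),
                      element = elem, resno = at$resno,
                      resname = toupper(trimws(at$resid)), chain = chain,
                      stringsAsFactors = FALSE)
  atoms$het <- at$type == "HETATM"
  md_structure(atoms, xyz)
}

# Index vector of atoms to keep after altloc resolution: highest occupancy,
# ties to the alphabetically first altloc letter.
.resolve_altloc <- function(at) {
  alt <- ifelse(is.na(at$alt), "", at$alt)
  key <- paste(at$chain, at$resno, at$resid, trimws(at$elety), sep = "|")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(key, -occ, alt)
  sort(ord[!duplicated(key[ord])])
}

#' Construct a trajectory
#'
#' @param topology an [md_structure()].
#' @param frames list of coordinate matrices (one per frame, same
#'   dimensions as `topology$xyz`), in Angstrom.
#' @param frame_interval optional time between frames (arbitrary units,
#'   bookkeeping only).
#' @return An object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, frames, frame_interval = NULL) {
  if (!inherits(topology, "md_structure")) stop("topology must be an md_structure")
  if (length(frames) < 1L) stop("a trajectory needs at least one frame")
  n <- nrow(topology$xyz)
  frames <- lapply(seq_along(frames), function(i) {
    f <- as.matrix(frames[[i]])
    if (nrow(f) != n || ncol(f) != 3L) {
      stop("frame ", i, ": expected ", n, " x 3 coordinates, found ",
           nrow(f), " x ", ncol(f))
    }
    if (!all(is.finite(f))) stop("frame ", i, ": non-finite coordinates")
    dimnames(f) <- list(NULL, c("x", "y", "z"))
    f
  })
  structure(list(topology = topology, frames = frames,
                 frame_interval = frame_interval),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", length(x$frames), "frames,",
      nrow(x$topology$xyz), "atoms\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

# Structure holding the coordinates of frame i (shares the topology atoms).
.frame_structure <- function(traj, i) {
  s <- traj$topology
  s$xyz <- traj$frames[[i]]
  s
}

#' Read a trajectory
#'
#' Multi-model PDB files are read with [bio3d::read.pdb()] (`multi = TRUE`);
#' DCD files with [bio3d::read.dcd()].  XTC is not supported; convert such
#' trajectories to DCD or multi-model PDB first.  Coordinates are stored in
#' Angstrom; set `units = "nm"` for inputs written in nanometres to scale
#' them by 10.
#'
#' @param topology an [md_structure()] matching the trajectory atoms.
#' @param path trajectory file.
#' @param format `"auto"` (by extension), `"pdb"` or `"dcd"`.
#' @param units `"angstrom"` (default) or `"nm"`.
#' @return An [md_trajectory()].
#' @export
read_trajectory <- function(topology, path, format = c("auto", "pdb", "dcd"),
                            units = c("angstrom", "nm")) {
  format <- match.arg(format)
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     pdb = "pdb", ent = "pdb", dcd = "dcd",
                     xtc = stop("XTC trajectories are not supported; ",
                                "convert to DCD or multi-model PDB"),
                     stop("cannot infer trajectory format from extension '",
                          ext, "'"))
  }
  n <- nrow(topology$xyz)
  if (format == "pdb") {
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                            verbose = FALSE))
    xyz <- pdb$xyz
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
    found <- ncol(xyz) / 3L
    if (found != n) {
      stop("atom-count mismatch: topology has ", n,
           " atoms but trajectory frames have ", found)
    }
  } else {
    xyz <- suppressWarnings(bio3d::read.dcd(path, verbose = FALSE))
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
    found <- ncol(xyz) / 3L
    if (found != n) {
      stop("atom-count mismatch: topology has ", n,
           " atoms but trajectory frames have ", found)
    }
  }
  if (any(!is.finite(xyz))) stop("truncated or malformed frame in ", path)
  scale <- if (units == "nm") 10 else 1
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3L, byrow = TRUE) * scale
  })
  md_trajectory(topology, frames)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame; inverse of [read_trajectory()] within
#' the 0.001 Angstrom precision of the PDB coordinate field.
#'
#' @param traj an [md_trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  if (!inherits(traj, "md_trajectory")) stop("traj must be an md_trajectory")
  if (length(traj$frames) < 1L) stop("cannot write an empty trajectory")
  at <- traj$topology$atoms
  rec <- ifelse(at$het, "HETATM", "ATOM  ")
  nm <- ifelse(nchar(at$name) < 4L, sprintf(" %-3s", at$name), at$name)
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing", call. = FALSE))
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    xyz <- traj$frames[[i]]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf(
      "%s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, at$serial, nm, at$resname, at$chain, at$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1.0, 0.0, at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a single structure as a PDB file
#'
#' @param structure an [md_structure()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  write_trajectory(md_trajectory(structure, list(structure$xyz)), path)
}

#' Select atoms of a structure
#'
#' Selection vocabulary:
#' \describe{
#'   \item{backbone}{N, CA, C, O atoms of amino-acid residues.}
#'   \item{heavy}{all non-hydrogen atoms.}
#'   \item{side_chain}{amino-acid heavy atoms that are not backbone.}
#'   \item{protein}{all atoms of amino-acid residues.}
#'   \item{ligand}{HETATM-style residues; restrict with `resname`.}
#'   \item{all}{every atom.}
#' }
#' Selections compose by intersection: `resno`, `resname` and `chain`
#' filters are applied on top of `what`.
#'
#' @param structure an [md_structure()].
#' @param what one of `"backbone"`, `"heavy"`, `"side_chain"`,
#'   `"protein"`, `"ligand"`, `"all"`.
#' @param resno optional residue numbers (or labels such as `"Phe44"`) the
#'   selection must come from; an error lists identifiers absent from the
#'   structure.
#' @param resname optional residue-name filter.
#' @param chain optional chain filter.
#' @return Integer vector of atom indices (class `atom_selection`) with a
#'   `label` attribute.
#' @export
select_atoms <- function(structure,
                         what = c("all", "backbone", "heavy", "side_chain",
                                  "protein", "ligand"),
                         resno = NULL, resname = NULL, chain = NULL) {
  what <- match.arg(what)
  at <- structure$atoms
  is_aa <- at$resname %in% .AA3
  keep <- switch(what,
    all        = rep(TRUE, nrow(at)),
    heavy      = !at$is_hydrogen,
    protein    = is_aa,
    backbone   = is_aa & at$name %in% .BACKBONE_NAMES,
    side_chain = is_aa & !at$is_hydrogen & !(at$name %in% .BACKBONE_NAMES),
    ligand     = !is_aa & !(at$resname %in% .WATER_RES))
  if (!is.null(resno)) {
    res <- .parse_residues(resno)
    present <- unique(at$resno)
    missing <- res$resno[!(res$resno %in% present)]
    if (length(missing) > 0L) {
      stop("residue(s) absent from structure: ",
           paste(unique(missing), collapse = ", "))
    }
    keep <- keep & at$resno %in% res$resno
  }
  if (!is.null(resname)) keep <- keep & at$resname %in% toupper(resname)
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  idx <- which(keep)
  label <- paste(c(what, if (!is.null(resname)) paste(resname, collapse = "+"),
                   if (!is.null(resno)) "resno-filtered"), collapse = ":")
  structure(idx, class = "atom_selection", label = label)
}

#' Binding-site configuration
#'
#' Holds the pocket-residue and key-residue sets of a target.  Both lists
#' are carried verbatim: the key set need not be a subset of the pocket set.
#'
#' @param pocket_residues residue labels (e.g. `"Gly43"`) or numbers.
#' @param key_residues residue labels or numbers.
#' @param target_name target identifier.
#' @return Object of class `site_config` with data.frame elements
#'   `pocket_residues` and `key_residues` (columns `resno`, `resname`).
#' @export
site_config <- function(pocket_residues, key_residues, target_name = "") {
  p <- .parse_residues(pocket_residues)
  k <- .parse_residues(key_residues)
  if (nrow(p) == 0L || nrow(k) == 0L) {
    stop("pocket_residues and key_residues must both be non-empty")
  }
  structure(list(target_name = target_name, pocket_residues = p,
                 key_residues = k), class = "site_config")
}

#' Read a site configuration from a YAML file
#'
#' Expects keys `target_name`, `pocket_residues`, `key_residues`.
#'
#' @param path YAML file.
#' @return A [site_config()].
#' @export
read_site_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (k in c("pocket_residues", "key_residues")) {
    if (is.null(cfg[[k]]) || length(cfg[[k]]) == 0L) {
      stop("site config '", path, "' is missing non-empty '", k, "'")
    }
  }
  site_config(cfg$pocket_residues, cfg$key_residues,
              target_name = if (is.null(cfg$target_name)) "" else cfg$target_name)
}

#' Built-in BRD9 binding-site configuration
#'
#' Pocket residues Gly43--Tyr106 monitored for apo-resemblance and the nine
#' residues regarded as crucial for ligand binding.
#'
#' @return A [site_config()].
#' @export
brd9_site <- function() {
  read_site_config(system.file("extdata", "brd9_site.yaml",
                               package = "mdtriage", mustWork = TRUE))
}

#' @export
print.site_config <- function(x, ...) {
  cat("site_config for", x$target_name, "-", nrow(x$pocket_residues),
      "pocket residues,", nrow(x$key_residues), "key residues\n")
  invisible(x)
}
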