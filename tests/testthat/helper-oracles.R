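# Independent oracles and small fixture builders used across the suite.

# Brute-force minimum RMSD over rotations: iterative Euler-angle (z-y-z)
# grid refinement with optimal translation by centroid alignment.
# Independent of the SVD route used by kabsch_superpose().
grid_min_rmsd <- function(mobile, reference, levels = 7L) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  n <- nrow(P)
  rot_zyz <- function(a, b, c) {
    rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0,
                               0, 0, 1), 3, byrow = TRUE)
    ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0,
                               -sin(t), 0, cos(t)), 3, byrow = TRUE)
    rz(a) %*% ry(b) %*% rz(c)
  }
  eval_rmsd <- function(ang) {
    R <- rot_zyz(ang[1], ang[2], ang[3])
    sqrt(sum((P %*% t(R) - Q)^2) / n)
  }
  centre <- c(pi, pi / 2, pi)
  span <- c(pi, pi / 2, pi)
  best <- c(0, 0, 0); best_val <- eval_rmsd(best)
  for (lev in seq_len(levels)) {
    grid <- expand.grid(
      a = seq(centre[1] - span[1], centre[1] + span[1], length.out = 13),
      b = seq(centre[2] - span[2], centre[2] + span[2], length.out = 13),
      c = seq(centre[3] - span[3], centre[3] + span[3], length.out = 13))
    vals <- apply(grid, 1, eval_rmsd)
    i <- which.min(vals)
    if (vals[i] < best_val) {
      best_val <- vals[i]
      best <- as.numeric(grid[i, ])
    }
    centre <- best
    span <- span * (2.2 / 12)   # twice the previous grid spacing
  }
  best_val
}

# A tiny hand-written PDB file; returns its path.
write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     rec = "ATOM  ", alt = " ", occ = 1.0, el = NULL) {
  if (is.null(el)) el <- substr(sub("^[0-9]*", "", name), 1, 1)
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%s%5d %-4s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, nm, alt, resname, chain, resno, x, y, z, occ, 0.0, el)
}

# Apply a global rigid motion to a structure or trajectory.
rigid_move <- function(xyz, angle_deg = 30, axis = c(1, 2, 3),
                       shift = c(4, -2, 7)) {
  R <- mdtriage:::.rotation_matrix(axis, angle_deg)
  sweep(xyz %*% R, 2, shift, "+")
}

extdata <- function(f) system.file("extdata", f, package = "mdtriage",
                                   mustWork = TRUE)
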