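# Internal helpers shared across modules.

# The twenty standard amino acids (3-letter codes, upper case).
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.BACKBONE_NAMES <- c("N", "CA", "C", "O")

# Residues whose carbon atoms count as hydrophobic contact partners.
.HYDROPHOBIC_RES <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET",
                      "TRP", "TYR", "CYS")

.WATER_RES <- c("HOH", "WAT", "TIP", "TIP3", "SPC", "SOL")

# Ring atom names of aromatic side chains.
.PROTEIN_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

.map_aa1to3 <- c(G = "GLY", A = "ALA", V = "VAL", L = "LEU", I = "ILE",
                 P = "PRO", F = "PHE", M = "MET", W = "TRP", C = "CYS",
                 S = "SER", T = "THR", Y = "TYR", N = "ASN", Q = "GLN",
                 D = "ASP", E = "GLU", K = "LYS", R = "ARG", H = "HIS")

# Parse residue labels such as "Gly43", "GLY43", "43" (or numerics) into a
# data.frame with columns resno and resname (resname NA when not given).
.parse_residues <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("resno") %in% names(x)))
    out <- data.frame(resno = as.integer(x$resno),
                      resname = if ("resname" %in% names(x))
                        toupper(as.character(x$resname)) else NA_character_,
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (is.numeric(x)) {
    return(data.frame(resno = as.integer(x), resname = NA_character_,
                      stringsAsFactors = FALSE))
  }
  x <- as.character(x)
  m <- regmatches(x, regexec("^([A-Za-z]*)([0-9]+)$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("cannot parse residue identifier(s): ",
         paste(x[bad], collapse = ", "))
  }
  resname <- toupper(vapply(m, `[`, "", 2L))
  resname[resname == ""] <- NA_character_
  data.frame(resno = as.integer(vapply(m, `[`, "", 3L)),
             resname = resname, stringsAsFactors = FALSE)
}

# Autodetect comma vs tab delimiter from the header line.
.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, comment.char = "#",
                    strip.white = TRUE)
}

.require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(what, ": missing required column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}

# Euclidean distances between the rows of a and rows of b (n x m matrix).
.crossdist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

.rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c_ + ux^2 * (1 - c_),      ux * uy * (1 - c_) - uz * s_, ux * uz * (1 - c_) + uy * s_,
    uy * ux * (1 - c_) + uz * s_, c_ + uy^2 * (1 - c_),      uy * uz * (1 - c_) - ux * s_,
    uz * ux * (1 - c_) - uy * s_, uz * uy * (1 - c_) + ux * s_, c_ + uz^2 * (1 - c_)
  ), nrow = 3, byrow = TRUE)
}
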