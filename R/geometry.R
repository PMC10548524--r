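## geometry: structure-level descriptors (signed dihedrals, ring-plane
## distances, contact shells) on single coordinate sets.

#' Single-structure container
#'
#' @param df data frame with columns `name`, `resname`, `resno`, `chain`,
#'   `element`, `x`, `y`, `z` (Angstrom) and optionally `occupancy` / `b`.
#'   Atom identifiers (chain, resno, name) must be unique.
#' @return A `structure_model` data frame.
#' @export
structure_model <- function(df) {
  need <- c("name", "resname", "resno", "chain", "element", "x", "y", "z")
  if (!is.data.frame(df) || !all(need %in% names(df)))
    .stopf("structure needs columns %s", paste(need, collapse = ", "))
  id <- paste(df$chain, df$resno, trimws(df$name))
  if (anyDuplicated(id))
    .stopf("duplicate atom identifier: %s", id[anyDuplicated(id)])
  if (anyNA(df[, c("x", "y", "z")])) .stopf("missing coordinates")
  class(df) <- c("structure_model", "data.frame")
  df
}

#' Read a single-model PDB file as a structure
#'
#' @param path PDB file (first model is used if several are present).
#' @return A [structure_model()].
#' @export
read_structure_pdb <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  structure_model(data.frame(
    name = trimws(at$elety), resname = at$resid, resno = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(trimws(at$elety), 1, 1), at$elesy),
    x = at$x, y = at$y, z = at$z,
    occupancy = at$o, b = at$b, stringsAsFactors = FALSE))
}

## Row index of a named atom (optionally qualified by resno/chain).
.atom_idx <- function(structure, name, resno = NULL, chain = NULL) {
  hit <- trimws(structure$name) == trimws(name)
  if (!is.null(resno)) hit <- hit & structure$resno == resno
  if (!is.null(chain)) hit <- hit & structure$chain == chain
  w <- which(hit)
  if (length(w) == 0) .stopf("atom '%s' not found", name)
  if (length(w) > 1) .stopf("atom '%s' is ambiguous (%d matches)", name,
                            length(w))
  w
}

.atom_xyz <- function(structure, name, resno = NULL, chain = NULL)
  as.numeric(structure[.atom_idx(structure, name, resno, chain),
                       c("x", "y", "z")])

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking from p2 towards p3, a clockwise rotation
#' of the p3-p4 bond relative to the p1-p2 bond is positive. The result is
#' in degrees in (-180, 180]. For the ligand-dioxygen dihedral Phi the
#' points are, in order, C4, C2, O2, O1.
#'
#' @param p1,p2,p3,p4 numeric length-3 points, Angstrom.
#' @return signed angle, degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sqrt(sum(b1^2)) < 1e-12 || sqrt(sum(b2^2)) < 1e-12 ||
      sqrt(sum(b3^2)) < 1e-12)
    .stopf("degenerate geometry: coincident consecutive points")
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    .stopf("degenerate geometry: colinear bond triplet")
  b2n <- b2 / sqrt(sum(b2^2))
  m1 <- .cross3(n1, b2n)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang == -180) 180 else ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Distance from a point to the least-squares plane of a set of atoms
#'
#' The plane is the total-least-squares fit through the ring atoms (normal =
#' smallest principal axis of the centered coordinates), appropriate for
#' slightly puckered rings. Returns the unsigned distance.
#'
#' @param point numeric length-3, Angstrom.
#' @param ring_atoms numeric matrix (>= 3 rows) of ring-atom coordinates.
#' @return distance, Angstrom.
#' @export
plane_distance <- function(point, ring_atoms) {
  ring_atoms <- rbind(ring_atoms)
  if (nrow(ring_atoms) < 3) .stopf("need at least 3 ring atoms")
  ctr <- colMeans(ring_atoms)
  X <- sweep(ring_atoms, 2, ctr)
  sv <- svd(X)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    .stopf("ring atoms are colinear: plane undefined")
  normal <- sv$v[, 3]
  abs(sum((point - ctr) * normal))
}

#' Atoms within a distance shell of a center atom
#'
#' Returns every atom (excluding the center itself) whose distance d from
#' the center satisfies `r_min <= d <= r_max`, sorted by distance with ties
#' broken by atom identifier (chain, residue number, atom name).
#'
#' @param structure a [structure_model()].
#' @param center center atom name (optionally qualified via `resno`,
#'   `chain`) or an index into the structure.
#' @param r_min,r_max shell radii, Angstrom (0 <= r_min <= r_max).
#' @param resno,chain optional qualifiers for a center given by name.
#' @return data frame: the shell atoms' identity columns plus `distance_A`.
#' @export
contact_shell <- function(structure, center, r_min = 0, r_max,
                          resno = NULL, chain = NULL) {
  stopifnot(inherits(structure, "structure_model"))
  if (r_min < 0 || r_max < r_min) .stopf("need 0 <= r_min <= r_max")
  if (is.numeric(center)) {
    self <- as.integer(center)
    if (self < 1 || self > nrow(structure)) .stopf("center index out of range")
  } else {
    self <- .atom_idx(structure, center, resno, chain)
  }
  cxyz <- as.numeric(structure[self, c("x", "y", "z")])
  d <- sqrt((structure$x - cxyz[1])^2 + (structure$y - cxyz[2])^2 +
            (structure$z - cxyz[3])^2)
  keep <- which(d >= r_min & d <= r_max)
  keep <- setdiff(keep, self)
  out <- structure[keep, c("name", "resname", "resno", "chain", "element")]
  out$distance_A <- d[keep]
  ord <- order(out$distance_A, out$chain, out$resno, trimws(out$name))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  as.data.frame(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
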