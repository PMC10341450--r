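# Side-chain dihedrals, named-atom distance distributions and up/down
# orientation classification.

#' Signed dihedral angle of four points
#'
#' Standard IUPAC convention, returned in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors (or a 4 x 3 matrix as
#'   \code{p1}).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  if (is.matrix(p1) && nrow(p1) == 4) {
    p4 <- p1[4, ]; p3 <- p1[3, ]; p2 <- p1[2, ]; p1 <- p1[1, ]
  }
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-12 || sqrt(sum(n2^2)) < 1e-12)
    stop("undefined dihedral: collinear atoms")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -atan2(y, x) * 180 / pi  # IUPAC sign convention
  if (ang <= -180) ang <- ang + 360
  ang
}

# chi-angle atom names per residue type (CHARMM/IUPAC), chi1..chi4 where
# applicable
.chi_atoms <- list(
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  HSD = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  HSE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")))

#' Side-chain chi dihedral series for one residue
#'
#' @param traj a \code{cf_trajectory}.
#' @param residue data.frame row with \code{chain} and \code{resid}.
#' @return data.frame: \code{frame}, one column per available chi angle
#'   (degrees).
#' @export
chi_dihedrals <- function(traj, residue) {
  sel <- select_atoms(traj$topology, chain = residue$chain,
                      resid = residue$resid)
  if (length(sel) == 0) stop("residue not found")
  rt <- traj$topology$resname[sel[1]]
  defs <- .chi_atoms[[rt]]
  if (is.null(defs)) stop("no chi angles defined for residue type ", rt)
  nm <- traj$topology$name[sel]
  out <- data.frame(frame = seq_len(n_frames(traj)))
  for (k in seq_along(defs)) {
    ids <- vapply(defs[[k]], function(a) {
      i <- sel[nm == a]
      if (length(i) != 1)
        stop(sprintf("atom %s missing in residue %s:%d", a,
                     residue$chain, residue$resid))
      i
    }, integer(1))
    out[[paste0("chi", k)]] <- vapply(seq_len(n_frames(traj)), function(f) {
      fc <- frame_coords(traj, f)
      dihedral_angle(fc[ids[1], ], fc[ids[2], ], fc[ids[3], ], fc[ids[4], ])
    }, numeric(1))
  }
  out
}

# measurement atoms for inter-residue distances: the polar side-chain atom
# (or the carboxyl/imidazole carbon bearing the equivalent atoms)
.distance_rule <- list(
  TYR = "OH", SER = "OG", THR = "OG1", LYS = "NZ",
  ASN = c("ND2", "OD1"), GLN = c("NE2", "OE1"),
  HIS = "CE1", HSD = "CE1", HSE = "CE1",
  ASP = "CG", ASPP = "CG", GLU = "CD", GLUP = "CD")

#' Measurement-atom rule for a residue type
#'
#' @param resname residue type.
#' @return Character vector of tracked atom names (two for Asn/Gln).
#' @export
distance_rule_atoms <- function(resname) {
  r <- .distance_rule[[resname]]
  if (is.null(r)) stop("no distance rule for residue type ", resname)
  r
}

#' Inter-residue distance series between rule atoms
#'
#' Per-frame distances between the measurement atoms of two residues; when
#' a residue type tracks two atoms (Asn: ND2 and OD1) one series per atom
#' combination is returned.
#'
#' @param traj a \code{cf_trajectory}.
#' @param res_a,res_b data.frame rows with \code{chain}, \code{resid}.
#' @param atoms_a,atoms_b optional explicit atom names overriding the rule.
#' @return data.frame: \code{frame} plus one distance column (Angstrom) per
#'   atom pair, named \code{atomA-atomB}.
#' @export
residue_distance_series <- function(traj, res_a, res_b,
                                    atoms_a = NULL, atoms_b = NULL) {
  find <- function(res, atoms) {
    sel <- select_atoms(traj$topology, chain = res$chain, resid = res$resid)
    if (length(sel) == 0)
      stop(sprintf("residue %s:%d not found", res$chain, res$resid))
    if (is.null(atoms))
      atoms <- distance_rule_atoms(traj$topology$resname[sel[1]])
    idx <- vapply(atoms, function(a) {
      i <- sel[traj$topology$name[sel] == a]
      if (length(i) != 1)
        stop(sprintf("atom %s missing in residue %s:%d", a, res$chain,
                     res$resid))
      i
    }, integer(1))
    setNames(idx, atoms)
  }
  ia <- find(res_a, atoms_a)
  ib <- find(res_b, atoms_b)
  out <- data.frame(frame = seq_len(n_frames(traj)))
  for (a in names(ia)) for (b in names(ib)) {
    ca <- traj$xyz[, (3 * ia[[a]] - 2):(3 * ia[[a]]), drop = FALSE]
    cb <- traj$xyz[, (3 * ib[[b]] - 2):(3 * ib[[b]]), drop = FALSE]
    out[[paste0(a, "-", b)]] <- sqrt(rowSums((ca - cb)^2))
  }
  out
}

#' Histogram of a distance series
#'
#' @param values distances in Angstrom.
#' @param bin bin width (default 0.1 Angstrom).
#' @return data.frame: bin \code{mid}, \code{count}, \code{density}.
#' @export
distance_histogram <- function(values, bin = 0.1) {
  rng <- range(values)
  breaks <- seq(floor(rng[1] / bin) * bin, ceiling(rng[2] / bin) * bin + bin,
                by = bin)
  h <- hist(values, breaks = breaks, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts, density = h$density)
}

#' Up/down side-chain orientation series
#'
#' A residue is "up" in a frame when the projection of its Calpha-to-rule-
#' atom vector onto the channel axis (oriented N-side to P-side) is
#' positive, "down" otherwise (a zero projection counts as down -- the
#' documented boundary convention).
#'
#' @param traj a \code{cf_trajectory}.
#' @param residue data.frame row with \code{chain}, \code{resid}.
#' @param axis length-3 channel-axis vector (N to P), e.g.
#'   \code{cylinder$axis}.
#' @param rule_atom optional explicit atom name (default: first rule atom).
#' @param dead_zone projections with absolute value below this (Angstrom)
#'   may be labelled \code{NA} when positive; default 0 (hard boundary).
#' @return Character vector of \code{"up"}/\code{"down"} per frame.
#' @export
classify_orientation <- function(traj, residue, axis, rule_atom = NULL,
                                 dead_zone = 0) {
  sel <- select_atoms(traj$topology, chain = residue$chain,
                      resid = residue$resid)
  if (length(sel) == 0) stop("residue not found")
  if (is.null(rule_atom))
    rule_atom <- distance_rule_atoms(traj$topology$resname[sel[1]])[1]
  tip <- sel[traj$topology$name[sel] == rule_atom]
  ca <- sel[traj$topology$name[sel] == "CA"]
  if (length(tip) != 1 || length(ca) != 1)
    stop("rule atom or Calpha missing for orientation")
  u <- axis / sqrt(sum(axis^2))
  vt <- traj$xyz[, (3 * tip - 2):(3 * tip), drop = FALSE] -
    traj$xyz[, (3 * ca - 2):(3 * ca), drop = FALSE]
  if (any(rowSums(vt^2) < 1e-20))
    stop("zero-length side-chain vector")
  proj <- as.vector(vt %*% u)
  lab <- ifelse(proj > dead_zone, "up", "down")
  lab
}
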