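#' @importFrom stats sd setNames rexp runif rnorm dist coef residuals
#' @importFrom graphics hist
#' @importFrom utils write.csv
NULL

#' Construct an atom topology table
#'
#' A topology is a plain \code{data.frame} with one row per atom and the
#' columns \code{index}, \code{name}, \code{resname}, \code{resid},
#' \code{chain}, \code{segid}, \code{mass} and \code{charge}.  Charges may be
#' \code{NA} (they are only required for electrostatics).
#'
#' @param name,resname,chain,segid character vectors (recycled).
#' @param resid integer residue ids.
#' @param mass atomic masses in amu; must be positive where set.
#' @param charge partial charges in elementary charge units, or \code{NA}.
#' @return A \code{data.frame} of class \code{cf_topology}.
#' @export
cf_topology <- function(name, resname, resid, chain = "A", segid = chain,
                        mass = NA_real_, charge = NA_real_) {
  n <- max(length(name), length(resid))
  top <- data.frame(
    index = seq_len(n),
    name = rep_len(as.character(name), n),
    resname = rep_len(as.character(resname), n),
    resid = rep_len(as.integer(resid), n),
    chain = rep_len(as.character(chain), n),
    segid = rep_len(as.character(segid), n),
    mass = rep_len(as.numeric(mass), n),
    charge = rep_len(as.numeric(charge), n),
    stringsAsFactors = FALSE
  )
  if (any(!is.na(top$mass) & top$mass <= 0))
    stop("atom masses must be positive where set")
  class(top) <- c("cf_topology", "data.frame")
  top
}

#' Construct a trajectory object
#'
#' @param topology a \code{cf_topology}.
#' @param xyz numeric matrix of dimension \code{n_frames x (3 * n_atoms)},
#'   coordinates in Angstrom ordered x1,y1,z1,x2,...
#' @param times frame times in ps; if \code{NULL}, \code{0, dt, 2 dt, ...}
#'   with \code{dt = frame_interval}.
#' @param box optional orthorhombic box edge lengths (length-3 vector), Angstrom.
#' @param frame_interval saving interval in ps (default 2, the usual value
#'   for production runs saved every 2 ps).
#' @return An object of class \code{cf_trajectory}.
#' @export
cf_trajectory <- function(topology, xyz, times = NULL, box = NULL,
                          frame_interval = 2) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(topology))
    stop(sprintf("coordinate columns (%d) do not match 3 x atom count (%d)",
                 ncol(xyz), 3L * nrow(topology)))
  if (any(!is.finite(xyz))) stop("non-finite coordinates in trajectory")
  if (frame_interval <= 0) stop("frame_interval must be positive")
  if (is.null(times)) times <- (seq_len(nrow(xyz)) - 1) * frame_interval
  if (length(times) != nrow(xyz)) stop("times length must equal frame count")
  if (nrow(xyz) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(topology = topology, xyz = xyz, times = as.numeric(times),
                 box = box, frame_interval = frame_interval),
            class = "cf_trajectory")
}

#' @export
print.cf_trajectory <- function(x, ...) {
  cat(sprintf("cf_trajectory: %d atoms, %d frames, %.6g-%.6g ps\n",
              nrow(x$topology), nrow(x$xyz),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a \code{cf_trajectory}.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame
#'
#' @param traj a \code{cf_trajectory}.
#' @param i frame index (1-based).
#' @return \code{n_atoms x 3} matrix, Angstrom.
#' @export
frame_coords <- function(traj, i) {
  v <- traj$xyz[i, ]
  matrix(v, ncol = 3, byrow = TRUE)
}

#' Select atoms from a topology
#'
#' All given filters are combined with AND; vector values are ORed within a
#' filter (e.g. \code{name = c("O","H1")}).
#'
#' @param topology a \code{cf_topology}.
#' @param name,resname,chain,segid optional character filters.
#' @param resid optional integer filter.
#' @return Integer vector of atom indices (topology row numbers).
#' @export
select_atoms <- function(topology, name = NULL, resname = NULL, resid = NULL,
                         chain = NULL, segid = NULL) {
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(name))    keep <- keep & topology$name %in% name
  if (!is.null(resname)) keep <- keep & topology$resname %in% resname
  if (!is.null(resid))   keep <- keep & topology$resid %in% resid
  if (!is.null(chain))   keep <- keep & topology$chain %in% chain
  if (!is.null(segid))   keep <- keep & topology$segid %in% segid
  which(keep)
}

#' Read a structure file (PDB or PSF)
#'
#' PDB files are parsed with \pkg{bio3d}; ATOM/HETATM records are first
#' validated for minimal column width so that malformed lines are reported
#' with their line number.  PSF files (X-PLOR/CHARMM dialect) supply partial
#' charges and masses.
#'
#' @param path file path.
#' @param format \code{"pdb"} or \code{"psf"}; default guessed from the
#'   file extension.
#' @return A list with \code{topology} (a \code{cf_topology}) and, for PDB,
#'   \code{coords} (the first model's \code{n_atoms x 3} matrix).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "psf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("pdb", "psf"))
      stop("unknown structure format: ", ext)
    format <- ext
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "pdb") read_pdb_structure(path) else read_psf_structure(path)
}

read_pdb_structure <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  bad <- which(is_atom & nchar(lines) < 54)
  if (length(bad))
    stop(sprintf("malformed ATOM/HETATM record at line %d of %s",
                 bad[1], path))
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  mass <- atom_mass_from_name(at$elety, at$elesy)
  top <- cf_topology(name = at$elety, resname = at$resid,
                     resid = at$resno,
                     chain = ifelse(is.na(at$chain), "A", at$chain),
                     segid = ifelse(is.na(at$segid) | at$segid == "",
                                    ifelse(is.na(at$chain), "A", at$chain),
                                    at$segid),
                     mass = mass, charge = NA_real_)
  coords <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  nmod <- nrow(pdb$xyz)
  xyz <- pdb$xyz
  list(topology = top, coords = coords, n_models = nmod, xyz = unclass(xyz))
}

# element masses used when only a PDB (no PSF) is available
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974, FE = 55.845, CU = 63.546,
                     NA. = 22.99, MG = 24.305, ZN = 65.38, CL = 35.45)

atom_mass_from_name <- function(name, elesy = NULL) {
  el <- toupper(ifelse(!is.null(elesy) & !is.na(elesy) & elesy != "",
                       elesy, substr(trimws(name), 1, 1)))
  m <- .element_masses[el]
  unname(ifelse(is.na(m), 12.011, m))
}

#' Read trajectory coordinates (DCD or multi-model PDB)
#'
#' DCD files (CHARMM/NAMD 32-bit dialect) are read with
#' \code{bio3d::read.dcd}.  Frame times come from \code{frame_interval}
#' (saved DCD headers rarely carry reliable physical times), starting at 0.
#'
#' @param path trajectory file.
#' @param topology matching \code{cf_topology}.
#' @param frame_interval ps between saved frames (default 2).
#' @param format \code{"dcd"} or \code{"pdb"}; guessed from extension.
#' @return A \code{cf_trajectory}.
#' @export
read_trajectory <- function(path, topology, frame_interval = 2,
                            format = c("auto", "dcd", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "dcd") {
    if (file.info(path)$size < 100) stop("no frames in trajectory ", path)
    xyz <- suppressWarnings(bio3d::read.dcd(path, verbose = FALSE))
    xyz <- unclass(xyz)
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    if (nrow(xyz) == 0) stop("no frames in trajectory ", path)
    if (ncol(xyz) != 3L * nrow(topology))
      stop(sprintf("trajectory has %d atoms but topology has %d",
                   ncol(xyz) %/% 3L, nrow(topology)))
    cf_trajectory(topology, xyz, frame_interval = frame_interval)
  } else if (format == "pdb") {
    s <- read_pdb_structure(path)
    if (nrow(s$topology) != nrow(topology))
      stop(sprintf("trajectory has %d atoms but topology has %d",
                   nrow(s$topology), nrow(topology)))
    cf_trajectory(topology, s$xyz, frame_interval = frame_interval)
  } else stop("unknown trajectory format: ", format)
}

#' Discard the equilibration part of a trajectory
#'
#' Frames with \code{time >= t_equil} are retained.  The conventional
#' analysis window discards the first 40 ns of a 200 ns production run,
#' leaving 160 ns.
#'
#' @param traj a \code{cf_trajectory}.
#' @param t_equil equilibration time to discard, in ns.
#' @return The truncated \code{cf_trajectory}.
#' @export
discard_equilibration <- function(traj, t_equil) {
  stopifnot(t_equil >= 0)
  keep <- traj$times >= t_equil * 1000
  if (!any(keep)) stop("empty analysis window: all frames discarded")
  cf_trajectory(traj$topology, traj$xyz[keep, , drop = FALSE],
                times = traj$times[keep], box = traj$box,
                frame_interval = traj$frame_interval)
}

#' Mass-weighted centre of mass of a selection in one frame
#'
#' @param traj a \code{cf_trajectory} (or an \code{n_atoms x 3} matrix via
#'   \code{coords}).
#' @param selection integer atom indices.
#' @param frame frame index, ignored when \code{coords} given.
#' @param coords optional explicit coordinate matrix.
#' @return length-3 numeric vector, Angstrom.
#' @export
center_of_mass <- function(traj, selection, frame = 1, coords = NULL) {
  if (is.null(coords)) coords <- frame_coords(traj, frame)
  if (length(selection) == 0) stop("empty selection")
  m <- traj$topology$mass[selection]
  if (any(is.na(m))) stop("masses not set for selection")
  tm <- sum(m)
  if (tm <= 0) stop("zero total mass")
  colSums(coords[selection, , drop = FALSE] * m) / tm
}

#' Frame closest to the time-averaged structure ("median structure")
#'
#' Per-atom coordinates of the selection are averaged over all frames; the
#' frame with the lowest RMSD from that average is returned (ties: lowest
#' index).  No superposition is applied: trajectories are assumed
#' pre-aligned or generated in a fixed frame.
#'
#' @param traj a \code{cf_trajectory}.
#' @param selection atom indices used for the RMSD (default: all atoms).
#' @return Integer frame index (1-based).
#' @export
median_structure <- function(traj, selection = seq_len(nrow(traj$topology))) {
  if (length(selection) == 0) stop("empty selection")
  cols <- as.vector(rbind(3 * selection - 2, 3 * selection - 1, 3 * selection))
  sub <- traj$xyz[, cols, drop = FALSE]
  avg <- colMeans(sub)
  dev <- sweep(sub, 2, avg)
  msd <- rowMeans(dev^2) * 3  # per-coordinate -> per-atom x3 constant factor
  which.min(msd)
}

#' Optional Kabsch rigid-body alignment of all frames to a reference frame
#'
#' Off by default in all pipelines; provided for externally produced
#' trajectories that are not in a fixed laboratory frame.
#'
#' @param traj a \code{cf_trajectory}.
#' @param selection atoms used for the fit.
#' @param ref reference frame index.
#' @return Aligned \code{cf_trajectory}.
#' @export
align_trajectory <- function(traj, selection = seq_len(nrow(traj$topology)),
                             ref = 1) {
  refc <- frame_coords(traj, ref)[selection, , drop = FALSE]
  ref0 <- sweep(refc, 2, colMeans(refc))
  xyz <- traj$xyz
  for (i in seq_len(nrow(xyz))) {
    fc <- frame_coords(traj, i)
    mob <- fc[selection, , drop = FALSE]
    mc <- colMeans(mob)
    m0 <- sweep(mob, 2, mc)
    s <- svd(crossprod(m0, ref0))
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    rot <- sweep(fc, 2, mc) %*% t(R)
    xyz[i, ] <- as.vector(t(sweep(rot, 2, colMeans(refc), `+`)))
  }
  cf_trajectory(traj$topology, xyz, times = traj$times, box = traj$box,
                frame_interval = traj$frame_interval)
}
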