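# PSF (X-PLOR/CHARMM) atoms section and a CHARMM 32-bit DCD writer.
# bio3d covers PDB read/write and DCD read; it has no PSF parser and no DCD
# writer, so those two live here.

read_psf_structure <- function(path) {
  lines <- readLines(path)
  if (!grepl("^PSF", lines[1])) stop("not a PSF file: ", path)
  natom_line <- grep("!NATOM", lines)
  if (length(natom_line) == 0) stop("PSF without !NATOM section: ", path)
  natom <- as.integer(sub("^\\s*(\\d+).*", "\\1", lines[natom_line[1]]))
  body <- lines[(natom_line[1] + 1):(natom_line[1] + natom)]
  toks <- strsplit(trimws(body), "\\s+")
  nt <- lengths(toks)
  bad <- which(nt < 8)
  if (length(bad))
    stop(sprintf("malformed PSF atom record at line %d of %s",
                 natom_line[1] + bad[1], path))
  f <- function(k) vapply(toks, `[[`, "", k)
  top <- cf_topology(name = f(5), resname = f(4),
                     resid = as.integer(f(3)),
                     chain = f(2), segid = f(2),
                     mass = as.numeric(f(8)),
                     charge = as.numeric(f(7)))
  list(topology = top, coords = NULL)
}

#' Write a minimal PSF file (atoms section)
#'
#' Enough of the X-PLOR/CHARMM PSF dialect to carry names, residues,
#' charges and masses; the bond section lists the explicit bonds given
#' (used for donor-hydrogen tables), or none.
#'
#' @param topology a \code{cf_topology}.
#' @param path output file.
#' @param bonds optional 2-column integer matrix of bonded atom index pairs.
#' @export
write_psf <- function(topology, path, bonds = NULL) {
  n <- nrow(topology)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("PSF", "", sprintf("%8d !NTITLE", 1L),
               " REMARKS generated by channelflow", ""), con)
  writeLines(sprintf("%8d !NATOM", n), con)
  writeLines(sprintf("%8d %-4s %-4d %-4s %-4s %-4s %14.6f %13.4f %11d",
                     topology$index, substr(topology$segid, 1, 4),
                     topology$resid, substr(topology$resname, 1, 4),
                     substr(topology$name, 1, 4),
                     substr(topology$name, 1, 4),
                     ifelse(is.na(topology$charge), 0, topology$charge),
                     ifelse(is.na(topology$mass), 0, topology$mass), 0L), con)
  nb <- if (is.null(bonds)) 0L else nrow(bonds)
  writeLines(c("", sprintf("%8d !NBOND: bonds", nb)), con)
  if (nb > 0) {
    flat <- as.integer(t(bonds))
    rows <- split(flat, (seq_along(flat) - 1) %/% 8)
    writeLines(vapply(rows, function(r) paste(sprintf("%8d", r), collapse = ""),
                      ""), con)
  }
  invisible(path)
}

#' Write a trajectory as a CHARMM-dialect binary DCD file
#'
#' 32-bit Fortran-record DCD with single-precision coordinates; readable by
#' \code{bio3d::read.dcd} and the usual MD toolchains.  Coordinates are
#' stored to float precision (about 1e-5 relative).
#'
#' @param traj a \code{cf_trajectory}.
#' @param path output file.
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nfrm <- n_frames(traj)
  natom <- nrow(traj$topology)
  has_box <- !is.null(traj$box)
  rec <- function(payload_writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
    payload_writer()
    writeBin(as.integer(nbytes), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nfrm                    # number of frames
  icntrl[2] <- 1L                      # first step
  icntrl[3] <- 1L                      # save interval (steps)
  icntrl[4] <- nfrm
  icntrl[10] <- 0L                     # timestep bit-pattern, unused here
  icntrl[11] <- if (has_box) 1L else 0L
  icntrl[20] <- 24L                    # CHARMM version stamp
  rec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    writeBin(icntrl, con, size = 4, endian = "little")
  }, 84)
  title <- sprintf("%-80s", "channelflow synthetic trajectory")
  rec(function() {
    writeBin(1L, con, size = 4, endian = "little")
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  rec(function() writeBin(as.integer(natom), con, size = 4,
                          endian = "little"), 4)
  for (i in seq_len(nfrm)) {
    fc <- frame_coords(traj, i)
    if (has_box) {
      b <- traj$box
      cell <- c(b[1], 0, b[2], 0, 0, b[3])  # unit cell, cos(angles)=0 => 90 deg
      rec(function() writeBin(as.numeric(cell), con, size = 8,
                              endian = "little"), 48)
    }
    for (k in 1:3)
      rec(function() writeBin(as.numeric(fc[, k]), con, size = 4,
                              endian = "little"), 4 * natom)
  }
  invisible(path)
}

#' Write a topology + coordinates as a PDB file
#'
#' @param topology a \code{cf_topology}.
#' @param coords \code{n_atoms x 3} coordinate matrix, Angstrom.
#' @param path output file.
#' @export
write_pdb_structure <- function(topology, coords, path) {
  # fixed-column ATOM records; 4-character residue names occupy columns
  # 18-21 (CHARMM convention), chain id column 22, segid columns 73-76
  name <- topology$name
  # short atom names start in column 14 by convention
  name <- ifelse(nchar(name) < 4, paste0(" ", name), name)
  lines <- sprintf(
    "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s",
    topology$index %% 100000, name, substr(topology$resname, 1, 4),
    substr(topology$chain, 1, 1), topology$resid %% 10000,
    coords[, 1], coords[, 2], coords[, 3], 1, 0,
    substr(topology$segid, 1, 4))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
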