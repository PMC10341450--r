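# Channel definition, per-frame polyhedron census, enveloping cylinder,
# height slices, 2D occupancy projections and channel-width series.

#' Define a channel by its corner residues
#'
#' The channel volume is the convex polyhedron spanned by the centres of
#' mass of the corner residues, rebuilt every frame.  The enveloping
#' cylinder is anchored on the Calpha centres of mass of the bottom and top
#' residue groups; when these are not given they default to the single
#' corner residue with the extreme projection on the dominant principal
#' axis of the corner points.
#'
#' @param name channel name, e.g. \code{"D"} or \code{"K"}.
#' @param corners data.frame with columns \code{chain}, \code{resid} and
#'   optionally \code{resname}.
#' @param width_pairs optional data.frame with columns \code{chain_a},
#'   \code{resid_a}, \code{chain_b}, \code{resid_b}: Calpha pairs measuring
#'   channel width.
#' @param key_residues optional data.frame (\code{chain}, \code{resid},
#'   \code{label}) of the residues used in H-bond/network analyses.
#' @param bottom_residues,top_residues optional integer row indices into
#'   \code{corners} naming the axis end groups.
#' @return Object of class \code{cf_channel}.
#' @export
channel_definition <- function(name, corners, width_pairs = NULL,
                               key_residues = NULL,
                               bottom_residues = NULL, top_residues = NULL) {
  stopifnot(is.data.frame(corners), all(c("chain", "resid") %in% names(corners)))
  if (nrow(corners) < 4)
    stop("need at least 4 corner residues for a 3D polyhedron")
  structure(list(name = name, corners = corners, width_pairs = width_pairs,
                 key_residues = key_residues,
                 bottom_residues = bottom_residues,
                 top_residues = top_residues),
            class = "cf_channel")
}

#' Built-in channel definitions
#'
#' Returns the shipped corner-residue lists for the two proton-uptake
#' channels of Cytochrome c Oxidase (D- and K-channel), read from the
#' package's \code{channels.yml}.
#'
#' @return Named list of \code{cf_channel} objects.
#' @export
default_channels <- function() {
  path <- system.file("extdata", "channels.yml", package = "channelflow")
  cfg <- yaml::read_yaml(path)
  lapply(cfg$channels, function(ch) {
    corners <- do.call(rbind, lapply(ch$corners, as.data.frame))
    wp <- if (!is.null(ch$width_pairs))
      do.call(rbind, lapply(ch$width_pairs, as.data.frame)) else NULL
    kr <- if (!is.null(ch$key_residues))
      do.call(rbind, lapply(ch$key_residues, as.data.frame)) else NULL
    channel_definition(ch$name, corners, wp, kr)
  })
}

corner_atom_sets <- function(topology, channel) {
  lapply(seq_len(nrow(channel$corners)), function(i) {
    row <- channel$corners[i, ]
    sel <- select_atoms(topology, resid = row$resid, chain = row$chain)
    if (length(sel) == 0)
      stop(sprintf("corner residue %s:%d not found in topology",
                   row$chain, row$resid))
    sel
  })
}

corner_coms <- function(traj, channel, frame,
                        sets = corner_atom_sets(traj$topology, channel)) {
  fc <- frame_coords(traj, frame)
  t(vapply(sets, function(s) center_of_mass(traj, s, coords = fc),
           numeric(3)))
}

#' Per-frame channel polyhedron
#'
#' Convex hull of the corner-residue centres of mass in one frame.
#'
#' @param traj a \code{cf_trajectory}.
#' @param channel a \code{cf_channel}.
#' @param frame frame index.
#' @return A \code{cf_hull} with an added \code{frame} element.
#' @export
build_polyhedron <- function(traj, channel, frame) {
  hull <- convex_hull_3d(corner_coms(traj, channel, frame))
  hull$frame <- frame
  hull
}

water_oxygen_indices <- function(topology,
                                 water_resnames = c("TIP3", "HOH", "WAT",
                                                    "SOL", "TIP"),
                                 oxygen_names = c("O", "OH2", "OW")) {
  select_atoms(topology, resname = water_resnames, name = oxygen_names)
}

water_key <- function(topology, idx) {
  paste0(topology$segid[idx], ":", topology$resid[idx])
}

#' Enveloping cylinder of a channel
#'
#' The axis runs from the Calpha centre of mass of the bottom residue
#' group to that of the top group in the median-structure frame, is
#' elongated by 10\% (5\% per end) to cover entrance and exit, and capped
#' symmetrically at \code{n_slices * slice_thickness} (30 Angstrom by
#' default).  The cylinder is built once per trajectory and held fixed.
#'
#' @param traj a \code{cf_trajectory}.
#' @param channel a \code{cf_channel}.
#' @param median_frame frame index (from \code{\link{median_structure}});
#'   default: computed on the corner-residue atoms.
#' @param radius cylinder radius, Angstrom (default 9.5).
#' @param n_slices number of axial slices (default 15).
#' @param slice_thickness slice thickness, Angstrom (default 2).
#' @param elongation fractional axis elongation (default 0.10, split evenly).
#' @param axis_hint approximate channel direction used to orient the axis
#'   bottom-to-top (N-side to P-side); default +z.
#' @return Object of class \code{cf_cylinder}: \code{base}, \code{tip},
#'   unit \code{axis}, orthonormal laterals \code{e1}, \code{e2},
#'   \code{length}, \code{radius}, \code{n_slices}, \code{slice_thickness}.
#' @export
build_cylinder <- function(traj, channel, median_frame = NULL, radius = 9.5,
                           n_slices = 15, slice_thickness = 2,
                           elongation = 0.10, axis_hint = c(0, 0, 1)) {
  sets <- corner_atom_sets(traj$topology, channel)
  if (is.null(median_frame))
    median_frame <- median_structure(traj, unlist(sets))
  fc <- frame_coords(traj, median_frame)
  coms <- corner_coms(traj, channel, median_frame, sets)

  bot <- channel$bottom_residues
  top <- channel$top_residues
  if (is.null(bot) || is.null(top)) {
    ctr <- sweep(coms, 2, colMeans(coms))
    pc1 <- svd(ctr)$v[, 1]
    if (sum(pc1 * axis_hint) < 0) pc1 <- -pc1
    proj <- ctr %*% pc1
    if (is.null(bot)) bot <- which.min(proj)
    if (is.null(top)) top <- which.max(proj)
  }
  ca_com <- function(rows) {
    sel <- unlist(lapply(rows, function(i) {
      row <- channel$corners[i, ]
      s <- select_atoms(traj$topology, name = "CA", resid = row$resid,
                        chain = row$chain)
      if (length(s) == 0) s <- sets[[i]]  # fall back to whole residue
      s
    }))
    center_of_mass(traj, sel, coords = fc)
  }
  base <- ca_com(bot)
  tip <- ca_com(top)
  len0 <- sqrt(sum((tip - base)^2))
  if (len0 < 1e-9) stop("zero-length cylinder axis")
  u <- (tip - base) / len0
  len <- len0 * (1 + elongation)
  mid <- (base + tip) / 2
  max_len <- n_slices * slice_thickness
  if (len > max_len) len <- max_len
  base <- mid - u * len / 2
  tip <- mid + u * len / 2
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- cross3(u, ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(u, e1)
  structure(list(base = base, tip = tip, axis = u, e1 = e1, e2 = e2,
                 length = len, radius = radius, n_slices = n_slices,
                 slice_thickness = slice_thickness,
                 median_frame = median_frame),
            class = "cf_cylinder")
}

#' Assign points to cylinder height slices
#'
#' Slices are half-open intervals \code{[low, high)} along the axis,
#' numbered 1..\code{n_slices} from the base (entrance, N-side).  Points
#' radially outside the cylinder wall or axially outside
#' \code{[0, length)} get \code{NA}; a point exactly on the wall counts as
#' inside.
#'
#' @param points \code{m x 3} matrix or length-3 vector.
#' @param cylinder a \code{cf_cylinder}.
#' @return Integer vector: slice index in 1..n_slices, or \code{NA} outside.
#' @export
assign_slice <- function(points, cylinder) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  rel <- sweep(points, 2, cylinder$base)
  ax <- as.vector(rel %*% cylinder$axis)
  rad2 <- rowSums(rel^2) - ax^2
  rad2[rad2 < 0] <- 0
  out <- sqrt(rad2) > cylinder$radius | ax < 0 | ax >= cylinder$length
  s <- pmin(floor(ax / cylinder$slice_thickness) + 1L, cylinder$n_slices)
  s[out] <- NA_integer_
  as.integer(s)
}

#' Water census of a channel
#'
#' For every frame, rebuilds the corner polyhedron and records which water
#' molecules (by their oxygen position) lie inside it; also bins all waters
#' into the fixed enveloping cylinder's height slices.  The "ever-inside"
#' set collects every water that hit the polyhedron at least once over the
#' analysed frames.
#'
#' @param traj a \code{cf_trajectory} (already truncated to the analysis
#'   window).
#' @param channel a \code{cf_channel}.
#' @param cylinder optional prebuilt \code{cf_cylinder}; default built from
#'   the median structure of the corner atoms.
#' @param water_resnames,oxygen_names residue/atom names identifying water
#'   oxygens.
#' @param wrap if \code{TRUE} and the trajectory has a box, water oxygens
#'   are minimum-imaged to the cylinder midpoint before censusing.
#' @return Object of class \code{cf_hydration}: per-frame polyhedron counts
#'   and inside-id lists, ever-inside ids, per-frame per-slice count matrix,
#'   per-frame inside-cylinder counts, polyhedron volumes, the cylinder.
#' @export
water_census <- function(traj, channel, cylinder = NULL,
                         water_resnames = c("TIP3", "HOH", "WAT", "SOL",
                                            "TIP"),
                         oxygen_names = c("O", "OH2", "OW"),
                         wrap = !is.null(traj$box)) {
  wox <- water_oxygen_indices(traj$topology, water_resnames, oxygen_names)
  nf <- n_frames(traj)
  if (is.null(cylinder)) cylinder <- build_cylinder(traj, channel)
  if (length(wox) == 0) {
    warning("no water molecules in system; census is empty")
    return(structure(list(
      frame_counts = rep(0L, nf), inside_ids = rep(list(character(0)), nf),
      ever_inside = character(0),
      slice_counts = matrix(0L, nf, cylinder$n_slices),
      cylinder_counts = rep(0L, nf), volumes = rep(NA_real_, nf),
      cylinder = cylinder, channel = channel$name),
      class = "cf_hydration"))
  }
  keys <- water_key(traj$topology, wox)
  mid <- (cylinder$base + cylinder$tip) / 2
  counts <- integer(nf)
  vols <- numeric(nf)
  inside_ids <- vector("list", nf)
  slice_counts <- matrix(0L, nf, cylinder$n_slices)
  for (i in seq_len(nf)) {
    fc <- frame_coords(traj, i)
    pts <- fc[wox, , drop = FALSE]
    if (wrap && !is.null(traj$box))
      pts <- minimum_image(pts, mid, traj$box)
    poly <- convex_hull_3d(corner_coms(traj, channel, i))
    ins <- point_in_hull(pts, poly)
    counts[i] <- sum(ins)
    vols[i] <- poly$volume
    inside_ids[[i]] <- keys[ins]
    sl <- assign_slice(pts, cylinder)
    tab <- tabulate(sl[!is.na(sl)], nbins = cylinder$n_slices)
    slice_counts[i, ] <- tab
  }
  structure(list(frame_counts = counts, inside_ids = inside_ids,
                 ever_inside = unique(unlist(inside_ids)),
                 slice_counts = slice_counts,
                 cylinder_counts = as.integer(rowSums(slice_counts)),
                 volumes = vols, cylinder = cylinder,
                 channel = channel$name),
            class = "cf_hydration")
}

#' Minimum-image shift of points toward a reference
#'
#' Shifts each point by integer multiples of the orthorhombic box edges so
#' it lies in the image nearest the reference point.
#'
#' @param points \code{m x 3} matrix.
#' @param ref length-3 reference point.
#' @param box length-3 box edge lengths.
#' @export
minimum_image <- function(points, ref, box) {
  d <- sweep(points, 2, ref)
  shift <- round(sweep(d, 2, box, "/"))
  points - sweep(shift, 2, box, "*")
}

#' @export
print.cf_hydration <- function(x, ...) {
  cat(sprintf(paste0("cf_hydration (%s-channel): %d frames, mean %.2f ",
                     "waters in polyhedron, %d ever inside\n"),
              x$channel, length(x$frame_counts), mean(x$frame_counts),
              length(x$ever_inside)))
  invisible(x)
}

#' Mean water count per cylinder slice, with replica statistics
#'
#' @param records list of \code{cf_hydration}, one per replica.
#' @return data.frame with \code{slice}, \code{height} (slice midpoint along
#'   the axis, Angstrom), per-replica means, \code{mean} and \code{se}
#'   across replicas.
#' @export
height_profile <- function(records) {
  if (inherits(records, "cf_hydration")) records <- list(records)
  per_rep <- vapply(records, function(r) colMeans(r$slice_counts),
                    numeric(records[[1]]$cylinder$n_slices))
  per_rep <- matrix(per_rep, ncol = length(records))
  stats <- t(apply(per_rep, 1, function(v) {
    s <- replica_average(v)
    c(s$mean, s$se)
  }))
  cyl <- records[[1]]$cylinder
  data.frame(slice = seq_len(cyl$n_slices),
             height = (seq_len(cyl$n_slices) - 0.5) * cyl$slice_thickness,
             mean = stats[, 1], se = stats[, 2])
}

#' 2D projection of water occupancy inside the cylinder
#'
#' Water-oxygen positions inside the cylinder accumulated on a grid in the
#' channel-local frame: horizontal axis is the lateral coordinate along
#' \code{e1} (view \code{"xz"}) or \code{e2} (view \code{"yz"}, rotated 90
#' degrees about the channel axis), vertical axis is the axial height.
#'
#' @param traj a \code{cf_trajectory}.
#' @param cylinder a \code{cf_cylinder}.
#' @param view \code{"xz"} or \code{"yz"}.
#' @param bin grid resolution, Angstrom (default 0.5).
#' @param water_resnames,oxygen_names water identification.
#' @return List: \code{counts} matrix (rows: lateral bins, cols: axial
#'   bins), \code{lateral_breaks}, \code{axial_breaks}, \code{view}.
#' @export
project_occupancy <- function(traj, cylinder, view = c("xz", "yz"), bin = 0.5,
                              water_resnames = c("TIP3", "HOH", "WAT", "SOL",
                                                 "TIP"),
                              oxygen_names = c("O", "OH2", "OW")) {
  view <- match.arg(view)
  wox <- water_oxygen_indices(traj$topology, water_resnames, oxygen_names)
  lat_axis <- if (view == "xz") cylinder$e1 else cylinder$e2
  r <- cylinder$radius
  lb <- seq(-r, r + bin, by = bin)
  ab <- seq(0, cylinder$length + bin, by = bin)
  counts <- matrix(0L, length(lb) - 1, length(ab) - 1)
  for (i in seq_len(n_frames(traj))) {
    pts <- frame_coords(traj, i)[wox, , drop = FALSE]
    sl <- assign_slice(pts, cylinder)
    pts <- pts[!is.na(sl), , drop = FALSE]
    if (nrow(pts) == 0) next
    rel <- sweep(pts, 2, cylinder$base)
    lat <- as.vector(rel %*% lat_axis)
    axl <- as.vector(rel %*% cylinder$axis)
    il <- findInterval(lat, lb, rightmost.closed = FALSE)
    ia <- findInterval(axl, ab, rightmost.closed = FALSE)
    ok <- il >= 1 & il <= nrow(counts) & ia >= 1 & ia <= ncol(counts)
    for (k in which(ok)) counts[il[k], ia[k]] <- counts[il[k], ia[k]] + 1L
  }
  list(counts = counts, lateral_breaks = lb, axial_breaks = ab, view = view)
}

#' Channel-width distance series
#'
#' Per-frame Euclidean distances between the Calpha atoms of the declared
#' width pairs (a standard proxy for channel width).
#'
#' @param traj a \code{cf_trajectory}.
#' @param width_pairs data.frame with \code{chain_a}, \code{resid_a},
#'   \code{chain_b}, \code{resid_b} (as in \code{cf_channel$width_pairs}).
#' @return Matrix \code{n_frames x n_pairs} of distances in Angstrom, with
#'   column names \code{chain:resid-chain:resid}.
#' @export
channel_width <- function(traj, width_pairs) {
  get_ca <- function(chain, resid) {
    s <- select_atoms(traj$topology, name = "CA", resid = resid,
                      chain = chain)
    if (length(s) == 0)
      stop(sprintf("no Calpha atom for residue %s:%d", chain, resid))
    s[1]
  }
  out <- vapply(seq_len(nrow(width_pairs)), function(i) {
    a <- get_ca(width_pairs$chain_a[i], width_pairs$resid_a[i])
    b <- get_ca(width_pairs$chain_b[i], width_pairs$resid_b[i])
    ca <- traj$xyz[, (3 * a - 2):(3 * a), drop = FALSE]
    cb <- traj$xyz[, (3 * b - 2):(3 * b), drop = FALSE]
    sqrt(rowSums((ca - cb)^2))
  }, numeric(n_frames(traj)))
  out <- matrix(out, nrow = n_frames(traj))
  colnames(out) <- paste0(width_pairs$chain_a, ":", width_pairs$resid_a, "-",
                          width_pairs$chain_b, ":", width_pairs$resid_b)
  out
}
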