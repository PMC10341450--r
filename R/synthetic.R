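# Toy channel systems with exact ground truth: a prism-shaped cage of
# corner pseudo-residues, waters with controllable per-slice occupancy, an
# optional stationary hydronium, and donor/acceptor probe residues whose
# hydrogen bonds to a partner water switch on and off as a two-state
# Markov process with known rates.

#' Specification of a synthetic channel system
#'
#' The corner cage is two rings of single-atom pseudo-residues whose
#' convex hull is a regular prism; ring geometry is chosen so that the
#' enveloping cylinder built by the pipeline (10\% elongation, 30 Angstrom
#' cap) spans exactly \code{n_slices} slices.  Waters assigned to a slice
#' stay in that slice (resampled i.i.d. or reflected-random-walk
#' diffusion), so per-slice counts are exact by construction; bulk waters
#' live far outside the cylinder.  Probe residues sit outside the channel
#' wall with a dedicated partner water that is moved into perfect
#' hydrogen-bond geometry whenever the probe's Markov state is "on" and
#' 6 Angstrom away when "off".
#'
#' @param n_frames number of frames (default 500).
#' @param frame_interval ps between frames (default 2).
#' @param per_slice_waters integer vector of target water counts per slice
#'   (length \code{n_slices}; default 10 each).
#' @param n_bulk_waters waters placed outside the channel (default 50).
#' @param ring_radius corner-ring circumradius, Angstrom (default 9).
#' @param n_ring corners per ring (default 12).
#' @param n_slices,slice_thickness cylinder discretisation (15 x 2
#'   Angstrom).
#' @param place_radius maximal radial distance of channel waters from the
#'   axis (default 6, safely inside both hull and cylinder).
#' @param hydronium \code{NA} or a position label \code{"a"}..\code{"f"}
#'   (heights mapped onto the toy channel as fractional distance from the
#'   top).
#' @param probes data.frame with columns \code{label}, \code{k_on},
#'   \code{k_off} (ps^-1), or \code{NULL}.
#' @param motion \code{"resample"} (i.i.d. per frame; exact censuses) or
#'   \code{"diffuse"} (reflected random walk, step sd 0.5 Angstrom).
#' @param excluded_radius minimal water-oxygen separation within a slice
#'   (default 1.4 Angstrom).
#' @param seed RNG seed fixing the full stream.
#' @return Object of class \code{cf_synth_spec}.
#' @export
synthetic_channel_spec <- function(n_frames = 500, frame_interval = 2,
                                   per_slice_waters = rep(10L, 15),
                                   n_bulk_waters = 50, ring_radius = 9,
                                   n_ring = 12, n_slices = 15,
                                   slice_thickness = 2, place_radius = 6,
                                   hydronium = NA_character_, probes = NULL,
                                   motion = c("resample", "diffuse"),
                                   excluded_radius = 1.4, seed = 1) {
  motion <- match.arg(motion)
  stopifnot(length(per_slice_waters) == n_slices, all(per_slice_waters >= 0),
            n_ring >= 3, place_radius < ring_radius * cos(pi / n_ring))
  if (!is.null(probes))
    stopifnot(all(probes$k_on > 0), all(probes$k_off > 0))
  # height chosen so that the 10%-elongated axis hits the cap exactly:
  # the cylinder then covers n_slices full slices
  height <- n_slices * slice_thickness / 1.1
  structure(list(n_frames = n_frames, frame_interval = frame_interval,
                 per_slice_waters = as.integer(per_slice_waters),
                 n_bulk_waters = n_bulk_waters, ring_radius = ring_radius,
                 n_ring = n_ring, n_slices = n_slices,
                 slice_thickness = slice_thickness,
                 place_radius = place_radius, height = height,
                 hydronium = hydronium, probes = probes, motion = motion,
                 excluded_radius = excluded_radius, seed = seed),
            class = "cf_synth_spec")
}

# uniform point in a disc of given radius (vectorised)
disc_points <- function(n, radius) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th))
}

# random unit vectors
random_units <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# water hydrogens at ~0.9572 A and 104.52 deg around an oxygen, random
# orientation
water_hydrogens <- function(opos) {
  n <- nrow(opos)
  u1 <- random_units(n)
  raw <- random_units(n)
  perp <- raw - u1 * rowSums(raw * u1)
  perp <- perp / sqrt(rowSums(perp^2))
  half <- 104.52 / 2 * pi / 180
  h1 <- opos + 0.9572 * (cos(half) * u1 + sin(half) * perp)
  h2 <- opos + 0.9572 * (cos(half) * u1 - sin(half) * perp)
  list(h1 = h1, h2 = h2)
}

enforce_spacing <- function(pts, zr, radius, min_d, max_iter = 200) {
  n <- nrow(pts)
  if (n < 2) return(pts)
  for (it in seq_len(max_iter)) {
    d <- as.matrix(dist(pts))
    diag(d) <- Inf
    idx <- which(d < min_d, arr.ind = TRUE)
    if (nrow(idx) == 0) return(pts)
    bad <- unique(pmax(idx[, 1], idx[, 2]))  # move the later of each pair
    pts[bad, 1:2] <- disc_points(length(bad), radius)
    pts[bad, 3] <- runif(length(bad), zr[1], zr[2])
  }
  stop("target waters exceed slice capacity at the excluded-volume radius")
}

#' Generate a synthetic channel system
#'
#' Builds topology, trajectory and exact ground truth from a
#' \code{\link{synthetic_channel_spec}}.  Deterministic under the spec's
#' seed.
#'
#' @param spec a \code{cf_synth_spec}.
#' @return List: \code{traj} (a \code{cf_trajectory}), \code{channel} (a
#'   matching \code{cf_channel} whose bottom/top groups are the two corner
#'   rings), \code{truth} (per-frame inside-polyhedron water keys, true
#'   per-slice count matrix, probe \code{h} matrix, true lifetimes and
#'   occupancies, hydronium height), and \code{spec}.
#' @export
generate_system <- function(spec) {
  set.seed(spec$seed)
  H <- spec$height
  n_ring <- spec$n_ring
  th <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  ring <- cbind(spec$ring_radius * cos(th), spec$ring_radius * sin(th))
  corners <- rbind(cbind(ring, 0), cbind(ring, H))
  n_cor <- nrow(corners)

  n_probe <- if (is.null(spec$probes)) 0L else nrow(spec$probes)
  has_h3o <- !is.na(spec$hydronium)
  n_chan <- sum(spec$per_slice_waters)
  n_bulk <- spec$n_bulk_waters

  # ---- topology -----------------------------------------------------------
  tops <- list(cf_topology(name = "CA", resname = "COR",
                           resid = seq_len(n_cor), chain = "A",
                           mass = 12.011, charge = 0))
  if (n_probe > 0)
    tops <- c(tops, list(cf_topology(
      name = rep(c("O", "H1"), n_probe), resname = "PRB",
      resid = rep(1000 + seq_len(n_probe), each = 2), chain = "P",
      mass = rep(c(15.999, 1.008), n_probe),
      charge = rep(c(-0.66, 0.43), n_probe))))
  if (has_h3o)
    tops <- c(tops, list(cf_topology(
      name = c("OH2", "H1", "H2", "H3"), resname = "H3O", resid = 2000,
      chain = "X", mass = c(15.999, rep(1.008, 3)),
      charge = c(-0.347, rep(0.449, 3)))))
  n_wat <- n_probe + n_chan + n_bulk   # partner + channel + bulk waters
  if (n_wat > 0)
    tops <- c(tops, list(cf_topology(
      name = rep(c("OH2", "H1", "H2"), n_wat), resname = "TIP3",
      resid = rep(3000 + seq_len(n_wat), each = 3), chain = "W",
      mass = rep(c(15.999, 1.008, 1.008), n_wat),
      charge = rep(c(-0.834, 0.417, 0.417), n_wat))))
  top <- do.call(rbind, tops)
  top$index <- seq_len(nrow(top))
  class(top) <- c("cf_topology", "data.frame")

  off_probe <- n_cor
  off_h3o <- off_probe + 2 * n_probe
  off_wat <- off_h3o + if (has_h3o) 4L else 0L
  o_idx <- function(w) off_wat + 3L * (w - 1L) + 1L  # water oxygen row

  # ---- static geometry ----------------------------------------------------
  # cylinder the pipeline will build: base 5% below the cage, 15 slices
  base_z <- -(spec$n_slices * spec$slice_thickness - H) / 2
  slice_z <- function(s)
    c(base_z + (s - 1) * spec$slice_thickness,
      base_z + s * spec$slice_thickness)
  zmargin <- 0.1
  slice_of_water <- rep(seq_len(spec$n_slices), spec$per_slice_waters)

  probe_pos <- NULL
  if (n_probe > 0) {
    pth <- 2 * pi * (seq_len(n_probe) - 1) / max(n_probe, 1)
    pr <- spec$ring_radius + 6
    probe_pos <- cbind(pr * cos(pth), pr * sin(pth),
                       H / 2 + 3 * (seq_len(n_probe) -
                                      (n_probe + 1) / 2))
    probe_dir <- cbind(cos(pth), sin(pth), 0)  # outward radial
  }
  h3o_z <- NA_real_
  if (has_h3o) {
    d <- hydronium_positions()
    h3o_z <- H * (1 - d$distance_to_Y288_CA[match(spec$hydronium,
                                                  d$position)] / 30)
  }

  # ---- probe Markov series ------------------------------------------------
  probe_h <- NULL
  if (n_probe > 0) {
    probe_h <- vapply(seq_len(n_probe), function(k)
      markov_onoff_series(spec$probes$k_on[k], spec$probes$k_off[k],
                          spec$frame_interval, spec$n_frames),
      integer(spec$n_frames))
    probe_h <- matrix(probe_h, ncol = n_probe)
  }

  # ---- frames -------------------------------------------------------------
  natom <- nrow(top)
  xyz <- matrix(0, spec$n_frames, 3 * natom)
  chan_pos <- NULL
  true_slices <- matrix(0L, spec$n_frames, spec$n_slices)
  inside_keys <- vector("list", spec$n_frames)
  wkeys <- paste0("W:", 3000 + seq_len(n_wat))
  chan_keys <- wkeys[n_probe + seq_len(n_chan)]

  sample_channel <- function(prev = NULL) {
    pos <- matrix(0, n_chan, 3)
    for (s in seq_len(spec$n_slices)) {
      w <- which(slice_of_water == s)
      if (length(w) == 0) next
      zr <- slice_z(s)
      zr <- c(max(zr[1], zmargin), min(zr[2], H - zmargin))
      if (zr[2] <= zr[1])
        stop("slice ", s, " has no usable height inside the cage")
      if (is.null(prev)) {
        p <- cbind(disc_points(length(w), spec$place_radius),
                   runif(length(w), zr[1], zr[2]))
        p <- enforce_spacing(p, zr, spec$place_radius,
                             spec$excluded_radius)
      } else {
        p <- prev[w, , drop = FALSE] +
          matrix(rnorm(3 * length(w), sd = 0.5), ncol = 3)
        # reflect into the slice box
        rad <- sqrt(rowSums(p[, 1:2, drop = FALSE]^2))
        over <- rad > spec$place_radius
        if (any(over)) {
          sc <- (2 * spec$place_radius - rad[over]) / rad[over]
          sc[sc < 0] <- 0.5 * spec$place_radius / rad[over][sc < 0]
          p[over, 1:2] <- p[over, 1:2, drop = FALSE] * sc
        }
        p[, 3] <- reflect_interval(p[, 3], zr[1], zr[2])
        # excluded volume: revert clashing movers
        if (length(w) > 1) {
          d <- as.matrix(dist(p)); diag(d) <- Inf
          bad <- unique(which(d < spec$excluded_radius,
                              arr.ind = TRUE)[, 1])
          if (length(bad)) p[bad, ] <- prev[w[bad], , drop = FALSE]
        }
      }
      pos[w, ] <- p
    }
    pos
  }

  for (f in seq_len(spec$n_frames)) {
    fc <- matrix(0, natom, 3)
    fc[seq_len(n_cor), ] <- corners
    if (n_probe > 0) {
      for (k in seq_len(n_probe)) {
        o <- probe_pos[k, ]
        hdir <- probe_dir[k, ]
        rows <- off_probe + 2 * (k - 1) + 1:2
        fc[rows[1], ] <- o
        fc[rows[2], ] <- o + 0.97 * hdir
        # partner water
        wrow <- o_idx(k)
        dist_o <- if (probe_h[f, k] == 1L) 2.8 else 6.0
        wo <- o + dist_o * hdir
        fc[wrow, ] <- wo
        # water hydrogens point away from the probe
        perp <- cross3(hdir, c(0, 0, 1))
        for (j in 1:2) {
          sgn <- if (j == 1) 1 else -1
          fc[wrow + j, ] <- wo + 0.9572 *
            (cos(pi / 3.44) * hdir + sgn * sin(pi / 3.44) * perp)
        }
      }
    }
    if (has_h3o) {
      orow <- off_h3o + 1L
      fc[orow, ] <- c(0, 0, h3o_z)
      u <- random_units(3)
      fc[orow + 1:3, ] <- matrix(c(0, 0, h3o_z), 3, 3, byrow = TRUE) +
        0.98 * u
    }
    chan_pos <- if (spec$motion == "resample" || is.null(chan_pos))
      sample_channel() else sample_channel(chan_pos)
    if (n_chan > 0) {
      orow <- o_idx(n_probe + seq_len(n_chan))
      fc[orow, ] <- chan_pos
      hh <- water_hydrogens(chan_pos)
      fc[orow + 1L, ] <- hh$h1
      fc[orow + 2L, ] <- hh$h2
    }
    if (n_bulk > 0) {
      # bulk annulus kept >4 A clear of probe sites and partner waters
      rr <- runif(n_bulk, spec$ring_radius + 16, spec$ring_radius + 26)
      tb <- runif(n_bulk, 0, 2 * pi)
      bp <- cbind(rr * cos(tb), rr * sin(tb), runif(n_bulk, -5, H + 5))
      orow <- o_idx(n_probe + n_chan + seq_len(n_bulk))
      fc[orow, ] <- bp
      hh <- water_hydrogens(bp)
      fc[orow + 1L, ] <- hh$h1
      fc[orow + 2L, ] <- hh$h2
    }
    xyz[f, ] <- as.vector(t(fc))
    true_slices[f, ] <- tabulate(slice_of_water, nbins = spec$n_slices)
    inside_keys[[f]] <- chan_keys[chan_pos[, 3] >= 0 & chan_pos[, 3] <= H]
  }

  traj <- cf_trajectory(top, xyz, frame_interval = spec$frame_interval)
  channel <- channel_definition(
    "toy",
    corners = data.frame(chain = "A", resid = seq_len(n_cor)),
    bottom_residues = seq_len(n_ring),
    top_residues = n_ring + seq_len(n_ring))
  truth <- list(
    inside_keys = inside_keys,
    slice_counts = true_slices,
    probe_h = probe_h,
    probe_labels = if (n_probe) spec$probes$label else character(0),
    true_lifetime = if (n_probe) 1 / spec$probes$k_off else numeric(0),
    true_occupancy = if (n_probe)
      spec$probes$k_on / (spec$probes$k_on + spec$probes$k_off)
    else numeric(0),
    hydronium_z = h3o_z, height = H, base_z = base_z)
  list(traj = traj, channel = channel, truth = truth, spec = spec)
}

reflect_interval <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

# two-state continuous-time Markov chain sampled on the frame grid;
# exact alternating-exponential sojourns, stationary initial state
markov_onoff_series <- function(k_on, k_off, dt, n_frames) {
  total <- n_frames * dt
  state0 <- as.integer(runif(1) < k_on / (k_on + k_off))
  mean_soj <- (1 / k_on + 1 / k_off) / 2
  n_draw <- max(100L, ceiling(total / mean_soj * 1.3))
  rates <- rep_len(if (state0 == 1L) c(k_off, k_on) else c(k_on, k_off),
                   n_draw)
  soj <- rexp(n_draw, rates)
  while (sum(soj) < total) {
    extra <- max(100L, ceiling(n_draw * 0.5))
    more_rates <- rep_len(if ((n_draw %% 2L) == 0L)
      rates[1:2] else rates[2:1], extra)
    soj <- c(soj, rexp(extra, more_rates))
    n_draw <- length(soj)
  }
  ends <- cumsum(soj)
  states <- rep_len(c(state0, 1L - state0), length(soj))
  tsamp <- (seq_len(n_frames) - 1) * dt
  idx <- findInterval(tsamp, c(0, ends), rightmost.closed = FALSE)
  states[idx]
}

#' Generate a binary hydrogen-bond indicator series with known kinetics
#'
#' Exact two-state continuous-time Markov chain (bond formation rate
#' \code{k_on}, breaking rate \code{k_off}) sampled every \code{dt} ps.
#' The continuous-time mean bonded dwell is \code{1/k_off} and the
#' equilibrium bond occupancy \code{k_on/(k_on+k_off)}; at coarse \code{dt}
#' the sampled series misses sub-frame excursions, so run-length means
#' exceed \code{1/k_off} by O(\code{k_on dt}).
#'
#' @param k_on,k_off rates in ps^-1.
#' @param dt sampling interval, ps.
#' @param n_frames series length.
#' @param seed optional RNG seed.
#' @return List: \code{h} (integer 0/1), \code{dt}, \code{true_lifetime}
#'   (ps), \code{true_occupancy}.
#' @export
generate_hbond_series <- function(k_on, k_off, dt, n_frames, seed = NULL) {
  stopifnot(dt > 0, k_on > 0, k_off > 0)
  if (!is.null(seed)) set.seed(seed)
  h <- markov_onoff_series(k_on, k_off, dt, n_frames)
  list(h = h, dt = dt, true_lifetime = 1 / k_off,
       true_occupancy = k_on / (k_on + k_off))
}

#' Write a synthetic system to disk (PDB + PSF + DCD + ground-truth JSON)
#'
#' @param system result of \code{\link{generate_system}}.
#' @param dir output directory (created if needed).
#' @param name file stem (default \code{"toy"}).
#' @return Named character vector of the written paths.
#' @export
write_system <- function(system, dir, name = "toy") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(pdb = file.path(dir, paste0(name, ".pdb")),
             psf = file.path(dir, paste0(name, ".psf")),
             dcd = file.path(dir, paste0(name, ".dcd")),
             truth = file.path(dir, paste0(name, "_truth.json")))
  write_pdb_structure(system$traj$topology, frame_coords(system$traj, 1),
                      paths["pdb"])
  write_psf(system$traj$topology, paths["psf"])
  write_dcd(system$traj, paths["dcd"])
  tr <- system$truth
  jsonlite::write_json(
    list(slice_counts = tr$slice_counts, probe_h = tr$probe_h,
         probe_labels = tr$probe_labels, true_lifetime = tr$true_lifetime,
         true_occupancy = tr$true_occupancy, height = tr$height,
         hydronium_z = tr$hydronium_z,
         inside_counts = vapply(tr$inside_keys, length, integer(1))),
    paths["truth"], auto_unbox = TRUE, digits = NA, na = "null")
  paths
}
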