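# Fixtures and independent oracles shared across the suite.

# topology of n free waters (TIP3) with random positions/orientations in a
# cubic box; returns topology + one frame of coordinates
random_water_frame <- function(n, box = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  top <- cf_topology(name = rep(c("OH2", "H1", "H2"), n), resname = "TIP3",
                     resid = rep(seq_len(n), each = 3), chain = "W",
                     mass = rep(c(15.999, 1.008, 1.008), n),
                     charge = rep(c(-0.834, 0.417, 0.417), n))
  o <- matrix(runif(3 * n, 0, box), ncol = 3)
  coords <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) {
    u1 <- rnorm(3); u1 <- u1 / sqrt(sum(u1^2))
    raw <- rnorm(3); perp <- raw - u1 * sum(raw * u1)
    perp <- perp / sqrt(sum(perp^2))
    half <- 104.52 / 2 * pi / 180
    coords[3 * i - 2, ] <- o[i, ]
    coords[3 * i - 1, ] <- o[i, ] + 0.9572 * (cos(half) * u1 + sin(half) * perp)
    coords[3 * i, ]     <- o[i, ] + 0.9572 * (cos(half) * u1 - sin(half) * perp)
  }
  list(topology = top, coords = coords)
}

# all-pairs scalar-ish brute force H-bond detection (independent of the
# package's prefiltered matrix implementation): loops over every
# donor-hydrogen and checks each acceptor directly
brute_force_hbonds <- function(coords, topology, donors, acceptors,
                               max_d = 3.5, min_angle = 145) {
  res <- list()
  dres <- paste0(topology$chain[donors$donor], ":",
                 topology$resid[donors$donor])
  ares <- paste0(topology$chain[acceptors], ":", topology$resid[acceptors])
  for (k in seq_len(nrow(donors))) {
    D <- coords[donors$donor[k], ]
    H <- coords[donors$hydrogen[k], ]
    dv <- sweep(coords[acceptors, , drop = FALSE], 2, D)
    dd <- sqrt(rowSums(dv^2))
    hv1 <- D - H
    hv2 <- sweep(coords[acceptors, , drop = FALSE], 2, H)
    cosang <- (hv2 %*% hv1) / (sqrt(sum(hv1^2)) * sqrt(rowSums(hv2^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    hit <- which(dd <= max_d & ang >= min_angle & ares != dres[k])
    for (a in hit)
      res[[length(res) + 1]] <- c(donors$donor[k], donors$hydrogen[k],
                                  acceptors[a])
  }
  if (length(res) == 0)
    return(matrix(integer(0), ncol = 3))
  do.call(rbind, res)
}

# breadth-first reachability oracle on an edge list over named nodes
bfs_reachable <- function(nodes, edges, from) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges) > 0) for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  queue <- from
  seen[from] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  names(seen)[seen]
}

# random non-degenerate corner set in a cube of the given edge
random_corner_set <- function(n = 17, edge = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(runif(3 * n, 0, edge), ncol = 3)
}

# random rigid motion (rotation from QR with positive determinant +
# translation)
random_rigid_motion <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  list(R = Q, t = runif(3, -50, 50))
}

# small probe system used in several H-bond tests: one probe residue kept
# permanently bonded (or not) to a partner water
static_probe_traj <- function(n_frames = 10, bonded = TRUE) {
  top <- rbind(
    cf_topology(name = c("O", "H1"), resname = "PRB", resid = 1001,
                chain = "P", mass = c(15.999, 1.008),
                charge = c(-0.66, 0.43)),
    cf_topology(name = c("OH2", "H1", "H2"), resname = "TIP3", resid = 3001,
                chain = "W", mass = c(15.999, 1.008, 1.008),
                charge = c(-0.834, 0.417, 0.417)))
  top$index <- seq_len(nrow(top))
  class(top) <- c("cf_topology", "data.frame")
  d <- if (bonded) 2.8 else 6
  fc <- rbind(c(0, 0, 0), c(0.97, 0, 0),
              c(d, 0, 0),
              c(d + 0.6, 0.75, 0), c(d + 0.6, -0.75, 0))
  cf_trajectory(top, matrix(rep(as.vector(t(fc)), n_frames),
                            nrow = n_frames, byrow = TRUE))
}

expect_same_events <- function(events, oracle) {
  pack <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
  expect_identical(pack(cbind(events$donor, events$hydrogen,
                              events$acceptor)),
                   pack(oracle))
}
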