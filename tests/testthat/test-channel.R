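# Cylinder construction, slice assignment, water census and width series.

# toy cage: two triangle rings of single-atom corner residues at z = 0 and
# z = height, radius r
make_cage <- function(height, r = 8, n_frames = 1) {
  th <- 2 * pi * (0:2) / 3
  corners <- rbind(cbind(r * cos(th), r * sin(th), 0),
                   cbind(r * cos(th + pi / 3), r * sin(th + pi / 3), height))
  top <- cf_topology(name = "CA", resname = "COR", resid = 1:6, chain = "A",
                     mass = 12)
  traj <- cf_trajectory(top, matrix(rep(as.vector(t(corners)), n_frames),
                                    nrow = n_frames, byrow = TRUE))
  ch <- channel_definition("toy", data.frame(chain = "A", resid = 1:6),
                           bottom_residues = 1:3, top_residues = 4:6)
  list(traj = traj, channel = ch)
}

test_that("cylinder defaults and axis elongation follow the construction", {
  cage <- make_cage(20)
  cyl <- build_cylinder(cage$traj, cage$channel)
  expect_equal(cyl$radius, 9.5)
  expect_equal(cyl$n_slices, 15)
  expect_equal(cyl$slice_thickness, 2)
  expect_equal(cyl$length, 22)                      # 20 A + 10%
  expect_equal(cyl$base, c(0, 0, -1), tolerance = 1e-9)
  expect_equal(cyl$tip, c(0, 0, 21), tolerance = 1e-9)
  # cap: 28 A + 10% = 30.8 -> 30, symmetric about the midpoint
  cyl2 <- build_cylinder(make_cage(28)$traj, make_cage(28)$channel)
  expect_equal(cyl2$length, 30)
  expect_equal(cyl2$base[3], -1, tolerance = 1e-9)
  expect_equal(cyl2$tip[3], 29, tolerance = 1e-9)
  expect_error(build_cylinder(make_cage(0)$traj, make_cage(0)$channel),
               "zero-length")
})

test_that("slice assignment matches the direct geometric oracle", {
  cage <- make_cage(300 / 11)
  cyl <- build_cylinder(cage$traj, cage$channel)
  expect_equal(cyl$length, 30)
  expect_equal(assign_slice(cyl$base + c(0, 0, 1), cyl), 1L)
  expect_true(is.na(assign_slice(cyl$base + c(9.6, 0, 1), cyl)))
  expect_equal(assign_slice(cyl$base + c(9.5, 0, 1), cyl), 1L)  # wall inside
  expect_true(is.na(assign_slice(cyl$base + c(0, 0, 30), cyl)))  # half-open
  set.seed(11)
  pts <- cbind(runif(1e4, -15, 15), runif(1e4, -15, 15), runif(1e4, -5, 35))
  got <- assign_slice(pts, cyl)
  ax <- pts[, 3] - cyl$base[3]
  rad <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  oracle <- ifelse(rad > 9.5 | ax < 0 | ax >= 30, NA_integer_,
                   pmin(floor(ax / 2) + 1L, 15L))
  expect_identical(got, as.integer(oracle))
  # totality: every point maps to exactly one slice or outside
  expect_true(all(is.na(got) | (got >= 1 & got <= 15)))
})

test_that("census conserves slice sums and nests polyhedron in cylinder", {
  spec <- synthetic_channel_spec(n_frames = 40, seed = 21,
                                 per_slice_waters = rep(4L, 15),
                                 n_bulk_waters = 30)
  sys <- generate_system(spec)
  hyd <- water_census(sys$traj, sys$channel)
  expect_identical(as.integer(rowSums(hyd$slice_counts)),
                   hyd$cylinder_counts)
  expect_true(all(hyd$frame_counts <= hyd$cylinder_counts))
  # every water inside the polyhedron is also inside the cylinder
  wox <- channelflow:::water_oxygen_indices(sys$traj$topology)
  keys <- channelflow:::water_key(sys$traj$topology, wox)
  for (f in c(1, 20, 40)) {
    pts <- frame_coords(sys$traj, f)[wox, , drop = FALSE]
    sl <- assign_slice(pts, hyd$cylinder)
    inside_poly <- keys %in% hyd$inside_ids[[f]]
    expect_true(all(!is.na(sl[inside_poly])))
  }
  # ground truth recovered exactly in resample mode
  expect_identical(hyd$slice_counts, sys$truth$slice_counts)
  expect_identical(hyd$frame_counts,
                   vapply(sys$truth$inside_keys, length, integer(1)))
})

test_that("height profiles recover per-slice occupancy", {
  specs <- lapply(1:2, function(r)
    generate_system(synthetic_channel_spec(n_frames = 20, seed = 30 + r,
                                           per_slice_waters = rep(10L, 15),
                                           n_bulk_waters = 0)))
  recs <- lapply(specs, function(s) water_census(s$traj, s$channel))
  prof <- height_profile(recs)
  expect_equal(prof$mean, rep(10, 15))
  expect_equal(prof$se, rep(0, 15))
  expect_equal(prof$height, seq(1, 29, by = 2))
  # empty system: all-zero profile
  empty <- generate_system(synthetic_channel_spec(
    n_frames = 3, seed = 1, per_slice_waters = rep(0L, 15),
    n_bulk_waters = 0))
  suppressWarnings(h0 <- water_census(empty$traj, empty$channel))
  expect_true(all(height_profile(list(h0))$mean == 0))
})

test_that("occupancy projections conserve counts and respect symmetry", {
  spec <- synthetic_channel_spec(n_frames = 60, seed = 40,
                                 per_slice_waters = rep(6L, 15),
                                 n_bulk_waters = 0)
  sys <- generate_system(spec)
  cyl <- build_cylinder(sys$traj, sys$channel)
  hyd <- water_census(sys$traj, sys$channel, cylinder = cyl)
  pxz <- project_occupancy(sys$traj, cyl, "xz")
  pyz <- project_occupancy(sys$traj, cyl, "yz")
  expect_equal(sum(pxz$counts), sum(hyd$cylinder_counts))
  expect_equal(sum(pyz$counts), sum(hyd$cylinder_counts))
  # axially symmetric placement: the axial marginal is view-independent
  # up to sampling noise
  m1 <- colSums(pxz$counts) / sum(pxz$counts)
  m2 <- colSums(pyz$counts) / sum(pyz$counts)
  expect_lt(max(abs(m1 - m2)), 0.05)
})

test_that("single stationary water occupies one projection bin", {
  top <- cf_topology(name = c("CA", "CA", "CA", "CA", "CA", "CA", "OH2"),
                     resname = c(rep("COR", 6), "TIP3"),
                     resid = c(1:6, 100), chain = "A",
                     mass = c(rep(12, 6), 15.999))
  th <- 2 * pi * (0:2) / 3
  corners <- rbind(cbind(8 * cos(th), 8 * sin(th), 0),
                   cbind(8 * cos(th), 8 * sin(th), 20))
  fc <- rbind(corners, c(1.2, 0.7, 10))
  traj <- cf_trajectory(top, matrix(rep(as.vector(t(fc)), 7), nrow = 7,
                                    byrow = TRUE))
  ch <- channel_definition("toy", data.frame(chain = "A", resid = 1:6),
                           bottom_residues = 1:3, top_residues = 4:6)
  cyl <- build_cylinder(traj, ch)
  p <- project_occupancy(traj, cyl, "xz")
  expect_equal(sum(p$counts), 7)
  expect_equal(sum(p$counts > 0), 1)
  expect_equal(max(p$counts), 7)
})

test_that("channel width series equal direct Calpha distances", {
  top <- cf_topology(name = rep("CA", 4), resname = "GLY", resid = 1:4,
                     chain = "A", mass = 12)
  f1 <- rbind(c(0, 0, 0), c(3, 4, 0), c(1, 1, 1), c(1, 1, 1))
  f2 <- rbind(c(0, 0, 0), c(0, 0, 2), c(0, 0, 0), c(5, 0, 0))
  traj <- cf_trajectory(top, rbind(as.vector(t(f1)), as.vector(t(f2))))
  wp <- data.frame(chain_a = "A", resid_a = c(1, 3),
                   chain_b = "A", resid_b = c(2, 4))
  w <- channel_width(traj, wp)
  expect_equal(w[, 1], c(5, 2))
  expect_equal(w[, 2], c(0, 5))
  expect_error(channel_width(traj, data.frame(chain_a = "A", resid_a = 9,
                                              chain_b = "A", resid_b = 1)),
               "9")
})
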