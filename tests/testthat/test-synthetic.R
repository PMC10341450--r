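# The ground-truth generator itself.

test_that("the same seed reproduces the system bit for bit", {
  spec <- synthetic_channel_spec(n_frames = 15, seed = 9,
                                 per_slice_waters = rep(3L, 15),
                                 probes = data.frame(label = "p", k_on = 0.05,
                                                     k_off = 0.05),
                                 hydronium = "c")
  a <- generate_system(spec)
  b <- generate_system(spec)
  expect_identical(a$traj$xyz, b$traj$xyz)
  expect_identical(a$traj$topology, b$traj$topology)
  expect_identical(a$truth, b$truth)
  # a different seed changes the coordinates
  spec2 <- synthetic_channel_spec(n_frames = 15, seed = 10,
                                  per_slice_waters = rep(3L, 15))
  expect_false(identical(generate_system(spec2)$traj$xyz, a$traj$xyz))
})

test_that("generated geometry realises the Markov bond states exactly", {
  spec <- synthetic_channel_spec(n_frames = 150, seed = 12,
                                 per_slice_waters = rep(2L, 15),
                                 probes = data.frame(label = "p",
                                                     k_on = 1 / 30,
                                                     k_off = 1 / 15))
  sys <- generate_system(spec)
  ser <- residue_water_hbond_stats(sys$traj,
                                   data.frame(chain = "P", resid = 1001))
  expect_identical(ser$h, sys$truth$probe_h[, 1])
  expect_identical(ser$counts, sys$truth$probe_h[, 1])  # exactly one bond
  # when on, the criterion is met by construction; when off, violated:
  # verified by the exact equality above on both states
  expect_gt(mean(ser$h), 0)
  expect_lt(mean(ser$h), 1)
})

test_that("hydronium oxygen is stationary at its labelled height", {
  for (posn in c("a", "f")) {
    spec <- synthetic_channel_spec(n_frames = 10, seed = 14,
                                   per_slice_waters = rep(1L, 15),
                                   hydronium = posn)
    sys <- generate_system(spec)
    oi <- select_atoms(sys$traj$topology, name = "OH2", resname = "H3O")
    expect_length(oi, 1)
    z <- sys$traj$xyz[, 3 * oi]
    expect_equal(unique(round(z, 10)), sys$truth$hydronium_z)
    d <- hydronium_positions()
    frac <- 1 - d$distance_to_Y288_CA[d$position == posn] / 30
    expect_equal(sys$truth$hydronium_z, sys$truth$height * frac)
  }
})

test_that("channel waters respect the excluded-volume radius", {
  spec <- synthetic_channel_spec(n_frames = 5, seed = 15,
                                 per_slice_waters = rep(10L, 15))
  sys <- generate_system(spec)
  wox <- select_atoms(sys$traj$topology, name = "OH2", resname = "TIP3")
  for (f in 1:5) {
    pts <- frame_coords(sys$traj, f)[wox, ]
    pts <- pts[pts[, 3] >= 0 & pts[, 3] <= sys$truth$height &
                 sqrt(pts[, 1]^2 + pts[, 2]^2) <= 6, ]
    # within every slice the generator enforces the 1.4 A separation
    sl <- floor((pts[, 3] - sys$truth$base_z) / 2)
    for (s in unique(sl)) {
      p <- pts[sl == s, , drop = FALSE]
      if (nrow(p) > 1) expect_gt(min(dist(p)), 1.4)
    }
  }
  # impossible packing is rejected
  tight <- synthetic_channel_spec(n_frames = 1, seed = 16,
                                  per_slice_waters = c(200L, rep(0L, 14)),
                                  place_radius = 2)
  expect_error(generate_system(tight), "capacity")
})

test_that("diffusing waters stay in their slices and keep censuses exact", {
  spec <- synthetic_channel_spec(n_frames = 30, seed = 17,
                                 per_slice_waters = rep(5L, 15),
                                 motion = "diffuse")
  sys <- generate_system(spec)
  hyd <- water_census(sys$traj, sys$channel)
  expect_identical(hyd$slice_counts, sys$truth$slice_counts)
  # successive frames are correlated (random walk, not resampling);
  # restrict to the channel waters (bulk is resampled every frame)
  wox <- select_atoms(sys$traj$topology, name = "OH2", resname = "TIP3",
                      resid = 3000 + seq_len(75))
  d12 <- mean(abs(frame_coords(sys$traj, 2)[wox, ] -
                    frame_coords(sys$traj, 1)[wox, ]))
  expect_lt(d12, 1.5)
})

test_that("Markov series dwell times match the discrete-chain closed form", {
  k_on <- 1 / 60; k_off <- 1 / 30; dt <- 0.5
  g <- generate_hbond_series(k_on, k_off, dt, 400000, seed = 18)
  r <- rle(g$h)
  dwell <- mean(r$lengths[r$values == 1L]) * dt
  # sampled-chain expectation: dt / (1 - p11); close to 1/k_off for
  # small dt
  ks <- k_on + k_off
  p11 <- (k_on + k_off * exp(-ks * dt)) / ks
  expect_equal(dwell, dt / (1 - p11), tolerance = 0.03)
  expect_equal(dwell, 1 / k_off, tolerance = 0.05)
  # symmetric rates: occupancy one half
  g2 <- generate_hbond_series(0.05, 0.05, 2, 50000, seed = 19)
  expect_equal(mean(g2$h), 0.5, tolerance = 0.03)
  # fast breaking: no two consecutive bonded frames (w.h.p.)
  g3 <- generate_hbond_series(0.02, 50, 2, 20000, seed = 20)
  expect_equal(max(rle(g3$h)$lengths[rle(g3$h)$values == 1L]), 1)
})

test_that("written systems round-trip through the standard formats", {
  spec <- synthetic_channel_spec(n_frames = 6, seed = 22,
                                 per_slice_waters = rep(1L, 15),
                                 hydronium = "d")
  sys <- generate_system(spec)
  dir <- file.path(tempdir(), "synthwrite")
  paths <- write_system(sys, dir)
  expect_true(all(file.exists(paths)))
  s <- read_structure(paths["psf"])
  expect_equal(nrow(s$topology), nrow(sys$traj$topology))
  expect_equal(s$topology$charge, sys$traj$topology$charge,
               tolerance = 1e-6)
  back <- read_trajectory(paths["dcd"], s$topology)
  expect_equal(back$xyz, sys$traj$xyz, tolerance = 1e-4,
               ignore_attr = TRUE)
  # the reloaded trajectory yields the same census as the in-memory one
  hyd1 <- water_census(sys$traj, sys$channel)
  hyd2 <- water_census(back, sys$channel)
  expect_identical(hyd1$frame_counts, hyd2$frame_counts)
  expect_identical(hyd1$slice_counts, hyd2$slice_counts)
})
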