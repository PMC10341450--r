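# Geometric H-bond detection, bond statistics, autocorrelation and the
# lifetime fit.

test_that("the distance/angle criterion is applied with its boundaries", {
  traj <- static_probe_traj(bonded = TRUE)
  tb <- hbond_atom_table()
  ga <- resolve_hbond_group(traj$topology, data.frame(chain = "P",
                                                      resid = 1001), tb)
  gb <- resolve_hbond_group(traj$topology, "water", tb)
  fc <- frame_coords(traj, 1)
  ev <- detect_hbonds(fc, traj$topology, ga$donors, gb$acceptors)
  expect_equal(nrow(ev), 1)           # collinear O-H...O at 2.8 A
  # beyond 3.5 A: no bond
  far <- static_probe_traj(bonded = FALSE)
  ev2 <- detect_hbonds(frame_coords(far, 1), far$topology, ga$donors,
                       gb$acceptors)
  expect_equal(nrow(ev2), 0)
  # exactly at 3.5 A and collinear: still a bond (<= boundary)
  fc3 <- fc; fc3[3, 1] <- 3.5
  expect_equal(nrow(detect_hbonds(fc3, traj$topology, ga$donors,
                                  gb$acceptors)), 1)
  # angle boundary: rotate the acceptor to exactly 35 deg off linear
  d <- 2.0  # H...A distance along the bent direction
  ang <- 145 * pi / 180
  fc4 <- fc
  fc4[3, ] <- c(0.97, 0, 0) + d * c(cos(pi - ang), sin(pi - ang), 0)
  expect_equal(nrow(detect_hbonds(fc4, traj$topology, ga$donors,
                                  gb$acceptors)), 1)
  fc5 <- fc
  fc5[3, ] <- c(0.97, 0, 0) + d * c(cos(pi - ang + 0.02),
                                    sin(pi - ang + 0.02), 0)
  expect_equal(nrow(detect_hbonds(fc5, traj$topology, ga$donors,
                                  gb$acceptors)), 0)
})

test_that("detection equals the all-pairs brute force on random waters", {
  tb <- hbond_atom_table()
  for (s in 1:3) {
    w <- random_water_frame(100, box = 18, seed = 500 + s)
    g <- resolve_hbond_group(w$topology, "water", tb)
    ev <- detect_hbonds(w$coords, w$topology, g$donors, g$acceptors)
    oracle <- brute_force_hbonds(w$coords, w$topology, g$donors, g$acceptors)
    expect_same_events(ev, oracle)
    expect_gt(nrow(ev), 0)  # the fixture must actually exercise bonds
  }
})

test_that("the geometric verdict of a (D,H,A) triple is selection-independent", {
  w <- random_water_frame(40, box = 14, seed = 77)
  tb <- hbond_atom_table()
  g <- resolve_hbond_group(w$topology, "water", tb)
  ev <- detect_hbonds(w$coords, w$topology, g$donors, g$acceptors)
  # restricting the donor selection only restricts the event set: each
  # triple's verdict does not depend on how the selections were formed
  half <- g$donors[g$donors$donor <= max(w$topology$index) / 2, ]
  ev_half <- detect_hbonds(w$coords, w$topology, half, g$acceptors)
  full_sub <- ev[ev$donor %in% half$donor, ]
  rownames(full_sub) <- NULL
  expect_identical(ev_half, full_sub)
})

test_that("residue-water bond statistics hit closed-form cases", {
  bonded <- static_probe_traj(n_frames = 8, bonded = TRUE)
  ser <- residue_water_hbond_stats(bonded, data.frame(chain = "P",
                                                      resid = 1001))
  expect_equal(ser$mean_count, 1)
  expect_equal(ser$probability, 1)
  expect_identical(ser$h, rep(1L, 8))
  # bond present in exactly half the frames
  off <- static_probe_traj(n_frames = 8, bonded = FALSE)
  mix <- bonded
  mix$xyz[seq(2, 8, by = 2), ] <- off$xyz[seq(2, 8, by = 2), ]
  ser2 <- residue_water_hbond_stats(mix, data.frame(chain = "P",
                                                    resid = 1001))
  expect_equal(ser2$mean_count, 0.5)
})

test_that("Markov bonding recovers its equilibrium occupancy", {
  g <- generate_hbond_series(k_on = 7 / 300, k_off = 3 / 300, dt = 2,
                             n_frames = 50000, seed = 88)
  expect_equal(g$true_occupancy, 0.7)
  # correlation time ~ 1/(k_on+k_off) = 30 ps -> ~3300 effective samples
  expect_equal(mean(g$h), 0.7, tolerance = 0.05)
})

test_that("autocorrelation is a survival curve with the right fixed points", {
  # permanently bonded: C == 1
  ac1 <- hbond_autocorrelation(rep(1L, 1000), dt = 2)
  expect_true(all(ac1$C == 1))
  # isolated single-frame bonds: C(0)=1, C(dt)=0
  h <- integer(1000); h[seq(1, 950, by = 60)] <- 1L  # on the origin grid
  ac2 <- hbond_autocorrelation(h, dt = 2)
  expect_equal(ac2$C[1], 1)
  expect_true(all(ac2$C[-1] == 0))
  # all-zero series: undefined
  expect_error(hbond_autocorrelation(integer(200), dt = 2), "undefined")
  # property: C(0)=1, monotone non-increasing, bounded in [0,1]
  set.seed(99)
  for (i in 1:100) {
    hr <- as.integer(runif(300) < runif(1, 0.2, 0.9))
    if (!any(hr[seq(1, 250, by = 60)] == 1)) next
    ac <- hbond_autocorrelation(hr, dt = 2)
    expect_equal(ac$C[1], 1)
    expect_true(all(diff(ac$C) <= 1e-12))
    expect_true(all(ac$C >= 0 & ac$C <= 1))
  }
})

test_that("Markov autocorrelation matches the independent re-simulation
           envelope and the discrete closed form", {
  k_on <- 1 / 60; k_off <- 1 / 30; dt <- 2; nfr <- 80000
  g <- generate_hbond_series(k_on, k_off, dt, nfr, seed = 123)
  ac <- hbond_autocorrelation(g$h, dt = dt)
  # closed form: sampled persistence decays as p11^k with
  # p11 = (k_on + k_off e^{-(k_on+k_off) dt}) / (k_on + k_off)
  ks <- k_on + k_off
  p11 <- (k_on + k_off * exp(-ks * dt)) / ks
  theory <- p11^(ac$tau / dt)
  # envelope from independent discrete-time transition-matrix simulations
  p01 <- (k_on - k_on * exp(-ks * dt)) / ks
  set.seed(321)
  nsim <- 40
  H <- matrix(0L, nfr, nsim)
  H[1, ] <- as.integer(runif(nsim) < k_on / ks)
  U <- matrix(runif(nfr * nsim), nfr, nsim)
  for (t in 2:nfr)
    H[t, ] <- as.integer(U[t, ] < ifelse(H[t - 1, ] == 1L, p11, p01))
  sims <- apply(H, 2, function(hh) hbond_autocorrelation(hh, dt = dt)$C)
  lo <- apply(sims, 1, quantile, 0.025)
  hi <- apply(sims, 1, quantile, 0.975)
  expect_true(all(ac$C >= lo - 1e-9 & ac$C <= hi + 1e-9))
  expect_lt(max(abs(ac$C - theory)), 0.06)
  # halving the origin spacing stays within the envelope too
  ac2 <- hbond_autocorrelation(g$h, dt = dt, origin_spacing = 60)
  expect_true(all(ac2$C >= lo - 1e-9 & ac2$C <= hi + 1e-9))
})

test_that("lifetime fit recovers known curves and flags degenerate ones", {
  tau <- seq(0, 100, 2)
  # noiseless bi-exponential: parameters within 1%
  lf <- fit_lifetime(list(tau = tau,
                          C = 0.6 * exp(-tau / 5) + 0.4 * exp(-tau / 50)))
  expect_equal(lf$A, 0.6, tolerance = 0.01)
  expect_equal(lf$tau1, 5, tolerance = 0.01)
  expect_equal(lf$tau2, 50, tolerance = 0.01)
  expect_equal(lf$tau, 23, tolerance = 0.01)
  expect_true(lf$determined)
  # constraint A + B = 1 and weighted lifetime identity
  expect_equal(lf$A + lf$B, 1, tolerance = 1e-12)
  expect_equal(lf$tau, lf$A * lf$tau1 + lf$B * lf$tau2, tolerance = 1e-12)
  # single-exponential limit
  lf1 <- fit_lifetime(list(tau = tau, C = exp(-tau / 10)))
  expect_equal(lf1$tau, 10, tolerance = 0.01)
  # flat curve: not determined
  lf2 <- fit_lifetime(list(tau = tau, C = rep(1, length(tau))))
  expect_false(lf2$determined)
  expect_error(fit_lifetime(list(tau = 0:3, C = exp(-(0:3)))), "5 lag")
})

test_that("fitted lifetimes recover Markov dwell times within 10%", {
  # 160 ns x 3 replicas at dt = 2 ps, true dwell 30 ps; per-replica fits
  # averaged as in the replica convention
  taus <- vapply(1:3, function(r) {
    g <- generate_hbond_series(1 / 60, 1 / 30, 2, 80000, seed = 600 + r)
    fit_lifetime(hbond_autocorrelation(g$h, dt = 2))$tau
  }, numeric(1))
  expect_equal(replica_average(taus)$mean, 30, tolerance = 0.10)
})
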