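test_that("zero-rate trace is flat and classified inactive", {
  tr <- gen_acma_trace(trace_gen_config(rate = 0, noise_sd = 0))
  expect_true(all(tr$fluorescence == 1))
  nt <- normalize_trace(tr)
  expect_false(classify_active(nt))
})

test_that("noiseless quench slope matches the closed-form OLS oracle", {
  cfg <- trace_gen_config(rate = 0.004, plateau = 0.5, noise_sd = 0)
  nt <- normalize_trace(gen_acma_trace(cfg))
  pr <- initial_rate(nt, 30)
  sel <- nt$time_s >= cfg$t_mg & nt$time_s <= cfg$t_mg + 30
  expect_equal(pr$slope, ols_slope(nt$time_s[sel], nt$fluorescence[sel]),
               tolerance = 1e-12)
  # curvature bias of OLS on the exponential quench is bounded by rate*k*T/2
  k <- cfg$rate / (1 - cfg$plateau)
  expect_lt(abs(pr$rate - cfg$rate), cfg$rate * k * 30 / 2)
  # and the trace's analytic derivative at t_mg is exactly -rate
  d0 <- (1 - cfg$plateau) * k
  expect_equal(d0, cfg$rate, tolerance = 1e-12)
})

test_that("trace generation is deterministic under a fixed seed", {
  cfg <- trace_gen_config(rate = 0.01, noise_sd = 0.01, seed = 33)
  t1 <- gen_acma_trace(cfg); t2 <- gen_acma_trace(cfg)
  expect_identical(t1$fluorescence, t2$fluorescence)
  t3 <- gen_acma_trace(trace_gen_config(rate = 0.01, noise_sd = 0.01, seed = 34))
  expect_false(identical(t1$fluorescence, t3$fluorescence))
})

test_that("invalid event ordering is a configuration error", {
  expect_error(trace_gen_config(t_mg = 500, t_cccp = 400), "ordering")
  expect_error(trace_gen_config(dt = 0), "dt")
  expect_error(gen_solubilization_series(1000, 100, 12, 0, 1:10), "slope")
})

test_that("solubilization series passes through the sigmoid exactly", {
  s <- gen_solubilization_series(1000, 100, 12, 2, seq(2, 30, by = 1))
  expect_equal(boltzmann(12, 1000, 100, 12, 2), 550)        # midpoint
  expect_equal(s$y[which(s$x == 12)], 550, tolerance = 1e-12)
  expect_equal(boltzmann(-1e4, 1000, 100, 12, 2), 1000)     # Top plateau
  expect_equal(s$y, boltzmann(s$x, 1000, 100, 12, 2), tolerance = 1e-12)
})

test_that("lipids are distributed symmetrically with largest-remainder counts", {
  cfg <- membrane_gen_config(n_frames = 2, seed = 1)
  g <- gen_membrane_trajectory(cfg)
  lc <- g$ground_truth$leaflet_counts
  expect_equal(sum(lc$n), 524)
  expect_equal(sum(lc$n[lc$leaflet == "upper"]), 262)
  expect_equal(sum(lc$n[lc$leaflet == "lower"]), 262)
  expect_equal(lc$n[lc$leaflet == "upper" & lc$species == "PS"], 26)
  expect_equal(lc$n[lc$leaflet == "upper" & lc$species == "PC"], 236)
  expect_equal(unname(largest_remainder(c(PS = 0.1, PC = 0.9), 262)),
               c(26L, 236L))
  # three species with awkward remainders still sum exactly
  lr <- largest_remainder(c(PS = 1 / 3, PE = 1 / 3, PC = 1 / 3), 100)
  expect_equal(sum(lr), 100)
})

test_that("generated topology counts and ground truth agree exactly", {
  g <- gen_membrane_trajectory(membrane_gen_config(n_frames = 3, seed = 2))
  topo <- g$topology
  n_prot <- sum(topo$role == "protein")
  expect_equal(n_prot, 10 * 12)                 # helix circle scaffold
  expect_equal(nrow(topo), n_prot + 4 * 524)    # 1 head + 3 tail beads
  tl <- table(g$ground_truth$lipid_leaflet)
  expect_equal(unname(tl[["upper"]]), 262)
  by_mol <- unique(topo[topo$role != "protein", c("molecule_id", "molecule_type")])
  expect_equal(unname(table(by_mol$molecule_type)[["PS"]]), 52)
})

test_that("wrapped coordinates stay inside the box", {
  g <- gen_membrane_trajectory(membrane_gen_config(
    n_frames = 50, n_lipids_total = 100, seed = 9, diffusion_step = 1.5))
  x <- g$trajectory$coords[, 1, ]; y <- g$trajectory$coords[, 2, ]
  expect_true(all(x >= 0 & x < 13))
  expect_true(all(y >= 0 & y < 13))
})

test_that("trajectory generation is reproducible byte-for-byte", {
  cfg <- membrane_gen_config(n_frames = 5, n_lipids_total = 60, seed = 12)
  g1 <- gen_membrane_trajectory(cfg)
  g2 <- gen_membrane_trajectory(cfg)
  expect_identical(g1$trajectory$coords, g2$trajectory$coords)
  f1 <- tempfile(fileext = ".gro"); f2 <- tempfile(fileext = ".gro")
  write_gro(g1$trajectory, g1$topology, f1)
  write_gro(g2$trajectory, g2$topology, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("stronger hotspots never weaken planted-residue contacts", {
  probs <- vapply(c(0, 1, 2, 4, 8), function(s) {
    fx <- hotspot_fixture(s, seed = 21, n_frames = 400)
    p <- contact_probabilities(fx$out$trajectory, fx$out$topology)
    ps <- p[p$species == "PS", ]
    mean(ps$probability[ps$residue_id %in% fx$planted])
  }, 0)
  expect_true(all(diff(probs) >= 0))
})

test_that("unbiased bilayers show uniform contacts at headgroup depth", {
  g <- gen_membrane_trajectory(membrane_gen_config(n_frames = 600, seed = 4))
  p <- contact_probabilities(g$trajectory, g$topology)
  ps <- p[p$species == "PS", ]
  # residues at the two headgroup-adjacent z-levels of each helix
  depth_res <- as.vector(outer(c(11L, 12L), 12L * (0:9), `+`))
  pr <- ps$probability[ps$residue_id %in% depth_res]
  n <- attr(p, "frames")
  se <- sqrt(mean(pr) * (1 - mean(pr)) / n)
  # Brownian frames are autocorrelated; allow the effective sample deflation
  expect_true(all(abs(pr - mean(pr)) <= 3 * se * sqrt(10)))
})
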