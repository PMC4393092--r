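pf0 <- pore_frame(NULL)

test_that("thermo and the Boltzmann closed form", {
  th <- thermo(300)
  expect_equal(th$RT_kcal, 0.5962, tolerance = 1e-4)
  prof <- zprofile(c(-1, 0, 1), values = c(1e-4, exp(1) * 1e-4),
                   n_samples = c(100L, 100L), quantity = "concentration")
  G <- free_energy_profile(prof, c_bulk = 1e-4, th)
  expect_equal(G$values[1], 0)
  expect_equal(G$values[2], -0.5962, tolerance = 1e-4)
  # zero-concentration bin -> NA, not a clipped barrier
  prof0 <- zprofile(c(-1, 0, 1), values = c(0, 1e-4),
                    n_samples = c(0L, 50L), quantity = "concentration")
  G0 <- free_energy_profile(prof0, 1e-4, th)
  expect_true(is.na(G0$values[1]))
  expect_error(free_energy_profile(prof, c_bulk = 0), "c_bulk")
})

test_that("occupancy histogram counts snapshot fractions per slab", {
  # atom fixed at z = 7: single bin value 1.0
  frames <- lapply(1:40, function(i) matrix(c(0, 0, 7), 1))
  traj <- traj_from_frames(frames)
  occ <- occupancy_histogram(traj, 1, pf0, slab_width_A = 1)
  expect_equal(sum(occ$values), 1)
  expect_equal(occ$values[slab_index(7, occ$bin_edges_A)], 1)

  # half frames at +7, half at -7
  frames <- c(lapply(1:20, function(i) matrix(c(0, 0, 7), 1)),
              lapply(1:20, function(i) matrix(c(0, 0, -7), 1)))
  # interleave to keep times increasing irrelevant; order is irrelevant
  occ <- occupancy_histogram(traj_from_frames(frames), 1, pf0, 1)
  expect_equal(occ$values[slab_index(7, occ$bin_edges_A)], 0.5)
  expect_equal(occ$values[slab_index(-7, occ$bin_edges_A)], 0.5)

  # uniform positions: multinomial 3-sigma gate per bin
  set.seed(301)
  zz <- runif(20000, -22, 22)
  traj <- traj_from_frames(lapply(zz, function(v) matrix(c(0, 0, v), 1)))
  occ <- occupancy_histogram(traj, 1, pf0, slab_width_A = 2)
  p <- 2 / 44
  sigma <- sqrt(p * (1 - p) / 20000)
  expect_true(all(abs(occ$values - p) < 3.5 * sigma))
  expect_equal(sum(occ$values), 1)
})

test_that("interaction profile divides contact snapshots by slab occupancy", {
  # 100 frames in one bin; contact formed in exactly 30 of them
  frames <- lapply(1:100, function(i) matrix(c(0, 0, 7.5), 1))
  traj <- traj_from_frames(frames)
  rec <- mk_records(0:29, "electrostatic", "lig", "K12", 3.5)
  prof <- interaction_profile(traj, rec, "K12", 1, pf0, 1)
  b <- slab_index(7.5, prof$bin_edges_A)
  expect_equal(prof$values[b], 0.3)
  expect_true(all(is.na(prof$values[-b])))
  expect_equal(prof$n_samples[b], 100L)

  # contact formed in every frame -> 1.0; never -> 0.0
  rec_all <- mk_records(0:99, "electrostatic", "lig", "K12", 3.5)
  expect_equal(interaction_profile(traj, rec_all, "K12", 1, pf0, 1)$values[b], 1)
  rec_none <- mk_records(integer(0), character(0), character(0),
                         character(0), numeric(0))
  expect_equal(interaction_profile(traj, rec_none, "K12", 1, pf0, 1)$values[b], 0)

  # values always within [0, 1] on random data
  set.seed(302)
  zz <- runif(500, -20, 20)
  traj <- traj_from_frames(lapply(zz, function(v) matrix(c(0, 0, v), 1)))
  rec <- mk_records(sample(0:499, 200), "electrostatic", "lig", "K12", 3.5)
  prof <- interaction_profile(traj, rec, "K12", 1, pf0, 1)
  v <- prof$values[!is.na(prof$values)]
  expect_true(all(v >= 0 & v <= 1))
})

test_that("pairing profile averages simultaneous distinct cations", {
  frames <- lapply(1:60, function(i) matrix(c(0, 0, 2.5), 1))
  traj <- traj_from_frames(frames)
  # exactly 2 cations in every frame
  rec <- rbind(mk_records(0:59, "cation_pairing", "phos", "cat1", 3.0),
               mk_records(0:59, "cation_pairing", "phos", "cat2", 3.0))
  prof <- pairing_profile(traj, rec, 1, pf0, 1)
  b <- slab_index(2.5, prof$bin_edges_A)
  expect_equal(prof$values[b], 2)

  # no cations -> 0
  prof0 <- pairing_profile(traj, rec[0, ], 1, pf0, 1)
  expect_equal(prof0$values[b], 0)

  # alternating 1 and 3 distinct cations -> mean 2
  odd <- seq(0, 58, 2); even <- seq(1, 59, 2)
  rec <- rbind(mk_records(odd, "cation_pairing", "phos", "cat1", 3.0),
               mk_records(even, "cation_pairing", "phos", "cat1", 3.0),
               mk_records(even, "cation_pairing", "phos", "cat2", 3.0),
               mk_records(even, "cation_pairing", "phos", "cat3", 3.0))
  prof <- pairing_profile(traj, rec, 1, pf0, 1)
  expect_equal(prof$values[b], 2)
})

test_that("concentration profile divides counts by the slab cylinder volume", {
  # one ion fixed inside a bin
  frames <- lapply(1:50, function(i) matrix(c(1, 0, 3.2), 1))
  traj <- traj_from_frames(frames)
  conc <- concentration_profile(traj, 1, pf0, slab_width_A = 1,
                                radial_cutoff_A = 10)
  b <- slab_index(3.2, conc$bin_edges_A)
  expect_equal(conc$values[b], 1 / (pi * 100 * 1))
  expect_equal(sum(conc$values[-b]), 0)

  # doubling slab width preserves density values
  conc2 <- concentration_profile(traj, 1, pf0, slab_width_A = 2,
                                 radial_cutoff_A = 10)
  b2 <- slab_index(3.2, conc2$bin_edges_A)
  expect_equal(conc2$values[b2], 1 / (pi * 100 * 2))

  # ideal gas at known density: every bin within Poisson error
  set.seed(303)
  n_part <- 50; nf <- 400; R <- 10
  frames <- lapply(seq_len(nf), function(i) {
    rho <- R * sqrt(runif(n_part)); phi <- runif(n_part, 0, 2 * pi)
    cbind(rho * cos(phi), rho * sin(phi), runif(n_part, -22, 22))
  })
  traj <- traj_from_frames(frames)
  conc <- concentration_profile(traj, seq_len(n_part), pf0, 2, R)
  rho_true <- n_part / (pi * R^2 * 44)
  lam <- rho_true * pi * R^2 * 2 * nf        # expected counts per bin
  expect_true(all(abs(conc$n_samples - lam) < 4 * sqrt(lam)))
})

test_that("bulk concentration estimation recovers a known density", {
  set.seed(304)
  n_part <- 60; nf <- 300; R <- 12; Lz <- 90
  frames <- lapply(seq_len(nf), function(i) {
    rho <- R * sqrt(runif(n_part)); phi <- runif(n_part, 0, 2 * pi)
    cbind(rho * cos(phi), rho * sin(phi), runif(n_part, -Lz / 2, Lz / 2))
  })
  traj <- traj_from_frames(frames)
  rho_true <- n_part / (pi * R^2 * Lz)
  est <- estimate_bulk_concentration(traj, seq_len(n_part), pf0,
                                     bulk_z_range = c(20, 45),
                                     radial_cutoff_A = R)
  n_expect <- rho_true * pi * R^2 * 25
  sigma <- sqrt(n_expect / nf) / (pi * R^2 * 25)
  expect_lt(abs(est - rho_true), 3 * sigma)
  expect_error(estimate_bulk_concentration(traj, 1, pf0, c(5, 5)), "zero volume")
})

test_that("block standard error matches hand computation and scaling", {
  expect_equal(block_standard_error(rep(3.2, 100), 4)$se, 0)
  bse <- block_standard_error(c(1, 1, 1, 2, 2, 2), 2)
  expect_equal(bse$mean, 1.5)
  expect_equal(bse$block_means, c(1, 2))
  expect_equal(bse$se, stats::sd(c(1, 2)) / sqrt(2))   # = 0.5
  expect_equal(bse$se, 0.5)
  expect_error(block_standard_error(1:3, 4), "shorter")

  # iid noise: se approx sigma/sqrt(n), up to the small-sample bias of
  # the sd of 6 block means (c4 correction)
  set.seed(305)
  reps <- replicate(200, block_standard_error(rnorm(600), 6)$se)
  c4 <- sqrt(2 / 5) * gamma(3) / gamma(2.5)
  expect_lt(abs(mean(reps) - c4 / sqrt(600)), 3 * stats::sd(reps) / sqrt(200))
  # 1/sqrt scaling: quadrupling the series length halves the se
  reps4 <- replicate(200, block_standard_error(rnorm(2400), 6)$se)
  expect_lt(abs(mean(reps) / mean(reps4) - 2), 0.3)
})

test_that("pairing profile is bounded by the number of cations", {
  set.seed(306)
  frames <- lapply(1:80, function(i) matrix(c(0, 0, runif(1, -10, 10)), 1))
  traj <- traj_from_frames(frames)
  picks <- lapply(0:79, function(f) sample(3, sample(0:3, 1)))
  rec <- do.call(rbind, lapply(seq_along(picks), function(k) {
    if (length(picks[[k]]) == 0) return(NULL)
    mk_records(k - 1L, "cation_pairing", "phos",
               paste0("cat", picks[[k]]), 3.0)
  }))
  prof <- pairing_profile(traj, rec, 1, pf0, 2)
  v <- prof$values[!is.na(prof$values)]
  expect_true(all(v >= 0 & v <= 3))
})

test_that("selectivity is stable under frame subsampling", {
  set.seed(307)
  n_an <- 30; n_cat <- 10; nf <- 600
  frames <- lapply(seq_len(nf), function(i) {
    cbind(runif(n_an + n_cat, -5, 5), runif(n_an + n_cat, -5, 5),
          runif(n_an + n_cat, -45, 45))
  })
  traj <- traj_from_frames(frames)
  full <- selectivity_ratio(traj, 1:n_an, n_an + 1:n_cat, pf0)
  half <- trajectory(traj$system, traj$coords[, , seq(1, nf, 2)],
                     dt_ns = 0.2)
  sub <- selectivity_ratio(half, 1:n_an, n_an + 1:n_cat, pf0)
  # iid frames: subsampled ratio within 3 sigma of the full-run ratio
  expect_lt(abs(sub$ratio - full$ratio) / full$ratio, 0.2)
})

test_that("selectivity ratio recovers density ratios and inverts on swap", {
  # constructed: always 3 anions and 1 cation inside
  frames <- lapply(1:30, function(i) {
    rbind(c(0, 0, 5), c(1, 0, -5), c(0, 1, 0), c(2, 0, 3),  # anions in
          c(0, 0, 40))                                      # cation outside
  })
  frames <- lapply(frames, function(m) { m[4, ] <- c(2, 0, 3); m })
  traj <- traj_from_frames(frames)
  res <- selectivity_ratio(traj, anion_atoms = 1:3, cation_atoms = 4, pf0)
  expect_equal(res$ratio, 3)
  swapped <- selectivity_ratio(traj, anion_atoms = 4, cation_atoms = 1:3, pf0)
  expect_equal(swapped$ratio, 1 / res$ratio)
  expect_error(selectivity_ratio(traj, 1:3, 5, pf0), "undefined")
})
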