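test_that("toy pore builder places tagged decorations deterministically", {
  pore <- build_toy_pore()
  nz <- tagged_indices(pore, "sidechain_nitrogen")
  xyz <- attr(pore, "coords")
  central <- sum(abs(xyz[nz, 3]) < 5)
  # default decoration: LYS + ARG(3 N) + LYS in |z| < 5
  expect_equal(central, 5L)
  expect_equal(length(unique(pore$atoms$resno[nz][abs(xyz[nz, 3]) < 5])), 3L)
  # peripheral sites exist beyond |z| > 5
  expect_gt(sum(abs(xyz[nz, 3]) > 5), 0)

  # bare cylinder
  bare <- build_toy_pore(sites = NULL)
  expect_equal(length(tagged_indices(bare, "sidechain_nitrogen")), 0L)

  # deterministic: two builds identical
  expect_identical(attr(build_toy_pore(), "coords"), xyz)

  # overlap detection
  expect_error(build_toy_pore(sites = data.frame(
    kind = c("LYS", "LYS"), z = c(0, 0), azimuth_deg = c(0, 0))),
    "overlap")
})

test_that("BD is reproducible under a fixed seed and frozen at D = 0", {
  spec <- synthetic_spec(seed = 99, n_frames = 50, save_every = 5,
                         species = list(list(name = "ANI", charge = -1L,
                                             count = 8,
                                             diffusion_A2_per_ns = 200,
                                             feels_potential = TRUE)))
  s1 <- simulate_bd(spec)
  s2 <- simulate_bd(spec)
  expect_identical(s1$trajectory$coords, s2$trajectory$coords)

  spec0 <- synthetic_spec(seed = 99, n_frames = 20, save_every = 2,
                          species = list(list(name = "ANI", charge = -1L,
                                              count = 5,
                                              diffusion_A2_per_ns = 0,
                                              feels_potential = TRUE)))
  s0 <- simulate_bd(spec0)
  for (i in 2:n_frames(s0$trajectory)) {
    expect_identical(s0$trajectory$coords[, , i], s0$trajectory$coords[, , 1])
  }
})

test_that("free diffusion with reflecting walls is uniform and unbiased in z", {
  spec <- synthetic_spec(seed = 7, potential = list(),
                         n_frames = 3000, save_every = 5,
                         species = list(list(name = "ANI", charge = -1L,
                                             count = 30,
                                             diffusion_A2_per_ns = 200,
                                             feels_potential = TRUE)))
  sim <- simulate_bd(spec)
  z <- as.vector(z_series(sim$trajectory, pore_frame(NULL),
                          seq_len(n_atoms(sim$trajectory$system))))
  # chi-square uniformity over 15 bins; thinned to reduce autocorrelation
  thin <- z[seq(1, length(z), by = 25)]
  h <- table(cut(thin, breaks = seq(-45, 45, length.out = 16)))
  p <- suppressWarnings(stats::chisq.test(h)$p.value)
  expect_gt(p, 0.01)
  # mean displacement from start -> 0 within 3 sigma of the sample mean
  expect_lt(abs(mean(thin)), 3 * stats::sd(thin) / sqrt(length(thin)))
})

test_that("BD stationary density recovers a single Gaussian well potential", {
  spec <- synthetic_spec(seed = 21,
                         potential = list(gaussian_term(-2.0, 0, 3)),
                         n_frames = 8000, save_every = 10,
                         species = list(list(name = "ANI", charge = -1L,
                                             count = 30,
                                             diffusion_A2_per_ns = 200,
                                             feels_potential = TRUE)))
  sim <- simulate_bd(spec)
  pf <- pore_frame(NULL)
  conc <- concentration_profile(sim$trajectory,
                                seq_len(n_atoms(sim$trajectory$system)),
                                pf, slab_width_A = 2,
                                radial_cutoff_A = spec$pore_radius_A)
  pmf <- free_energy_profile(conc, sim$ground_truth$true_bulk_density$ANI)
  U <- potential_u(bin_centers(pmf), spec$potential)
  ok <- conc$n_samples >= 500 & !is.na(pmf$values)
  expect_gt(sum(ok), 10)
  expect_lt(max(abs(pmf$values[ok] - U[ok])), 0.3)
})

test_that("divergent steps and coarse time steps are flagged", {
  spec <- synthetic_spec(seed = 1, n_frames = 5, save_every = 1,
                         timestep_ns = 40,
                         potential = list(gaussian_term(-2, 0, 3)),
                         species = list(list(name = "ANI", charge = -1L,
                                             count = 3,
                                             diffusion_A2_per_ns = 200,
                                             feels_potential = TRUE)))
  expect_warning(try(simulate_bd(spec), silent = TRUE), "time step")
})

test_that("ligand beads move rigidly and carry the advertised tags", {
  spec <- synthetic_spec(seed = 5, n_frames = 30, save_every = 2,
                         species = list(list(name = "CAT", charge = 1L,
                                             count = 4,
                                             diffusion_A2_per_ns = 100,
                                             feels_potential = FALSE)),
                         ligand = list(name = "PLG",
                                       diffusion_A2_per_ns = 50,
                                       start_z_A = 0,
                                       feels_potential = TRUE))
  sim <- simulate_bd(spec, pore = build_toy_pore())
  sys <- sim$trajectory$system
  expect_equal(length(tagged_indices(sys, "phosphorus_terminal")), 1L)
  expect_equal(length(tagged_indices(sys, "phosphate_oxygen")), 3L)
  expect_equal(length(sys$topology_groups$ligand_ring), 3L)
  # rigid: inter-bead distances constant over time
  pidx <- tagged_indices(sys, "phosphorus_terminal")
  oidx <- tagged_indices(sys, "phosphate_oxygen")[1]
  d <- vapply(seq_len(n_frames(sim$trajectory)), function(i) {
    cc <- get_frame(sim$trajectory, i)$coords
    sqrt(sum((cc[pidx, ] - cc[oidx, ])^2))
  }, numeric(1))
  expect_equal(max(d) - min(d), 0, tolerance = 1e-12)
  # static pore atoms never move
  shell <- select_atoms(sys, resname = "CYL")[1]
  s <- vapply(seq_len(n_frames(sim$trajectory)), function(i) {
    get_frame(sim$trajectory, i)$coords[shell, 1]
  }, numeric(1))
  expect_equal(max(s) - min(s), 0)
})
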