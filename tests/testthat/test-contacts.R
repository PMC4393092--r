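test_that("criteria boundary fixtures reproduce the stated inclusivity", {
  fx <- make_contact_fixture("electrostatic")
  r <- detect_electrostatic(fx$coords, fx$phosphate_oxygens, fx$basic_nitrogens)
  expect_setequal(r$partner_b, fx$expected)      # 3.9 and 4.0 hit, 4.1 misses

  fx <- make_contact_fixture("pairing")
  r <- detect_cation_pairing(fx$coords, fx$phosphate_oxygens, fx$cations)
  expect_setequal(r$partner_b, fx$expected)      # 4.0 exactly is a miss

  fx <- make_contact_fixture("pipi")
  hits <- names(fx$partners)[vapply(names(fx$partners), function(nm) {
    nrow(detect_pi_pi(fx$coords, fx$ring_a, fx$partners[[nm]],
                      partner_b = nm)) > 0
  }, logical(1))]
  expect_setequal(hits, fx$expected)             # 29 deg at 5.9 A hits; 6.0 A misses

  fx <- make_contact_fixture("cationpi")
  r <- detect_cation_pi(fx$coords, fx$ring, fx$basic_residues)
  expect_setequal(r$partner_b, fx$expected)      # plane angle exactly 60 misses

  fx <- make_contact_fixture("guanidinium")
  hits <- names(fx$partners)[vapply(names(fx$partners), function(nm) {
    nrow(detect_guanidinium_stack(fx$coords, fx$ring, fx$partners[[nm]],
                                  partner_b = nm)) > 0
  }, logical(1))]
  expect_setequal(hits, fx$expected)             # 29.9 deg at 5.9 A hits

  fx <- make_contact_fixture("hbond")
  r <- detect_hbond(fx$coords, fx$donors, fx$acceptors)
  expect_setequal(r$partner_b, paste0("A", fx$acceptors[fx$expected]))
})

test_that("detectors equal the brute-force O(n^2) oracle on random frames", {
  set.seed(101)
  for (trial in 1:50) {
    n_o <- sample(2:5, 1); n_res <- sample(2:5, 1); n_cat <- sample(2:4, 1)
    coords <- matrix(runif((n_o + 2 * n_res + n_cat) * 3, -6, 6), ncol = 3)
    oxy <- list(lig = seq_len(n_o))
    nitro <- split(n_o + seq_len(2 * n_res),
                   rep(paste0("res", seq_len(n_res)), each = 2))
    cations <- as.list(n_o + 2 * n_res + seq_len(n_cat))
    names(cations) <- paste0("cat", seq_len(n_cat))

    r_el <- detect_electrostatic(coords, oxy, nitro)
    expect_setequal(r_el$partner_b,
                    oracle_electrostatic(coords, oxy$lig, nitro))
    r_pr <- detect_cation_pairing(coords, oxy, cations)
    expect_setequal(r_pr$partner_b,
                    oracle_pairing(coords, oxy$lig, cations))
  }
})

test_that("hbond detector matches its oracle and validates donors", {
  set.seed(102)
  for (trial in 1:30) {
    nd <- sample(1:3, 1); na_ <- sample(2:5, 1)
    D <- matrix(runif(nd * 3, -4, 4), ncol = 3)
    Hoff <- matrix(rnorm(nd * 3), ncol = 3)
    Hoff <- Hoff / sqrt(rowSums(Hoff^2))
    coords <- rbind(D, D + Hoff, matrix(runif(na_ * 3, -4, 4), ncol = 3))
    donors <- cbind(seq_len(nd), nd + seq_len(nd))
    acceptors <- 2 * nd + seq_len(na_)
    r <- detect_hbond(coords, donors, acceptors)
    orc <- oracle_hbond(coords, donors, acceptors)
    expect_equal(nrow(r), length(orc))
    if (length(orc) > 0) {
      expect_setequal(paste(r$partner_a, r$partner_b),
                      vapply(orc, function(p) paste0("D", p[1], " A", p[2]),
                             character(1)))
    }
  }
  # mis-specified donor: |D-H| > 1.2 A
  coords <- rbind(c(0, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_error(detect_hbond(coords, cbind(1L, 2L), 3L), "mis-specified")
})

test_that("detectors are invariant under rigid rotation + translation", {
  # random (generic, off-threshold) geometries: the rotated frame must
  # yield exactly the partner sets of the unrotated frame. Geometries
  # exactly ON a threshold are zero-measure and excluded: a rigid
  # rotation perturbs distances at the 1e-15 level, which flips the
  # strict/inclusive comparison right at the boundary.
  set.seed(103)
  for (rep_ in 1:10) {
    coords <- matrix(runif(36, -6, 6), ncol = 3)
    oxy <- list(lig = 1:3)
    nitro <- list(res1 = 4:5, res2 = 6:7, res3 = 8:9)
    donors <- cbind(10L, 11L)
    coords[11, ] <- coords[10, ] + c(1, 0, 0)
    R <- random_rotation(); tvec <- runif(3, -20, 20)
    xf <- sweep(coords %*% t(R), 2, tvec, "+")
    expect_setequal(
      detect_electrostatic(xf, oxy, nitro)$partner_b,
      detect_electrostatic(coords, oxy, nitro)$partner_b)
    expect_setequal(
      detect_cation_pairing(xf, oxy, list(c1 = 12L))$partner_b,
      detect_cation_pairing(coords, oxy, list(c1 = 12L))$partner_b)
    expect_setequal(
      detect_hbond(xf, donors, 12L)$partner_b,
      detect_hbond(coords, donors, 12L)$partner_b)
    expect_setequal(
      detect_cation_pi(xf, 1:3, list(res = matrix(c(10L, 11L), 1)))$partner_b,
      detect_cation_pi(coords, 1:3, list(res = matrix(c(10L, 11L), 1)))$partner_b)
  }
})

test_that("ring_plane returns centroid and a true normal; collinear errors", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  pl <- ring_plane(tri, 1:3)
  expect_equal(abs(pl$normal), c(0, 0, 1))
  expect_equal(pl$center, colMeans(tri))
  set.seed(104)
  tri <- matrix(rnorm(9), 3)
  pl <- ring_plane(tri, 1:3)
  expect_lt(abs(sum(pl$normal * (tri[2, ] - tri[1, ]))), 1e-10)
  expect_lt(abs(sum(pl$normal * (tri[3, ] - tri[1, ]))), 1e-10)
  # mass weighting moves the center toward the heavy atom
  pl_w <- ring_plane(tri, 1:3, masses = c(2, 1, 1))
  expect_equal(pl_w$center, colSums(tri * c(2, 1, 1)) / 4)
  expect_error(ring_plane(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)), 1:3),
               "collinear")
})

test_that("minimum-image distances apply when a box is present", {
  coords <- rbind(c(1, 0, 0), c(39, 0, 0))   # 2 A apart across the boundary
  box <- c(40, 40, 40)
  r <- detect_electrostatic(coords, list(lig = 1L), list(res = 2L),
                            box = box)
  expect_equal(nrow(r), 1)
  expect_equal(r$distance, 2)
  r_nobox <- detect_electrostatic(coords, list(lig = 1L), list(res = 2L))
  expect_equal(nrow(r_nobox), 0)
})

test_that("timelines and long-lived classification follow run-length counting", {
  # contact in frames 0..99 at dt = 0.1 -> one 10 ns run, long-lived
  rec <- mk_records(0:99, "electrostatic", "lig", "res1", 3.0)
  tl <- build_timelines(rec)
  cls <- classify_longlived(tl, dt_ns = 0.1)
  expect_equal(cls$max_run_ns, 10)
  expect_true(cls$is_longlived)

  # frames {0, 2, 4}: three 0.1 ns runs, not long-lived
  rec <- mk_records(c(0L, 2L, 4L), "electrostatic", "lig", "res1", 3.0)
  cls <- classify_longlived(build_timelines(rec), dt_ns = 0.1)
  expect_equal(cls$max_run_ns, 0.1)
  expect_equal(cls$n_runs, 3L)
  expect_false(cls$is_longlived)

  # exactly 5 ns is not long-lived (strict >)
  rec <- mk_records(0:49, "hbond", "lig", "res2", 3.0)
  cls <- classify_longlived(build_timelines(rec), dt_ns = 0.1)
  expect_equal(cls$max_run_ns, 5)
  expect_false(cls$is_longlived)

  # random patterns match an independent run-length encoding
  set.seed(105)
  for (trial in 1:20) {
    present <- which(runif(200) < 0.4) - 1L
    if (length(present) == 0) next
    rec <- mk_records(present, "hbond", "a", "b", 3.0)
    cls <- classify_longlived(build_timelines(rec), dt_ns = 0.05)
    # oracle: longest run of consecutive integers
    runs <- rle(cumsum(c(TRUE, diff(present) != 1L)))$lengths
    expect_equal(cls$max_run_ns, max(runs) * 0.05)
  }
})
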