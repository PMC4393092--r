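# Slice-averaged statistics along the pore axis and Boltzmann-inversion
# energetics. Slices are half-open [lo, hi) bins on the pore-frame z
# coordinate; the default grid spans [-22, 22] Angstrom.

#' Thermodynamic constants
#'
#' @param temperature_K absolute temperature (default 300 K; RT at 300 K
#'   is 0.5962 kcal/mol).
#' @return list with `temperature_K` and `RT_kcal` (R = 0.0019872041
#'   kcal/mol/K).
#' @export
thermo <- function(temperature_K = 300) {
  if (temperature_K <= 0) stop("temperature must be positive")
  list(temperature_K = temperature_K,
       RT_kcal = 0.0019872041 * temperature_K)
}

#' Occupancy histogram of a tracked atom along z
#'
#' Per slab, the fraction of MD snapshots with the tracked atom's z
#' inside the slab (the "relative number of snapshots featuring" the
#' group there). Values sum to at most 1; less when the atom leaves the
#' binned range.
#'
#' @param traj a `trajectory`.
#' @param tracked_atom atom index (typically the terminal phosphorus).
#' @param pf a `pore_frame`.
#' @param slab_width_A slab thickness; ignored if `edges` given.
#' @param edges explicit bin edges (default uniform grid over the pore
#'   frame's slab range).
#' @return a `zprofile` with quantity `occupancy_fraction`.
#' @export
occupancy_histogram <- function(traj, tracked_atom, pf, slab_width_A = 1,
                                edges = NULL) {
  nf <- n_frames(traj)
  if (nf == 0) stop("trajectory has zero frames")
  if (is.null(edges)) {
    edges <- slab_edges(slab_width_A, range(pf$slab_edges_A))
  }
  z <- z_series(traj, pf, tracked_atom)
  bi <- slab_index(z, edges)
  counts <- tabulate(bi[!is.na(bi)], nbins = length(edges) - 1L)
  zprofile(edges, counts / nf, n_samples = counts,
           quantity = "occupancy_fraction")
}

#' Slice-averaged interaction profile (N_int)
#'
#' Per slab: the number of snapshots in which the tracked group is in the
#' slab AND its contact with `residue_id` is formed, divided by the total
#' number of snapshots with the group in that slab. Unvisited slabs get
#' `NA` with `n_samples = 0`. Slice thickness defaults: 1 Angstrom for
#' hydrogen-bond/electrostatic profiles, 2 Angstrom for cation-pi/pi-pi.
#'
#' @param traj a `trajectory`.
#' @param records contact records over the trajectory (0-based frames),
#'   e.g. from [detect_over_trajectory()].
#' @param residue_id value of `partner_b` identifying the residue.
#' @param tracked_atom atom index tracked along z.
#' @param pf a `pore_frame`.
#' @param slab_width_A slab thickness.
#' @param edges explicit bin edges.
#' @param partner_a optional `partner_a` filter (default all ligand
#'   groups).
#' @return a `zprofile` with quantity `n_int`; values in [0, 1].
#' @export
interaction_profile <- function(traj, records, residue_id, tracked_atom, pf,
                                slab_width_A = 1, edges = NULL,
                                partner_a = NULL) {
  if (is.null(edges)) edges <- slab_edges(slab_width_A, range(pf$slab_edges_A))
  z <- z_series(traj, pf, tracked_atom)
  bi <- slab_index(z, edges)
  sel <- records$partner_b == residue_id
  if (!is.null(partner_a)) sel <- sel & records$partner_a %in% partner_a
  contact_frames <- unique(records$frame[sel]) + 1L   # to 1-based
  formed <- seq_len(n_frames(traj)) %in% contact_frames
  nb <- length(edges) - 1L
  tot <- tabulate(bi[!is.na(bi)], nbins = nb)
  hit <- tabulate(bi[!is.na(bi) & formed], nbins = nb)
  vals <- ifelse(tot > 0, hit / pmax(tot, 1), NA_real_)
  zprofile(edges, vals, n_samples = tot, quantity = "n_int")
}

#' Ion-pairing profile
#'
#' Per slab: the mean, over snapshots with the tracked group in the slab,
#' of the number of distinct cations simultaneously paired with it.
#'
#' @inheritParams interaction_profile
#' @param pairing_records records from [detect_cation_pairing()] via
#'   [detect_over_trajectory()].
#' @return a `zprofile` with quantity `n_pairing`.
#' @export
pairing_profile <- function(traj, pairing_records, tracked_atom, pf,
                            slab_width_A = 1, edges = NULL) {
  if (is.null(edges)) edges <- slab_edges(slab_width_A, range(pf$slab_edges_A))
  z <- z_series(traj, pf, tracked_atom)
  bi <- slab_index(z, edges)
  nf <- n_frames(traj)
  npair <- integer(nf)
  if (nrow(pairing_records) > 0) {
    per_frame <- tapply(pairing_records$partner_b, pairing_records$frame,
                        function(x) length(unique(x)))
    f1 <- as.integer(names(per_frame)) + 1L
    ok <- f1 >= 1 & f1 <= nf
    npair[f1[ok]] <- as.integer(per_frame)[ok]
  }
  nb <- length(edges) - 1L
  tot <- tabulate(bi[!is.na(bi)], nbins = nb)
  sums <- numeric(nb)
  inb <- !is.na(bi)
  if (any(inb)) {
    agg <- tapply(npair[inb], bi[inb], sum)
    sums[as.integer(names(agg))] <- agg
  }
  vals <- ifelse(tot > 0, sums / pmax(tot, 1), NA_real_)
  zprofile(edges, vals, n_samples = tot, quantity = "n_pairing")
}

#' Concentration profile of a species inside the pore cylinder
#'
#' Per slab: time-averaged count of species atoms with z in the slab and
#' radial distance from the pore axis below `radial_cutoff_A`, divided by
#' the slab cylinder volume. Units: atoms per cubic Angstrom.
#'
#' @param traj a `trajectory`.
#' @param species_atoms atom indices of the species.
#' @param pf a `pore_frame`.
#' @param slab_width_A slab thickness.
#' @param radial_cutoff_A radius of the sampling cylinder.
#' @param edges explicit bin edges.
#' @return a `zprofile` with quantity `concentration`.
#' @export
concentration_profile <- function(traj, species_atoms, pf, slab_width_A = 1,
                                  radial_cutoff_A = 12, edges = NULL) {
  if (radial_cutoff_A <= 0) stop("radial cutoff must be positive")
  if (is.null(edges)) edges <- slab_edges(slab_width_A, range(pf$slab_edges_A))
  nf <- n_frames(traj)
  zm <- z_series(traj, pf, species_atoms)
  if (is.null(dim(zm))) zm <- matrix(zm, ncol = 1)
  rm_ <- radial_series(traj, pf, species_atoms)
  inside <- rm_ < radial_cutoff_A
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  bi <- slab_index(as.vector(zm), edges)
  keep <- !is.na(bi) & as.vector(inside)
  if (any(keep)) counts <- tabulate(bi[keep], nbins = nb)
  widths <- diff(edges)
  vol <- pi * radial_cutoff_A^2 * widths
  zprofile(edges, counts / nf / vol, n_samples = counts,
           quantity = "concentration")
}

#' Boltzmann-inversion free-energy profile
#'
#' Converts a concentration profile to a free energy,
#' \deqn{\Delta G_i(z) = -RT \ln(C_i(z)/C_{bulk}),}
#' in kcal/mol. Bins with zero concentration yield `NA` (an unresolved,
#' effectively infinite barrier) rather than a clipped large number.
#'
#' @param conc_profile a `zprofile` of quantity `concentration`.
#' @param c_bulk bulk concentration of the species (same units).
#' @param th a [thermo()] list.
#' @return a `zprofile` with quantity `free_energy_kcal`; per-bin `se`
#'   propagated from Poisson counting error when sample counts are
#'   available (se_G = RT * se_C / C).
#' @export
free_energy_profile <- function(conc_profile, c_bulk, th = thermo()) {
  if (!is.numeric(c_bulk) || c_bulk <= 0) stop("c_bulk must be > 0")
  C <- conc_profile$values
  G <- ifelse(!is.na(C) & C > 0, -th$RT_kcal * log(C / c_bulk), NA_real_)
  se <- NULL
  n <- conc_profile$n_samples
  if (!all(is.na(n))) {
    se <- ifelse(!is.na(n) & n > 0, th$RT_kcal / sqrt(pmax(n, 1)), NA_real_)
  }
  zprofile(conc_profile$bin_edges_A, G, se = se, n_samples = n,
           quantity = "free_energy_kcal")
}

#' Estimate bulk concentration from a designated z range
#'
#' Time-averaged species density over the bulk region: a cylinder of
#' `radial_cutoff_A` spanning `bulk_z_range` (which should lie outside
#' the pore, |z| > pore half-length plus a margin).
#'
#' @inheritParams concentration_profile
#' @param bulk_z_range length-2 z interval (Angstrom).
#' @return density in atoms per cubic Angstrom.
#' @export
estimate_bulk_concentration <- function(traj, species_atoms, pf,
                                        bulk_z_range, radial_cutoff_A = 12) {
  if (diff(bulk_z_range) <= 0) stop("bulk region has zero volume")
  zm <- z_series(traj, pf, species_atoms)
  if (is.null(dim(zm))) zm <- matrix(zm, ncol = 1)
  rm_ <- radial_series(traj, pf, species_atoms)
  inside <- zm >= bulk_z_range[1] & zm < bulk_z_range[2] &
    rm_ < radial_cutoff_A
  vol <- pi * radial_cutoff_A^2 * diff(bulk_z_range)
  mean(rowSums(inside)) / vol
}

#' Block-averaged mean and standard error
#'
#' Splits a per-frame series into `n_blocks` contiguous, near-equal
#' blocks; reports the mean of block means and the standard error of the
#' block means (sd / sqrt(n_blocks)). This is the windowed error estimate
#' used for time-correlated simulation series.
#'
#' @param x numeric per-frame series.
#' @param n_blocks number of contiguous blocks (>= 2).
#' @return list with `mean`, `se`, `block_means`.
#' @export
block_standard_error <- function(x, n_blocks) {
  if (n_blocks < 2) stop("need at least 2 blocks")
  if (length(x) < n_blocks) stop("series shorter than number of blocks")
  grp <- ceiling(seq_along(x) * n_blocks / length(x))
  bm <- as.numeric(tapply(x, grp, mean))
  list(mean = mean(bm), se = stats::sd(bm) / sqrt(n_blocks),
       block_means = bm)
}

#' Anion/cation selectivity ratio of the pore
#'
#' Ratio of time-averaged simultaneous occupancies (number of particles
#' inside the pore region) of anions over cations. The pore region is a
#' cylinder |z| <= `z_max_A` with radius `radial_cutoff_A`.
#'
#' @param traj a `trajectory`.
#' @param anion_atoms,cation_atoms atom index vectors for the two species.
#' @param pf a `pore_frame`.
#' @param z_max_A axial half-extent of the pore region (default 15,
#'   matching the translocation slab).
#' @param radial_cutoff_A cylinder radius (default 12).
#' @return object of class `selectivity_result`: list with `n_anion_avg`,
#'   `n_cation_avg`, `ratio`, `pore_region`.
#' @export
selectivity_ratio <- function(traj, anion_atoms, cation_atoms, pf,
                              z_max_A = 15, radial_cutoff_A = 12) {
  count_inside <- function(atoms) {
    zm <- z_series(traj, pf, atoms)
    if (is.null(dim(zm))) zm <- matrix(zm, ncol = 1)
    rm_ <- radial_series(traj, pf, atoms)
    rowSums(abs(zm) <= z_max_A & rm_ < radial_cutoff_A)
  }
  na_ <- mean(count_inside(anion_atoms))
  nc <- mean(count_inside(cation_atoms))
  if (nc == 0) stop("zero time-averaged cation occupancy: ratio undefined")
  structure(list(n_anion_avg = na_, n_cation_avg = nc, ratio = na_ / nc,
                 pore_region = list(z_max_A = z_max_A,
                                    radial_cutoff_A = radial_cutoff_A)),
            class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf(
    "selectivity N_anion/N_cation = %.3f (anion %.3f, cation %.3f; |z| <= %g A, r < %g A)\n",
    x$ratio, x$n_anion_avg, x$n_cation_avg,
    x$pore_region$z_max_A, x$pore_region$radial_cutoff_A))
  invisible(x)
}
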