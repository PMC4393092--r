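# Ground-truth-known synthetic inputs: a toy cylindrical pore decorated
# with basic/aromatic interaction sites, and overdamped Brownian-dynamics
# (Euler-Maruyama) trajectories of point ions and a rigid bead-model
# ligand in a stated axial potential. The dynamics' stationary law is
# the Boltzmann distribution exp(-U/RT) — exactly the assumption that
# Boltzmann-inversion free-energy profiles rely on — with no claim of
# reproducing all-atom MD physics.

#' Gaussian term for an axial potential
#' @param amplitude_kcal signed well (-) or barrier (+) height, kcal/mol.
#' @param center_z_A center along z, Angstrom.
#' @param width_A Gaussian sigma, Angstrom (> 0).
#' @return list usable in `synthetic_spec(potential = list(...))`.
#' @export
gaussian_term <- function(amplitude_kcal, center_z_A, width_A) {
  if (width_A <= 0) stop("Gaussian width must be positive")
  list(amplitude_kcal = amplitude_kcal, center_z_A = center_z_A,
       width_A = width_A)
}

#' Evaluate a Gaussian-sum axial potential
#' @param z numeric vector (Angstrom).
#' @param potential list of [gaussian_term()]s.
#' @return U(z) in kcal/mol.
#' @export
potential_u <- function(z, potential) {
  u <- numeric(length(z))
  for (g in potential) {
    u <- u + g$amplitude_kcal * exp(-(z - g$center_z_A)^2 / (2 * g$width_A^2))
  }
  u
}

potential_force <- function(z, potential) {
  f <- numeric(length(z))
  for (g in potential) {
    f <- f + g$amplitude_kcal * (z - g$center_z_A) / g$width_A^2 *
      exp(-(z - g$center_z_A)^2 / (2 * g$width_A^2))
  }
  f   # = -dU/dz
}

#' Specify a synthetic Brownian-dynamics system
#'
#' Defaults describe the stated world the analysis emulates: a wide pore
#' (radius 12 A, half-length 15 A) in a 90-A box; an ATP-like double
#' well (depths 2.0 and 1.0 kcal/mol at z = -5 and +7 A) felt by the
#' anionic species; small-ion diffusion of 200 A^2/ns (about the bulk
#' value for Cl-); 2-fs-scale BD time step of 0.002 ns so D*dt is far
#' below the squared width of the narrowest Gaussian.
#'
#' @param seed master RNG seed; the whole generation is bit-reproducible.
#' @param box_A orthorhombic box lengths (x, y, z), Angstrom.
#' @param pore_half_length_A,pore_radius_A pore slab geometry.
#' @param potential list of [gaussian_term()]s; U(z) applies to species
#'   with `feels_potential = TRUE`.
#' @param timestep_ns BD time step.
#' @param n_frames number of recorded frames.
#' @param save_every record every this many BD steps.
#' @param temperature_K temperature for the Boltzmann factor.
#' @param species list of lists with fields `name`, `charge`, `count`,
#'   `diffusion_A2_per_ns`, `feels_potential`.
#' @param ligand optional rigid bead-model ligand: list with `name`,
#'   `diffusion_A2_per_ns`, `start_z_A`, `feels_potential`.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           box_A = c(40, 40, 90),
                           pore_half_length_A = 15,
                           pore_radius_A = 12,
                           potential = list(
                             gaussian_term(-2.0, -5, 3),
                             gaussian_term(-1.0, 7, 2)),
                           timestep_ns = 0.002,
                           n_frames = 2000,
                           save_every = 10,
                           temperature_K = 300,
                           species = list(
                             list(name = "ANI", charge = -1L, count = 30,
                                  diffusion_A2_per_ns = 200,
                                  feels_potential = TRUE),
                             list(name = "CAT", charge = +1L, count = 30,
                                  diffusion_A2_per_ns = 200,
                                  feels_potential = FALSE)),
                           ligand = NULL) {
  if (timestep_ns <= 0) stop("timestep must be positive")
  if (n_frames < 1 || save_every < 1) stop("n_frames and save_every must be >= 1")
  for (g in potential) if (g$width_A <= 0) stop("Gaussian width must be positive")
  for (s in species) {
    if (s$count < 0) stop("species count must be >= 0")
    if (s$diffusion_A2_per_ns < 0) stop("diffusion constant must be >= 0")
  }
  structure(list(seed = as.integer(seed), box_A = box_A,
                 pore_half_length_A = pore_half_length_A,
                 pore_radius_A = pore_radius_A, potential = potential,
                 timestep_ns = timestep_ns, n_frames = n_frames,
                 save_every = save_every, temperature_K = temperature_K,
                 species = species, ligand = ligand),
            class = "synthetic_spec")
}

# equilateral triangle of unit circumradius in the plane through `center`
# with normal `normal`
place_ring <- function(center, normal, radius = 1.4) {
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  rbind(center + radius * u,
        center + radius * (-0.5 * u + sqrt(3) / 2 * v),
        center + radius * (-0.5 * u - sqrt(3) / 2 * v))
}

#' Build a toy pore system
#'
#' A cylindrical shell of inert pseudo-atoms decorated with interaction
#' sites: Lys-like (NZ + one H), Arg-like (NE/NH1/NH2 guanidinium plane +
#' one H) and Phe-like (aromatic ring triplet) groups at chosen axial
#' positions. The default decoration emulates the central basic cluster
#' (three sites within |z| < 5 A, like K12/R15/K20) plus one cytosolic
#' and one intermembrane-side site (like R218 and K119). The nitrogen
#' atoms face the axis at a configurable radial distance.
#'
#' @param pore_radius_A,pore_half_length_A cylinder geometry.
#' @param sites data.frame with columns `kind` ("LYS", "ARG" or "PHE"),
#'   `z` (axial position), optional `azimuth_deg`; `NULL` gives a bare
#'   cylinder, missing gives the default decoration.
#' @param site_radius_A radial distance of site atoms from the axis.
#' @param n_shell_rings,n_shell_per_ring shell discretisation.
#' @return a `molecular_system` with coordinates attached as attribute
#'   `"coords"`; topology groups `ring_<resno>` and `guanidinium_<resno>`
#'   expose plane triplets.
#' @export
build_toy_pore <- function(pore_radius_A = 12, pore_half_length_A = 15,
                           sites = NULL, site_radius_A = 8,
                           n_shell_rings = 7, n_shell_per_ring = 12) {
  if (missing(sites)) {
    sites <- data.frame(
      kind = c("LYS", "ARG", "LYS", "ARG", "LYS"),
      z = c(-2, 0, 2, 8, -12),
      azimuth_deg = c(0, 72, 144, 216, 288),
      stringsAsFactors = FALSE)
  }
  atoms <- list(); coords <- list(); groups <- list()
  serial <- 0L; resno <- 0L
  add <- function(name, element, resname, xyz, tags = character(0)) {
    serial <<- serial + 1L
    atoms[[serial]] <<- data.frame(serial = serial, name = name,
                                   element = element, resname = resname,
                                   resno = resno, chain = "P",
                                   stringsAsFactors = FALSE)
    atoms[[serial]]$tags <<- list(tags)
    coords[[serial]] <<- xyz
    serial
  }
  # inert shell
  for (iz in seq_len(n_shell_rings)) {
    resno <- resno + 1L
    zz <- -pore_half_length_A +
      (iz - 1) * 2 * pore_half_length_A / max(n_shell_rings - 1, 1)
    for (ia in seq_len(n_shell_per_ring)) {
      th <- 2 * pi * (ia - 1) / n_shell_per_ring
      add("SH", "C", "CYL",
          c(pore_radius_A * cos(th), pore_radius_A * sin(th), zz))
    }
  }
  if (!is.null(sites) && nrow(sites) > 0) {
    if (is.null(sites$azimuth_deg)) {
      sites$azimuth_deg <- seq(0, 359, length.out = nrow(sites))
    }
    placed <- NULL
    for (k in seq_len(nrow(sites))) {
      resno <- resno + 1L
      th <- sites$azimuth_deg[k] * pi / 180
      radial <- c(cos(th), sin(th), 0)         # outward unit vector
      base <- site_radius_A * radial + c(0, 0, sites$z[k])
      if (!is.null(placed)) {
        dmin <- min(sqrt(colSums((t(placed) - base)^2)))
        if (dmin < 1.0) stop("site placement overlap at row ", k)
      }
      placed <- rbind(placed, base)
      kind <- sites$kind[k]
      if (kind == "LYS") {
        i_n <- add("NZ", "N", "LYS", base, "sidechain_nitrogen")
        add("HZ1", "H", "LYS", base - 1.0 * radial, "hydrogen")
      } else if (kind == "ARG") {
        # guanidinium plane facing the axis, normal along the radial
        tri <- place_ring(base, radial, radius = 1.15)
        i1 <- add("NE", "N", "ARG", tri[1, ], "sidechain_nitrogen")
        i2 <- add("NH1", "N", "ARG", tri[2, ], "sidechain_nitrogen")
        i3 <- add("NH2", "N", "ARG", tri[3, ], "sidechain_nitrogen")
        add("HH11", "H", "ARG", tri[2, ] - 1.0 * radial, "hydrogen")
        groups[[paste0("guanidinium_", resno)]] <- c(i1, i2, i3)
      } else if (kind == "PHE") {
        tri <- place_ring(base, radial, radius = 1.39)
        i1 <- add("CG", "C", "PHE", tri[1, ], "ring_atom")
        i2 <- add("CE1", "C", "PHE", tri[2, ], "ring_atom")
        i3 <- add("CE2", "C", "PHE", tri[3, ], "ring_atom")
        groups[[paste0("ring_", resno)]] <- c(i1, i2, i3)
      } else stop("unknown site kind: ", kind)
    }
  }
  tab <- do.call(rbind, atoms)
  sys <- molecular_system(tab, groups)
  attr(sys, "coords") <- do.call(rbind, coords)
  sys
}

# rigid bead template for the model ligand (offsets in Angstrom from the
# diffusing center, which carries the terminal phosphorus)
ligand_template <- function(name = "PLG") {
  data.frame(
    name = c("P", "O1", "O2", "O3", "N6", "H6", "C4A", "C4B", "C4C"),
    element = c("P", "O", "O", "O", "N", "H", "C", "C", "C"),
    dx = c(0, 1.5, -0.75, -0.75, 4.0, 4.0, 4.5, 5.9, 5.2),
    dy = c(0, 0, 1.3, -1.3, 0, 0, 1.8, 1.8, 3.0),
    dz = c(0, 0, 0, 0, 1.0, 2.0, 0, 0, 0),
    tag = c("phosphorus_terminal", "phosphate_oxygen", "phosphate_oxygen",
            "phosphate_oxygen", "donor_heavy", "hydrogen",
            "ring_atom", "ring_atom", "ring_atom"),
    stringsAsFactors = FALSE)
}

#' Simulate overdamped Brownian dynamics
#'
#' Euler-Maruyama update per axis:
#' `dr = -(D/RT) dU/dr dt + sqrt(2 D dt) eta`, `eta ~ N(0,1)`,
#' with reflecting walls at the cylinder radius and the box z faces. The
#' axial potential acts only on species with `feels_potential = TRUE`;
#' x/y motion is free diffusion inside the cylinder. Optionally a static
#' toy pore is embedded (its atoms never move) and a rigid bead-model
#' ligand diffuses as a unit.
#'
#' @param spec a [synthetic_spec()].
#' @param pore optional `molecular_system` from [build_toy_pore()],
#'   embedded as static atoms.
#' @return list with `trajectory` (a [trajectory()]; box attached),
#'   `ground_truth` (potential, RT, per-species true bulk density inside
#'   the cylinder, expected anion/cation pore-occupancy ratio) and
#'   `spec`.
#' @export
simulate_bd <- function(spec, pore = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  th <- thermo(spec$temperature_K)
  RT <- th$RT_kcal
  R <- spec$pore_radius_A
  Lz <- spec$box_A[3]
  dt <- spec$timestep_ns
  # time-step sanity: D*dt must stay well below the narrowest feature
  wmin2 <- if (length(spec$potential) > 0) {
    min(vapply(spec$potential, function(g) g$width_A^2, numeric(1)))
  } else Inf
  dmax <- max(c(vapply(spec$species, function(s) s$diffusion_A2_per_ns,
                       numeric(1)),
                if (!is.null(spec$ligand)) spec$ligand$diffusion_A2_per_ns))
  if (is.finite(wmin2) && dmax * dt > 0.5 * wmin2) {
    warning("BD time step too coarse: D*dt = ", dmax * dt,
            " A^2 vs narrowest width^2 = ", wmin2)
  }

  # assemble the system: static pore atoms first, then ligand beads,
  # then ions
  atoms <- list(); static_xyz <- NULL
  if (!is.null(pore)) {
    a <- pore$atoms
    static_xyz <- attr(pore, "coords")
    atoms[[1]] <- a
  }
  n_static <- if (is.null(static_xyz)) 0L else nrow(static_xyz)
  serial0 <- if (n_static > 0) max(atoms[[1]]$serial) else 0L

  lig_tpl <- NULL
  if (!is.null(spec$ligand)) {
    lig_tpl <- ligand_template()
    la <- data.frame(serial = serial0 + seq_len(nrow(lig_tpl)),
                     name = lig_tpl$name, element = lig_tpl$element,
                     resname = spec$ligand$name, resno = 9000L, chain = "L",
                     stringsAsFactors = FALSE)
    la$tags <- lapply(lig_tpl$tag, identity)
    atoms[[length(atoms) + 1L]] <- la
    serial0 <- max(la$serial)
  }
  ion_rows <- list()
  for (s in spec$species) {
    if (s$count == 0) next
    tag <- if (s$charge < 0) "anion" else "cation"
    ir <- data.frame(serial = serial0 + seq_len(s$count),
                     name = s$name, element = s$name,
                     resname = s$name,
                     resno = 9500L + seq_len(s$count), chain = "I",
                     stringsAsFactors = FALSE)
    ir$tags <- replicate(s$count, tag, simplify = FALSE)
    ion_rows[[length(ion_rows) + 1L]] <- ir
    serial0 <- max(ir$serial)
  }
  atoms <- c(atoms, ion_rows)
  tab <- do.call(rbind, atoms)
  groups <- if (is.null(pore)) list() else pore$topology_groups
  if (!is.null(lig_tpl)) {
    off <- n_static
    groups$ligand_phosphate_oxygens <- off + which(lig_tpl$tag == "phosphate_oxygen")
    groups$ligand_terminal_P <- off + which(lig_tpl$tag == "phosphorus_terminal")
    groups$ligand_ring <- off + which(lig_tpl$tag == "ring_atom")
    groups$ligand_donor <- off + which(lig_tpl$tag %in% c("donor_heavy", "hydrogen"))
  }
  sys <- molecular_system(tab, groups)

  # mobile degrees of freedom: ligand center + each ion
  n_lig <- if (is.null(lig_tpl)) 0L else 1L
  sp_count <- vapply(spec$species, function(s) s$count, numeric(1))
  n_ion <- sum(sp_count)
  n_mob <- n_lig + n_ion
  D <- numeric(n_mob); feels <- logical(n_mob)
  if (n_lig > 0) {
    D[1] <- spec$ligand$diffusion_A2_per_ns
    feels[1] <- isTRUE(spec$ligand$feels_potential)
  }
  k <- n_lig
  for (s in spec$species) {
    if (s$count == 0) next
    D[k + seq_len(s$count)] <- s$diffusion_A2_per_ns
    feels[k + seq_len(s$count)] <- isTRUE(s$feels_potential)
    k <- k + s$count
  }

  # initial positions: z from the stationary density (rejection
  # sampling against exp(-U/RT)), x/y uniform in the disk
  umin <- if (length(spec$potential) > 0) {
    min(potential_u(seq(-Lz / 2, Lz / 2, length.out = 2001), spec$potential))
  } else 0
  draw_z <- function(n, feels_pot) {
    if (!feels_pot || length(spec$potential) == 0) {
      return(stats::runif(n, -Lz / 2, Lz / 2))
    }
    out <- numeric(0)
    while (length(out) < n) {
      cand <- stats::runif(n, -Lz / 2, Lz / 2)
      acc <- stats::runif(n) < exp(-(potential_u(cand, spec$potential) - umin) / RT)
      out <- c(out, cand[acc])
    }
    out[seq_len(n)]
  }
  pos <- matrix(0, n_mob, 3)
  for (i in seq_len(n_mob)) {
    rho <- R * sqrt(stats::runif(1)); phi <- stats::runif(1, 0, 2 * pi)
    pos[i, 1] <- rho * cos(phi); pos[i, 2] <- rho * sin(phi)
  }
  pos[, 3] <- vapply(seq_len(n_mob), function(i) draw_z(1, feels[i]),
                     numeric(1))
  if (n_lig > 0 && !is.null(spec$ligand$start_z_A)) {
    pos[1, 3] <- spec$ligand$start_z_A
  }

  sig <- sqrt(2 * D * dt)
  mob_amp <- D / RT * dt
  n_steps <- spec$n_frames * spec$save_every
  na_tot <- n_atoms(sys)
  coords <- array(NA_real_, dim = c(na_tot, 3, spec$n_frames))
  lig_off <- if (n_lig > 0) as.matrix(lig_tpl[, c("dx", "dy", "dz")]) else NULL
  record <- function(slot) {
    fr <- matrix(0, na_tot, 3)
    if (n_static > 0) fr[seq_len(n_static), ] <- static_xyz
    if (n_lig > 0) {
      fr[n_static + seq_len(nrow(lig_tpl)), ] <-
        sweep(lig_off, 2, pos[1, ], "+")
    }
    if (n_ion > 0) {
      fr[(na_tot - n_ion + 1):na_tot, ] <- pos[n_lig + seq_len(n_ion), ,
                                               drop = FALSE]
    }
    coords[, , slot] <<- fr
  }
  half <- c(spec$box_A[1] / 2, spec$box_A[2] / 2, Lz / 2)
  frame_slot <- 0L
  for (step in seq_len(n_steps)) {
    drift <- ifelse(feels, mob_amp * potential_force(pos[, 3], spec$potential),
                    0)
    disp <- matrix(stats::rnorm(3 * n_mob), n_mob, 3) * sig
    disp[, 3] <- disp[, 3] + drift
    if (any(abs(disp) > half[3])) stop("divergent BD step: displacement exceeds box/2")
    pos <- pos + disp
    # reflect at the z faces
    over <- pos[, 3] > half[3]
    pos[over, 3] <- 2 * half[3] - pos[over, 3]
    under <- pos[, 3] < -half[3]
    pos[under, 3] <- -2 * half[3] - pos[under, 3]
    # reflect radially at the cylinder wall
    rho <- sqrt(pos[, 1]^2 + pos[, 2]^2)
    out <- rho > R
    if (any(out)) {
      scale <- (2 * R - rho[out]) / rho[out]
      scale[scale < 0] <- 0
      pos[out, 1] <- pos[out, 1] * scale
      pos[out, 2] <- pos[out, 2] * scale
    }
    if (step %% spec$save_every == 0L) {
      frame_slot <- frame_slot + 1L
      record(frame_slot)
    }
  }
  dt_frame <- dt * spec$save_every
  traj <- trajectory(sys, coords, dt_ns = dt_frame,
                     time_ns = seq_len(spec$n_frames) * dt_frame)

  # ground truth: stationary densities inside the cylinder
  area <- pi * R^2
  zpart <- function(feels_pot, lo = -Lz / 2, hi = Lz / 2) {
    if (!feels_pot || length(spec$potential) == 0) return(hi - lo)
    stats::integrate(function(zz) exp(-potential_u(zz, spec$potential) / RT),
                     lo, hi, subdivisions = 500L)$value
  }
  dens <- list(); n_in <- c(anion = 0, cation = 0); n_tot <- c(anion = 0, cation = 0)
  L <- spec$pore_half_length_A
  for (s in spec$species) {
    Zfull <- zpart(isTRUE(s$feels_potential))
    dens[[s$name]] <- s$count / (area * Zfull)
    cls <- if (s$charge < 0) "anion" else "cation"
    n_in[cls] <- n_in[cls] + s$count * zpart(isTRUE(s$feels_potential), -L, L) / Zfull
    n_tot[cls] <- n_tot[cls] + s$count
  }
  expected_ratio <- if (n_in["cation"] > 0) {
    unname(n_in["anion"] / n_in["cation"])
  } else NA_real_
  gt <- list(potential = spec$potential, RT_kcal = RT,
             true_bulk_density = dens,
             expected_pore_occupancy = as.list(n_in),
             expected_ratio = expected_ratio)
  list(trajectory = traj, ground_truth = gt, spec = spec)
}

#' Hand-placed contact fixtures straddling the criteria thresholds
#'
#' Returns small systems with exactly known geometry and the expected
#' detector output enumerated, including every strict/inclusive boundary
#' (4.0 A inclusive for the electrostatic criterion, strict elsewhere).
#'
#' @param kind one of `"electrostatic"`, `"pairing"`, `"pipi"`,
#'   `"cationpi"`, `"guanidinium"`, `"hbond"`, `"boundary_cases"`.
#' @return list with `kind`, `coords`, detector argument lists (named by
#'   the detector's parameters) and `expected` — the partner_b labels
#'   the detector must report, in order.
#' @export
make_contact_fixture <- function(kind = c("electrostatic", "pairing", "pipi",
                                          "cationpi", "guanidinium", "hbond",
                                          "boundary_cases")) {
  kind <- match.arg(kind)
  deg <- pi / 180
  if (kind == "electrostatic") {
    # one phosphate O at the origin; NZ partners at 3.9 / 4.0 / 4.1 A
    coords <- rbind(c(0, 0, 0), c(3.9, 0, 0), c(0, 4.0, 0), c(0, 0, 4.1))
    return(list(kind = kind, coords = coords,
                phosphate_oxygens = list(lig = 1L),
                basic_nitrogens = list(res1 = 2L, res2 = 3L, res3 = 4L),
                expected = c("res1", "res2")))
  }
  if (kind == "pairing") {
    coords <- rbind(c(0, 0, 0), c(3.5, 0, 0), c(0, 4.0, 0), c(0, 0, 3.999))
    return(list(kind = kind, coords = coords,
                phosphate_oxygens = list(phos = 1L),
                cations = list(na1 = 2L, na2 = 3L, na3 = 4L),
                expected = c("na1", "na3")))
  }
  if (kind == "pipi") {
    ringA <- place_ring(c(0, 0, 0), c(0, 0, 1))
    parallel4 <- place_ring(c(0, 0, 4), c(0, 0, 1))          # hit, angle 0
    perp4 <- place_ring(c(4, 0, 0), c(1, 0, 0))              # miss, angle 90
    tilted <- place_ring(c(0, 0, 5.9),
                         c(0, sin(29 * deg), cos(29 * deg))) # hit, 29 deg
    far <- place_ring(c(0, 0, 6.0), c(0, 0, 1))              # miss, d = 6 strict
    coords <- rbind(ringA, parallel4, perp4, tilted, far)
    return(list(kind = kind, coords = coords,
                ring_a = 1:3,
                partners = list(parallel4 = 4:6, perp4 = 7:9,
                                tilted29 = 10:12, at6A = 13:15),
                expected = c("parallel4", "tilted29")))
  }
  if (kind == "cationpi") {
    ring <- place_ring(c(0, 0, 0), c(0, 0, 1))
    # NH parallel to the normal: plane angle 90 -> hit
    n1 <- c(0, 0, 5); h1 <- c(0, 0, 6)
    # NH lying in the ring plane: plane angle 0 -> miss
    n2 <- c(0, 5, 0); h2 <- c(1, 5, 0)
    # plane angle exactly 60 (vector 30 deg off the normal) -> miss, strict
    v60 <- c(sin(30 * deg), 0, cos(30 * deg))
    n3 <- c(3, 0, 3); h3 <- n3 + v60
    # N beyond 6 A -> miss despite perfect angle
    n4 <- c(0, 0, 6.5); h4 <- c(0, 0, 7.5)
    coords <- rbind(ring, n1, h1, n2, h2, n3, h3, n4, h4)
    return(list(kind = kind, coords = coords,
                ring = 1:3,
                basic_residues = list(resA = matrix(c(4L, 5L), 1),
                                      resB = matrix(c(6L, 7L), 1),
                                      resC = matrix(c(8L, 9L), 1),
                                      resD = matrix(c(10L, 11L), 1)),
                expected = "resA"))
  }
  if (kind == "guanidinium") {
    ring <- place_ring(c(0, 0, 0), c(0, 0, 1))
    stacked <- place_ring(c(0, 0, 3.8), c(0, 0, 1), radius = 1.15)  # hit
    tilted45 <- place_ring(c(0, 0, 4), c(0, sin(45 * deg), cos(45 * deg)),
                           radius = 1.15)                           # miss
    near30 <- place_ring(c(0, 0, 5.9),
                         c(0, sin(29.9 * deg), cos(29.9 * deg)),
                         radius = 1.15)                             # hit
    coords <- rbind(ring, stacked, tilted45, near30)
    return(list(kind = kind, coords = coords,
                ring = 1:3,
                partners = list(stacked = 4:6, tilted45 = 7:9,
                                near30 = 10:12),
                expected = c("stacked", "near30")))
  }
  if (kind == "hbond") {
    # donor D-H along +x; acceptors linear at 2.9 (hit), 3.6 (miss),
    # and a bent 119-degree geometry (miss, strict > 120)
    D <- c(0, 0, 0); H <- c(1, 0, 0)
    a1 <- c(2.9, 0, 0)
    a2 <- c(3.6, 0, 0)
    # place acceptor so the D-H-A angle is exactly 119 degrees at H
    ang <- 119 * deg
    a3 <- H + 1.9 * c(cos(pi - ang), sin(pi - ang), 0)
    coords <- rbind(D, H, a1, a2, a3)
    return(list(kind = kind, coords = coords,
                donors = matrix(c(1L, 2L), 1),
                acceptors = c(A3 = 3L, A4 = 4L, A5 = 5L),
                expected = "A3"))
  }
  # boundary_cases: union of the per-criterion boundary geometries
  list(kind = "boundary_cases",
       fixtures = lapply(c("electrostatic", "pairing", "pipi", "cationpi",
                           "guanidinium", "hbond"), make_contact_fixture))
}
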