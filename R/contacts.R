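# Geometric interaction criteria. All detectors work on a single frame's
# coordinate matrix and return rows of a common contact-record table
# (frame, criterion, partner_a, partner_b, distance, angle). Boundary
# inclusivity follows the literal wording of each criterion: the
# phosphate-nitrogen electrostatic cutoff is inclusive ("4 A or less"),
# every other threshold is strict ("smaller/less/lower/larger than").

#' Interaction criteria thresholds
#'
#' Distances in Angstrom, angles in degrees. Defaults:
#' \itemize{
#'   \item electrostatic (phosphate O to Lys/Arg side-chain N): <= 4.0
#'         (inclusive)
#'   \item cation pairing (phosphate O to cation): < 4.0 (strict)
#'   \item pi-pi: ring-center distance < 6.0 and inter-plane angle < 30
#'   \item cation-pi: ring-center to side-chain N < 6.0 and NH-vector
#'         angle to the ring plane > 60
#'   \item guanidinium stacking: ring-center distance < 6.0 and
#'         inter-plane angle < 30
#'   \item hydrogen bond: donor-acceptor heavy-atom distance < 3.5 and
#'         donor-hydrogen-acceptor angle > 120
#'   \item long-lived contact: maximal contiguous lifetime > 5 ns
#' }
#' @param electrostatic_max_A,pairing_max_A,pipi_max_A,pipi_max_angle_deg
#'   thresholds, see Details.
#' @param cationpi_max_A,cationpi_min_angle_deg,guanidinium_stack_max_angle_deg
#'   thresholds, see Details.
#' @param hbond_heavy_max_A,hbond_min_angle_deg,longlived_min_ns
#'   thresholds, see Details.
#' @return object of class `interaction_criteria`.
#' @export
interaction_criteria <- function(electrostatic_max_A = 4.0,
                                 pairing_max_A = 4.0,
                                 pipi_max_A = 6.0,
                                 pipi_max_angle_deg = 30,
                                 cationpi_max_A = 6.0,
                                 cationpi_min_angle_deg = 60,
                                 guanidinium_stack_max_angle_deg = 30,
                                 hbond_heavy_max_A = 3.5,
                                 hbond_min_angle_deg = 120,
                                 longlived_min_ns = 5.0) {
  dists <- c(electrostatic_max_A, pairing_max_A, pipi_max_A,
             cationpi_max_A, hbond_heavy_max_A)
  angs <- c(pipi_max_angle_deg, cationpi_min_angle_deg,
            guanidinium_stack_max_angle_deg, hbond_min_angle_deg)
  if (any(dists <= 0)) stop("distance thresholds must be positive")
  if (any(angs <= 0 | angs >= 180)) stop("angle thresholds must lie in (0, 180)")
  structure(list(electrostatic_max_A = electrostatic_max_A,
                 pairing_max_A = pairing_max_A,
                 pipi_max_A = pipi_max_A,
                 pipi_max_angle_deg = pipi_max_angle_deg,
                 cationpi_max_A = cationpi_max_A,
                 cationpi_min_angle_deg = cationpi_min_angle_deg,
                 guanidinium_stack_max_angle_deg = guanidinium_stack_max_angle_deg,
                 hbond_heavy_max_A = hbond_heavy_max_A,
                 hbond_min_angle_deg = hbond_min_angle_deg,
                 longlived_min_ns = longlived_min_ns),
            class = "interaction_criteria")
}

contact_record <- function(frame, criterion, partner_a, partner_b,
                           distance, angle = NA_real_) {
  data.frame(frame = as.integer(frame), criterion = criterion,
             partner_a = partner_a, partner_b = partner_b,
             distance = distance, angle = angle,
             stringsAsFactors = FALSE)
}

empty_contacts <- function() {
  contact_record(integer(0), character(0), character(0), character(0),
                 numeric(0), numeric(0))
}

# minimum-image displacement components when an orthorhombic box is given
min_image <- function(d, box = NULL) {
  if (is.null(box)) return(d)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

# all pairwise distances between two coordinate sets (minimum image)
pair_dists <- function(A, B, box = NULL) {
  na <- nrow(A); nb <- nrow(B)
  d <- matrix(0, na, nb)
  for (j in seq_len(nb)) {
    disp <- sweep(A, 2, B[j, ])
    disp <- min_image(disp, box)
    d[, j] <- sqrt(rowSums(disp^2))
  }
  d
}

as_group_list <- function(x, prefix) {
  if (is.list(x) && !is.null(names(x))) return(x)
  if (is.list(x)) { names(x) <- paste0(prefix, seq_along(x)); return(x) }
  stats::setNames(as.list(x), paste0(prefix, seq_along(x)))
}

#' Detect electrostatic phosphate-basic residue contacts
#'
#' A contact between a phosphate group and a Lys/Arg residue is formed
#' when the minimum distance between any phosphate oxygen and any
#' side-chain nitrogen of the residue is 4 Angstrom or less (inclusive).
#' One record per (ligand group, residue) pair, storing that minimum
#' distance.
#'
#' @param coords n_atoms x 3 frame coordinates.
#' @param phosphate_oxygens named list: ligand group id -> oxygen atom
#'   indices (a bare integer vector is treated as one group per atom).
#' @param basic_nitrogens named list: residue id -> side-chain nitrogen
#'   indices.
#' @param criteria an [interaction_criteria()].
#' @param box optional orthorhombic box lengths for minimum-image
#'   distances.
#' @param frame frame index stored in the records.
#' @return contact-record data.frame.
#' @export
detect_electrostatic <- function(coords, phosphate_oxygens, basic_nitrogens,
                                 criteria = interaction_criteria(),
                                 box = NULL, frame = 0L) {
  og <- as_group_list(phosphate_oxygens, "lig")
  ng <- as_group_list(basic_nitrogens, "res")
  if (length(og) == 0 || length(unlist(og)) == 0) stop("empty phosphate-oxygen selection")
  if (length(ng) == 0 || length(unlist(ng)) == 0) stop("empty nitrogen selection")
  out <- list()
  for (a in names(og)) {
    A <- coords[og[[a]], , drop = FALSE]
    for (b in names(ng)) {
      dmin <- min(pair_dists(A, coords[ng[[b]], , drop = FALSE], box))
      if (dmin <= criteria$electrostatic_max_A) {
        out[[length(out) + 1L]] <- contact_record(frame, "electrostatic",
                                                  a, b, dmin)
      }
    }
  }
  if (length(out) == 0) empty_contacts() else do.call(rbind, out)
}

#' Detect phosphate-cation ion pairing
#'
#' A cation is paired with a phosphate group when its distance to any of
#' the group's oxygens is strictly smaller than 4 Angstrom. One record
#' per (phosphate group, cation).
#'
#' @inheritParams detect_electrostatic
#' @param cations named list or integer vector of cation atom indices.
#' @return contact-record data.frame.
#' @export
detect_cation_pairing <- function(coords, phosphate_oxygens, cations,
                                  criteria = interaction_criteria(),
                                  box = NULL, frame = 0L) {
  og <- as_group_list(phosphate_oxygens, "phos")
  cg <- as_group_list(cations, "cat")
  if (length(og) == 0 || length(unlist(og)) == 0) stop("empty phosphate-oxygen selection")
  if (length(cg) == 0) stop("empty cation selection")
  out <- list()
  for (a in names(og)) {
    A <- coords[og[[a]], , drop = FALSE]
    for (b in names(cg)) {
      dmin <- min(pair_dists(A, coords[cg[[b]], , drop = FALSE], box))
      if (dmin < criteria$pairing_max_A) {
        out[[length(out) + 1L]] <- contact_record(frame, "cation_pairing",
                                                  a, b, dmin)
      }
    }
  }
  if (length(out) == 0) empty_contacts() else do.call(rbind, out)
}

#' Ring plane from three atoms
#'
#' @param coords frame coordinates.
#' @param ring_triplet indices of three non-collinear ring atoms.
#' @param masses optional atomic masses for a mass-weighted center
#'   (default equal weights, i.e. the centroid).
#' @return list with `center` (3-vector) and `normal` (unit 3-vector).
#' @export
ring_plane <- function(coords, ring_triplet, masses = NULL) {
  if (length(ring_triplet) != 3) stop("ring triplet must have exactly 3 atoms")
  P <- coords[ring_triplet, , drop = FALSE]
  if (is.null(masses)) masses <- rep(1, 3)
  center <- colSums(P * masses) / sum(masses)
  e1 <- P[2, ] - P[1, ]
  e2 <- P[3, ] - P[1, ]
  n <- c(e1[2] * e2[3] - e1[3] * e2[2],
         e1[3] * e2[1] - e1[1] * e2[3],
         e1[1] * e2[2] - e1[2] * e2[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-8 * sqrt(sum(e1^2)) * sqrt(sum(e2^2)) || nn == 0) {
    stop("ring atoms are collinear; no plane defined")
  }
  list(center = center, normal = n / nn)
}

# angle between two directions folded into [0, 90] degrees
folded_angle <- function(u, v) {
  cosang <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  cosang <- min(max(cosang, -1), 1)
  acos(cosang) * 180 / pi
}

#' Detect a pi-pi stacking contact between two rings
#'
#' Formed when the ring-center distance is < 6 Angstrom and the angle
#' between the two ring planes (folded into [0, 90] degrees) is < 30
#' degrees, both strict.
#'
#' @inheritParams ring_plane
#' @param ring_a_triplet,ring_b_triplet index triplets of the two rings.
#' @param criteria an [interaction_criteria()].
#' @param frame frame index for the record.
#' @param partner_a,partner_b labels stored in the record.
#' @return contact-record data.frame (zero or one row).
#' @export
detect_pi_pi <- function(coords, ring_a_triplet, ring_b_triplet,
                         criteria = interaction_criteria(), frame = 0L,
                         partner_a = "ringA", partner_b = "ringB") {
  pa <- ring_plane(coords, ring_a_triplet)
  pb <- ring_plane(coords, ring_b_triplet)
  d <- sqrt(sum((pa$center - pb$center)^2))
  ang <- folded_angle(pa$normal, pb$normal)
  if (d < criteria$pipi_max_A && ang < criteria$pipi_max_angle_deg) {
    contact_record(frame, "pi_pi", partner_a, partner_b, d, ang)
  } else empty_contacts()
}

#' Detect cation-pi contacts between a ring and basic residues
#'
#' Formed when some side-chain nitrogen of the residue lies < 6 Angstrom
#' from the ring center AND some N-H bond vector of the side chain makes
#' an angle with the ring plane > 60 degrees (strict). The plane-vector
#' angle is 90 degrees minus the folded angle between the vector and the
#' ring normal, so it lies in [0, 90].
#'
#' @inheritParams detect_pi_pi
#' @param ring_triplet index triplet of the aromatic/adenine ring.
#' @param basic_residues named list: residue id -> two-column matrix of
#'   (nitrogen index, hydrogen index) N-H pairs.
#' @return contact-record data.frame, at most one row per residue, with
#'   the minimal N-center distance and the maximal plane angle.
#' @export
detect_cation_pi <- function(coords, ring_triplet, basic_residues,
                             criteria = interaction_criteria(), frame = 0L) {
  pl <- ring_plane(coords, ring_triplet)
  if (!is.list(basic_residues) || is.null(names(basic_residues))) {
    stop("basic_residues must be a named list of N-H index pair matrices")
  }
  out <- list()
  for (res in names(basic_residues)) {
    nh <- basic_residues[[res]]
    if (is.null(dim(nh))) nh <- matrix(nh, ncol = 2, byrow = TRUE)
    if (nrow(nh) == 0) stop("residue '", res, "' provides no N-H pairs")
    nidx <- unique(nh[, 1])
    dmin <- min(sqrt(colSums((t(coords[nidx, , drop = FALSE]) - pl$center)^2)))
    plane_ang <- apply(nh, 1, function(p) {
      v <- coords[p[2], ] - coords[p[1], ]
      90 - folded_angle(v, pl$normal)
    })
    amax <- max(plane_ang)
    if (dmin < criteria$cationpi_max_A && amax > criteria$cationpi_min_angle_deg) {
      out[[length(out) + 1L]] <- contact_record(frame, "cation_pi",
                                                "ring", res, dmin, amax)
    }
  }
  if (length(out) == 0) empty_contacts() else do.call(rbind, out)
}

#' Detect arginine guanidinium stacking on a ring
#'
#' Same distance criterion as pi-pi (< 6 Angstrom between the ring center
#' and the guanidinium-plane center) with an inter-plane angle < 30
#' degrees (strict). The guanidinium plane defaults to the NE, NH1, NH2
#' triplet.
#'
#' @inheritParams detect_pi_pi
#' @param ring_triplet index triplet of the aromatic/adenine ring.
#' @param guanidinium_triplet index triplet of the Arg guanidinium plane.
#' @return contact-record data.frame (zero or one row).
#' @export
detect_guanidinium_stack <- function(coords, ring_triplet, guanidinium_triplet,
                                     criteria = interaction_criteria(),
                                     frame = 0L, partner_a = "ring",
                                     partner_b = "ARG") {
  if (length(guanidinium_triplet) != 3) {
    stop("guanidinium plane needs exactly 3 atoms (NE, NH1, NH2)")
  }
  pr <- ring_plane(coords, ring_triplet)
  pg <- ring_plane(coords, guanidinium_triplet)
  d <- sqrt(sum((pr$center - pg$center)^2))
  ang <- folded_angle(pr$normal, pg$normal)
  if (d < criteria$cationpi_max_A &&
      ang < criteria$guanidinium_stack_max_angle_deg) {
    contact_record(frame, "guanidinium_stack", partner_a, partner_b, d, ang)
  } else empty_contacts()
}

#' Detect hydrogen bonds
#'
#' A donor (heavy atom D with attached hydrogen H) is bonded to an
#' acceptor heavy atom A when |D-A| < 3.5 Angstrom and the D-H-A angle
#' (at the hydrogen) is > 120 degrees, both strict.
#'
#' @inheritParams detect_electrostatic
#' @param donors two-column matrix of (donor heavy index, hydrogen index);
#'   the pair must be covalently plausible (|D-H| <= 1.2 Angstrom).
#' @param acceptors integer vector or named list of acceptor heavy-atom
#'   indices.
#' @return contact-record data.frame, one row per (donor pair, acceptor)
#'   meeting the criterion.
#' @export
detect_hbond <- function(coords, donors, acceptors,
                         criteria = interaction_criteria(), box = NULL,
                         frame = 0L) {
  if (is.null(dim(donors))) donors <- matrix(donors, ncol = 2, byrow = TRUE)
  acc <- if (is.list(acceptors)) unlist(acceptors) else acceptors
  if (nrow(donors) == 0 || length(acc) == 0) stop("empty donor or acceptor selection")
  out <- list()
  for (k in seq_len(nrow(donors))) {
    D <- coords[donors[k, 1], ]
    H <- coords[donors[k, 2], ]
    dh <- sqrt(sum(min_image(matrix(D - H, 1), box)^2))
    if (dh > 1.2) {
      stop("mis-specified donor: |D-H| = ", round(dh, 3),
           " A for atoms ", donors[k, 1], "-", donors[k, 2])
    }
    for (j in acc) {
      A <- coords[j, ]
      da <- sqrt(sum(min_image(matrix(D - A, 1), box)^2))
      if (da >= criteria$hbond_heavy_max_A) next
      v1 <- D - H; v2 <- A - H
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(min(max(cosang, -1), 1)) * 180 / pi
      if (ang > criteria$hbond_min_angle_deg) {
        out[[length(out) + 1L]] <- contact_record(
          frame, "hbond", paste0("D", donors[k, 1]), paste0("A", j), da, ang)
      }
    }
  }
  if (length(out) == 0) empty_contacts() else do.call(rbind, out)
}

#' Run a per-frame detector over a whole trajectory
#'
#' @param traj a `trajectory`.
#' @param detector function(coords, ..., frame=, box=) returning a
#'   contact-record data.frame, e.g. [detect_electrostatic()].
#' @param ... passed to the detector.
#' @return row-bound contact records over all frames (frame indices are
#'   0-based positions in the trajectory).
#' @export
detect_over_trajectory <- function(traj, detector, ...) {
  res <- vector("list", n_frames(traj))
  for (i in seq_len(n_frames(traj))) {
    fr <- get_frame(traj, i)
    res[[i]] <- detector(fr$coords, ..., box = fr$box, frame = i - 1L)
  }
  do.call(rbind, res)
}

#' Build contact timelines
#'
#' Groups contact records by (partner_a, partner_b, criterion) into
#' sorted unique frame-index vectors — the data behind tick-style
#' interaction timeline plots.
#'
#' @param records contact-record data.frame from one trajectory.
#' @return named list of sorted integer frame vectors; names are
#'   `partner_a|partner_b|criterion`.
#' @export
build_timelines <- function(records) {
  if (nrow(records) == 0) return(structure(list(), class = "contact_timelines"))
  key <- paste(records$partner_a, records$partner_b, records$criterion,
               sep = "|")
  tl <- lapply(split(records$frame, key), function(f) sort(unique(f)))
  structure(tl, class = "contact_timelines")
}

#' Classify contact lifetimes
#'
#' A run is a maximal set of consecutive frames containing the contact;
#' its duration is run_length * dt_ns (each snapshot stands for one
#' sampling interval). A pair is long-lived when its maximal run exceeds
#' `longlived_min_ns` strictly (> 5 ns by default).
#'
#' @param timelines output of [build_timelines()].
#' @param dt_ns frame spacing in ns.
#' @param criteria an [interaction_criteria()].
#' @return data.frame with columns `pair`, `max_run_ns`, `n_runs`,
#'   `is_longlived`.
#' @export
classify_longlived <- function(timelines, dt_ns,
                               criteria = interaction_criteria()) {
  if (length(timelines) == 0) {
    return(data.frame(pair = character(0), max_run_ns = numeric(0),
                      n_runs = integer(0), is_longlived = logical(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(names(timelines), function(k) {
    f <- timelines[[k]]
    # lengths of maximal consecutive stretches
    brk <- which(diff(f) != 1L)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, length(f))
    run_len <- ends - starts + 1L
    data.frame(pair = k, max_run_ns = max(run_len) * dt_ns,
               n_runs = length(run_len),
               is_longlived = max(run_len) * dt_ns > criteria$longlived_min_ns,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
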