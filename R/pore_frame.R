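# The pore-axis reaction coordinate z. z = 0 at the geometric center of
# designated reference residues; z > 0 on the cytosolic side. Every
# profile and event computation expresses particle positions in this
# frame.

#' Define a pore frame
#'
#' @param center_atom_indices atom indices whose geometric center defines
#'   the origin (backbone carbons of the reference residues); `NULL` for
#'   a fixed laboratory origin (synthetic systems whose pore is built at
#'   the origin by construction).
#' @param origin fixed origin used when `center_atom_indices` is `NULL`.
#' @param axis membrane-normal direction; normalised internally. Default
#'   laboratory +z, pointing to the cytosolic side.
#' @param pore_half_length_A half-length of the pore slab in Angstrom;
#'   the translocation boundaries sit at +/- this value.
#' @param slab_edges_A monotone bin-edge vector for profiles; default a
#'   1 Angstrom grid over [-22, 22] (the reaction-coordinate range used
#'   for metabolite translocation).
#' @return object of class `pore_frame`.
#' @export
pore_frame <- function(center_atom_indices = NULL, axis = c(0, 0, 1),
                       pore_half_length_A = 15,
                       slab_edges_A = seq(-22, 22, by = 1),
                       origin = c(0, 0, 0)) {
  if (!is.null(center_atom_indices) && length(center_atom_indices) == 0) {
    stop("empty center atom selection")
  }
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("axis must be a nonzero vector")
  if (any(diff(slab_edges_A) <= 0)) stop("slab edges must be strictly increasing")
  structure(list(center_atom_indices = if (is.null(center_atom_indices)) {
                   NULL
                 } else as.integer(center_atom_indices),
                 origin = origin,
                 axis = axis / nrm,
                 pore_half_length_A = pore_half_length_A,
                 slab_edges_A = slab_edges_A),
            class = "pore_frame")
}

#' Pore frame from reference residues of a system
#'
#' Selects the backbone carbons of the reference residues. The default
#' residue list is the set used for the VDAC pore center (R15, V17, L58,
#' F99, A141, S193, L259). `backbone_atoms` may be `"CA"` or
#' `c("CA","C")` (default both: the literal plural "backbone carbon
#' atoms"; the difference is fractions of an Angstrom).
#'
#' @param system a `molecular_system`.
#' @param reference_residues residue numbers defining the center.
#' @param backbone_atoms atom names used per residue.
#' @param ... passed to [pore_frame()].
#' @return a `pore_frame`.
#' @export
pore_frame_from_system <- function(system,
                                   reference_residues = c(15, 17, 58, 99, 141, 193, 259),
                                   backbone_atoms = c("CA", "C"), ...) {
  idx <- select_atoms(system, name = backbone_atoms,
                      resno = reference_residues)
  if (length(idx) == 0) {
    stop("no backbone atoms found for reference residues ",
         paste(reference_residues, collapse = ","))
  }
  pore_frame(idx, ...)
}

#' Geometric center of the pore in one frame
#' @param coords n_atoms x 3 coordinate matrix.
#' @param pf a `pore_frame`.
#' @return length-3 numeric vector (Angstrom).
#' @export
pore_center <- function(coords, pf) {
  idx <- pf$center_atom_indices
  if (is.null(idx)) return(pf$origin)
  if (any(idx > nrow(coords))) stop("center atom index beyond frame atoms")
  colMeans(coords[idx, , drop = FALSE])
}

#' Signed axial coordinate of a particle
#'
#' Projection of (particle - pore center) onto the pore axis; positive
#' toward the cytosolic side.
#'
#' @param coords n_atoms x 3 coordinate matrix.
#' @param pf a `pore_frame`.
#' @param particle_index atom index of the tracked particle.
#' @return signed z in Angstrom.
#' @export
z_of <- function(coords, pf, particle_index) {
  if (particle_index < 1 || particle_index > nrow(coords)) {
    stop("particle index out of range: ", particle_index)
  }
  ctr <- pore_center(coords, pf)
  sum((coords[particle_index, ] - ctr) * pf$axis)
}

#' z time series for tracked atoms over a trajectory
#'
#' @param traj a `trajectory`.
#' @param pf a `pore_frame`.
#' @param atom_indices one or more tracked atom indices.
#' @return if one index, numeric vector over frames; otherwise an
#'   n_frames x n_atoms matrix.
#' @export
z_series <- function(traj, pf, atom_indices) {
  nf <- n_frames(traj)
  out <- matrix(NA_real_, nf, length(atom_indices))
  ax <- pf$axis
  for (i in seq_len(nf)) {
    cc <- traj$coords[, , i]
    if (is.null(dim(cc))) dim(cc) <- dim(traj$coords)[1:2]
    ctr <- pore_center(cc, pf)
    rel <- cc[atom_indices, , drop = FALSE]
    out[i, ] <- (rel[, 1] - ctr[1]) * ax[1] + (rel[, 2] - ctr[2]) * ax[2] +
      (rel[, 3] - ctr[3]) * ax[3]
  }
  if (length(atom_indices) == 1) drop(out) else out
}

#' Radial distance from the pore axis
#'
#' @inheritParams z_series
#' @return n_frames x n_atoms matrix of distances from the axis line
#'   through the pore center (Angstrom).
#' @export
radial_series <- function(traj, pf, atom_indices) {
  nf <- n_frames(traj)
  out <- matrix(NA_real_, nf, length(atom_indices))
  ax <- pf$axis
  for (i in seq_len(nf)) {
    cc <- traj$coords[, , i]
    if (is.null(dim(cc))) dim(cc) <- dim(traj$coords)[1:2]
    ctr <- pore_center(cc, pf)
    rel <- sweep(cc[atom_indices, , drop = FALSE], 2, ctr)
    zc <- rel %*% ax
    perp <- rel - zc %*% t(ax)
    out[i, ] <- sqrt(rowSums(perp^2))
  }
  out
}

#' Slab index of a z value
#'
#' Half-open binning `[edge_i, edge_{i+1})`: a value exactly on an
#' interior edge belongs to the higher bin. Values outside the grid give
#' `NA`.
#'
#' @param z numeric vector of axial coordinates.
#' @param slab_edges monotone increasing edge vector.
#' @return integer bin indices (1-based) or `NA`.
#' @export
slab_index <- function(z, slab_edges) {
  if (any(diff(slab_edges) <= 0)) stop("slab edges must be strictly increasing")
  i <- findInterval(z, slab_edges)
  i[i == 0 | i == length(slab_edges) | z >= slab_edges[length(slab_edges)]] <- NA_integer_
  as.integer(i)
}

#' Uniform slab-edge grid
#' @param slab_width_A bin width (Angstrom).
#' @param z_range range to cover, default `c(-22, 22)`.
#' @return numeric edge vector.
#' @export
slab_edges <- function(slab_width_A, z_range = c(-22, 22)) {
  seq(z_range[1], z_range[2], by = slab_width_A)
}
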