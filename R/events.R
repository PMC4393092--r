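# Translocation events: full passages of a tracked particle between the
# boundary regions z > +15 and z < -15 Angstrom. The crossing definition
# uses hysteresis: an event requires having last visited one boundary
# region and then reaching the other, so boundary jitter is never double
# counted and partial entries (into the slab and back) are not events.

#' Detect translocation events in a z time series
#'
#' A cyt-to-IMS event is recorded when the particle, having last been in
#' the region z > `z_hi`, subsequently reaches z < `z_lo` without
#' re-crossing `z_hi` in between; symmetrically for IMS-to-cyt. The entry
#' frame is the last frame above `z_hi` (below `z_lo`) before the
#' crossing; the exit frame is the first frame beyond the far boundary.
#' A particle starting inside the slab produces an event only after it
#' first visits one boundary region.
#'
#' @param z numeric z series (Angstrom), one value per frame.
#' @param dt_ns frame spacing in ns.
#' @param z_hi,z_lo slab boundaries (default +15 / -15 Angstrom).
#' @param particle_id label stored in the events.
#' @return data.frame with columns `particle_id`, `direction`
#'   (`cyt_to_ims` / `ims_to_cyt`), `entry_frame`, `exit_frame`
#'   (0-based), `duration_ns`.
#' @export
detect_translocations <- function(z, dt_ns, z_hi = 15, z_lo = -15,
                                  particle_id = "p1") {
  if (z_hi <= z_lo) stop("z_hi must exceed z_lo")
  if (length(z) < 2) stop("need at least 2 frames")
  state <- 0L            # 0 none, +1 last boundary was high, -1 low
  entry <- NA_integer_
  out <- list()
  for (i in seq_along(z)) {
    if (z[i] > z_hi) {
      if (state == -1L && !is.na(entry)) {
        # completed low -> high passage
        out[[length(out) + 1L]] <- data.frame(
          particle_id = particle_id, direction = "ims_to_cyt",
          entry_frame = entry - 1L, exit_frame = i - 1L,
          duration_ns = (i - entry) * dt_ns, stringsAsFactors = FALSE)
      }
      state <- 1L
      entry <- i
    } else if (z[i] < z_lo) {
      if (state == 1L && !is.na(entry)) {
        out[[length(out) + 1L]] <- data.frame(
          particle_id = particle_id, direction = "cyt_to_ims",
          entry_frame = entry - 1L, exit_frame = i - 1L,
          duration_ns = (i - entry) * dt_ns, stringsAsFactors = FALSE)
      }
      state <- -1L
      entry <- i
    }
    # frames inside the slab leave state and entry untouched: entry is
    # always the most recent frame seen in the current boundary region
  }
  if (length(out) == 0) {
    return(data.frame(particle_id = character(0), direction = character(0),
                      entry_frame = integer(0), exit_frame = integer(0),
                      duration_ns = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Count translocation events per species
#'
#' Applies [detect_translocations()] to each tracked particle of each
#' species and totals the two directions.
#'
#' @param traj a `trajectory`.
#' @param species_atoms named list: species name -> atom index vector.
#' @param pf a `pore_frame`; boundaries at +/- `pf$pore_half_length_A`.
#' @param ... passed to [detect_translocations()].
#' @return data.frame with columns `species`, `n_cyt_to_ims`,
#'   `n_ims_to_cyt`.
#' @export
count_events_by_species <- function(traj, species_atoms, pf, ...) {
  stopifnot(is.list(species_atoms), !is.null(names(species_atoms)))
  rows <- lapply(names(species_atoms), function(sp) {
    idx <- species_atoms[[sp]]
    zm <- z_series(traj, pf, idx)
    if (is.null(dim(zm))) zm <- matrix(zm, ncol = 1)
    n_down <- 0L; n_up <- 0L
    for (j in seq_along(idx)) {
      ev <- detect_translocations(zm[, j], traj$dt_ns,
                                  z_hi = pf$pore_half_length_A,
                                  z_lo = -pf$pore_half_length_A,
                                  particle_id = paste0(sp, "_", idx[j]), ...)
      n_down <- n_down + sum(ev$direction == "cyt_to_ims")
      n_up <- n_up + sum(ev$direction == "ims_to_cyt")
    }
    data.frame(species = sp, n_cyt_to_ims = n_down, n_ims_to_cyt = n_up,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
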