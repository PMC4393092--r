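# Binned quantities along the pore axis: occupancy fractions, N_int,
# pairing numbers, concentrations, free energies.

PROFILE_QUANTITIES <- c("occupancy_fraction", "n_int", "n_pairing",
                        "concentration", "free_energy_kcal", "value")

#' Construct a z-profile
#'
#' @param bin_edges_A monotone increasing edges (Angstrom).
#' @param values per-bin values (length = n_bins); `NA` marks bins with
#'   no estimate (e.g. unvisited slabs, infinite barriers).
#' @param se optional per-bin standard errors.
#' @param n_samples per-bin sample counts.
#' @param quantity label, one of occupancy_fraction, n_int, n_pairing,
#'   concentration, free_energy_kcal, value.
#' @return object of class `zprofile`.
#' @export
zprofile <- function(bin_edges_A, values, se = NULL, n_samples = NULL,
                     quantity = "value") {
  quantity <- match.arg(quantity, PROFILE_QUANTITIES)
  nb <- length(bin_edges_A) - 1L
  if (any(diff(bin_edges_A) <= 0)) stop("bin edges must be strictly increasing")
  if (length(values) != nb) stop("values length must equal number of bins")
  if (is.null(n_samples)) n_samples <- rep(NA_integer_, nb)
  if (!is.null(se) && length(se) != nb) stop("se length must equal number of bins")
  if (length(n_samples) != nb) stop("n_samples length must equal number of bins")
  structure(list(bin_edges_A = bin_edges_A,
                 values = as.numeric(values),
                 se = if (is.null(se)) NULL else as.numeric(se),
                 n_samples = as.integer(round(n_samples)),
                 quantity = quantity),
            class = "zprofile")
}

#' Bin centers of a z-profile
#' @param profile a `zprofile`.
#' @return numeric vector of bin midpoints.
#' @export
bin_centers <- function(profile) {
  e <- profile$bin_edges_A
  (e[-1] + e[-length(e)]) / 2
}

#' @export
as.data.frame.zprofile <- function(x, ...) {
  data.frame(z_center = bin_centers(x),
             value = x$values,
             se = if (is.null(x$se)) NA_real_ else x$se,
             n_samples = x$n_samples)
}

#' @export
print.zprofile <- function(x, ...) {
  nb <- length(x$values)
  cat("zprofile [", x$quantity, "]: ", nb, " bins over [",
      x$bin_edges_A[1], ", ", x$bin_edges_A[nb + 1], "] A, ",
      sum(!is.na(x$values)), " estimated\n", sep = "")
  invisible(x)
}
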