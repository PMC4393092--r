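# Shared builders for small in-code fixtures.

# a minimal system of n generic particles (no tags)
toy_system <- function(n, resname = "ION", name = "X", element = "X") {
  molecular_system(data.frame(
    serial = seq_len(n), name = name, element = element,
    resname = resname, resno = seq_len(n), chain = "A",
    stringsAsFactors = FALSE))
}

# trajectory from a list of coordinate matrices
traj_from_frames <- function(frames, dt_ns = 0.1, system = NULL, box = NULL) {
  n <- nrow(frames[[1]])
  if (is.null(system)) system <- toy_system(n)
  arr <- array(unlist(frames), dim = c(n, 3, length(frames)))
  trajectory(system, arr, dt_ns = dt_ns, box = box)
}

# trajectory of a single particle following a given z path (x = y = 0)
z_path_traj <- function(z, dt_ns = 0.1) {
  traj_from_frames(lapply(z, function(v) matrix(c(0, 0, v), 1)), dt_ns)
}

# random rigid rotation matrix (seeded by caller)
random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# write a small aligned FASTA and read it back
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  }
  path
}

# brute-force O(n^2) oracles used by the detector-equivalence tests;
# deliberately independent of the package's vectorised path
oracle_electrostatic <- function(coords, oxy, nitro, cutoff = 4.0) {
  hits <- character(0)
  for (b in names(nitro)) {
    dmin <- Inf
    for (i in oxy) for (j in nitro[[b]]) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d < dmin) dmin <- d
    }
    if (dmin <= cutoff) hits <- c(hits, b)
  }
  hits
}

oracle_pairing <- function(coords, oxy, cations, cutoff = 4.0) {
  hits <- character(0)
  for (b in names(cations)) {
    dmin <- Inf
    for (i in oxy) for (j in cations[[b]]) {
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d < dmin) dmin <- d
    }
    if (dmin < cutoff) hits <- c(hits, b)
  }
  hits
}

oracle_hbond <- function(coords, donors, acceptors) {
  hits <- list()
  for (k in seq_len(nrow(donors))) {
    D <- coords[donors[k, 1], ]; H <- coords[donors[k, 2], ]
    for (j in seq_along(acceptors)) {
      A <- coords[acceptors[j], ]
      da <- sqrt(sum((D - A)^2))
      v1 <- D - H; v2 <- A - H
      ang <- acos(min(max(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
      if (da < 3.5 && ang > 120) {
        hits[[length(hits) + 1L]] <- c(donors[k, 1], acceptors[j])
      }
    }
  }
  hits
}

# hysteresis replay oracle for translocation counting: a literal
# two-state scan independent of detect_translocations' bookkeeping
oracle_event_counts <- function(z, z_hi = 15, z_lo = -15) {
  region <- ifelse(z > z_hi, 1L, ifelse(z < z_lo, -1L, 0L))
  visited <- region[region != 0L]
  if (length(visited) == 0) return(c(down = 0L, up = 0L))
  trans <- diff(visited)
  c(down = sum(trans == -2L), up = sum(trans == 2L))
}

# contact-record rows built directly (mirrors the package's record schema)
mk_records <- function(frames, criterion, partner_a, partner_b, distance,
                       angle = NA_real_) {
  if (length(frames) == 0) {
    return(data.frame(frame = integer(0), criterion = character(0),
                      partner_a = character(0), partner_b = character(0),
                      distance = numeric(0), angle = numeric(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(frame = as.integer(frames), criterion = criterion,
             partner_a = partner_a, partner_b = partner_b,
             distance = distance, angle = angle, stringsAsFactors = FALSE)
}
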