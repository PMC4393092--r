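# Readers and writers for the external formats: PDB structures (plus a
# TSV structure table for hand-written fixtures), CHARMM/NAMD DCD and a
# plain-text trajectory dialect, aligned FASTA, I/V CSV, profile TSV.

#' Read a structure file into a molecular system
#'
#' Accepts standard PDB (ATOM/HETATM records only) or a plain-text TSV
#' atom table with header `serial name element resname resno chain`.
#' Role tags are populated from `tagging_rules`.
#'
#' @param path input file.
#' @param tagging_rules rules data.frame, see [default_tagging_rules()].
#' @param format `"auto"` (by extension), `"pdb"` or `"tsv"`.
#' @return a `molecular_system`; PDB coordinates are attached as
#'   attribute `"coords"` (n_atoms x 3 matrix).
#' @export
read_structure <- function(path, tagging_rules = default_tagging_rules(),
                           format = c("auto", "pdb", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "tsv" else "pdb"
  }
  if (format == "pdb") read_pdb(path, tagging_rules)
  else read_structure_tsv(path, tagging_rules)
}

read_structure_tsv <- function(path, tagging_rules) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("serial", "name", "element", "resname", "resno", "chain")
  if (!all(need %in% names(tab))) {
    stop("structure TSV must have columns: ", paste(need, collapse = " "))
  }
  tab$chain <- as.character(tab$chain)
  sys <- molecular_system(tab[need])
  apply_tagging(sys, tagging_rules)
}

#' Read a PDB file
#'
#' Fixed-column parser for ATOM/HETATM records. Element is taken from
#' columns 77-78 when present, otherwise guessed from the atom name.
#'
#' @inheritParams read_structure
#' @return a `molecular_system` with attribute `"coords"`.
#' @export
read_pdb <- function(path, tagging_rules = default_tagging_rules()) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(keep) == 0) stop("no ATOM/HETATM records in ", path)
  fld <- function(i, a, b) trimws(substr(lines[i], a, b))
  num <- function(i, a, b, what) {
    v <- suppressWarnings(as.numeric(fld(i, a, b)))
    if (any(is.na(v))) {
      stop("malformed ", what, " in PDB line ", i[which(is.na(v))[1]])
    }
    v
  }
  serial <- as.integer(num(keep, 7, 11, "serial"))
  name <- fld(keep, 13, 16)
  resname <- fld(keep, 18, 20)
  chain <- substr(lines[keep], 22, 22)
  resno <- as.integer(num(keep, 23, 26, "residue number"))
  x <- num(keep, 31, 38, "x coordinate")
  y <- num(keep, 39, 46, "y coordinate")
  z <- num(keep, 47, 54, "z coordinate")
  element <- trimws(substr(lines[keep], 77, 78))
  guess <- sub("[0-9']*$", "", sub("^[0-9]*", "", name))
  guess <- ifelse(nchar(guess) > 1 &
                    toupper(substr(guess, 1, 2)) %in%
                      c("CL", "NA", "MG", "BR", "FE", "ZN", "CA"),
                  substr(guess, 1, 2), substr(guess, 1, 1))
  element <- ifelse(element == "", toupper(guess), element)
  if (anyDuplicated(serial)) {
    stop("duplicate atom serial ", serial[duplicated(serial)][1],
         " in PDB line ", keep[duplicated(serial)][1])
  }
  atoms <- data.frame(serial = serial, name = name, element = element,
                      resname = resname, resno = resno, chain = chain,
                      stringsAsFactors = FALSE)
  sys <- apply_tagging(molecular_system(atoms), tagging_rules)
  attr(sys, "coords") <- cbind(x = x, y = y, z = z)
  sys
}

#' Write a system as a structure TSV
#'
#' Plain-text atom table readable by [read_structure()]; role tags are
#' re-derived from tagging rules on read.
#' @param system a `molecular_system`.
#' @param path output file.
#' @export
write_structure_tsv <- function(system, path) {
  a <- system$atoms[c("serial", "name", "element", "resname", "resno", "chain")]
  utils::write.table(a, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a system + coordinates as PDB
#' @param system a `molecular_system`.
#' @param coords n_atoms x 3 matrix (Angstrom).
#' @param path output file.
#' @export
write_pdb <- function(system, coords, path) {
  a <- system$atoms
  stopifnot(nrow(coords) == nrow(a))
  nm <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name),
               sprintf("%-4s", a$name))
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    a$serial %% 100000L, nm, a$resname, a$chain, a$resno %% 10000L,
    coords[, 1], coords[, 2], coords[, 3], toupper(a$element))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# ---- trajectory text dialect -------------------------------------------
# header:  natoms N dt_ns X
# frame:   frame I time_ns T [box a b c]   then N lines "x y z"

#' Read a trajectory
#'
#' @param system the `molecular_system` the frames belong to; the file's
#'   atom count must match.
#' @param path trajectory file.
#' @param format `"auto"` (by extension), `"text"` or `"dcd"`.
#' @param dt_ns frame spacing override; defaults to the value stored in
#'   the file.
#' @return a `trajectory`.
#' @export
read_trajectory <- function(system, path, format = c("auto", "text", "dcd"),
                            dt_ns = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "text"
  }
  if (format == "text") read_trajectory_text(system, path, dt_ns)
  else read_dcd(system, path, dt_ns)
}

read_trajectory_text <- function(system, path, dt_ns = NULL) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 4 || hdr[1] != "natoms" || hdr[3] != "dt_ns") {
    stop("bad trajectory header (expected 'natoms N dt_ns X'): line 1")
  }
  na <- as.integer(hdr[2])
  file_dt <- as.numeric(hdr[4])
  if (na != n_atoms(system)) {
    stop("atom count mismatch: file has ", na, ", system has ",
         n_atoms(system))
  }
  if (is.null(dt_ns)) dt_ns <- file_dt
  pos <- 2L
  coords <- list(); times <- numeric(0); boxes <- list()
  has_box <- NA
  while (pos <= length(lines)) {
    if (trimws(lines[pos]) == "") { pos <- pos + 1L; next }
    fh <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
    if (fh[1] != "frame") stop("expected 'frame' record at line ", pos)
    t <- as.numeric(fh[4])
    box <- NULL
    if (length(fh) >= 8 && fh[5] == "box") box <- as.numeric(fh[6:8])
    if (is.na(has_box)) has_box <- !is.null(box)
    if (pos + na > length(lines)) {
      stop("truncated frame block starting at line ", pos,
           " (need ", na, " coordinate lines)")
    }
    block <- lines[(pos + 1L):(pos + na)]
    m <- matrix(suppressWarnings(
      as.numeric(unlist(strsplit(trimws(block), "\\s+")))),
      ncol = 3, byrow = TRUE)
    if (nrow(m) != na || any(is.na(m))) {
      stop("malformed coordinate block starting at line ", pos + 1L)
    }
    coords[[length(coords) + 1L]] <- m
    times <- c(times, t)
    boxes[[length(boxes) + 1L]] <- box
    pos <- pos + na + 1L
  }
  if (length(coords) == 0) stop("no frames in ", path)
  arr <- array(unlist(coords), dim = c(na, 3, length(coords)))
  box <- if (isTRUE(has_box)) do.call(rbind, boxes) else NULL
  trajectory(system, arr, dt_ns = dt_ns, time_ns = times, box = box)
}

#' Write a trajectory
#' @param traj a `trajectory`.
#' @param path output file.
#' @param format `"text"` or `"dcd"`.
#' @export
write_trajectory <- function(traj, path, format = c("text", "dcd")) {
  format <- match.arg(format)
  if (format == "text") write_trajectory_text(traj, path)
  else write_dcd(traj, path)
  invisible(path)
}

write_trajectory_text <- function(traj, path) {
  na <- dim(traj$coords)[1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("natoms %d dt_ns %.10g", na, traj$dt_ns), con)
  for (i in seq_len(n_frames(traj))) {
    fr <- get_frame(traj, i)
    hdr <- sprintf("frame %d time_ns %.10g", i - 1L, fr$time_ns)
    if (!is.null(fr$box)) {
      hdr <- paste(hdr, sprintf("box %.10g %.10g %.10g",
                                fr$box[1], fr$box[2], fr$box[3]))
    }
    writeLines(hdr, con)
    writeLines(sprintf("%.6f %.6f %.6f",
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
  }
}

# ---- DCD (CHARMM/NAMD flavour) -----------------------------------------
# Binary Fortran-record format: 84-byte "CORD" header with 20 icntrl ints,
# title record, natoms record, then per frame an optional 48-byte unit
# cell record followed by x, y, z float32 records.

read_fort_record <- function(con) {
  len <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(len) == 0) return(NULL)
  raw <- readBin(con, "raw", len)
  tail <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(tail) == 0 || tail != len) stop("corrupt DCD record")
  raw
}

write_fort_record <- function(con, raw) {
  writeBin(as.integer(length(raw)), con, size = 4, endian = "little")
  writeBin(raw, con)
  writeBin(as.integer(length(raw)), con, size = 4, endian = "little")
}

read_dcd <- function(system, path, dt_ns = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_fort_record(con)
  if (is.null(hdr) || length(hdr) != 84 ||
      rawToChar(hdr[1:4]) != "CORD") {
    stop("not a CHARMM/NAMD DCD file: ", path)
  }
  icntrl <- readBin(hdr[5:84], "integer", 20, size = 4, endian = "little")
  nframes_hdr <- icntrl[1]
  delta <- readBin(hdr[41:44], "numeric", 1, size = 4, endian = "little")
  has_cell <- icntrl[11] != 0
  invisible(read_fort_record(con))            # title block
  na_raw <- read_fort_record(con)
  na <- readBin(na_raw, "integer", 1, size = 4, endian = "little")
  if (na != n_atoms(system)) {
    stop("atom count mismatch: file has ", na, ", system has ",
         n_atoms(system))
  }
  if (is.null(dt_ns)) dt_ns <- if (delta > 0) delta else 1
  coords <- list(); boxes <- list()
  repeat {
    first <- read_fort_record(con)
    if (is.null(first)) break
    if (has_cell) {
      cell <- readBin(first, "numeric", 6, size = 8, endian = "little")
      # XTLABC order: a, gamma, b, beta, alpha, c
      boxes[[length(boxes) + 1L]] <- cell[c(1, 3, 6)]
      first <- read_fort_record(con)
      if (is.null(first)) stop("truncated DCD frame (missing x record)")
    }
    x <- readBin(first, "numeric", na, size = 4, endian = "little")
    yr <- read_fort_record(con); zr <- read_fort_record(con)
    if (is.null(yr) || is.null(zr)) stop("truncated DCD frame")
    y <- readBin(yr, "numeric", na, size = 4, endian = "little")
    z <- readBin(zr, "numeric", na, size = 4, endian = "little")
    coords[[length(coords) + 1L]] <- cbind(x, y, z)
  }
  if (length(coords) == 0) stop("no frames in DCD ", path)
  if (nframes_hdr > 0 && length(coords) != nframes_hdr) {
    warning("DCD header declares ", nframes_hdr, " frames, read ",
            length(coords))
  }
  arr <- array(unlist(coords), dim = c(na, 3, length(coords)))
  box <- if (has_cell) do.call(rbind, boxes) else NULL
  trajectory(system, arr, dt_ns = dt_ns, box = box)
}

write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj)
  na <- dim(traj$coords)[1]
  has_cell <- !is.null(traj$box)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- if (has_cell) 1L else 0L
  icntrl[20] <- 24L                           # CHARMM version stamp
  hdr <- c(charToRaw("CORD"),
           writeBin(icntrl, raw(), size = 4, endian = "little"))
  # store dt_ns in the delta slot (float32 at icntrl[10])
  hdr[41:44] <- writeBin(as.numeric(traj$dt_ns), raw(), size = 4,
                         endian = "little")
  write_fort_record(con, hdr)
  title <- sprintf("%-80s", "porescope trajectory")
  write_fort_record(con, c(writeBin(1L, raw(), size = 4, endian = "little"),
                           charToRaw(title)))
  write_fort_record(con, writeBin(as.integer(na), raw(), size = 4,
                                  endian = "little"))
  for (i in seq_len(nf)) {
    fr <- get_frame(traj, i)
    if (has_cell) {
      cell <- c(fr$box[1], 90, fr$box[2], 90, 90, fr$box[3])
      write_fort_record(con, writeBin(as.numeric(cell), raw(), size = 8,
                                      endian = "little"))
    }
    for (d in 1:3) {
      write_fort_record(con, writeBin(as.numeric(fr$coords[, d]), raw(),
                                      size = 4, endian = "little"))
    }
  }
}

# ---- MSA, I/V, profile TSV ---------------------------------------------

#' Read an aligned FASTA multiple sequence alignment
#'
#' @param path aligned FASTA file.
#' @param ref_id id of the reference record (default: first record).
#' @return object of class `msa`: list with `ids`, `seqs` (named uppercase
#'   character vector), `width`, `ref_id`.
#' @export
read_msa <- function(path, ref_id = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no sequences in ", path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  names(seqs) <- ids
  w <- unique(nchar(seqs))
  if (length(w) != 1) {
    stop("ragged alignment: sequence lengths ", paste(sort(w), collapse = ", "))
  }
  if (is.null(ref_id)) ref_id <- ids[1]
  if (!ref_id %in% ids) stop("reference id '", ref_id, "' not in alignment")
  structure(list(ids = ids, seqs = seqs, width = w, ref_id = ref_id),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", length(x$ids), "sequences x", x$width,
      "columns, reference", x$ref_id, "\n")
  invisible(x)
}

#' Read a current-voltage series from CSV
#'
#' Expects header `voltage_mV,current_pA`.
#' @param path CSV file.
#' @return object of class `iv_series`: data.frame with the two columns.
#' @export
read_iv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("voltage_mV", "current_pA") %in% names(tab))) {
    stop("I/V CSV must have header 'voltage_mV,current_pA'")
  }
  v <- suppressWarnings(as.numeric(tab$voltage_mV))
  i <- suppressWarnings(as.numeric(tab$current_pA))
  if (any(is.na(v)) || any(is.na(i))) {
    stop("non-numeric cell in I/V CSV row ",
         which(is.na(v) | is.na(i))[1])
  }
  iv_series(v, i)
}

#' Construct an I/V series
#' @param voltage_mV,current_pA equal-length numeric vectors; at least two
#'   distinct voltages required.
#' @return an `iv_series` data.frame.
#' @export
iv_series <- function(voltage_mV, current_pA) {
  if (length(voltage_mV) != length(current_pA)) {
    stop("voltage and current vectors differ in length")
  }
  if (length(unique(voltage_mV)) < 2) {
    stop("I/V series needs at least 2 distinct voltages")
  }
  structure(data.frame(voltage_mV = voltage_mV, current_pA = current_pA),
            class = c("iv_series", "data.frame"))
}

#' Write a z-profile as TSV
#'
#' Columns `z_center`, `value`, `se`, `n_samples`; missing values written
#' as `NA`.
#' @param profile a `zprofile`, see [zprofile()].
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  tab <- as.data.frame(profile)
  utils::write.table(format(tab, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a profile TSV written by [write_profile()]
#' @param path TSV file.
#' @param quantity quantity label to attach.
#' @return a `zprofile` (bin edges reconstructed from centers, assuming a
#'   uniform grid).
#' @export
read_profile <- function(path, quantity = "value") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  zc <- tab$z_center
  if (length(zc) < 1) stop("empty profile file ", path)
  w <- if (length(zc) > 1) stats::median(diff(zc)) else 1
  edges <- c(zc - w / 2, zc[length(zc)] + w / 2)
  zprofile(edges, tab$value, se = tab$se, n_samples = tab$n_samples,
           quantity = quantity)
}
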