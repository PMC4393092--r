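# Role tags recognised throughout the package.  Tags name chemical roles,
# not atom names: criteria select atoms by role so that non-standard
# residue or ligand naming can be accommodated via tagging rules.
ROLE_TAGS <- c(
  "backbone_carbon", "sidechain_nitrogen", "phosphate_oxygen",
  "phosphorus_terminal", "ring_atom", "donor_heavy", "hydrogen",
  "cation", "anion"
)

#' Construct a molecular system
#'
#' A `molecular_system` is the package's topology container: an ordered
#' atom table plus named index sets ("topology groups", e.g. the three
#' atoms spanning an adenine ring plane). Coordinates live in
#' [trajectory()] frames, never in the system.
#'
#' @param atoms data.frame with columns `serial` (integer, unique),
#'   `name`, `element`, `resname`, `resno`, `chain`, and optionally a
#'   list-column `tags` of role-tag character vectors.
#' @param topology_groups named list of integer atom-index vectors.
#' @return object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, topology_groups = list()) {
  required <- c("serial", "name", "element", "resname", "resno", "chain")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atoms table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(atoms$serial)) {
    dup <- atoms$serial[duplicated(atoms$serial)][1]
    stop("duplicate atom serial: ", dup)
  }
  if (is.null(atoms$tags)) {
    atoms$tags <- replicate(nrow(atoms), character(0), simplify = FALSE)
  }
  bad <- setdiff(unlist(atoms$tags), ROLE_TAGS)
  if (length(bad) > 0) stop("unknown role tag(s): ", paste(bad, collapse = ", "))
  # hydrogen tag must sit on element H and vice-versa tags stay consistent
  is_h_tag <- vapply(atoms$tags, function(t) "hydrogen" %in% t, logical(1))
  if (any(is_h_tag & toupper(atoms$element) != "H")) {
    stop("'hydrogen' role tag on a non-H element")
  }
  n <- nrow(atoms)
  for (g in names(topology_groups)) {
    idx <- topology_groups[[g]]
    if (length(idx) == 0 || any(idx < 1L | idx > n)) {
      stop("topology group '", g, "' has out-of-range atom indices")
    }
  }
  structure(list(atoms = atoms, topology_groups = topology_groups),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat("molecular_system:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues,",
      length(x$topology_groups), "topology groups\n")
  invisible(x)
}

#' Number of atoms in a system
#' @param system a `molecular_system`.
#' @return integer atom count.
#' @export
n_atoms <- function(system) nrow(system$atoms)

#' Indices of atoms carrying a role tag
#' @param system a `molecular_system`.
#' @param tag one of the recognised role tags.
#' @return integer vector of atom indices (1-based, system order).
#' @export
tagged_indices <- function(system, tag) {
  tag <- match.arg(tag, ROLE_TAGS)
  which(vapply(system$atoms$tags, function(t) tag %in% t, logical(1)))
}

#' Select atom indices by attribute
#'
#' @param system a `molecular_system`.
#' @param name,resname,element,chain optional character filters (exact match).
#' @param resno optional integer filter.
#' @return integer vector of matching atom indices.
#' @export
select_atoms <- function(system, name = NULL, resname = NULL, resno = NULL,
                         element = NULL, chain = NULL) {
  a <- system$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(element)) keep <- keep & toupper(a$element) %in% toupper(element)
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  which(keep)
}

#' Default role-tagging rules
#'
#' Rules map (residue name, atom name) regex patterns to role tags.
#' Defaults cover the standard selections: Lys NZ and Arg NE/NH1/NH2 are
#' basic side-chain nitrogens; nucleotide phosphate oxygens and the
#' terminal (gamma for ATP, beta for ADP) phosphorus are identified by
#' CHARMM-style template names; element H is tagged hydrogen. Groups are
#' identified chemically via templates rather than bare atom names so the
#' mapping is explicit and overridable.
#'
#' @return data.frame with columns `resname_pattern`, `name_pattern`, `tag`.
#' @export
default_tagging_rules <- function() {
  r <- function(res, nm, tag) data.frame(resname_pattern = res,
                                         name_pattern = nm, tag = tag,
                                         stringsAsFactors = FALSE)
  rbind(
    r("^LYS$", "^NZ$",            "sidechain_nitrogen"),
    r("^ARG$", "^(NE|NH1|NH2)$",  "sidechain_nitrogen"),
    r("^.*$",  "^(CA|C)$",        "backbone_carbon"),
    # nucleotide / phosphate templates
    r("^(ATP|ADP|AMP)$", "^O[123][ABG]$", "phosphate_oxygen"),
    r("^(ATP|ADP|AMP)$", "^O5'$",         "phosphate_oxygen"),
    r("^(PO4|H2PO4|HPO4|PI)$", "^O[1-4]$", "phosphate_oxygen"),
    r("^ATP$", "^PG$", "phosphorus_terminal"),
    r("^ADP$", "^PB$", "phosphorus_terminal"),
    r("^AMP$", "^P$",  "phosphorus_terminal"),
    r("^(PO4|H2PO4|HPO4|PI)$", "^P$", "phosphorus_terminal"),
    # monatomic ions (incl. the synthetic generator's species names)
    r("^(SOD|NA|POT|K|CAT)$", ".*", "cation"),
    r("^(CLA|CL|ANI)$",       ".*", "anion"),
    # synthetic bead-model ligand
    r("^PLG$", "^P$",        "phosphorus_terminal"),
    r("^PLG$", "^O[1-3]$",   "phosphate_oxygen"),
    r("^PLG$", "^N6$",       "donor_heavy"),
    r("^PLG$", "^C4[ABC]$",  "ring_atom")
  )
}

#' Apply tagging rules to a system
#'
#' Deterministic: running twice with the same rules yields identical tags.
#' Element H is always tagged `hydrogen` regardless of rules.
#'
#' @param system a `molecular_system`.
#' @param rules data.frame as returned by [default_tagging_rules()].
#' @return the system with `tags` repopulated.
#' @export
apply_tagging <- function(system, rules = default_tagging_rules()) {
  a <- system$atoms
  tags <- replicate(nrow(a), character(0), simplify = FALSE)
  for (k in seq_len(nrow(rules))) {
    hit <- grepl(rules$resname_pattern[k], a$resname) &
      grepl(rules$name_pattern[k], a$name)
    for (i in which(hit)) tags[[i]] <- union(tags[[i]], rules$tag[k])
  }
  for (i in which(toupper(a$element) == "H")) {
    tags[[i]] <- union(tags[[i]], "hydrogen")
  }
  system$atoms$tags <- tags
  molecular_system(system$atoms, system$topology_groups)
}

#' Construct a trajectory
#'
#' @param system a `molecular_system`.
#' @param coords numeric array `n_atoms x 3 x n_frames` in Angstrom.
#' @param time_ns numeric vector of frame times (strictly increasing); if
#'   `NULL`, `(0:(n_frames-1)) * dt_ns`.
#' @param dt_ns nominal frame spacing in ns (> 0).
#' @param box optional `n_frames x 3` matrix (or length-3 vector recycled)
#'   of orthorhombic box lengths in Angstrom.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(system, coords, dt_ns, time_ns = NULL, box = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[1] != n_atoms(system)) {
    stop("coords atom count (", dim(coords)[1],
         ") does not match system atom count (", n_atoms(system), ")")
  }
  nf <- dim(coords)[3]
  if (nf < 1) stop("trajectory needs at least one frame")
  if (!is.numeric(dt_ns) || dt_ns <= 0) stop("dt_ns must be > 0")
  if (is.null(time_ns)) time_ns <- (seq_len(nf) - 1) * dt_ns
  if (length(time_ns) != nf) stop("time_ns length must equal frame count")
  if (nf > 1 && any(diff(time_ns) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
    if (nrow(box) != nf || ncol(box) != 3) stop("box must be n_frames x 3")
  }
  structure(list(system = system, coords = coords, time_ns = time_ns,
                 dt_ns = dt_ns, box = box),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", dim(x$coords)[3], "frames x", dim(x$coords)[1],
      "atoms, dt =", x$dt_ns, "ns, span",
      round(x$time_ns[length(x$time_ns)] - x$time_ns[1], 4), "ns\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @return list with `coords` (n_atoms x 3), `time_ns`, `box` (or NULL).
#' @export
get_frame <- function(traj, i) {
  nf <- n_frames(traj)
  if (i < 1 || i > nf) stop("frame index out of range: ", i)
  cc <- traj$coords[, , i, drop = FALSE]
  dim(cc) <- dim(cc)[1:2]
  list(coords = cc,
       time_ns = traj$time_ns[i],
       box = if (is.null(traj$box)) NULL else traj$box[i, ])
}
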