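# Alignment-column conservation relative to a reference sequence:
# per-position percent identity and percent substituted to Lys/Arg.
# Conventions (documented, configurable): gap characters are excluded
# from the denominator, and the reference sequence itself is excluded
# ("conservation across species" semantics).

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$seqs, ""))
}

#' Map a reference residue number to an alignment column
#'
#' @param msa an `msa` (see [read_msa()]).
#' @param ref_residue_number 1-based position in the ungapped reference
#'   sequence.
#' @param ref_id reference record id (default the alignment's).
#' @return 1-based alignment column index.
#' @export
map_ref_position <- function(msa, ref_residue_number, ref_id = msa$ref_id) {
  if (!ref_id %in% msa$ids) stop("reference id '", ref_id, "' not in alignment")
  chars <- strsplit(msa$seqs[[ref_id]], "")[[1]]
  nongap <- which(chars != "-")
  if (ref_residue_number < 1 || ref_residue_number > length(nongap)) {
    stop("residue number ", ref_residue_number,
         " outside ungapped reference length ", length(nongap))
  }
  nongap[ref_residue_number]
}

#' Conservation statistics at one reference position
#'
#' Over the non-reference sequences carrying a non-gap character at the
#' mapped column: `conserved_pct` is the percentage identical to the
#' reference character; `to_K_pct` / `to_R_pct` the percentage equal to K
#' or R when the reference is not that letter (0 when it is).
#' Percentages use the counted (non-gap) sequences as denominator and are
#' reported to one decimal.
#'
#' @inheritParams map_ref_position
#' @param include_reference count the reference sequence itself
#'   (default `FALSE`).
#' @return data.frame (one row) with `ref_residue_number`, `ref_residue`,
#'   `conserved_pct`, `to_K_pct`, `to_R_pct`, `n_sequences_counted`.
#'   All-gap columns yield `NA` percentages with a zero count.
#' @export
conservation_at <- function(msa, ref_residue_number, ref_id = msa$ref_id,
                            include_reference = FALSE) {
  col <- map_ref_position(msa, ref_residue_number, ref_id)
  chars <- substr(msa$seqs, col, col)
  ref_char <- chars[[which(msa$ids == ref_id)[1]]]
  if (!include_reference) chars <- chars[msa$ids != ref_id]
  chars <- toupper(chars)
  counted <- chars[chars != "-"]
  n <- length(counted)
  pct <- function(x) round(100 * x / n, 1)
  if (n == 0) {
    return(data.frame(ref_residue_number = ref_residue_number,
                      ref_residue = ref_char, conserved_pct = NA_real_,
                      to_K_pct = NA_real_, to_R_pct = NA_real_,
                      n_sequences_counted = 0L, stringsAsFactors = FALSE))
  }
  data.frame(
    ref_residue_number = ref_residue_number,
    ref_residue = ref_char,
    conserved_pct = pct(sum(counted == ref_char)),
    to_K_pct = if (ref_char == "K") 0 else pct(sum(counted == "K")),
    to_R_pct = if (ref_char == "R") 0 else pct(sum(counted == "R")),
    n_sequences_counted = n,
    stringsAsFactors = FALSE)
}

#' Conservation table over several positions
#'
#' @inheritParams conservation_at
#' @param positions vector of reference residue numbers.
#' @return data.frame, one row per position (column layout of a
#'   residue-conservation table: Cons \% and changed-to-K/R \%).
#' @export
conservation_table <- function(msa, positions, ref_id = msa$ref_id,
                               include_reference = FALSE) {
  do.call(rbind, lapply(positions, conservation_at, msa = msa,
                        ref_id = ref_id,
                        include_reference = include_reference))
}
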