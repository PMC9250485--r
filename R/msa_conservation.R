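# Ortholog-alignment conservation checks around a mutation site.
# The alignment itself is an input (aligned FASTA); this module maps a
# protein position to its alignment column and summarizes identity in a
# window around it.

#' Construct a protein multiple sequence alignment object
#'
#' @param sequences named character vector of equal-length aligned
#'   amino-acid strings using `-` for gaps (e.g. from [read_fasta()] on
#'   an aligned FASTA).
#' @param reference which row is the reference (human) sequence: an index
#'   or a sequence name.  Default 1.
#' @return object of class `protein_msa`.
#' @export
protein_msa <- function(sequences, reference = 1L) {
  nms <- names(sequences)
  sequences <- stats::setNames(toupper(as.character(sequences)), nms)
  if (length(unique(nchar(sequences))) != 1L)
    stop_famvar("aligned rows must all have the same length",
                class = "famvar_format_error")
  if (is.character(reference)) {
    reference <- match(reference, names(sequences))
    if (is.na(reference))
      stop_famvar("reference name not found in alignment")
  }
  reference <- as.integer(reference)
  if (reference < 1L || reference > length(sequences))
    stop_famvar("reference index out of range")
  if (!nchar(gsub("-", "", sequences[reference])))
    stop_famvar("reference row contains no residues",
                class = "famvar_format_error")
  structure(list(names = names(sequences) %||%
                   paste0("seq", seq_along(sequences)),
                 rows = unname(sequences),
                 reference_index = reference),
            class = "protein_msa")
}

msa_char_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$rows, ""))
}

#' Map an ungapped reference position to its alignment column
#'
#' @param msa a [protein_msa()].
#' @param reference_position 1-based position in the *ungapped* reference
#'   sequence (e.g. 444 for p.Y444C).
#' @return the 1-based alignment column index holding that residue.
#' @export
column_of_residue <- function(msa, reference_position) {
  ref <- strsplit(msa$rows[msa$reference_index], "")[[1]]
  ungapped <- cumsum(ref != "-")
  col <- which(ref != "-" & ungapped == reference_position)
  if (!length(col))
    stop_famvar("position %d beyond ungapped reference length (%d)",
                reference_position, max(ungapped))
  col[1]
}

#' Is an alignment column universally conserved?
#'
#' @param msa a [protein_msa()].
#' @param column 1-based alignment column.
#' @return TRUE iff at least one non-gap residue exists in the column and
#'   all non-gap residues are identical.
#' @export
is_position_conserved <- function(msa, column) {
  m <- msa_char_matrix(msa)
  if (column < 1L || column > ncol(m))
    stop_famvar("column %d outside alignment (width %d)", column, ncol(m))
  res <- m[, column]
  res <- res[res != "-"]
  length(res) > 0L && length(unique(res)) == 1L
}

#' Percent identity in a window around an alignment column
#'
#' Summarizes conservation of the region surrounding a mutation site:
#' over the window `column +/- flank` (clipped to the alignment), each
#' ortholog row is compared position-wise against the reference row.  A
#' position matches when both residues are non-gap and identical; a gap
#' in either sequence counts as a mismatch.  The returned value is the
#' mean per-ortholog identity, in percent.
#'
#' @param msa a [protein_msa()] with at least two rows.
#' @param column 1-based alignment column of the mutation site.
#' @param flank number of columns on each side (default 5).
#' @param scheme `"reference"` (default): mean identity of each ortholog
#'   to the reference; `"all_pairs"`: mean over all unordered row pairs.
#' @return percent identity in \[0, 100\].
#' @export
window_identity <- function(msa, column, flank = 5,
                            scheme = c("reference", "all_pairs")) {
  scheme <- match.arg(scheme)
  m <- msa_char_matrix(msa)
  if (nrow(m) < 2L)
    stop_famvar("identity undefined for a single-sequence alignment",
                class = "famvar_config_error")
  if (column < 1L || column > ncol(m))
    stop_famvar("column %d outside alignment (width %d)", column, ncol(m))
  cols <- max(1L, column - flank):min(ncol(m), column + flank)
  w <- m[, cols, drop = FALSE]
  pair_identity <- function(a, b)
    mean(a == b & a != "-" & b != "-")
  if (scheme == "reference") {
    ref <- w[msa$reference_index, ]
    others <- setdiff(seq_len(nrow(w)), msa$reference_index)
    100 * mean(vapply(others, function(i) pair_identity(ref, w[i, ]), 0))
  } else {
    pairs <- utils::combn(nrow(w), 2)
    100 * mean(apply(pairs, 2, function(p)
      pair_identity(w[p[1], ], w[p[2], ])))
  }
}

#' Conservation summary around a protein position
#'
#' Convenience wrapper combining [column_of_residue()],
#' [is_position_conserved()] and [window_identity()].
#'
#' @param msa a [protein_msa()].
#' @param position 1-based ungapped reference position.
#' @param flank window half-width (default 5).
#' @param scheme identity scheme, see [window_identity()].
#' @return one-row data frame with `position`, `column`, `conserved`,
#'   `window_identity_pct`.
#' @export
conservation_summary <- function(msa, position, flank = 5,
                                 scheme = "reference") {
  col <- column_of_residue(msa, position)
  data.frame(position = position, column = col,
             conserved = is_position_conserved(msa, col),
             window_identity_pct = window_identity(msa, col, flank,
                                                   scheme = scheme))
}
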