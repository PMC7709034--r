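#' Load a circularized mitochondrial reference genome
#'
#' Reads a single-record FASTA and builds the extended ("circularized")
#' sequence used for alignment-free coordinate work around the origin: the
#' first 80 nucleotides (fewer for short toy references) are appended after
#' the last position, so features spanning the origin of the circular
#' mtGenome can be addressed on one linear axis.
#'
#' @param fasta_path Path to a FASTA file containing exactly one record.
#' @return An object of class `mt_reference` with fields `name`, `sequence`
#'   (upper-case character string), `extended_sequence`, `L` (genome length)
#'   and `ext_len` (number of appended bases, `min(80, L)`).
#' @details The canonical human reference (rCRS) has L = 16,569; other
#'   lengths are accepted with a warning so that small toy circles can be
#'   used in tests and simulations.
#' @export
load_reference <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) {
    stop("no sequence records found in '", fasta_path, "'")
  }
  if (length(seqs) > 1L) {
    stop("expected a single-record FASTA, found ", length(seqs), " records")
  }
  mt_reference(as.character(seqs[[1]]), name = names(seqs)[1])
}

#' Construct an `mt_reference` from a sequence string
#'
#' @param sequence Character scalar over A/C/G/T/N.
#' @param name Sequence name.
#' @return An `mt_reference` object; see [load_reference()].
#' @export
mt_reference <- function(sequence, name = "chrM") {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L == 0L) stop("empty reference sequence")
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L) {
    stop("reference contains characters outside A/C/G/T/N: ",
         substr(bad, 1L, 10L))
  }
  if (L != 16569L) {
    warning("reference length ", L, " differs from rCRS (16,569 nt)")
  }
  ext_len <- min(80L, L)
  structure(
    list(
      name = name,
      sequence = sequence,
      extended_sequence = paste0(sequence, substr(sequence, 1L, ext_len)),
      L = L,
      ext_len = ext_len
    ),
    class = "mt_reference"
  )
}

#' @export
print.mt_reference <- function(x, ...) {
  cat("<mt_reference> ", x$name, ": ", x$L, " nt circle (extended ",
      nchar(x$extended_sequence), " nt)\n", sep = "")
  invisible(x)
}

#' Reference base(s) at circular positions
#'
#' @param ref An `mt_reference`.
#' @param positions Integer vector of 1-based circular positions.
#' @return Character vector of single bases.
#' @export
ref_base <- function(ref, positions) {
  stopifnot(inherits(ref, "mt_reference"))
  if (any(positions < 1L | positions > ref$L)) {
    stop("positions out of range 1..", ref$L)
  }
  substring(ref$sequence, positions, positions)
}

#' Map a position on the extended axis back to the circle
#'
#' Positions up to `L` map to themselves; positions on the appended copy of
#' the origin (`L+1 .. L+ext`) map back to `1 .. ext`.
#'
#' @param extended_pos Integer vector of 1-based positions on the extended
#'   axis.
#' @param L Genome length (16,569 for rCRS).
#' @param ext Length of the appended tail (default 80).
#' @return Integer vector of 1-based circular positions.
#' @export
canonical_position <- function(extended_pos, L, ext = 80L) {
  extended_pos <- as.integer(extended_pos)
  if (any(is.na(extended_pos)) ||
      any(extended_pos < 1L | extended_pos > L + ext)) {
    stop("extended positions must lie in 1..", L + ext)
  }
  ifelse(extended_pos > L, extended_pos - L, extended_pos)
}
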