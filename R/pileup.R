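#' Stranded per-position allele-count pileups
#'
#' A pileup stores, for every circular position, stranded read counts for
#' the five spanning-read states A/C/G/T/deletion, plus insertion-carrying
#' read counts keyed by the inserted sequence and anchored at the 5'
#' position preceding the insertion. Insertion reads are a subset of the
#' spanning reads and are never added again to the total depth.
#'
#' @param sample_id Sample label.
#' @param L Circle length.
#' @param metadata Free-form list (input DNA mass, mtGenome copies, run id,
#'   role, ...).
#' @return An `mt_pileup`: `counts` is an integer `L x 10` matrix with
#'   columns `<allele>_fwd` / `<allele>_rev`; `insertions` is a data.frame
#'   with columns `position`, `seq`, `fwd`, `rev`.
#' @export
mt_pileup <- function(sample_id, L = 16569L, metadata = list()) {
  counts <- matrix(0L, nrow = L, ncol = 10L,
                   dimnames = list(NULL, count_cols()))
  structure(
    list(sample_id = sample_id, L = as.integer(L), counts = counts,
         insertions = empty_insertions(), metadata = metadata),
    class = "mt_pileup"
  )
}

PILEUP_ALLELES <- c("A", "C", "G", "T", "del")

count_cols <- function() {
  as.vector(t(outer(PILEUP_ALLELES, c("fwd", "rev"), paste, sep = "_")))
}

empty_insertions <- function() {
  data.frame(position = integer(), seq = character(),
             fwd = integer(), rev = integer(), stringsAsFactors = FALSE)
}

#' @export
print.mt_pileup <- function(x, ...) {
  d <- depth_vector(x)
  cat("<mt_pileup> ", x$sample_id, ": ", x$L, " positions, ",
      sum(d > 0L), " with reads, mean depth ",
      round(mean(d), 1), "X\n", sep = "")
  invisible(x)
}

#' Set stranded counts at one position of a pileup
#'
#' @param p An `mt_pileup`.
#' @param position 1-based circular position.
#' @param ... Named counts. Scalars count forward reads only; length-2
#'   vectors are `c(fwd, rev)`. Names are `A`, `C`, `G`, `T`, `del`, or
#'   `ins_<seq>` for insertion reads (e.g. `ins_C = c(20, 15)`).
#' @return The modified pileup.
#' @export
set_counts <- function(p, position, ...) {
  stopifnot(inherits(p, "mt_pileup"))
  vals <- list(...)
  for (nm in names(vals)) {
    v <- as.integer(vals[[nm]])
    if (length(v) == 1L) v <- c(v, 0L)
    stopifnot(length(v) == 2L, all(v >= 0L))
    if (startsWith(nm, "ins_")) {
      p$insertions <- rbind(
        p$insertions[!(p$insertions$position == position &
                         p$insertions$seq == sub("^ins_", "", nm)), ],
        data.frame(position = as.integer(position),
                   seq = sub("^ins_", "", nm),
                   fwd = v[1], rev = v[2], stringsAsFactors = FALSE))
      rownames(p$insertions) <- NULL
    } else {
      stopifnot(nm %in% PILEUP_ALLELES)
      p$counts[position, paste0(nm, c("_fwd", "_rev"))] <- v
    }
  }
  p
}

#' Extract the stranded counts at one position
#'
#' @param p An `mt_pileup`.
#' @param position 1-based circular position.
#' @return A `position_counts` object: `counts` is a 5 x 2 matrix (rows
#'   A/C/G/T/del, columns fwd/rev); `insertions` the insertion rows anchored
#'   there.
#' @export
position_counts <- function(p, position) {
  stopifnot(inherits(p, "mt_pileup"),
            position >= 1L, position <= p$L)
  cm <- matrix(p$counts[position, ], nrow = 5L, byrow = TRUE,
               dimnames = list(PILEUP_ALLELES, c("fwd", "rev")))
  ins <- p$insertions[p$insertions$position == position,
                      c("seq", "fwd", "rev"), drop = FALSE]
  rownames(ins) <- NULL
  structure(list(position = as.integer(position), counts = cm,
                 insertions = ins),
            class = "position_counts")
}

#' Build a `position_counts` directly from counts
#'
#' Convenience constructor for worked examples and tests.
#'
#' @param position Position label (default 1).
#' @inheritParams set_counts
#' @export
pos_counts <- function(..., position = 1L) {
  p <- mt_pileup("adhoc", L = max(1L, position))
  p <- set_counts(p, position, ...)
  position_counts(p, position)
}

#' @export
print.position_counts <- function(x, ...) {
  cat("<position_counts> position ", x$position, ", depth ",
      total_depth(x), "X\n", sep = "")
  print(x$counts)
  if (nrow(x$insertions)) {
    cat("insertions:\n")
    print(x$insertions)
  }
  invisible(x)
}

#' Total read depth
#'
#' The total depth at a position is the sum of forward and reverse reads
#' over the five spanning states A/C/G/T/del. Insertion-carrying reads are
#' already included among those and are not added again.
#'
#' @param pc A `position_counts`.
#' @return Integer read count.
#' @export
total_depth <- function(pc) {
  stopifnot(inherits(pc, "position_counts"))
  sum(pc$counts)
}

# per-position depth for a whole pileup (vectorized)
depth_vector <- function(p) {
  stopifnot(inherits(p, "mt_pileup"))
  as.integer(rowSums(p$counts))
}

# L x 5 matrix of per-allele read counts (fwd + rev)
allele_count_matrix <- function(p) {
  m <- p$counts[, seq(1L, 9L, by = 2L), drop = FALSE] +
    p$counts[, seq(2L, 10L, by = 2L), drop = FALSE]
  colnames(m) <- PILEUP_ALLELES
  m
}

#' Sequence variant frequency of an allele
#'
#' Read depth of the allele (or deletion) relative to the total read depth
#' at the position: A at 10 reads over G at 90 reads gives 10/100 = 10%.
#'
#' @param pc A `position_counts`.
#' @param allele One of `"A"`, `"C"`, `"G"`, `"T"`, `"del"`.
#' @return Fraction in `[0, 1]`; `NA` (with a warning) when the position
#'   has no reads — an undefined frequency is never reported as 0.
#' @export
variant_frequency <- function(pc, allele) {
  stopifnot(inherits(pc, "position_counts"), allele %in% PILEUP_ALLELES)
  depth <- total_depth(pc)
  if (depth == 0L) {
    warning("total depth is 0 at position ", pc$position,
            "; variant frequency undefined")
    return(NA_real_)
  }
  sum(pc$counts[allele, ]) / depth
}

#' Insertion frequency at a position
#'
#' Total insertion-carrying reads (all inserted sequences pooled) relative
#' to the total read depth at the anchor position.
#'
#' @param pc A `position_counts`.
#' @return Fraction in `[0, 1]`; `NA` with a warning at zero depth.
#' @export
insertion_frequency <- function(pc) {
  stopifnot(inherits(pc, "position_counts"))
  depth <- total_depth(pc)
  if (depth == 0L) {
    warning("total depth is 0 at position ", pc$position,
            "; insertion frequency undefined")
    return(NA_real_)
  }
  sum(pc$insertions$fwd + pc$insertions$rev) / depth
}

#' Dominant inserted sequence
#'
#' Among insertion-carrying reads at the anchor, the inserted sequence with
#' the most reads; its fraction is taken over insertion reads only (not
#' over total depth). Ties are broken toward the lexicographically smaller
#' sequence and flagged, never resolved silently.
#'
#' @param pc A `position_counts` with at least one insertion read.
#' @return List with `seq`, `fraction` (share of all insertion reads) and
#'   logical `tie`.
#' @export
dominant_insertion <- function(pc) {
  stopifnot(inherits(pc, "position_counts"))
  ins <- pc$insertions
  reads <- ins$fwd + ins$rev
  if (nrow(ins) == 0L || sum(reads) == 0L) {
    stop("no insertion reads at position ", pc$position)
  }
  top <- max(reads)
  winners <- sort(ins$seq[reads == top])
  list(seq = winners[1L], fraction = top / sum(reads),
       tie = length(winners) > 1L)
}

#' Strand bias of an allele
#'
#' `1 - (reads in the minor direction / reads in the major direction)`:
#' 0 means perfectly balanced strands, 1 means all reads in one direction.
#' Computed by default from the reads supporting the given allele; set
#' `mode = "position"` to use all reads at the position regardless of
#' allele.
#'
#' @param pc A `position_counts`.
#' @param allele Allele whose supporting reads are used (ignored for
#'   `mode = "position"`).
#' @param mode `"allele"` (default) or `"position"`.
#' @return Value in `[0, 1]`.
#' @export
strand_bias <- function(pc, allele = NULL, mode = c("allele", "position")) {
  stopifnot(inherits(pc, "position_counts"))
  mode <- match.arg(mode)
  if (mode == "allele") {
    stopifnot(!is.null(allele), allele %in% PILEUP_ALLELES)
    fwd <- pc$counts[allele, "fwd"]
    rev <- pc$counts[allele, "rev"]
  } else {
    fwd <- sum(pc$counts[, "fwd"])
    rev <- sum(pc$counts[, "rev"])
  }
  if (fwd + rev == 0L) {
    stop("no reads", if (mode == "allele") paste0(" for allele ", allele),
         " at position ", pc$position)
  }
  1 - min(fwd, rev) / max(fwd, rev)
}

# strand bias of pooled insertion reads at the anchor
insertion_strand_bias <- function(pc) {
  fwd <- sum(pc$insertions$fwd)
  rev <- sum(pc$insertions$rev)
  if (fwd + rev == 0L) stop("no insertion reads at position ", pc$position)
  1 - min(fwd, rev) / max(fwd, rev)
}
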