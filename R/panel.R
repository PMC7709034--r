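#' Amplicon panels on the circular mtGenome
#'
#' A panel is an ordered table of tiled, overlapping amplicons covering the
#' mitochondrial circle, split across two PCR primer pools. Amplicon spans
#' are 1-based inclusive; `end < start` means the amplicon wraps across the
#' origin. Summary geometry (mean length, mean adjacent overlap) is always
#' recomputed from the amplicon table, never trusted from input.
#'
#' @param amplicons data.frame with columns `id`, `pool`, `start`, `end`.
#' @param L Circle length the spans live on.
#' @return An object of class `mt_panel`: the amplicon table (with a
#'   recomputed `length` column), `mean_length`, `mean_overlap`, `L`.
#' @export
mt_panel <- function(amplicons, L) {
  stopifnot(is.data.frame(amplicons),
            all(c("id", "pool", "start", "end") %in% names(amplicons)))
  a <- amplicons[, c("id", "pool", "start", "end")]
  a$id <- as.character(a$id)
  a$start <- as.integer(a$start)
  a$end <- as.integer(a$end)
  if (anyDuplicated(a$id)) {
    stop("duplicate amplicon ids: ",
         paste(unique(a$id[duplicated(a$id)]), collapse = ", "))
  }
  if (any(a$start < 1L | a$start > L | a$end < 1L | a$end > L)) {
    stop("amplicon coordinates out of range 1..", L)
  }
  a$length <- ifelse(a$end >= a$start,
                     a$end - a$start + 1L,
                     L - a$start + 1L + a$end)
  a <- a[order(a$start), , drop = FALSE]
  rownames(a) <- NULL

  uncovered <- setdiff(seq_len(L), unlist(lapply(seq_len(nrow(a)), function(i)
    amplicon_positions(a$start[i], a$end[i], L))))
  if (length(uncovered) > 0L) {
    warning(length(uncovered), " positions not covered by any amplicon ",
            "(first: ", paste(utils::head(uncovered, 5L), collapse = ", "), ")")
  }

  structure(
    list(
      amplicons = a,
      mean_length = mean(a$length),
      mean_overlap = mean(adjacent_overlaps(a, L)),
      L = L
    ),
    class = "mt_panel"
  )
}

# 1-based positions of a circular span (end < start wraps across the origin)
amplicon_positions <- function(start, end, L) {
  if (end >= start) start:end else c(start:L, 1:end)
}

# Overlap (shared bases) at each junction between circularly adjacent
# amplicons, taken in start order; the last junction wraps to the first
# amplicon one turn later. A junction with a gap contributes 0.
adjacent_overlaps <- function(a, L) {
  n <- nrow(a)
  start_lin <- a$start
  end_lin <- ifelse(a$end >= a$start, a$end, a$end + L)
  nxt_start <- c(start_lin[-1L], start_lin[1L] + L)
  pmax(0L, pmin(end_lin - nxt_start + 1L, c(a$length[-1L], a$length[1L])))
}

#' @export
print.mt_panel <- function(x, ...) {
  cat("<mt_panel> ", nrow(x$amplicons), " amplicons on a ", x$L,
      " nt circle; mean length ", round(x$mean_length, 1),
      " bp, mean overlap ", round(x$mean_overlap, 1), " bp\n", sep = "")
  invisible(x)
}

#' Read an amplicon panel from a BED-like file
#'
#' Columns: chrom, start (0-based half-open), end, name (amplicon id),
#' score (unused), strand (unused), pool. Converted internally to 1-based
#' inclusive circular coordinates; an `end` beyond the circle length wraps.
#'
#' @param bed_path Path to the tab-separated panel file (no header).
#' @param L Circle length (default rCRS 16,569).
#' @return An `mt_panel`.
#' @export
load_panel <- function(bed_path, L = 16569L) {
  tab <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 7L) {
    stop("panel BED needs 7 columns (chrom, start, end, name, score, ",
         "strand, pool); found ", ncol(tab))
  }
  start1 <- as.integer(tab[[2]]) + 1L
  end1 <- as.integer(tab[[3]])
  wraps <- end1 > L
  end1[wraps] <- end1[wraps] - L
  mt_panel(data.frame(id = tab[[4]], pool = as.integer(tab[[7]]),
                      start = start1, end = end1,
                      stringsAsFactors = FALSE), L = L)
}

#' Write an amplicon panel to a BED-like file
#'
#' Inverse of [load_panel()]: 1-based inclusive spans become 0-based
#' half-open; wrapped spans are written with `end` beyond the circle length.
#'
#' @param panel An `mt_panel`.
#' @param bed_path Output path.
#' @export
write_panel <- function(panel, bed_path) {
  stopifnot(inherits(panel, "mt_panel"))
  a <- panel$amplicons
  end_lin <- ifelse(a$end >= a$start, a$end, a$end + panel$L)
  utils::write.table(
    data.frame("chrM", a$start - 1L, end_lin, a$id, 0L, "+", a$pool),
    bed_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(bed_path)
}
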