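#' Median read depth over an amplicon span
#'
#' Median of total depth over all positions in the (possibly
#' origin-wrapping) amplicon span; an even-length span uses the mean of the
#' two middle values.
#'
#' @param p An `mt_pileup`.
#' @param start,end 1-based inclusive circular span (end < start wraps).
#' @return Median depth (numeric).
#' @export
amplicon_median_depth <- function(p, start, end) {
  stopifnot(inherits(p, "mt_pileup"))
  pos <- amplicon_positions(as.integer(start), as.integer(end), p$L)
  if (length(pos) == 0L) stop("empty amplicon span")
  stats::median(depth_vector(p)[pos])
}

#' Per-amplicon balance
#'
#' Each amplicon's median read depth divided by the median of all
#' amplicons' median depths for the sample (100X over an overall 150X gives
#' 0.67); 1.0 indicates balanced amplicons.
#'
#' @param p An `mt_pileup`.
#' @param panel An `mt_panel`.
#' @return data.frame with `amplicon_id`, `pool`, `median_depth`,
#'   `balance`.
#' @export
amplicon_balance <- function(p, panel) {
  stopifnot(inherits(p, "mt_pileup"), inherits(panel, "mt_panel"))
  a <- panel$amplicons
  med <- vapply(seq_len(nrow(a)), function(i)
    amplicon_median_depth(p, a$start[i], a$end[i]), numeric(1))
  overall <- stats::median(med)
  if (overall == 0) stop("all amplicon median depths are zero")
  data.frame(amplicon_id = a$id, pool = a$pool, median_depth = med,
             balance = med / overall, stringsAsFactors = FALSE)
}

#' Coverage breadth at a depth threshold
#'
#' Fraction of the circle's positions whose total depth meets the minimum;
#' the denominator is always the full genome length.
#'
#' @param p An `mt_pileup`.
#' @param min_depth Depth threshold (default 20).
#' @return Fraction in `[0, 1]`.
#' @export
coverage_breadth <- function(p, min_depth = 20L) {
  stopifnot(inherits(p, "mt_pileup"))
  sum(depth_vector(p) >= min_depth) / p$L
}

#' Relative read depth of a negative control
#'
#' Per-position depth of the negative control as a percentage of a paired
#' positive control from the same run (50X over 2000X gives 2.5%).
#' Positions where the positive has no reads are undefined (`NA`), never 0
#' or infinite.
#'
#' @param neg,pos `mt_pileup`s on the same reference axis.
#' @return Numeric vector of length L (percent; `NA` where undefined).
#' @export
relative_read_depth <- function(neg, pos) {
  stopifnot(inherits(neg, "mt_pileup"), inherits(pos, "mt_pileup"),
            neg$L == pos$L)
  dn <- depth_vector(neg)
  dp <- depth_vector(pos)
  out <- rep(NA_real_, neg$L)
  ok <- dp > 0L
  out[ok] <- 100 * dn[ok] / dp[ok]
  out
}

#' Per-sample QC report
#'
#' @param p An `mt_pileup`.
#' @param panel An `mt_panel`.
#' @param th A `calling_thresholds` (supplies the depth minimum).
#' @return A list with `sample_id`, `per_amplicon` (see
#'   [amplicon_balance()]), `breadth_at_min_depth`, `mean_depth`.
#' @export
qc_report <- function(p, panel, th = calling_thresholds()) {
  list(sample_id = p$sample_id,
       per_amplicon = amplicon_balance(p, panel),
       breadth_at_min_depth = coverage_breadth(p, th$min_depth),
       mean_depth = mean(depth_vector(p)))
}

#' Contamination assessment over negative controls
#'
#' For each position, the mean (and SD, when more than one negative) of
#' the relative read depth across negatives versus the paired positive;
#' the fraction of assessable positions whose mean stays below the bound;
#' and the spans that exceed it, annotated with overlapping amplicons when
#' a panel is supplied.
#'
#' @param negatives List of `mt_pileup`s (negative controls).
#' @param pos Positive-control `mt_pileup` from the same run.
#' @param bound Relative-depth bound in percent (default 10).
#' @param panel Optional `mt_panel` for annotating flagged spans.
#' @return List with `profile` (data.frame `position`, `mean_rel`,
#'   `sd_rel`), `frac_below_bound`, `flagged` (data.frame `start`, `end`,
#'   `amplicons`).
#' @export
contamination_summary <- function(negatives, pos, bound = 10,
                                  panel = NULL) {
  stopifnot(length(negatives) >= 1L)
  rel <- vapply(negatives, relative_read_depth, numeric(pos$L), pos = pos)
  rel <- matrix(rel, nrow = pos$L)
  mean_rel <- rowMeans(rel)
  sd_rel <- if (ncol(rel) > 1L) apply(rel, 1L, stats::sd) else
    rep(0, pos$L)
  defined <- !is.na(mean_rel)
  frac_below <- sum(mean_rel[defined] < bound) / sum(defined)

  over <- which(defined & mean_rel >= bound)
  flagged <- data.frame(start = integer(), end = integer(),
                        amplicons = character(), stringsAsFactors = FALSE)
  if (length(over)) {
    brk <- c(0L, which(diff(over) > 1L), length(over))
    for (i in seq_len(length(brk) - 1L)) {
      a <- over[brk[i] + 1L]; b <- over[brk[i + 1L]]
      amps <- ""
      if (!is.null(panel)) {
        hit <- vapply(seq_len(nrow(panel$amplicons)), function(j) {
          span <- amplicon_positions(panel$amplicons$start[j],
                                     panel$amplicons$end[j], panel$L)
          any(span >= a & span <= b)
        }, logical(1))
        amps <- paste(panel$amplicons$id[hit], collapse = ",")
      }
      flagged <- rbind(flagged,
                       data.frame(start = a, end = b, amplicons = amps,
                                  stringsAsFactors = FALSE))
    }
  }
  list(profile = data.frame(position = seq_len(pos$L),
                            mean_rel = mean_rel, sd_rel = sd_rel),
       frac_below_bound = frac_below, flagged = flagged)
}
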