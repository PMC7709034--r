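#' Compare two haplotypes and classify every discordance
#'
#' Calls at positions masked (below minimum depth) in either haplotype are
#' excluded from comparison. Concordant calls produce no record. Each
#' discordance receives exactly one category, applied in order:
#'
#' 1. `suspect_deletion` — a deletion on the suspect list (e.g. `309del`);
#' 2. `dominant_variant_differs` — both sources call an insertion at the
#'    same position but the dominant inserted run differs;
#' 3. `homopolymer_indel` — an indel inside or abutting a reference
#'    homopolymer tract of at least `homopolymer_min` bases;
#' 4. `threshold_miss` — the variant allele is present in the partner's
#'    pileup but below its calling threshold (requires the pileup);
#' 5. `php_only_one_source` — a point heteroplasmy seen in one source only;
#' 6. `other`.
#'
#' @param a,b `mt_haplotype`s.
#' @param ref Optional `mt_reference` (needed for the homopolymer rule).
#' @param pileup_a,pileup_b Optional `mt_pileup`s backing each haplotype
#'   (enable the `threshold_miss` rule).
#' @param th A `calling_thresholds`.
#' @param suspect_list Suspect-deletion names.
#' @param homopolymer_min Minimum tract length for the homopolymer rule.
#' @param labels Length-2 labels for the two sources.
#' @return data.frame with `variant`, `present_in`, `category`, `note`.
#' @export
compare_haplotypes <- function(a, b, ref = NULL,
                               pileup_a = NULL, pileup_b = NULL,
                               th = calling_thresholds(),
                               suspect_list = default_suspect_deletions(),
                               homopolymer_min = 4L,
                               labels = c("a", "b")) {
  stopifnot(inherits(a, "mt_haplotype"), inherits(b, "mt_haplotype"))
  excluded <- union(a$coverage_mask, b$coverage_mask)
  ca <- a$calls[!(a$calls$position %in% excluded) &
                  a$calls$status != "suppressed_suspect", , drop = FALSE]
  cb <- b$calls[!(b$calls$position %in% excluded) &
                  b$calls$status != "suppressed_suspect", , drop = FALSE]

  records <- data.frame(variant = character(), present_in = character(),
                        category = character(), note = character(),
                        stringsAsFactors = FALSE)
  add <- function(variant, present_in, category, note = "") {
    rbind(records, data.frame(variant = variant, present_in = present_in,
                              category = category, note = note,
                              stringsAsFactors = FALSE))
  }

  # insertion anchors called by both but with a different dominant run
  ins_a <- unique(ca$position[ca$kind == "insertion"])
  ins_b <- unique(cb$position[cb$kind == "insertion"])
  dom_differs <- integer(0)
  for (pos in intersect(ins_a, ins_b)) {
    run_a <- paste(ca$allele[ca$kind == "insertion" & ca$position == pos],
                   collapse = "")
    run_b <- paste(cb$allele[cb$kind == "insertion" & cb$position == pos],
                   collapse = "")
    if (run_a != run_b) {
      dom_differs <- c(dom_differs, pos)
      records <- add(paste0(pos, ".ins"), paste(labels, collapse = "+"),
                     "dominant_variant_differs",
                     paste0(labels[1], ": ", run_a, "; ",
                            labels[2], ": ", run_b))
    }
  }

  classify_one_sided <- function(call, partner_pileup, label) {
    if (call$kind == "deletion" && call$rendered %in% suspect_list) {
      return(c("suspect_deletion", ""))
    }
    if (call$kind %in% c("insertion", "deletion") && !is.null(ref) &&
        in_homopolymer(ref, call$position, homopolymer_min)) {
      return(c("homopolymer_indel", ""))
    }
    if (!is.null(partner_pileup)) {
      pc <- position_counts(partner_pileup, call$position)
      present <- switch(call$kind,
        substitution = ,
        heteroplasmy = {
          al <- if (call$kind == "substitution") call$allele else call$a2
          d <- total_depth(pc)
          d > 0L && sum(pc$counts[al, ]) > 0L
        },
        insertion = nrow(pc$insertions) > 0L &&
          sum(pc$insertions$fwd + pc$insertions$rev) > 0L,
        deletion = sum(pc$counts["del", ]) > 0L,
        FALSE)
      if (present) {
        return(c("threshold_miss",
                 paste0("present below threshold in ", label)))
      }
    }
    if (call$kind == "heteroplasmy") return(c("php_only_one_source", ""))
    c("other", "")
  }

  only_a <- ca[!(ca$rendered %in% cb$rendered) &
                 !(ca$position %in% dom_differs & ca$kind == "insertion"), ,
               drop = FALSE]
  only_b <- cb[!(cb$rendered %in% ca$rendered) &
                 !(cb$position %in% dom_differs & cb$kind == "insertion"), ,
               drop = FALSE]
  for (i in seq_len(nrow(only_a))) {
    cat_note <- classify_one_sided(only_a[i, ], pileup_b, labels[2])
    records <- add(only_a$rendered[i], labels[1], cat_note[1], cat_note[2])
  }
  for (i in seq_len(nrow(only_b))) {
    cat_note <- classify_one_sided(only_b[i, ], pileup_a, labels[1])
    records <- add(only_b$rendered[i], labels[2], cat_note[1], cat_note[2])
  }
  rownames(records) <- NULL
  records
}

#' Maximum pairwise difference in variant frequency
#'
#' Across replicate measurements of one variant's frequency, the largest
#' absolute difference between any two replicates, in percentage points;
#' equal to `100 * (max - min)`.
#'
#' @param freqs Numeric vector of per-replicate frequencies (fractions),
#'   length at least 2.
#' @return Percentage points.
#' @export
max_pairwise_difference <- function(freqs) {
  freqs <- freqs[!is.na(freqs)]
  if (length(freqs) < 2L) {
    stop("need at least 2 replicate frequencies, got ", length(freqs))
  }
  100 * (max(freqs) - min(freqs))
}

#' Bundle replicates of one sample
#'
#' @param sample_id Sample label.
#' @param replicates Named list; each element a list with `haplotype`
#'   (`mt_haplotype`) and optionally `pileup` (`mt_pileup`).
#' @return A `replicate_set`.
#' @export
replicate_set <- function(sample_id, replicates) {
  stopifnot(length(replicates) >= 2L)
  if (is.null(names(replicates))) {
    names(replicates) <- paste0("rep", seq_along(replicates))
  }
  structure(list(sample_id = sample_id, replicates = replicates),
            class = "replicate_set")
}

variant_type <- function(kind) {
  ifelse(kind == "substitution", "substitution",
         ifelse(kind == "heteroplasmy", "PHP",
                ifelse(kind %in% c("insertion", "deletion"), "indel",
                       "other")))
}

# frequency of a previously named variant looked up directly in a pileup
lookup_variant_frequency <- function(p, v, dominant = FALSE) {
  pc <- position_counts(p, v$position)
  d <- total_depth(pc)
  if (d == 0L) return(NA_real_)
  switch(v$kind,
    substitution = sum(pc$counts[v$allele, ]) / d,
    heteroplasmy = {
      al <- iupac_alleles(v$allele)
      f <- (sum(pc$counts[al[1], ]) + 0) / d
      g <- sum(pc$counts[al[2], ]) / d
      min(f, g)  # the heteroplasmy is tracked by its minor component
    },
    deletion = sum(pc$counts["del", ]) / d,
    insertion = {
      ins_reads <- sum(pc$insertions$fwd + pc$insertions$rev)
      if (ins_reads == 0L) return(0)
      if (dominant) {
        dom <- dominant_insertion(pc)
        dom$fraction
      } else {
        ins_reads / d
      }
    },
    NA_real_)
}

#' Replicate reproducibility summary
#'
#' For every variant called in at least one replicate (suppressed suspect
#' deletions excluded), the variant's frequency is measured in every
#' replicate's pileup and summarised as the maximum pairwise difference,
#' grouped by variant type (substitution / PHP / indel). For indels the
#' dominant-variant fraction is summarised as well. Replicates where a
#' variant is present in the reads but below its calling threshold are
#' counted as sub-threshold.
#'
#' @param rs A `replicate_set` whose elements carry pileups.
#' @param th A `calling_thresholds`.
#' @return data.frame with one row per variant: `variant`, `type`,
#'   `n_called`, `n_subthreshold`, `max_pairwise_diff` (percentage points),
#'   `max_pairwise_diff_dominant` (indels; `NA` otherwise).
#' @export
replicate_summary <- function(rs, th = calling_thresholds()) {
  stopifnot(inherits(rs, "replicate_set"))
  reps <- rs$replicates
  all_calls <- lapply(reps, function(r) {
    cc <- r$haplotype$calls
    cc[cc$status != "suppressed_suspect", , drop = FALSE]
  })
  variants <- unique(unlist(lapply(all_calls, `[[`, "rendered")))
  if (length(variants) == 0L) {
    return(data.frame(variant = character(), type = character(),
                      n_called = integer(), n_subthreshold = integer(),
                      max_pairwise_diff = numeric(),
                      max_pairwise_diff_dominant = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(variants, function(rv) {
    v <- parse_variant(rv)
    called <- vapply(all_calls, function(cc) rv %in% cc$rendered, logical(1))
    freqs <- vapply(reps, function(r) {
      if (is.null(r$pileup)) return(NA_real_)
      lookup_variant_frequency(r$pileup, v)
    }, numeric(1))
    thr <- switch(v$kind, heteroplasmy = th$php_min,
                  insertion = th$ins_min, deletion = th$del_min,
                  substitution = 1 - th$php_min, 0)
    sub <- !called & !is.na(freqs) & freqs > 0 & freqs < thr
    domdiff <- NA_real_
    if (v$kind %in% c("insertion", "deletion")) {
      domf <- vapply(reps, function(r) {
        if (is.null(r$pileup)) return(NA_real_)
        lookup_variant_frequency(r$pileup, v, dominant = TRUE)
      }, numeric(1))
      if (sum(!is.na(domf)) >= 2L) {
        domdiff <- max_pairwise_difference(domf)
      }
    }
    data.frame(variant = rv, type = variant_type(v$kind),
               n_called = sum(called), n_subthreshold = sum(sub),
               max_pairwise_diff = if (sum(!is.na(freqs)) >= 2L)
                 max_pairwise_difference(freqs) else NA_real_,
               max_pairwise_diff_dominant = domdiff,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
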