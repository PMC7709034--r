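#' Calling thresholds
#'
#' The frequency and depth parameters of threshold-based haplotype calling:
#' 10% for point heteroplasmies, 30% for insertions, 40% for deletions, a
#' 20X minimum read depth for any call, a strand-bias bound above which
#' calls are flagged for analyst review rather than suppressed, and the
#' minimum number of mixed variant sites that indicates a mixture. All
#' frequency thresholds are inclusive: a variant exactly at the threshold
#' is called.
#'
#' @param php_min Point-heteroplasmy frequency threshold (fraction).
#' @param ins_min Insertion frequency threshold (fraction of total depth
#'   carried by insertion reads).
#' @param del_min Deletion frequency threshold (fraction).
#' @param min_depth Minimum total read depth for calling.
#' @param strand_bias_review Strand-bias value above which a call is
#'   flagged for review.
#' @param mv_min_count Minimum number of mixed variant sites flagging a
#'   mixture (3 allows for personal point heteroplasmies).
#' @return A `calling_thresholds` list.
#' @export
calling_thresholds <- function(php_min = 0.10, ins_min = 0.30,
                               del_min = 0.40, min_depth = 20L,
                               strand_bias_review = 0.89,
                               mv_min_count = 3L) {
  stopifnot(php_min > 0, php_min <= ins_min, ins_min <= del_min,
            del_min <= 1, min_depth >= 1,
            strand_bias_review >= 0, strand_bias_review <= 1,
            mv_min_count >= 1)
  structure(list(php_min = php_min, ins_min = ins_min, del_min = del_min,
                 min_depth = as.integer(min_depth),
                 strand_bias_review = strand_bias_review,
                 mv_min_count = as.integer(mv_min_count)),
            class = "calling_thresholds")
}

empty_calls <- function() {
  data.frame(position = integer(), kind = character(),
             allele = character(), insert_index = integer(),
             rendered = character(), frequency = numeric(),
             depth = integer(), strand_bias = numeric(),
             dominant_fraction = numeric(), status = character(),
             a1 = character(), a2 = character(), evidence = character(),
             stringsAsFactors = FALSE)
}

call_row <- function(position, kind, allele, insert_index, frequency,
                     depth, sb, dominant_fraction, th, evidence = "") {
  v <- variant_name(position, kind, allele = allele,
                    insert_index = insert_index)
  status <- if (!is.na(sb) && sb > th$strand_bias_review) "review" else
    "confirmed"
  data.frame(position = v$position, kind = kind,
             allele = if (is.na(v$allele)) NA_character_ else v$allele,
             insert_index = v$insert_index, rendered = v$rendered,
             frequency = frequency, depth = as.integer(depth),
             strand_bias = sb, dominant_fraction = dominant_fraction,
             status = status, a1 = NA_character_, a2 = NA_character_,
             evidence = evidence, stringsAsFactors = FALSE)
}

#' Threshold-based variant calling at a single position
#'
#' Applies the inclusive frequency thresholds to the stranded counts at one
#' position. A non-reference base at a frequency of at least `php_min` but
#' below `1 - php_min` is a point heteroplasmy (two-base IUPAC code);
#' at `1 - php_min` or above it is a substitution. Deletion-supporting
#' reads at `del_min` or more of total depth give a deletion; pooled
#' insertion reads at `ins_min` or more give an insertion named by the
#' dominant inserted sequence, expanded to one call per inserted base
#' (`pos.1C`, `pos.2C`, ...). Calls whose supporting reads exceed the
#' strand-bias review bound are flagged `status = "review"`, never dropped.
#' Positions below `min_depth` yield no calls.
#'
#' @param pc A `position_counts`.
#' @param ref_base Reference base at the position.
#' @param th A `calling_thresholds`.
#' @return data.frame of calls (possibly zero rows).
#' @export
call_position <- function(pc, ref_base, th = calling_thresholds()) {
  stopifnot(inherits(pc, "position_counts"))
  ref_base <- toupper(ref_base)
  depth <- total_depth(pc)
  calls <- empty_calls()
  if (depth < th$min_depth) return(calls)

  base_reads <- rowSums(pc$counts[c("A", "C", "G", "T"), , drop = FALSE])
  freq <- base_reads / depth

  nonref <- setdiff(names(freq), ref_base)
  top_nonref <- nonref[which.max(freq[nonref])]
  if (freq[top_nonref] >= 1 - th$php_min) {
    row <- call_row(pc$position, "substitution", top_nonref, NULL,
                    freq[[top_nonref]], depth,
                    strand_bias(pc, top_nonref), NA_real_, th)
    row$a1 <- top_nonref
    calls <- rbind(calls, row)
  } else if (freq[top_nonref] >= th$php_min) {
    top2 <- names(sort(freq, decreasing = TRUE))[1:2]
    minor <- top2[2L]
    note <- if (sum(freq >= th$php_min) > 2L) "multi-allele site" else ""
    row <- call_row(pc$position, "heteroplasmy",
                    iupac_code(top2[1L], top2[2L]), NULL,
                    freq[[minor]], depth, strand_bias(pc, minor),
                    NA_real_, th, evidence = note)
    row$a1 <- top2[1L]
    row$a2 <- minor
    calls <- rbind(calls, row)
  }

  del_freq <- sum(pc$counts["del", ]) / depth
  if (del_freq >= th$del_min) {
    calls <- rbind(calls, call_row(pc$position, "deletion", NULL, NULL,
                                   del_freq, depth, strand_bias(pc, "del"),
                                   NA_real_, th))
  }

  ins_reads <- sum(pc$insertions$fwd + pc$insertions$rev)
  if (ins_reads > 0L && ins_reads / depth >= th$ins_min) {
    dom <- dominant_insertion(pc)
    sb <- insertion_strand_bias(pc)
    note <- if (dom$tie) "dominant-insertion tie" else ""
    bases <- strsplit(dom$seq, "")[[1]]
    for (k in seq_along(bases)) {
      calls <- rbind(calls, call_row(pc$position, "insertion", bases[k], k,
                                     ins_reads / depth, depth, sb,
                                     dom$fraction, th, evidence = note))
    }
  }
  rownames(calls) <- NULL
  calls
}

#' Assemble a difference-coded haplotype from a pileup
#'
#' Scans every position: positions below the minimum read depth go into the
#' coverage mask and are excluded from interpretation; the rest are called
#' with [call_position()]. Deletions inside homopolymer tracts are
#' right-aligned (3'-most tract position), matching forensic nomenclature.
#'
#' @param p An `mt_pileup`.
#' @param ref An `mt_reference` of matching length.
#' @param panel Optional `mt_panel`, carried for report annotation.
#' @param th A `calling_thresholds`.
#' @return An `mt_haplotype`: `calls` (data.frame sorted by position),
#'   `coverage_mask` (integer positions below `min_depth`), `sample_id`.
#' @export
assemble_haplotype <- function(p, ref, panel = NULL,
                               th = calling_thresholds()) {
  stopifnot(inherits(p, "mt_pileup"), inherits(ref, "mt_reference"),
            p$L == ref$L)
  depth <- depth_vector(p)
  mask <- which(depth < th$min_depth)

  acm <- allele_count_matrix(p)
  freq <- acm / pmax(depth, 1L)
  refvec <- strsplit(ref$sequence, "")[[1]]
  base_cols <- c("A", "C", "G", "T")
  fb <- freq[, base_cols, drop = FALSE]
  ref_idx <- match(refvec, base_cols)
  known <- !is.na(ref_idx)
  fb[cbind(which(known), ref_idx[known])] <- -Inf
  max_nonref <- do.call(pmax, as.data.frame(fb))

  ins_depth <- numeric(p$L)
  if (nrow(p$insertions)) {
    agg <- tapply(p$insertions$fwd + p$insertions$rev,
                  p$insertions$position, sum)
    ins_depth[as.integer(names(agg))] <- agg
  }

  interesting <- which(depth >= th$min_depth &
                         (max_nonref >= th$php_min |
                            freq[, "del"] >= th$del_min |
                            ins_depth / pmax(depth, 1L) >= th$ins_min))

  call_list <- lapply(interesting, function(pos) {
    calls <- call_position(position_counts(p, pos), refvec[pos], th)
    if (nrow(calls)) {
      dels <- calls$kind == "deletion"
      if (any(dels)) {
        ra <- right_align_deletion(ref, pos)
        calls$position[dels] <- ra
        calls$rendered[dels] <- paste0(ra, "del")
      }
    }
    calls
  })
  calls <- do.call(rbind, c(list(empty_calls()), call_list))
  calls <- calls[!duplicated(calls$rendered), , drop = FALSE]
  calls <- calls[!(calls$position %in% mask), , drop = FALSE]
  calls <- calls[order(calls$position,
                       ifelse(is.na(calls$insert_index), 0L,
                              calls$insert_index)), , drop = FALSE]
  rownames(calls) <- NULL
  structure(list(sample_id = p$sample_id, calls = calls,
                 coverage_mask = as.integer(mask), L = p$L),
            class = "mt_haplotype")
}

#' @export
print.mt_haplotype <- function(x, ...) {
  cat("<mt_haplotype> ", x$sample_id, ": ", nrow(x$calls), " calls, ",
      length(x$coverage_mask), " masked positions\n", sep = "")
  if (nrow(x$calls)) cat(" ", paste(x$calls$rendered, collapse = " "), "\n")
  invisible(x)
}

# 3'-most position of the homopolymer run of the base at `pos`
right_align_deletion <- function(ref, pos) {
  b <- ref_base(ref, pos)
  end <- pos
  while (end < ref$L && ref_base(ref, end + 1L) == b) end <- end + 1L
  end
}

# maximal identical-base run containing `pos`; list(start, end, base, len)
homopolymer_tract <- function(ref, pos) {
  b <- ref_base(ref, pos)
  start <- pos
  while (start > 1L && ref_base(ref, start - 1L) == b) start <- start - 1L
  end <- pos
  while (end < ref$L && ref_base(ref, end + 1L) == b) end <- end + 1L
  list(start = start, end = end, base = b, len = end - start + 1L)
}

# does a tract of >= min_len identical bases contain or abut the position?
in_homopolymer <- function(ref, pos, min_len = 4L) {
  cand <- unique(pmin(pmax(c(pos - 1L, pos, pos + 1L), 1L), ref$L))
  any(vapply(cand, function(q) homopolymer_tract(ref, q)$len,
             integer(1)) >= min_len)
}

#' Default suspect-deletion list
#'
#' Deletions at the 3' ends of the long HVI/HVII C-stretches that recur as
#' false calls above the 40% threshold and are resolved by external
#' concordance rather than a computable rule.
#' @return Character vector of variant names.
#' @export
default_suspect_deletions <- function() c("309del", "315del", "16193del")

#' Suppress suspect deletions from a haplotype
#'
#' Deletion calls whose rendered name is on the suspect list get
#' `status = "suppressed_suspect"`: they are excluded from exported
#' haplotypes but retained in the call table as an audit record.
#'
#' @param h An `mt_haplotype`.
#' @param suspect_list Character vector of deletion names.
#' @return The modified haplotype.
#' @export
apply_suspect_deletions <- function(h,
                                    suspect_list = default_suspect_deletions()) {
  stopifnot(inherits(h, "mt_haplotype"))
  hit <- h$calls$kind == "deletion" & h$calls$rendered %in% suspect_list
  h$calls$status[hit] <- "suppressed_suspect"
  h$calls$evidence[hit] <- paste0(h$calls$evidence[hit],
                                  "; suspect deletion (external concordance)")
  h
}

#' Flag NUMT-associated variants as N-calls
#'
#' A point heteroplasmy whose minor allele matches a catalogued
#' nuclear-insert allele at that position cannot be distinguished from
#' co-amplified NUMT reads; it is re-labelled `uncalled_N` and exported as
#' `posN`. Substitutions (catalog allele at 90% or more, i.e. the true
#' sample allele) are never flagged.
#'
#' @param h An `mt_haplotype`.
#' @param numt_catalog data.frame with columns `position`, `allele`.
#' @return The modified haplotype.
#' @export
flag_nav <- function(h, numt_catalog) {
  stopifnot(inherits(h, "mt_haplotype"))
  if (is.null(numt_catalog) || nrow(numt_catalog) == 0L) return(h)
  for (i in seq_len(nrow(h$calls))) {
    if (h$calls$kind[i] != "heteroplasmy") next
    hit <- numt_catalog$position == h$calls$position[i] &
      toupper(numt_catalog$allele) == h$calls$a2[i]
    if (any(hit)) {
      old <- h$calls$rendered[i]
      h$calls$kind[i] <- "uncalled_N"
      h$calls$rendered[i] <- paste0(h$calls$position[i], "N")
      h$calls$allele[i] <- NA_character_
      h$calls$status[i] <- "uncalled_N"
      h$calls$evidence[i] <- paste0(h$calls$evidence[i], "; possible NAV (",
                                    old, " matches NUMT catalog)")
    }
  }
  h
}

#' Count catalogued NUMT alleles reaching the heteroplasmy threshold
#'
#' For each catalog entry, the catalogued allele's variant frequency is
#' checked against `php_min` at positions meeting the depth minimum; the
#' count of positions reaching it is the NUMT-associated-variant (NAV)
#' count, which rises as mtDNA input falls.
#'
#' @param p An `mt_pileup`.
#' @param numt_catalog data.frame with columns `position`, `allele`.
#' @param th A `calling_thresholds`.
#' @return Integer count.
#' @export
count_navs <- function(p, numt_catalog, th = calling_thresholds()) {
  stopifnot(inherits(p, "mt_pileup"))
  if (is.null(numt_catalog) || nrow(numt_catalog) == 0L) return(0L)
  depth <- depth_vector(p)
  acm <- allele_count_matrix(p)
  pos <- as.integer(numt_catalog$position)
  al <- toupper(numt_catalog$allele)
  reads <- acm[cbind(pos, match(al, colnames(acm)))]
  sum(depth[pos] >= th$min_depth & reads / depth[pos] >= th$php_min)
}

# collapse sorted integer positions into "a-b" range text
position_ranges <- function(pos) {
  if (length(pos) == 0L) return("")
  pos <- sort(unique(as.integer(pos)))
  brk <- c(0L, which(diff(pos) > 1L), length(pos))
  paste(vapply(seq_len(length(brk) - 1L), function(i) {
    a <- pos[brk[i] + 1L]; b <- pos[brk[i + 1L]]
    if (a == b) as.character(a) else paste0(a, "-", b)
  }, character(1)), collapse = ", ")
}

#' Export a haplotype as difference-coded text
#'
#' Confirmed calls (and N-calls) joined by spaces in the field's standard
#' style, e.g. `"263G 309.1C 315.1C"`. Suppressed suspect deletions are
#' omitted; strand-bias review calls are omitted unless
#' `include_review = TRUE` (they await analyst confirmation). Regions below
#' the minimum read depth are annotated on a comment line.
#'
#' @param h An `mt_haplotype`.
#' @param include_review Include calls flagged for strand-bias review.
#' @return A single text string (variant line, plus an annotation line when
#'   positions are masked).
#' @export
export_haplotype <- function(h, include_review = FALSE) {
  stopifnot(inherits(h, "mt_haplotype"))
  keep <- h$calls$status %in% c("confirmed", "uncalled_N")
  if (include_review) keep <- keep | h$calls$status == "review"
  line <- paste(h$calls$rendered[keep], collapse = " ")
  if (length(h$coverage_mask)) {
    line <- paste0(line, "\n# positions below minimum depth: ",
                   position_ranges(h$coverage_mask))
  }
  line
}

#' Export a haplotype as a minimal VCF
#'
#' 1-based positions on the circular axis. Deletions are anchored one base
#' 5' per VCF convention; a deletion at position 1 anchors at position L
#' with `INFO/CIRCULAR=1`. Insertions are collapsed to one record per
#' anchor with the full dominant inserted sequence. N-calls are written
#' with ALT `.` and FILTER `NUMT_N`; review calls carry FILTER
#' `strand_bias_review`; suppressed suspect deletions carry FILTER
#' `suspect_deletion`.
#'
#' @param h An `mt_haplotype`.
#' @param ref An `mt_reference`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_vcf <- function(h, ref, path) {
  stopifnot(inherits(h, "mt_haplotype"), inherits(ref, "mt_reference"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", ref$name, ",length=", ref$L, ">"),
    "##INFO=<ID=VF,Number=1,Type=Float,Description=\"Variant frequency\">",
    "##INFO=<ID=SB,Number=1,Type=Float,Description=\"Strand bias\">",
    "##INFO=<ID=CIRCULAR,Number=0,Type=Flag,Description=\"Anchored across the circular origin\">",
    "##FILTER=<ID=strand_bias_review,Description=\"Strand bias above review bound\">",
    "##FILTER=<ID=suspect_deletion,Description=\"Suppressed suspect deletion\">",
    "##FILTER=<ID=NUMT_N,Description=\"Possible NUMT-associated variant\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  calls <- h$calls
  done_ins <- character(0)
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    filt <- switch(cl$status, confirmed = "PASS",
                   review = "strand_bias_review",
                   suppressed_suspect = "suspect_deletion",
                   uncalled_N = "NUMT_N", "PASS")
    info <- sprintf("VF=%.4g;SB=%.4g", cl$frequency, cl$strand_bias)
    if (cl$kind %in% c("substitution", "heteroplasmy")) {
      alt <- if (cl$kind == "substitution") cl$allele else
        paste(setdiff(iupac_alleles(cl$allele), ref_base(ref, cl$position)),
              collapse = ",")
      if (alt == "") alt <- cl$allele  # both het alleles non-reference
      rows <- c(rows, paste(ref$name, cl$position, cl$rendered,
                            ref_base(ref, cl$position), alt, ".",
                            filt, info, sep = "\t"))
    } else if (cl$kind == "uncalled_N") {
      rows <- c(rows, paste(ref$name, cl$position, cl$rendered,
                            ref_base(ref, cl$position), ".", ".",
                            filt, info, sep = "\t"))
    } else if (cl$kind == "deletion") {
      if (cl$position > 1L) {
        anchor <- cl$position - 1L
        rows <- c(rows, paste(ref$name, anchor, cl$rendered,
                              paste0(ref_base(ref, anchor),
                                     ref_base(ref, cl$position)),
                              ref_base(ref, anchor), ".", filt, info,
                              sep = "\t"))
      } else {
        rows <- c(rows, paste(ref$name, ref$L, cl$rendered,
                              paste0(ref_base(ref, ref$L),
                                     ref_base(ref, 1L)),
                              ref_base(ref, ref$L), ".", filt,
                              paste0(info, ";CIRCULAR"), sep = "\t"))
      }
    } else if (cl$kind == "insertion") {
      key <- as.character(cl$position)
      if (key %in% done_ins) next
      done_ins <- c(done_ins, key)
      seq_ins <- paste(calls$allele[calls$kind == "insertion" &
                                      calls$position == cl$position],
                       collapse = "")
      rows <- c(rows, paste(ref$name, cl$position,
                            paste0(cl$position, ".ins", seq_ins),
                            ref_base(ref, cl$position),
                            paste0(ref_base(ref, cl$position), seq_ins),
                            ".", filt, info, sep = "\t"))
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
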