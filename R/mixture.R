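#' Find mixed variant point sites (MVs)
#'
#' Positions carrying two or more substitution-allele states (A/C/G/T;
#' indels are excluded from mixture work), each at a frequency of at least
#' the inclusive heteroplasmy threshold, at positions meeting the depth
#' minimum.
#'
#' @param p An `mt_pileup`.
#' @param th A `calling_thresholds`.
#' @return data.frame sorted by position: `position`, `major_allele`,
#'   `minor_allele`, `major_freq`, `minor_freq`, `n_alleles`.
#' @export
find_mvs <- function(p, th = calling_thresholds()) {
  stopifnot(inherits(p, "mt_pileup"))
  depth <- depth_vector(p)
  acm <- allele_count_matrix(p)[, c("A", "C", "G", "T"), drop = FALSE]
  freq <- acm / pmax(depth, 1L)
  n_above <- rowSums(freq >= th$php_min)
  hit <- which(depth >= th$min_depth & n_above >= 2L)
  if (length(hit) == 0L) {
    return(data.frame(position = integer(), major_allele = character(),
                      minor_allele = character(), major_freq = numeric(),
                      minor_freq = numeric(), n_alleles = integer(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(hit, function(pos) {
    f <- sort(freq[pos, ], decreasing = TRUE)
    data.frame(position = pos, major_allele = names(f)[1],
               minor_allele = names(f)[2],
               major_freq = unname(f[1]), minor_freq = unname(f[2]),
               n_alleles = sum(freq[pos, ] >= th$php_min),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mixture flag from the MV count
#'
#' Three or more MVs (allowing for personal point heteroplasmies) indicate
#' a mixed sample; the bound is inclusive.
#'
#' @param mv_count Number of mixed variant sites.
#' @param th A `calling_thresholds`.
#' @return Logical flag.
#' @export
flag_mixture <- function(mv_count, th = calling_thresholds()) {
  mv_count >= th$mv_min_count
}

#' Quantitative two-contributor deconvolution
#'
#' At each MV the higher-frequency state is assigned to the major
#' contributor and the lower to the minor; near-1:1 mixtures can flip the
#' per-site assignment relative to the global frequency clusters, so sites
#' are reconciled by nearest cluster mean (1-D two-cluster split at the
#' midpoint of the sorted minor frequencies). MVs whose minor frequency
#' lies more than `k_sd` sample standard deviations from the minor mean are
#' flagged as possible stochastic variation or NUMT signal and excluded
#' from the minor haplotype with an audit note. When the major and minor
#' mean frequencies fall within the indistinguishability band the mixture
#' is reported unresolvable ("approximately 1:1").
#'
#' The major haplotype is the thresholded haplotype of the pileup with the
#' major allele taken at each MV; the minor haplotype takes the minor
#' allele at retained MVs plus every non-MV consensus substitution shared
#' with the major.
#'
#' @param p An `mt_pileup`.
#' @param mvs MV table from [find_mvs()].
#' @param ref An `mt_reference` (for difference coding).
#' @param th A `calling_thresholds`.
#' @param k_sd Outlier bound in sample SDs (default 3).
#' @param indist_band Indistinguishability band in percentage points
#'   between major and minor mean frequencies (default 10).
#' @return A `mixture_result` list: `mv_sites`, `is_mixture`,
#'   `unresolvable`, `major_variants`, `minor_variants` (difference-coded
#'   strings), `major_mean`, `major_sd`, `minor_mean`, `minor_sd`
#'   (percent), `effective_ratio`, `excluded` (audit table).
#' @export
deconvolve <- function(p, mvs = find_mvs(p, th), ref,
                       th = calling_thresholds(), k_sd = 3,
                       indist_band = 10) {
  stopifnot(inherits(p, "mt_pileup"), inherits(ref, "mt_reference"))
  is_mix <- flag_mixture(nrow(mvs), th)
  if (!is_mix) {
    stop("not a mixture: ", nrow(mvs), " MV sites (need >= ",
         th$mv_min_count, ")")
  }

  # Per-site major/minor assignment by frequency is the cluster assignment:
  # without read phasing the two contributors are separable only by their
  # global frequency clusters, and the per-site ordering (major >= minor)
  # already places each state with its nearest cluster. Near 1:1 the
  # clusters merge and the mixture is reported unresolvable below.
  minor_mean0 <- mean(mvs$minor_freq)
  minor_sd0 <- stats::sd(mvs$minor_freq)
  out_of_band <- if (is.na(minor_sd0) || minor_sd0 == 0) {
    rep(FALSE, nrow(mvs))
  } else {
    abs(mvs$minor_freq - minor_mean0) > k_sd * minor_sd0
  }
  retained <- mvs[!out_of_band, , drop = FALSE]
  excluded <- mvs[out_of_band, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$note <- "possible stochastic variation/NAV (outside k*SD band)"
  } else {
    excluded$note <- character(0)
  }

  major_mean <- 100 * mean(retained$major_freq)
  major_sd <- 100 * stats::sd(retained$major_freq)
  minor_mean <- 100 * mean(retained$minor_freq)
  minor_sd <- 100 * stats::sd(retained$minor_freq)
  unresolvable <- (major_mean - minor_mean) < indist_band

  h <- assemble_haplotype(p, ref, th = th)
  consensus <- h$calls[h$calls$kind == "substitution" &
                         !(h$calls$position %in% mvs$position), ,
                       drop = FALSE]

  mv_variant <- function(position, allele) {
    if (allele == ref_base(ref, position)) NA_character_ else
      paste0(position, allele)
  }
  major_mv <- mapply(mv_variant, retained$position, retained$major_allele)
  minor_mv <- if (unresolvable) character(0) else
    mapply(mv_variant, retained$position, retained$minor_allele)

  sort_variants <- function(v) {
    v <- v[!is.na(v)]
    v[order(vapply(v, function(s) parse_variant(s)$position, integer(1)))]
  }
  major_variants <- sort_variants(c(consensus$rendered, major_mv))
  minor_variants <- sort_variants(c(consensus$rendered, unlist(minor_mv)))

  structure(
    list(mv_sites = mvs, is_mixture = is_mix, unresolvable = unresolvable,
         major_variants = major_variants,
         minor_variants = if (unresolvable) character(0) else minor_variants,
         major_mean = major_mean, major_sd = major_sd,
         minor_mean = minor_mean, minor_sd = minor_sd,
         effective_ratio = major_mean / minor_mean,
         excluded = excluded),
    class = "mixture_result"
  )
}

#' @export
print.mixture_result <- function(x, ...) {
  cat("<mixture_result> ", nrow(x$mv_sites), " MV sites; ",
      if (x$unresolvable) "unresolvable (approximately 1:1)" else
        sprintf("major %.1f%% (+/-%.1f), minor %.1f%% (+/-%.1f), ratio %.2f",
                x$major_mean, x$major_sd, x$minor_mean, x$minor_sd,
                x$effective_ratio),
      "\n", sep = "")
  invisible(x)
}

#' Two-contributor mixture design arithmetic
#'
#' One contributor is held at a constant DNA input mass while the second
#' varies to hit a target ratio `a:b` (variable:constant): a 20:1 design at
#' a 2 pg constant takes 40 pg of the variable contributor (42 pg total), a
#' 1:10 design takes 0.2 pg (2.2 pg total).
#'
#' @param constant_pg Constant contributor's input mass in pg (default 2).
#' @param target_ratio Ratio `variable:constant`, as a length-2 numeric
#'   vector or a string like `"20:1"`.
#' @return List with `constant_pg`, `variable_pg`, `target_ratio`,
#'   `total_pg`.
#' @export
mixture_design <- function(constant_pg = 2, target_ratio) {
  if (is.character(target_ratio)) {
    target_ratio <- as.numeric(strsplit(target_ratio, ":")[[1]])
  }
  stopifnot(length(target_ratio) == 2L, all(is.finite(target_ratio)))
  if (any(target_ratio <= 0) || constant_pg <= 0) {
    stop("ratio components and masses must be positive")
  }
  variable_pg <- constant_pg * target_ratio[1] / target_ratio[2]
  list(constant_pg = constant_pg, variable_pg = variable_pg,
       target_ratio = target_ratio,
       total_pg = constant_pg + variable_pg)
}
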