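#' Synthetic circular reference sequence
#'
#' A seeded random A/C/G/T circle standing in for a real mitochondrial
#' reference in simulations and tests (it is synthetic, not the rCRS).
#' By default, poly-C tracts are planted at the canonical HVI/HVII
#' homopolymer locations (303-315 interrupted by the 310T, and
#' 16184-16193), plus a short C-tract at 568-573, so that homopolymer
#' behaviour can be exercised at the familiar coordinates.
#'
#' @param L Circle length (default 16,569).
#' @param seed Integer seed.
#' @param plant_tracts Plant the canonical control-region homopolymers
#'   (only when L is large enough to hold them).
#' @return An `mt_reference`.
#' @export
synthetic_reference <- function(L = 16569L, seed = 7L,
                                plant_tracts = TRUE) {
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  if (plant_tracts && L >= 16200L) {
    bases[303:309] <- "C"
    bases[310] <- "T"
    bases[311:315] <- "C"
    bases[16184:16193] <- "C"
    bases[16194] <- "A"
    bases[568:573] <- "C"
  }
  suppressWarnings(mt_reference(paste(bases, collapse = ""),
                                name = "chrM_synthetic"))
}

#' Simulate a tiled, overlapping amplicon panel
#'
#' Amplicons are spaced evenly around the circle; each spans from its
#' start to `target_mean_overlap` bases past the next amplicon's start, so
#' coverage of the circle is complete by construction and every junction
#' overlaps by about the target. Pools alternate 1/2 in start order.
#' The printed geometry of a real panel over-determines (n, mean length,
#' mean overlap, L); the generator honours n and full coverage and reports
#' the achieved means on the returned panel.
#'
#' @param n_amplicons Number of amplicons.
#' @param target_mean_length Target mean amplicon length (bp).
#' @param target_mean_overlap Target junction overlap (bp).
#' @param L Circle length.
#' @param seed Integer seed (start-phase jitter).
#' @return An `mt_panel`.
#' @export
simulate_panel <- function(n_amplicons, target_mean_length,
                           target_mean_overlap, L = 16569L, seed = 1L) {
  n <- as.integer(n_amplicons)
  if (n * (target_mean_length - target_mean_overlap) < L) {
    stop("infeasible panel: n_amplicons * (mean_length - mean_overlap) = ",
         n * (target_mean_length - target_mean_overlap),
         " < L = ", L)
  }
  set.seed(seed)
  phase <- sample.int(L, 1L)
  starts <- ((floor((seq_len(n) - 1L) * L / n) + phase - 1L) %% L) + 1L
  starts <- sort(as.integer(starts))
  nxt <- c(starts[-1L], starts[1L] + L)
  ends_lin <- pmin(nxt + as.integer(target_mean_overlap) - 1L,
                   starts + L - 1L)
  ends <- ((ends_lin - 1L) %% L) + 1L
  mt_panel(data.frame(
    id = sprintf("mt_%d", seq_len(n)),
    pool = rep_len(c(1L, 2L), n),
    start = starts, end = ends, stringsAsFactors = FALSE), L = L)
}

#' Per-amplicon depth model
#'
#' @param target_median Target median read depth per amplicon.
#' @param sdlog Log-normal dispersion of per-amplicon depth (0 for a flat
#'   profile); the observed amplicon-balance spread of real short-amplicon
#'   panels corresponds to sdlog around 0.5.
#' @param balance Optional fixed per-amplicon balance multipliers
#'   (recycled), overriding the log-normal draw.
#' @return A `depth_model` list.
#' @export
depth_model <- function(target_median = 500, sdlog = 0, balance = NULL) {
  stopifnot(target_median >= 0, sdlog >= 0)
  structure(list(target_median = target_median, sdlog = sdlog,
                 balance = balance), class = "depth_model")
}

#' Sequencing error model
#'
#' @param substitution_rate Per read-base substitution error rate
#'   (default 0.002); an erroneous base is uniform over the other three.
#' @param base_indel_rate Base homopolymer indel rate; the indel noise rate
#'   at a tract's 3' end is `base_indel_rate * tract_length` (split evenly
#'   between one-base insertion and deletion reads), capped at 0.5.
#' @param min_tract Minimum tract length that receives indel noise.
#' @return An `error_model` list.
#' @export
error_model <- function(substitution_rate = 0.002,
                        base_indel_rate = 0.005, min_tract = 3L) {
  stopifnot(substitution_rate >= 0, substitution_rate <= 1,
            base_indel_rate >= 0, base_indel_rate <= 1)
  structure(list(substitution_rate = substitution_rate,
                 base_indel_rate = base_indel_rate,
                 min_tract = as.integer(min_tract)),
            class = "error_model")
}

#' NUMT co-amplification model
#'
#' A catalog of nuclear-insert alleles and a fixed absolute read count per
#' catalog position: nuclear copy number does not dilute with mtDNA input,
#' so the NUMT share of depth grows as mtDNA depth falls.
#'
#' @param catalog data.frame with columns `position`, `allele`.
#' @param reads Fixed NUMT read count per catalog position.
#' @return A `numt_model` list.
#' @export
numt_model <- function(catalog, reads = 10L) {
  stopifnot(is.data.frame(catalog),
            all(c("position", "allele") %in% names(catalog)), reads >= 0)
  structure(list(catalog = catalog, reads = as.integer(reads)),
            class = "numt_model")
}

#' Negative-control background model
#'
#' @param scale Background depth as a percent of the paired positive's
#'   per-position depth.
#' @param hotspots Optional data.frame `start`, `end`, `scale` of
#'   primer-artifact spans whose relative depth replaces the background.
#' @return A `negative_model` list.
#' @export
negative_model <- function(scale = 1, hotspots = NULL) {
  stopifnot(scale >= 0)
  structure(list(scale = scale, hotspots = hotspots),
            class = "negative_model")
}

normalize_haplotype <- function(h) {
  if (is.null(h) || length(h) == 0L) {
    return(data.frame(variant = character(), frequency = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (is.character(h)) h <- data.frame(variant = h, frequency = 1,
                                       stringsAsFactors = FALSE)
  stopifnot(is.data.frame(h), "variant" %in% names(h))
  if (!"frequency" %in% names(h)) h$frequency <- 1
  h
}

#' Generative scenario for synthetic pileups
#'
#' Bundles everything the generator needs: reference and panel, one or two
#' difference-coded haplotypes (with optional per-variant heteroplasmy
#' fractions), the mixture minor fraction, and the depth / error / strand /
#' NUMT / negative models, under one seed that fixes all outputs.
#'
#' @param reference An `mt_reference`.
#' @param panel An `mt_panel`.
#' @param haplotypes List of 1-2 haplotypes; each a character vector of
#'   variant names (frequency 1) or a data.frame `variant`, `frequency`.
#' @param minor_fraction Fraction of reads from the second haplotype
#'   (0 for single source).
#' @param depth A `depth_model`.
#' @param error An `error_model` (use `error_model(0, 0)` for noiseless).
#' @param strand_fraction Expected forward-read fraction.
#' @param numt Optional `numt_model`.
#' @param negative Optional `negative_model`.
#' @param seed Integer seed.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(reference, panel, haplotypes = list(character(0)),
                         minor_fraction = 0, depth = depth_model(),
                         error = error_model(), strand_fraction = 0.5,
                         numt = NULL, negative = NULL, seed = 1L) {
  stopifnot(inherits(reference, "mt_reference"), inherits(panel, "mt_panel"),
            length(haplotypes) %in% 1:2,
            minor_fraction >= 0, minor_fraction < 1,
            strand_fraction > 0, strand_fraction < 1)
  if (minor_fraction > 0 && length(haplotypes) != 2L) {
    stop("a mixture scenario needs two haplotypes")
  }
  structure(
    list(reference = reference, panel = panel,
         haplotypes = lapply(haplotypes, normalize_haplotype),
         minor_fraction = minor_fraction, depth = depth, error = error,
         strand_fraction = strand_fraction, numt = numt,
         negative = negative, seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

# expected per-position depth implied by the panel and depth model
expected_lambda <- function(sc) {
  a <- sc$panel$amplicons
  n <- nrow(a)
  bal <- if (!is.null(sc$depth$balance)) rep_len(sc$depth$balance, n) else
    if (sc$depth$sdlog > 0) stats::rlnorm(n, 0, sc$depth$sdlog) else
      rep(1, n)
  lambda <- numeric(sc$panel$L)
  for (i in seq_len(n)) {
    posn <- amplicon_positions(a$start[i], a$end[i], sc$panel$L)
    lambda[posn] <- lambda[posn] + sc$depth$target_median * bal[i]
  }
  lambda
}

# contributor allele-probability matrix (L x A,C,G,T,del) + insertion table
contributor_model <- function(ref, hap) {
  L <- ref$L
  P <- matrix(0, nrow = L, ncol = 5L,
              dimnames = list(NULL, PILEUP_ALLELES))
  refvec <- strsplit(ref$sequence, "")[[1]]
  P[cbind(seq_len(L), match(refvec, PILEUP_ALLELES))] <- 1
  ins <- data.frame(position = integer(), seq = character(),
                    prob = numeric(), stringsAsFactors = FALSE)
  if (nrow(hap) == 0L) return(list(P = P, ins = ins))
  parsed <- lapply(hap$variant, parse_variant)
  ins_rows <- list()
  for (i in seq_along(parsed)) {
    v <- parsed[[i]]
    q <- hap$frequency[i]
    if (v$kind == "substitution" || v$kind == "heteroplasmy") {
      al <- if (v$kind == "substitution") v$allele else {
        # a heteroplasmy in a contributor: the non-reference component at q
        setdiff(iupac_alleles(v$allele), refvec[v$position])[1]
      }
      P[v$position, ] <- P[v$position, ] * (1 - q)
      P[v$position, al] <- P[v$position, al] + q
    } else if (v$kind == "deletion") {
      P[v$position, ] <- P[v$position, ] * (1 - q)
      P[v$position, "del"] <- P[v$position, "del"] + q
    } else if (v$kind == "insertion") {
      ins_rows[[length(ins_rows) + 1L]] <-
        data.frame(position = v$position, index = v$insert_index,
                   base = v$allele, prob = q, stringsAsFactors = FALSE)
    }
  }
  if (length(ins_rows)) {
    ir <- do.call(rbind, ins_rows)
    # pos.1C + pos.2C at equal frequency collapse to one inserted run "CC"
    for (pos in unique(ir$position)) {
      sub <- ir[ir$position == pos, , drop = FALSE]
      sub <- sub[order(sub$index), , drop = FALSE]
      ins <- rbind(ins, data.frame(position = pos,
                                   seq = paste(sub$base, collapse = ""),
                                   prob = max(sub$prob),
                                   stringsAsFactors = FALSE))
    }
  }
  list(P = P, ins = ins)
}

# homopolymer tracts (3'-end position, base, length) of at least min_len
reference_tracts <- function(ref, min_len) {
  r <- rle(strsplit(ref$sequence, "")[[1]])
  ends <- cumsum(r$lengths)
  keep <- r$lengths >= min_len
  data.frame(end = ends[keep], base = r$values[keep],
             len = r$lengths[keep], stringsAsFactors = FALSE)
}

# round counts to target totals, preserving row sums exactly
exact_allocate <- function(depth, P) {
  counts <- round(P * depth)
  fix <- depth - rowSums(counts)
  if (any(fix != 0L)) {
    top <- max.col(P, ties.method = "first")
    idx <- which(fix != 0L)
    counts[cbind(idx, top[idx])] <- counts[cbind(idx, top[idx])] + fix[idx]
  }
  counts
}

#' Simulate a pileup from a scenario
#'
#' Per-position total depth is Poisson around the panel/depth-model
#' expectation; allele counts are multinomial over the mixture of the
#' contributor models plus the error model; strands split binomially.
#' Insertion reads are drawn at their anchors; NUMT reads are added as a
#' fixed count of the catalog allele. With `exact = TRUE` all draws are
#' replaced by expectation rounding, giving a deterministic "noiseless"
#' pileup (used for boundary analyses).
#'
#' @param sc A `sim_scenario`.
#' @param sample_id Sample label.
#' @param exact Deterministic expectation-rounding mode.
#' @return A `sim_result` list: `pileup` (an `mt_pileup`) and `truth`
#'   (data.frame of injected variants with expected read fractions, plus
#'   attribute `differing_positions` for mixtures).
#' @export
simulate_pileup <- function(sc, sample_id = "sim", exact = FALSE) {
  stopifnot(inherits(sc, "sim_scenario"))
  set.seed(sc$seed)
  ref <- sc$reference
  L <- ref$L

  lambda <- expected_lambda(sc)
  cms <- lapply(sc$haplotypes, contributor_model, ref = ref)
  w <- if (length(cms) == 2L) c(1 - sc$minor_fraction, sc$minor_fraction)
       else 1
  P <- Reduce(`+`, Map(function(cm, wi) cm$P * wi, cms, w))

  ins <- do.call(rbind, c(list(data.frame(position = integer(),
                                          seq = character(),
                                          prob = numeric())),
                          Map(function(cm, wi) {
                            if (nrow(cm$ins)) transform(cm$ins,
                                                        prob = prob * wi)
                            else cm$ins
                          }, cms, w)))

  # homopolymer indel noise at tract 3' ends
  if (sc$error$base_indel_rate > 0) {
    tr <- reference_tracts(ref, sc$error$min_tract)
    for (i in seq_len(nrow(tr))) {
      r <- min(0.5, sc$error$base_indel_rate * tr$len[i])
      pos <- tr$end[i]
      P[pos, ] <- P[pos, ] * (1 - r / 2)
      P[pos, "del"] <- P[pos, "del"] + r / 2
      ins <- rbind(ins, data.frame(position = pos, seq = tr$base[i],
                                   prob = r / 2, stringsAsFactors = FALSE))
    }
  }

  # substitution error: each read-base wrong uniformly among the other 3
  e <- sc$error$substitution_rate
  if (e > 0) {
    B <- P[, c("A", "C", "G", "T"), drop = FALSE]
    s <- rowSums(B)
    P[, c("A", "C", "G", "T")] <- B * (1 - e) + (s - B) * e / 3
  }

  # pool insertion entries sharing anchor and sequence
  if (nrow(ins)) {
    ins <- stats::aggregate(prob ~ position + seq, data = ins, FUN = sum)
  }

  depth <- if (exact) as.integer(round(lambda)) else
    stats::rpois(L, lambda)

  if (exact) {
    counts5 <- exact_allocate(depth, P)
  } else {
    counts5 <- matrix(0L, nrow = L, ncol = 5L,
                      dimnames = list(NULL, PILEUP_ALLELES))
    remaining <- depth
    pleft <- rep(1, L)
    for (k in seq_len(5L)) {
      pk <- P[, k]
      pr <- ifelse(pleft > 1e-12, pmin(1, pk / pleft), 0)
      ck <- if (k < 5L) stats::rbinom(L, remaining, pr) else remaining
      counts5[, k] <- ck
      remaining <- remaining - ck
      pleft <- pleft - pk
    }
  }

  p <- mt_pileup(sample_id, L = L,
                 metadata = list(seed = sc$seed,
                                 minor_fraction = sc$minor_fraction))
  sf <- sc$strand_fraction
  for (k in seq_len(5L)) {
    ck <- counts5[, k]
    fwd <- if (exact) as.integer(round(ck * sf)) else
      stats::rbinom(L, ck, sf)
    p$counts[, 2L * k - 1L] <- as.integer(fwd)
    p$counts[, 2L * k] <- as.integer(ck - fwd)
  }

  if (nrow(ins)) {
    ins_counts <- integer(nrow(ins))
    for (i in seq_len(nrow(ins))) {
      d <- depth[ins$position[i]]
      ins_counts[i] <- if (exact) as.integer(round(d * ins$prob[i])) else
        stats::rbinom(1L, d, min(1, ins$prob[i]))
    }
    keep <- ins_counts > 0L
    if (any(keep)) {
      fwd <- if (exact) as.integer(round(ins_counts[keep] * sf)) else
        stats::rbinom(sum(keep), ins_counts[keep], sf)
      p$insertions <- data.frame(position = ins$position[keep],
                                 seq = ins$seq[keep], fwd = fwd,
                                 rev = ins_counts[keep] - fwd,
                                 stringsAsFactors = FALSE)
    }
  }

  # fixed-count NUMT reads of the catalog allele
  if (!is.null(sc$numt) && sc$numt$reads > 0L) {
    cat_pos <- as.integer(sc$numt$catalog$position)
    cat_al <- toupper(sc$numt$catalog$allele)
    nfwd <- as.integer(ceiling(sc$numt$reads / 2))
    for (i in seq_along(cat_pos)) {
      col_f <- paste0(cat_al[i], "_fwd")
      col_r <- paste0(cat_al[i], "_rev")
      p$counts[cat_pos[i], col_f] <- p$counts[cat_pos[i], col_f] + nfwd
      p$counts[cat_pos[i], col_r] <- p$counts[cat_pos[i], col_r] +
        (sc$numt$reads - nfwd)
    }
  }

  truth <- build_truth(sc, cms, w)
  structure(list(pileup = p, truth = truth, scenario = sc),
            class = "sim_result")
}

build_truth <- function(sc, cms, w) {
  rows <- list()
  src <- c("major", "minor")[seq_along(cms)]
  if (length(cms) == 1L) src <- "single"
  for (ci in seq_along(cms)) {
    hap <- sc$haplotypes[[ci]]
    if (nrow(hap) == 0L) next
    for (i in seq_len(nrow(hap))) {
      v <- parse_variant(hap$variant[i])
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v$rendered, position = v$position, kind = v$kind,
        source = src[ci],
        true_frequency = hap$frequency[i] * w[ci],
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(sc$numt)) {
    for (i in seq_len(nrow(sc$numt$catalog))) {
      rows[[length(rows) + 1L]] <- data.frame(
        variant = paste0(sc$numt$catalog$position[i],
                         toupper(sc$numt$catalog$allele[i])),
        position = as.integer(sc$numt$catalog$position[i]),
        kind = "numt", source = "numt", true_frequency = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant = character(), position = integer(),
               kind = character(), source = character(),
               true_frequency = numeric(), stringsAsFactors = FALSE)
  if (length(cms) == 2L) {
    attr(truth, "differing_positions") <-
      haplotype_differing_positions(sc$haplotypes[[1]],
                                    sc$haplotypes[[2]])
  }
  truth
}

# substitution positions at which two difference-coded haplotypes differ
haplotype_differing_positions <- function(h1, h2) {
  subs <- function(h) {
    h <- normalize_haplotype(h)
    keep <- vapply(h$variant, function(s)
      parse_variant(s)$kind == "substitution", logical(1))
    h$variant[keep]
  }
  s1 <- subs(h1); s2 <- subs(h2)
  diff <- union(setdiff(s1, s2), setdiff(s2, s1))
  sort(unique(vapply(diff, function(s) parse_variant(s)$position,
                     integer(1))))
}

#' Random difference-coded haplotype
#'
#' Samples `n_subs` substitution variants at distinct positions (avoiding
#' the planted homopolymer tracts so indel-free round trips stay exact).
#'
#' @param ref An `mt_reference`.
#' @param n_subs Number of substitutions.
#' @param seed Integer seed.
#' @param avoid Positions to exclude (default: positions inside reference
#'   homopolymer tracts of length 4+ and their flanks).
#' @return Character vector of variant names, sorted by position.
#' @export
random_haplotype <- function(ref, n_subs, seed = 1L, avoid = NULL) {
  set.seed(seed)
  if (is.null(avoid)) {
    tr <- reference_tracts(ref, 4L)
    avoid <- unlist(lapply(seq_len(nrow(tr)), function(i)
      max(1L, tr$end[i] - tr$len[i]):min(ref$L, tr$end[i] + 1L)))
  }
  pool <- setdiff(seq_len(ref$L), avoid)
  pos <- sort(sample(pool, n_subs))
  bases <- c("A", "C", "G", "T")
  vapply(pos, function(pp) {
    alt <- sample(setdiff(bases, ref_base(ref, pp)), 1L)
    paste0(pp, alt)
  }, character(1))
}

#' Simulate a two-contributor mixture
#'
#' Each read is drawn from the minor contributor with probability
#' `minor_fraction` (in `exact` mode, an exact share of the depth).
#'
#' @param sc A `sim_scenario` carrying two haplotypes.
#' @param minor_fraction Minor contributor's read fraction; overrides the
#'   scenario's value when given.
#' @param sample_id Sample label.
#' @param exact Deterministic expectation-rounding mode.
#' @return A `sim_result`; `truth` carries `differing_positions`.
#' @export
simulate_mixture <- function(sc, minor_fraction = NULL,
                             sample_id = "mix", exact = FALSE) {
  stopifnot(inherits(sc, "sim_scenario"), length(sc$haplotypes) == 2L)
  if (!is.null(minor_fraction)) sc$minor_fraction <- minor_fraction
  stopifnot(sc$minor_fraction > 0)
  if (identical(sc$haplotypes[[1]], sc$haplotypes[[2]])) {
    warning("the two contributor haplotypes are identical; ",
            "the mixture is undetectable by design")
  }
  simulate_pileup(sc, sample_id = sample_id, exact = exact)
}

#' Simulate a negative control paired to a positive pileup
#'
#' Background depth is `negative_model$scale` percent of the positive's
#' per-position depth (reads carry the reference base); optional hotspot
#' spans take their own relative scale, emulating primer artifacts and
#' amplicon-overlap reads.
#'
#' @param sc A `sim_scenario` with a `negative` model.
#' @param positive The paired positive-control `mt_pileup`.
#' @param sample_id Sample label.
#' @param exact Deterministic expectation-rounding mode.
#' @return An `mt_pileup` with `metadata$role = "negative"`.
#' @export
simulate_negative <- function(sc, positive, sample_id = "neg",
                              exact = FALSE) {
  stopifnot(inherits(sc, "sim_scenario"), inherits(positive, "mt_pileup"))
  nm <- sc$negative
  if (is.null(nm)) nm <- negative_model()
  set.seed(sc$seed + 104729L)
  dp <- depth_vector(positive)
  scale <- rep(nm$scale, positive$L)
  if (!is.null(nm$hotspots)) {
    for (i in seq_len(nrow(nm$hotspots))) {
      span <- amplicon_positions(nm$hotspots$start[i], nm$hotspots$end[i],
                                 positive$L)
      scale[span] <- nm$hotspots$scale[i]
    }
  }
  lambda <- dp * scale / 100
  depth <- if (exact) as.integer(round(lambda)) else
    stats::rpois(positive$L, lambda)
  p <- mt_pileup(sample_id, L = positive$L,
                 metadata = list(role = "negative", scale = nm$scale))
  refvec <- strsplit(sc$reference$sequence, "")[[1]]
  fwd <- if (exact) as.integer(round(depth * sc$strand_fraction)) else
    stats::rbinom(positive$L, depth, sc$strand_fraction)
  col_f <- match(paste0(refvec, "_fwd"), colnames(p$counts))
  col_r <- match(paste0(refvec, "_rev"), colnames(p$counts))
  p$counts[cbind(seq_len(positive$L), col_f)] <- fwd
  p$counts[cbind(seq_len(positive$L), col_r)] <- depth - fwd
  p
}

#' Simulate a dilution series
#'
#' The depth model is scaled by each factor while any NUMT model keeps its
#' fixed read count, so the NUMT-associated share of depth rises as mtDNA
#' input falls.
#'
#' @param sc A `sim_scenario`.
#' @param factors Positive, descending scale factors (e.g.
#'   `0.5^(0:6)` for seven two-fold dilutions).
#' @param exact Deterministic expectation-rounding mode.
#' @return List of `sim_result`, one per factor.
#' @export
dilution_series <- function(sc, factors = 0.5^(0:6), exact = FALSE) {
  stopifnot(inherits(sc, "sim_scenario"), all(factors > 0),
            !is.unsorted(rev(factors)))
  lapply(seq_along(factors), function(i) {
    sci <- sc
    sci$depth$target_median <- sc$depth$target_median * factors[i]
    sci$seed <- sc$seed + i
    simulate_pileup(sci, sample_id = sprintf("dil_%02d", i), exact = exact)
  })
}
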