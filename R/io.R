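#' Read a pileup from the per-position allele-count TSV dialect
#'
#' One row per position per allele: columns `sample_id`, `position`,
#' `allele` (`A`/`C`/`G`/`T`/`del`, or `ins:<seq>` for insertion reads),
#' `fwd`, `rev`. Positions with no rows have zero counts.
#'
#' @param tsv_path Path to the tab-separated file (with header).
#' @param L Circle length (default rCRS 16,569).
#' @param metadata Optional metadata list attached to the pileup.
#' @return An `mt_pileup`.
#' @export
read_pileup <- function(tsv_path, L = 16569L, metadata = list()) {
  tab <- utils::read.table(tsv_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "position", "allele", "fwd", "rev")
  if (!all(need %in% names(tab))) {
    stop("pileup TSV must have columns ", paste(need, collapse = ", "))
  }
  sample_id <- if (nrow(tab)) tab$sample_id[1] else "empty"
  p <- mt_pileup(sample_id, L = L, metadata = metadata)
  if (nrow(tab) == 0L) return(p)
  if (any(tab$position < 1L | tab$position > L)) {
    stop("pileup positions out of range 1..", L)
  }
  is_ins <- startsWith(tab$allele, "ins:")
  base <- tab[!is_ins, , drop = FALSE]
  if (nrow(base)) {
    if (!all(base$allele %in% PILEUP_ALLELES)) {
      stop("unknown alleles in pileup: ",
           paste(unique(setdiff(base$allele, PILEUP_ALLELES)), collapse = ", "))
    }
    p$counts[cbind(base$position, match(paste0(base$allele, "_fwd"),
                                        colnames(p$counts)))] <-
      as.integer(base$fwd)
    p$counts[cbind(base$position, match(paste0(base$allele, "_rev"),
                                        colnames(p$counts)))] <-
      as.integer(base$rev)
  }
  ins <- tab[is_ins, , drop = FALSE]
  if (nrow(ins)) {
    p$insertions <- data.frame(position = as.integer(ins$position),
                               seq = sub("^ins:", "", ins$allele),
                               fwd = as.integer(ins$fwd),
                               rev = as.integer(ins$rev),
                               stringsAsFactors = FALSE)
  }
  p
}

#' Write a pileup in the per-position allele-count TSV dialect
#'
#' Only positions/alleles with nonzero counts are written; see
#' [read_pileup()] for the format.
#'
#' @param p An `mt_pileup`.
#' @param tsv_path Output path.
#' @export
write_pileup <- function(p, tsv_path) {
  stopifnot(inherits(p, "mt_pileup"))
  rows <- list()
  for (al in PILEUP_ALLELES) {
    fwd <- p$counts[, paste0(al, "_fwd")]
    rev <- p$counts[, paste0(al, "_rev")]
    keep <- which(fwd > 0L | rev > 0L)
    if (length(keep)) {
      rows[[al]] <- data.frame(sample_id = p$sample_id, position = keep,
                               allele = al, fwd = fwd[keep], rev = rev[keep],
                               stringsAsFactors = FALSE)
    }
  }
  if (nrow(p$insertions)) {
    rows$ins <- data.frame(sample_id = p$sample_id,
                           position = p$insertions$position,
                           allele = paste0("ins:", p$insertions$seq),
                           fwd = p$insertions$fwd, rev = p$insertions$rev,
                           stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), position = integer(),
               allele = character(), fwd = integer(), rev = integer())
  out <- out[order(out$position, out$allele), , drop = FALSE]
  utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tsv_path)
}

#' Write a reference as single-record FASTA
#' @param ref An `mt_reference`.
#' @param fasta_path Output path.
#' @export
write_reference <- function(ref, fasta_path) {
  stopifnot(inherits(ref, "mt_reference"))
  seqs <- Biostrings::DNAStringSet(ref$sequence)
  names(seqs) <- ref$name
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(fasta_path)
}
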