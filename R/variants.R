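#' Forensic mtDNA variant nomenclature
#'
#' Variants are difference-coded against the circular reference and rendered
#' in the field's standard style: substitutions as `263G`, point
#' heteroplasmies with a two-base IUPAC code as `11562R`, insertions with a
#' dot index into the inserted run as `309.1C`, deletions as `16193del`, and
#' positions left uninterpreted (e.g. suspected NUMT signal) as `8943N`.
#'
#' @name variant-nomenclature
NULL

IUPAC2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Two-base IUPAC code for a pair of alleles
#' @param a,b Single bases (order-free).
#' @return The ambiguity code, e.g. `iupac_code("A", "G")` is `"R"`.
#' @export
iupac_code <- function(a, b) {
  key <- paste(sort(c(toupper(a), toupper(b))), collapse = "")
  code <- IUPAC2[[key]]
  if (is.null(code)) stop("no two-base IUPAC code for alleles ", a, "/", b)
  code
}

#' Alleles encoded by a two-base IUPAC code
#' @param code A single ambiguity character.
#' @return Character vector of the two bases.
#' @export
iupac_alleles <- function(code) {
  key <- names(IUPAC2)[IUPAC2 == toupper(code)]
  if (length(key) != 1L) stop("'", code, "' is not a two-base IUPAC code")
  strsplit(key, "")[[1]]
}

#' Construct a variant name
#'
#' @param position 1-based circular position (the 5' anchor for insertions).
#' @param kind One of `"substitution"`, `"heteroplasmy"`, `"insertion"`,
#'   `"deletion"`, `"uncalled_N"`.
#' @param allele Base for substitutions, two-base IUPAC code for
#'   heteroplasmies, inserted base for insertions; ignored for deletions and
#'   N-calls.
#' @param insert_index 1-based index within the inserted run (insertions
#'   only), the `n` of `pos.nC`.
#' @return A `variant_name` object with a `rendered` canonical text field.
#' @export
variant_name <- function(position, kind, allele = NULL, insert_index = NULL) {
  kind <- match.arg(kind, c("substitution", "heteroplasmy", "insertion",
                            "deletion", "uncalled_N"))
  position <- as.integer(position)
  stopifnot(length(position) == 1L, position >= 1L)
  if (kind %in% c("substitution", "heteroplasmy", "insertion")) {
    stopifnot(is.character(allele), nchar(allele) == 1L)
    allele <- toupper(allele)
  }
  if (kind == "substitution" && !allele %in% c("A", "C", "G", "T")) {
    stop("substitution allele must be A/C/G/T, got '", allele, "'")
  }
  if (kind == "heteroplasmy" && !allele %in% IUPAC2) {
    stop("heteroplasmy allele must be a two-base IUPAC code, got '",
         allele, "'")
  }
  if (kind == "insertion") {
    if (!allele %in% c("A", "C", "G", "T")) {
      stop("inserted base must be A/C/G/T, got '", allele, "'")
    }
    insert_index <- as.integer(insert_index)
    stopifnot(length(insert_index) == 1L, insert_index >= 1L)
  } else {
    insert_index <- NA_integer_
  }
  if (kind %in% c("deletion", "uncalled_N")) allele <- NA_character_
  rendered <- switch(kind,
    substitution = paste0(position, allele),
    heteroplasmy = paste0(position, allele),
    insertion    = paste0(position, ".", insert_index, allele),
    deletion     = paste0(position, "del"),
    uncalled_N   = paste0(position, "N"))
  structure(
    list(position = position, kind = kind, allele = allele,
         insert_index = insert_index, rendered = rendered),
    class = "variant_name"
  )
}

#' @export
print.variant_name <- function(x, ...) {
  cat("<variant_name> ", x$rendered, " (", x$kind, ")\n", sep = "")
  invisible(x)
}

#' @rdname variant_name
#' @param v A `variant_name`.
#' @return `render_variant()`: the canonical text.
#' @export
render_variant <- function(v) {
  stopifnot(inherits(v, "variant_name"))
  v$rendered
}

#' Parse canonical variant text back into a `variant_name`
#'
#' `parse_variant(render_variant(v))` recovers `v` for every valid name.
#'
#' @param text A single variant string such as `"263G"`, `"11562R"`,
#'   `"309.1C"`, `"16193del"` or `"8943N"`.
#' @return A `variant_name`.
#' @export
parse_variant <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- toupper(trimws(text))
  if (grepl("^[0-9]+DEL$", s)) {
    return(variant_name(sub("DEL$", "", s), "deletion"))
  }
  if (grepl("^[0-9]+N$", s)) {
    return(variant_name(sub("N$", "", s), "uncalled_N"))
  }
  m <- regmatches(s, regexec("^([0-9]+)\\.([0-9]+)([ACGT])$", s))[[1]]
  if (length(m) == 4L) {
    return(variant_name(m[2], "insertion", allele = m[4],
                        insert_index = as.integer(m[3])))
  }
  m <- regmatches(s, regexec("^([0-9]+)([ACGT])$", s))[[1]]
  if (length(m) == 3L) {
    return(variant_name(m[2], "substitution", allele = m[3]))
  }
  m <- regmatches(s, regexec("^([0-9]+)([RYSWKM])$", s))[[1]]
  if (length(m) == 3L) {
    return(variant_name(m[2], "heteroplasmy", allele = m[3]))
  }
  # locate the first offending character for the error message
  ok <- regmatches(s, regexec("^[0-9]*\\.?[0-9]*", s))[[1]]
  stop("cannot parse variant name '", text, "' (unexpected text at ",
       "character ", nchar(ok) + 1L, ")")
}
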