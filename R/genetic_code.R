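#' Standard genetic code tables for codon models
#'
#' Builds the codon alphabet used throughout the package: the 64-codon
#' translation table and the ordered list of the 61 sense (non-stop) codons
#' over which all codon substitution models are defined. The table itself is
#' taken from \code{Biostrings::GENETIC_CODE}; only the standard nuclear code
#' is exercised, but the constructor accepts any 64-entry table so an
#' alternative code can be plugged in.
#'
#' @param table Named character vector of length 64 mapping codons (DNA
#'   alphabet, e.g. \code{"ATG"}) to one-letter amino acids, stop = \code{"*"}.
#'   Defaults to the standard code.
#' @return An object of class \code{genetic_code}: a list with elements
#'   \code{table} (codon to amino acid), \code{sense} (the 61 sense codons in
#'   stable order), \code{stops} (the 3 stop codons), and \code{index} (named
#'   integer vector mapping a sense codon to its 1..61 index).
#' @examples
#' gc <- genetic_code()
#' length(gc$sense)      # 61
#' gc$table[["ATG"]]     # "M"
#' @export
genetic_code <- function(table = NULL) {
  if (is.null(table)) {
    table <- Biostrings::GENETIC_CODE
    names(table) <- gsub("U", "T", names(table))
  }
  if (length(table) != 64L || is.null(names(table))) {
    stop("genetic code table must be a named vector with 64 codons")
  }
  stops <- names(table)[table == "*"]
  if (length(stops) != 3L) {
    stop("expected exactly 3 stop codons, got ", length(stops))
  }
  sense <- names(table)[table != "*"]
  stopifnot(length(sense) == 61L)
  idx <- seq_along(sense)
  names(idx) <- sense
  structure(
    list(table = table, sense = sense, stops = stops, index = idx),
    class = "genetic_code"
  )
}

# Cached default code + codon-pair metadata (computed once per session).
.chromosel_cache <- new.env(parent = emptyenv())

default_code <- function() {
  if (is.null(.chromosel_cache$code)) {
    .chromosel_cache$code <- genetic_code()
  }
  .chromosel_cache$code
}

#' Translate an in-frame DNA sequence
#'
#' @param dna DNA string, length divisible by 3.
#' @param code A \code{genetic_code} object.
#' @return Amino-acid string; in-frame stops translate to \code{"*"}.
#' @export
translate_dna <- function(dna, code = default_code()) {
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  if (n == 0L) return("")
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- code$table[codons]
  if (anyNA(aa)) {
    bad <- which(is.na(aa))[1L]
    stop("untranslatable codon '", codons[bad], "' at codon position ", bad)
  }
  paste(aa, collapse = "")
}

#' Classify all single-nucleotide codon pairs
#'
#' Returns a 61 x 61 integer matrix over the sense codons coding each ordered
#' pair: 0 = multi-nucleotide change (rate zero), 1 = synonymous transversion,
#' 2 = synonymous transition, 3 = nonsynonymous transversion,
#' 4 = nonsynonymous transition. This is the structural skeleton of the
#' Goldman-Yang style rate matrix and is cached after first use.
#'
#' @param code A \code{genetic_code} object.
#' @return Integer matrix with dimnames = sense codons.
#' @export
codon_pair_classes <- function(code = default_code()) {
  if (!is.null(.chromosel_cache$pair_classes)) return(.chromosel_cache$pair_classes)
  sense <- code$sense
  n <- length(sense)
  mat <- do.call(rbind, strsplit(sense, ""))
  aa <- code$table[sense]
  is_transition <- function(x, y) {
    (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
  }
  cls <- matrix(0L, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    diffs <- mat[rep(i, n), , drop = FALSE] != mat
    ndiff <- rowSums(diffs)
    one <- which(ndiff == 1L)
    for (j in one) {
      pos <- which(diffs[j, ])
      ts <- is_transition(mat[i, pos], mat[j, pos])
      syn <- aa[i] == aa[j]
      cls[i, j] <- if (syn && !ts) 1L else if (syn && ts) 2L
        else if (!syn && !ts) 3L else 4L
    }
  }
  .chromosel_cache$pair_classes <- cls
  cls
}

codon_to_index <- function(codons, code = default_code()) {
  idx <- code$index[toupper(codons)]
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop("'", codons[bad], "' is not a sense codon")
  }
  unname(idx)
}

index_to_codon <- function(idx, code = default_code()) {
  code$sense[idx]
}
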