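#' Gap-cleaned in-frame codon alignment
#'
#' The container all likelihood work runs on: an integer matrix of sense-codon
#' indices (1..61 over the standard code's sense codons), one row per taxon,
#' after removal of every column that contained a gap, an ambiguous
#' nucleotide, or a stop codon in any taxon. Removed original column indices
#' are kept so site numbers can be reported against the input alignment.
#'
#' @param codons Integer matrix (taxa x sites) of sense-codon indices, with
#'   rownames = taxa.
#' @param ncols_original Number of codon columns before cleaning.
#' @param removed_columns Sorted original (1-based) indices of removed columns.
#' @param code A \code{genetic_code}.
#' @return Object of class \code{codon_alignment}.
#' @export
codon_alignment <- function(codons, ncols_original = ncol(codons),
                            removed_columns = integer(0), code = default_code()) {
  stopifnot(is.matrix(codons), !is.null(rownames(codons)))
  if (anyDuplicated(rownames(codons))) stop("duplicate taxon ids")
  storage.mode(codons) <- "integer"
  if (nrow(codons) == 0L) stop("alignment has no taxa")
  if (any(codons < 1L | codons > length(code$sense))) {
    stop("codon indices must lie in 1..", length(code$sense))
  }
  removed_columns <- sort(as.integer(removed_columns))
  if (ncol(codons) + length(removed_columns) != ncols_original) {
    stop("kept + removed columns must equal ncols_original")
  }
  structure(
    list(taxa = rownames(codons), codons = codons,
         ncols_original = as.integer(ncols_original),
         ncols_kept = ncol(codons),
         removed_columns = removed_columns),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", length(x$taxa), "taxa,", x$ncols_kept, "codon sites")
  if (length(x$removed_columns)) {
    cat(" (", length(x$removed_columns), " columns removed in cleaning)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Convert a codon alignment back to DNA strings
#'
#' @param aln A \code{codon_alignment}.
#' @param code A \code{genetic_code}.
#' @return Named character vector of in-frame DNA sequences (kept columns only).
#' @export
codon_alignment_to_dna <- function(aln, code = default_code()) {
  out <- apply(aln$codons, 1L, function(row) {
    paste(code$sense[row], collapse = "")
  })
  names(out) <- aln$taxa
  out
}

#' Thread a protein alignment back onto its coding sequences
#'
#' Reproduces the RevTrans-style construction of a codon alignment: each
#' aligned protein residue is replaced by its source codon and each protein
#' gap by a codon gap, after verifying that every CDS translates exactly to
#' its ungapped protein row (a trailing stop codon on the CDS is tolerated and
#' dropped). Columns containing a gap, an ambiguous nucleotide, or a stop
#' codon in any taxon are then removed.
#'
#' @param protein_alignment Named character vector of aligned protein rows
#'   (equal lengths, gaps as \code{"-"}).
#' @param cds Named character vector of unaligned in-frame DNA sequences; the
#'   names must cover all taxa in \code{protein_alignment}.
#' @param code A \code{genetic_code}.
#' @return A \code{codon_alignment}.
#' @examples
#' prot <- c(a = "MK-", b = "MKR")
#' cds  <- c(a = "ATGAAA", b = "ATGAAACGT")
#' aln <- thread_codon_alignment(prot, cds)
#' aln$ncols_kept        # 2: the gapped third column is cleaned away
#' @export
thread_codon_alignment <- function(protein_alignment, cds, code = default_code()) {
  taxa <- names(protein_alignment)
  if (is.null(taxa)) stop("protein alignment rows must be named")
  if (length(unique(nchar(protein_alignment))) != 1L) {
    stop("protein alignment rows differ in length")
  }
  missing <- setdiff(taxa, names(cds))
  if (length(missing)) stop("no CDS for taxa: ", paste(missing, collapse = ", "))
  naa <- nchar(protein_alignment[[1L]])
  rows <- matrix("---", nrow = length(taxa), ncol = naa, dimnames = list(taxa, NULL))
  for (tx in taxa) {
    d <- toupper(cds[[tx]])
    if (nchar(d) %% 3L != 0L) {
      stop("CDS length of '", tx, "' is not divisible by 3")
    }
    codons <- substring(d, seq(1L, nchar(d), 3L), seq(3L, nchar(d), 3L))
    aa <- code$table[codons]
    aa[is.na(aa)] <- "X"                       # ambiguous codon
    if (length(aa) && aa[length(aa)] == "*") { # tolerate trailing stop
      aa <- aa[-length(aa)]
      codons <- codons[-length(codons)]
    }
    if (any(aa == "*")) {
      stop("internal stop codon in CDS of '", tx, "' at codon ",
           which(aa == "*")[1L])
    }
    prot <- strsplit(toupper(protein_alignment[[tx]]), "")[[1L]]
    residues <- prot[prot != "-"]
    if (length(residues) != length(aa)) {
      stop("taxon '", tx, "': CDS translates to ", length(aa),
           " residues but protein row has ", length(residues))
    }
    mism <- which(residues != aa & aa != "X")
    if (length(mism)) {
      stop("taxon '", tx, "': translation mismatch at residue ", mism[1L],
           " (protein '", residues[mism[1L]], "' vs CDS '", aa[mism[1L]], "')")
    }
    rows[tx, prot != "-"] <- codons
  }
  clean_codon_columns(rows, code)
}

# Apply the cleaning rule and index codons. `rows` is a character matrix of
# codon strings (or "---" gaps), taxa x columns.
clean_codon_columns <- function(rows, code = default_code()) {
  ncols <- ncol(rows)
  ok_codon <- rows %in% code$sense
  dim(ok_codon) <- dim(rows)
  keep <- colSums(ok_codon) == nrow(rows)
  kept <- rows[, keep, drop = FALSE]
  idx <- matrix(code$index[kept], nrow = nrow(rows),
                dimnames = list(rownames(rows), NULL))
  codon_alignment(idx, ncols_original = ncols,
                  removed_columns = which(!keep), code = code)
}
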