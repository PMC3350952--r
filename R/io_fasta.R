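IUPAC_DNA <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-", ".")
IUPAC_PROTEIN <- c(LETTERS, "*", "-", ".")

#' Read a FASTA file
#'
#' Thin wrapper over \code{Biostrings::readBStringSet} that enforces the
#' package's record invariants: non-empty file, unique non-empty ids,
#' non-empty sequences, and an alphabet consistent with \code{moltype}.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @param moltype One of \code{"dna"} or \code{"protein"}; controls alphabet
#'   validation. Gap characters are always permitted so alignments round-trip.
#' @return Named character vector of upper-case sequences, in file order, with
#'   attribute \code{moltype}.
#' @export
read_fasta <- function(path, moltype = c("dna", "protein")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicated FASTA id '", ids[duplicated(ids)][1L], "' in ", path)
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for record '", ids[nchar(seqs) == 0L][1L], "'")
  }
  allowed <- if (moltype == "dna") IUPAC_DNA else IUPAC_PROTEIN
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "")[[1L]]
    bad <- which(!chars %in% allowed)
    if (length(bad)) {
      stop("non-IUPAC character '", chars[bad[1L]], "' in record '", ids[i],
           "' at position ", bad[1L])
    }
  }
  attr(seqs, "moltype") <- moltype
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be named")
  }
  set <- Biostrings::BStringSet(unlist(unname(as.list(seqs)))) # keep order
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}
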