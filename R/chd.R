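#' Weighted consensus motif patterns for chromodomain classification
#'
#' Patterns follow the field's consensus notation: at each position a set of
#' prominent residues (weight 1.0, upper case in the notation) and minor
#' residues (weight 0.5, lower case); an \code{X} position accepts anything
#' (weight 0). The default acceptance threshold is 70 percent of the
#' pattern's maximum score.
#'
#' Built-in patterns:
#' \describe{
#'   \item{chromo_box}{(Y/f)-(L/F/Y)-(L/I/V)-K-(W/y)-(k/r)-g, the classical
#'     chromo-box whose first residue is the Y24 homologue slot.}
#'   \item{galadriel_box}{(Y/f)-(L/Y)-(I/V)-k-W-k-g, the Galadriel-clade
#'     variant of the box.}
#'   \item{tekay_KxLRxK}{(K/R)-X-(L/T)-R-X-(k/r), present in Tekay-like
#'     chromodomains.}
#'   \item{tekay_EExTWExE}{E-E-X-T-W-E-X-E, highly conserved in Tekay; its
#'     TWE core is tracked separately as \code{twe_core}.}
#' }
#'
#' @param name Pattern name.
#' @param positions List of lists with elements \code{prominent} and
#'   \code{minor} (character vectors of residues; both empty = any residue).
#' @param min_score Acceptance threshold; default 0.7 * maximum score.
#' @return Object of class \code{motif_pattern}.
#' @export
motif_pattern <- function(name, positions, min_score = NULL) {
  w <- vapply(positions, function(p) {
    if (length(p$prominent)) 1 else if (length(p$minor)) 0.5 else 0
  }, numeric(1))
  max_score <- sum(w)
  if (!any(w == 1)) stop("pattern needs at least one prominent position")
  if (is.null(min_score)) min_score <- 0.7 * max_score
  if (min_score > max_score) stop("min_score exceeds the maximum score")
  structure(list(name = name, positions = positions, max_score = max_score,
                 min_score = min_score),
            class = "motif_pattern")
}

pos <- function(prominent = character(0), minor = character(0)) {
  list(prominent = prominent, minor = minor)
}

#' @rdname motif_pattern
#' @export
chd_motif_patterns <- function() {
  list(
    chromo_box = motif_pattern("chromo_box", list(
      pos("Y", "F"), pos(c("L", "F", "Y")), pos(c("L", "I", "V")),
      pos("K"), pos("W", "Y"), pos(minor = c("K", "R")), pos(minor = "G"))),
    galadriel_box = motif_pattern("galadriel_box", list(
      pos("Y", "F"), pos(c("L", "Y")), pos(c("I", "V")),
      pos(minor = "K"), pos("W"), pos(minor = "K"), pos(minor = "G"))),
    tekay_KxLRxK = motif_pattern("tekay_KxLRxK", list(
      pos(c("K", "R")), pos(), pos(c("L", "T")), pos("R"), pos(),
      pos(minor = c("K", "R")))),
    tekay_EExTWExE = motif_pattern("tekay_EExTWExE", list(
      pos("E"), pos("E"), pos(), pos("T"), pos("W"), pos("E"), pos(),
      pos("E")))
  )
}

#' Scan a peptide with a weighted consensus pattern
#'
#' Scores every ungapped placement of the pattern along the peptide: the
#' score of a placement is the sum of weights of satisfied positions
#' (prominent residue matched = 1, minor = 0.5). Returns the best placement,
#' or \code{NULL} when the best score falls below the pattern's
#' \code{min_score}.
#'
#' @param peptide Amino-acid string.
#' @param pattern A \code{motif_pattern}.
#' @param min_score Override of the pattern threshold (use 0 to always get
#'   the best placement).
#' @return \code{NULL}, or list with \code{offset} (1-based), \code{score},
#'   \code{max_score}.
#' @export
motif_scan <- function(peptide, pattern, min_score = pattern$min_score) {
  aa <- strsplit(toupper(peptide), "")[[1L]]
  k <- length(pattern$positions)
  n <- length(aa) - k + 1L
  if (n < 1L) return(NULL)
  best <- -1; best_off <- NA_integer_
  for (off in seq_len(n)) {
    s <- 0
    for (j in seq_len(k)) {
      p <- pattern$positions[[j]]
      r <- aa[off + j - 1L]
      if (r %in% p$prominent) s <- s + 1
      else if (r %in% p$minor) s <- s + 0.5
    }
    if (s > best) { best <- s; best_off <- off }
  }
  if (best < min_score) return(NULL)
  list(offset = best_off, score = best, max_score = pattern$max_score)
}

#' Extract the chromodomain window from a polyprotein
#'
#' The chromodomain of chromoviruses sits C-terminal to the integrase, so
#' candidate windows are taken downstream of \code{int_end_hint} (or within
#' the last 150 aa when no hint is given) and scored by the chromo-box
#' placement; the best-scoring ~56 aa window is returned.
#'
#' @param polyprotein Amino-acid string (>= 100 aa).
#' @param int_end_hint 1-based position of the integrase end, or \code{NULL}.
#' @param window_len Length of the returned peptide window (default 56).
#' @return \code{NULL} if nothing scores above zero, else list with
#'   \code{peptide}, \code{start} (1-based position in the polyprotein) and
#'   \code{score}.
#' @export
extract_chd <- function(polyprotein, int_end_hint = NULL, window_len = 56L) {
  n <- nchar(polyprotein)
  if (n < 100L) stop("polyprotein too short (need >= 100 aa)")
  from <- if (is.null(int_end_hint)) max(1L, n - 150L + 1L)
    else min(max(1L, int_end_hint + 1L), n)
  region <- substring(polyprotein, from, n)
  hit <- motif_scan(region, chd_motif_patterns()$chromo_box, min_score = 0)
  if (is.null(hit) || hit$score <= 0) return(NULL)
  start <- from + hit$offset - 1L
  end <- min(n, start + window_len - 1L)
  list(peptide = substring(polyprotein, start, end), start = start,
       score = hit$score)
}

#' Classify a chromodomain from its aromatic-cage flags
#'
#' Total function of the three presence flags for the Y24, W45 and Y48
#' homologue slots: group I requires both Y24 and W45; group II retains W45
#' but lacks Y24 (Y48 is recorded as evidence but is not decisive); without
#' W45 the domain is unclassified.
#'
#' @param y24,w45,y48 Logical flags.
#' @return \code{"CHD_I"}, \code{"CHD_II"} or \code{"unclassified"}.
#' @export
classify_chd <- function(y24, w45, y48 = NA) {
  if (!w45) return("unclassified")
  if (y24) "CHD_I" else "CHD_II"
}

#' Detect clade-characteristic motifs in a chromodomain peptide
#'
#' Runs each built-in pattern independently (a peptide may satisfy several)
#' and reports the extremely conserved TWE tripeptide whenever present.
#'
#' @param peptide Amino-acid string.
#' @return Character vector of motif names (subset of \code{chromo_box},
#'   \code{galadriel_box}, \code{tekay_KxLRxK}, \code{tekay_EExTWExE},
#'   \code{twe_core}).
#' @export
detect_clade_motifs <- function(peptide) {
  pats <- chd_motif_patterns()
  hits <- names(pats)[!vapply(pats, function(p) {
    is.null(motif_scan(peptide, p))
  }, logical(1))]
  if (grepl("TWE", toupper(peptide), fixed = TRUE)) hits <- c(hits, "twe_core")
  hits
}

#' Full chromodomain call for one peptide
#'
#' Anchors the peptide to the reference numbering by the best chromo-box
#' placement (alignment position 1 = first chromo-box residue = the Y24
#' slot; positions 28 and 31 are the W45 and Y48 slots), derives the
#' aromatic-cage flags, classifies the group, and collects clade motifs.
#'
#' @param peptide Chromodomain-scale peptide (~50-70 aa).
#' @param id Source identifier carried through to the output.
#' @param anchor_offsets Offsets (0-based, relative to the anchor) of the
#'   W45 and Y48 slots; defaults 27 and 30 (alignment positions 28/31).
#' @return Object of class \code{chromodomain_call}.
#' @export
chd_call <- function(peptide, id = NA_character_,
                     anchor_offsets = c(w45 = 27L, y48 = 30L)) {
  aa <- strsplit(toupper(peptide), "")[[1L]]
  hit <- motif_scan(peptide, chd_motif_patterns()$chromo_box, min_score = 0)
  anchor <- if (is.null(hit)) 1L else hit$offset
  at <- function(i) if (i >= 1L && i <= length(aa)) aa[i] else ""
  y24 <- at(anchor) == "Y"
  w45 <- at(anchor + anchor_offsets[["w45"]]) == "W"
  y48 <- at(anchor + anchor_offsets[["y48"]]) == "Y"
  structure(
    list(id = id, peptide = peptide,
         anchor = c(y24 = anchor, w45 = anchor + anchor_offsets[["w45"]],
                    y48 = anchor + anchor_offsets[["y48"]]),
         y24 = y24, w45 = w45, y48 = y48,
         group = classify_chd(y24, w45, y48),
         motif_hits = detect_clade_motifs(peptide)),
    class = "chromodomain_call")
}

#' @export
print.chromodomain_call <- function(x, ...) {
  cat("Chromodomain call", if (!is.na(x$id)) paste0("[", x$id, "]"), ":",
      x$group, "\n  flags: Y24 =", x$y24, ", W45 =", x$w45, ", Y48 =", x$y48,
      "\n  motifs:", if (length(x$motif_hits)) paste(x$motif_hits, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Classify chromodomains for a set of polyproteins
#'
#' Convenience wrapper: extracts the best chromodomain window from each
#' protein and classifies it.
#'
#' @param proteins Named character vector of polyprotein sequences.
#' @param int_end_hints Optional named integer vector of integrase end
#'   positions.
#' @return data.frame with one row per protein: group, flags, motif hits and
#'   window coordinates (NA rows when no window scored).
#' @export
classify_chd_sequences <- function(proteins, int_end_hints = NULL) {
  rows <- lapply(names(proteins), function(id) {
    hint <- if (!is.null(int_end_hints) && id %in% names(int_end_hints)) {
      int_end_hints[[id]]
    }
    win <- extract_chd(proteins[[id]], hint)
    if (is.null(win)) {
      return(data.frame(id = id, group = "unclassified", y24 = NA, w45 = NA,
                        y48 = NA, window_start = NA_integer_,
                        window_end = NA_integer_, motifs = ""))
    }
    call <- chd_call(win$peptide, id)
    data.frame(id = id, group = call$group, y24 = call$y24, w45 = call$w45,
               y48 = call$y48, window_start = win$start,
               window_end = win$start + nchar(win$peptide) - 1L,
               motifs = paste(call$motif_hits, collapse = ","))
  })
  do.call(rbind, rows)
}
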