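# De-novo structural annotation of LTR retroelements. All coordinates in
# this file are 0-based half-open; write_gff3() converts on output.

#' Percent identity of two sequences by global alignment
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap open 2, gap
#' extend 0.5) with identity defined as matches divided by alignment length,
#' so gaps count against identity. This definition is used everywhere the
#' package reports an identity percentage.
#'
#' @param a,b Sequences (DNA strings).
#' @return Percent identity in [0, 100].
#' @export
identity_pct <- function(a, b) {
  if (nchar(a) == nchar(b)) {
    # common fast path: equal-length ungapped alignment of direct repeats
    av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
    direct <- 100 * mean(av == bv)
    if (direct >= 95) return(direct)
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 0.5)
  100 * Biostrings::nmatch(al) / Biostrings::nchar(al)
}

#' Find candidate LTR pairs
#'
#' Seed-and-extend search for long direct repeats: exact shared k-mers anchor
#' candidate diagonals, each diagonal's matched core is extended outward
#' under a +1/-1 score until the score drops, and the repeat boundaries are
#' snapped to the outermost position where both copies start with TG and the
#' best-scoring position where both end with CA (the inverted terminal
#' dinucleotides of LTRs). Candidates are filtered by length and global
#' alignment identity, made non-overlapping, and ranked by identity then
#' length.
#'
#' @param seq DNA string.
#' @param min_len,max_len LTR length window (default 100-1500 bp).
#' @param min_identity Minimum percent identity of the two repeats (80).
#' @param max_interior Maximum interior (between-repeat) span (10 kb).
#' @param k Seed length; defaults to 20, or 12 for inputs under 20 kb.
#' @return List of candidates: \code{ltr5}, \code{ltr3} (0-based half-open
#'   intervals), \code{identity} (percent).
#' @export
find_ltr_pairs <- function(seq, min_len = 100, max_len = 1500,
                           min_identity = 80, max_interior = 10000,
                           k = NULL) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 2 * min_len) return(list())
  if (is.null(k)) k <- if (L < 20000) 12L else 20L
  x <- strsplit(seq, "")[[1L]]
  n_kmer <- L - k + 1L
  kmers <- substring(seq, seq_len(n_kmer), seq_len(n_kmer) + k - 1L)
  groups <- split(seq_len(n_kmer), kmers)
  groups <- groups[lengths(groups) > 1L]
  # collect seed pairs by diagonal (j - i); same-length repeats only
  diag_seeds <- list()
  for (g in groups) {
    if (length(g) > 12L) g <- g[seq_len(12L)]   # repetitive k-mer guard
    for (ii in seq_len(length(g) - 1L)) {
      for (jj in (ii + 1L):length(g)) {
        d <- g[jj] - g[ii]
        if (d < min_len + 1L || d > max_len + max_interior) next
        key <- as.character(d)
        diag_seeds[[key]] <- c(diag_seeds[[key]], g[ii])
      }
    }
  }
  cands <- list()
  for (key in names(diag_seeds)) {
    d <- as.integer(key)
    starts <- sort(unique(diag_seeds[[key]]))
    core_start <- min(starts)            # 1-based
    core_end <- max(starts) + k - 1L
    # score-based outward extension (match +1, mismatch -1, stop at drop 8)
    ext_left <- core_start
    sc <- 0; best <- 0
    p <- core_start - 1L
    while (p >= 1L && p + d <= L && sc > best - 8) {
      sc <- sc + (if (x[p] == x[p + d]) 1 else -1)
      if (sc > best) { best <- sc; ext_left <- p }
      p <- p - 1L
    }
    ext_right <- core_end
    sc <- 0; best <- 0
    p <- core_end + 1L
    while (p + d <= L && sc > best - 8) {
      sc <- sc + (if (x[p] == x[p + d]) 1 else -1)
      if (sc > best) { best <- sc; ext_right <- p }
      p <- p + 1L
    }
    if (ext_right - ext_left + 1L < min_len) next
    # candidate boundaries: both copies start "TG" / end "CA"
    win <- ext_left:ext_right
    match_sc <- ifelse(x[win] == x[win + d], 1, -1)
    cs <- c(0, cumsum(match_sc))         # segment score via prefix sums
    tg <- win[x[win] == "T" & x[pmin(win + 1L, L)] == "G" &
              x[pmin(win + d, L)] == "T" & x[pmin(win + d + 1L, L)] == "G"]
    ca <- win[x[win] == "A" & x[pmax(win - 1L, 1L)] == "C" &
              x[pmin(win + d, L)] == "A" & x[pmax(win + d - 1L, 1L)] == "C"]
    if (!length(tg) || !length(ca)) next
    best_sc <- -Inf; bs <- NA; be <- NA
    for (s in tg) {
      ends <- ca[ca - s + 1L >= min_len & ca - s + 1L <= max_len]
      if (!length(ends)) next
      segs <- cs[ends - ext_left + 2L] - cs[s - ext_left + 1L]
      o <- order(-segs, ends)            # max score, innermost end on ties
      e <- ends[o[1L]]; scv <- segs[o[1L]]
      if (scv > best_sc + 1e-9 ||
          (abs(scv - best_sc) <= 1e-9 && (is.na(bs) || s < bs))) {
        best_sc <- scv; bs <- s; be <- e
      }
    }
    if (is.na(bs)) next
    len <- be - bs + 1L
    interior <- d - len
    if (interior < 1L || interior > max_interior) next
    ltr5 <- substring(seq, bs, be)
    ltr3 <- substring(seq, bs + d, be + d)
    idt <- identity_pct(ltr5, ltr3)
    if (idt < min_identity) next
    cands[[length(cands) + 1L]] <- list(
      ltr5 = c(bs - 1L, be), ltr3 = c(bs + d - 1L, be + d),
      identity = idt, length = len)
  }
  if (!length(cands)) return(list())
  # rank by identity then length; greedy non-overlapping selection
  ord <- order(-vapply(cands, `[[`, numeric(1), "identity"),
               -vapply(cands, `[[`, numeric(1), "length"))
  chosen <- list()
  occupied <- matrix(numeric(0), ncol = 2)
  for (i in ord) {
    cd <- cands[[i]]
    span <- c(cd$ltr5[1L], cd$ltr3[2L])
    clash <- nrow(occupied) > 0 &&
      any(occupied[, 1] < span[2] & span[1] < occupied[, 2])
    if (!clash) {
      chosen[[length(chosen) + 1L]] <- cd
      occupied <- rbind(occupied, span)
    }
  }
  chosen
}

#' Inverted terminal repeat check
#'
#' @param ltr_seq LTR sequence (>= 4 bp).
#' @return \code{TRUE} iff the sequence starts with TG and ends with CA.
#' @export
check_itr <- function(ltr_seq) {
  ltr_seq <- toupper(ltr_seq)
  n <- nchar(ltr_seq)
  if (n < 4) stop("LTR shorter than 4 bp")
  substring(ltr_seq, 1, 2) == "TG" && substring(ltr_seq, n - 1, n) == "CA"
}

#' Detect a target-site duplication
#'
#' Longest exact match (length within \code{len_range}) between the sequence
#' immediately 5' of the element and the sequence immediately 3' of it; on
#' ties the longer match wins.
#'
#' @param seq Genomic DNA string.
#' @param element_interval 0-based half-open interval of the element
#'   (including both LTRs).
#' @param len_range Allowed TSD lengths, default 4-6.
#' @return The TSD string, or \code{NULL}.
#' @export
detect_tsd <- function(seq, element_interval, len_range = c(4L, 6L)) {
  seq <- toupper(seq)
  start <- element_interval[[1L]]; end <- element_interval[[2L]]
  for (l in rev(seq(len_range[1L], len_range[2L]))) {
    if (start - l < 0 || end + l > nchar(seq)) next
    left <- substring(seq, start - l + 1L, start)
    right <- substring(seq, end + 1L, end + l)
    if (left == right) return(left)
  }
  NULL
}

#' Synthetic tRNA-Met 3'-end fixture
#'
#' The default (and only shipped) entry of the tRNA 3'-end library used for
#' primer-binding-site detection: a synthetic stand-in for a plant initiator
#' tRNA-Met 3' end (DNA alphabet, ending in the universal CCA), shared by
#' the genome simulator so planted PBS features are detectable. Real
#' screens should supply their own library via the \code{trna_3ends}
#' argument of \code{\link{find_pbs}}.
#'
#' @return Named character vector of tRNA 3'-end sequences.
#' @export
default_trna_3ends <- function() {
  c(tRNA_Met = "GTCGGTTCGATCCCGACCCA")
}

#' Find a primer binding site downstream of the 5' LTR
#'
#' The PBS anneals to the 3' end of a host tRNA (tRNA-Met for these
#' elements): the function looks for the longest reverse-complement match
#' between the region starting at most \code{max_spacer} bases after the 5'
#' LTR and the 3'-terminal bases of any library tRNA.
#'
#' @param seq Genomic DNA string.
#' @param ltr5_end 0-based position just past the 5' LTR.
#' @param trna_3ends Named vector of tRNA 3'-end sequences (DNA alphabet,
#'   5' to 3').
#' @param min_len Minimum match length (default 11).
#' @param max_spacer Maximum spacer between LTR and PBS (default 2).
#' @return \code{NULL}, or list with \code{interval} (0-based half-open),
#'   \code{trna}, \code{match_len}, \code{spacer}.
#' @export
find_pbs <- function(seq, ltr5_end, trna_3ends = default_trna_3ends(),
                     min_len = 11, max_spacer = 2) {
  if (length(trna_3ends) == 0L) stop("tRNA 3'-end library is empty")
  seq <- toupper(seq)
  best <- NULL
  for (id in names(trna_3ends)) {
    trna <- toupper(gsub("U", "T", trna_3ends[[id]]))
    tl <- nchar(trna)
    for (spacer in 0:max_spacer) {
      start <- ltr5_end + spacer        # 0-based
      for (l in seq(min(tl, nchar(seq) - start), min_len)) {
        if (l < min_len) break
        region <- substring(seq, start + 1L, start + l)
        expected <- revcomp(substring(trna, tl - l + 1L, tl))
        if (region == expected) {
          if (is.null(best) || l > best$match_len) {
            best <- list(interval = c(start, start + l), trna = id,
                         match_len = l, spacer = spacer)
          }
          break
        }
      }
    }
  }
  best
}

#' Find a polypurine tract upstream of the 3' LTR
#'
#' Longest run of purines (A/G) of at least \code{min_len} bases ending at
#' most \code{max_gap} bases before the 3' LTR start.
#'
#' @param seq Genomic DNA string.
#' @param ltr3_start 0-based start of the 3' LTR.
#' @param min_len Minimum run length (default 12).
#' @param max_gap Maximum gap to the LTR (default 2).
#' @return \code{NULL}, or list with \code{interval} and \code{length}.
#' @export
find_ppt <- function(seq, ltr3_start, min_len = 12, max_gap = 2) {
  seq <- toupper(seq)
  lo <- max(0L, ltr3_start - 250L)
  region <- strsplit(substring(seq, lo + 1L, ltr3_start), "")[[1L]]
  if (length(region) < min_len) return(NULL)
  pur <- region %in% c("A", "G")
  r <- rle(pur)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= min_len &
                (length(region) - ends) <= max_gap)
  if (!length(ok)) return(NULL)
  i <- ok[which.max(r$lengths[ok])]
  list(interval = c(lo + starts[i] - 1L, lo + ends[i]),
       length = r$lengths[i])
}

#' Find open reading frames
#'
#' ATG-to-stop spans of at least \code{min_len_nt} on both strands (stop
#' codon included), reported in forward-strand coordinates, sorted by start.
#'
#' @param seq DNA string.
#' @param min_len_nt Minimum ORF length in nucleotides (default 300).
#' @param code A \code{genetic_code}.
#' @return List of ORFs: \code{interval} (0-based half-open, forward
#'   strand), \code{strand} (+/-), \code{frame} (0-2 on its strand).
#' @export
find_orfs <- function(seq, min_len_nt = 300, code = default_code()) {
  seq <- toupper(seq)
  L <- nchar(seq)
  scan_strand <- function(s, strand) {
    out <- list()
    for (frame in 0:2) {
      n_codons <- (nchar(s) - frame) %/% 3L
      if (n_codons < 1L) next
      cpos <- frame + seq(1L, by = 3L, length.out = n_codons)
      codons <- substring(s, cpos, cpos + 2L)
      is_stop <- codons %in% code$stops
      is_atg <- codons == "ATG"
      open <- NA_integer_
      for (i in seq_len(n_codons)) {
        if (is.na(open) && is_atg[i]) open <- i
        if (!is.na(open) && is_stop[i]) {
          len <- (i - open + 1L) * 3L
          if (len >= min_len_nt) {
            s0 <- cpos[open] - 1L; e0 <- cpos[i] + 2L
            iv <- if (strand == "+") c(s0, e0) else c(L - e0, L - s0)
            out[[length(out) + 1L]] <- list(interval = iv, strand = strand,
                                            frame = frame)
          }
          open <- NA_integer_
        }
      }
    }
    out
  }
  orfs <- c(scan_strand(seq, "+"), scan_strand(revcomp(seq), "-"))
  orfs[order(vapply(orfs, function(o) o$interval[1L], numeric(1)))]
}

#' Translate a pseudo-ORF through its stop codons
#'
#' Reconstructs the conceptual translation of a coding region whose frame is
#' intact but which is interrupted by in-frame stop codons (as in degenerate
#' elements): translation continues through stops, recording their count and
#' positions. Frameshifts are not repaired; the in-frame region must be a
#' whole number of codons.
#'
#' @param seq DNA string.
#' @param frame Frame offset 0-2.
#' @param code A \code{genetic_code}.
#' @return List with \code{peptide} (stops as \code{*}),
#'   \code{stop_positions} (1-based codon indices, excluding a terminal
#'   stop) and \code{n_stops}.
#' @export
reconstruct_pseudo_orf <- function(seq, frame = 0, code = default_code()) {
  seq <- toupper(seq)
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  body <- substring(seq, frame + 1L, nchar(seq))
  if (nchar(body) %% 3L != 0L) {
    stop("region is out of frame: ", nchar(body), " nt is not a whole number",
         " of codons")
  }
  pep <- translate_dna(body, code)
  aa <- strsplit(pep, "")[[1L]]
  stops <- which(aa == "*")
  stops <- stops[stops != length(aa)]   # a terminal stop is not an interruption
  list(peptide = pep, stop_positions = stops, n_stops = length(stops))
}

CANONICAL_DOMAIN_ORDER <- c("CCHC", "PR", "RT", "RNH", "INT", "CHD")

#' Check Gag-Pol domain order
#'
#' @param detected_domains Character vector of domain labels in detected
#'   order (subset of CCHC, PR, RT, RNH, INT, CHD).
#' @return List with \code{ok} (detected labels form a subsequence of the
#'   canonical order), \code{canonical}, \code{detected}.
#' @export
check_domain_order <- function(detected_domains) {
  ranks <- match(detected_domains, CANONICAL_DOMAIN_ORDER)
  ok <- !anyNA(ranks) && !is.unsorted(ranks, strictly = TRUE)
  list(ok = ok, canonical = CANONICAL_DOMAIN_ORDER, detected = detected_domains)
}

# The CCHC Zn-finger knuckle: C-X2-C-X4-H-X4-C.
CCHC_REGEX <- "C.{2}C.{4}H.{4}C"

# Sentinel peptides used by the synthetic genomes to mark domains the real
# pipeline would locate by similarity search (out of scope here); CCHC and
# CHD are found by their true sequence patterns instead.
DOMAIN_SENTINELS <- c(
  PR = "SPVALLDTGADDTV",
  RT = "KGLYEYLVMPFGLKNA",
  RNH = "HIDGSAKGNPGPAGAG",
  INT = "AGHLSGHQGVKRTLD"
)

#' Locate Gag-Pol domains in a polyprotein translation
#'
#' CCHC is located by its C-X2-C-X4-H-X4-C pattern and the chromodomain by
#' chromo-box motif scanning; PR/RT/RNH/INT are located by the package's
#' sentinel peptides (similarity-search domain assignment is out of scope).
#'
#' @param peptide Polyprotein amino-acid string.
#' @return data.frame with columns \code{domain} and \code{aa_pos} (1-based
#'   start), sorted by position.
#' @export
scan_domains <- function(peptide) {
  peptide <- toupper(peptide)
  rows <- list()
  m <- regexpr(CCHC_REGEX, peptide)
  if (m > 0) rows[[length(rows) + 1L]] <- data.frame(domain = "CCHC", aa_pos = as.integer(m))
  for (dm in names(DOMAIN_SENTINELS)) {
    i <- regexpr(DOMAIN_SENTINELS[[dm]], peptide, fixed = TRUE)
    if (i > 0) rows[[length(rows) + 1L]] <- data.frame(domain = dm, aa_pos = as.integer(i))
  }
  hit <- motif_scan(peptide, chd_motif_patterns()$chromo_box)
  if (is.null(hit)) hit <- motif_scan(peptide, chd_motif_patterns()$galadriel_box)
  if (!is.null(hit)) {
    rows[[length(rows) + 1L]] <- data.frame(domain = "CHD", aa_pos = hit$offset)
  }
  if (!length(rows)) {
    return(data.frame(domain = character(0), aa_pos = integer(0)))
  }
  df <- do.call(rbind, rows)
  df[order(df$aa_pos), , drop = FALSE]
}

#' Annotate LTR retroelements in a genomic sequence
#'
#' Full structural annotation: LTR pair search, inverted-termini check,
#' target-site duplication, primer binding site, polypurine tract, ORFs in
#' the interior, and Gag-Pol domain order from the longest ORF's
#' translation. An element is flagged \code{intact} when it has TG...CA
#' termini, a TSD, at least one ORF and domains in canonical order.
#'
#' @param seq Genomic DNA string.
#' @param seq_id Sequence identifier for reports.
#' @param trna_3ends tRNA 3'-end library for PBS detection.
#' @param ... Passed to \code{\link{find_ltr_pairs}}.
#' @return List of \code{element_annotation} objects (possibly empty).
#' @export
annotate_genome <- function(seq, seq_id = "seq", trna_3ends = default_trna_3ends(),
                            ...) {
  seq <- toupper(seq)
  pairs <- find_ltr_pairs(seq, ...)
  lapply(pairs, function(cd) {
    element <- c(cd$ltr5[1L], cd$ltr3[2L])
    ltr5_seq <- substring(seq, cd$ltr5[1L] + 1L, cd$ltr5[2L])
    ltr3_seq <- substring(seq, cd$ltr3[1L] + 1L, cd$ltr3[2L])
    itr_ok <- check_itr(ltr5_seq) && check_itr(ltr3_seq)
    tsd <- detect_tsd(seq, element)
    pbs <- find_pbs(seq, cd$ltr5[2L], trna_3ends)
    ppt <- find_ppt(seq, cd$ltr3[1L])
    interior <- substring(seq, cd$ltr5[2L] + 1L, cd$ltr3[1L])
    orfs <- find_orfs(interior)
    orfs <- lapply(orfs, function(o) {
      o$interval <- o$interval + cd$ltr5[2L]
      o$pseudo <- NULL
      o
    })
    domains <- data.frame(domain = character(0), aa_pos = integer(0))
    if (length(orfs)) {
      lens <- vapply(orfs, function(o) diff(o$interval), numeric(1))
      main <- orfs[[which.max(lens)]]
      orf_seq <- substring(seq, main$interval[1L] + 1L, main$interval[2L])
      if (main$strand == "-") orf_seq <- revcomp(orf_seq)
      pep <- reconstruct_pseudo_orf(orf_seq, 0)
      domains <- scan_domains(pep$peptide)
    }
    ord <- check_domain_order(domains$domain)
    structure(
      list(seq_id = seq_id, element = element,
           ltr5 = cd$ltr5, ltr3 = cd$ltr3, ltr_identity = cd$identity,
           itr_ok = itr_ok, tsd = tsd, pbs = pbs, ppt = ppt, orfs = orfs,
           domains = domains, domain_order_ok = ord$ok,
           intact = itr_ok && !is.null(tsd) && length(orfs) > 0 && ord$ok),
      class = "element_annotation")
  })
}

#' @export
print.element_annotation <- function(x, ...) {
  g <- to_gff_coords(x$element)
  cat(sprintf("LTR retroelement on %s: %d..%d (%d bp)%s\n", x$seq_id,
              g[["start"]], g[["end"]], diff(x$element),
              if (x$intact) " [intact]" else ""))
  cat(sprintf("  LTRs %d/%d bp, identity %.1f%%, TG...CA termini: %s\n",
              diff(x$ltr5), diff(x$ltr3), x$ltr_identity, x$itr_ok))
  cat("  TSD:", if (is.null(x$tsd)) "not detected" else x$tsd, "\n")
  if (!is.null(x$pbs)) cat(sprintf("  PBS: %d bp match to %s, spacer %d\n",
                                   x$pbs$match_len, x$pbs$trna, x$pbs$spacer))
  if (!is.null(x$ppt)) cat(sprintf("  PPT: %d purines\n", x$ppt$length))
  cat("  domains:", if (nrow(x$domains)) paste(x$domains$domain, collapse = "-")
      else "none", "\n")
  invisible(x)
}

#' Element annotation summary table
#'
#' One row per element with the columns of a structural-characteristics
#' table: element size, LTR sizes, LTR identity percent, TSD and ITR status.
#'
#' @param annotations List of \code{element_annotation}.
#' @return data.frame (1-based inclusive coordinates).
#' @export
annotation_table <- function(annotations) {
  do.call(rbind, lapply(annotations, function(a) {
    g <- to_gff_coords(a$element)
    data.frame(seq_id = a$seq_id, start = g[["start"]], end = g[["end"]],
               size_bp = diff(a$element),
               ltr5_bp = diff(a$ltr5), ltr3_bp = diff(a$ltr3),
               ltr_identity = round(a$ltr_identity, 1),
               tsd = if (is.null(a$tsd)) "ND" else a$tsd,
               itr = if (a$itr_ok) "TG...CA" else "ND",
               intact = a$intact)
  }))
}
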