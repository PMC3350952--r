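#' Specification of a synthetic LTR retroelement
#'
#' Describes one element to plant in a toy genome, mirroring the structural
#' feature inventory of chromodomain-containing Gypsy elements: paired LTRs
#' with TG...CA termini at a configurable divergence, a 4-6 bp target-site
#' duplication, a primer binding site complementary to the library tRNA-Met
#' 3' end (11-13 bp, spacer 0-2), a polypurine tract (>= 12 bp), and a
#' single Gag-Pol ORF carrying the canonical CCHC-PR-RT-RNH-INT-CHD domain
#' order with a group I or II chromodomain and optional clade motifs.
#'
#' @param ltr_len LTR length in bp (>= 100).
#' @param ltr_divergence Fraction of mutated LTR positions in [0, 0.5].
#' @param tsd TSD string (4-6 bp), or \code{NULL} for no TSD.
#' @param pbs_len PBS length (11-13).
#' @param pbs_spacer Spacer between 5' LTR and PBS (0-2).
#' @param ppt_len Polypurine tract length (>= 12).
#' @param orf_domains Ordered subset of CCHC, PR, RT, RNH, INT, CHD.
#' @param chd_group \code{"CHD_I"}, \code{"CHD_II"} or \code{"none"}.
#' @param clade_motifs Subset of \code{c("galadriel_box", "tekay_KxLRxK",
#'   "tekay_EExTWExE")} to embed in the chromodomain peptide.
#' @return Object of class \code{element_spec}.
#' @export
element_spec <- function(ltr_len = 300, ltr_divergence = 0.01, tsd = "CCTAT",
                         pbs_len = 13, pbs_spacer = 1, ppt_len = 14,
                         orf_domains = c("CCHC", "PR", "RT", "RNH", "INT", "CHD"),
                         chd_group = c("CHD_I", "CHD_II", "none"),
                         clade_motifs = character(0)) {
  chd_group <- match.arg(chd_group)
  if (ltr_len < 100) stop("ltr_len must be >= 100")
  if (ltr_divergence < 0 || ltr_divergence > 0.5) {
    stop("ltr_divergence must lie in [0, 0.5]")
  }
  if (!is.null(tsd)) {
    tsd <- toupper(tsd)
    if (!nchar(tsd) %in% 4:6) stop("TSD length must be 4, 5 or 6")
  }
  if (!pbs_len %in% 11:13) stop("pbs_len must be 11-13")
  if (!pbs_spacer %in% 0:2) stop("pbs_spacer must be 0-2")
  if (ppt_len < 12) stop("ppt_len must be >= 12")
  ranks <- match(orf_domains, CANONICAL_DOMAIN_ORDER)
  if (anyNA(ranks) || is.unsorted(ranks, strictly = TRUE)) {
    stop("orf_domains must respect the canonical order ",
         paste(CANONICAL_DOMAIN_ORDER, collapse = " < "))
  }
  if (chd_group == "none" && "CHD" %in% orf_domains) {
    orf_domains <- setdiff(orf_domains, "CHD")
  }
  structure(list(ltr_len = ltr_len, ltr_divergence = ltr_divergence,
                 tsd = tsd, pbs_len = pbs_len, pbs_spacer = pbs_spacer,
                 ppt_len = ppt_len, orf_domains = orf_domains,
                 chd_group = chd_group, clade_motifs = clade_motifs),
            class = "element_spec")
}

#' Default element inventory for synthetic genomes
#'
#' Three specs exercising the feature combinations of the target element
#' family: a 5 bp CCTAT TSD with a 13 bp PBS (1 bp spacer) and 14-purine
#' PPT on a group I element; a 6 bp GTTTCT TSD with a 12 bp PBS (2 bp
#' spacer) on a group II element with Tekay motifs; and a 5 bp TSD element
#' with an 11 bp zero-spacer PBS and a 13-purine PPT.
#'
#' @return List of \code{element_spec}.
#' @export
default_element_specs <- function() {
  list(
    element_spec(ltr_len = 300, ltr_divergence = 0.003, tsd = "CCTAT",
                 pbs_len = 13, pbs_spacer = 1, ppt_len = 14,
                 chd_group = "CHD_I"),
    element_spec(ltr_len = 220, ltr_divergence = 0.014, tsd = "GTTTCT",
                 pbs_len = 12, pbs_spacer = 2, ppt_len = 14,
                 chd_group = "CHD_II",
                 clade_motifs = c("tekay_KxLRxK", "tekay_EExTWExE")),
    element_spec(ltr_len = 233, ltr_divergence = 0.013, tsd = "TGCCC",
                 pbs_len = 11, pbs_spacer = 0, ppt_len = 13,
                 chd_group = "CHD_I")
  )
}

#' Mutate an LTR into a diverged pair
#'
#' Each position outside the TG/CA terminal dinucleotides is mutated to a
#' different base with probability \code{divergence}, so the expected
#' pairwise identity of the two copies is 1 - divergence (up to the
#' protected termini).
#'
#' @param ltr LTR sequence (TG...CA).
#' @param divergence Per-position mutation probability in [0, 0.5].
#' @param seed Optional integer seed.
#' @return List with \code{ltr5} (the input) and \code{ltr3} (mutated copy).
#' @export
mutate_ltr_pair <- function(ltr, divergence, seed = NULL) {
  if (divergence < 0 || divergence > 0.5) stop("divergence must lie in [0, 0.5]")
  with_local_seed(seed, {
    x <- strsplit(toupper(ltr), "")[[1L]]
    n <- length(x)
    mutable <- setdiff(seq_len(n), c(1L, 2L, n - 1L, n))
    hit <- mutable[stats::runif(length(mutable)) < divergence]
    for (i in hit) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1L)
    list(ltr5 = ltr, ltr3 = paste(x, collapse = ""))
  })
}

# Encode a peptide into DNA deterministically (first sense codon per residue).
encode_peptide <- function(peptide, code = default_code()) {
  aa <- strsplit(toupper(peptide), "")[[1L]]
  tab <- vapply(split(code$sense, code$table[code$sense]), `[[`, character(1), 1L)
  codons <- tab[aa]
  if (anyNA(codons)) stop("cannot encode residue ", aa[which(is.na(codons))[1L]])
  paste(codons, collapse = "")
}

# Build the chromodomain peptide for a spec: chromo-box at alignment
# position 1 (the Y24 slot), W at position 28 (W45), Y at 31 (Y48), the
# conserved TWE core, and any requested clade motifs. CHD_II drops the
# position-1 tyrosine.
chd_peptide <- function(group, clade_motifs = character(0)) {
  box <- if ("galadriel_box" %in% clade_motifs) "YLVKWKG" else "YLIKWKG"
  aa <- strsplit(paste0(box, "ADEGNSTQADEGNSTQADEG"), "")[[1L]]  # pos 1..27
  aa <- c(aa, "W", "E", "T", "Y")                                 # pos 28..31
  tail <- strsplit("DNSTAGEQDNSTAGEQDNSTAGEQD", "")[[1L]]         # pos 32..56
  if ("tekay_EExTWExE" %in% clade_motifs) {
    tail[1:8] <- strsplit("EELTWEAE", "")[[1L]]
  } else {
    tail[1:3] <- c("T", "W", "E")    # the near-universal TWE core
  }
  if ("tekay_KxLRxK" %in% clade_motifs) {
    tail[12:17] <- strsplit("KALRQK", "")[[1L]]
  }
  aa <- c(aa, tail)
  if (group == "CHD_II") aa[1L] <- "S"
  paste(aa, collapse = "")
}

# Assemble one element sequence plus relative feature coordinates
# (0-based half-open, relative to the element start).
assemble_element <- function(spec, seed = NULL, code = default_code()) {
  with_local_seed(seed, {
    ltr <- paste0("TG", random_dna(spec$ltr_len - 4L), "CA")
    pair <- mutate_ltr_pair(ltr, spec$ltr_divergence)
    trna <- default_trna_3ends()[[1L]]
    pbs <- revcomp(substring(trna, nchar(trna) - spec$pbs_len + 1L, nchar(trna)))
    spacer <- random_dna(spec$pbs_spacer)
    # Gag-Pol peptide: start codon, fillers, domain marks in canonical order
    filler <- function(n) {
      paste(sample(c("A", "D", "E", "G", "H", "I", "L", "N", "P", "Q", "S",
                     "T", "V"), n, replace = TRUE), collapse = "")
    }
    parts <- c("M", filler(20))
    dom_aa <- list()
    for (dm in spec$orf_domains) {
      pepd <- switch(dm,
        CCHC = "CAACGRSDHGAEDC",             # matches C-X2-C-X4-H-X4-C
        PR = DOMAIN_SENTINELS[["PR"]],
        RT = DOMAIN_SENTINELS[["RT"]],
        RNH = DOMAIN_SENTINELS[["RNH"]],
        INT = DOMAIN_SENTINELS[["INT"]],
        CHD = chd_peptide(spec$chd_group, spec$clade_motifs))
      dom_aa[[dm]] <- c(start = sum(nchar(parts)) + 1L, len = nchar(pepd))
      parts <- c(parts, pepd, filler(15))
    }
    pep <- paste(parts, collapse = "")
    orf_dna <- paste0(encode_peptide(pep, code), "TAA")
    ppt <- paste(sample(c("A", "G"), spec$ppt_len, replace = TRUE), collapse = "")
    # untranslated spacers are shaped so planted feature boundaries stay
    # unambiguous: the base after the PBS must not extend the tRNA
    # complementarity, an in-frame stop sits right before the ORF's ATG so
    # the detected ORF start is exact, and a pyrimidine precedes the PPT so
    # the purine run has the planted length
    trna_next <- revcomp(substring(trna, nchar(trna) - spec$pbs_len,
                                   nchar(trna) - spec$pbs_len))
    utr5 <- paste0("C", substring(random_dna(36L), 1L, 36L), "TAA")
    if (substring(utr5, 1L, 1L) == trna_next) utr5 <- sub("^C", "G", utr5)
    utr3 <- paste0(random_dna(29L), "C")
    elem <- paste0(pair$ltr5, spacer, pbs, utr5, orf_dna, utr3, ppt, pair$ltr3)
    L5 <- nchar(pair$ltr5)
    pbs_start <- L5 + spec$pbs_spacer
    orf_start <- pbs_start + spec$pbs_len + 40L
    orf_len <- nchar(orf_dna)
    ppt_start <- orf_start + orf_len + 30L
    ltr3_start <- ppt_start + spec$ppt_len
    list(seq = elem,
         features = list(
           ltr5 = c(0L, L5),
           pbs = c(pbs_start, pbs_start + spec$pbs_len),
           orf = c(orf_start, orf_start + orf_len),
           ppt = c(ppt_start, ppt_start + spec$ppt_len),
           ltr3 = c(ltr3_start, ltr3_start + nchar(pair$ltr3))),
         domain_aa = dom_aa)
  })
}

#' Plant synthetic LTR retroelements in a random genome
#'
#' Builds an i.i.d. uniform-ACGT background and inserts each element (5'
#' LTR + spacer + PBS + Gag-Pol ORF + PPT + 3' LTR, flanked on both sides by
#' its TSD) at non-overlapping positions with at least 1 kb margins. The
#' returned truth records exact coordinates for every planted feature.
#'
#' @param background_len Background length in bp (before insertions).
#' @param specs List of \code{element_spec} (default
#'   \code{\link{default_element_specs}}).
#' @param seed Integer seed; per-element child streams are derived from it.
#' @param margin Minimum distance between elements and to the sequence ends.
#' @return Object of class \code{synthetic_genome}: list with \code{seq} and
#'   \code{truth} (per element: spec, insertion point, element interval and
#'   absolute feature intervals, all 0-based half-open).
#' @export
plant_elements <- function(background_len, specs = default_element_specs(),
                           seed = NULL, margin = 1000L) {
  parts <- lapply(seq_along(specs), function(i) {
    assemble_element(specs[[i]], seed = if (is.null(seed)) NULL
                     else derive_seed(seed, i))
  })
  total_elem <- sum(vapply(parts, function(p) nchar(p$seq), numeric(1))) +
    sum(vapply(specs, function(s) 2L * nchar(s$tsd %||% ""), numeric(1)))
  need <- (length(specs) + 1L) * margin + total_elem
  if (background_len < need) {
    stop("background too short: need at least ", need, " bp for ",
         length(specs), " elements with ", margin, " bp margins")
  }
  with_local_seed(if (is.null(seed)) NULL else derive_seed(seed, 0L), {
    bg <- random_dna(background_len)
    # choose insertion points in the background, left to right
    gaps <- background_len - 2L * margin
    ok <- FALSE
    for (try in 1:50) {
      pts <- sort(sample(seq(margin, background_len - margin), length(specs)))
      if (length(pts) < 2L || min(diff(pts)) >= margin) { ok <- TRUE; break }
    }
    if (!ok && length(specs) >= 2L) stop("could not place elements without overlap")
    genome <- ""
    truth <- list()
    prev <- 0L
    offset <- 0L
    for (i in seq_along(specs)) {
      spec <- specs[[i]]
      tsd <- spec$tsd %||% ""
      insert <- paste0(tsd, parts[[i]]$seq, tsd)
      genome <- paste0(genome, substring(bg, prev + 1L, pts[i]), insert)
      elem_start <- pts[i] + offset + nchar(tsd)
      feats <- lapply(parts[[i]]$features, function(iv) iv + elem_start)
      truth[[i]] <- list(
        spec = spec, insertion_point = pts[i],
        element = c(elem_start, elem_start + nchar(parts[[i]]$seq)),
        features = feats, domain_aa = parts[[i]]$domain_aa)
      offset <- offset + nchar(insert)
      prev <- pts[i]
    }
    genome <- paste0(genome, substring(bg, prev + 1L, background_len))
    structure(list(seq = genome, truth = truth), class = "synthetic_genome")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("Synthetic genome:", nchar(x$seq), "bp,", length(x$truth),
      "planted element(s)\n")
  for (tr in x$truth) {
    cat(sprintf("  element at [%d, %d) tsd=%s ltr=%d bp\n",
                tr$element[1L], tr$element[2L], tr$spec$tsd %||% "none",
                tr$spec$ltr_len))
  }
  invisible(x)
}
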