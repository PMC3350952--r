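# Coordinate conventions: every interval inside the package is 0-based
# half-open [start, end); everything emitted (GFF3, reports) is 1-based
# inclusive. These two helpers are the only conversion layer.

#' Convert internal to emitted coordinates and back
#'
#' Internal intervals are 0-based half-open; GFF3/report coordinates are
#' 1-based inclusive. The two functions are inverse bijections.
#'
#' @param iv Numeric vector \code{c(start, end)} (internal), or matrix with
#'   two columns.
#' @return Converted interval(s).
#' @export
to_gff_coords <- function(iv) {
  if (is.matrix(iv)) return(cbind(start = iv[, 1L] + 1L, end = iv[, 2L]))
  c(start = iv[[1L]] + 1L, end = iv[[2L]])
}

#' @rdname to_gff_coords
#' @export
from_gff_coords <- function(iv) {
  if (is.matrix(iv)) return(cbind(start = iv[, 1L] - 1L, end = iv[, 2L]))
  c(start = iv[[1L]] - 1L, end = iv[[2L]])
}

#' Write element annotations as GFF3
#'
#' Emits one \code{LTR_retrotransposon} feature per annotated element with
#' child \code{long_terminal_repeat}, \code{primer_binding_site},
#' \code{RR_tract} (polypurine tract) and \code{ORF} features, plus a
#' \code{Note} carrying the target-site duplication when one was detected.
#' Output goes through \code{rtracklayer::export}, so coordinates follow the
#' GFF3 1-based inclusive convention.
#'
#' @param annotations List of \code{element_annotation} objects
#'   (see \code{\link{annotate_genome}}).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gff3 <- function(annotations, path) {
  if (length(annotations) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  rows <- list()
  add <- function(seqid, iv, type, id, parent = NA_character_, note = NA_character_) {
    g <- to_gff_coords(iv)
    rows[[length(rows) + 1L]] <<- data.frame(
      seqid = seqid, start = g[["start"]], end = g[["end"]], type = type,
      ID = id, Parent = parent, Note = note, stringsAsFactors = FALSE)
  }
  for (k in seq_along(annotations)) {
    a <- annotations[[k]]
    eid <- sprintf("%s_elem%02d", a$seq_id, k)
    note <- if (is.null(a$tsd)) NA_character_ else
      paste0("target_site_duplication=", a$tsd)
    add(a$seq_id, a$element, "LTR_retrotransposon", eid, note = note)
    add(a$seq_id, a$ltr5, "long_terminal_repeat", paste0(eid, "_ltr5"), eid)
    add(a$seq_id, a$ltr3, "long_terminal_repeat", paste0(eid, "_ltr3"), eid)
    if (!is.null(a$pbs)) {
      add(a$seq_id, a$pbs$interval, "primer_binding_site", paste0(eid, "_pbs"), eid)
    }
    if (!is.null(a$ppt)) {
      add(a$seq_id, a$ppt$interval, "RR_tract", paste0(eid, "_ppt"), eid)
    }
    for (j in seq_along(a$orfs)) {
      add(a$seq_id, a$orfs[[j]]$interval, "ORF", sprintf("%s_orf%d", eid, j), eid)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    type = df$type)
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), NA_character_, df$Parent)
  S4Vectors::mcols(gr)$Note <- df$Note
  S4Vectors::mcols(gr)$source <- "chromosel"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
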