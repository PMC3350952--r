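#' Cluster elements into families
#'
#' Single-linkage clustering on pairwise global-alignment identity: elements
#' sharing more than \code{threshold} percent nucleotide identity join the
#' same family. Each family's exemplar is its first member (input order);
#' members whose LTR identity with the exemplar's LTR falls below
#' \code{ltr_threshold} are split off into their own families.
#'
#' @param elements Named character vector of element DNA sequences.
#' @param threshold Family identity threshold in percent (default 80).
#' @param ltr_threshold Minimum LTR identity with the exemplar (default 50).
#' @param ltrs Optional named character vector of 5' LTR sequences (same
#'   names); when absent the LTR criterion is skipped.
#' @return List of family assignments: \code{family_id}, \code{members},
#'   \code{mean_identity}, \code{mean_ltr_identity} (NA when unavailable).
#' @export
cluster_families <- function(elements, threshold = 80, ltr_threshold = 50,
                             ltrs = NULL) {
  ids <- names(elements)
  if (is.null(ids)) stop("elements must be named")
  n <- length(elements)
  idm <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        idm[i, j] <- idm[j, i] <- identity_pct(elements[[i]], elements[[j]])
      }
    }
  }
  # union-find single linkage
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (idm[i, j] > threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  clusters <- split(seq_len(n), roots)
  out <- list()
  for (cl in clusters) {
    cl <- sort(cl)
    if (!is.null(ltrs)) {
      exemplar <- cl[1L]
      keep <- vapply(cl, function(i) {
        i == exemplar ||
          identity_pct(ltrs[[ids[i]]], ltrs[[ids[exemplar]]]) >= ltr_threshold
      }, logical(1))
      for (i in cl[!keep]) out[[length(out) + 1L]] <- i
      cl <- cl[keep]
    }
    out[[length(out) + 1L]] <- cl
  }
  out <- out[order(vapply(out, min, integer(1)))]
  lapply(seq_along(out), function(f) {
    cl <- out[[f]]
    pid <- if (length(cl) > 1L) mean(idm[cl, cl][upper.tri(idm[cl, cl])]) else 100
    lid <- if (!is.null(ltrs) && length(cl) > 1L) {
      mean(vapply(cl[-1L], function(i) {
        identity_pct(ltrs[[ids[i]]], ltrs[[ids[cl[1L]]]])
      }, numeric(1)))
    } else NA_real_
    list(family_id = sprintf("family_%02d", f), members = ids[cl],
         mean_identity = pid, mean_ltr_identity = lid)
  })
}

#' Majority-rule consensus of aligned copies
#'
#' Column-wise majority base; a gap wins a column only when gaps exceed half
#' the copies; among tied bases the base of the first-listed copy carrying
#' one of the tied bases wins.
#'
#' @param copies Named character vector of aligned sequences (equal length).
#' @return Consensus sequence string (may contain gaps).
#' @export
build_consensus <- function(copies) {
  m <- as_char_matrix(copies)
  apply_col <- function(col) {
    gaps <- sum(col == "-")
    if (gaps > length(col) / 2) return("-")
    col2 <- col[col != "-"]
    tab <- table(col2)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) return(top)
    col2[col2 %in% top][1L]   # first-listed copy among the tied bases
  }
  paste(apply(m, 2L, apply_col), collapse = "")
}
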