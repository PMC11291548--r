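#' The conserved partial laminin-G anchor peptides
#'
#' The two conserved peptides that delimit the variable insert of the
#' partial LG domain of Pif/BMSP proteins: a 32-residue N-terminal
#' anchor and a 59-residue C-terminal anchor.
#'
#' @return Named list with `n` and `c` anchor strings.
#' @export
lg_anchors <- function() {
  list(
    n = "AYFNGRAGLKIPRFSGVPYGKSVFIKMKYKED",
    c = "WKTVSLKISNGHIRGRRDDREDKDVLDGDLKTTFSGFQIGQGASNKNFKGYMDEVYIYF"
  )
}

#' Locate an LG anchor peptide on a protein
#'
#' Aligns the anchor locally ([local_align()]) against the protein
#' suffix after `search_after` and reports a match iff the aligned
#' identity is at least `min_identity` and the alignment covers at
#' least `min_coverage` of the anchor. The reported span is the
#' full-anchor projection onto the protein: the aligned subject span
#' extended by the anchor residues trimmed from either end (clamped to
#' the protein), so that terminal substitutions do not shift the insert
#' boundary. Absence is a value, not an error.
#'
#' @param protein One-row protein record (`id`, `seq`).
#' @param anchor Anchor peptide (length >= 10).
#' @param min_identity Identity threshold in (0, 1\] (default 0.5).
#' @param min_coverage Minimal aligned-column fraction of the anchor
#'   (default 0.8).
#' @param search_after Only matches starting after this 1-based
#'   position are considered (default 0 = whole protein).
#' @return List with `span` (length-2 integer), `identity`, `score`;
#'   or `NULL` when no acceptable match exists.
#' @export
locate_anchor <- function(protein, anchor, min_identity = 0.5,
                          min_coverage = 0.8, search_after = 0L) {
  if (nchar(anchor) < 10L) stop("anchor too short (< 10)", call. = FALSE)
  plen <- nchar(protein$seq)
  if (search_after >= plen) return(NULL)
  suffix <- substr(protein$seq, search_after + 1L, plen)
  if (nchar(suffix) < 1L) return(NULL)
  al <- local_align(anchor, suffix)
  if (is.null(al$q_span)) return(NULL)
  if (al$identity < min_identity) return(NULL)
  if (al$n_columns < min_coverage * nchar(anchor)) return(NULL)
  s_start <- al$s_span[1] + search_after
  s_end <- al$s_span[2] + search_after
  # project the untrimmed anchor ends back onto the protein
  start <- max(1L, s_start - (al$q_span[1] - 1L))
  end <- min(plen, s_end + (nchar(anchor) - al$q_span[2]))
  list(span = c(start, end), identity = al$identity, score = al$score)
}

#' Extract the inter-anchor insert region
#'
#' The insert is everything strictly between the end of the N-anchor
#' and the start of the C-anchor. An empty insert (adjacent anchors) is
#' legal; out-of-order or overlapping anchors are hard errors.
#'
#' @param protein One-row protein record (`id`, `seq`).
#' @param n_span,c_span Length-2 spans of the located anchors.
#' @return List with `protein_id`, `span` (`NULL` when empty), `seq`,
#'   `length`.
#' @export
extract_insert <- function(protein, n_span, c_span) {
  if (n_span[2] >= c_span[1]) {
    stop("anchors out of order or overlapping (N ends ", n_span[2],
         ", C starts ", c_span[1], ")", call. = FALSE)
  }
  start <- n_span[2] + 1L
  end <- c_span[1] - 1L
  len <- end - start + 1L
  list(protein_id = protein$id,
       span = if (len > 0) c(start, end) else NULL,
       seq = if (len > 0) substr(protein$seq, start, end) else "",
       length = max(0L, len))
}

#' Classify LG-domain completeness
#'
#' `complete` requires both anchors plus evidence of the intervening
#' domain body (a middle Laminin_G_3 hit, or a short inter-anchor gap
#' as judged by the caller); `partial` at least one anchor; `absent`
#' neither.
#'
#' @param n_found,c_found,middle_lg_hit Logical flags.
#' @return `"complete"`, `"partial"` or `"absent"`.
#' @export
lg_completeness <- function(n_found, c_found, middle_lg_hit) {
  if (n_found && c_found && middle_lg_hit) {
    "complete"
  } else if (n_found || c_found) {
    "partial"
  } else {
    "absent"
  }
}

#' Locate both anchors and extract the insert for one protein
#'
#' Convenience wrapper: searches the N-anchor first, then constrains the
#' C-anchor strictly downstream of it. When an anchor matches several
#' loci the highest-scoring match is taken.
#'
#' @inheritParams locate_anchor
#' @param anchors Anchor set as from [lg_anchors()].
#' @return List with `n` and `c` (each `NULL` or a [locate_anchor()]
#'   result) and `insert` (`NULL` unless both anchors found).
#' @export
find_lg_region <- function(protein, anchors = lg_anchors(),
                           min_identity = 0.5, min_coverage = 0.8) {
  n_hit <- locate_anchor(protein, anchors$n, min_identity, min_coverage)
  c_hit <- if (!is.null(n_hit)) {
    locate_anchor(protein, anchors$c, min_identity, min_coverage,
                  search_after = n_hit$span[2])
  } else {
    locate_anchor(protein, anchors$c, min_identity, min_coverage)
  }
  insert <- NULL
  if (!is.null(n_hit) && !is.null(c_hit) &&
      n_hit$span[2] < c_hit$span[1]) {
    insert <- extract_insert(protein, n_hit$span, c_hit$span)
  }
  list(n = n_hit, c = c_hit, insert = insert)
}
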