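#' Assemble the domain architecture of one protein
#'
#' Turns raw domain hits plus anchor/signal annotation into an ordered,
#' non-overlapping domain layout. Overlapping hits are resolved greedily
#' by keeping, among overlapping candidates, the hit with the smaller
#' independent E-value (ties: longer span, then smaller start).
#' Chitin-binding (`CBM_14`) hits are retained at any tier (see
#' [assign_tier()]; tier `none` is dropped); hits of every other class
#' must be confident (`ievalue < confident_ceiling`).
#'
#' LG status is derived from the anchor annotation: `complete` when both
#' anchors are present and either a `Laminin_G_3` hit lies between them
#' or the inter-anchor gap is at most `max_complete_gap` residues;
#' `partial` when at least one anchor is present; `absent` otherwise.
#'
#' @param protein One-row protein record (`id`, `seq`).
#' @param hits Domain-hit `data.frame` (rows for this protein; others
#'   are an error).
#' @param signal_span Optional length-2 integer vector (signal peptide
#'   span) or `NULL`.
#' @param anchors Optional list with elements `n` and/or `c`, each a
#'   length-2 span of the N-/C-terminal LG anchor, or `NULL`.
#' @param confident_ceiling E-value ceiling for non-CB classes
#'   (default `1e-5`).
#' @param max_complete_gap Largest inter-anchor gap still counted as a
#'   complete LG domain when no middle `Laminin_G_3` hit is seen
#'   (default 250 residues).
#' @return An `architecture`: list with `protein_id`, `length`,
#'   `signal_span`, `elements` (`data.frame` of `class`, `tier`,
#'   `start`, `end`, `ievalue`, sorted, non-overlapping), `anchors`,
#'   `n_vwa`, `has_cb`, `lg_status`.
#' @export
assemble_architecture <- function(protein, hits, signal_span = NULL,
                                  anchors = NULL,
                                  confident_ceiling = 1e-5,
                                  max_complete_gap = 250L) {
  id <- protein$id
  plen <- nchar(protein$seq)
  if (nrow(hits) > 0 && any(hits$protein_id != id)) {
    stop("hits reference protein(s) other than ", id, call. = FALSE)
  }
  h <- hits
  if (nrow(h) > 0) {
    is_cb <- h$domain_class == "CBM_14"
    tier <- rep(NA_character_, nrow(h))
    tier[is_cb] <- assign_tier(h$ievalue[is_cb])
    keep <- (is_cb & tier != "none") |
      (!is_cb & h$ievalue < confident_ceiling)
    h <- h[keep, , drop = FALSE]
    tier <- tier[keep]
  } else {
    tier <- character(0)
  }
  # greedy overlap resolution: smaller ievalue, then longer, then left
  if (nrow(h) > 0) {
    ord <- order(h$ievalue, -(h$end - h$start), h$start)
    occupied <- rep(FALSE, plen)
    kept <- logical(nrow(h))
    for (k in ord) {
      span <- h$start[k]:min(h$end[k], plen)
      if (!any(occupied[span])) {
        kept[k] <- TRUE
        occupied[span] <- TRUE
      }
    }
    h <- h[kept, , drop = FALSE]
    tier <- tier[kept]
    o <- order(h$start)
    h <- h[o, , drop = FALSE]
    tier <- tier[o]
  }
  elements <- data.frame(
    class = if (nrow(h)) h$domain_class else character(0),
    tier = if (nrow(h)) tier else character(0),
    start = if (nrow(h)) h$start else integer(0),
    end = if (nrow(h)) h$end else integer(0),
    ievalue = if (nrow(h)) h$ievalue else numeric(0),
    stringsAsFactors = FALSE
  )
  if (!is.null(signal_span) && nrow(elements) > 0) {
    clash <- any(elements$start <= signal_span[2] &
                   elements$end >= signal_span[1])
    if (clash) {
      warning("signal peptide span overlaps a kept domain in ", id,
              "; signal kept", call. = FALSE)
    }
  }
  n_found <- !is.null(anchors$n)
  c_found <- !is.null(anchors$c)
  middle <- FALSE
  if (n_found && c_found) {
    gap <- anchors$c[1] - anchors$n[2] - 1L
    lam <- elements$class == "Laminin_G_3" &
      elements$start > anchors$n[2] & elements$end < anchors$c[1]
    middle <- any(lam) || gap <= max_complete_gap
  }
  lg_status <- if (n_found && c_found && middle) {
    "complete"
  } else if (n_found || c_found) {
    "partial"
  } else {
    "absent"
  }
  structure(
    list(protein_id = id, length = plen,
         signal_span = signal_span,
         elements = elements,
         anchors = anchors,
         n_vwa = sum(elements$class == "VWA"),
         has_cb = any(elements$class == "CBM_14"),
         lg_status = lg_status),
    class = "architecture"
  )
}

#' @export
print.architecture <- function(x, ...) {
  cat(sprintf("architecture of %s (%d aa): %d VWA, CB %s, LG %s\n",
              x$protein_id, x$length, x$n_vwa,
              if (x$has_cb) "yes" else "no", x$lg_status))
  if (nrow(x$elements)) {
    lab <- ifelse(is.na(x$elements$tier), x$elements$class,
                  x$elements$tier)
    cat("  ", paste(sprintf("%s[%d-%d]", lab, x$elements$start,
                            x$elements$end), collapse = " - "), "\n")
  }
  invisible(x)
}
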