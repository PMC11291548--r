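#' Low-complexity segmentation parameters
#'
#' The classic SEG-style parameterization: a 12-residue window, trigger
#' entropy 2.2 bits and extension entropy 2.5 bits. Windows at or below
#' the trigger seed a segment; the segment absorbs flanking windows at
#' or below the extension entropy; merged segments shorter than
#' `min_len` are dropped.
#'
#' @param window Window width W (>= 4; default 12).
#' @param trigger Trigger entropy in bits (default 2.2).
#' @param extend Extension entropy in bits (>= trigger; default 2.5).
#' @param min_len Minimal reported segment length (default = `window`).
#' @return An `lcr_params` list.
#' @export
lcr_params <- function(window = 12L, trigger = 2.2, extend = 2.5,
                       min_len = window) {
  if (window < 4L) stop("window must be >= 4", call. = FALSE)
  if (trigger > extend) {
    stop("trigger entropy must be <= extension entropy", call. = FALSE)
  }
  structure(list(window = as.integer(window), trigger = trigger,
                 extend = extend, min_len = as.integer(min_len)),
            class = "lcr_params")
}

#' Shannon entropy of a residue window
#'
#' `-sum(f * log2(f))` over the observed residue frequencies; `'X'`
#' residues are excluded from the counts. A window of only `'X'` is a
#' hard error.
#'
#' @param window Amino-acid string (length >= 1).
#' @return Entropy in bits.
#' @examples
#' window_entropy("AAAAAAAAAAAA")  # 0
#' @export
window_entropy <- function(window) {
  chars <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  chars <- chars[chars != "X"]
  if (length(chars) == 0L) {
    stop("window contains only 'X'", call. = FALSE)
  }
  f <- table(chars) / length(chars)
  -sum(f * log2(f))
}

# Internal: entropies of all W-windows of a character vector, excluding
# 'X' from the counts, via a sliding count update.
.all_window_entropies <- function(chars, w) {
  L <- length(chars)
  n_win <- L - w + 1L
  ab <- c(aa_alphabet(), "X")
  idx <- match(chars, ab)
  counts <- tabulate(idx[1:w], nbins = 21L)
  ent <- function(ct) {
    ct <- ct[1:20]
    n <- sum(ct)
    if (n == 0L) return(NA_real_)
    f <- ct[ct > 0] / n
    -sum(f * log2(f))
  }
  out <- numeric(n_win)
  out[1] <- ent(counts)
  if (n_win > 1L) {
    for (p in 2:n_win) {
      counts[idx[p - 1L]] <- counts[idx[p - 1L]] - 1L
      counts[idx[p + w - 1L]] <- counts[idx[p + w - 1L]] + 1L
      out[p] <- ent(counts)
    }
  }
  out
}

#' Detect low-complexity regions in a protein
#'
#' Entropy-triggered segmentation: every window with entropy at most
#' the trigger seeds a segment; the segment spans the maximal run of
#' consecutive windows with entropy at most the extension value that
#' contains the seed. Overlapping/adjacent segments are merged and
#' segments shorter than `min_len` dropped. Zone is left unset
#' (see [assign_zones()]).
#'
#' @param protein One-row protein record (`id`, `seq`); length >= W.
#' @param params An [lcr_params()] object.
#' @return `data.frame` with columns `protein_id`, `start`, `end`,
#'   `mean_entropy`, `zone` (`NA`), `ordinal` (`NA`), sorted by start.
#' @export
detect_lcrs <- function(protein, params = lcr_params()) {
  w <- params$window
  chars <- strsplit(toupper(protein$seq), "", fixed = TRUE)[[1]]
  empty <- data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), mean_entropy = numeric(0),
                      zone = character(0), ordinal = integer(0),
                      stringsAsFactors = FALSE)
  if (length(chars) < w) return(empty)
  H <- .all_window_entropies(chars, w)
  ok <- !is.na(H)
  low <- ok & H <= params$extend
  trig <- ok & H <= params$trigger
  if (!any(trig)) return(empty)
  r <- rle(low)
  ends_w <- cumsum(r$lengths)
  starts_w <- ends_w - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    a <- starts_w[k]
    b <- ends_w[k]
    if (any(trig[a:b])) {
      segs[[length(segs) + 1L]] <- c(a, b + w - 1L, mean(H[a:b]))
    }
  }
  if (length(segs) == 0L) return(empty)
  m <- do.call(rbind, segs)
  # merge overlapping/adjacent residue spans
  o <- order(m[, 1])
  m <- m[o, , drop = FALSE]
  merged <- list(m[1, ])
  if (nrow(m) > 1L) {
    for (i in 2:nrow(m)) {
      last <- merged[[length(merged)]]
      if (m[i, 1] <= last[2] + 1) {
        last[2] <- max(last[2], m[i, 2])
        last[3] <- mean(c(last[3], m[i, 3]))
        merged[[length(merged)]] <- last
      } else {
        merged[[length(merged) + 1L]] <- m[i, ]
      }
    }
  }
  m <- do.call(rbind, merged)
  keep <- (m[, 2] - m[, 1] + 1) >= params$min_len
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(empty)
  data.frame(protein_id = protein$id, start = as.integer(m[, 1]),
             end = as.integer(m[, 2]), mean_entropy = m[, 3],
             zone = NA_character_, ordinal = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Architecture-anchored zone intervals
#'
#' The four positional zones of a Pif/BMSP protein: zone 1 upstream of
#' the first VWA domain (after any signal peptide), zone 2 the gaps
#' between tandem VWA domains, zone 3 between the last VWA and the
#' first chitin-binding element of any tier, and zone 4 between the two
#' conserved LG anchors. Empty or undefined zones are omitted.
#'
#' @param arch An [assemble_architecture()] result.
#' @return Named list mapping `"zone1"`..`"zone4"` to a `data.frame`
#'   of `start`/`end` spans (possibly several for zone 2).
#' @export
zone_intervals <- function(arch) {
  e <- arch$elements
  vwa <- e[e$class == "VWA", , drop = FALSE]
  cb <- e[e$class == "CBM_14", , drop = FALSE]
  zones <- list()
  add <- function(name, start, end) {
    if (length(start) && any(start <= end)) {
      keep <- start <= end
      zones[[name]] <<- data.frame(start = as.integer(start[keep]),
                                   end = as.integer(end[keep]))
    }
  }
  if (nrow(vwa) > 0) {
    z1_start <- if (!is.null(arch$signal_span)) {
      arch$signal_span[2] + 1L
    } else 1L
    add("zone1", z1_start, vwa$start[1] - 1L)
    if (nrow(vwa) > 1) {
      add("zone2", vwa$end[-nrow(vwa)] + 1L, vwa$start[-1] - 1L)
    }
    if (nrow(cb) > 0) {
      first_cb <- min(cb$start[cb$start > vwa$end[nrow(vwa)]])
      if (is.finite(first_cb)) {
        add("zone3", vwa$end[nrow(vwa)] + 1L, first_cb - 1L)
      }
    }
  }
  a <- arch$anchors
  if (!is.null(a$n) && !is.null(a$c) && a$n[2] < a$c[1]) {
    add("zone4", a$n[2] + 1L, a$c[1] - 1L)
  }
  zones
}

#' Assign LCRs to zones and number them
#'
#' Each LCR is assigned to the zone interval containing its midpoint
#' (boundary-straddling segments thus go to the zone holding most of
#' their centre); segments outside every zone get `"outside"`.
#' Ordinals number the LCRs 1..k by start within each zone.
#'
#' @param lcrs `data.frame` from [detect_lcrs()] (one protein).
#' @param zones [zone_intervals()] mapping for the same protein.
#' @return The `lcrs` data.frame with `zone` and `ordinal` filled in.
#' @export
assign_zones <- function(lcrs, zones) {
  if (nrow(lcrs) == 0L) return(lcrs)
  mid <- floor((lcrs$start + lcrs$end) / 2)
  zone <- rep("outside", nrow(lcrs))
  for (zn in names(zones)) {
    iv <- zones[[zn]]
    for (r in seq_len(nrow(iv))) {
      inside <- mid >= iv$start[r] & mid <= iv$end[r]
      zone[inside] <- zn
    }
  }
  lcrs$zone <- zone
  lcrs <- lcrs[order(lcrs$start), , drop = FALSE]
  lcrs$ordinal <- stats::ave(lcrs$start, lcrs$zone,
                             FUN = function(x) rank(x, ties.method = "first"))
  lcrs$ordinal <- as.integer(lcrs$ordinal)
  rownames(lcrs) <- NULL
  lcrs
}
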