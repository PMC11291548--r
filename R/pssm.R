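#' Build a position-specific scoring matrix from a seed alignment
#'
#' Computes per-column log-odds scores (bits) from a gapless seed
#' alignment: `score[a, j] = log2(((count[a, j] + pc * bg[a]) /
#' (N + pc)) / bg[a])` where `N` is the number of non-`'X'` residues
#' observed in column `j` and `pc` the pseudocount weight. `'X'`
#' residues are excluded from the counts; a column consisting only of
#' `'X'` is a hard error.
#'
#' @param seed_alignment Character vector of >= 2 equal-length gapless
#'   sequences (width >= 4).
#' @param background 20-vector of background probabilities summing to 1.
#' @param pseudocount Positive pseudocount weight (default 1).
#' @param name Profile name recorded on hits (default `"profile"`).
#' @return A `pssm`: list with `name`, `width`, `scores` (20 x W bits
#'   matrix, rows in [aa_alphabet()] order), `background`,
#'   `pseudocount`, and `consensus` (highest-scoring residue per column).
#' @export
build_pssm <- function(seed_alignment, background = background_composition(),
                       pseudocount = 1, name = "profile") {
  if (length(seed_alignment) < 2L) {
    stop("seed alignment needs >= 2 sequences", call. = FALSE)
  }
  w <- unique(nchar(seed_alignment))
  if (length(w) != 1L) {
    stop("seed sequences must have equal length", call. = FALSE)
  }
  if (w < 4L) stop("profile width must be >= 4", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  background <- check_composition(background, "background")
  chars <- do.call(rbind, strsplit(toupper(seed_alignment), "", fixed = TRUE))
  bad <- !(chars %in% c(aa_alphabet(), "X"))
  if (any(bad)) {
    stop("invalid residue '", chars[bad][1], "' in seed alignment",
         call. = FALSE)
  }
  scores <- matrix(0, nrow = 20L, ncol = w,
                   dimnames = list(aa_alphabet(), NULL))
  for (j in seq_len(w)) {
    col <- chars[, j]
    col <- col[col != "X"]
    if (length(col) == 0L) {
      stop("column ", j, " contains only 'X'", call. = FALSE)
    }
    counts <- table(factor(col, levels = aa_alphabet()))
    p <- (as.numeric(counts) + pseudocount * background) /
      (length(col) + pseudocount)
    scores[, j] <- log2(p / background)
  }
  consensus <- paste(rownames(scores)[apply(scores, 2L, which.max)],
                     collapse = "")
  structure(list(name = name, width = w, scores = scores,
                 background = background, pseudocount = pseudocount,
                 consensus = consensus),
            class = "pssm")
}

# Internal: summed log-odds of every window of a residue string against
# a pssm score matrix ('X' scores 0).
.window_scores <- function(chars, scores) {
  w <- ncol(scores)
  L <- length(chars)
  if (L < w) return(numeric(0))
  full <- rbind(scores, X = 0)
  idx <- match(chars, rownames(full))
  n_win <- L - w + 1L
  # per-position per-offset lookup, summed across offsets
  out <- numeric(n_win)
  for (j in seq_len(w)) {
    out <- out + full[cbind(idx[j:(j + n_win - 1L)], j)]
  }
  out
}

#' Scan a protein with a PSSM and empirical E-values
#'
#' Slides the profile across the protein, scoring each window by summed
#' log-odds. Window significance is calibrated against a shuffle null:
#' the protein's residues are shuffled `n_null` times and all windows of
#' every shuffle scored, giving the null score pool. The per-window
#' E-value is the empirical exceedance probability
#' `(#null >= s + 1) / (pool size + 1)` scaled by the number of windows
#' scanned. Overlapping windows are resolved greedily best-score-first;
#' surviving hits are sorted by start.
#'
#' @param pssm A [build_pssm()] profile.
#' @param protein One-row protein record (`id`, `seq`) or a list with
#'   those fields; length must be >= profile width.
#' @param n_null Number of shuffled nulls (>= 100; coarser calibration
#'   is refused).
#' @param seed Integer seed for the shuffles.
#' @param max_evalue Report only hits with E-value <= this (default 10).
#' @return `data.frame` in domain-hit layout (`protein_id`,
#'   `domain_class`, `start`, `end`, `score`, `ievalue`).
#' @export
scan_pssm <- function(pssm, protein, n_null = 200L, seed = 1L,
                      max_evalue = 10) {
  stopifnot(inherits(pssm, "pssm"))
  if (n_null < 100L) {
    stop("n_null must be >= 100 (calibration too coarse)", call. = FALSE)
  }
  seq <- protein$seq
  id <- protein$id
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(chars) < pssm$width) {
    stop("protein shorter than profile width", call. = FALSE)
  }
  obs <- .window_scores(chars, pssm$scores)
  n_win <- length(obs)
  null_scores <- withr::with_seed(seed, {
    unlist(lapply(seq_len(n_null), function(i) {
      .window_scores(sample(chars), pssm$scores)
    }), use.names = FALSE)
  })
  pool <- sort(null_scores)
  n_pool <- length(pool)
  # exceedance count via binary search on the sorted pool
  n_ge <- n_pool - findInterval(obs - 1e-12, pool)
  ev <- (n_ge + 1) / (n_pool + 1) * n_win
  ord <- order(-obs, seq_along(obs))
  kept <- logical(n_win)
  occupied <- rep(FALSE, length(chars))
  for (k in ord) {
    span <- k:(k + pssm$width - 1L)
    if (!any(occupied[span])) {
      kept[k] <- TRUE
      occupied[span] <- TRUE
    }
  }
  keep <- which(kept & ev <= max_evalue)
  keep <- keep[order(keep)]
  data.frame(protein_id = rep(id, length(keep)),
             domain_class = rep(pssm$name, length(keep)),
             start = keep,
             end = keep + pssm$width - 1L,
             score = obs[keep],
             ievalue = ev[keep],
             stringsAsFactors = FALSE)
}

#' Tier classification of chitin-binding-like domains
#'
#' Maps an independent E-value to the three-tier chitin-binding domain
#' classification: confident `CBM_14` below `1e-5`, degenerate
#' `CBM_14L1` in `[1e-5, 1)`, `CBM_14L2` in `[1, 1e4)`, and `none`
#' beyond. Windows are half-open and lower-inclusive, so every
#' non-negative E-value maps to exactly one tier.
#'
#' @param ievalue Numeric vector of independent E-values (>= 0).
#' @return Character vector over `{"CBM_14", "CBM_14L1", "CBM_14L2",
#'   "none"}`.
#' @examples
#' assign_tier(c(1e-6, 0.5, 5000, 20000))
#' @export
assign_tier <- function(ievalue) {
  if (any(!is.finite(ievalue) & !is.infinite(ievalue)) ||
      any(ievalue < 0)) {
    stop("ievalue must be non-negative", call. = FALSE)
  }
  ifelse(ievalue < 1e-5, "CBM_14",
         ifelse(ievalue < 1.0, "CBM_14L1",
                ifelse(ievalue < 1e4, "CBM_14L2", "none")))
}
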