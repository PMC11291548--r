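# Alignment alphabet: 20 standard residues plus X (unknown).
.align_alphabet <- function() c(aa_alphabet(), "X")

.pkg_cache <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix with neutral 'X'
#'
#' The standard BLOSUM62 matrix restricted to the 20 amino acids plus
#' `'X'`, with every score involving `'X'` set to 0 so unknown residues
#' neither reward nor penalise an alignment.
#'
#' @return 21 x 21 integer matrix.
#' @export
blosum62_matrix <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    ab <- .align_alphabet()
    m <- e$BLOSUM62[ab, ab]
    m["X", ] <- 0L
    m[, "X"] <- 0L
    storage.mode(m) <- "integer"
    .pkg_cache$blosum62 <- m
  }
  .pkg_cache$blosum62
}

.encode_seq <- function(seq, alphabet) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(v, alphabet)
  if (anyNA(idx)) {
    stop("residue '", v[which(is.na(idx))[1]],
         "' not present in the substitution matrix", call. = FALSE)
  }
  idx - 1L
}

#' Optimal local alignment with affine gaps
#'
#' Smith-Waterman local alignment under an affine gap model in which a
#' gap of length g costs `gap_open + (g - 1) * gap_extend`. Defaults
#' (BLOSUM62, open 11, extend 1) follow common protein-BLAST practice.
#' One optimal alignment is returned with deterministic tie-breaking:
#' smaller query start, then smaller subject start, then fewer gaps
#' (via diagonal-move preference).
#'
#' @param query,subject Non-empty amino-acid strings (may contain `'X'`).
#' @param matrix Substitution matrix with row/column names covering all
#'   residues used; default [blosum62_matrix()].
#' @param gap_open,gap_extend Positive integer penalties with
#'   `gap_open >= gap_extend >= 1`.
#' @return An `alignment_result`: list with `score` (>= 0), `q_span` and
#'   `s_span` (1-based inclusive, `NULL` for an empty alignment),
#'   `n_columns`, `n_matches`, `n_gapcols`, `identity`
#'   (matches / columns, `NA` if empty).
#' @examples
#' local_align("HEAGAWGHEE", "PAWHEAE")
#' @export
local_align <- function(query, subject, matrix = blosum62_matrix(),
                        gap_open = 11L, gap_extend = 1L) {
  if (!nzchar(query) || !nzchar(subject)) {
    stop("query and subject must be non-empty", call. = FALSE)
  }
  if (!(gap_open >= gap_extend && gap_extend >= 1)) {
    stop("require gap_open >= gap_extend >= 1", call. = FALSE)
  }
  ab <- rownames(matrix)
  q <- .encode_seq(query, ab)
  s <- .encode_seq(subject, ab)
  storage.mode(matrix) <- "integer"
  r <- sw_align_cpp(q, s, matrix, as.integer(gap_open),
                    as.integer(gap_extend))
  empty <- r$n_columns == 0L
  structure(
    list(
      score = r$score,
      q_span = if (empty) NULL else c(r$qstart, r$qend),
      s_span = if (empty) NULL else c(r$sstart, r$send),
      n_columns = r$n_columns,
      n_matches = r$n_matches,
      n_gapcols = r$n_gapcols,
      identity = if (empty) NA_real_ else r$n_matches / r$n_columns
    ),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  if (is.null(x$q_span)) {
    cat("alignment_result: empty (score 0)\n")
  } else {
    cat(sprintf(
      "alignment_result: score %d, query %d-%d, subject %d-%d, identity %.3f\n",
      x$score, x$q_span[1], x$q_span[2], x$s_span[1], x$s_span[2],
      x$identity))
  }
  invisible(x)
}

#' Construct or calibrate a Karlin-Altschul E-value model
#'
#' The E-value of a local alignment score S against sequences of lengths
#' m and n is `E = K * m * n * exp(-lambda * S)`. Two calibrations are
#' provided. `"canonical"` uses the published ungapped BLOSUM62
#' constants (lambda = 0.3176, K = 0.134) as documented defaults.
#' `"shuffle"` fits a Gumbel distribution by the method of moments to
#' the scores of `query` against `n_shuffles` residue-shuffles of
#' `subject`, which is exact on synthetic alphabets where no published
#' constants apply.
#'
#' @param calibration `"canonical"` or `"shuffle"`.
#' @param query,subject Sequences for shuffle calibration.
#' @param n_shuffles Number of shuffles (default 200; minimum 50).
#' @param seed Integer seed for the shuffles.
#' @param matrix,gap_open,gap_extend Alignment parameters, as in
#'   [local_align()].
#' @return An `evalue_model`: list with `lambda`, `K`, `calibration`.
#' @export
evalue_model <- function(calibration = c("canonical", "shuffle"),
                         query = NULL, subject = NULL, n_shuffles = 200L,
                         seed = 1L, matrix = blosum62_matrix(),
                         gap_open = 11L, gap_extend = 1L) {
  calibration <- match.arg(calibration)
  if (calibration == "canonical") {
    return(structure(list(lambda = 0.3176, K = 0.134,
                          calibration = "canonical"),
                     class = "evalue_model"))
  }
  if (is.null(query) || is.null(subject)) {
    stop("shuffle calibration needs query and subject", call. = FALSE)
  }
  if (n_shuffles < 50L) stop("n_shuffles must be >= 50", call. = FALSE)
  sv <- strsplit(subject, "", fixed = TRUE)[[1]]
  scores <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      shuf <- paste(sample(sv), collapse = "")
      local_align(query, shuf, matrix = matrix, gap_open = gap_open,
                  gap_extend = gap_extend)$score
    }, numeric(1))
  })
  # Gumbel fit by moments: beta = sd * sqrt(6) / pi, mu = mean - gamma*beta
  beta <- stats::sd(scores) * sqrt(6) / pi
  if (!is.finite(beta) || beta <= 0) {
    stop("degenerate shuffle score distribution; cannot calibrate",
         call. = FALSE)
  }
  mu <- mean(scores) - 0.5772156649 * beta
  lambda <- 1 / beta
  K <- exp(mu / beta) / (nchar(query) * nchar(subject))
  structure(list(lambda = lambda, K = K, calibration = "shuffle",
                 n_shuffles = n_shuffles, seed = seed),
            class = "evalue_model")
}

#' Karlin-Altschul E-value of a local alignment score
#'
#' @param score Alignment score.
#' @param m,n Query and subject lengths (>= 1).
#' @param model An [evalue_model()].
#' @return `E = K * m * n * exp(-lambda * score)`; strictly decreasing
#'   in score, linear in m and n.
#' @export
evalue <- function(score, m, n, model) {
  if (!inherits(model, "evalue_model")) {
    stop("model must be a calibrated evalue_model", call. = FALSE)
  }
  if (any(m < 1) || any(n < 1)) stop("m and n must be >= 1", call. = FALSE)
  model$K * m * n * exp(-model$lambda * score)
}

#' Homology gate for VWA regions against a reference
#'
#' Labels each candidate VWA region pass/fail by whether the E-value of
#' its optimal local alignment to the reference VWA sequence falls below
#' `threshold` (default `1e-10`, the conventional strict protein-BLAST
#' cutoff for "high homology"). Input order is preserved.
#'
#' @param regions `data.frame` with columns `protein_id` and `seq`
#'   (typically VWA-domain subsequences extracted per hit span), or an
#'   empty data.frame.
#' @param reference Reference VWA amino-acid sequence.
#' @param threshold Positive E-value threshold.
#' @param model An [evalue_model()]; default canonical calibration.
#' @param matrix,gap_open,gap_extend Alignment parameters.
#' @return `data.frame` with columns `protein_id`, `score`, `evalue`,
#'   `pass`.
#' @export
select_candidates <- function(regions, reference, threshold = 1e-10,
                              model = evalue_model("canonical"),
                              matrix = blosum62_matrix(),
                              gap_open = 11L, gap_extend = 1L) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (nrow(regions) == 0L) {
    return(data.frame(protein_id = character(), score = numeric(),
                      evalue = numeric(), pass = logical()))
  }
  stopifnot(all(c("protein_id", "seq") %in% names(regions)))
  score <- vapply(regions$seq, function(s) {
    local_align(s, reference, matrix = matrix, gap_open = gap_open,
                gap_extend = gap_extend)$score
  }, numeric(1), USE.NAMES = FALSE)
  ev <- evalue(score, nchar(regions$seq), nchar(reference), model)
  data.frame(protein_id = regions$protein_id, score = score,
             evalue = ev, pass = ev < threshold,
             stringsAsFactors = FALSE)
}
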