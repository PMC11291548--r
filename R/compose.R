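#' Amino-acid composition of a region
#'
#' Percentage of each of the 20 standard residues in a sequence; `'X'`
#' is excluded from the denominator. Rows built this way sum to 100.
#'
#' @param seq Amino-acid string with at least one non-`'X'` residue.
#' @return Named numeric 20-vector of percentages in [aa_alphabet()]
#'   order.
#' @examples
#' composition_vector("DKDK")
#' @export
composition_vector <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  chars <- chars[chars != "X"]
  if (length(chars) == 0L) {
    stop("region contains no standard residues", call. = FALSE)
  }
  bad <- !(chars %in% aa_alphabet())
  if (any(bad)) {
    stop("invalid residue '", chars[bad][1], "'", call. = FALSE)
  }
  counts <- table(factor(chars, levels = aa_alphabet()))
  setNames(100 * as.numeric(counts) / length(chars), aa_alphabet())
}

#' Build a composition matrix from named region sequences
#'
#' @param seqs Named character vector (unique region ids -> sequences).
#' @return Numeric matrix, regions x 20, rows summing to 100 within
#'   1e-9 (checked).
#' @export
composition_matrix <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("region ids must be present and unique", call. = FALSE)
  }
  m <- t(vapply(seqs, composition_vector, numeric(20)))
  colnames(m) <- aa_alphabet()
  if (any(abs(rowSums(m) - 100) > 1e-9)) {
    stop("composition rows must sum to 100", call. = FALSE)
  }
  m
}

#' Ward linkage of composition rows
#'
#' Agglomerative clustering minimizing the increase in within-cluster
#' sum of squares at each merge, computed on Euclidean distances
#' between raw percentage rows via [stats::hclust()] with method
#' `"ward.D2"` (squared-distance Lance-Williams update; heights
#' reported on the Euclidean scale, so the ESS increase of a merge is
#' height^2 / 2).
#'
#' @param mat Composition matrix (>= 2 rows, unique row names).
#' @param standardize If `TRUE`, z-score the columns first (default
#'   `FALSE`: the ratios are clustered directly).
#' @return An [stats::hclust] object (fields `merge`, `height`,
#'   `order`, `labels`).
#' @export
ward_linkage <- function(mat, standardize = FALSE) {
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat))) {
    stop("duplicate or missing row labels", call. = FALSE)
  }
  if (nrow(mat) < 2L) stop("need >= 2 rows", call. = FALSE)
  if (standardize) {
    keep <- apply(mat, 2L, sd) > 0
    mat <- scale(mat[, keep, drop = FALSE])
  }
  stats::hclust(stats::dist(mat), method = "ward.D2")
}

#' Mean silhouette width of a labelled partition
#'
#' For each row i, `a_i` is its mean distance to its own cluster
#' (excluding itself) and `b_i` the smallest mean distance to another
#' cluster; `s_i = (b_i - a_i) / max(a_i, b_i)`. Rows in singleton
#' clusters score 0. Requires at least two clusters.
#'
#' @param mat Numeric matrix of observations (rows).
#' @param labels Cluster labels, one per row.
#' @return Mean silhouette in \[-1, 1\].
#' @export
silhouette_mean <- function(mat, labels) {
  if (length(unique(labels)) < 2L) {
    stop("silhouette needs >= 2 clusters", call. = FALSE)
  }
  d <- as.matrix(stats::dist(mat))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) {
      s[i] <- 0
      next
    }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(d[i, labels == g])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Cut the Ward tree at every k and choose the silhouette-optimal k
#'
#' Cuts the Ward dendrogram at each `k` in `2..k_max`, computes the
#' mean silhouette, and picks the argmax (ties broken toward smaller
#' k). When even the best mean silhouette is below 0.25 the result is
#' flagged `weak_structure`: the data show no convincing cluster
#' separation and the chosen k is reported for completeness only.
#'
#' @param mat Composition matrix (>= 3 rows).
#' @param k_max Largest k to consider (default `min(8, nrow - 1)`).
#' @param standardize Passed to [ward_linkage()].
#' @return A `cluster_result`: list with `linkage` (hclust), `per_k`
#'   (`data.frame` of `k`, `mean_silhouette`), `chosen_k`, `labels`
#'   (named by row), `mean_silhouette`, `weak_structure`, `variant`
#'   (`"ward.D2"`).
#' @export
choose_k <- function(mat, k_max = min(8L, nrow(mat) - 1L),
                     standardize = FALSE) {
  if (nrow(mat) < 3L) stop("need >= 3 rows to choose k", call. = FALSE)
  if (k_max < 2L || k_max > nrow(mat) - 1L) {
    stop("k_max must be in [2, rows - 1]", call. = FALSE)
  }
  hc <- ward_linkage(mat, standardize = standardize)
  ks <- 2:k_max
  sil <- vapply(ks, function(k) {
    silhouette_mean(mat, stats::cutree(hc, k = k))
  }, numeric(1))
  chosen <- ks[which.max(sil)]  # which.max takes the first (smallest) k
  labels <- stats::cutree(hc, k = chosen)
  structure(
    list(linkage = hc,
         per_k = data.frame(k = ks, mean_silhouette = sil),
         chosen_k = chosen,
         labels = labels,
         mean_silhouette = max(sil),
         weak_structure = max(sil) < 0.25,
         variant = "ward.D2"),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: k = %d (mean silhouette %.3f%s)\n",
              x$chosen_k, x$mean_silhouette,
              if (x$weak_structure) ", weak structure" else ""))
  print(table(x$labels))
  invisible(x)
}
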