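# Independent oracles used to cross-check the package implementations.
# Each oracle is written against the mathematical definition, not the
# package's code path.

# Plain-R Gotoh dynamic programme (score only): the Bellman form of
# exhaustive local-alignment enumeration.
oracle_sw_dp <- function(q, s, mat, open = 11, ext = 1) {
  qv <- strsplit(q, "", fixed = TRUE)[[1]]
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  m <- length(qv)
  n <- length(sv)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - open, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[qv[i - 1], sv[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Literal exhaustive enumeration over every local alignment path
# (every column sequence), tractable for sequences of length <= 4.
oracle_sw_enum <- function(q, s, mat, open = 11, ext = 1) {
  qv <- strsplit(q, "", fixed = TRUE)[[1]]
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  m <- length(qv)
  n <- length(sv)
  best <- 0
  rec <- function(i, j, score, last) {
    best <<- max(best, score)
    if (i <= m && j <= n) rec(i + 1L, j + 1L, score + mat[qv[i], sv[j]], 0L)
    if (j <= n) rec(i, j + 1L, score - (if (last == 1L) ext else open), 1L)
    if (i <= m) rec(i + 1L, j, score - (if (last == 2L) ext else open), 2L)
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      rec(i + 1L, j + 1L, mat[qv[i], sv[j]], 0L)
    }
  }
  best
}

# Random amino-acid string over a restricted alphabet (so that matches
# occur often enough to exercise gaps).
random_peptide <- function(len, letters = c("A", "D", "K", "G", "W", "C")) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

.rank3 <- c(weak = 1L, medium = 2L, strong = 3L)

# Brute-force family-clade search: enumerate every internal node via
# phangorn::Descendants and apply the definition directly.
oracle_family_clade <- function(stree, refs, min_class = "strong",
                                medium_ufboot_only = FALSE) {
  phy <- stree$phylo
  ntip <- length(phy$tip.label)
  classes <- classify_support(stree$alrt, stree$ufboot,
                              medium_ufboot_only = medium_ufboot_only)
  desc <- phangorn::Descendants(phy, (ntip + 1):(ntip + phy$Nnode), "tips")
  tipsets <- lapply(desc, function(ix) phy$tip.label[ix])
  contains <- vapply(tipsets, function(ts) all(refs %in% ts), logical(1))
  supported <- .rank3[classes] >= .rank3[min_class]
  depth <- vapply(seq_len(phy$Nnode) + ntip, function(nd) {
    length(phangorn::Ancestors(phy, nd, "all"))
  }, integer(1))
  cand <- which(contains & supported)
  if (length(cand) == 0L) {
    cand <- which(contains)
    k <- cand[which.max(depth[cand])]
    return(list(node = k + ntip, tips = sort(tipsets[[k]]),
                unsupported = TRUE))
  }
  sizes <- lengths(tipsets[cand])
  cand <- cand[sizes == max(sizes)]
  k <- cand[which.min(depth[cand])]
  list(node = k + ntip, tips = sort(tipsets[[k]]), unsupported = FALSE)
}

# Brute-force subfamily partition: all supported proper sub-clades of
# the family with >= 2 leaves, kept iff maximal under set inclusion.
oracle_partition <- function(stree, family_tips, min_class = "medium",
                             medium_ufboot_only = FALSE) {
  phy <- stree$phylo
  ntip <- length(phy$tip.label)
  classes <- classify_support(stree$alrt, stree$ufboot,
                              medium_ufboot_only = medium_ufboot_only)
  desc <- phangorn::Descendants(phy, (ntip + 1):(ntip + phy$Nnode), "tips")
  tipsets <- lapply(desc, function(ix) sort(phy$tip.label[ix]))
  ok <- vapply(seq_along(tipsets), function(k) {
    ts <- tipsets[[k]]
    length(ts) >= 2L && length(ts) < length(family_tips) &&
      all(ts %in% family_tips) &&
      .rank3[classes[k]] >= .rank3[min_class]
  }, logical(1))
  sel <- which(ok)
  maximal <- sel[vapply(sel, function(k) {
    !any(vapply(setdiff(sel, k), function(k2) {
      all(tipsets[[k]] %in% tipsets[[k2]])
    }, logical(1)))
  }, logical(1))]
  leafsets <- lapply(maximal, function(k) tipsets[[k]])
  ord <- order(vapply(leafsets, `[[`, "", 1L))
  leafsets <- leafsets[ord]
  list(leafsets = leafsets,
       classes = classes[maximal][ord],
       unassigned = sort(setdiff(family_tips, unlist(leafsets))))
}

# Random rooted binary tree with random dual supports (some missing,
# some single-valued).
random_support_tree <- function(n = 12L, seed = 1L) {
  withr::with_seed(seed, {
    phy <- ape::rtree(n)
    phy$node.label <- vapply(seq_len(phy$Nnode), function(i) {
      r <- runif(1)
      if (r < 0.15) {
        ""
      } else if (r < 0.3) {
        as.character(sample(0:100, 1))
      } else {
        paste0(sample(0:100, 1), "/", sample(0:100, 1))
      }
    }, "")
    parse_support_tree(ape::write.tree(phy))
  })
}

# Greedy minimum-ESS-increase agglomeration; heights on the Euclidean
# ward.D2 scale (sqrt of twice the ESS increase).
oracle_ward_heights <- function(x) {
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf
    bi <- bj <- NA_integer_
    for (i in 1:(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        a <- x[clusters[[i]], , drop = FALSE]
        b <- x[clusters[[j]], , drop = FALSE]
        dess <- nrow(a) * nrow(b) / (nrow(a) + nrow(b)) *
          sum((colMeans(a) - colMeans(b))^2)
        if (dess < best) {
          best <- dess
          bi <- i
          bj <- j
        }
      }
    }
    heights <- c(heights, sqrt(2 * best))
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}
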