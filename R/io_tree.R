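#' Parse a Newick tree with dual node-support labels
#'
#' Reads a Newick string (or file) whose internal-node labels carry
#' support values as emitted by IQ-TREE: either a `"x/y"` pair
#' (SH-aLRT/UFBoot by default), a single real (taken as UFBoot), or no
#' label. Returns a `support_tree`: an [ape::phylo] topology plus
#' per-internal-node `alrt` and `ufboot` percent vectors.
#'
#' An unrooted input (basal multifurcation) is resolved into a rooted
#' binary tree at an arbitrary basal edge via [ape::multi2di()]; the
#' choice is recorded in the `rooted_arbitrarily` field so downstream
#' consumers can report it. Inserted nodes carry missing support.
#'
#' @param newick Newick text, or a path to a file containing it.
#' @param label_order `"alrt_ufboot"` (IQ-TREE's emission order, default)
#'   or `"ufboot_alrt"`.
#' @return A `support_tree` object: list with `phylo` (rooted
#'   [ape::phylo]), `alrt`, `ufboot` (numeric vectors indexed by internal
#'   node, `NA` = missing), and `rooted_arbitrarily` (logical).
#' @details Supports outside \[0, 100\] and unbalanced parentheses are
#'   hard errors. Missing values are legal everywhere, including the
#'   root.
#' @export
parse_support_tree <- function(newick,
                               label_order = c("alrt_ufboot", "ufboot_alrt")) {
  label_order <- match.arg(label_order)
  text <- if (length(newick) == 1L && file.exists(newick) &&
              !grepl("\\(", newick)) {
    paste(readLines(newick, warn = FALSE), collapse = "")
  } else {
    paste(newick, collapse = "")
  }
  n_open <- lengths(regmatches(text, gregexpr("\\(", text)))
  n_close <- lengths(regmatches(text, gregexpr("\\)", text)))
  if (n_open != n_close) {
    stop("unbalanced parentheses in Newick input", call. = FALSE)
  }
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick input", call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf name ",
         tr$tip.label[duplicated(tr$tip.label)][1], call. = FALSE)
  }
  rooted_arbitrarily <- FALSE
  if (!ape::is.binary(tr) || !ape::is.rooted(tr)) {
    tr <- ape::multi2di(tr, random = FALSE)
    rooted_arbitrarily <- TRUE
  }
  labs <- tr$node.label
  if (is.null(labs)) labs <- rep("", tr$Nnode)
  labs[is.na(labs)] <- ""
  alrt <- rep(NA_real_, tr$Nnode)
  ufboot <- rep(NA_real_, tr$Nnode)
  pair <- grepl("^[0-9.eE+-]+/[0-9.eE+-]+$", labs)
  single <- !pair & grepl("^[0-9.eE+-]+$", labs) & nzchar(labs)
  if (any(pair)) {
    parts <- strsplit(labs[pair], "/", fixed = TRUE)
    first <- as.numeric(vapply(parts, `[[`, "", 1L))
    second <- as.numeric(vapply(parts, `[[`, "", 2L))
    if (label_order == "alrt_ufboot") {
      alrt[pair] <- first
      ufboot[pair] <- second
    } else {
      ufboot[pair] <- first
      alrt[pair] <- second
    }
  }
  # single-number labels are UFBoot by convention (SH-aLRT unavailable)
  ufboot[single] <- as.numeric(labs[single])
  vals <- c(alrt, ufboot)
  if (any(!is.na(vals) & (vals < 0 | vals > 100))) {
    stop("support value outside [0, 100]", call. = FALSE)
  }
  structure(
    list(phylo = tr, alrt = alrt, ufboot = ufboot,
         rooted_arbitrarily = rooted_arbitrarily),
    class = "support_tree"
  )
}

#' @export
print.support_tree <- function(x, ...) {
  cat("support_tree:", length(x$phylo$tip.label), "leaves,",
      x$phylo$Nnode, "internal nodes\n")
  cat("  with SH-aLRT on", sum(!is.na(x$alrt)), "and UFBoot on",
      sum(!is.na(x$ufboot)), "nodes\n")
  if (x$rooted_arbitrarily) cat("  (rooted at an arbitrary basal edge)\n")
  invisible(x)
}

# Internal: tip-name sets for every node (tips and internals) of a
# phylo, by a single postorder pass over the edge matrix.
node_tip_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  sets <- vector("list", ntip + phy$Nnode)
  sets[seq_len(ntip)] <- as.list(phy$tip.label)
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]
    ch <- edge[i, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# Internal: node depths (edges from the root), root = 0.
node_depths <- function(phy) {
  ntip <- length(phy$tip.label)
  depth <- rep(NA_real_, ntip + phy$Nnode)
  root <- ntip + 1L
  depth[root] <- 0
  edge <- phy$edge[order(phy$edge[, 1L]), , drop = FALSE]
  # edges in preorder via repeated passes (trees here are small)
  todo <- phy$edge
  while (anyNA(depth[unique(todo[, 2L])])) {
    ready <- !is.na(depth[todo[, 1L]]) & is.na(depth[todo[, 2L]])
    if (!any(ready)) break
    depth[todo[ready, 2L]] <- depth[todo[ready, 1L]] + 1
  }
  depth
}
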