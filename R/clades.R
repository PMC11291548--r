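#' Classify dual branch support into strong / medium / weak
#'
#' A branch is `strong` when UFBoot >= 95 and SH-aLRT >= 85; `medium`
#' when not strong but UFBoot >= 75 and SH-aLRT >= 65; otherwise
#' `weak`. A missing value fails every comparison it appears in
#' (conservative). Because two medium-support conventions circulate —
#' with and without the SH-aLRT clause — `medium_ufboot_only = TRUE`
#' drops the SH-aLRT >= 65 requirement.
#'
#' @param alrt,ufboot Support percentages in \[0, 100\], or `NA`.
#' @param medium_ufboot_only If `TRUE`, medium requires only
#'   UFBoot >= 75.
#' @return `"strong"`, `"medium"` or `"weak"` (vectorised).
#' @examples
#' classify_support(85, 95)   # strong
#' classify_support(65, 75)   # medium
#' classify_support(NA, 96)   # weak: missing SH-aLRT fails its test
#' @export
classify_support <- function(alrt, ufboot, medium_ufboot_only = FALSE) {
  vals <- c(alrt, ufboot)
  if (any(!is.na(vals) & (vals < 0 | vals > 100))) {
    stop("support value outside [0, 100]", call. = FALSE)
  }
  ge <- function(x, t) !is.na(x) & x >= t
  strong <- ge(ufboot, 95) & ge(alrt, 85)
  medium <- if (medium_ufboot_only) {
    !strong & ge(ufboot, 75)
  } else {
    !strong & ge(ufboot, 75) & ge(alrt, 65)
  }
  out <- rep("weak", max(length(alrt), length(ufboot)))
  out[medium] <- "medium"
  out[strong] <- "strong"
  out
}

# Internal: rank for class comparisons (class >= min_class).
.class_rank <- function(x) {
  unname(c(weak = 1L, medium = 2L, strong = 3L)[x])
}

# Internal: per-internal-node support class vector for a support_tree.
.node_classes <- function(stree, medium_ufboot_only = FALSE) {
  classify_support(stree$alrt, stree$ufboot,
                   medium_ufboot_only = medium_ufboot_only)
}

#' Extract the family clade containing all reference leaves
#'
#' Finds the largest clade (by leaf count) that contains every
#' designated reference leaf and whose subtending branch has support
#' class at least `min_class` (default `strong`, mirroring how the
#' Pif/BMSP family clade is delimited around the PfuPif reference).
#' Among equally large supported clades the one closest to the root
#' wins. When no supported clade contains all references, the MRCA of
#' the references is returned flagged `unsupported`.
#'
#' @param stree A [parse_support_tree()] object.
#' @param references Character vector of reference leaf names (all must
#'   be present).
#' @param min_class Minimal support class (`"strong"`, `"medium"`,
#'   `"weak"`).
#' @param medium_ufboot_only Passed to [classify_support()].
#' @return List with `node` (internal node number), `tips` (leaf
#'   names), `class` (support class of the subtending branch), and
#'   `unsupported` (logical).
#' @export
find_family_clade <- function(stree, references, min_class = "strong",
                              medium_ufboot_only = FALSE) {
  phy <- stree$phylo
  ntip <- length(phy$tip.label)
  missing_ref <- setdiff(references, phy$tip.label)
  if (length(missing_ref) > 0) {
    stop("reference leaf absent from tree: ", missing_ref[1],
         call. = FALSE)
  }
  sets <- node_tip_sets(phy)
  classes <- .node_classes(stree, medium_ufboot_only)
  depth <- node_depths(phy)
  internal <- ntip + seq_len(phy$Nnode)
  contains <- vapply(internal, function(nd) {
    all(references %in% sets[[nd]])
  }, logical(1))
  supported <- .class_rank(classes) >= .class_rank(min_class)
  cand <- internal[contains & supported]
  if (length(cand) == 0L) {
    mrca_nodes <- internal[contains]
    nd <- mrca_nodes[which.max(depth[mrca_nodes])]
    return(list(node = nd, tips = sets[[nd]],
                class = classes[nd - ntip], unsupported = TRUE))
  }
  sizes <- lengths(sets[cand])
  cand <- cand[sizes == max(sizes)]
  nd <- cand[which.min(depth[cand])]
  list(node = nd, tips = sets[[nd]], class = classes[nd - ntip],
       unsupported = FALSE)
}

#' Partition a family clade into supported subfamilies
#'
#' Subfamilies are the maximal proper sub-clades of the family clade
#' whose subtending branch has support class at least `min_class`
#' (default `medium`) and which contain at least two leaves, chosen
#' top-down so that a supported clade nested inside a chosen one is
#' absorbed. Leaves covered by no such clade are reported unassigned.
#' Subfamilies are ordered (and numbered) by their smallest leaf name.
#'
#' @inheritParams find_family_clade
#' @param family Result of [find_family_clade()].
#' @param min_class Minimal support class for a subfamily branch.
#' @return A `subfamily_partition`: list with `family_tips`,
#'   `subfamilies` (`data.frame` of `subfamily`, `class`, `n_leaves`,
#'   `leaves` comma-joined), `membership` (named vector leaf ->
#'   subfamily id or `NA`), `unassigned`.
#' @export
partition_subfamilies <- function(stree, family, min_class = "medium",
                                  medium_ufboot_only = FALSE) {
  phy <- stree$phylo
  ntip <- length(phy$tip.label)
  if (length(family$tips) < 2L) {
    stop("family clade has fewer than 2 leaves", call. = FALSE)
  }
  sets <- node_tip_sets(phy)
  classes <- .node_classes(stree, medium_ufboot_only)
  children <- split(phy$edge[, 2L], phy$edge[, 1L])
  min_rank <- .class_rank(min_class)
  sub_nodes <- integer(0)
  unassigned <- character(0)
  descend <- function(nd) {
    for (ch in children[[as.character(nd)]]) {
      if (ch <= ntip) {
        unassigned <<- c(unassigned, phy$tip.label[ch])
      } else if (.class_rank(classes[ch - ntip]) >= min_rank &&
                 length(sets[[ch]]) >= 2L) {
        sub_nodes <<- c(sub_nodes, ch)
      } else {
        descend(ch)
      }
    }
  }
  descend(family$node)
  leaf_sets <- lapply(sub_nodes, function(nd) sort(sets[[nd]]))
  ord <- order(vapply(leaf_sets, `[[`, "", 1L))
  sub_nodes <- sub_nodes[ord]
  leaf_sets <- leaf_sets[ord]
  membership <- setNames(rep(NA_character_, length(family$tips)),
                         sort(family$tips))
  subfam <- data.frame(
    subfamily = if (length(sub_nodes)) {
      paste0("sf", seq_along(sub_nodes))
    } else character(0),
    class = if (length(sub_nodes)) {
      classes[sub_nodes - ntip]
    } else character(0),
    n_leaves = lengths(leaf_sets),
    leaves = vapply(leaf_sets, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(leaf_sets)) {
    membership[leaf_sets[[i]]] <- subfam$subfamily[i]
  }
  structure(
    list(family_tips = sort(family$tips), subfamilies = subfam,
         membership = membership, unassigned = sort(unassigned)),
    class = "subfamily_partition"
  )
}

#' @export
print.subfamily_partition <- function(x, ...) {
  cat("subfamily_partition:", nrow(x$subfamilies), "subfamilies over",
      length(x$family_tips), "family leaves;",
      length(x$unassigned), "unassigned\n")
  if (nrow(x$subfamilies)) {
    for (i in seq_len(nrow(x$subfamilies))) {
      cat(sprintf("  %s (%s, %d leaves)\n", x$subfamilies$subfamily[i],
                  x$subfamilies$class[i], x$subfamilies$n_leaves[i]))
    }
  }
  invisible(x)
}
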