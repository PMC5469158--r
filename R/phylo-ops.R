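# Branch filtering and tree-guided alignment splitting: the preparation steps
# that turn one large alignment/tree pair into tractable training units.

#' Filter a tree by branch length
#'
#' Removes uninformative or noisy branches before training: internal branches
#' of length `<= min_len` are collapsed into polytomies, leaves attached by
#' terminal branches of length `<= min_len` are dropped, and every branch of
#' length `>= max_len` is cut, separating the tree into a forest whose parts
#' become independent units. Cutting is applied recursively (fusing two
#' retained branches across a removed degree-2 node can itself produce an
#' over-long path, which is then cut too).
#'
#' Path lengths between leaves that stay in the same part are never altered,
#' and the total retained branch length never increases.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param min_len Lower cutoff, exclusive (default 0: exact-zero branches go).
#' @param max_len Upper cutoff, inclusive cut (default 2 substitutions/site).
#' @return A list: `trees` (subtrees with >= 2 leaves), `partition` (leaf-name
#'   sets of all parts, singletons included), `dropped` (leaves removed for
#'   zero-length terminal branches), `collapsed` (number of internal branches
#'   collapsed into polytomies).
#' @export
filter_branches <- function(tree, min_len = 0, max_len = 2) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  # drop leaves on short terminal branches
  term <- tree$edge[, 2] <= ntip
  short_term <- term & tree$edge.length <= min_len
  dropped <- tree$tip.label[tree$edge[short_term, 2]]
  if (length(dropped) > 0L) {
    if (ntip - length(dropped) < 2L) {
      stop("branch filtering would leave fewer than 2 leaves", call. = FALSE)
    }
    tree <- ape::drop.tip(tree, dropped)
  }
  # collapse short internal branches into polytomies
  ntip <- length(tree$tip.label)
  internal <- tree$edge[, 2] > ntip
  collapse <- internal & tree$edge.length <= min_len
  collapsed <- sum(collapse)
  if (collapsed > 0L) {
    tree$edge.length[collapse] <- 0
    tree <- ape::di2multi(tree, tol = 1e-12)
  }
  parts <- cut_long_edges(tree, max_len)
  trees <- Filter(function(p) inherits(p, "phylo"), parts)
  partition <- lapply(parts, function(p) {
    if (inherits(p, "phylo")) sort(p$tip.label) else sort(p)
  })
  list(trees = trees, partition = partition, dropped = dropped,
       collapsed = collapsed)
}

# recursively cut every edge with length >= max_len; returns a list whose
# elements are phylo subtrees or bare leaf-name vectors (singleton parts)
cut_long_edges <- function(tree, max_len) {
  if (!inherits(tree, "phylo")) return(list(tree))
  long <- which(tree$edge.length >= max_len)
  if (length(long) == 0L) return(list(tree))
  info <- edge_leaf_sides(tree)
  tree <- info$tree  # postorder; sides align with its edges
  long <- which(tree$edge.length >= max_len)
  side <- info$sides[[long[1]]]
  other <- setdiff(tree$tip.label, side)
  take <- function(leaves) {
    if (length(leaves) < 2L) return(list(leaves))
    cut_long_edges(ape::keep.tip(tree, leaves), max_len)
  }
  c(take(side), take(other))
}

#' Split an alignment into parts of bounded size along a guide tree
#'
#' Recursively cuts the guide tree at the edge whose bipartition is most
#' balanced (smallest size difference between the two sides; ties broken by
#' the lexicographically smallest canonical split key, so the procedure is
#' deterministic) until every part has at most `max_size` leaves. Each part
#' keeps all alignment columns; the parts' leaf sets partition the guide's
#' leaves.
#'
#' @param alignment An [aa_alignment()] whose names cover the guide's leaves.
#' @param guide A `phylo` guide tree (branch lengths not required).
#' @param max_size Maximum sequences per part (default 128, minimum 4).
#' @return A list of parts, each a list with `alignment` (sub-alignment) and
#'   `tree` (induced subtree; `NULL` for a singleton part).
#' @export
split_alignment <- function(alignment, guide, max_size = 128L) {
  stopifnot(inherits(alignment, "aa_alignment"), inherits(guide, "phylo"))
  max_size <- as.integer(max_size)
  if (max_size < 4L) stop("max_size must be at least 4", call. = FALSE)
  miss <- setdiff(guide$tip.label, alignment$names)
  if (length(miss) > 0L) {
    stop("guide leaves missing from alignment: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pieces <- split_tree_balanced(guide, max_size)
  lapply(pieces, function(p) {
    leaves <- if (inherits(p, "phylo")) p$tip.label else p
    list(alignment = subset_alignment(alignment, leaves),
         tree = if (inherits(p, "phylo")) p else NULL)
  })
}

split_tree_balanced <- function(tree, max_size) {
  if (!inherits(tree, "phylo")) return(list(tree))
  n <- length(tree$tip.label)
  if (n <= max_size) return(list(tree))
  info <- edge_leaf_sides(tree)
  tree <- info$tree
  sizes <- lengths(info$sides)
  balance <- abs(n - 2L * sizes)
  best <- which(balance == min(balance))
  if (length(best) > 1L) {
    keys <- vapply(info$sides[best], canonical_split, character(1),
                   leaves = tree$tip.label)
    best <- best[order(keys)[1]]
  }
  side <- info$sides[[best[1]]]
  other <- setdiff(tree$tip.label, side)
  take <- function(leaves) {
    if (length(leaves) < 2L) return(list(leaves))
    split_tree_balanced(ape::keep.tip(tree, leaves), max_size)
  }
  c(take(side), take(other))
}
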