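# Trees are ape "phylo" objects throughout; all operations treat them as
# unrooted (a degree-2 root is collapsed on parsing).

#' Parse a Newick tree string
#'
#' Wraps the standard Newick reader with up-front structural validation
#' (balanced parentheses with error position, unique leaf names) and collapses
#' a degree-2 root so the result is an unrooted tree. Branch lengths and a
#' trailing semicolon are optional.
#'
#' @param text A Newick string.
#' @return An unrooted `phylo` tree.
#' @examples
#' tr <- parse_newick("((1,2),4,(3,5));")
#' length(tr$tip.label)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("unbalanced ')' at position ", i, call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop("unbalanced '(': ", depth, " unclosed at end of string",
         call. = FALSE)
  }
  if (!grepl(";[[:space:]]*$", text)) text <- paste0(text, ";")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick string", call. = FALSE)
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup) > 0L) {
    stop("duplicate leaf names: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (length(tree$tip.label) > 2L) tree <- ape::unroot(tree)
  tree
}

#' Serialize a tree to Newick
#'
#' @param tree A `phylo` tree.
#' @param digits Significant digits for branch lengths.
#' @return A Newick string with trailing semicolon.
#' @export
write_newick <- function(tree, digits = 10L) {
  ape::write.tree(tree, digits = digits)
}

# leaf-name sides below each edge of a phylo object, as a list of character
# vectors aligned with rows of tree$edge
edge_leaf_sides <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  list(tree = tree, sides = lapply(tree$edge[, 2], function(ch) below[[ch]]))
}

# canonical key for a split: the sorted side NOT containing the
# lexicographically smallest leaf
canonical_split <- function(side, leaves) {
  anchor <- min(leaves)
  if (anchor %in% side) side <- setdiff(leaves, side)
  paste(sort(side), collapse = "|")
}

#' Leaf bipartitions induced by a tree
#'
#' Every edge of an unrooted tree splits the leaves into two sides; a split is
#' *trivial* if one side is a single leaf. Splits are stored in canonical form
#' (the side not containing the lexicographically smallest leaf, sorted), so
#' sets from different trees over the same leaves are directly comparable. A
#' binary unrooted tree over `n` leaves has `2n - 3` edges, hence `2n - 3`
#' bipartitions including the trivial ones.
#'
#' @param tree A `phylo` tree with at least 2 leaves.
#' @param include_trivial Keep the single-leaf splits (default `FALSE`).
#' @return An object of class `bipartition_set`: `keys` (canonical strings),
#'   `sides` (leaf-name vectors), `trivial` (flags), `leaves`.
#' @examples
#' bipartitions(parse_newick("((1,2),4,(3,5));"))$keys
#' @export
bipartitions <- function(tree, include_trivial = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  leaves <- tree$tip.label
  if (length(leaves) < 2L) stop("tree must have >= 2 leaves", call. = FALSE)
  if (length(leaves) == 2L) {
    # single edge between the two leaves: one trivial split
    keys <- canonical_split(leaves[1], leaves)
    sides <- list(setdiff(leaves, min(leaves)))
    out <- list(keys = keys, sides = sides, trivial = TRUE, leaves = leaves)
    if (!include_trivial) {
      out$keys <- character(0)
      out$sides <- list()
      out$trivial <- logical(0)
    }
    return(structure(out, class = "bipartition_set"))
  }
  info <- edge_leaf_sides(tree)
  n <- length(leaves)
  keys <- character(0)
  sides <- list()
  trivial <- logical(0)
  for (side in info$sides) {
    sz <- length(side)
    if (sz == 0L || sz == n) next
    key <- canonical_split(side, leaves)
    if (key %in% keys) next  # both halves of the root edge map to one split
    keys <- c(keys, key)
    sides <- c(sides, list(strsplit(key, "|", fixed = TRUE)[[1]]))
    trivial <- c(trivial, sz == 1L || sz == n - 1L)
  }
  if (!include_trivial) {
    sides <- sides[!trivial]
    keys <- keys[!trivial]
    trivial <- trivial[!trivial]
  }
  structure(list(keys = keys, sides = sides, trivial = trivial,
                 leaves = sort(leaves)),
            class = "bipartition_set")
}

#' @export
print.bipartition_set <- function(x, ...) {
  cat("<bipartition_set> ", length(x$keys), " splits over ",
      length(x$leaves), " leaves (", sum(x$trivial), " trivial)\n", sep = "")
  invisible(x)
}

check_same_leaves <- function(a, b) {
  la <- sort(a$tip.label)
  lb <- sort(b$tip.label)
  if (!identical(la, lb)) {
    only_a <- setdiff(la, lb)
    only_b <- setdiff(lb, la)
    stop("leaf sets differ; only in first: {",
         paste(only_a, collapse = ", "), "}; only in second: {",
         paste(only_b, collapse = ", "), "}", call. = FALSE)
  }
  invisible(la)
}

#' Robinson-Foulds distance between two trees
#'
#' The number of nontrivial bipartitions present in exactly one of the two
#' trees (the symmetric difference of their split sets). Trivial single-leaf
#' splits are always shared between trees on the same leaves, so excluding
#' them changes nothing for binary trees; the count matches the usual RF
#' convention in which two binary trees sharing no internal splits on `n`
#' leaves are at distance `2(n - 3)`.
#'
#' @param a,b `phylo` trees over identical leaf-name sets.
#' @return A non-negative integer.
#' @examples
#' rf_distance(parse_newick("((1,2),4,(3,5));"),
#'             parse_newick("((1,5),2,(3,4));"))
#' @export
rf_distance <- function(a, b) {
  check_same_leaves(a, b)
  ka <- bipartitions(a)$keys
  kb <- bipartitions(b)$keys
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' Normalized Robinson-Foulds distance
#'
#' [rf_distance()] divided by `2n - 3`, the total number of bipartitions
#' (trivial included) of a binary unrooted tree on `n` leaves.
#'
#' @inheritParams rf_distance
#' @return A real in `[0, 1]`.
#' @export
normalized_rf <- function(a, b) {
  leaves <- check_same_leaves(a, b)
  n <- length(leaves)
  if (n < 3L) stop("normalized RF needs >= 3 leaves", call. = FALSE)
  rf_distance(a, b) / (2L * n - 3L)
}

#' Lower bound on incorrect bipartitions in the worse of two trees
#'
#' For two binary unrooted trees inferred from the same alignment, the tree
#' with the worse likelihood must contain at least a quarter of the RF
#' distance between them as incorrect bipartitions, whatever the true tree
#' is: the union of the two split sets exceeds the true tree's capacity of
#' `2n - 3` splits by half the RF distance, and the worse tree carries at
#' least half of that excess.
#'
#' @param rf A non-negative even integer (a symmetric difference is even).
#' @return A list with `bound` (`rf/4`) and `ceiling` (smallest integer count
#'   consistent with the bound).
#' @examples
#' incorrect_bipartition_bound(4)
#' @export
incorrect_bipartition_bound <- function(rf) {
  if (!is.numeric(rf) || length(rf) != 1L || rf < 0 || rf != round(rf)) {
    stop("rf must be a single non-negative integer", call. = FALSE)
  }
  if (rf %% 2 != 0) {
    stop("rf must be even: a symmetric difference of equal-size split sets",
         call. = FALSE)
  }
  list(bound = rf / 4, ceiling = as.integer(ceiling(rf / 4)))
}

#' Count incorrect bipartitions in the union of two trees' splits
#'
#' Number of nontrivial bipartitions present in `a` or `b` but absent from
#' `truth`. This is the quantity the quarter-RF bound of
#' [incorrect_bipartition_bound()] is derived from: it is always at least
#' half of `rf_distance(a, b)`.
#'
#' @param a,b,truth `phylo` trees over identical leaf-name sets.
#' @return A non-negative integer.
#' @export
count_incorrect_in_union <- function(a, b, truth) {
  check_same_leaves(a, b)
  check_same_leaves(a, truth)
  ku <- union(bipartitions(a)$keys, bipartitions(b)$keys)
  kt <- bipartitions(truth)$keys
  length(setdiff(ku, kt))
}
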