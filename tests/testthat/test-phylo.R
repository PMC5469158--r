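test_that("Newick parsing validates structure and preserves topology", {
  tr <- parse_newick("((1,2),4,(3,5));")
  expect_length(tr$tip.label, 5L)
  expect_equal(nrow(tr$edge), 7L)  # binary unrooted: 2n - 3 edges
  two <- parse_newick("(a,b);")
  expect_length(two$tip.label, 2L)
  expect_error(parse_newick("((a,b),c;"), "unbalanced")
  expect_error(parse_newick("(a,b))c;"), "position")
  expect_error(parse_newick("((a,b),(a,c));"), "duplicate")
  # roundtrip preserves the bipartition set
  tr2 <- parse_newick(write_newick(tr))
  expect_setequal(bipartitions(tr2, include_trivial = TRUE)$keys,
                  bipartitions(tr, include_trivial = TRUE)$keys)
})

test_that("bipartition sets have the right size and canonical members", {
  tr <- parse_newick("((1,2),4,(3,5));")
  expect_length(bipartitions(tr, include_trivial = TRUE)$keys, 7L)
  expect_setequal(bipartitions(tr)$keys, c("3|4|5", "3|5"))

  star <- parse_newick("(1,2,3,4,5);")
  bs <- bipartitions(star, include_trivial = TRUE)
  expect_length(bs$keys, 5L)
  expect_true(all(bs$trivial))
  expect_length(bipartitions(star)$keys, 0L)

  # every 5-leaf binary topology induces 7 splits (2 nontrivial) and agrees
  # with an independent clade-enumeration oracle
  for (tr5 in all_five_leaf_topologies()) {
    expect_length(bipartitions(tr5, include_trivial = TRUE)$keys, 7L)
    expect_setequal(bipartitions(tr5)$keys, oracle_nontrivial_splits(tr5))
  }
})

test_that("RF distance matches oracles and is a metric on topologies", {
  a <- parse_newick("((1,2),4,(3,5));")
  b <- parse_newick("((1,5),2,(3,4));")
  expect_identical(rf_distance(a, b), 4L)
  expect_identical(rf_distance(a, a), 0L)
  expect_error(rf_distance(a, parse_newick("((1,2),4,(3,6));")),
               "leaf sets differ")

  trees <- all_five_leaf_topologies()
  n <- length(trees)
  rf <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      rf[i, j] <- rf_distance(trees[[i]], trees[[j]])
      # brute-force oracle: symmetric difference of enumerated splits
      sa <- oracle_nontrivial_splits(trees[[i]])
      sb <- oracle_nontrivial_splits(trees[[j]])
      expect_identical(rf[i, j],
                       length(setdiff(sa, sb)) + length(setdiff(sb, sa)))
    }
  }
  # independent implementation cross-check
  ph <- sapply(trees, function(x) sapply(trees, phangorn::RF.dist, tree2 = x))
  expect_equal(rf, unname(ph), ignore_attr = TRUE)
  # metric properties
  expect_equal(rf, t(rf))
  expect_true(all(diag(rf) == 0L))
  expect_true(all(rf[upper.tri(rf)] > 0L))  # distinct topologies
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(rf[i, k], rf[i, j] + rf[j, k])
  }
})

test_that("normalized RF divides by 2n - 3", {
  a <- parse_newick("((1,2),4,(3,5));")
  b <- parse_newick("((1,5),2,(3,4));")
  expect_equal(normalized_rf(a, b), 4 / 7)
  expect_equal(normalized_rf(a, a), 0)
  # 5-leaf binary trees can share no nontrivial splits, but never exceed 4
  trees <- all_five_leaf_topologies()
  mx <- max(vapply(trees, function(x) {
    max(vapply(trees, rf_distance, integer(1), a = x))
  }, integer(1)))
  expect_identical(mx, 4L)
})

test_that("the quarter-RF bound is valid for every consistent true tree", {
  expect_equal(incorrect_bipartition_bound(4)$bound, 1)
  expect_equal(incorrect_bipartition_bound(4)$ceiling, 1L)
  expect_equal(incorrect_bipartition_bound(0)$bound, 0)
  expect_equal(incorrect_bipartition_bound(6)$ceiling, 2L)
  expect_error(incorrect_bipartition_bound(3), "even")
  expect_error(incorrect_bipartition_bound(-2))

  # exhaustively over 5-leaf topologies: whichever of the two trees is the
  # worse one, the pair's maximum incorrect count reaches the bound for
  # every possible true tree
  trees <- all_five_leaf_topologies()
  count_incorrect <- function(tree, truth) {
    length(setdiff(bipartitions(tree)$keys, bipartitions(truth)$keys))
  }
  for (i in seq_along(trees)) {
    for (j in seq_along(trees)) {
      bound <- incorrect_bipartition_bound(
        rf_distance(trees[[i]], trees[[j]]))$bound
      for (truth in trees) {
        worst <- max(count_incorrect(trees[[i]], truth),
                     count_incorrect(trees[[j]], truth))
        expect_gte(worst, bound)
      }
    }
  }
})

test_that("union incorrect counts match the worked example and the half-RF
           property", {
  a <- parse_newick("((1,2),4,(3,5));")
  b <- parse_newick("((1,5),2,(3,4));")
  truth <- parse_newick("((1,2),5,(3,4));")
  expect_identical(count_incorrect_in_union(a, b, truth), 2L)
  expect_identical(count_incorrect_in_union(truth, truth, truth), 0L)
  trees <- all_five_leaf_topologies()
  set.seed(5)
  for (rep in 1:20) {
    pick <- sample(length(trees), 3L, replace = TRUE)
    expect_gte(count_incorrect_in_union(trees[[pick[1]]], trees[[pick[2]]],
                                        trees[[pick[3]]]),
               rf_distance(trees[[pick[1]]], trees[[pick[2]]]) / 2)
  }
})

test_that("branch filtering collapses, drops, and cuts as specified", {
  # all lengths inside (0, 2): unchanged singleton
  t1 <- parse_newick("((a:0.1,b:0.2):0.3,c:0.4,(d:0.5,e:0.6):0.7);")
  f1 <- filter_branches(t1)
  expect_length(f1$partition, 1L)
  expect_setequal(f1$trees[[1]]$tip.label, t1$tip.label)
  expect_equal(sum(f1$trees[[1]]$edge.length), sum(t1$edge.length))

  # one long internal branch cuts the tree into two parts that partition
  # the leaves, preserving within-part path lengths
  t2 <- parse_newick(
    "((a:0.1,b:0.2):2.5,(c:0.3,d:0.1):0.4,(e:0.2,f:0.3):0.5);")
  f2 <- filter_branches(t2)
  expect_length(f2$partition, 2L)
  expect_setequal(unlist(f2$partition), t2$tip.label)
  small <- f2$trees[[which(lengths(f2$partition) == 2L)]]
  expect_setequal(small$tip.label, c("a", "b"))
  d0 <- ape::cophenetic.phylo(t2)
  for (tr in f2$trees) {
    d1 <- ape::cophenetic.phylo(tr)
    expect_equal(d1, d0[rownames(d1), colnames(d1)], tolerance = 1e-10)
  }
  expect_lt(sum(vapply(f2$trees, function(x) sum(x$edge.length),
                       numeric(1))),
            sum(t2$edge.length))

  # zero-length terminal branch: that leaf dropped, the rest intact
  t3 <- parse_newick("((a:0.0,b:0.2):0.3,c:0.3,(d:0.1,e:0.2):0.2);")
  f3 <- filter_branches(t3)
  expect_identical(f3$dropped, "a")
  expect_setequal(f3$trees[[1]]$tip.label, c("b", "c", "d", "e"))

  # zero-length internal branch collapses into a polytomy
  t4 <- parse_newick("((a:0.1,b:0.2):0.0,c:0.3,(d:0.1,e:0.2):0.2);")
  f4 <- filter_branches(t4)
  expect_identical(f4$collapsed, 1L)
  expect_lt(nrow(f4$trees[[1]]$edge), nrow(t4$edge))

  expect_error(filter_branches(ape::rtopology(5, br = NULL)),
               "branch lengths")
})

test_that("tree-guided splitting bounds part sizes and partitions the taxa", {
  set.seed(31)
  # under the cap: unchanged
  tree100 <- random_tree(100)
  aln100 <- aa_alignment(matrix(sample(c("A", "R", "N"), 100 * 8,
                                       replace = TRUE),
                                100, 8,
                                dimnames = list(tree100$tip.label, NULL)))
  one <- split_alignment(aln100, tree100, 128)
  expect_length(one, 1L)
  expect_identical(n_sequences(one[[1]]$alignment), 100L)

  # 300-leaf random tree: every part <= 128, parts partition the taxa,
  # columns preserved
  tree300 <- random_tree(300)
  aln300 <- aa_alignment(matrix(sample(aa_alphabet()$residues, 300 * 6,
                                       replace = TRUE),
                                300, 6,
                                dimnames = list(tree300$tip.label, NULL)))
  parts <- split_alignment(aln300, tree300, 128)
  sizes <- vapply(parts, function(p) n_sequences(p$alignment), integer(1))
  expect_true(all(sizes <= 128L))
  expect_setequal(unlist(lapply(parts, function(p) p$alignment$names)),
                  tree300$tip.label)
  expect_identical(sum(sizes), 300L)
  expect_true(all(vapply(parts, function(p) n_sites(p$alignment) == 6L,
                         logical(1))))

  # a perfectly balanced 256-leaf tree falls into exactly two parts of 128
  bal <- function(k, pre) {
    if (k == 1) pre
    else paste0("(", bal(k / 2, paste0(pre, "L")), ":1,",
                bal(k / 2, paste0(pre, "R")), ":1)")
  }
  tree256 <- parse_newick(paste0(bal(256, "x"), ";"))
  aln256 <- aa_alignment(matrix("A", 256, 4,
                                dimnames = list(tree256$tip.label, NULL)))
  two <- split_alignment(aln256, tree256, 128)
  expect_length(two, 2L)
  expect_setequal(vapply(two, function(p) n_sequences(p$alignment),
                         integer(1)), c(128L, 128L))

  expect_error(split_alignment(aln256, tree256, 3), "at least 4")
  # determinism
  again <- split_alignment(aln300, tree300, 128)
  expect_identical(lapply(parts, function(p) p$alignment$names),
                   lapply(again, function(p) p$alignment$names))
})
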