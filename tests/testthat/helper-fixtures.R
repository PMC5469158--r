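# Shared fixtures, all generated in code with fixed seeds.

# a valid random model: positive exchangeabilities, non-uniform frequencies
random_model <- function(seed, name = paste0("rand", seed)) {
  set.seed(seed)
  f <- runif(20, 0.5, 2)
  substitution_model(name, runif(190, 0.05, 2.5), f / sum(f))
}

# small simulated alignment with its generating tree attached
sim_fixture <- function(seed, n_taxa = 6, n_sites = 100,
                        model = bundled_model("WAG"),
                        alpha = 0.8, v = 0.1, C = 4) {
  spec <- simulation_spec(model, discretize_gamma(alpha, v, C),
                          n_sites = n_sites, seed = seed, n_taxa = n_taxa)
  simulate_alignment(spec)
}

# all 15 unrooted binary topologies over 5 labelled leaves: pick the
# non-cherry partner of leaf 1 and the pairing of the remaining three
all_five_leaf_topologies <- function(labels = as.character(1:5)) {
  trees <- list()
  for (mate in 2:5) {
    rest <- setdiff(2:5, mate)
    for (k in 1:3) {
      pair <- rest[-k]
      lone <- rest[k]
      txt <- sprintf("((%s,%s),%s,(%s,%s));", labels[1], labels[mate],
                     labels[lone], labels[pair[1]], labels[pair[2]])
      trees[[length(trees) + 1L]] <- parse_newick(txt)
    }
  }
  trees
}

# independent split enumeration via ape's clade decomposition (used as an
# oracle against the package's own bipartition code)
oracle_nontrivial_splits <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  n <- length(labs)
  keys <- character(0)
  for (part in pp) {
    side <- labs[part]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (min(labs) %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

# brute-force site likelihood by summing over all internal-state assignments
exhaustive_site_likelihood <- function(tree, Q, site) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  ninternal <- tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e) {
    transition_probabilities(Q, tree$edge.length[e])
  })
  tipsets <- lapply(tree$tip.label, function(lab) {
    match(aasubst:::aa_permitted(site[[lab]]), aasubst:::AA_RESIDUES)
  })
  root <- tree$edge[nrow(tree$edge), 1]
  internals <- (ntip + 1L):nnode
  grid <- as.matrix(expand.grid(rep(list(1:20), ninternal)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    assign_state <- integer(nnode)
    assign_state[internals] <- grid[g, ]
    pr <- Q$frequencies[[assign_state[root]]]
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]
      ch <- tree$edge[e, 2]
      pe <- P[[e]]
      pr <- pr * if (ch <= ntip) {
        sum(pe[assign_state[p], tipsets[[ch]]])
      } else {
        pe[assign_state[p], assign_state[ch]]
      }
    }
    total <- total + pr
  }
  total
}
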