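# Sequence simulation under a known (tree, model, alpha, v): the ground-truth
# generator that makes every estimation and comparison stage testable.
#
# Study conditions emulated by the defaults: training units are sub-alignments
# of modest size (16 taxa, 500 sites, 8 alignments per collection), branch
# lengths are drawn from an exponential with mean 0.15 substitutions/site
# truncated to (0, 2) -- the same window the branch filter keeps -- and
# per-alignment gamma shapes vary across a realistic 0.5-2 range with a small
# invariant fraction.

#' Specification for one simulated alignment
#'
#' @param model A [substitution_model()] (the generating truth).
#' @param het A [discretize_gamma()] object (generating `alpha`, `v`, `C`).
#' @param n_sites Number of sites (`>= 1`).
#' @param seed Integer seed; the spec fully determines the output.
#' @param tree Optional `phylo` tree with branch lengths; if `NULL` a random
#'   topology over `n_taxa` leaves is drawn with branch lengths from the
#'   truncated exponential.
#' @param n_taxa Number of leaves when `tree` is `NULL`.
#' @param brlen_mean Mean of the exponential branch-length draw.
#' @param brlen_window Truncation window (open below, open above).
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(model, het, n_sites, seed, tree = NULL,
                            n_taxa = 16L, brlen_mean = 0.15,
                            brlen_window = c(0, 2)) {
  stopifnot(inherits(model, "substitution_model"),
            inherits(het, "rate_heterogeneity"),
            n_sites >= 1L, is.numeric(seed))
  structure(list(model = model, het = het, n_sites = as.integer(n_sites),
                 seed = as.integer(seed), tree = tree,
                 n_taxa = as.integer(n_taxa), brlen_mean = brlen_mean,
                 brlen_window = brlen_window),
            class = "simulation_spec")
}

#' Random unrooted tree with truncated-exponential branch lengths
#'
#' Draws a topology uniformly over labelled unrooted topologies (sequential
#' random leaf attachment) and assigns branch lengths from an exponential
#' with mean `brlen_mean`, rejected outside the open `brlen_window`. Uses the
#' active RNG stream; seed it for reproducibility.
#'
#' @param n_taxa Number of leaves (`>= 2`).
#' @param brlen_mean Mean of the exponential draw (substitutions/site).
#' @param brlen_window Open truncation interval.
#' @param labels Leaf labels.
#' @return A `phylo` tree.
#' @export
random_tree <- function(n_taxa, brlen_mean = 0.15, brlen_window = c(0, 2),
                        labels = paste0("t", seq_len(n_taxa))) {
  stopifnot(n_taxa >= 2L)
  tree <- ape::rtopology(n_taxa, rooted = FALSE, tip.label = labels)
  ne <- nrow(tree$edge)
  draw <- function(k) {
    out <- numeric(0)
    while (length(out) < k) {
      x <- rexp(k, rate = 1 / brlen_mean)
      out <- c(out, x[x > brlen_window[1] & x < brlen_window[2]])
    }
    out[seq_len(k)]
  }
  tree$edge.length <- draw(ne)
  tree
}

#' Simulate an alignment under a known model
#'
#' Per site: an invariant flag is drawn with probability `v`, otherwise a
#' gamma category; the root residue is drawn from the equilibrium
#' frequencies and evolved down the tree with the transition matrices
#' `P(rho_c * t)` per branch (invariant sites keep the root residue
#' everywhere). The same seed always reproduces the same alignment.
#'
#' @param spec A [simulation_spec()].
#' @return An [aa_alignment()] with attributes `tree` (the generating tree),
#'   `categories` (per-site category; 0 = invariant) and `spec`.
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  tree <- spec$tree
  if (is.null(tree)) {
    tree <- random_tree(spec$n_taxa, spec$brlen_mean, spec$brlen_window)
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  Q <- build_rate_matrix(spec$model, normalize = TRUE)
  het <- spec$het
  n <- spec$n_sites
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nedge <- nrow(tree$edge)
  # site classes: 0 = invariant, 1..C gamma categories
  cls <- ifelse(runif(n) < het$v, 0L, sample.int(het$C, n, replace = TRUE))
  root <- tree$edge[nedge, 1]
  states <- matrix(0L, nnode, n)
  states[root, ] <- sample.int(20L, n, replace = TRUE,
                               prob = Q$frequencies)
  # transition matrices per (edge, category)
  P <- vector("list", het$C)
  for (c in seq_len(het$C)) {
    P[[c]] <- lapply(seq_len(nedge), function(e) {
      transition_probabilities(Q, tree$edge.length[e] * het$rho[c])
    })
  }
  for (e in rev(seq_len(nedge))) {  # preorder: root-to-tip
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    states[ch, ] <- states[p, ]  # invariant sites copy through
    for (c in seq_len(het$C)) {
      idx <- which(cls == c)
      if (length(idx) == 0L) next
      par_states <- states[p, idx]
      for (a in unique(par_states)) {
        sel <- idx[par_states == a]
        states[ch, sel] <- sample.int(20L, length(sel), replace = TRUE,
                                      prob = P[[c]][[e]][a, ])
      }
    }
  }
  m <- matrix(AA_RESIDUES[states[seq_len(ntip), , drop = FALSE]],
              nrow = ntip, dimnames = list(tree$tip.label, NULL))
  aln <- aa_alignment(m)
  attr(aln, "tree") <- tree
  attr(aln, "categories") <- cls
  attr(aln, "spec") <- spec
  aln
}

#' Simulate a training collection on disk
#'
#' Writes `n_alignments` FASTA alignments plus their generating Newick trees
#' and a plain-text manifest of the true parameters. Per alignment, a fresh
#' random topology is drawn with truncated-exponential branch lengths (mean
#' `brlen_mean`, window `brlen_window`), the gamma shape is drawn uniformly
#' from `alpha_range` and the invariant proportion uniformly from `v_range`.
#'
#' @param n_alignments Number of alignments (`>= 1`).
#' @param dir Output directory (created if needed).
#' @param model Generating [substitution_model()].
#' @param n_taxa,n_sites Size of each alignment.
#' @param alpha_range,v_range Per-alignment parameter draw ranges.
#' @param brlen_mean,brlen_window Branch-length draw (see above).
#' @param C Gamma categories.
#' @param seed Master seed; per-alignment seeds are derived from it.
#' @return Invisibly, a list: `training` (a [training_set()] of the simulated
#'   alignments), `manifest` (data frame), `dir`.
#' @export
simulate_training_set <- function(n_alignments, dir, model,
                                  n_taxa = 16L, n_sites = 500L,
                                  alpha_range = c(0.5, 2),
                                  v_range = c(0, 0.2),
                                  brlen_mean = 0.15, brlen_window = c(0, 2),
                                  C = 4L, seed = 1L) {
  stopifnot(n_alignments >= 1L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  alphas <- runif(n_alignments, alpha_range[1], alpha_range[2])
  vs <- runif(n_alignments, v_range[1], v_range[2])
  seeds <- sample.int(2^30, n_alignments)
  alns <- vector("list", n_alignments)
  rows <- vector("list", n_alignments)
  for (i in seq_len(n_alignments)) {
    spec <- simulation_spec(model, discretize_gamma(alphas[i], vs[i], C),
                            n_sites, seeds[i], n_taxa = n_taxa,
                            brlen_mean = brlen_mean,
                            brlen_window = brlen_window)
    aln <- simulate_alignment(spec)
    fasta <- file.path(dir, sprintf("aln%03d.fasta", i))
    nwk <- file.path(dir, sprintf("aln%03d.nwk", i))
    write_fasta(aln, fasta)
    ape::write.tree(attr(aln, "tree"), nwk)
    alns[[i]] <- aln
    rows[[i]] <- data.frame(alignment = basename(fasta),
                            tree = basename(nwk),
                            n_taxa = n_taxa, n_sites = n_sites,
                            alpha = alphas[i], v = vs[i], seed = seeds[i])
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(training = training_set(alns), manifest = manifest,
                 dir = dir))
}

#' Recover the divergence of a simulated two-taxon alignment
#'
#' Convenience check instrument: the one-dimensional ML distance between the
#' two sequences of a pairwise simulation, for verifying that simulated
#' divergence is recovered by the likelihood machinery.
#'
#' @param aln A two-sequence [aa_alignment()].
#' @param model A [substitution_model()] or [build_rate_matrix()].
#' @return The estimated distance.
#' @export
pairwise_distance_check <- function(aln, model) {
  stopifnot(inherits(aln, "aa_alignment"))
  if (n_sequences(aln) != 2L) stop("need exactly 2 sequences",
                                   call. = FALSE)
  if (n_sites(aln) == 0L) stop("zero-length alignment", call. = FALSE)
  ml_pairwise_distance(aln, model)
}
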