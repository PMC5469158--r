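# Alignment likelihood under a reversible model with +I+G rate heterogeneity.
#
# The per-site likelihood is the standard mixture
#   L_i = v * L(Invariant; D_i) + (1 - v) * (1/C) * sum_c L(rho_c T, Q; D_i),
# where rho_c T is the tree with branch lengths multiplied by the category
# rate, L(Invariant; D_i) is the frequency of the residue a constant site is
# fixed at (ambiguity-compatible; 0 for a non-constant site), and each
# category term is a pruning likelihood. The total log-likelihood is the sum
# of per-site logs of this mixture.

#' Pruning likelihood of a single alignment column
#'
#' Computes the probability of one site on a tree by Felsenstein's post-order
#' pruning: each node carries a 20-vector of partial likelihoods, ambiguity
#' codes enter as indicator sets, and the root sum is weighted by the
#' equilibrium frequencies. This is the plain single-rate site likelihood
#' (no rate heterogeneity); [alignment_loglik()] mixes it over rate classes.
#'
#' This reference implementation is written in straightforward R; the
#' alignment-level engine reproduces it exactly and is the one used in
#' optimization loops.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param Q A [build_rate_matrix()] result.
#' @param site Named character vector of residue codes covering the tree's
#'   leaves (or unnamed, in `tree$tip.label` order).
#' @return The site probability (not logged).
#' @export
site_likelihood <- function(tree, Q, site) {
  stopifnot(inherits(tree, "phylo"), inherits(Q, "rate_matrix"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  tips <- tree$tip.label
  if (!is.null(names(site))) {
    miss <- setdiff(tips, names(site))
    if (length(miss) > 0L) {
      stop("no data for leaves: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    site <- site[tips]
  } else if (length(site) != length(tips)) {
    stop("unnamed site must have one residue per leaf", call. = FALSE)
  }
  if (length(tips) == 1L) {
    return(sum(Q$frequencies[aa_permitted(site[1])]))
  }
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tips)
  nnode <- ntip + tree$Nnode
  partial <- matrix(NA_real_, 20L, nnode)
  partial[, seq_len(ntip)] <- aa_indicator(site)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    P <- transition_probabilities(Q, tree$edge.length[e])
    msg <- as.vector(P %*% partial[, ch])
    partial[, p] <- if (anyNA(partial[, p])) msg else partial[, p] * msg
  }
  root <- tree$edge[nrow(tree$edge), 1]
  sum(Q$frequencies * partial[, root])
}

# shared preparation for the C++ engine: postorder edges, tip cube, patterns
prep_likelihood <- function(tree, aln) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  tree <- ape::reorder.phylo(tree, "postorder")
  pat <- compress_patterns(aln)
  cube <- tip_partial_cube(pat$patterns, tree$tip.label)
  list(tree = tree, edge = tree$edge, el = tree$edge.length,
       cube = cube, weights = pat$weights, index = pat$index,
       patterns = pat$patterns)
}

# engine call on prepared data; Q is a rate_matrix, het a rate_heterogeneity
engine_loglik <- function(prep, Q, het, el = NULL,
                          grad_q = FALSE, grad_t = FALSE) {
  invlik <- invariant_likelihood(prep$patterns, Q$frequencies)
  cpp_mix_loglik(prep$cube, prep$edge,
                 if (is.null(el)) prep$el else el,
                 Q$eigen$vectors, Q$eigen$values, Q$eigen$inverse,
                 unname(Q$frequencies), het$rho, het$v, invlik,
                 prep$weights, grad_q, grad_t)
}

#' Log-likelihood of an alignment under a model with +I+G heterogeneity
#'
#' Evaluates the total and per-site log-likelihood of an alignment on a tree
#' under a substitution model with proportion-invariant plus discrete-gamma
#' rate heterogeneity. Site patterns are compressed before the pruning pass
#' and per-node scaling guards against underflow; per-site values are
#' returned in alignment order.
#'
#' @param tree A `phylo` tree with branch lengths (substitutions/site under
#'   the normalized generator).
#' @param model A [substitution_model()], or a prebuilt [build_rate_matrix()].
#' @param het A [discretize_gamma()] rate-heterogeneity object.
#' @param aln An [aa_alignment()] containing all tree leaves.
#' @return An object of class `likelihood_result`: `loglik`, `site_loglik`
#'   (alignment order), and `params` (model name, alpha, v, C, tree).
#' @examples
#' aln <- aa_alignment(c(a = "AR", b = "AR", c = "AN"))
#' tr <- parse_newick("(a:0.1,b:0.1,c:0.2);")
#' alignment_loglik(tr, uniform_model(), discretize_gamma(1), aln)$loglik
#' @export
alignment_loglik <- function(tree, model, het, aln) {
  Q <- if (inherits(model, "rate_matrix")) model else
    build_rate_matrix(model, normalize = TRUE)
  stopifnot(inherits(het, "rate_heterogeneity"),
            inherits(aln, "aa_alignment"))
  prep <- prep_likelihood(tree, aln)
  res <- engine_loglik(prep, Q, het)
  if (!is.finite(res$loglik)) {
    bad <- which(!is.finite(res$sitelog[prep$index]))
    stop("non-finite log-likelihood at site(s) ",
         paste(head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  likelihood_result(res$loglik, res$sitelog[prep$index],
                    model = if (inherits(model, "rate_matrix")) NULL
                            else model,
                    het = het, tree = prep$tree)
}

likelihood_result <- function(loglik, site_loglik, model, het, tree) {
  structure(list(loglik = loglik,
                 site_loglik = site_loglik,
                 params = list(model_name = if (is.null(model)) NA_character_
                                            else model$name,
                               alpha = het$alpha, v = het$v, C = het$C,
                               tree = tree)),
            class = "likelihood_result")
}

#' @export
print.likelihood_result <- function(x, ...) {
  cat("<likelihood_result> lnL = ", format(x$loglik, digits = 10),
      " over ", length(x$site_loglik), " sites\n", sep = "")
  invisible(x)
}

#' Optimize branch lengths by maximum likelihood
#'
#' Maximizes the +I+G alignment log-likelihood over all branch lengths
#' jointly, working on the log scale with the analytic gradient from the
#' pruning engine (quasi-Newton with box constraints). Rounds are repeated
#' until the improvement falls below `tol_lnl`; the log-likelihood never
#' decreases, and re-running on an optimized tree is a no-op within
#' tolerance. Missing or non-positive starting lengths are initialized at
#' 0.1 substitutions/site.
#'
#' @param tree A `phylo` tree (branch lengths optional).
#' @param model A [substitution_model()] or [build_rate_matrix()].
#' @param het A [discretize_gamma()] object.
#' @param aln An [aa_alignment()].
#' @param min_len,max_len Box bounds on branch lengths.
#' @param tol_lnl Stop when a full round improves the log-likelihood by less
#'   than this (default `1e-4`).
#' @param max_rounds Maximum optimizer restarts.
#' @return A list: `tree` (optimized lengths), `result`
#'   ([likelihood_result]), `iterations`.
#' @export
optimize_branch_lengths <- function(tree, model, het, aln,
                                    min_len = 1e-8, max_len = 100,
                                    tol_lnl = 1e-4, max_rounds = 5L) {
  Q <- if (inherits(model, "rate_matrix")) model else
    build_rate_matrix(model, normalize = TRUE)
  prep <- prep_likelihood(tree, aln)
  el <- prep$el
  if (is.null(el)) el <- rep(0.1, nrow(prep$edge))
  el[!is.finite(el) | el <= 0] <- 0.1
  el <- pmin(pmax(el, min_len), max_len)
  invlik <- invariant_likelihood(prep$patterns, Q$frequencies)
  ev <- Q$eigen
  fn <- function(lx) {
    r <- cpp_mix_loglik(prep$cube, prep$edge, exp(lx), ev$vectors, ev$values,
                        ev$inverse, unname(Q$frequencies), het$rho, het$v,
                        invlik, prep$weights, FALSE, FALSE)
    if (!is.finite(r$loglik)) return(1e10)
    -r$loglik
  }
  gr <- function(lx) {
    r <- cpp_mix_loglik(prep$cube, prep$edge, exp(lx), ev$vectors, ev$values,
                        ev$inverse, unname(Q$frequencies), het$rho, het$v,
                        invlik, prep$weights, FALSE, TRUE)
    -r$grad_t * exp(lx)
  }
  start_lnl <- -fn(log(el))
  if (!is.finite(start_lnl)) {
    stop("non-finite log-likelihood at starting branch lengths",
         call. = FALSE)
  }
  best <- log(el)
  best_lnl <- start_lnl
  iterations <- 0L
  for (round in seq_len(max_rounds)) {
    opt <- stats::optim(best, fn, gr, method = "L-BFGS-B",
                        lower = log(min_len), upper = log(max_len),
                        control = list(maxit = 200L, factr = 1e7))
    iterations <- iterations + 1L
    gain <- (-opt$value) - best_lnl
    if (is.finite(opt$value) && gain > 0) {
      best <- opt$par
      best_lnl <- -opt$value
    }
    if (!is.finite(opt$value) || gain < tol_lnl) break
  }
  new_tree <- prep$tree
  new_tree$edge.length <- exp(best)
  res <- alignment_loglik(new_tree, Q, het, aln)
  list(tree = new_tree, result = res, iterations = iterations)
}

#' Optimize rate-heterogeneity parameters
#'
#' Maximizes the alignment log-likelihood over the gamma shape `alpha`
#' (bounds `[0.02, 100]`) and the invariant proportion `v` (bounds
#' `[0, 0.99]`) with the model and branch lengths fixed, by bounded
#' quasi-Newton search from the supplied starting values. The fitted
#' log-likelihood never falls below the starting one.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param model A [substitution_model()] or [build_rate_matrix()].
#' @param het0 Starting [discretize_gamma()] values (`alpha` default 1,
#'   `v` default 0.1 are conventional).
#' @param aln An [aa_alignment()].
#' @param optimize_v Set `FALSE` to keep `v` fixed at its starting value.
#' @return A list: `het` (fitted), `result` ([likelihood_result]).
#' @export
optimize_rate_model <- function(tree, model, het0, aln, optimize_v = TRUE) {
  Q <- if (inherits(model, "rate_matrix")) model else
    build_rate_matrix(model, normalize = TRUE)
  prep <- prep_likelihood(tree, aln)
  invlik <- invariant_likelihood(prep$patterns, Q$frequencies)
  ev <- Q$eigen
  eval_lnl <- function(alpha, v) {
    het <- discretize_gamma(alpha, v, het0$C)
    r <- cpp_mix_loglik(prep$cube, prep$edge, prep$el, ev$vectors, ev$values,
                        ev$inverse, unname(Q$frequencies), het$rho, het$v,
                        invlik, prep$weights, FALSE, FALSE)
    r$loglik
  }
  start <- c(log(min(max(het0$alpha, 0.02), 100)),
             min(max(het0$v, 0), 0.99))
  fn <- function(p) {
    val <- eval_lnl(exp(p[1]), if (optimize_v) p[2] else het0$v)
    if (!is.finite(val)) 1e10 else -val
  }
  opt <- stats::optim(start, fn, method = "L-BFGS-B",
                      lower = c(log(0.02), 0), upper = c(log(100), 0.99),
                      control = list(maxit = 200L, factr = 1e7))
  start_lnl <- -fn(start)
  if (is.finite(opt$value) && -opt$value >= start_lnl) {
    alpha <- exp(opt$par[1])
    v <- if (optimize_v) opt$par[2] else het0$v
  } else {
    alpha <- het0$alpha
    v <- het0$v
  }
  het <- discretize_gamma(alpha, v, het0$C)
  list(het = het, result = alignment_loglik(prep$tree, Q, het, aln))
}

# joint optimization of branch lengths, gamma shape and invariant proportion:
# L-BFGS-B over (log el, log alpha, v) with the engine's analytic gradient for
# the branch block and central differences for the two rate parameters.
# The alternating one-block optimizers above are kept as building blocks; the
# joint search avoids the slow zigzag of strongly coupled (length, shape)
# updates.
optimize_alignment_jointly <- function(tree, Q, het0, aln,
                                       min_len = 1e-8, max_len = 100) {
  prep <- prep_likelihood(tree, aln)
  el <- prep$el
  if (is.null(el)) el <- rep(0.1, nrow(prep$edge))
  el[!is.finite(el) | el <= 0] <- 0.1
  el <- pmin(pmax(el, min_len), max_len)
  invlik <- invariant_likelihood(prep$patterns, Q$frequencies)
  ev <- Q$eigen
  ne <- length(el)
  C <- het0$C
  eval_raw <- function(lel, alpha, v, grad_t = FALSE) {
    rho <- discretize_gamma(alpha, 0, C)$rho
    cpp_mix_loglik(prep$cube, prep$edge, exp(lel), ev$vectors, ev$values,
                   ev$inverse, unname(Q$frequencies), rho, v, invlik,
                   prep$weights, FALSE, grad_t)
  }
  fn <- function(p) {
    r <- eval_raw(p[seq_len(ne)], exp(p[ne + 1L]), p[ne + 2L])
    if (!is.finite(r$loglik)) 1e10 else -r$loglik
  }
  gr <- function(p) {
    r <- eval_raw(p[seq_len(ne)], exp(p[ne + 1L]), p[ne + 2L],
                  grad_t = TRUE)
    h <- 1e-5
    la <- p[ne + 1L]
    da <- (eval_raw(p[seq_len(ne)], exp(la + h), p[ne + 2L])$loglik -
             eval_raw(p[seq_len(ne)], exp(la - h), p[ne + 2L])$loglik) /
      (2 * h)
    v <- p[ne + 2L]
    hv <- min(1e-5, (0.99 - v) / 2, if (v > 0) v / 2 else 1e-5)
    dv <- if (hv > 0) {
      (eval_raw(p[seq_len(ne)], exp(la), v + hv)$loglik -
         eval_raw(p[seq_len(ne)], exp(la), v - hv)$loglik) / (2 * hv)
    } else 0
    out <- c(-r$grad_t * exp(p[seq_len(ne)]), -da, -dv)
    out[!is.finite(out)] <- 0
    out
  }
  p0 <- c(log(el), log(min(max(het0$alpha, 0.02), 100)),
          min(max(het0$v, 0), 0.989))
  lnl0 <- -fn(p0)
  if (!is.finite(lnl0)) {
    stop("non-finite log-likelihood at starting parameters", call. = FALSE)
  }
  opt <- stats::optim(p0, fn, gr, method = "L-BFGS-B",
                      lower = c(rep(log(min_len), ne), log(0.02), 0),
                      upper = c(rep(log(max_len), ne), log(100), 0.99),
                      control = list(maxit = 500L, factr = 1e7))
  p <- if (is.finite(opt$value) && -opt$value >= lnl0) opt$par else p0
  new_tree <- prep$tree
  new_tree$edge.length <- exp(p[seq_len(ne)])
  het <- discretize_gamma(exp(p[ne + 1L]), p[ne + 2L], C)
  list(tree = new_tree, het = het,
       result = alignment_loglik(new_tree, Q, het, aln))
}

#' Information criteria from a log-likelihood
#'
#' `AIC = 2k - 2 lnL` and `BIC = k ln(n) - 2 lnL`, with per-site versions
#' dividing by the number of sites. The parameter count `k` is supplied
#' explicitly by the caller (what counts as free -- branch lengths, rate
#' parameters, matrix entries -- depends on the protocol).
#'
#' @param lnl Log-likelihood.
#' @param k Number of free parameters.
#' @param n_sites Number of sites (`>= 1`).
#' @return Named numeric vector: `AIC`, `BIC`, `AIC_per_site`,
#'   `BIC_per_site`.
#' @examples
#' information_criteria(-1000, 10, 500)
#' @export
information_criteria <- function(lnl, k, n_sites) {
  stopifnot(is.numeric(lnl), is.numeric(k), n_sites >= 1)
  aic <- 2 * k - 2 * lnl
  bic <- k * log(n_sites) - 2 * lnl
  c(AIC = aic, BIC = bic,
    AIC_per_site = aic / n_sites, BIC_per_site = bic / n_sites)
}

#' Export per-site log-likelihoods in the CONSEL input format
#'
#' Writes the TREE-PUZZLE-style site-likelihood matrix that CONSEL ingests
#' for tree tests: a header line `<n_trees> <n_sites>` followed by one row
#' per fitted (tree, model) of whitespace-separated per-site
#' log-likelihoods, at full precision.
#'
#' @param results A list of [likelihood_result] objects for the same
#'   alignment (equal site counts).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
export_site_lnl <- function(results, path) {
  stopifnot(length(results) >= 1L)
  ns <- vapply(results, function(r) length(r$site_loglik), integer(1))
  if (length(unique(ns)) != 1L) {
    stop("results have differing site counts: ",
         paste(unique(ns), collapse = ", "), call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(results), ns[1]), con)
  for (r in results) {
    writeLines(paste(sprintf("%.10g", r$site_loglik), collapse = " "), con)
  }
  invisible(path)
}

#' Read a site log-likelihood matrix written by [export_site_lnl()]
#'
#' @param path Input file.
#' @return A numeric matrix, one row per (tree, model).
#' @export
read_site_lnl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
  vals <- lapply(lines[1 + seq_len(hdr[1])], function(l) {
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])
  })
  if (any(lengths(vals) != hdr[2])) {
    stop("ragged site-likelihood rows", call. = FALSE)
  }
  do.call(rbind, vals)
}
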