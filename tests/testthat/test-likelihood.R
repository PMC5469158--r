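test_that("discrete-gamma category rates match the integration oracle", {
  for (alpha in c(0.3, 1, 2.7)) {
    het <- discretize_gamma(alpha, C = 4)
    expect_lt(abs(mean(het$rho) - 1), 1e-10)
    expect_true(all(diff(het$rho) > 0))
    # numeric-integration oracle for the conditional bin means
    cuts <- c(0, qgamma(1:3 / 4, alpha, rate = alpha), Inf)
    oracle <- vapply(1:4, function(c) {
      4 * integrate(function(x) x * dgamma(x, alpha, rate = alpha),
                    cuts[c], cuts[c + 1], rel.tol = 1e-10)$value
    }, numeric(1))
    expect_equal(het$rho, oracle, tolerance = 1e-6)
  }
  # frozen reference values for the exponential case
  expect_equal(discretize_gamma(1, C = 4)$rho,
               c(0.1369, 0.4768, 1.0000, 2.3863), tolerance = 5e-4)
  # degenerate limits
  # degenerate limit: bin means approach 1 at rate 1/sqrt(alpha)
  expect_true(all(abs(discretize_gamma(1e7, C = 4)$rho - 1) < 1e-3))
  expect_identical(discretize_gamma(0.5, C = 1)$rho, 1)
  expect_error(discretize_gamma(0), "positive")
  expect_error(discretize_gamma(1, v = 1), "\\[0, 1\\)")
})

test_that("site likelihood agrees with closed forms and the exhaustive
           ancestral-state oracle", {
  m <- random_model(7)
  Q <- build_rate_matrix(m)
  # two taxa joined through the root: pi_x P_xy(t1 + t2)
  tr2 <- ape::read.tree(text = "(a:0.13,b:0.21);")
  P <- transition_probabilities(Q, 0.34)
  expect_equal(site_likelihood(tr2, Q, c(a = "W", b = "H")),
               m$frequencies[["W"]] * P["W", "H"], tolerance = 1e-12)
  # ambiguity code sums over its residue set
  expect_equal(site_likelihood(tr2, Q, c(a = "W", b = "B")),
               m$frequencies[["W"]] * (P["W", "N"] + P["W", "D"]),
               tolerance = 1e-12)
  # 4-taxon tree vs brute-force sum over all 20^2 internal states
  tr4 <- parse_newick("((a:0.11,b:0.32):0.17,c:0.25,d:0.09);")
  set.seed(8)
  for (rep in 1:4) {
    site <- setNames(sample(c(aa_alphabet()$residues, "X", "-"), 4,
                            replace = TRUE, prob = c(rep(1, 20), 3, 3)),
                     c("a", "b", "c", "d"))
    expect_equal(site_likelihood(tr4, Q, site),
                 exhaustive_site_likelihood(tr4, Q, site),
                 tolerance = 1e-12)
  }
})

test_that("alignment log-likelihood equals the per-site mixture built from
           the reference pruning implementation", {
  wag <- bundled_model("WAG")
  Q <- build_rate_matrix(wag)
  het <- discretize_gamma(0.8, v = 0.15, C = 4)
  aln <- sim_fixture(19, n_taxa = 5, n_sites = 40, alpha = 0.8, v = 0.15)
  tr <- attr(aln, "tree")
  res <- alignment_loglik(tr, wag, het, aln)
  expect_equal(sum(res$site_loglik), res$loglik, tolerance = 1e-6)
  oracle <- vapply(seq_len(n_sites(aln)), function(i) {
    col <- setNames(aln$seqs[, i], aln$names)
    compat <- Reduce(intersect, lapply(col, aasubst:::aa_permitted),
                     aa_alphabet()$residues)
    inv <- sum(wag$frequencies[compat])
    cats <- vapply(het$rho, function(r) {
      scaled <- tr
      scaled$edge.length <- scaled$edge.length * r
      site_likelihood(scaled, Q, col)
    }, numeric(1))
    log(het$v * inv + (1 - het$v) * mean(cats))
  }, numeric(1))
  expect_equal(res$site_loglik, oracle, tolerance = 1e-8)

  # v = 0, C = 1 collapses to plain per-site pruning
  het0 <- discretize_gamma(1, v = 0, C = 1)
  res0 <- alignment_loglik(tr, wag, het0, aln)
  plain <- vapply(seq_len(n_sites(aln)), function(i) {
    log(site_likelihood(tr, Q, setNames(aln$seqs[, i], aln$names)))
  }, numeric(1))
  expect_equal(res0$site_loglik, plain, tolerance = 1e-8)
})

test_that("likelihood agrees with an independent implementation at v = 0", {
  wag <- bundled_model("WAG")
  het <- discretize_gamma(0.7, v = 0, C = 4)
  aln <- sim_fixture(3, n_taxa = 8, n_sites = 120, alpha = 0.7, v = 0)
  tr <- attr(aln, "tree")
  mine <- alignment_loglik(tr, wag, het, aln)$loglik
  pd <- phangorn::phyDat(aln$seqs, type = "AA")
  fit <- phangorn::pml(tr, pd, model = "WAG", k = 4, shape = 0.7, inv = 0)
  expect_equal(mine, fit$logLik, tolerance = 1e-6)
})

test_that("pattern compression, leaf order, and rooting do not change the
           likelihood", {
  wag <- bundled_model("WAG")
  het <- discretize_gamma(1.2, v = 0.1, C = 4)
  aln <- sim_fixture(23, n_taxa = 6, n_sites = 50)
  tr <- attr(aln, "tree")
  base <- alignment_loglik(tr, wag, het, aln)
  # duplicated columns: total doubles, per-site values repeat
  dup <- aa_alignment(cbind(aln$seqs, aln$seqs))
  both <- alignment_loglik(tr, wag, het, dup)
  expect_equal(both$loglik, 2 * base$loglik, tolerance = 1e-8)
  expect_equal(both$site_loglik, rep(base$site_loglik, 2),
               tolerance = 1e-10)
  # row order of the alignment is irrelevant
  perm <- aa_alignment(aln$seqs[rev(aln$names), ])
  expect_equal(alignment_loglik(tr, wag, het, perm)$loglik, base$loglik,
               tolerance = 1e-8)
  # re-rooting is irrelevant for a reversible model
  rooted <- ape::root(tr, outgroup = tr$tip.label[3], resolve.root = TRUE)
  expect_equal(alignment_loglik(rooted, wag, het, aln)$loglik, base$loglik,
               tolerance = 1e-6)
})

test_that("invariant mass cannot help an alignment without constant sites", {
  wag <- bundled_model("WAG")
  aln <- sim_fixture(29, n_taxa = 6, n_sites = 80, alpha = 2, v = 0)
  keep <- vapply(seq_len(n_sites(aln)), function(i) {
    length(unique(aln$seqs[, i])) > 1L
  }, logical(1))
  aln <- aa_alignment(aln$seqs[, keep, drop = FALSE])
  tr <- attr(sim_fixture(29, n_taxa = 6, n_sites = 80), "tree")
  l0 <- alignment_loglik(tr, wag, discretize_gamma(2, v = 0), aln)$loglik
  l3 <- alignment_loglik(tr, wag, discretize_gamma(2, v = 0.3), aln)$loglik
  expect_lt(l3, l0)
})

test_that("branch-length optimization recovers simulated lengths and is a
           monotone, idempotent fixed point", {
  wag <- bundled_model("WAG")
  truth <- parse_newick(paste0("((a:0.3,b:0.05):0.12,(c:0.6,d:0.1):0.2,",
                               "(e:1.0,f:0.4):0.08);"))
  het <- discretize_gamma(1, v = 0, C = 1)
  spec <- simulation_spec(wag, het, n_sites = 2000, seed = 41, tree = truth)
  aln <- simulate_alignment(spec)
  start <- truth
  start$edge.length <- rep(0.25, nrow(truth$edge))
  fit <- optimize_branch_lengths(start, wag, het, aln)
  ord <- match(apply(truth$edge, 1, paste, collapse = "-"),
               apply(fit$tree$edge, 1, paste, collapse = "-"))
  err <- abs(fit$tree$edge.length[ord] - truth$edge.length)
  rel <- err / truth$edge.length
  # relative recovery for informative lengths; short branches are bounded by
  # their absolute sampling error (SE ~ sqrt(t/n))
  expect_true(all(rel[truth$edge.length >= 0.1] < 0.15))
  expect_true(all(err[truth$edge.length < 0.1] < 0.02))
  # monotone vs the starting likelihood, idempotent on re-run
  l_start <- alignment_loglik(start, wag, het, aln)$loglik
  expect_gte(fit$result$loglik, l_start)
  fit2 <- optimize_branch_lengths(fit$tree, wag, het, aln)
  expect_lt(abs(fit2$result$loglik - fit$result$loglik), 1e-3)
  expect_equal(fit2$tree$edge.length, fit$tree$edge.length,
               tolerance = 1e-2)
})

test_that("two-taxon branch optimization matches the closed-form pairwise
           maximum likelihood", {
  m <- random_model(44)
  het <- discretize_gamma(1, v = 0, C = 1)
  spec <- simulation_spec(m, het, n_sites = 3000, seed = 45,
                          tree = ape::read.tree(text = "(a:0.25,b:0.25);"))
  aln <- simulate_alignment(spec)
  fit <- optimize_branch_lengths(attr(aln, "spec")$tree, m, het, aln)
  d_tree <- sum(fit$tree$edge.length)
  d_ml <- ml_pairwise_distance(aln, m)
  expect_equal(d_tree, d_ml, tolerance = 1e-4)
})

test_that("rate-heterogeneity optimization recovers simulated alpha and v", {
  wag <- bundled_model("WAG")
  aln <- sim_fixture(53, n_taxa = 16, n_sites = 5000, alpha = 0.5, v = 0.2)
  tr <- attr(aln, "tree")
  fit <- optimize_rate_model(tr, wag, discretize_gamma(1, v = 0.1), aln)
  expect_gt(fit$het$alpha, 0.35)
  expect_lt(fit$het$alpha, 0.7)
  expect_gt(fit$het$v, 0.1)
  expect_lt(fit$het$v, 0.3)
  # rate-uniform data: either alpha runs high or the gamma model is within
  # a couple of log units of the fixed-rate fit
  unif <- sim_fixture(54, n_taxa = 8, n_sites = 1000, alpha = 500, v = 0)
  tru <- attr(unif, "tree")
  fitu <- optimize_rate_model(tru, wag, discretize_gamma(1, v = 0), unif,
                              optimize_v = FALSE)
  fixed <- alignment_loglik(tru, wag, discretize_gamma(1e6, v = 0), unif)
  expect_true(fitu$het$alpha > 10 ||
                abs(fitu$result$loglik - fixed$loglik) < 2)
  # v pinned at 0 with C = 1: nothing to optimize, likelihood unchanged
  het1 <- discretize_gamma(1, v = 0, C = 1)
  aln1 <- sim_fixture(55, n_taxa = 5, n_sites = 60)
  tr1 <- attr(aln1, "tree")
  fit1 <- optimize_rate_model(tr1, wag, het1, aln1, optimize_v = FALSE)
  expect_equal(fit1$result$loglik,
               alignment_loglik(tr1, wag, het1, aln1)$loglik,
               tolerance = 1e-8)
})

test_that("likelihood is invariant to generator normalization once branch
           lengths are re-optimized", {
  m <- random_model(61)
  het <- discretize_gamma(1, v = 0, C = 2)
  aln <- sim_fixture(62, n_taxa = 6, n_sites = 300, model = m, alpha = 1,
                     v = 0)
  tr <- attr(aln, "tree")
  Qn <- build_rate_matrix(m, normalize = TRUE)
  Qu <- build_rate_matrix(m, normalize = FALSE)
  fit_n <- optimize_branch_lengths(tr, Qn, het, aln)
  fit_u <- optimize_branch_lengths(tr, Qu, het, aln)
  expect_equal(fit_n$result$loglik, fit_u$result$loglik, tolerance = 1e-3)
  # branch lengths absorb exactly the normalization constant
  expect_equal(fit_u$tree$edge.length * Qu$mu, fit_n$tree$edge.length,
               tolerance = 0.05)
})

test_that("information criteria follow their definitions", {
  expect_equal(unname(information_criteria(0, 0, 10)), c(0, 0, 0, 0))
  ic <- information_criteria(-1000, 10, 500)
  expect_equal(ic[["AIC"]], 2020)
  expect_equal(ic[["AIC_per_site"]], 4.04)
  expect_equal(ic[["BIC"]], 10 * log(500) + 2000, tolerance = 1e-12)
  # equal-k model pairs: delta AIC = -2 delta lnL
  ic2 <- information_criteria(-990, 10, 500)
  expect_equal(ic2[["AIC"]] - ic[["AIC"]], -2 * (-990 - -1000))
})

test_that("site-likelihood export writes the CONSEL matrix and roundtrips", {
  wag <- bundled_model("WAG")
  het <- discretize_gamma(1, v = 0, C = 2)
  aln <- sim_fixture(71, n_taxa = 5, n_sites = 100)
  tr <- attr(aln, "tree")
  r1 <- alignment_loglik(tr, wag, het, aln)
  r2 <- alignment_loglik(tr, bundled_model("LG"), het, aln)
  path <- withr::local_tempfile(fileext = ".sitelh")
  export_site_lnl(list(r1, r2), path)
  lines <- readLines(path)
  expect_identical(lines[1], "2 100")
  expect_length(lines, 3L)
  m <- read_site_lnl(path)
  expect_equal(dim(m), c(2L, 100L))
  expect_equal(rowSums(m), c(r1$loglik, r2$loglik), tolerance = 1e-6)
  # file re-serializes identically
  path2 <- withr::local_tempfile(fileext = ".sitelh")
  export_site_lnl(list(r1, r2), path2)
  expect_identical(readLines(path2), lines)
  short <- structure(list(loglik = 0, site_loglik = numeric(10),
                          params = list()), class = "likelihood_result")
  expect_error(export_site_lnl(list(r1, short), path), "site counts")
})
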