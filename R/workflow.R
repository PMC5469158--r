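# Model-comparison pipeline: the evaluation protocol in which candidate
# models' exchangeabilities and frequencies stay fixed while, per alignment
# and model, the tree's branch lengths and the rate-heterogeneity parameters
# (alpha, v) are optimized; models are then ranked by log-likelihood and
# per-site information criteria.

#' Compare fixed substitution models across alignments
#'
#' For every alignment x model pair: build a starting tree under the model
#' (unless one is supplied), optimize branch lengths and `(alpha, v)` with
#' the model's exchangeabilities and frequencies fixed, and record the fit.
#' The free-parameter count used for the information criteria is the number
#' of branch lengths plus 2 (alpha and v); the matrix entries are fixed
#' constants here, exactly as when published empirical models are applied.
#' Best-fit ties are broken by model name order and recorded.
#'
#' @param alignments List of [aa_alignment()] (or a single alignment).
#' @param models List of [substitution_model()] (`>= 2`).
#' @param trees Optional list of guide trees, one per alignment.
#' @param alpha,v,C Starting rate-heterogeneity values.
#' @return An object of class `comparison_report`: `table` (one row per
#'   alignment x model: lnL, lnL/site, AIC/site, BIC/site, fitted alpha and
#'   v, best-fit flag), `best` (per-alignment best model), `pairwise_mean`
#'   (matrix of mean lnL/site differences, row minus column), `site_loglik`
#'   (per alignment, matrix of per-site lnL rows usable with
#'   [export_site_lnl()]).
#' @export
compare_models <- function(alignments, models, trees = NULL,
                           alpha = 1, v = 0.1, C = 4L) {
  if (inherits(alignments, "aa_alignment")) alignments <- list(alignments)
  stopifnot(length(alignments) >= 1L, length(models) >= 2L)
  model_names <- vapply(models, `[[`, character(1), "name")
  if (anyDuplicated(model_names)) {
    stop("model names must be unique", call. = FALSE)
  }
  aln_names <- names(alignments)
  if (is.null(aln_names)) {
    aln_names <- sprintf("alignment%03d", seq_along(alignments))
  }
  rows <- list()
  site_ll <- list()
  for (i in seq_along(alignments)) {
    aln <- alignments[[i]]
    results <- vector("list", length(models))
    for (m in seq_along(models)) {
      model <- models[[m]]
      Q <- build_rate_matrix(model, normalize = TRUE)
      tree <- if (!is.null(trees) && !is.null(trees[[i]])) trees[[i]]
              else initial_tree(aln, Q)
      het <- discretize_gamma(alpha, v, C)
      jo <- optimize_alignment_jointly(tree, Q, het, aln)
      tree <- jo$tree
      het <- jo$het
      res <- jo$result
      k <- nrow(tree$edge) + 2L
      ic <- information_criteria(res$loglik, k, n_sites(aln))
      results[[m]] <- list(res = res, het = het, k = k, ic = ic)
    }
    lnls <- vapply(results, function(r) r$res$loglik, numeric(1))
    best_idx <- order(-lnls, model_names)[1]
    tie <- sum(abs(lnls - lnls[best_idx]) < 1e-9) > 1L
    rows[[i]] <- data.frame(
      alignment = aln_names[i],
      model = model_names,
      loglik = lnls,
      loglik_per_site = lnls / n_sites(aln),
      AIC_per_site = vapply(results, function(r) r$ic[["AIC_per_site"]],
                            numeric(1)),
      BIC_per_site = vapply(results, function(r) r$ic[["BIC_per_site"]],
                            numeric(1)),
      alpha = vapply(results, function(r) r$het$alpha, numeric(1)),
      v = vapply(results, function(r) r$het$v, numeric(1)),
      k = vapply(results, function(r) r$k, integer(1)),
      n_sites = n_sites(aln),
      best = seq_along(models) == best_idx,
      tie_broken_by_name = tie & seq_along(models) == best_idx)
    sl <- do.call(rbind, lapply(results, function(r) r$res$site_loglik))
    rownames(sl) <- model_names
    site_ll[[aln_names[i]]] <- sl
  }
  tab <- do.call(rbind, rows)
  # order-invariant presentation
  tab <- tab[order(tab$alignment, tab$model), ]
  rownames(tab) <- NULL
  nm <- sort(model_names)
  pw <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  for (a in nm) {
    for (b in nm) {
      da <- tab$loglik_per_site[tab$model == a]
      db <- tab$loglik_per_site[tab$model == b]
      pw[a, b] <- mean(da - db)
    }
  }
  best <- tab[tab$best, c("alignment", "model")]
  rownames(best) <- NULL
  structure(list(table = tab, best = best, pairwise_mean = pw,
                 site_loglik = site_ll),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", length(unique(x$table$alignment)),
      " alignments x ", length(unique(x$table$model)), " models\n", sep = "")
  tally <- table(x$best$model)
  cat("  best-fit counts: ",
      paste(names(tally), tally, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a comparison report as TSV
#'
#' @param report A [compare_models()] result.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  utils::write.table(report$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pairwise Robinson-Foulds matrices for a set of trees
#'
#' @param trees A list (or `multiPhylo`) of trees over the same leaves.
#' @param normalized Also divide by `2n - 3`.
#' @return A list: `rf` (integer matrix), `normalized_rf` (or `NULL`).
#' @export
rf_matrix <- function(trees, normalized = FALSE) {
  k <- length(trees)
  rf <- matrix(0L, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j > i) rf[i, j] <- rf_distance(trees[[i]], trees[[j]])
    }
  }
  rf <- rf + t(rf)
  nrf <- NULL
  if (normalized) {
    n <- length(trees[[1]]$tip.label)
    nrf <- rf / (2L * n - 3L)
  }
  nm <- names(trees)
  if (!is.null(nm)) dimnames(rf) <- list(nm, nm)
  if (!is.null(nrf) && !is.null(nm)) dimnames(nrf) <- list(nm, nm)
  list(rf = rf, normalized_rf = nrf)
}
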