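#' Pearson correlation between two substitution models
#'
#' Correlates either the 190 lower-triangular exchangeability coefficients or
#' the 20 equilibrium frequencies of two models. Exchangeabilities are
#' rescaled to mean 1 in each model before correlating; Pearson correlation is
#' invariant to this positive rescaling, so the step only documents that
#' published matrices on different absolute scales are compared on equal
#' footing. Raw coefficients (not logs, not frequency-weighted rates) are
#' used.
#'
#' @param a,b [substitution_model()] objects.
#' @param component `"exchangeabilities"` (default) or `"frequencies"`.
#' @return A single correlation in `[-1, 1]`.
#' @examples
#' model_correlation(bundled_model("LG"), bundled_model("WAG"))
#' @export
model_correlation <- function(a, b,
                              component = c("exchangeabilities",
                                            "frequencies")) {
  stopifnot(inherits(a, "substitution_model"),
            inherits(b, "substitution_model"))
  component <- match.arg(component)
  if (component == "exchangeabilities") {
    va <- lower_triangle(a)
    vb <- lower_triangle(b)
    va <- va / mean(va)
    vb <- vb / mean(vb)
  } else {
    va <- a$frequencies
    vb <- b$frequencies
  }
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("undefined correlation: zero-variance ", component, call. = FALSE)
  }
  stats::cor(va, vb)
}

#' Element-wise exchangeability ratio table between two models
#'
#' Forms the 20x20 table of ratios \eqn{r^a_{xy} / r^b_{xy}}. Ratios above
#' `cap` are reported as `cap` and flagged; zero denominators are flagged and
#' reported as `cap` (infinite ratio) or `NA` (0/0).
#'
#' @param a,b [substitution_model()] objects (numerator and denominator).
#' @param cap Positive trimming threshold for large ratios (default 10).
#' @return A list of class `exchangeability_ratios`: `ratios` (20x20, `NA`
#'   diagonal), `capped` and `zero_denominator` (logical 20x20 flags).
#' @export
exchangeability_ratios <- function(a, b, cap = 10) {
  stopifnot(inherits(a, "substitution_model"),
            inherits(b, "substitution_model"),
            is.numeric(cap), length(cap) == 1L, cap > 0)
  ra <- a$exchangeabilities
  rb <- b$exchangeabilities
  zero_den <- rb == 0 & !diag(20L)
  ratios <- ra / rb
  ratios[zero_den & ra > 0] <- Inf
  ratios[zero_den & ra == 0] <- NA_real_
  capped <- is.finite(ratios) & ratios > cap
  capped[is.na(capped)] <- FALSE
  capped <- capped | (zero_den & ra > 0)
  ratios[capped] <- cap
  diag(ratios) <- NA_real_
  diag(capped) <- FALSE
  diag(zero_den) <- FALSE
  dimnames(capped) <- dimnames(zero_den) <- dimnames(ratios)
  structure(list(ratios = ratios, capped = capped,
                 zero_denominator = zero_den, cap = cap,
                 models = c(a$name, b$name)),
            class = "exchangeability_ratios")
}

#' @export
print.exchangeability_ratios <- function(x, ...) {
  cat("<exchangeability_ratios> ", x$models[1], " / ", x$models[2],
      " (cap ", format(x$cap), ")\n", sep = "")
  cat("  capped cells:", sum(x$capped), "; zero denominators:",
      sum(x$zero_denominator), "\n")
  invisible(x)
}

#' Number of free parameters of a general time-reversible model
#'
#' A GTR model over `n` states has `n(n-1)/2` symmetric exchangeabilities
#' (one of which only sets the overall scale, hence `n(n-1)/2 - 1` free) plus
#' `n - 1` free equilibrium frequencies: 208 free parameters for the 20-state
#' amino-acid model, 8 for the 4-state nucleotide model.
#'
#' @param n_states Number of states (default 20).
#' @return Integer count of free parameters.
#' @examples
#' gtr_free_parameters(20)  # 208
#' gtr_free_parameters(4)   # 8
#' @export
gtr_free_parameters <- function(n_states = 20L) {
  n <- as.integer(n_states)
  stopifnot(n >= 2L)
  (n * (n - 1L)) %/% 2L - 1L + (n - 1L)
}
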