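#' Build the instantaneous rate matrix of a substitution model
#'
#' Constructs the general time-reversible generator with off-diagonal entries
#' \eqn{q_{xy} = \pi_y r_{xy}} and diagonal entries making every row sum to
#' zero. With `normalize = TRUE` (the default) the matrix is divided by the
#' expected substitution rate \eqn{\mu = -\sum_x \pi_x q_{xx}} so that one
#' time unit corresponds to one expected substitution per site; branch lengths
#' under the normalized generator are therefore in substitutions/site.
#' Normalization changes only the time scale, never likelihood optima or tree
#' topologies once branch lengths are re-optimized.
#'
#' The frequency-weighted \eqn{\mu} is the form that makes the one-unit/one-
#' substitution calibration exact; the unweighted sum of diagonal rates,
#' \eqn{\mu = -\sum_x q_{xx}}, which some descriptions of this normalization
#' print, is available with `mu_weighted = FALSE`.
#'
#' The generator is reversible, so its similarity transform
#' \eqn{\Pi^{1/2} Q \Pi^{-1/2}} is symmetric; the builder stores the symmetric
#' eigendecomposition, which [transition_probabilities()] and the likelihood
#' engine reuse. If the eigensystem fails to reconstruct the generator to
#' `1e-12` (numerically degenerate spectrum) the object is flagged and
#' transition probabilities fall back to a scaling-and-squaring series.
#'
#' @param model A [substitution_model()].
#' @param normalize Rescale so the expected rate is 1 (default `TRUE`).
#' @param mu_weighted Use the frequency-weighted expected-rate constant
#'   (default `TRUE`); `FALSE` uses the unweighted diagonal sum.
#' @return An object of class `rate_matrix`: `entries` (20x20 generator),
#'   `mu` (normalization constant of the unnormalized generator),
#'   `normalized` (flag), `frequencies`, and the cached eigensystem.
#' @examples
#' Q <- build_rate_matrix(uniform_model())
#' range(rowSums(Q$entries))
#' @export
build_rate_matrix <- function(model, normalize = TRUE, mu_weighted = TRUE) {
  stopifnot(inherits(model, "substitution_model"))
  pi <- model$frequencies
  Q <- model$exchangeabilities * rep(pi, each = 20L)  # q_xy = pi_y r_xy
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- if (mu_weighted) sum(pi * -diag(Q)) else sum(-diag(Q))
  if (mu <= 0 || !is.finite(mu)) {
    stop("degenerate model: all exchangeabilities zero (mu = 0)",
         call. = FALSE)
  }
  if (normalize) Q <- Q / mu
  es <- reversible_eigen(Q, pi)
  recon <- es$vectors %*% (es$values * es$inverse)
  use_series <- max(abs(recon - Q)) > 1e-12 * max(1, max(abs(Q)))
  structure(list(entries = Q, mu = mu, normalized = normalize,
                 frequencies = pi, eigen = es, use_series = use_series),
            class = "rate_matrix")
}

# symmetric eigendecomposition of a reversible generator:
# S = Pi^{1/2} Q Pi^{-1/2} is symmetric; Q = A diag(lambda) Ainv with
# A = Pi^{-1/2} U, Ainv = U' Pi^{1/2}
reversible_eigen <- function(Q, pi) {
  sq <- sqrt(pi)
  S <- Q * (sq %o% (1 / sq))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  A <- es$vectors / sq
  Ainv <- t(es$vectors) * rep(sq, each = 20L)
  list(values = es$values, vectors = A, inverse = Ainv)
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("<rate_matrix> ", if (x$normalized) "normalized" else "unnormalized",
      ", mu = ", format(x$mu, digits = 8), "\n", sep = "")
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computes the matrix exponential of the generator scaled by a branch length
#' `t` (substitutions/site under a normalized generator), via the cached
#' symmetric eigendecomposition (exact for reversible generators), or by a
#' scaling-and-squaring series when the spectrum was flagged degenerate.
#'
#' @param Q A [build_rate_matrix()] result.
#' @param t Branch length, must be `>= 0`.
#' @return A 20x20 stochastic matrix: rows sum to 1, entries in `[0, 1]`.
#' @examples
#' Q <- build_rate_matrix(uniform_model())
#' range(rowSums(transition_probabilities(Q, 0.3)))
#' @export
transition_probabilities <- function(Q, t) {
  stopifnot(inherits(Q, "rate_matrix"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("branch length t must be a single non-negative number",
         call. = FALSE)
  }
  P <- if (isTRUE(Q$use_series)) {
    expm_series(Q$entries * t)
  } else {
    es <- Q$eigen
    es$vectors %*% (exp(es$values * t) * es$inverse)
  }
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- dimnames(Q$entries)
  P
}

# scaling-and-squaring Taylor evaluation of exp(M); used as the independent
# fallback (and, in tests, as an oracle against the eigendecomposition path)
expm_series <- function(M) {
  n <- nrow(M)
  s <- max(0L, ceiling(log2(max(1e-300, norm(M, "I")))) + 1L)
  X <- M / 2^s
  E <- diag(n)
  term <- diag(n)
  for (k in 1:40) {
    term <- term %*% X / k
    E <- E + term
    if (max(abs(term)) < 1e-18) break
  }
  for (i in seq_len(s)) E <- E %*% E
  E
}
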