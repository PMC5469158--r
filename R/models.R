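#' Construct a time-reversible amino-acid substitution model
#'
#' A substitution model is the pair of a symmetric matrix of exchangeability
#' coefficients \eqn{r_{xy}} (how readily residues \eqn{x} and \eqn{y} replace
#' one another, independent of how common the target is) and an equilibrium
#' frequency vector \eqn{\pi}. The instantaneous rate of an \eqn{x \to y}
#' substitution is \eqn{q_{xy} = \pi_y r_{xy}} (see [build_rate_matrix()]).
#'
#' @param name Model name (used in reports and file headers).
#' @param exchangeabilities Either a symmetric 20x20 non-negative matrix with
#'   zero diagonal, or a vector of the 190 lower-triangular coefficients in
#'   row-major PAML order (A-R first).
#' @param frequencies Vector of 20 non-negative equilibrium frequencies in
#'   PAML residue order, summing to 1 (renormalized if within `1e-4` of 1).
#' @return An object of class `substitution_model` with elements `name`,
#'   `exchangeabilities` (20x20) and `frequencies` (length 20), both carrying
#'   residue dimnames.
#' @examples
#' m <- uniform_model()
#' m$exchangeabilities["A", "R"]
#' @export
substitution_model <- function(name, exchangeabilities, frequencies) {
  if (is.vector(exchangeabilities)) {
    if (length(exchangeabilities) != 190L) {
      stop("expected 190 lower-triangular exchangeabilities, got ",
           length(exchangeabilities), call. = FALSE)
    }
    exch <- matrix(0, 20, 20)
    # row-major lower triangle == column-major upper triangle
    exch[upper.tri(exch)] <- exchangeabilities
    exch <- exch + t(exch)
  } else {
    exch <- as.matrix(exchangeabilities)
  }
  if (!all(dim(exch) == c(20L, 20L))) {
    stop("exchangeability matrix must be 20x20", call. = FALSE)
  }
  if (any(exch < 0)) stop("negative exchangeability coefficient", call. = FALSE)
  if (max(abs(exch - t(exch))) > 1e-8 * max(1, max(exch))) {
    stop("exchangeability matrix must be symmetric", call. = FALSE)
  }
  exch <- (exch + t(exch)) / 2
  diag(exch) <- 0
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) != 20L) {
    stop("expected 20 frequencies, got ", length(frequencies), call. = FALSE)
  }
  if (any(frequencies < 0)) stop("negative frequency", call. = FALSE)
  s <- sum(frequencies)
  if (abs(s - 1) > 1e-4) {
    stop("frequencies sum to ", format(s), ", more than 1e-4 away from 1",
         call. = FALSE)
  }
  frequencies <- frequencies / s
  dimnames(exch) <- list(AA_RESIDUES, AA_RESIDUES)
  names(frequencies) <- AA_RESIDUES
  structure(list(name = as.character(name),
                 exchangeabilities = exch,
                 frequencies = frequencies),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("<substitution_model> ", x$name, "\n", sep = "")
  cat("  mean exchangeability:", format(mean(lower_triangle(x)), digits = 6),
      "\n")
  cat("  frequency range: [",
      format(min(x$frequencies), digits = 4), ", ",
      format(max(x$frequencies), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Lower-triangular exchangeability coefficients of a model
#'
#' Returns the 190 pairwise coefficients in PAML row-major order (the order
#' they appear in a `.dat` file: A-R first, then the N row, and so on).
#'
#' @param model A [substitution_model()].
#' @return Numeric vector of length 190.
#' @export
lower_triangle <- function(model) {
  # row-major lower triangle of a symmetric matrix == column-major upper
  model$exchangeabilities[upper.tri(model$exchangeabilities)]
}

#' Uniform (all-equal-rates) reference model
#'
#' All 190 exchangeabilities equal to 1 and uniform frequencies (1/20). The
#' customary neutral starting point for exchangeability estimation.
#'
#' @return A `substitution_model`.
#' @export
uniform_model <- function() {
  substitution_model("uniform", rep(1, 190), rep(1 / 20, 20))
}

#' Read a substitution model from a PAML .dat file
#'
#' Parses the standard PAML rate-matrix layout: 19 rows of lower-triangular
#' exchangeability coefficients (row 1 holds the single A-R coefficient)
#' followed by the 20 equilibrium frequencies. Blank lines are skipped and
#' anything on a line after the numeric tokens, as well as trailing text
#' lines, is treated as a comment.
#'
#' @param path Path to a `.dat` model file.
#' @param name Model name; defaults to the file name without extension.
#' @return A validated [substitution_model()].
#' @examples
#' wag <- read_paml_model(system.file("extdata", "models", "WAG.dat",
#'                                    package = "aasubst"))
#' sum(wag$frequencies)
#' @export
read_paml_model <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  values <- numeric(0)
  lineno <- integer(0)
  for (i in seq_along(lines)) {
    tokens <- strsplit(trimws(lines[i]), "[[:space:],]+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) == 0L) next
    nums <- suppressWarnings(as.numeric(tokens))
    keep <- which(!is.na(nums))
    # numeric prefix of the line; the remainder is a comment
    if (length(keep) > 0L && keep[1] == 1L) {
      run <- seq_len(which.max(c(diff(keep) != 1L, TRUE)))
      take <- nums[keep[run]]
      values <- c(values, take)
      lineno <- c(lineno, rep(i, length(take)))
    } else if (length(values) < 210L) {
      stop("line ", i, ": expected numeric data, found '",
           substr(lines[i], 1, 40), "'", call. = FALSE)
    }
    if (length(values) >= 210L) break
  }
  if (length(values) < 210L) {
    stop("malformed model file: found ", length(values),
         " numeric values, need 190 exchangeabilities + 20 frequencies",
         call. = FALSE)
  }
  values <- values[seq_len(210L)]
  lineno <- lineno[seq_len(210L)]
  neg <- which(values < 0)
  if (length(neg) > 0L) {
    stop("line ", lineno[neg[1]], ": negative coefficient ",
         format(values[neg[1]]), call. = FALSE)
  }
  freqs <- values[191:210]
  if (abs(sum(freqs) - 1) > 1e-4) {
    stop("line ", lineno[191], ": frequencies sum to ", format(sum(freqs)),
         ", more than 1e-4 away from 1", call. = FALSE)
  }
  substitution_model(name, values[1:190], freqs)
}

#' Write a substitution model in PAML .dat layout
#'
#' Emits the canonical layout read by [read_paml_model()] and by standard
#' phylogenetics programs: 19 lower-triangular rows, a blank line, then the 20
#' frequencies, at `digits` significant digits (default 10, which makes a
#' write/read roundtrip reproduce the model to that precision).
#'
#' @param model A [substitution_model()].
#' @param path Output file path.
#' @param digits Significant digits to print (minimum 10).
#' @return Invisibly, `path`.
#' @export
write_paml_model <- function(model, path, digits = 10L) {
  stopifnot(inherits(model, "substitution_model"))
  digits <- max(10L, as.integer(digits))
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  exch <- model$exchangeabilities
  rows <- vapply(2:20, function(i) {
    paste(fmt(exch[i, seq_len(i - 1L)]), collapse = " ")
  }, character(1))
  out <- c(rows, "", paste(fmt(model$frequencies), collapse = " "), "",
           paste0("Model ", model$name, ": symmetric exchangeabilities",
                  " (lower triangle, PAML residue order ",
                  paste(AA_RESIDUES, collapse = " "), ") and frequencies."))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Load one of the bundled published substitution models
#'
#' The package ships the published general models LG and WAG and the published
#' mitochondrial models mtREV (the 24-taxon matrix), mtArt and mtZoa as
#' plain-text PAML files under `extdata/models` (see the `PROVENANCE` file
#' there for sources).
#'
#' @param name One of `"LG"`, `"WAG"`, `"mtREV"`, `"mtArt"`, `"mtZoa"`.
#' @return A [substitution_model()].
#' @examples
#' lg <- bundled_model("LG")
#' @export
bundled_model <- function(name = c("LG", "WAG", "mtREV", "mtArt", "mtZoa")) {
  name <- match.arg(name)
  path <- system.file("extdata", "models", paste0(name, ".dat"),
                      package = "aasubst")
  if (!nzchar(path)) stop("bundled model not found: ", name, call. = FALSE)
  read_paml_model(path, name = name)
}
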