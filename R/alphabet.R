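# 20-state amino-acid alphabet, fixed to the canonical PAML residue order.
# All file I/O and matrix algebra in the package use this order; readers for
# formats with other orders must convert explicitly.

AA_RESIDUES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# ambiguity codes -> permitted residue subsets; gaps and unknowns permit all
AA_AMBIGUITY <- list(
  B = c("N", "D"),
  Z = c("Q", "E"),
  J = c("I", "L"),
  X = AA_RESIDUES,
  U = AA_RESIDUES,  # selenocysteine: treated as fully ambiguous
  O = AA_RESIDUES,  # pyrrolysine: treated as fully ambiguous
  "-" = AA_RESIDUES,
  "?" = AA_RESIDUES,
  "." = AA_RESIDUES,
  "*" = AA_RESIDUES
)

#' Amino-acid alphabet used throughout the package
#'
#' Returns the ordered 20-letter amino-acid alphabet (canonical PAML order
#' `A R N D C Q E G H I L K M F P S T W Y V`) together with the ambiguity map
#' used when computing likelihoods: each ambiguity or gap code maps to the
#' non-empty set of residues it is compatible with.
#'
#' @return A list with elements `residues` (character vector of length 20) and
#'   `ambiguity` (named list mapping each ambiguity code to a residue subset).
#' @examples
#' aa_alphabet()$residues
#' aa_alphabet()$ambiguity$B
#' @export
aa_alphabet <- function() {
  list(residues = AA_RESIDUES, ambiguity = AA_AMBIGUITY)
}

# residue set permitted by a single character (stops on garbage)
aa_permitted <- function(ch) {
  ch <- toupper(ch)
  if (ch %in% AA_RESIDUES) return(ch)
  hit <- AA_AMBIGUITY[[ch]]
  if (is.null(hit)) {
    stop("unknown amino-acid code: '", ch, "'", call. = FALSE)
  }
  hit
}

# 20 x n indicator matrix for a character vector of residue codes
aa_indicator <- function(chars) {
  m <- matrix(0, nrow = 20L, ncol = length(chars),
              dimnames = list(AA_RESIDUES, NULL))
  for (j in seq_along(chars)) {
    m[aa_permitted(chars[j]), j] <- 1
  }
  m
}
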