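#' Protein multiple sequence alignment container
#'
#' Holds aligned amino-acid sequences as a character matrix (one row per
#' sequence, one column per site) over the 20-letter alphabet plus gap and
#' ambiguity codes. Site-pattern compression for the likelihood engine is
#' performed lazily by [compress_patterns()].
#'
#' @param seqs Either a named character vector of equal-length strings or a
#'   character matrix with row names.
#' @return An object of class `aa_alignment` with elements `names` and `seqs`
#'   (character matrix, upper-cased).
#' @examples
#' aln <- aa_alignment(c(s1 = "ARND", s2 = "ARNE"))
#' dim(aln$seqs)
#' @export
aa_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
    if (is.null(rownames(m))) stop("sequence matrix needs row names",
                                   call. = FALSE)
  } else {
    nm <- names(seqs)
    seqs <- as.character(seqs)  # drops attributes, so keep names aside
    names(seqs) <- nm
    if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
      stop("sequences must be named", call. = FALSE)
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      stop("sequences have unequal lengths: ",
           paste(range(lens), collapse = " vs "), call. = FALSE)
    }
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- names(seqs)
  }
  m[] <- toupper(m)
  if (anyDuplicated(rownames(m))) {
    stop("duplicate sequence names", call. = FALSE)
  }
  ok <- m %in% c(AA_RESIDUES, names(AA_AMBIGUITY))
  if (!all(ok)) {
    bad <- unique(m[!ok])
    stop("unknown residue codes: ", paste(bad, collapse = " "),
         call. = FALSE)
  }
  structure(list(names = rownames(m), seqs = m), class = "aa_alignment")
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("<aa_alignment> ", nrow(x$seqs), " sequences x ", ncol(x$seqs),
      " sites\n", sep = "")
  invisible(x)
}

#' Number of sites / sequences of an alignment
#' @param aln An `aa_alignment`.
#' @return Integer count.
#' @export
n_sites <- function(aln) ncol(aln$seqs)

#' @rdname n_sites
#' @export
n_sequences <- function(aln) nrow(aln$seqs)

#' Subset an alignment to a set of sequences
#' @param aln An `aa_alignment`.
#' @param names Sequence names to keep (order preserved as given).
#' @return An `aa_alignment`.
#' @export
subset_alignment <- function(aln, names) {
  miss <- setdiff(names, aln$names)
  if (length(miss) > 0L) {
    stop("sequences not in alignment: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  aa_alignment(aln$seqs[names, , drop = FALSE])
}

#' Read a protein alignment (FASTA or relaxed PHYLIP)
#'
#' FASTA files are read with the Biostrings reader; PHYLIP files (sequential
#' or interleaved, relaxed names) with the phangorn reader. With
#' `format = "auto"` the format is chosen by inspecting the first
#' non-whitespace character (`>` means FASTA).
#'
#' @param path Input file.
#' @param format `"auto"`, `"fasta"` or `"phylip"`.
#' @return An [aa_alignment()].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "phylip")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    first <- trimws(readLines(path, n = 10L, warn = FALSE))
    first <- first[nzchar(first)][1]
    format <- if (!is.na(first) && startsWith(first, ">")) "fasta"
              else "phylip"
  }
  if (format == "fasta") {
    ss <- Biostrings::readAAStringSet(path)
    seqs <- as.character(ss)
    names(seqs) <- sub("[[:space:]].*$", "", names(ss))
    aa_alignment(seqs)
  } else {
    pd <- phangorn::read.phyDat(path, format = "phylip", type = "AA")
    m <- as.character(pd)
    m[] <- toupper(m)
    aa_alignment(m)
  }
}

#' Write an alignment as FASTA
#'
#' @param aln An [aa_alignment()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "aa_alignment"))
  ss <- Biostrings::AAStringSet(apply(aln$seqs, 1, paste, collapse = ""))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Compress an alignment into unique site patterns
#'
#' Columns with identical residue content collapse into one pattern with a
#' multiplicity; the likelihood of an alignment is the pattern-weighted sum of
#' pattern log-likelihoods, which never changes the total.
#'
#' @param aln An [aa_alignment()].
#' @return A list: `patterns` (character matrix, sequences x patterns),
#'   `weights` (multiplicities summing to the alignment length), `index`
#'   (pattern id of every original site).
#' @export
compress_patterns <- function(aln) {
  stopifnot(inherits(aln, "aa_alignment"))
  keys <- apply(aln$seqs, 2, paste, collapse = "\r")
  uq <- !duplicated(keys)
  index <- match(keys, keys[uq])
  list(patterns = aln$seqs[, uq, drop = FALSE],
       weights = as.numeric(tabulate(index, nbins = sum(uq))),
       index = index)
}

# 20 x npat x ntip cube of tip partial indicators, tips ordered as tip_names
tip_partial_cube <- function(patterns, tip_names) {
  miss <- setdiff(tip_names, rownames(patterns))
  if (length(miss) > 0L) {
    stop("tree leaves missing from alignment: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  npat <- ncol(patterns)
  cube <- array(0, dim = c(20L, npat, length(tip_names)))
  for (i in seq_along(tip_names)) {
    cube[, , i] <- aa_indicator(patterns[tip_names[i], ])
  }
  cube
}

# per-pattern invariant-class likelihood: sum of pi over residues compatible
# with a constant column (0 if no residue fits; 1 for an all-gap column)
invariant_likelihood <- function(patterns, pi) {
  npat <- ncol(patterns)
  out <- numeric(npat)
  for (j in seq_len(npat)) {
    compat <- AA_RESIDUES
    for (ch in patterns[, j]) {
      compat <- intersect(compat, aa_permitted(ch))
      if (length(compat) == 0L) break
    }
    out[j] <- sum(pi[compat])
  }
  out
}

# empirical residue proportions over a list of alignments; ambiguity codes are
# skipped; a small pseudocount keeps every frequency strictly positive
empirical_frequencies <- function(alignments, pseudocount = 0.5) {
  counts <- setNames(rep(pseudocount, 20L), AA_RESIDUES)
  for (aln in alignments) {
    tab <- table(factor(aln$seqs, levels = AA_RESIDUES))
    counts <- counts + as.numeric(tab)
  }
  counts / sum(counts)
}
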