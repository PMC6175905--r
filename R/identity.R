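# Pairwise global alignment percent identity for antigen panels.
#
# Alignment is Needleman-Wunsch/Gotoh with affine gaps (BLOSUM62, gap
# open 10, gap extend 0.5 — EMBOSS-needle-style defaults), computed via
# Biostrings::pairwiseAlignment.  Percent identity uses the pinned
# convention: identical columns over columns where neither row is a
# gap.

#' Global pairwise alignment of two peptide sequences
#'
#' @param a,b Amino-acid sequence strings (non-empty).
#' @param substitution Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties: a gap of length
#'   `len` costs `gap_open + len * gap_extend`.
#' @return List with the two aligned strings (`a`, `b`, equal length,
#'   `-` for gaps) and the alignment `score`.
#' @export
global_align <- function(a, b, substitution = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = substitution, type = "global",
    gapOpening = gap_open, gapExtension = gap_extend)
  list(a = as.character(Biostrings::alignedPattern(al)),
       b = as.character(Biostrings::alignedSubject(al)),
       score = Biostrings::score(al))
}

#' Percent identity of an aligned pair
#'
#' `100 * identical columns / columns where neither row is a gap`.
#' Symmetric in its two arguments.
#'
#' @param alignment A list from [global_align()] (elements `a` and `b`,
#'   equal-length aligned strings).
#' @return Percent identity in \[0, 100\].
#' @export
percent_identity <- function(alignment) {
  ca <- strsplit(alignment$a, "")[[1]]
  cb <- strsplit(alignment$b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  both <- ca != "-" & cb != "-"
  if (!any(both)) stop("no gap-free columns in alignment")
  100 * sum(ca[both] == cb[both]) / sum(both)
}

#' Pairwise percent-identity matrix of an antigen panel
#'
#' @param antigens List of [antigen()] objects (or a named character
#'   vector of sequences).
#' @param ... Passed to [global_align()].
#' @return Symmetric matrix of percent identities with a 100 diagonal.
#' @export
identity_matrix <- function(antigens, ...) {
  if (is.character(antigens)) {
    seqs <- antigens
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  } else {
    antigens <- as_antigen_list(antigens)
    seqs <- vapply(antigens, `[[`, "", "sequence")
  }
  n <- length(seqs)
  m <- diag(100, n)
  dimnames(m) <- list(names(seqs), names(seqs))
  if (n > 1L)
    for (i in seq_len(n - 1L))
      for (j in seq.int(i + 1L, n)) {
        pid <- percent_identity(global_align(seqs[[i]], seqs[[j]], ...))
        m[i, j] <- m[j, i] <- pid
      }
  m
}
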