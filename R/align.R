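#' Global pairwise alignment
#'
#' Needleman-Wunsch global alignment with a linear gap penalty (defaults:
#' match +1, mismatch -1, gap -2) and a deterministic traceback (diagonal
#' preferred over a gap in `b`, preferred over a gap in `a`). This is the
#' internal alignment engine behind the gap-excluded similarity; any
#' function accepting an `engine` argument also takes a user function with
#' the same signature, so an external aligner can be substituted.
#'
#' @param a,b DNA strings.
#' @param match,mismatch,gap scoring parameters.
#' @return A list with aligned strings `a` and `b` (gaps as `-`) and the
#'   alignment `score`.
#' @export
align_global <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  stopifnot(nzchar(a), nzchar(b))
  nw_align_cpp(toupper(a), toupper(b), match, mismatch, gap)
}

#' Gap-excluded percent similarity of an aligned pair
#'
#' Similarity is computed over the aligned columns where neither sequence
#' has a gap: `100 x identities / gap-free columns`. Gaps are not
#' considered, so at a cutoff of 100 sequences differing only by indels
#' still group together. With zero gap-free columns the similarity is
#' undefined and `NA` is returned (treated as "no match" downstream).
#'
#' @param alignment a list with aligned strings `a` and `b` (as returned by
#'   [align_global()]).
#' @return Percent similarity in `[0, 100]`, or `NA`.
#' @export
alignment_similarity <- function(alignment) {
  ca <- strsplit(alignment$a, "")[[1]]
  cb <- strsplit(alignment$b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  gapfree <- ca != "-" & cb != "-"
  if (!any(gapfree)) return(NA_real_)
  100 * sum(ca[gapfree] == cb[gapfree]) / sum(gapfree)
}

# number of gap-free columns (used as a tie-break for best-hit selection)
alignment_span <- function(alignment) {
  ca <- strsplit(alignment$a, "")[[1]]
  cb <- strsplit(alignment$b, "")[[1]]
  sum(ca != "-" & cb != "-")
}

#' Gap-excluded percent similarity of two sequences
#'
#' Convenience wrapper: aligns with `engine` (default [align_global()]) and
#' applies [alignment_similarity()]. Symmetric in its arguments.
#'
#' @param a,b DNA strings.
#' @param engine alignment function with the signature of [align_global()].
#' @return Percent similarity in `[0, 100]`, or `NA`.
#' @export
pair_similarity <- function(a, b, engine = align_global) {
  alignment_similarity(engine(a, b))
}
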