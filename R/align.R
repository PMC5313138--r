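# Pairwise alignment wrappers around the affine-gap DP kernel.

#' Smith-Waterman local alignment
#'
#' Optimal local alignment under affine gap penalties (a gap of length k
#' costs `gap_open + k * gap_extend`). Traceback ties prefer diagonal, then
#' up, then left, making results deterministic.
#'
#' @param a,b protein sequences (character scalars).
#' @param substitution 21x21 score matrix over the residue alphabet plus `X`
#'   (default BLOSUM62 as bundled by Biostrings).
#' @param gap_open,gap_extend affine gap parameters (protein-search defaults
#'   11 / 1).
#' @return list with `score`, `a_span` / `b_span` (1-based inclusive),
#'   `identity` (matching columns / alignment columns), `columns`, `matches`,
#'   and the aligned strings `a_aln`, `b_aln`.
#' @export
smith_waterman <- function(a, b, substitution = blosum62(),
                           gap_open = 11, gap_extend = 1) {
  align_pair(a, b, mode = "local", substitution, gap_open, gap_extend)
}

#' Global / overlap alignment
#'
#' `mode = "global"` is Needleman-Wunsch; `mode = "overlap"` makes end gaps
#' free on both sequences (the identity convention used by the clustering
#' stage).
#'
#' @inheritParams smith_waterman
#' @param mode `"local"`, `"global"` or `"overlap"`.
#' @return see [smith_waterman].
#' @export
align_pair <- function(a, b, mode = c("local", "global", "overlap"),
                       substitution = blosum62(), gap_open = 11,
                       gap_extend = 1) {
  mode <- match.arg(mode)
  ea <- encode_protein(a); eb <- encode_protein(b)
  r <- align_pair_cpp(ea, eb, substitution, gap_open, gap_extend,
                      match(mode, c("local", "global", "overlap")) - 1L)
  finish_alignment(r, toupper(a), toupper(b))
}

finish_alignment <- function(r, a, b) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  a_aln <- ifelse(r$ai >= 0, ac[r$ai + 1], "-")
  b_aln <- ifelse(r$bi >= 0, bc[r$bi + 1], "-")
  list(score = r$score,
       a_span = c(r$a_start + 1L, r$a_end),
       b_span = c(r$b_start + 1L, r$b_end),
       identity = r$identity, columns = r$columns, matches = r$matches,
       a_aln = paste(a_aln, collapse = ""),
       b_aln = paste(b_aln, collapse = ""))
}

# local alignment of a PSSM (width x 21 half-bit scores) against a sequence;
# returns spans plus the query-position mapping used for profile stacking.
pssm_align <- function(pssm, b, gap_open = 11, gap_extend = 1) {
  eb <- encode_protein(b)
  r <- pssm_align_cpp(pssm, eb, gap_open, gap_extend)
  r
}
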