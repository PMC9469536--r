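## Pairwise global alignment surface over the Gotoh C++ core.

#' Global pairwise alignment (Needleman-Wunsch with affine gaps)
#'
#' Optimal global alignment under the stated scoring; a gap run of length
#' L costs `gap_open + gap_extend * (L - 1)`. Tie-breaking is
#' deterministic (diagonal preferred, then a gap in `b`), so identical
#' inputs always give identical alignments.
#'
#' @param a,b DNA (or protein) strings.
#' @param match,mismatch,gap_open,gap_extend Scores (penalties negative).
#' @return Object of class `pairwise_alignment`: gapped strings `a` and
#'   `b` of equal length, `score`, and the scoring parameters used.
#' @export
align_pair <- function(a, b, match = 1, mismatch = -1,
                       gap_open = -2, gap_extend = -0.5) {
  stopifnot(is_string(a), is_string(b), nchar(a) > 0L, nchar(b) > 0L)
  res <- .gotoh_align(a, b, match, mismatch, gap_open, gap_extend)
  structure(list(a = res$a, b = res$b, score = res$score,
                 params = c(match = match, mismatch = mismatch,
                            gap_open = gap_open, gap_extend = gap_extend)),
            class = "pairwise_alignment")
}

#' Wrap two pre-aligned (equal-length) sequences as an alignment
#'
#' For sequence pairs that are already columnwise homologous (e.g. sister
#' sequences simulated without indels) this avoids re-alignment.
#'
#' @param a,b Equal-length gapped or ungapped strings.
#' @return A `pairwise_alignment`.
#' @export
as_alignment <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  structure(list(a = toupper(a), b = toupper(b), score = NA_real_,
                 params = NULL),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, width = 60L, ...) {
  n <- nchar(x$a)
  cat(sprintf("<pairwise_alignment> %d columns, score %s\n", n,
              format(x$score)))
  for (i in seq(1L, n, by = width)) {
    j <- min(i + width - 1L, n)
    cat(substr(x$a, i, j), "\n", substr(x$b, i, j), "\n\n", sep = "")
  }
  invisible(x)
}

## degap an aligned string
degap <- function(x) gsub("-", "", x, fixed = TRUE)
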