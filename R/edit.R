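#' Full (unpruned) edit distance
#'
#' Standard Levenshtein distance with unit-cost substitution, insertion and
#' deletion and the usual initialization \code{d[i,0] = i}, \code{d[0,j] = j}.
#' \code{N} in either string always counts as a mismatch.
#'
#' @param x,y Strings.
#' @return Integer edit distance.
#' @export
full_edit_distance <- function(x, y) full_edit_cpp(x, y)

#' Threshold-pruned edit distance
#'
#' Answers the query "is the edit distance of \code{x} and \code{y} at most
#' \code{t}?" exactly, without always computing the full distance: a banded
#' dynamic program (cells with \code{|i - j| <= t}) stops as soon as every
#' entry of the current row within the band exceeds \code{t} and returns the
#' sentinel \code{t + 1}. Thus the returned value equals the true distance
#' whenever that distance is \code{<= t}, and is \code{t + 1} otherwise --
#' the distance is \code{<= t} if and only if the returned value is.
#'
#' The published pseudo-code initializes the first DP row and column to zero,
#' which makes the distance of an empty string to any string zero and is not
#' the edit-distance recurrence required by the extension step; the default
#' here uses the standard initialization. \code{literal_init = TRUE}
#' reproduces the zero-initialized variant for study.
#'
#' @param x,y Strings.
#' @param t Non-negative distance threshold.
#' @param literal_init Use the zero-initialized first row/column variant.
#' @return List with \code{value} (the distance if \code{<= t}, else
#'   \code{t + 1}), \code{exceeded} (\code{TRUE} iff the distance is
#'   \code{> t}) and \code{max_band_offset} (largest \code{|i - j|}
#'   evaluated; always \code{<= t} for the default implementation).
#' @export
bound_edit_distance <- function(x, y, t, literal_init = FALSE) {
  bound_edit_cpp(x, y, as.integer(t), isTRUE(literal_init))
}
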