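seed_frame <- function(lst) {
  data.frame(read_i = lst$read_i, read_j = lst$read_j,
             genome_start = lst$genome_start, length = lst$length,
             wrapped = lst$wrapped, len_f = lst$len_f, len_b = lst$len_b,
             q_b_end = lst$q_b_end, stringsAsFactors = FALSE)
}

#' Common substrings of a read and the genome anchored at position p
#'
#' Finds long exact common substrings through the (1-based) read position
#' \code{p}: the maximal backward match of \code{r[.. p-1]} and the maximal
#' forward match of \code{r[p ..]} are computed with the FM-index pair, and
#' every backward occurrence ending at genome position \code{e} is joined
#' with every forward occurrence starting at \code{e + 1} (contiguity in the
#' genome). Joined matches of total length at least \code{W} become seeds.
#' When one side has no match at all, occurrences of the other side alone
#' qualify, subject to the same length filter. The contiguity test probes a
#' sorted set of backward end positions for each forward start, which
#' computes the same seed set as the quadratic pairing loop.
#'
#' @param pair An \code{fm_index_pair}.
#' @param read Read sequence (string).
#' @param p Anchor position, \code{2 <= p <= nchar(read)} (use
#'   [wraparound_seeds()] for \code{p = 1}).
#' @param params An \code{aligner_params} (supplies \code{W},
#'   \code{max_hits}).
#' @return data.frame of seeds: \code{read_i}, \code{read_j} (1-based
#'   inclusive read interval), \code{genome_start} (0-based), \code{length},
#'   \code{wrapped} (always \code{FALSE} here).
#' @export
common_substrings <- function(pair, read, p, params) {
  stopifnot(inherits(params, "aligner_params"))
  seed_frame(common_substrings_cpp(pair$ptr, toupper(read), as.integer(p),
                                   params$W, params$max_hits))
}

#' Wrap-around seeds (the p = 1 case)
#'
#' At anchor \code{p = 1} the read is treated as circular: the backward match
#' becomes a maximal \emph{suffix} match of the read and the forward match a
#' maximal \emph{prefix} match, two contiguous genome strings separated by a
#' gap. A prefix occurrence starting at \code{q_f} and a suffix occurrence
#' ending at \code{q_b_end} pair up when their genome span
#' \code{q_b_end - q_f + 1} deviates from the read length by at most
#' \code{t} (the gap absorbs at most \code{t} indels) and the combined
#' matched length reaches \code{W}; such pairs are emitted as wrapped seeds.
#' A prefix or suffix match that alone reaches length \code{W} is also
#' emitted as an ordinary seed. An error-free read matches over its full
#' length and yields one ordinary seed per occurrence.
#'
#' @inheritParams common_substrings
#' @return data.frame of seeds; wrapped rows carry the pair geometry in
#'   \code{len_f}, \code{len_b}, \code{q_b_end}.
#' @export
wraparound_seeds <- function(pair, read, params) {
  stopifnot(inherits(params, "aligner_params"))
  seed_frame(wraparound_seeds_cpp(pair$ptr, toupper(read), params$W,
                                  params$t, params$max_hits))
}
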