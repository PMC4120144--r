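#' Extend one seed into a candidate alignment
#'
#' An ordinary seed covering \code{r[i..j]} at genome start \code{g} pairs
#' the read prefix \code{r[1..i-1]} with the \code{(i-1)}-length genome
#' substring immediately left of the seed and the read suffix
#' \code{r[j+1..m]} with the \code{(m-j)}-length substring immediately
#' right. The left flank distance is computed with budget \code{t}, the
#' right with the remaining budget; the candidate is accepted iff the total
#' is at most \code{t}. A flank running past a genome end is truncated, the
#' missing bases costing one edit each through the length difference. For a
#' wrapped seed the read interior between the matched prefix and suffix is
#' compared against the genome gap between the two parts.
#'
#' @param pair An \code{fm_index_pair}.
#' @param read Read sequence.
#' @param seed One-row seed data.frame (from [common_substrings()] or
#'   [wraparound_seeds()]).
#' @param t Edit distance budget.
#' @return \code{NULL} on rejection, otherwise a list with
#'   \code{genome_start}, \code{genome_end} (0-based half-open),
#'   \code{dist}, \code{dist_left}, \code{dist_right}.
#' @export
extend_seed <- function(pair, read, seed, t) {
  r <- extend_seed_cpp(pair$ptr, toupper(read), seed$read_i[1L],
                       seed$read_j[1L], seed$genome_start[1L],
                       seed$length[1L], seed$wrapped[1L], seed$len_f[1L],
                       seed$len_b[1L], seed$q_b_end[1L], as.integer(t))
  if (!isTRUE(r$accepted)) return(NULL)
  r$accepted <- NULL
  r
}

status_labels <- c("ALIGNED", "AMBIGUOUS", "UNALIGNED")

#' Align one read
#'
#' Randomized seed-and-extend alignment: attempt 1 anchors at \code{p = 1}
#' (wrap-around seeding); each further attempt draws \code{p} uniformly from
#' \code{1..m} (a drawn \code{p = 1} uses wrap-around seeding again). Every
#' seed of the attempt is extended; candidates from the read and its reverse
#' complement are pooled and duplicates (same genome start and strand)
#' collapsed. A non-empty candidate set stops the loop: more than two
#' distinct candidates means the read sits in a repeat and the result is
#' \code{AMBIGUOUS}; one or two candidates give \code{ALIGNED}, the primary
#' being the lower edit distance (ties: leftmost genome start, then
#' \code{+} strand). After \code{A} fruitless attempts the read is
#' \code{UNALIGNED}.
#'
#' @param pair An \code{fm_index_pair}.
#' @param read Read sequence (string).
#' @param params An \code{aligner_params}.
#' @param ordinal Read ordinal used (with \code{params$rng_seed}) to derive
#'   the per-read RNG stream, making results independent of batch
#'   partitioning.
#' @return List with \code{status} (\code{"ALIGNED"}, \code{"AMBIGUOUS"},
#'   \code{"UNALIGNED"}), \code{attempts_used} and \code{candidates}
#'   (data.frame, primary first; 0-based \code{genome_start}).
#' @export
align_read <- function(pair, read, params, ordinal = 1L) {
  stopifnot(inherits(params, "aligner_params"))
  r <- align_read_cpp(pair$ptr, toupper(read), params$t, params$W, params$A,
                      params$max_hits, params$rng_seed, as.integer(ordinal))
  list(status = status_labels[r$status + 1L],
       attempts_used = r$attempts_used, candidates = r$candidates)
}

#' Align a set of reads
#'
#' Vectorized driver over [align_read()]'s compiled core. Per-read RNG
#' streams are derived from \code{(params$rng_seed, ordinal)}, so the same
#' seed gives identical results regardless of how the batch is split or
#' ordered.
#'
#' @param pair An \code{fm_index_pair}.
#' @param reads data.frame with \code{id}, \code{sequence} (and optionally
#'   \code{quality}), e.g. from [read_fastq()] or [sample_reads()].
#' @param params An \code{aligner_params}.
#' @param sam Optional path; when given, alignments are also written as SAM.
#' @param ordinals Integer vector of per-read ordinals (defaults to row
#'   numbers).
#' @return data.frame with one row per read: \code{id}, \code{sequence},
#'   \code{status}, \code{attempts_used}, 0-based \code{genome_start},
#'   \code{genome_end}, \code{dist}, \code{strand}, \code{n_candidates} and
#'   the secondary candidate columns \code{genome_start2}, \code{dist2},
#'   \code{strand2}.
#' @export
align_all <- function(pair, reads, params, sam = NULL, ordinals = NULL) {
  stopifnot(inherits(params, "aligner_params"))
  if (is.null(ordinals)) ordinals <- seq_len(nrow(reads))
  r <- align_batch_cpp(pair$ptr, toupper(reads$sequence), params$t, params$W,
                       params$A, params$max_hits, params$rng_seed,
                       as.integer(ordinals))
  out <- data.frame(id = reads$id, sequence = reads$sequence,
                    status = status_labels[r$status + 1L],
                    attempts_used = r$attempts_used,
                    genome_start = r$genome_start, genome_end = r$genome_end,
                    dist = r$dist, strand = r$strand,
                    n_candidates = r$n_candidates,
                    genome_start2 = r$genome_start2, dist2 = r$dist2,
                    strand2 = r$strand2, stringsAsFactors = FALSE)
  if (!is.null(reads$quality)) out$quality <- reads$quality
  if (!is.null(sam)) write_sam(out, pair$genome, sam)
  out
}
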