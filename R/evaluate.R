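#' Score alignments against simulated truth
#'
#' A read counts as \emph{aligned} iff its primary record is not flag-4;
#' it is \emph{correct} iff it is aligned, on the truth strand, and its
#' 1-based mapping position is within \code{tolerance_bp} of the truth start
#' (default 20 bp, absorbing small indel-induced offsets). Metrics:
#' \deqn{precision = correct / aligned, \quad recall = correct / total,}
#' \deqn{misalignment = (aligned - correct) / total.}
#' Ambiguous (repeat-trapped) and attempt-exhausted reads both count as not
#' aligned: they enter the recall denominator but not the precision
#' denominator.
#'
#' @param alignments Either the data.frame returned by [align_all()] or a
#'   path to a SAM file written by [write_sam()].
#' @param truth Optional data.frame with \code{id}, \code{truth_start},
#'   \code{truth_strand}; when NULL the truth is parsed from the read names
#'   (see [encode_truth_name()]).
#' @param tolerance_bp Positional tolerance in bp.
#' @return An \code{eval_report}: list with \code{n_reads},
#'   \code{n_aligned}, \code{n_correct}, \code{precision}, \code{recall},
#'   \code{misalignment_rate}, \code{tolerance_bp}.
#' @export
evaluate_alignments <- function(alignments, truth = NULL, tolerance_bp = 20L) {
  if (is.character(alignments)) {
    sam <- read_sam(alignments)
    sam <- sam[sam$primary, , drop = FALSE]
    df <- data.frame(id = sam$id,
                     aligned = bitwAnd(sam$flag, 4L) == 0L,
                     pos = sam$pos, strand = sam$strand,
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(id = alignments$id,
                     aligned = alignments$status == "ALIGNED",
                     pos = alignments$genome_start + 1L,
                     strand = alignments$strand, stringsAsFactors = FALSE)
  }
  if (is.null(truth)) {
    tn <- parse_truth_name(df$id)
    truth <- data.frame(id = df$id, truth_start = tn$start,
                        truth_strand = tn$strand, stringsAsFactors = FALSE)
  }
  miss <- setdiff(df$id, truth$id)
  if (length(miss) > 0L)
    stop("reads missing from truth: ",
         paste(head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) ", ..." else "")
  i <- match(df$id, truth$id)
  correct <- df$aligned & !is.na(df$pos) &
    df$strand == truth$truth_strand[i] &
    abs(df$pos - truth$truth_start[i]) <= tolerance_bp
  correct[is.na(correct)] <- FALSE
  n <- nrow(df); na <- sum(df$aligned); nc <- sum(correct)
  structure(list(n_reads = n, n_aligned = na, n_correct = nc,
                 precision = if (na > 0L) nc / na else 0,
                 recall = nc / n,
                 misalignment_rate = (na - nc) / n,
                 tolerance_bp = as.integer(tolerance_bp)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> %d reads, %d aligned, %d correct ",
                     "(tol %d bp)\n  precision %.4f  recall %.4f  ",
                     "misalignment %.4f\n"),
              x$n_reads, x$n_aligned, x$n_correct, x$tolerance_bp,
              x$precision, x$recall, x$misalignment_rate))
  invisible(x)
}

#' k-mer repeat density of a genome
#'
#' The repeat density \eqn{D(S|k)} is the fraction of k-mer window positions
#' of \eqn{S} whose k-mer occurs at least twice in \eqn{S}; equivalently,
#' the sum of the occurrence counts \eqn{f(l)} over distinct k-mers \eqn{l}
#' with \eqn{f(l) \ge 2}, divided by \eqn{|S| - k + 1}. It is the
#' probability that a random length-k read drawn from \eqn{S} is a repeat;
#' the larger it is, the harder reads of that length are to place uniquely.
#' Windows containing \code{N} are excluded from numerator and denominator.
#' Forward strand only (no reverse-complement folding). Computed exactly via
#' the suffix array and LCP array of \eqn{S}.
#'
#' @param genome A \code{genome}.
#' @param k Word length(s), each in \code{[1, genome length]}; vectorized.
#' @return Numeric vector of densities in \code{[0, 1]} (NA when no valid
#'   window exists).
#' @export
repeat_density <- function(genome, k) {
  stopifnot(inherits(genome, "genome"))
  k <- as.integer(k)
  if (any(k < 1L) || any(k > genome$length))
    stop("k must be within [1, genome length]")
  repeat_density_cpp(genome$sequence, k)
}

#' Repeat-density profile over several k
#'
#' @param genome A \code{genome}.
#' @param ks Integer vector of word lengths.
#' @return data.frame with \code{genome_name}, \code{k}, \code{density}.
#' @export
repeat_density_profile <- function(genome, ks = c(35L, 51L, 76L, 100L, 200L, 400L)) {
  data.frame(genome_name = genome$name, k = as.integer(ks),
             density = repeat_density(genome, ks), stringsAsFactors = FALSE)
}

#' Pearson correlation of repeat density and aligner performance
#'
#' Joins per-genome repeat densities with per-genome performance and returns
#' the Pearson correlation coefficient for each (k, metric) pair. A vector
#' with zero variance makes the coefficient undefined; it is reported as NA.
#'
#' @param profiles data.frame with \code{genome_name}, \code{k},
#'   \code{density} (e.g. rows of [repeat_density_profile()]).
#' @param performance data.frame with \code{genome_name}, \code{k} and one
#'   or more metric columns (e.g. \code{precision}, \code{recall}).
#' @param metrics Metric column names to correlate.
#' @return data.frame with \code{k}, \code{metric}, \code{r}, \code{n}.
#' @export
density_correlation <- function(profiles, performance,
                                metrics = intersect(c("precision", "recall"),
                                                    names(performance))) {
  joined <- merge(profiles, performance, by = c("genome_name", "k"))
  out <- do.call(rbind, lapply(sort(unique(joined$k)), function(kk) {
    sub <- joined[joined$k == kk, , drop = FALSE]
    do.call(rbind, lapply(metrics, function(mt) {
      x <- sub$density; y <- sub[[mt]]
      if (length(x) < 3L)
        stop("need at least 3 paired observations per k (k=", kk, ")")
      r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else cor(x, y)
      data.frame(k = kk, metric = mt, r = r, n = length(x),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
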