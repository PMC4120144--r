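#' Build the bidirectional FM-index pair for a genome
#'
#' Builds two FM indices: a conventional backward index over the genome
#' sequence \code{S}, and a forward index over \code{reverse(S)} whose
#' backward search is equivalent to forward search in \code{S}. Together they
#' support maximal exact extension of a read in both directions from an
#' anchor position. Construction is deterministic (suffix array by prefix
#' doubling; the full suffix array is retained, \code{sa_stride = 1}).
#'
#' \code{N} characters are stored in the text (coordinates are preserved) but
#' never matched during search, so seeds cannot span an \code{N}.
#'
#' @param genome A \code{genome} object (see [read_fasta()], [genome()]).
#' @return An \code{fm_index_pair} object holding both indices behind an
#'   external pointer, plus the genome.
#' @export
fm_index_pair <- function(genome) {
  stopifnot(inherits(genome, "genome"))
  ptr <- fm_build_pair_cpp(genome$sequence)
  structure(list(ptr = ptr, genome = genome, sa_stride = 1L),
            class = "fm_index_pair")
}

#' @export
print.fm_index_pair <- function(x, ...) {
  cat("<fm_index_pair>", x$genome$name, "-",
      format(x$genome$length, big.mark = ","), "bp, backward + forward FM index\n")
  invisible(x)
}

#' Burrows-Wheeler transform underlying an index
#'
#' Exposes the BWT string (with the \code{$} sentinel) of the backward index
#' over \code{S} or the forward index over \code{reverse(S)}.
#'
#' @param pair An \code{fm_index_pair}.
#' @param which \code{"backward"} or \code{"forward"}.
#' @return The BWT as a single string.
#' @export
fm_bwt <- function(pair, which = c("backward", "forward")) {
  which <- match.arg(which)
  fm_bwt_cpp(pair$ptr, which == "forward")
}

#' Count exact occurrences of a pattern
#'
#' Backward search over the chosen index. An empty pattern matches every
#' suffix-array row; a pattern containing \code{N} matches nothing.
#'
#' @param pair An \code{fm_index_pair}.
#' @param pattern Nucleotide string.
#' @param which Index to search (\code{"backward"} counts occurrences in
#'   \code{S}; \code{"forward"} in \code{reverse(S)}).
#' @return Integer occurrence count.
#' @export
fm_count <- function(pair, pattern, which = c("backward", "forward")) {
  which <- match.arg(which)
  fm_count_cpp(pair$ptr, toupper(pattern), which == "forward")
}

#' Locate exact occurrences of a pattern in the genome
#'
#' @param pair An \code{fm_index_pair}.
#' @param pattern Nucleotide string.
#' @param cap Maximum number of positions to return (ascending order).
#' @return Integer vector of 0-based start positions in \code{S}.
#' @export
fm_locate <- function(pair, pattern, cap = 1000L) {
  fm_locate_cpp(pair$ptr, toupper(pattern), as.integer(cap))
}

#' Extend a suffix-array interval backward by one character
#'
#' One step of FM-index backward search: from the interval of a pattern
#' \code{P} to the interval of \code{cP}. \code{N} yields the empty interval
#' (no error): it never matches.
#'
#' @param pair An \code{fm_index_pair}.
#' @param interval Integer vector \code{c(lo, hi)}, half-open row range.
#' @param ch Single character to prepend.
#' @param which Which index to step in.
#' @return Integer vector \code{c(lo, hi)}; \code{lo == hi} signals no match.
#' @export
fm_extend_backward <- function(pair, interval, ch,
                               which = c("backward", "forward")) {
  which <- match.arg(which)
  fm_extend_backward_cpp(pair$ptr, as.integer(interval[1L]),
                         as.integer(interval[2L]), ch, which == "forward")
}

#' Full suffix-array interval (matches the empty pattern)
#'
#' @param pair An \code{fm_index_pair}.
#' @param which Which index.
#' @return Integer vector \code{c(0, text_length + 1)}.
#' @export
fm_full_interval <- function(pair, which = c("backward", "forward")) {
  which <- match.arg(which)
  fm_full_interval_cpp(pair$ptr, which == "forward")
}

#' Maximal backward match of a read prefix ending at p-1
#'
#' The largest \code{l} such that \code{r[p-l .. p-1]} (1-based) occurs in
#' the genome, searched right-to-left with the backward index, together with
#' the 0-based genome positions where that longest string \emph{ends}
#' (ascending, capped at \code{max_hits}). \code{l == 0} when \code{p == 1}
#' or the single character \code{r[p-1]} does not occur.
#'
#' @param pair An \code{fm_index_pair}.
#' @param read Read sequence (string).
#' @param p 1-based anchor position, \code{1 <= p <= nchar(read)}.
#' @param max_hits Occurrence cap per side.
#' @return List with \code{length} and \code{positions}.
#' @export
maximal_backward_match <- function(pair, read, p, max_hits = 100L) {
  max_match_cpp(pair$ptr, toupper(read), as.integer(p), TRUE,
                as.integer(max_hits))
}

#' Maximal forward match of a read suffix starting at p
#'
#' The largest \code{l} such that \code{r[p .. p+l-1]} occurs in the genome,
#' realized as backward search in the index of the reversed genome, with the
#' 0-based genome \emph{start} positions of the longest match.
#'
#' @inheritParams maximal_backward_match
#' @return List with \code{length} and \code{positions}.
#' @export
maximal_forward_match <- function(pair, read, p, max_hits = 100L) {
  max_match_cpp(pair$ptr, toupper(read), as.integer(p), FALSE,
                as.integer(max_hits))
}

#' Save an index to disk
#'
#' Persists the genome and index metadata; the FM pair itself lives behind an
#' external pointer and is rebuilt deterministically on load (construction
#' takes seconds at the genome sizes this package targets).
#'
#' @param pair An \code{fm_index_pair}.
#' @param prefix Output path prefix; writes \code{<prefix>.idx}.
#' @return The index file path, invisibly.
#' @export
save_index <- function(pair, prefix) {
  obj <- list(format_version = 1L, genome = pair$genome,
              sa_stride = pair$sa_stride)
  saveRDS(obj, paste0(prefix, ".idx"))
  invisible(paste0(prefix, ".idx"))
}

#' Load an index saved with [save_index()]
#'
#' @param prefix Path prefix used at save time.
#' @return An \code{fm_index_pair}.
#' @export
load_index <- function(prefix) {
  path <- paste0(prefix, ".idx")
  if (!file.exists(path)) stop("index file not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format_version, 1L)) stop("unsupported index format version")
  fm_index_pair(obj$genome)
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Nucleotide string over \code{A,C,G,T,N}.
#' @return The reverse complement (\code{N} maps to \code{N}).
#' @export
reverse_complement <- function(seq) revcomp_cpp(toupper(seq))
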