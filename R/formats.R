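#' Read a reference genome from a FASTA file
#'
#' Reads the first record of a (single- or multi-line) FASTA file, upper-cases
#' it and maps every character outside \code{A,C,G,T} to \code{N}. If the file
#' holds more than one record the extra records are skipped with a warning:
#' the aligner indexes one genome/chromosome at a time.
#'
#' @param path Path to a FASTA file.
#' @return A \code{genome} object: list with \code{name}, \code{sequence}
#'   (uppercase string over \code{A,C,G,T,N}) and \code{length} (bp).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a valid FASTA file: ", path,
                                           " (", conditionMessage(e), ")"))
  if (length(set) == 0L) stop("FASTA file has no records: ", path)
  if (length(set) > 1L)
    warning(length(set) - 1L, " additional FASTA record(s) in ", path,
            " skipped; only the first is used")
  seq <- toupper(as.character(set[[1L]]))
  seq <- gsub("[^ACGT]", "N", seq)
  genome(names(set)[1L], seq)
}

#' Construct a genome object
#'
#' @param name Text identifier.
#' @param sequence Uppercase nucleotide string over \code{A,C,G,T,N}.
#' @return A \code{genome} object.
#' @export
genome <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  if (grepl("[^ACGTN]", sequence))
    stop("genome sequence must contain only A, C, G, T, N")
  structure(list(name = name, sequence = sequence, length = nchar(sequence)),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome>", x$name, "-", format(x$length, big.mark = ","), "bp\n")
  invisible(x)
}

#' Write a genome to a FASTA file
#'
#' @param genome A \code{genome} object.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome"))
  starts <- seq(1L, genome$length, by = width)
  lines <- substring(genome$sequence, starts, pmin(starts + width - 1L, genome$length))
  writeLines(c(paste0(">", genome$name), lines), path)
  invisible(path)
}

#' Read single-end reads from a FASTQ file
#'
#' Parses 4-line-per-record FASTQ, preserving ids verbatim (leading \code{@}
#' stripped). A truncated trailing record is a format error naming the record
#' index.
#'
#' @param path Path to a FASTQ file.
#' @return A data.frame with columns \code{id}, \code{sequence},
#'   \code{quality}, one row per read, in file order.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  ln <- readLines(path)
  if (length(ln) == 0L)
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  if (length(ln) %% 4L != 0L)
    stop("truncated FASTQ record at record index ", length(ln) %/% 4L + 1L,
         " in ", path)
  ids <- ln[seq(1L, length(ln), by = 4L)]
  if (any(!startsWith(ids, "@")))
    stop("malformed FASTQ header at record index ",
         which(!startsWith(ids, "@"))[1L], " in ", path)
  seqs <- toupper(ln[seq(2L, length(ln), by = 4L)])
  quals <- ln[seq(4L, length(ln), by = 4L)]
  if (any(nchar(seqs) == 0L))
    stop("empty read sequence at record index ", which(nchar(seqs) == 0L)[1L])
  if (any(nchar(seqs) != nchar(quals)))
    stop("sequence/quality length mismatch at record index ",
         which(nchar(seqs) != nchar(quals))[1L])
  data.frame(id = sub("^@", "", ids), sequence = seqs, quality = quals,
             stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame with \code{id}, \code{sequence}, \code{quality}.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  out <- character(4L * nrow(reads))
  out[seq(1L, length(out), by = 4L)] <- paste0("@", reads$id)
  out[seq(2L, length(out), by = 4L)] <- reads$sequence
  out[seq(3L, length(out), by = 4L)] <- "+"
  out[seq(4L, length(out), by = 4L)] <- reads$quality
  writeLines(out, path)
  invisible(path)
}

#' Encode a simulated read's origin into its name
#'
#' Truth encoding in read names, wgsim-style:
#' \code{<source>_<start>_<end>_<strand>_<serial>} with 1-based inclusive
#' reference coordinates. Round-trips through [parse_truth_name()].
#'
#' @param source_name Genome name the read was sampled from.
#' @param start,end 1-based inclusive reference interval of the read's origin.
#' @param strand \code{"+"} or \code{"-"}.
#' @param serial Integer serial number.
#' @return The encoded read name.
#' @export
encode_truth_name <- function(source_name, start, end, strand, serial) {
  stopifnot(strand %in% c("+", "-"), start >= 1, start <= end)
  paste(source_name, start, end, strand, serial, sep = "_")
}

#' Decode a truth-encoded read name
#'
#' Inverse of [encode_truth_name()]. The source name may itself contain
#' underscores; the four trailing fields are taken from the right.
#'
#' @param name Encoded read name (vectorized).
#' @return data.frame with \code{source_name}, \code{start}, \code{end},
#'   \code{strand}, \code{serial}.
#' @export
parse_truth_name <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 5L
  if (any(bad)) stop("not a truth-encoded read name: ", name[bad][1L])
  f <- function(p) {
    n <- length(p)
    c(paste(p[1:(n - 4L)], collapse = "_"), p[(n - 3L):n])
  }
  m <- t(vapply(parts, f, character(5L)))
  data.frame(source_name = m[, 1L], start = as.integer(m[, 2L]),
             end = as.integer(m[, 3L]), strand = m[, 4L],
             serial = as.integer(m[, 5L]), stringsAsFactors = FALSE)
}

#' Write alignments as SAM
#'
#' Emits a SAM v1.6 file with \code{@HD}/\code{@SQ} headers. Aligned reads
#' carry 1-based positions, a \code{<m>M} CIGAR (the method reports an
#' aligned interval plus edit distance, not a base-level path) and the edit
#' distance in the \code{NM} tag. Reverse-strand hits get flag 16 and the
#' reverse-complemented sequence. When a read has a second candidate it is
#' emitted as a flag-256 secondary record. Unaligned reads (ambiguous or
#' attempt-exhausted) get flag 4 and a \code{ZS} tag saying which.
#'
#' @param alignments data.frame as returned by [align_all()].
#' @param genome The reference \code{genome}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_sam <- function(alignments, genome, path) {
  stopifnot(inherits(genome, "genome"))
  a <- alignments
  pos1 <- a$genome_start + 1L          # 0-based internal -> 1-based SAM
  ok <- is.na(pos1) | (pos1 >= 1L & pos1 <= genome$length)
  if (!all(ok))
    stop("alignment position outside [1, ", genome$length, "] for read ",
         a$id[!ok][1L])
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", genome$name, "\tLN:", genome$length),
           paste0("@PG\tID:randalign\tPN:randalign\tVN:",
                  as.character(utils::packageVersion("randalign"))))
  recs <- character(0L)
  for (i in seq_len(nrow(a))) {
    m <- nchar(a$sequence[i])
    if (a$status[i] == "ALIGNED") {
      rev <- identical(a$strand[i], "-")
      seq_out <- if (rev) revcomp_cpp(a$sequence[i]) else a$sequence[i]
      qual <- if (!is.null(a$quality)) a$quality[i] else strrep("I", m)
      if (rev) qual <- paste(rev(strsplit(qual, "")[[1]]), collapse = "")
      recs <- c(recs, paste(a$id[i], if (rev) 16L else 0L, genome$name,
                            pos1[i], 255L, paste0(m, "M"), "*", 0L, 0L,
                            seq_out, qual, paste0("NM:i:", a$dist[i]),
                            sep = "\t"))
      if (!is.na(a$genome_start2[i])) {
        rev2 <- identical(a$strand2[i], "-")
        flag2 <- 256L + if (rev2) 16L else 0L
        recs <- c(recs, paste(a$id[i], flag2, genome$name,
                              a$genome_start2[i] + 1L, 255L, paste0(m, "M"),
                              "*", 0L, 0L, "*", "*",
                              paste0("NM:i:", a$dist2[i]), sep = "\t"))
      }
    } else {
      zs <- if (a$status[i] == "AMBIGUOUS") "ambiguous" else "exhausted"
      qual <- if (!is.null(a$quality)) a$quality[i] else strrep("I", m)
      recs <- c(recs, paste(a$id[i], 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                            a$sequence[i], qual, paste0("ZS:Z:", zs),
                            sep = "\t"))
    }
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Parse a SAM file written by this package
#'
#' Minimal SAM reader for evaluation: keeps the columns the evaluator needs.
#'
#' @param path Path to a SAM file.
#' @return data.frame with \code{id}, \code{flag}, \code{pos} (1-based),
#'   \code{strand}, \code{nm}, \code{primary}.
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (length(ln) == 0L)
    return(data.frame(id = character(), flag = integer(), pos = integer(),
                      strand = character(), nm = integer(),
                      primary = logical(), stringsAsFactors = FALSE))
  fields <- strsplit(ln, "\t", fixed = TRUE)
  id <- vapply(fields, `[[`, "", 1L)
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  pos <- as.integer(vapply(fields, `[[`, "", 4L))
  nm <- vapply(fields, function(f) {
    tag <- grep("^NM:i:", f, value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1L])) else NA_integer_
  }, 1L)
  data.frame(id = id, flag = flag, pos = pos,
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"), nm = nm,
             primary = bitwAnd(flag, 256L) == 0L, stringsAsFactors = FALSE)
}
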