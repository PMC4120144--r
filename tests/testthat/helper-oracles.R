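# Independent brute-force oracles used to cross-check the FM-index route.
# These deliberately avoid the package's compiled search machinery.

# all 0-based start positions of `pattern` in `text`, overlapping included;
# patterns containing N never match (mirrors the search contract)
naive_occurrences <- function(text, pattern) {
  np <- nchar(pattern)
  if (np == 0L || np > nchar(text) || grepl("N", pattern, fixed = TRUE))
    return(integer(0))
  starts <- 1:(nchar(text) - np + 1L)
  which(substring(text, starts, starts + np - 1L) == pattern) - 1L
}

naive_count <- function(text, pattern) length(naive_occurrences(text, pattern))

# BWT via explicit sorted rotations (radix sort = bytewise, C locale)
naive_bwt <- function(text) {
  s <- paste0(text, "$")
  n <- nchar(s)
  rot <- vapply(0:(n - 1L), function(i)
    paste0(substr(s, i + 1L, n), substr(s, 1L, i)), "")
  rot <- sort(rot, method = "radix")
  paste(substring(rot, n, n), collapse = "")
}

# longest l such that r[p-l .. p-1] occurs in text, with 0-based end positions
naive_max_backward <- function(text, r, p) {
  best_l <- 0L; ends <- integer(0)
  for (l in seq_len(p - 1L)) {
    pat <- substr(r, p - l, p - 1L)
    occ <- naive_occurrences(text, pat)
    if (length(occ) == 0L) break
    best_l <- l; ends <- occ + l - 1L
  }
  list(length = best_l, positions = ends)
}

# longest l such that r[p .. p+l-1] occurs in text, with 0-based start positions
naive_max_forward <- function(text, r, p) {
  m <- nchar(r)
  best_l <- 0L; starts <- integer(0)
  for (l in seq_len(m - p + 1L)) {
    pat <- substr(r, p, p + l - 1L)
    occ <- naive_occurrences(text, pat)
    if (length(occ) == 0L) break
    best_l <- l; starts <- occ
  }
  list(length = best_l, positions = starts)
}

# literal quadratic pairing of maximal backward/forward occurrences
# (the common-substrings-at-p algorithm, longest-only reading)
naive_common_substrings <- function(text, r, p, W) {
  b <- naive_max_backward(text, r, p)
  f <- naive_max_forward(text, r, p)
  out <- data.frame(read_i = integer(0), read_j = integer(0),
                    genome_start = integer(0), length = integer(0))
  if (b$length > 0L && f$length > 0L) {
    for (e in b$positions) for (q in f$positions) {
      if (q == e + 1L && b$length + f$length >= W)
        out <- rbind(out, data.frame(read_i = p - b$length,
                                     read_j = p + f$length - 1L,
                                     genome_start = q - b$length,
                                     length = b$length + f$length))
    }
  } else if (b$length == 0L && f$length >= W) {
    out <- data.frame(read_i = p, read_j = p + f$length - 1L,
                      genome_start = f$positions, length = f$length)
  } else if (f$length == 0L && b$length >= W) {
    out <- data.frame(read_i = p - b$length, read_j = p - 1L,
                      genome_start = b$positions - b$length + 1L,
                      length = b$length)
  }
  out[order(out$genome_start), , drop = FALSE]
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# plant k substitutions at distinct positions of a sequence
plant_substitutions <- function(seq, positions) {
  for (p in positions) {
    orig <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(c("A", "C", "G", "T"), orig), 1L)
  }
  seq
}

tmpfile <- function(ext) tempfile(fileext = ext)
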