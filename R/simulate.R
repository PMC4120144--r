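#' Simulation configuration
#'
#' wgsim-style defaults: 2\% per-base sequencing error, polymorphism rate
#' 0.001 per site, 15\% of polymorphisms are indels, indel lengths geometric
#' with density \code{0.7 * 0.3^(l-1)} (continuation probability 0.3, mean
#' \code{1/0.7}).
#'
#' @param n_reads Number of reads to sample.
#' @param read_length Read length m (bp).
#' @param base_error_rate Per-base sequencing error probability.
#' @param mutation_rate Per-site polymorphism probability.
#' @param indel_fraction Probability a polymorphism is an indel.
#' @param indel_ext Geometric continuation probability for indel length.
#' @param rng_seed Integer seed.
#' @return A \code{sim_config} object.
#' @export
sim_config <- function(n_reads, read_length, base_error_rate = 0.02,
                       mutation_rate = 0.001, indel_fraction = 0.15,
                       indel_ext = 0.3, rng_seed = 1L) {
  stopifnot(n_reads >= 1, read_length >= 1,
            base_error_rate >= 0, base_error_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            indel_fraction >= 0, indel_fraction <= 1,
            indel_ext >= 0, indel_ext < 1)
  structure(list(n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 base_error_rate = base_error_rate,
                 mutation_rate = mutation_rate,
                 indel_fraction = indel_fraction, indel_ext = indel_ext,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

rand_other_base <- function(ref) {
  # uniform over the three bases differing from ref; any base when ref is N
  vapply(ref, function(b) {
    pool <- if (b %in% BASES) setdiff(BASES, b) else BASES
    pool[sample.int(length(pool), 1L)]
  }, "", USE.NAMES = FALSE)
}

#' Mutate a reference genome into a donor genome
#'
#' Each site independently becomes a polymorphism with probability
#' \code{mutation_rate}; a polymorphism is a SNP (uniform over the three
#' other bases) with probability \code{1 - indel_fraction}, otherwise an
#' indel (insertion or deletion, equiprobable) of length \code{L} with
#' \code{P(L = l) = (1-indel_ext) * indel_ext^(l-1)}. Insertions place
#' random bases after the site; deletions remove \code{l} bases starting at
#' the site. A site falling inside a previous deletion is skipped. Uses the
#' current R RNG state (see [simulate_reads()] for the seeded entry point).
#'
#' @param genome Reference \code{genome}.
#' @param cfg A \code{sim_config}.
#' @return A \code{mutated_genome}: list with \code{donor} (a
#'   \code{genome}), \code{variants} (data.frame: \code{position} 1-based
#'   reference coordinate, \code{kind} in SNP/INS/DEL, \code{ref_allele},
#'   \code{alt_allele}, \code{length}), \code{ref_of_donor} (integer vector
#'   mapping each donor base to a reference coordinate; inserted bases
#'   inherit the preceding reference base) and \code{ref_name}.
#' @export
mutate_genome <- function(genome, cfg) {
  stopifnot(inherits(genome, "genome"), inherits(cfg, "sim_config"))
  L <- genome$length
  chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1L]]
  sites <- which(runif(L) < cfg$mutation_rate)
  kind <- character(0); pos <- integer(0); refa <- character(0)
  alta <- character(0); vlen <- integer(0)
  covered_until <- 0L
  for (s in sites) {
    if (s <= covered_until) next  # inside a previous deletion
    if (runif(1L) < cfg$indel_fraction) {
      l <- rgeom(1L, 1 - cfg$indel_ext) + 1L
      if (runif(1L) < 0.5) {  # deletion of l bases starting at s
        l <- min(l, L - s + 1L)
        pos <- c(pos, s); kind <- c(kind, "DEL")
        refa <- c(refa, paste(chars[s:(s + l - 1L)], collapse = ""))
        alta <- c(alta, ""); vlen <- c(vlen, l)
        covered_until <- s + l - 1L
      } else {                # insertion of l bases after s
        ins <- paste(BASES[sample.int(4L, l, replace = TRUE)], collapse = "")
        pos <- c(pos, s); kind <- c(kind, "INS")
        refa <- c(refa, chars[s]); alta <- c(alta, ins); vlen <- c(vlen, l)
      }
    } else {
      alt <- rand_other_base(chars[s])
      pos <- c(pos, s); kind <- c(kind, "SNP")
      refa <- c(refa, chars[s]); alta <- c(alta, alt); vlen <- c(vlen, 1L)
      chars[s] <- alt          # SNPs applied in place
    }
  }
  variants <- data.frame(position = pos, kind = kind, ref_allele = refa,
                         alt_allele = alta, length = vlen,
                         stringsAsFactors = FALSE)
  # assemble donor + donor->reference coordinate map around the indels
  seg_seq <- list(); seg_map <- list(); cur <- 1L
  sv <- variants[variants$kind != "SNP", , drop = FALSE]
  for (i in seq_len(nrow(sv))) {
    p <- sv$position[i]; l <- sv$length[i]
    if (sv$kind[i] == "DEL") {
      if (cur <= p - 1L) {
        seg_seq[[length(seg_seq) + 1L]] <- chars[cur:(p - 1L)]
        seg_map[[length(seg_map) + 1L]] <- cur:(p - 1L)
      }
      cur <- p + l
    } else {  # INS after p
      seg_seq[[length(seg_seq) + 1L]] <- chars[cur:p]
      seg_map[[length(seg_map) + 1L]] <- cur:p
      seg_seq[[length(seg_seq) + 1L]] <-
        strsplit(sv$alt_allele[i], "", fixed = TRUE)[[1L]]
      seg_map[[length(seg_map) + 1L]] <- rep(p, l)
      cur <- p + 1L
    }
  }
  if (cur <= L) {
    seg_seq[[length(seg_seq) + 1L]] <- chars[cur:L]
    seg_map[[length(seg_map) + 1L]] <- cur:L
  }
  donor_chars <- unlist(seg_seq, use.names = FALSE)
  ref_of <- unlist(seg_map, use.names = FALSE)
  donor <- genome(paste0(genome$name, "_donor"),
                  paste(donor_chars, collapse = ""))
  structure(list(donor = donor, variants = variants, ref_of_donor = ref_of,
                 ref_name = genome$name),
            class = "mutated_genome")
}

#' Sample reads from a donor genome with sequencing errors
#'
#' Each read starts at a uniform position on the donor and comes from a
#' uniform strand; minus-strand reads are reverse-complemented. Each base is
#' then flipped to a uniformly chosen different base with probability
#' \code{base_error_rate}. Qualities are constant. The read name encodes the
#' \emph{reference}-coordinate interval of the sampled donor segment
#' (mapped through the variant offsets) and the strand, wgsim-style. Uses
#' the current R RNG state.
#'
#' @param mut A \code{mutated_genome} from [mutate_genome()] (pass a
#'   reference genome wrapped by \code{mutate_genome} with
#'   \code{mutation_rate = 0} for a polymorphism-free donor).
#' @param cfg A \code{sim_config}.
#' @return data.frame with \code{id}, \code{sequence}, \code{quality}, plus
#'   truth columns \code{truth_start}, \code{truth_end} (1-based reference),
#'   \code{truth_strand}.
#' @export
sample_reads <- function(mut, cfg) {
  stopifnot(inherits(mut, "mutated_genome"), inherits(cfg, "sim_config"))
  donor <- mut$donor
  m <- cfg$read_length
  n <- cfg$n_reads
  if (donor$length < m) stop("donor genome shorter than the read length")
  starts <- sample.int(donor$length - m + 1L, n, replace = TRUE)
  minus <- runif(n) < 0.5
  seqs <- substring(donor$sequence, starts, starts + m - 1L)
  seqs[minus] <- vapply(seqs[minus], revcomp_cpp, "", USE.NAMES = FALSE)
  if (cfg$base_error_rate > 0) {
    err <- which(runif(n * m) < cfg$base_error_rate)
    rd <- (err - 1L) %/% m + 1L
    off <- (err - 1L) %% m + 1L
    for (k in seq_along(err)) {
      orig <- substr(seqs[rd[k]], off[k], off[k])
      substr(seqs[rd[k]], off[k], off[k]) <- rand_other_base(orig)
    }
  }
  t_start <- mut$ref_of_donor[starts]
  t_end <- mut$ref_of_donor[starts + m - 1L]
  strand <- ifelse(minus, "-", "+")
  ids <- encode_truth_name(mut$ref_name, t_start, t_end, strand, seq_len(n))
  data.frame(id = ids, sequence = seqs, quality = strrep("I", m),
             truth_start = t_start, truth_end = t_end, truth_strand = strand,
             stringsAsFactors = FALSE)
}

#' Simulate reads from a reference genome (seeded entry point)
#'
#' Mutates the reference into a donor haplotype and samples error-carrying
#' reads from it, all under \code{cfg$rng_seed}; the same seed gives
#' byte-identical output.
#'
#' @param genome Reference \code{genome}.
#' @param cfg A \code{sim_config}.
#' @return List with \code{reads} (data.frame as in [sample_reads()]),
#'   \code{donor}, \code{variants}.
#' @export
simulate_reads <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$rng_seed, {
    mut <- mutate_genome(genome, cfg)
    reads <- sample_reads(mut, cfg)
    list(reads = reads, donor = mut$donor, variants = mut$variants)
  })
}

#' Generate a random i.i.d. nucleotide genome
#'
#' Uniform A/C/G/T sequence; with its near-zero repeat density at the read
#' lengths used here it stands in for a repeat-poor reference.
#'
#' @param length Genome length (bp).
#' @param name Genome name.
#' @param seed Optional seed (uses the current RNG state when NULL).
#' @return A \code{genome}.
#' @export
random_genome <- function(length, name = "random", seed = NULL) {
  gen <- function() paste(BASES[sample.int(4L, length, replace = TRUE)],
                          collapse = "")
  seqc <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  genome(name, seqc)
}
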