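mk_aln <- function(id, status, pos0, strand) {
  data.frame(id = id, status = status, genome_start = pos0, strand = strand,
             stringsAsFactors = FALSE)
}

test_that("exact alignments score perfect precision and recall", {
  al <- mk_aln(paste0("g_", c(10, 50, 90), "_", c(29, 69, 109), "_+_", 1:3),
               "ALIGNED", c(9L, 49L, 89L), "+")
  rep <- evaluate_alignments(al)
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_equal(rep$misalignment_rate, 0)
})

test_that("the printed metric definitions are computed verbatim", {
  # 10 reads: 8 aligned, of which 7 correct
  ids <- paste0("g_", 100 * (1:10), "_", 100 * (1:10) + 49, "_+_", 1:10)
  status <- c(rep("ALIGNED", 8), rep("UNALIGNED", 2))
  pos0 <- c(100 * (1:7) - 1L, 5000L, NA, NA)   # read 8 aligned far away
  al <- mk_aln(ids, status, pos0, c(rep("+", 8), NA, NA))
  rep <- evaluate_alignments(al)
  expect_equal(rep$n_reads, 10L)
  expect_equal(rep$n_aligned, 8L)
  expect_equal(rep$n_correct, 7L)
  expect_equal(rep$precision, 7 / 8)
  expect_equal(rep$recall, 0.7)
  expect_equal(rep$misalignment_rate, 0.1)
  # identity among the definitions
  expect_equal(rep$misalignment_rate + rep$recall, rep$n_aligned / rep$n_reads)
})

test_that("the positional tolerance is inclusive at 20 and fails at 21", {
  id20 <- "g_100_149_+_1"; id21 <- "g_100_149_+_2"
  al <- mk_aln(c(id20, id21), "ALIGNED", c(99L + 20L, 99L + 21L), "+")
  rep <- evaluate_alignments(al)
  expect_equal(rep$n_correct, 1L)
  # and strand agreement is required
  al2 <- mk_aln("g_100_149_+_1", "ALIGNED", 99L, "-")
  expect_equal(evaluate_alignments(al2)$n_correct, 0L)
})

test_that("reads missing from the truth raise a consistency error", {
  al <- mk_aln("g_100_149_+_1", "ALIGNED", 99L, "+")
  truth <- data.frame(id = "other", truth_start = 1L, truth_strand = "+",
                      stringsAsFactors = FALSE)
  expect_error(evaluate_alignments(al, truth = truth), "missing from truth")
})

test_that("evaluation through a SAM file matches the in-memory route", {
  set.seed(163)
  g <- random_genome(20000, "ref", seed = 167)
  cfg <- sim_config(200, 80, rng_seed = 173L)
  sim <- simulate_reads(g, cfg)
  pair <- fm_index_pair(g)
  params <- derive_parameters(80, 0.02, rng_seed = 179L)
  f <- tmpfile(".sam")
  res <- align_all(pair, sim$reads, params, sam = f)
  rep_mem <- evaluate_alignments(res)
  rep_sam <- evaluate_alignments(f)
  expect_equal(rep_sam$n_aligned, rep_mem$n_aligned)
  expect_equal(rep_sam$n_correct, rep_mem$n_correct)
  expect_equal(rep_sam$precision, rep_mem$precision)
})

test_that("repeat density follows its definition on closed-form cases", {
  expect_equal(repeat_density(genome("g", "ACGT"), 2), 0)
  expect_equal(repeat_density(genome("g", "AAAA"), 2), 1)   # f(AA)=3, denom 3
  # k = 1 on a longer-than-alphabet ACGT-only genome: pigeonhole forces 1
  set.seed(181)
  expect_equal(repeat_density(genome("g", random_seq(50)), 1), 1)
  # windows containing N are excluded from both sides of the fraction
  expect_equal(repeat_density(genome("g", "ACGTNACGT"), 2), 1)
  expect_equal(repeat_density(genome("g", "ACGTNTGCA"), 2), 0)
  expect_error(repeat_density(genome("g", "ACGT"), 5), "within")
  # vectorized k, plus the profile wrapper
  prof <- repeat_density_profile(genome("g", "AAAAAAAA"), ks = c(2L, 3L))
  expect_equal(prof$density, c(1, 1))
})

test_that("hand-counted density on a small repeat structure is reproduced", {
  # S = ACGACGT, k=3: windows ACG,CGA,GAC,ACG,CGT -> ACG occurs twice
  expect_equal(repeat_density(genome("g", "ACGACGT"), 3), 2 / 5)
})

test_that("random genomes have near-zero density above the birthday length", {
  for (s in c(191, 193)) {
    g <- random_genome(20000, "g", seed = s)
    k <- ceiling(2 * log(20000, base = 4)) + 4
    expect_lt(repeat_density(g, k), 0.01)
  }
})

test_that("density-performance correlation recovers designed relationships", {
  prof <- data.frame(genome_name = paste0("g", 1:6), k = 35L,
                     density = c(0.02, 0.05, 0.08, 0.11, 0.14, 0.18))
  perf <- data.frame(genome_name = paste0("g", 1:6), k = 35L,
                     precision = prof$density,            # r = +1
                     recall = -prof$density + 1)          # r = -1
  r <- density_correlation(prof, perf)
  expect_equal(r$r[r$metric == "precision"], 1)
  expect_equal(r$r[r$metric == "recall"], -1)

  # random paired data vs the textbook formula
  set.seed(197)
  x <- runif(12); y <- runif(12)
  prof2 <- data.frame(genome_name = paste0("g", 1:12), k = 100L, density = x)
  perf2 <- data.frame(genome_name = paste0("g", 1:12), k = 100L, precision = y)
  r2 <- density_correlation(prof2, perf2, metrics = "precision")$r
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r2, manual)

  # zero variance -> undefined, reported as NA
  perf3 <- data.frame(genome_name = paste0("g", 1:6), k = 35L, precision = 0.5)
  expect_true(is.na(density_correlation(prof, perf3,
                                        metrics = "precision")$r))
  expect_error(density_correlation(prof[1:2, ], perf[1:2, ]), "at least 3")
})
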