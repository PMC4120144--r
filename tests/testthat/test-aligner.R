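test_that("seed extension computes flank distances and honors the budget", {
  set.seed(43)
  S <- random_seq(2000)
  pair <- fm_index_pair(genome("g", S))
  t <- 8L
  m <- 100L
  s0 <- 800L
  r <- substr(S, s0, s0 + m - 1L)

  # full-length error-free seed: empty flanks, d = 0
  seed <- data.frame(read_i = 1L, read_j = m, genome_start = s0 - 1L,
                     length = m, wrapped = FALSE, len_f = 0L, len_b = 0L,
                     q_b_end = 0L)
  cand <- extend_seed(pair, r, seed, t)
  expect_equal(cand$dist, 0L)
  expect_equal(cand$genome_start, s0 - 1L)
  expect_equal(cand$genome_end, s0 - 1L + m)

  # one substitution in the left flank
  r2 <- plant_substitutions(r, 5L)
  seed2 <- data.frame(read_i = 21L, read_j = m, genome_start = s0 + 19L,
                      length = m - 20L, wrapped = FALSE, len_f = 0L,
                      len_b = 0L, q_b_end = 0L)
  cand2 <- extend_seed(pair, r2, seed2, t)
  expect_equal(cand2$dist_left, 1L)
  expect_equal(cand2$dist_right, 0L)
  expect_equal(cand2$dist, as.integer(adist(substr(r2, 1, 20),
                                            substr(S, s0, s0 + 19))))

  # a flank whose true distance exceeds t is rejected
  r3 <- plant_substitutions(r, 1:(t + 1L))
  d3 <- as.integer(adist(substr(r3, 1, 20), substr(S, s0, s0 + 19)))
  cand3 <- extend_seed(pair, r3, seed2, t)
  if (d3 > t) expect_null(cand3) else expect_equal(cand3$dist_left, d3)
  # and an unambiguous overload: whole flank replaced by a homopolymer
  r4 <- paste0(strrep("A", 20), substr(r, 21, m))
  d4 <- as.integer(adist(strrep("A", 20), substr(S, s0, s0 + 19)))
  expect_gt(d4, t)  # a random 20-mer is far from poly-A
  expect_null(extend_seed(pair, r4, seed2, t))
})

test_that("an error-free unique read aligns on the first attempt at its origin", {
  set.seed(47)
  S <- random_seq(20000)
  pair <- fm_index_pair(genome("g", S))
  params <- derive_parameters(100, 0.02, rng_seed = 5L)
  for (i in 1:10) {
    s0 <- sample(19900, 1)
    r <- substr(S, s0, s0 + 99L)
    res <- align_read(pair, r, params, ordinal = i)
    expect_equal(res$status, "ALIGNED")
    expect_equal(res$attempts_used, 1L)
    expect_equal(res$candidates$dist[1], 0L)
    expect_equal(res$candidates$genome_start[1], s0 - 1L)
    expect_equal(res$candidates$strand[1], "+")
  }
})

test_that("reverse-complemented reads align to the forward coordinates", {
  set.seed(53)
  S <- random_seq(20000)
  pair <- fm_index_pair(genome("g", S))
  params <- derive_parameters(100, 0.02, rng_seed = 5L)
  s0 <- 7000L
  r <- reverse_complement(substr(S, s0, s0 + 99L))
  res <- align_read(pair, r, params)
  expect_equal(res$status, "ALIGNED")
  expect_equal(res$candidates$genome_start[1], s0 - 1L)
  expect_equal(res$candidates$strand[1], "-")
})

test_that("a read from a verbatim triplicated segment is ambiguous", {
  set.seed(59)
  seg <- random_seq(300)
  S <- paste0(random_seq(500), seg, random_seq(500), seg, random_seq(500),
              seg, random_seq(500))
  pair <- fm_index_pair(genome("g", S))
  params <- derive_parameters(100, 0.02, rng_seed = 5L)
  r <- substr(seg, 100, 199)
  res <- align_read(pair, r, params)
  expect_equal(res$status, "AMBIGUOUS")
})

test_that("a random unrelated read exhausts all attempts unaligned", {
  set.seed(61)
  S <- random_seq(20000)
  pair <- fm_index_pair(genome("g", S))
  params <- derive_parameters(100, 0.02, rng_seed = 5L)
  r <- random_seq(100)
  res <- align_read(pair, r, params)
  expect_equal(res$status, "UNALIGNED")
  expect_equal(res$attempts_used, params$A)
})

test_that("aligned reads satisfy the distance budget against the genome substring", {
  set.seed(67)
  g <- random_genome(30000, "inv")
  pair <- fm_index_pair(g)
  cfg <- sim_config(200, 100, rng_seed = 71L)
  sim <- simulate_reads(g, cfg)
  params <- derive_parameters(100, 0.02, rng_seed = 73L)
  res <- align_all(pair, sim$reads, params)
  al <- res[res$status == "ALIGNED", ]
  expect_gt(nrow(al), 150)
  for (k in seq_len(nrow(al))) {
    sub <- substr(g$sequence, al$genome_start[k] + 1L, al$genome_end[k])
    q <- if (al$strand[k] == "-") reverse_complement(al$sequence[k]) else
      al$sequence[k]
    expect_lte(bound_edit_distance(q, sub, params$t)$value, params$t)
  }
})

test_that("alignment is deterministic and independent of batch order", {
  set.seed(79)
  g <- random_genome(20000, "det")
  pair <- fm_index_pair(g)
  cfg <- sim_config(100, 100, rng_seed = 83L)
  sim <- simulate_reads(g, cfg)
  params <- derive_parameters(100, 0.02, rng_seed = 89L)

  f1 <- tmpfile(".sam"); f2 <- tmpfile(".sam")
  r1 <- align_all(pair, sim$reads, params, sam = f1)
  r2 <- align_all(pair, sim$reads, params, sam = f2)
  expect_identical(readLines(f1), readLines(f2))

  # permuted reads with their original ordinals give the same per-read result
  perm <- sample(nrow(sim$reads))
  r3 <- align_all(pair, sim$reads[perm, ], params, ordinals = perm)
  r3 <- r3[order(perm), ]
  rownames(r3) <- NULL
  rownames(r1) <- NULL
  expect_equal(r3, r1)
})

test_that("raising the attempt budget never loses alignments", {
  set.seed(97)
  g <- random_genome(20000, "mono")
  pair <- fm_index_pair(g)
  cfg <- sim_config(300, 100, base_error_rate = 0.04, rng_seed = 101L)
  sim <- simulate_reads(g, cfg)
  p9 <- derive_parameters(100, 0.04, rng_seed = 103L)
  p3 <- override_parameters(p9, A = 3L)
  res3 <- align_all(pair, sim$reads, p3)
  res9 <- align_all(pair, sim$reads, p9)
  ok3 <- res3$status == "ALIGNED"
  # every read aligned with A=3 is aligned identically with the larger budget
  expect_true(all(res9$status[ok3] == "ALIGNED"))
  expect_equal(res9$genome_start[ok3], res3$genome_start[ok3])
  expect_gte(sum(res9$status == "ALIGNED"), sum(ok3))
})
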