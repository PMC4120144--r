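test_that("BWT matches the sorted-rotations construction", {
  for (txt in c("ACGT", "AAAA", "A", "ACGTACGT", "GATTACA")) {
    pair <- fm_index_pair(genome("g", txt))
    expect_equal(fm_bwt(pair, "backward"), naive_bwt(txt))
    rev_txt <- paste(rev(strsplit(txt, "")[[1]]), collapse = "")
    expect_equal(fm_bwt(pair, "forward"), naive_bwt(rev_txt))
  }
})

test_that("index construction is deterministic", {
  set.seed(11)
  txt <- random_seq(300)
  p1 <- fm_index_pair(genome("g", txt))
  p2 <- fm_index_pair(genome("g", txt))
  expect_identical(fm_bwt(p1), fm_bwt(p2))
  expect_identical(fm_bwt(p1, "forward"), fm_bwt(p2, "forward"))
})

test_that("counting and locating agree with naive search on random cases", {
  set.seed(42)
  for (case in 1:200) {
    txt <- random_seq(sample(20:200, 1))
    pat <- if (case %% 2 == 0) {  # planted substring
      s <- sample(nchar(txt) - 5L, 1L)
      substr(txt, s, s + sample(1:5, 1))
    } else {
      random_seq(sample(1:8, 1))
    }
    pair <- fm_index_pair(genome("g", txt))
    expect_equal(fm_count(pair, pat), naive_count(txt, pat), info = pat)
    expect_equal(fm_locate(pair, pat, cap = 1000L),
                 naive_occurrences(txt, pat), info = pat)
  }
})

test_that("single-character and empty-pattern counting behave at the edges", {
  pair <- fm_index_pair(genome("g", "A"))
  expect_equal(fm_count(pair, "A"), 1L)
  expect_equal(fm_count(pair, "C"), 0L)
  pair2 <- fm_index_pair(genome("g", "AAAA"))
  expect_equal(fm_count(pair2, "AA"), 3L)
})

test_that("stepwise backward extension matches whole-pattern search", {
  pair <- fm_index_pair(genome("g", "ACGTACGT"))
  iv <- fm_full_interval(pair)
  ivA <- fm_extend_backward(pair, iv, "A")
  expect_equal(ivA[2] - ivA[1], 2L)            # "A" occurs twice
  # build "AC" by extending "C" with A
  ivC <- fm_extend_backward(pair, iv, "C")
  ivAC <- fm_extend_backward(pair, ivC, "A")
  expect_equal(ivAC[2] - ivAC[1], naive_count("ACGTACGT", "AC"))
  # absent character: empty interval
  pairT <- fm_index_pair(genome("g", "AAAA"))
  ivT <- fm_extend_backward(pairT, fm_full_interval(pairT), "T")
  expect_equal(ivT[1], ivT[2])
  # N never matches, and is not an error
  ivN <- fm_extend_backward(pair, iv, "N")
  expect_equal(ivN[1], ivN[2])
  # cap contract on locate
  expect_length(fm_locate(pair, "AC", cap = 1L), 1L)
})

test_that("maximal backward/forward matches equal the brute-force longest match", {
  S <- "ACGTACGT"
  pair <- fm_index_pair(genome("g", S))
  # spec worked example: r = "TTCG", p = 4 matches suffixes of "TTC"
  got <- maximal_backward_match(pair, "TTCG", 4)
  want <- naive_max_backward(S, "TTCG", 4)
  expect_equal(got$length, want$length)
  expect_equal(got$positions, want$positions)
  # p = 1: empty prefix
  expect_equal(maximal_backward_match(pair, "TTCG", 1)$length, 0L)
  # forward: r = "ACGA", p = 1 -> longest prefix "ACG" at starts 0 and 4
  gotf <- maximal_forward_match(pair, "ACGA", 1)
  expect_equal(gotf$length, 3L)
  expect_equal(gotf$positions, c(0L, 4L))
  # leading N never matches
  expect_equal(maximal_forward_match(pair, "NACG", 1)$length, 0L)
  expect_error(maximal_backward_match(pair, "ACGT", 9), "out of range")

  set.seed(13)
  for (i in 1:60) {
    txt <- random_seq(sample(30:250, 1))
    pr <- fm_index_pair(genome("g", txt))
    # read: a genome substring with a couple of substitutions
    s <- sample(nchar(txt) - 20L, 1L)
    r <- plant_substitutions(substr(txt, s, s + 19L), sample(2:19, 2))
    p <- sample(1:20, 1)
    gb <- maximal_backward_match(pr, r, p, max_hits = 1000L)
    nb <- naive_max_backward(txt, r, p)
    expect_equal(gb$length, nb$length)
    expect_equal(gb$positions, nb$positions)
    gf <- maximal_forward_match(pr, r, p, max_hits = 1000L)
    nf <- naive_max_forward(txt, r, p)
    expect_equal(gf$length, nf$length)
    expect_equal(gf$positions, nf$positions)
  }
})

test_that("a read copied verbatim from the genome matches back to its full prefix", {
  set.seed(23)
  txt <- random_seq(400)
  pair <- fm_index_pair(genome("g", txt))
  r <- substr(txt, 101, 140)
  m <- nchar(r)
  got <- maximal_backward_match(pair, r, m)
  expect_equal(got$length, m - 1L)  # all of r[1..m-1]
})

test_that("forward matching on S mirrors backward matching on reverse(S)", {
  set.seed(31)
  for (i in 1:20) {
    txt <- random_seq(80)
    rts <- paste(rev(strsplit(txt, "")[[1]]), collapse = "")
    p1 <- fm_index_pair(genome("g", txt))
    r <- random_seq(12)
    rr <- paste(rev(strsplit(r, "")[[1]]), collapse = "")
    m <- nchar(r)
    f <- maximal_forward_match(p1, r, 1, max_hits = 1000L)
    # the maximal prefix match of r in S is the maximal suffix match of
    # reverse(r) in reverse(S), with mirrored coordinates
    bb <- naive_max_backward(rts, rr, m + 1L)
    expect_equal(f$length, bb$length)
    if (f$length > 0) {
      mapped <- sort(nchar(txt) - (bb$positions) - 1L)
      expect_equal(f$positions, mapped)
    }
  }
})

test_that("index persistence round-trips through save/load", {
  set.seed(5)
  g <- genome("persisted", random_seq(200))
  pair <- fm_index_pair(g)
  prefix <- tempfile()
  save_index(pair, prefix)
  pair2 <- load_index(prefix)
  expect_equal(pair2$genome$sequence, g$sequence)
  expect_identical(fm_bwt(pair2), fm_bwt(pair))
  expect_error(load_index(tempfile()), "not found")
})
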