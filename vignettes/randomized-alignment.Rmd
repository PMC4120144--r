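---
title: "Randomized seed-and-extend alignment: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomized seed-and-extend alignment: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(randalign)
```

## The alignment model

A read `r` of length `m` is assumed to originate from a genome of the same
species as the reference `S`, so it differs from its true source interval by
a small number `d` of single-base differences: sequencing errors and
polymorphisms, including short indels. Treating each base as independently
different with probability `b`, `d` is Binomial(`m`, `b`) with mean `mb` and
variance `mb(1-b)`.

The `d` differences cut the read into `d + 1` error-free blocks, each of
which appears verbatim in `S`. The aligner exploits this: it anchors at a
read position `p`, finds the maximal exact match extending left of `p` and
the maximal exact match extending right of `p` with a pair of FM indices
(one over `S`, one over `reverse(S)`), and joins left/right occurrences that
are contiguous in the genome into a single seed. If `p` lands inside an
error-free block, the seed is that whole block. Seeds are then extended:
the unmatched read prefix is compared with the genome segment immediately
left of the seed and the unmatched suffix with the segment immediately
right, under a total edit-distance budget `t`.

Because `p` is chosen uniformly at random, landing in a given block has
probability proportional to its length (size-biased sampling). The expected
length of the sampled block is `sum(m_i^2)/m`, which by Cauchy–Schwarz is at
least `m/(d+1)`; `simulate_block_model()` reproduces this bound by direct
Monte Carlo. This is the basis for both the seed-length filter and the
attempt budget below.

## Tunable parameters

All three governing parameters are derived by `derive_parameters(m, b)`;
each can be overridden explicitly.

* **`b`** — per-base error-plus-polymorphism probability (dimensionless,
  default 0.02 to match the simulator's default sequencing error rate).
  The polymorphism contribution at wgsim-default rates (0.001/site) is an
  order of magnitude below the sequencing error and is deliberately not
  added on top; callers aligning real data should supply their own `b`.
* **`c_sigma`** — the width of the distance bound in standard deviations
  (default 4). `t = ceiling(m*b + c_sigma*sqrt(m*b*(1-b)))` is the edit
  budget; at 4 sigma the probability that a read carries more than `t`
  differences is far below 1% over the whole supported `(m, b)` range
  (checked by simulation in the test suite). Larger `c_sigma` trades speed
  (larger `t`, hence wider DP bands and more attempts) for recall.
* **`W`** — minimum seed length in bp, `floor(m / max(t, 1))`. Random
  `W`-mers of a non-repetitive genome are essentially unique for the `W`
  values arising here (12 at `m = 100, b = 0.02`), so the filter removes
  spurious seeds without discarding true blocks, whose sampled length is
  at least `m/(d+1) >= m/t` in expectation.
* **`A`** — attempt budget, `a_multiplier * (t + 1)`. By pigeonhole the
  longest error-free block has length at least `m/(d+1)`, so a uniform
  anchor hits it with probability at least `1/(d+1) >= 1/(t+1)`; `t + 1`
  attempts therefore sample it in expectation. `a_multiplier` (default 1)
  exponentially increases that certainty at proportional cost; 1 is enough
  in practice because non-longest blocks usually extend to the correct
  alignment too.
* **`max_hits`** — cap on occurrence lists per seeding side (default 100).
  Bounds work on pathological repeats; a capped side keeps its first
  `max_hits` occurrences. For the forward index the cap is applied in
  reversed-genome order before coordinate mapping; the difference is only
  observable when a single maximal match has over 100 occurrences, in which
  case the read is overwhelmingly likely to end ambiguous anyway.

The first attempt always uses `p = 1` (wrap-around seeding, below);
subsequent anchors are uniform on `1..m`, repeats allowed, matching the
sampling model behind `A`.

## Edit-distance pruning

`bound_edit_distance(x, y, t)` answers `d(x, y) <= t` exactly: it computes
the DP only inside the band `|i - j| <= t` (cells outside can never be
reached within budget) and stops as soon as the row minimum inside the band
exceeds `t`, returning the sentinel `t + 1`. The equivalence — verdict
`<= t` iff the true distance is `<= t`, with exact value agreement below
the threshold — is verified exhaustively over small alphabets and against
an independent implementation on random pairs.

Two deliberate deviations from a literal transliteration of the published
pruned recurrence:

* The printed pseudo-code initializes the first DP row and column to zero,
  which makes the distance from an empty string to anything zero — a
  "free end gaps" behavior that would let a seed at the very start of a
  read accept an arbitrary genome flank at zero cost, contradicting the
  distance budget the extension step relies on. The default here is the
  standard initialization (`d[i,0] = i`, `d[0,j] = j`);
  `literal_init = TRUE` reproduces the zero-initialized variant for study.
* The printed cell update adds an *equality* indicator to the diagonal
  term; read literally it would charge matches and reward mismatches. It
  is implemented as the usual mismatch indicator.

`N` never matches anything, including another `N` — in seeding (seeds
cannot span an `N`) and in the DP (always a mismatch).

## Wrap-around seeding and other concretizations

At `p = 1` the backward side of the anchor is empty, so the read is treated
as circular: the maximal *prefix* match and the maximal *suffix* match of
the read are two genome segments separated by a gap. A prefix occurrence
starting at `q_f` and a suffix occurrence ending at `q_e` are paired when
`|(q_e - q_f + 1) - m| <= t`: the gap between the two parts can absorb at
most `t` indels, so any larger span deviation cannot be closed within
budget. A prefix or suffix that alone reaches `W` is also emitted as an
ordinary seed, so a read whose other half is error-dense still gets
anchored. Extension of a wrapped pair scores the read interior against the
genome gap.

Other points where the design was genuinely open, and the choices made:

* **Maximality.** For each anchor one maximal match length is taken per
  direction, with all occurrences of that longest string; shorter-than-
  maximal matches are not enumerated. This keeps the candidate pairing
  bounded and reflects that a single long block anchored at `p` is the
  object the randomization argument reasons about.
* **Strand.** The candidate set of an attempt pools the read and its
  reverse complement (the simulator samples both strands uniformly).
  Pooling rather than alternating keeps the full attempt budget available
  to both orientations; duplicates (same genome start and strand) collapse
  before the ambiguity test.
* **Ambiguity threshold.** An attempt yielding more than two distinct
  candidates fails the read as ambiguous — the literal reading of the
  candidate-set rule, giving repeats an explicit outcome distinct from
  "no seed found".
* **Primary selection.** SAM needs a primary record when two candidates
  are reported: lower edit distance wins, ties broken by leftmost genome
  start, then `+` strand. Deterministic and order-independent.
* **Flank truncation.** A flank running past a genome end is truncated;
  the DP then charges the missing bases as indels, i.e. one edit per
  missing base.
* **Coordinates.** Internally everything is 0-based half-open; SAM records
  and truth names are 1-based inclusive, converted only at the I/O
  boundary.
* **CIGAR.** Emitted as a single match-length run (`<m>M`): the method
  reports an aligned interval and an edit distance, not a base-level
  operation path, and the evaluation only consumes positions.
* **Suffix arrays.** Built by prefix doubling (deterministic, safe on
  degenerate repetitive inputs); the full suffix array is stored. At the
  genome scales this package targets (up to a few Mb) that is a few bytes
  per base, and it keeps `locate` exact and simple. The on-disk "index"
  stores the genome plus metadata and rebuilds the FM pair on load.

## What the simulator does and does not emulate

`simulate_reads()` follows the wgsim model: a single donor haplotype is
derived from the reference (per-site polymorphism probability 0.001, of
which 15% are indels with geometric lengths, density `0.7 * 0.3^(l-1)`,
mean 1/0.7 ≈ 1.43); reads are sampled uniformly from either strand and
each base is flipped to a uniformly chosen different base with probability
`base_error_rate` (default 0.02). Truth intervals are reported in
*reference* coordinates through the variant offset map; a read starting
inside an insertion inherits the preceding reference coordinate, an
ambiguity absorbed by the 20-bp evaluation tolerance.

Deliberately not modeled: diploidy (a single rate `b` is what the aligner
reasons about), quality-score-dependent error profiles, platform-specific
error modes (homopolymer indels, chimeras), coverage biases, and reads
spanning the genome end. Consequently, passing the simulation benchmarks
shows that the randomized seeding and bounded extension work as analyzed
under the binomial error model on low-repeat sequence; it does not certify
performance on repeat-rich real genomes, where the repeat density
`repeat_density()` quantifies how much harder unique placement becomes, nor
robustness to structured error processes.

## Evaluation conventions

A read is *aligned* iff its primary record is not flag-4, and *correct* iff
aligned, on the truth strand, within 20 bp of the truth start. Precision is
correct/aligned, recall correct/total, misalignment (aligned −
correct)/total; ambiguous and attempt-exhausted reads count against recall
but not precision. Strand agreement is required — a reverse-complement
placement at the right coordinate is not "correct" here, a strictness that
can only lower the reported numbers.

Repeat density is computed on the forward strand only, without
reverse-complement folding, exactly (suffix array + LCP), with N-containing
windows excluded from numerator and denominator.

## Problem sizes

The shipped tests and the acceptance script run, by choice, at desk scale:
random genomes of 20–100 kb, 10,000 simulated reads for the headline
benchmark, 10^5 Monte-Carlo trials for the distributional checks, and
exhaustive small-alphabet enumeration for the pruning equivalence. A random
100-kb genome has repeat density ≈ 0 at k = 35–100, so these benchmarks
isolate the method's statistical behavior from repeat handling; the
ambiguity rule is exercised separately with engineered repeats. The same
code paths scale to bacterial genomes (a few Mb) with proportional index
build time and memory.

## Known limitations

* Single-end reads only; no paired-end constraints.
* No mapping-quality model (MAPQ is emitted as 255) and no base-quality
  weighting.
* Alignment is global over the read against a genome window — no soft
  clipping, so chimeric or adapter-contaminated reads either pay full edit
  cost or go unaligned.
* One reference sequence per index; multi-record FASTA inputs use the
  first record with a warning.
* The occurrence cap makes extremely high-copy repeats (above `max_hits`
  occurrences of a maximal match) behave as "first `max_hits`" rather than
  exhaustively; such reads are effectively destined for the ambiguous
  outcome regardless.
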