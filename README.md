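# randalign

Randomized seed-and-extend alignment of single-end DNA sequencing reads to a
reference genome, for read lengths from ~35 bp up to several hundred bp and
per-base error rates up to a few percent.

## The method

Given a reference genome *S* and a read *r* of length *m*, the aligner looks
for a long exact common substring of *r* and *S* anchored at a read position
*p*, then extends it to a full alignment under a bounded edit distance:

- **Bidirectional FM-index seeding.** Two FM indices are kept: a
  conventional backward index of *S* and an index of *reverse(S)*, whose
  backward search is forward search in *S*. At an anchor *p* the maximal
  exact match of `r[..p-1]` going left and of `r[p..]` going right are found
  in O(length) time; a left occurrence ending at genome position *e* joins a
  right occurrence starting at *e + 1* into one seed. Seeds shorter than a
  minimum length *W* are discarded. At *p = 1* the read is treated as
  circular: a read-*suffix* match and a read-*prefix* match at consistent
  genome spacing jointly anchor the alignment ("wrap-around" seeding).
- **Derived parameters.** With *b* the per-base error/polymorphism rate, the
  number of differences *d* between the read and its true origin is
  approximately Binomial(*m*, *b*). The edit-distance budget is
  *t* = ⌈*mb* + c·√(*mb*(1−*b*))⌉ with c = 4 (a 4σ bound, so
  P(*d* > *t*) ≪ 1%). The *d* differences cut the read into *d*+1 blocks;
  the block containing a uniformly random *p* has expected length at least
  *m*/(*d*+1), so the seed filter is *W* = ⌊*m*/*t*⌋, and *A* = *t*+1
  random anchors suffice in expectation to sample the longest block. At
  *m* = 100, *b* = 0.02: *t* = 8, *W* = 12, *A* = 9.
- **Threshold-pruned edit distance.** Seed flanks are scored with a banded
  dynamic program that stops as soon as every cell of the current row
  exceeds *t*, returning the exact distance whenever it is ≤ *t* and a
  sentinel *t*+1 otherwise — O(*t*·*m*) instead of Θ(*m*²).
- **Ambiguity rule.** Candidates from both strands are pooled per attempt;
  more than two distinct candidates means the read sits in a repeat and it
  is reported as ambiguous (unaligned, tagged `ZS:Z:ambiguous` in the SAM).

The package also provides a wgsim-style read simulator (donor-genome
polymorphisms with 15% indels of geometric length, per-base sequencing
errors, truth encoded in read names), an evaluator (precision, recall,
misalignment rate at a 20-bp positional tolerance), and the k-mer **repeat
density** D(S|k) — the fraction of k-mer windows of *S* whose k-mer occurs
at least twice, i.e. the probability that a random length-k read is a
repeat — with a Pearson-correlation helper relating it to aligner
performance.

## Worked example

```r
library(randalign)

g      <- random_genome(50000, "toy", seed = 404)
cfg    <- sim_config(n_reads = 2000, read_length = 100, rng_seed = 7)
sim    <- simulate_reads(g, cfg)          # donor mutations + 2% base error
pair   <- fm_index_pair(g)
params <- derive_parameters(m = 100, b = 0.02, rng_seed = 11)
params
#> <aligner_params> b=0.02 c=4  t=8  W=12  A=9  max_hits=100 seed=11

res <- align_all(pair, sim$reads, params, sam = "toy.sam")
table(res$status)
#>   ALIGNED UNALIGNED
#>      1991         9

evaluate_alignments(res)
#> <eval_report> 2000 reads, 1991 aligned, 1991 correct (tol 20 bp)
#>   precision 1.0000  recall 0.9955  misalignment 0.0000

repeat_density(g, 35)
#> [1] 0
```

Every aligned read here maps within 20 bp of its simulated origin
(precision 1), 99.6% of all reads are recovered (recall), and no read is
placed at a wrong position (misalignment 0). The nine unaligned reads drew
more errors than the t = 8 budget or lost all seeds to them. A random
50-kb genome has repeat density 0 at k = 35: every 35-mer is unique, which
is what makes the toy benchmark easy; real genomes have D(S|k) up to ~0.2
and correspondingly harder placement.

The same pipeline is scriptable from a shell:

```sh
randal=$(Rscript -e 'cat(system.file("cli","randal.R",package="randalign"))')
Rscript $randal index ref.fa -o ref
Rscript $randal simulate ref.fa -n 10000 -l 100 -e 0.02 --seed 7 -o reads.fq --truth truth.tsv
Rscript $randal align ref reads.fq -o out.sam --error-rate 0.02 --seed 42
Rscript $randal evaluate out.sam --truth truth.tsv --json report.json
Rscript $randal density ref.fa -k 35,100 --tsv density.tsv
```

Each output gets a JSON run manifest (parameters, paths, seed) alongside it;
re-running with the same seed reproduces outputs byte-identically.

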