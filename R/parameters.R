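#' Derive the aligner's governing parameters from read length and error rate
#'
#' Under a binomial error model, the number of differences \code{d} between a
#' read of length \code{m} and its true origin has mean \code{mb} and
#' variance \code{mb(1-b)}, where \code{b} is the per-base probability of a
#' polymorphism or sequencing error. The parameters are:
#' \itemize{
#'   \item \code{t = ceiling(m*b + c_sigma*sqrt(m*b*(1-b)))} -- the edit
#'     distance budget, a \code{c_sigma}-standard-deviation upper bound on
#'     \code{d} (default \code{c_sigma = 4}, which keeps the miss probability
#'     well under 1\%);
#'   \item \code{W = max(1, floor(m / max(t, 1)))} -- the minimum seed
#'     length; \code{d} differences cut the read into \code{d+1} blocks, and
#'     the block containing a uniformly random position has expected length
#'     at least \code{m/(d+1)};
#'   \item \code{A = a_multiplier * (t + 1)} -- the attempt budget; by the
#'     pigeonhole principle the longest error-free block has length at least
#'     \code{m/(d+1)}, so it is sampled in expectation within \code{t+1}
#'     uniform draws. \code{a_multiplier = 1} works well in practice.
#' }
#' \code{t} is rounded up (conservative distance budget) and \code{W} down
#' (permissive seed filter); the \code{max(t, 1)} guard covers the
#' error-free case \code{t = 0}, where \code{W = m} forces exact matching.
#'
#' @param m Read length (bp), \code{m >= 1}.
#' @param b Per-base error + polymorphism rate, \code{0 <= b < 1}.
#' @param c_sigma Standard-deviation multiplier (default 4).
#' @param a_multiplier Attempt multiplier (default 1).
#' @param max_hits Cap on FM-index occurrences per seeding side (default 100).
#' @param rng_seed Integer seed driving the random anchor positions.
#' @return An \code{aligner_params} object with fields \code{b},
#'   \code{c_sigma}, \code{t}, \code{W}, \code{A}, \code{max_hits},
#'   \code{rng_seed}.
#' @examples
#' derive_parameters(100, 0.02)  # t = 8, W = 12, A = 9
#' @export
derive_parameters <- function(m, b, c_sigma = 4, a_multiplier = 1L,
                              max_hits = 100L, rng_seed = 1L) {
  if (!is.numeric(m) || length(m) != 1L || m < 1)
    stop("read length m must be >= 1")
  if (!is.numeric(b) || length(b) != 1L || b < 0 || b >= 1)
    stop("error rate b must satisfy 0 <= b < 1")
  if (c_sigma <= 0) stop("c_sigma must be > 0")
  t <- as.integer(ceiling(m * b + c_sigma * sqrt(m * b * (1 - b))))
  W <- max(1L, as.integer(floor(m / max(t, 1L))))
  A <- as.integer(a_multiplier) * (t + 1L)
  structure(list(b = b, c_sigma = c_sigma, t = t, W = W, A = A,
                 max_hits = as.integer(max_hits),
                 rng_seed = as.integer(rng_seed)),
            class = "aligner_params")
}

#' @export
print.aligner_params <- function(x, ...) {
  cat(sprintf("<aligner_params> b=%g c=%g  t=%d  W=%d  A=%d  max_hits=%d seed=%d\n",
              x$b, x$c_sigma, x$t, x$W, x$A, x$max_hits, x$rng_seed))
  invisible(x)
}

#' Override derived parameters
#'
#' Replaces individual fields of an \code{aligner_params} (e.g. an explicit
#' \code{t}, \code{W} or \code{A} bypassing derivation), keeping invariants.
#'
#' @param params An \code{aligner_params}.
#' @param t,W,A,max_hits,rng_seed Optional replacement values.
#' @return The modified \code{aligner_params}.
#' @export
override_parameters <- function(params, t = NULL, W = NULL, A = NULL,
                                max_hits = NULL, rng_seed = NULL) {
  stopifnot(inherits(params, "aligner_params"))
  if (!is.null(t)) params$t <- as.integer(t)
  if (!is.null(W)) params$W <- as.integer(W)
  if (!is.null(A)) params$A <- as.integer(A)
  if (!is.null(max_hits)) params$max_hits <- as.integer(max_hits)
  if (!is.null(rng_seed)) params$rng_seed <- as.integer(rng_seed)
  stopifnot(params$t >= 0L, params$W >= 1L, params$A >= 1L)
  params
}

#' Simulate the random-block model behind the seed-length bound
#'
#' Monte-Carlo check of the expected-seed-length argument: \code{d} cut
#' points are placed uniformly at random on a length-\code{m} read, splitting
#' it into \code{d+1} blocks; a uniform position \code{p} is drawn and the
#' length of the block containing \code{p} is recorded. The mean of that
#' length is at least \code{m/(d+1)} (size-biased sampling plus
#' Cauchy-Schwarz).
#'
#' @param m Read length.
#' @param d Number of differences (cut points).
#' @param n_trials Number of Monte-Carlo trials.
#' @param seed Integer seed for the simulation's own RNG stream.
#' @return Mean sampled-block length over the trials.
#' @export
simulate_block_model <- function(m, d, n_trials = 1e5, seed = 1L) {
  stopifnot(m >= 1, d >= 0, d <= m)
  block_model_mean_cpp(as.integer(m), as.integer(d), as.integer(n_trials),
                       as.integer(seed))
}
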