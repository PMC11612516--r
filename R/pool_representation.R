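#' Distinct individuals represented by a read depth
#'
#' Draws `depth` reads uniformly with replacement over the `n_pool`
#' individuals of a pool and counts how many distinct individuals were hit.
#' This is the occupancy model behind the minimum-depth threshold: a site's
#' read depth only "represents" the pool members its reads happened to
#' sample.
#'
#' @param n_pool Number of individuals in the pool (>= 1).
#' @param depth Number of reads drawn (>= 1).
#' @param n_draws Number of independent resampling events to simulate.
#' @return Integer vector of length `n_draws` of distinct-individual counts,
#'   each in `[1, min(n_pool, depth)]`.
#' @export
sample_distinct <- function(n_pool, depth, n_draws = 1) {
  if (n_pool < 1 || depth < 1) stop("n_pool and depth must be >= 1",
                                    call. = FALSE)
  stopifnot(n_draws >= 1)
  n_pool <- as.integer(n_pool)
  out <- integer(n_draws)
  # chunked multinomial occupancy: counts per individual, then occupied cells
  chunk <- max(1L, as.integer(4e6 %/% n_pool))
  done <- 0L
  pr <- rep(1 / n_pool, n_pool)
  while (done < n_draws) {
    k <- min(chunk, n_draws - done)
    m <- stats::rmultinom(k, depth, pr)
    out[done + seq_len(k)] <- as.integer(.colSums(m > 0, n_pool, k))
    done <- done + k
  }
  out
}

#' Expected distinct individuals under uniform sampling
#'
#' Closed form `n * (1 - (1 - 1/n)^d)` for the expected number of occupied
#' cells when `d` balls fall uniformly into `n` boxes.
#'
#' @param n_pool Pool size.
#' @param depth Read depth.
#' @return Expected distinct-individual count.
#' @export
expected_distinct <- function(n_pool, depth) {
  n_pool * (1 - (1 - 1 / n_pool)^depth)
}

#' Monte-Carlo summary of pool representation at a given depth
#'
#' Repeats the resampling experiment of [sample_distinct()] `n_reps` times
#' and summarizes the distribution of distinct individuals represented.
#' `lower95` is read as the lower bound of the central 95% interval, i.e.
#' the empirical 2.5% quantile (`interval = "central"`); a one-sided 5%
#' quantile is available via `interval = "lower"`. Both conventions yield 13
#' for a pool of 25 at depth 25.
#'
#' @param n_pool Pool size.
#' @param depth Read depth.
#' @param n_reps Number of resampling events (the reference experiment uses
#'   one million).
#' @param seed Optional RNG seed for reproducibility.
#' @param interval `"central"` (2.5% quantile) or `"lower"` (5% quantile).
#' @return An object of class `representation_summary`: list with
#'   `n_pool`, `depth`, `n_reps`, `mean_distinct`, `lower95`, and
#'   `quantiles` (probabilities 0.025--0.975).
#' @export
representation_summary <- function(n_pool, depth, n_reps = 1e6, seed = NULL,
                                   interval = c("central", "lower")) {
  interval <- match.arg(interval)
  stopifnot(n_reps >= 1)
  d <- local_seed(seed, sample_distinct(n_pool, depth, n_reps))
  probs <- c(0.025, 0.05, 0.25, 0.5, 0.75, 0.95, 0.975)
  qs <- stats::quantile(d, probs, type = 1, names = FALSE)
  lower_p <- if (interval == "central") 0.025 else 0.05
  structure(list(
    n_pool = n_pool, depth = depth, n_reps = n_reps,
    mean_distinct = mean(d),
    lower95 = as.integer(stats::quantile(d, lower_p, type = 1, names = FALSE)),
    quantiles = stats::setNames(as.integer(qs), probs),
    interval = interval
  ), class = "representation_summary")
}

#' @export
print.representation_summary <- function(x, ...) {
  cat(sprintf("pool representation: n_pool=%d depth=%d (%s reps)\n",
              x$n_pool, x$depth,
              format(x$n_reps, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  mean distinct individuals: %.2f (closed form %.2f)\n",
              x$mean_distinct, expected_distinct(x$n_pool, x$depth)))
  cat(sprintf("  lower 95%% limit (%s): %d\n", x$interval, x$lower95))
  invisible(x)
}

#' Smallest depth representing a fraction of the pool with confidence
#'
#' Searches for the smallest read depth whose lower `(1 - confidence)`-tail
#' quantile of the distinct-individual distribution reaches
#' `ceiling(fraction * n_pool)`. This reproduces the reasoning behind a
#' minimum-depth filter: e.g. for pools of 25, depth 25 already represents
#' at least half the pool (13 individuals) with 95% confidence.
#'
#' @param n_pool Pool size.
#' @param fraction Required represented fraction of the pool, in (0, 1].
#' @param confidence Confidence level of the lower quantile.
#' @param n_reps Monte-Carlo replicates per candidate depth.
#' @param seed Optional base seed; each candidate depth uses `seed + depth`.
#' @param interval Quantile convention, see [representation_summary()].
#' @param max_depth Search ceiling.
#' @return The smallest qualifying integer depth.
#' @export
min_depth_for_representation <- function(n_pool, fraction = 0.5,
                                         confidence = 0.95, n_reps = 1e5,
                                         seed = NULL,
                                         interval = c("central", "lower"),
                                         max_depth = 10000L) {
  interval <- match.arg(interval)
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  target <- ceiling(fraction * n_pool)
  if (target > n_pool) stop("unreachable fraction", call. = FALSE)
  lower_p <- if (interval == "central") (1 - confidence) / 2 else 1 - confidence
  ok <- function(depth) {
    s <- local_seed(if (is.null(seed)) NULL else seed + depth,
                    sample_distinct(n_pool, depth, n_reps))
    stats::quantile(s, lower_p, type = 1, names = FALSE) >= target
  }
  # distinct count cannot exceed depth, so `target` bounds the search below
  lo <- as.integer(target)
  if (ok(lo)) return(lo)
  hi <- lo
  repeat {
    hi <- min(2L * hi, as.integer(max_depth))
    if (ok(hi)) break
    if (hi >= max_depth) stop("no qualifying depth below max_depth",
                              call. = FALSE)
  }
  # binary search on the (stochastically) monotone criterion
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (ok(mid)) hi <- mid else lo <- mid
  }
  hi
}
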