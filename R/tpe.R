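# Tree-structured Parzen estimator for a one-dimensional log-uniform
# search space.  Minimal but faithful: random startup trials, then a split
# of the history at the gamma-quantile of the objective into "good" (l) and
# "rest" (g) sets, candidate draws from the Parzen mixture of l, and
# selection by the density ratio l(x)/g(x).  Everything runs in log space
# and is deterministic under the seed.

parzen_density <- function(x, pts, bw, lo, hi) {
  # mixture of the observed points plus one uniform pseudo-component over
  # the search range, which keeps densities bounded away from zero
  n <- length(pts)
  kernel <- if (n == 0) 0 else
    rowMeans(outer(x, pts, function(a, b) dnorm(a, mean = b, sd = bw)))
  (n * kernel + 1 / (hi - lo)) / (n + 1)
}

parzen_bandwidth <- function(pts, lo, hi) {
  span <- hi - lo
  if (length(pts) < 2L) return(span / 4)
  max(span / 20, stats::sd(pts) * length(pts)^(-0.2))
}

# Minimize fn(lambda) over lambda in [low, high] (log-uniform prior).
# Returns list(best = lambda, trials = tibble(lambda, objective)).
tpe_optimize <- function(fn, low, high, n_trials, seed,
                         n_startup = 10L, gamma = 0.25, n_candidates = 24L) {
  if (low == high) {
    obj <- fn(low)
    return(list(best = low,
                trials = tibble::tibble(lambda = low, objective = obj)))
  }
  lo <- log(low)
  hi <- log(high)
  xs <- numeric(0)
  ys <- numeric(0)
  with_seed(seed, {
    for (t in seq_len(n_trials)) {
      if (t <= n_startup || length(xs) < 3L) {
        x <- runif(1, lo, hi)
      } else {
        ord <- order(ys)
        n_best <- max(2L, ceiling(gamma * length(ys)))
        lpts <- xs[ord[seq_len(n_best)]]
        gpts <- xs[ord[-seq_len(n_best)]]
        bw_l <- parzen_bandwidth(lpts, lo, hi)
        bw_g <- parzen_bandwidth(gpts, lo, hi)
        centers <- lpts[sample.int(length(lpts), n_candidates, replace = TRUE)]
        cand <- pmin(pmax(rnorm(n_candidates, centers, bw_l), lo), hi)
        score <- parzen_density(cand, lpts, bw_l, lo, hi) /
          parzen_density(cand, gpts, bw_g, lo, hi)
        x <- cand[which.max(score)]
      }
      xs <- c(xs, x)
      ys <- c(ys, fn(exp(x)))
    }
  })
  list(best = exp(xs[which.min(ys)]),
       trials = tibble::tibble(lambda = exp(xs), objective = ys))
}
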