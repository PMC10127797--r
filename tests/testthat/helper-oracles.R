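# Independent brute-force oracles used to validate package computations.
# These deliberately share no code with the implementation.

# Exact two-sided paired Wilcoxon signed-rank p by enumerating all 2^n sign
# patterns of the absolute differences (no ties assumed).
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  # two-sided: distance from the null mean n(n+1)/4
  mu <- n * (n + 1) / 4
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Exact two-sided p for equal Poisson rates via the conditional binomial
# distribution: sum of probabilities of outcomes no more likely than observed.
oracle_poisson_rate <- function(n1, n2) {
  n <- n1 + n2
  probs <- stats::dbinom(0:n, n, 0.5)
  min(1, sum(probs[probs <= probs[n1 + 1] * (1 + 1e-7)]))
}

# Closed-form Savage-Dickey log10 Bayes factor for the conjugate 1-D normal
# model: y_i ~ N(theta, sigma^2) with sigma known, theta ~ N(0, s0^2).
oracle_log10_bf_normal <- function(y, sigma, s0) {
  n <- length(y)
  v1 <- 1 / (n / sigma^2 + 1 / s0^2)
  m1 <- v1 * sum(y) / sigma^2
  log10(stats::dnorm(0, 0, s0)) - log10(stats::dnorm(0, m1, sqrt(v1)))
}

# All circularly consecutive centre-to-centre distances by brute force:
# for every ordered pair, the clockwise gap; keep, for each peak, the gap to
# its nearest clockwise neighbour.
oracle_interpeak <- function(centers, L) {
  n <- length(centers)
  out <- numeric(n)
  for (i in seq_len(n)) {
    gaps <- (centers - centers[i]) %% L
    gaps <- gaps[gaps > 0]
    out[i] <- min(gaps)
  }
  sort(out)
}

# Spearman correlation from the rank formula, independent of stats::cor.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Exact permutation p for a difference in means, all label reassignments.
oracle_perm_exact <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  obs <- mean(a) - mean(b)
  idx <- utils::combn(length(pool), n1)
  diffs <- apply(idx, 2, function(ii) mean(pool[ii]) - mean(pool[-ii]))
  mean(abs(diffs) >= abs(obs) - 1e-12)
}

# Small shared simulation fixture (kept small so the suite stays fast).
tiny_config <- function(seed = 11, ...) {
  sim_config(genome_length = 4e5, n_tus = 80, n_primary_sites = 20,
             seed = seed, ...)
}

flat_track <- function(values, bin_size = 25, stage = "raw", meta = NULL) {
  occupancy_track(values, bin_size = bin_size, meta = meta, stage = stage)
}

# force a track to a given stage without computation (for unit tests of
# stage-guarded operations)
as_stage <- function(track, stage) {
  track$stage <- stage
  track
}
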