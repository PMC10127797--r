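# Statistics for clustered ("bridged") binding: local peak counts at a fixed
# radius, permutation comparison of counts between genotypes, and the
# interpeak-distance distribution against a shuffled null with a smoothed
# density and pointwise 95% band.

circ_gap <- function(s1, e1, s2, e2, L) {
  # edge-to-edge distance between two disjoint intervals on a circle
  # (0 if they touch or overlap)
  d1 <- (s2 - e1) %% L
  d2 <- (s1 - e2) %% L
  ov <- (s1 < e2 & s2 < e1)  # linear overlap
  out <- pmin(d1, d2)
  out[ov] <- 0
  out
}

#' Local peak counts at a fixed radius
#'
#' For every peak, the number of peaks whose nearest-edge distance to it is
#' at most `radius` along the circular replicon.  By default the focal peak
#' counts itself (counts are >= 1, so an isolated peak scores 1 and "self
#' plus one neighbour" scores 2).
#'
#' @param peaks Peak data frame with `start`/`end`, sorted and disjoint.
#' @param replicon_length Circular replicon length in bases.
#' @param radius Locality radius in bases (default 2000).
#' @param include_self Count the focal peak itself (default TRUE).
#' @return List of class \code{"bridging_stats"}: `local_count` (per peak),
#'   `mean_local_count`, `radius`.
#' @export
local_peak_counts <- function(peaks, replicon_length, radius = 2000,
                              include_self = TRUE) {
  n <- nrow(peaks)
  if (n == 0) {
    return(structure(list(local_count = integer(0),
                          mean_local_count = NA_real_, radius = radius),
                     class = "bridging_stats"))
  }
  counts <- vapply(seq_len(n), function(i) {
    g <- circ_gap(peaks$start[i], peaks$end[i], peaks$start, peaks$end,
                  replicon_length)
    sum(g[-i] <= radius) + as.integer(include_self)
  }, integer(1))
  structure(list(local_count = counts, mean_local_count = mean(counts),
                 radius = radius),
            class = "bridging_stats")
}

#' @export
print.bridging_stats <- function(x, ...) {
  cat(sprintf("<bridging_stats> %d peaks, radius %d bp, mean local count %.2f\n",
              length(x$local_count), x$radius, x$mean_local_count))
  invisible(x)
}

#' Permutation test for a difference in mean local counts
#'
#' Pools the two groups of per-peak local counts, reassigns group labels
#' `n_perm` times, and reports the two-sided p-value
#' `(1 + #[|null diff| >= |observed diff|]) / (1 + n_perm)`.
#'
#' @param counts_a,counts_b Integer vectors of per-peak local counts.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed.
#' @return List: `p`, `observed` (difference in means), `null` (vector).
#' @export
local_count_permutation <- function(counts_a, counts_b, n_perm = 999,
                                    seed = 1) {
  stopifnot(length(counts_a) >= 1, length(counts_b) >= 1, n_perm >= 1)
  obs <- mean(counts_a) - mean(counts_b)
  pool <- c(counts_a, counts_b)
  n1 <- length(counts_a)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(length(pool), n1)
      mean(pool[idx]) - mean(pool[-idx])
    }, numeric(1))
  })
  list(p = (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (1 + n_perm),
       observed = obs, null = null)
}

#' Centre-to-centre distances between consecutive peaks
#'
#' Peak centres are sorted along the circular replicon; distances are taken
#' between each pair of circularly consecutive peaks, so `n` peaks yield `n`
#' distances (including the wrap-around gap).
#'
#' @param peaks Peak data frame with `start`/`end`.
#' @param replicon_length Circular replicon length in bases.
#' @return Numeric vector of distances in bases (empty for < 2 peaks).
#' @export
interpeak_distances <- function(peaks, replicon_length) {
  if (nrow(peaks) < 2) return(numeric(0))
  centers <- sort(((peaks$start + peaks$end) / 2) %% replicon_length)
  d <- diff(centers)
  c(d, replicon_length - (centers[length(centers)] - centers[1]))
}

#' Assign peaks to fixed-span cluster regions
#'
#' Groups peaks whose centres are within `span` of each other (single
#' linkage along the replicon) and assigns each group a region extending
#' `span / 2` beyond its outermost peak edges.  These regions are the units
#' within which peak locations are shuffled for the null distribution.
#'
#' @param peaks Peak data frame.
#' @param replicon_length Circular replicon length in bases.
#' @param span Region span parameter in bases (default 10000).
#' @return Data frame: `region_id`, `start`, `end` per peak (same order as
#'   `peaks`).
#' @export
cluster_regions <- function(peaks, replicon_length, span = 10000) {
  n <- nrow(peaks)
  stopifnot(n >= 1)
  ord <- order(peaks$start)
  centers <- (peaks$start + peaks$end)[ord] / 2
  grp <- cumsum(c(1, diff(centers) > span))
  # merge first and last groups across the origin if close
  if (n > 1 && (replicon_length - (centers[n] - centers[1])) <= span &&
      grp[1] != grp[n]) {
    grp[grp == grp[n]] <- grp[1]
  }
  region <- integer(n)
  region[ord] <- grp
  starts <- tapply(peaks$start, region, min) - span / 2
  ends <- tapply(peaks$end, region, max) + span / 2
  ids <- as.integer(names(starts))
  data.frame(region_id = region,
             start = as.numeric(starts[match(region, ids)]),
             end = as.numeric(ends[match(region, ids)]))
}

place_without_overlap <- function(widths, lo, hi, max_tries = 1000) {
  # uniform placement of intervals of given widths inside [lo, hi) without
  # overlap, by rejection sampling
  k <- length(widths)
  for (try in seq_len(max_tries)) {
    st <- stats::runif(k, lo, hi - widths)
    en <- st + widths
    ord <- order(st)
    if (all(st[ord][-1] >= en[ord][-k])) return(cbind(st, en))
  }
  NULL
}

#' Shuffled null for the interpeak-distance distribution
#'
#' Each peak is re-placed uniformly at random (width preserved, no overlap)
#' within its assigned region, `n_shuffles` times; the interpeak-distance
#' set and its smoothed density are recomputed for every shuffle, giving a
#' pointwise null mean and central 95% band over the distance grid.
#'
#' @param peaks Peak data frame with `start`/`end`.
#' @param regions Per-peak regions as from [cluster_regions()].
#' @param replicon_length Circular replicon length in bases.
#' @param n_shuffles Number of shuffles (default 200).
#' @param grid Distance grid for the density (default 0 to 10 kb in 100 bp
#'   steps).
#' @param seed Integer seed.
#' Densities are evaluated on the bounded `grid`: distances beyond its range
#' (typically the large gaps between peak clusters) are excluded before
#' smoothing, so the bandwidth adapts to the kilobase-scale structure of
#' interest rather than to multi-10-kb inter-cluster spacing.
#'
#' @return List of class \code{"interpeak_null"}: `observed_distances`,
#'   `observed_density`, `grid`, `null_mean`, `band_lo`, `band_hi`,
#'   `null_distances` (list), `n_shuffles`, `seed`.
#' @export
shuffle_null <- function(peaks, regions, replicon_length, n_shuffles = 200,
                         grid = seq(0, 10000, by = 100), seed = 1) {
  stopifnot(nrow(peaks) == nrow(regions), n_shuffles >= 1)
  widths <- peaks$end - peaks$start
  for (r in unique(regions$region_id)) {
    sel <- regions$region_id == r
    room <- (regions$end[sel][1] - regions$start[sel][1]) - sum(widths[sel])
    if (room <= 0) {
      stop("region ", r, " is too small to fit its peaks (needs ",
           sum(widths[sel]) - (regions$end[sel][1] - regions$start[sel][1]),
           " more bases)")
    }
  }
  grid_density <- function(d) {
    smooth_density(d[d >= min(grid) & d <= max(grid)], grid)
  }
  obs_d <- interpeak_distances(peaks, replicon_length)
  obs_dens <- grid_density(obs_d)
  with_seed(seed, {
    null_d <- vector("list", n_shuffles)
    dens <- matrix(NA_real_, n_shuffles, length(grid))
    for (b in seq_len(n_shuffles)) {
      sh <- peaks
      for (r in unique(regions$region_id)) {
        sel <- which(regions$region_id == r)
        pl <- place_without_overlap(widths[sel], regions$start[sel][1],
                                    regions$end[sel][1])
        if (is.null(pl)) stop("could not place peaks in region ", r,
                              " without overlap after 1000 tries")
        sh$start[sel] <- pl[, 1]
        sh$end[sel] <- pl[, 2]
      }
      null_d[[b]] <- interpeak_distances(sh, replicon_length)
      dens[b, ] <- grid_density(null_d[[b]])
    }
    structure(list(observed_distances = obs_d, observed_density = obs_dens,
                   grid = grid, null_mean = colMeans(dens),
                   band_lo = apply(dens, 2, stats::quantile, 0.025),
                   band_hi = apply(dens, 2, stats::quantile, 0.975),
                   null_distances = null_d, n_shuffles = n_shuffles,
                   seed = seed),
              class = "interpeak_null")
  })
}

#' @export
print.interpeak_null <- function(x, ...) {
  cat(sprintf("<interpeak_null> %d observed distances, %d shuffles\n",
              length(x$observed_distances), x$n_shuffles))
  invisible(x)
}

#' Gaussian kernel density over a fixed grid
#'
#' Plain Gaussian KDE evaluated on `grid`, with Scott's-rule bandwidth
#' (`sd(x) * n^(-1/5)`) by default.  Densities integrate to 1 over the real
#' line; choose a grid wide enough to cover the support.
#'
#' @param x Numeric observations.
#' @param grid Evaluation grid.
#' @param bandwidth Kernel SD; default Scott's rule.
#' @return Numeric density values over `grid`.
#' @export
smooth_density <- function(x, grid, bandwidth = NULL) {
  if (length(x) == 0) return(rep(0, length(grid)))
  if (is.null(bandwidth)) {
    s <- stats::sd(x)
    if (length(x) < 2 || !is.finite(s) || s == 0) s <- max(abs(x), 1)
    bandwidth <- s * length(x)^(-1 / 5)
  }
  vapply(grid, function(g) mean(stats::dnorm(g, mean = x, sd = bandwidth)),
         numeric(1))
}
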