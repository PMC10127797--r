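# Peak calling on knockout-subtracted occupancy, cross-condition consensus
# sites, and the count/proportion tests used to compare genotypes.

#' Call occupancy peaks on a scar-subtracted track
#'
#' Finds maximal runs of bins at or above `threshold`, bridges gaps of up to
#' `merge_gap` bases between runs, and drops runs narrower than `min_width`.
#' Coordinates are 0-based half-open in bases.
#'
#' @param track An [occupancy_track()] at stage \code{"scar_subtracted"}.
#' @param threshold Calling threshold in robust-z units (default 4).  Values
#'   <= 0 are permitted but flagged with a warning, since the statistic is
#'   centred near zero genome-wide.
#' @param min_width Minimum peak width in bases (default 2 bins).
#' @param merge_gap Maximum sub-threshold gap to bridge, in bases (default
#'   4 bins).
#' @return Data frame with columns replicon, start, end, summit (bin index of
#'   the maximum, 1-based), summit_pos (base of bin centre), score (maximum
#'   occupancy), sorted by coordinate.
#' @export
call_peaks <- function(track, threshold = 4, min_width = 2 * track$bin_size,
                       merge_gap = 4 * track$bin_size) {
  stopifnot(inherits(track, "occupancy_track"))
  if (track$stage != "scar_subtracted") {
    stop("call_peaks() expects a scar_subtracted track, got stage '",
         track$stage, "'")
  }
  if (threshold <= 0) {
    warning("call_peaks() threshold <= 0: the occupancy statistic is ",
            "centred near zero, so most of the genome will be called")
  }
  bs <- track$bin_size
  above <- track$values >= threshold
  empty <- data.frame(replicon = character(0), start = integer(0),
                      end = integer(0), summit = integer(0),
                      summit_pos = numeric(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # bridge gaps <= merge_gap bases
  gap_bins <- floor(merge_gap / bs)
  if (nrow(runs) > 1) {
    keep <- rep(TRUE, nrow(runs))
    for (i in 2:nrow(runs)) {
      j <- max(which(keep[1:(i - 1)]))
      if (runs$start[i] - runs$end[j] - 1 <= gap_bins) {
        runs$end[j] <- runs$end[i]
        keep[i] <- FALSE
      }
    }
    runs <- runs[keep, ]
  }
  width_ok <- (runs$end - runs$start + 1) * bs >= min_width
  runs <- runs[width_ok, ]
  if (nrow(runs) == 0) return(empty)
  summit <- mapply(function(a, b) a + which.max(track$values[a:b]) - 1L,
                   runs$start, runs$end)
  data.frame(replicon = track$replicon,
             start = as.integer((runs$start - 1) * bs),
             end = as.integer(runs$end * bs),
             summit = as.integer(summit),
             summit_pos = (summit - 0.5) * bs,
             score = mapply(function(a, b) max(track$values[a:b]),
                            runs$start, runs$end),
             stringsAsFactors = FALSE)
}

merge_intervals <- function(df) {
  if (nrow(df) == 0) return(df[, c("start", "end")])
  df <- df[order(df$start, df$end), ]
  out_s <- df$start[1]; out_e <- df$end[1]
  res_s <- integer(0); res_e <- integer(0)
  if (nrow(df) > 1) {
    for (i in 2:nrow(df)) {
      if (df$start[i] < out_e) {        # overlap (half-open: touching != overlap)
        out_e <- max(out_e, df$end[i])
      } else {
        res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
        out_s <- df$start[i]; out_e <- df$end[i]
      }
    }
  }
  data.frame(start = c(res_s, out_s), end = c(res_e, out_e))
}

#' Build consensus sites and the sites-by-samples occupancy matrix
#'
#' Takes per-sample peak lists, merges the union of all intervals (gap 0)
#' into disjoint consensus sites — every site was significant in at least one
#' sample — and, when tracks are supplied, fills a matrix of each sample's
#' mean scar-subtracted occupancy over each site.
#'
#' @param peak_sets Named list of peak data frames (as from [call_peaks()]).
#' @param tracks Optional named list of scar-subtracted
#'   [occupancy_track()]s, parallel to `peak_sets` (or any samples to
#'   quantify over the sites).
#' @return List with `sites` (data frame: site_id, start, end, plus one
#'   logical membership column per peak set) and `matrix` (sites x samples,
#'   `NULL` when no tracks are given).
#' @export
consensus_union <- function(peak_sets, tracks = NULL) {
  stopifnot(is.list(peak_sets), length(peak_sets) >= 1)
  if (is.null(names(peak_sets))) {
    names(peak_sets) <- paste0("sample", seq_along(peak_sets))
  }
  all_peaks <- do.call(rbind, lapply(peak_sets, function(p) {
    p[, c("start", "end"), drop = FALSE]
  }))
  if (is.null(all_peaks) || nrow(all_peaks) == 0) {
    sites <- data.frame(site_id = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
    return(list(sites = sites, matrix = NULL))
  }
  merged <- merge_intervals(all_peaks)
  sites <- data.frame(site_id = sprintf("site%04d", seq_len(nrow(merged))),
                      start = as.integer(merged$start),
                      end = as.integer(merged$end), stringsAsFactors = FALSE)
  for (nm in names(peak_sets)) {
    p <- peak_sets[[nm]]
    hit <- vapply(seq_len(nrow(sites)), function(i) {
      any(p$start < sites$end[i] & p$end > sites$start[i])
    }, logical(1))
    sites[[paste0("in_", nm)]] <- hit
  }
  mat <- NULL
  if (!is.null(tracks)) {
    mat <- vapply(tracks, function(tr) {
      bs <- tr$bin_size
      vapply(seq_len(nrow(sites)), function(i) {
        b0 <- floor(sites$start[i] / bs) + 1
        b1 <- ceiling(sites$end[i] / bs)
        mean(tr$values[b0:b1])
      }, numeric(1))
    }, numeric(nrow(sites)))
    if (nrow(sites) == 1) mat <- matrix(mat, nrow = 1,
                                        dimnames = list(NULL, names(tracks)))
    rownames(mat) <- sites$site_id
  }
  list(sites = sites, matrix = mat)
}

reciprocal_overlap <- function(a_start, a_end, b_start, b_end) {
  ov <- pmin(a_end, b_end) - pmax(a_start, b_start)
  ov <- pmax(ov, 0)
  pmin(ov / (a_end - a_start), ov / (b_end - b_start))
}

#' Peaks in one set absent from another
#'
#' Returns the peaks of `set_a` that have less than `min_overlap` reciprocal
#' overlap with every peak of `set_b` — e.g. the binding sites unique to a
#' mutant genotype relative to wild type.
#'
#' @param set_a,set_b Peak data frames with `start`/`end` columns.
#' @param min_overlap Reciprocal overlap fraction (of both peak widths)
#'   below which a peak counts as novel.  Default 0.25.
#' @return The novel subset of `set_a`.
#' @export
novel_peaks <- function(set_a, set_b, min_overlap = 0.25) {
  if (nrow(set_a) == 0 || nrow(set_b) == 0) return(set_a)
  novel <- vapply(seq_len(nrow(set_a)), function(i) {
    ro <- reciprocal_overlap(set_a$start[i], set_a$end[i],
                             set_b$start, set_b$end)
    all(ro < min_overlap)
  }, logical(1))
  set_a[novel, , drop = FALSE]
}

#' Exact Poisson rate-equality test for two peak counts
#'
#' Two-sided exact conditional test that two counts arise at equal rates
#' (equal exposure): conditional on the total, the first count is binomial
#' with p = 1/2.  Delegates to [stats::poisson.test()].
#'
#' @param n1,n2 Non-negative integer counts.
#' @return The two-sided p-value.
#' @export
poisson_rate_test <- function(n1, n2) {
  stopifnot(n1 >= 0, n2 >= 0, n1 + n2 > 0)
  unname(stats::poisson.test(c(n1, n2))$p.value)
}

#' Two-sample equality-of-proportions test
#'
#' Chi-square test with continuity correction on the 2x2 table, as in
#' [stats::prop.test()] — used to compare e.g. the fraction of peaks at
#' promoters between genotypes.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return The two-sided p-value.
#' @export
proportion_test <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("both sample sizes must be positive")
  stopifnot(x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2)
  unname(suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), correct = TRUE)$p.value))
}
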