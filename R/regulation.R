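# Connecting binding to transcription: TSS overlap and permutation
# enrichment, TU-level RNAP occupancy changes, direct-target calling, the
# leucine-modulation score, classification into the six regulation modes,
# TSS-centred pileup matrices, and heat-map clustering.

#' Map peaks to overlapped transcription start sites
#'
#' A peak overlaps a TSS when the TSS position falls inside the peak's
#' half-open interval `[start, end)`.  A peak may hit several TSSs and a TSS
#' several peaks.
#'
#' @param peaks Peak data frame with `start`/`end` columns.
#' @param tss_set Data frame with `position` and `tu_id` columns.
#' @return List with `pairs` (data frame: peak row index, tu_id, position),
#'   `fraction` (share of peaks hitting >= 1 TSS), and `n_peaks`.
#' @export
overlap_tss <- function(peaks, tss_set) {
  if (nrow(peaks) == 0) {
    return(list(pairs = data.frame(peak = integer(0), tu_id = character(0),
                                   position = integer(0)),
                fraction = NA_real_, n_peaks = 0L))
  }
  pairs <- do.call(rbind, lapply(seq_len(nrow(peaks)), function(i) {
    hit <- which(tss_set$position >= peaks$start[i] &
                   tss_set$position < peaks$end[i])
    if (length(hit) == 0) return(NULL)
    data.frame(peak = i, tu_id = tss_set$tu_id[hit],
               position = tss_set$position[hit], stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) {
    pairs <- data.frame(peak = integer(0), tu_id = character(0),
                        position = integer(0))
  }
  list(pairs = pairs,
       fraction = length(unique(pairs$peak)) / nrow(peaks),
       n_peaks = nrow(peaks))
}

# fraction of peaks (given widths and random starts) covering >= 1 TSS on a
# circular replicon; ts must be sorted
overlap_fraction_circ <- function(starts, widths, ts, L) {
  s <- starts %% L
  e <- s + widths
  k <- integer(length(s))
  nw <- e <= L
  k[nw] <- findInterval(e[nw] - 1e-9, ts) - findInterval(s[nw] - 1e-9, ts)
  if (any(!nw)) {  # peaks wrapping the origin
    k[!nw] <- (length(ts) - findInterval(s[!nw] - 1e-9, ts)) +
      findInterval(e[!nw] - L - 1e-9, ts)
  }
  mean(k > 0)
}

#' Permutation test for TSS enrichment of peaks
#'
#' Observed statistic: fraction of peaks overlapping at least one TSS.  Null:
#' each peak is re-placed uniformly at random on the circular replicon (width
#' preserved), and the fraction recomputed; the p-value is
#' `(1 + #[null >= observed]) / (1 + n_perm)`.
#'
#' @param peaks Peak data frame with `start`/`end`.
#' @param tss_set Data frame with `position`.
#' @param replicon_length Circular replicon length in bases.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List: `observed`, `null` (vector of null fractions), `p`.
#' @export
tss_enrichment <- function(peaks, tss_set, replicon_length, n_perm = 999,
                           seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (nrow(peaks) == 0) stop("no peaks supplied")
  ts <- sort(tss_set$position)
  widths <- peaks$end - peaks$start
  if (length(ts) == 0) {
    return(list(observed = 0, null = rep(0, n_perm), p = 1))
  }
  obs <- overlap_fraction_circ(peaks$start, widths, ts, replicon_length)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      st <- floor(stats::runif(length(widths), 0, replicon_length))
      overlap_fraction_circ(st, widths, ts, replicon_length)
    }, numeric(1))
  })
  list(observed = obs, null = null,
       p = (1 + sum(null >= obs)) / (1 + n_perm))
}

#' TU-level regulator-dependent RNAP log2 fold change
#'
#' For one transcription unit: the mean over TU-body bins of the RNAP
#' log2(ChIP/input) statistic in the regulator-carrying genotype minus the
#' same quantity in the scar knockout, i.e. the regulator-dependent log2
#' fold change in RNAP occupancy.  With replicate track pairs the standard
#' error across replicate differences is reported.
#'
#' @param geno_tracks,scar_tracks Lists of log_ratio-stage
#'   [occupancy_track()]s (RNAP), one per replicate.  Replicates are paired
#'   by position when of equal number, otherwise all genotype-vs-scar means
#'   are contrasted.
#' @param tu One row of a TU annotation (needs `start`, `end`).
#' @return List: `log2fc`, `se`, `per_replicate` (genotype replicate means
#'   minus mean scar signal).
#' @export
tu_log2fc <- function(geno_tracks, scar_tracks, tu) {
  tu_mean <- function(tr) {
    b0 <- floor(tu$start / tr$bin_size) + 1
    b1 <- ceiling(tu$end / tr$bin_size)
    mean(tr$values[b0:b1])
  }
  gm <- vapply(geno_tracks, tu_mean, numeric(1))
  sm <- vapply(scar_tracks, tu_mean, numeric(1))
  per_rep <- gm - mean(sm)
  se <- if (length(per_rep) > 1) {
    stats::sd(per_rep) / sqrt(length(per_rep))
  } else NA_real_
  list(log2fc = mean(gm) - mean(sm), se = se, per_replicate = per_rep)
}

#' Permutation significance for TU-level differences, with BH adjustment
#'
#' For each TU, the observed statistic is the studentized difference in mean
#' per-replicate TU signal between genotype and scar replicates (a Welch
#' t-statistic).  Replicate labels are shuffled between the two groups
#' `n_perm` times, and — because every TU shares the same noise structure —
#' the null statistics are pooled across TUs before comparison, so that with
#' small replicate numbers the attainable p-values are much finer than the
#' `1 / choose(n1 + n2, n1)` floor of a per-TU permutation:
#' `p = (1 + #[|pooled null| >= |obs|]) / (1 + n_perm * n_TU)`.
#' Benjamini-Hochberg adjustment across TUs follows.
#'
#' @param geno_mat,scar_mat Matrices of per-replicate TU statistics, TUs in
#'   rows, replicates in columns.
#' @param n_perm Number of label shuffles (default 200; the pooled null has
#'   `n_perm * n_TU` draws).
#' @param seed Integer seed.
#' @return Data frame: `stat` (mean difference), `t` (studentized), `p`, `q`
#'   per TU.
#' @export
diff_significance <- function(geno_mat, scar_mat, n_perm = 200, seed = 1) {
  stopifnot(is.matrix(geno_mat), is.matrix(scar_mat),
            nrow(geno_mat) == nrow(scar_mat))
  n1 <- ncol(geno_mat); n2 <- ncol(scar_mat)
  stopifnot(n1 >= 2, n2 >= 2)
  all_mat <- cbind(geno_mat, scar_mat)
  welch_t <- function(a, b) {
    se2 <- apply(a, 1, stats::var) / ncol(a) +
      apply(b, 1, stats::var) / ncol(b)
    d <- rowMeans(a) - rowMeans(b)
    t <- d / sqrt(se2)
    t[se2 == 0] <- 0  # constant rows carry no evidence
    t
  }
  obs_d <- rowMeans(geno_mat) - rowMeans(scar_mat)
  obs_t <- welch_t(geno_mat, scar_mat)
  null_t <- with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(b) {
      idx <- sample.int(n1 + n2, n1)
      welch_t(all_mat[, idx, drop = FALSE], all_mat[, -idx, drop = FALSE])
    }))
  })
  null_abs <- sort(abs(null_t))
  n_null <- length(null_abs)
  exceed <- n_null - findInterval(abs(obs_t) - 1e-12, null_abs)
  p <- (1 + exceed) / (1 + n_null)
  data.frame(stat = obs_d, t = obs_t, p = p,
             q = stats::p.adjust(p, method = "BH"))
}

#' Call direct regulatory targets
#'
#' A TU is a direct target when its TSS is overlapped by a regulator peak
#' and its RNAP occupancy changes significantly (q <= `q_cut`) in a
#' regulator-dependent manner under at least one condition.
#'
#' @param bound_tus Character vector of TU ids whose TSS lies in a peak
#'   (union over conditions).
#' @param change_tables Named list (one per condition) of data frames with
#'   `tu_id` and `q` columns.
#' @param q_cut Significance cutoff on BH-adjusted q (default 0.05).
#' @return Character vector of direct-target TU ids.
#' @export
call_direct_targets <- function(bound_tus, change_tables, q_cut = 0.05) {
  sig <- unique(unlist(lapply(change_tables, function(tb) {
    tb$tu_id[tb$q <= q_cut]
  })))
  intersect(bound_tus, sig)
}

#' Leucine-modulation score
#'
#' `(log2fc_LIV - log2fc_Min) * sign(log2fc_Min)`: the change in the
#' regulator-dependent RNAP effect induced by adding leucine, signed so that
#' positive values mean leucine strengthens the regulator's effect and
#' negative values mean it weakens it.
#'
#' @param change_min,change_liv Regulator-dependent log2 fold changes in the
#'   two media (vectorised).
#' @return Numeric score(s).
#' @export
leucine_modulation_score <- function(change_min, change_liv) {
  (change_liv - change_min) * sign(change_min)
}

#' Classify a TU into one of the six regulation modes
#'
#' The regulator can activate or repress (sign of the significant RNAP
#' effect, minimal medium taking precedence), and leucine can leave the
#' effect unchanged (independent), strengthen it (concerted), or weaken it
#' (reciprocal).  The leucine axis is decided from the change in effect
#' magnitude between media using a normal z-test on
#' `|log2fc_LIV| - |log2fc_Min|` at level `alpha`, with loss of TSS binding
#' or loss of significance in LIV also counting as reciprocal (and the
#' mirror case as concerted).  TUs that are not direct targets (no
#' significant effect while bound under any condition) are `unclassified`.
#'
#' @param bound_min,bound_liv Logical: peak overlapping the TSS in each
#'   medium.
#' @param fc_min,fc_liv Regulator-dependent log2 fold changes.
#' @param se_min,se_liv Standard errors of the fold changes.
#' @param q_min,q_liv Adjusted significance of the fold changes.
#' @param q_cut Significance cutoff (default 0.05).
#' @param alpha Level for the effect-magnitude difference test (default
#'   0.05).
#' @return A list of class \code{"regulation_call"}: `mode`, `direction`,
#'   `leucine_axis`, `bound_min`, `bound_liv`.
#' @export
classify_mode <- function(bound_min, bound_liv, fc_min, fc_liv,
                          se_min, se_liv, q_min, q_liv,
                          q_cut = 0.05, alpha = 0.05) {
  sig_min <- isTRUE(bound_min) && q_min <= q_cut
  sig_liv <- isTRUE(bound_liv) && q_liv <= q_cut
  make <- function(mode, direction = NA_character_,
                   axis = NA_character_) {
    structure(list(mode = mode, direction = direction, leucine_axis = axis,
                   bound_min = bound_min, bound_liv = bound_liv),
              class = "regulation_call")
  }
  if (!sig_min && !sig_liv) return(make("unclassified"))
  direction <- if (sig_min) {
    if (fc_min > 0) "activating" else "repressing"
  } else {
    if (fc_liv > 0) "activating" else "repressing"
  }
  axis <- if (sig_min && !sig_liv) {
    "reciprocal"        # effect (or binding) lost upon leucine addition
  } else if (!sig_min && sig_liv) {
    "concerted"         # effect appears only with leucine
  } else {
    d <- abs(fc_liv) - abs(fc_min)
    se_d <- sqrt(se_min^2 + se_liv^2)
    z <- if (se_d > 0) d / se_d else sign(d) * Inf
    zc <- stats::qnorm(1 - alpha / 2)
    if (z <= -zc) "reciprocal" else if (z >= zc) "concerted" else "independent"
  }
  make(paste(axis, direction, sep = "_"), direction, axis)
}

#' @export
print.regulation_call <- function(x, ...) {
  cat("<regulation_call>", x$mode, "\n")
  invisible(x)
}

#' TSS-centred occupancy pileup matrix
#'
#' One row per TSS: the track values within `half_width` bases of the TSS,
#' at bin resolution, with minus-strand rows reversed so that transcription
#' always proceeds towards positive offsets.  Windows wrap circularly.
#'
#' @param track An [occupancy_track()].
#' @param tss_set Data frame with `position`, `strand` (and optionally
#'   `tu_id` used for row names).
#' @param half_width Window half-width in bases (default 1000).
#' @return Matrix TSS x offset; column names are offsets in bases.
#' @export
tss_pileup <- function(track, tss_set, half_width = 1000) {
  bs <- track$bin_size
  n <- length(track$values)
  hw <- floor(half_width / bs)
  offs <- (-hw):hw
  mat <- t(vapply(seq_len(nrow(tss_set)), function(i) {
    cb <- floor(tss_set$position[i] / bs) + 1
    idx <- ((cb + offs - 1) %% n) + 1
    row <- track$values[idx]
    if (tss_set$strand[i] == "-") row <- rev(row)
    row
  }, numeric(length(offs))))
  colnames(mat) <- offs * bs
  if (!is.null(tss_set$tu_id)) rownames(mat) <- tss_set$tu_id
  mat
}

#' Hierarchical clustering order for heat-map axes
#'
#' Agglomerative clustering with Euclidean distance and average linkage,
#' as used to order the rows and columns of occupancy heat maps.
#'
#' @param mat Numeric matrix.
#' @param axis `"rows"` or `"cols"`.
#' @return List: `order` (leaf order, indices into the chosen axis) and
#'   `tree` (the [stats::hclust()] object).
#' @export
cluster_order <- function(mat, axis = c("rows", "cols")) {
  axis <- match.arg(axis)
  x <- if (axis == "cols") t(mat) else mat
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "average")
  list(order = hc$order, tree = hc)
}
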