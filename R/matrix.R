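#' Row-normalise a sites-by-samples occupancy matrix
#'
#' Divides each row by its maximum, so every row maxes at 1 — the
#' normalisation used for cross-condition occupancy heat maps.  Rows whose
#' maximum is not positive carry no interpretable occupancy; dividing by a
#' zero or negative maximum would flip signs, so such rows are set to zero
#' and flagged in the \code{"flagged_rows"} attribute.
#'
#' @param mat Numeric matrix, sites in rows and samples in columns.
#' @return The normalised matrix, with an integer attribute
#'   \code{"flagged_rows"} listing rows whose max was <= 0.
#' @export
row_normalize <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  mx <- apply(mat, 1, max)
  bad <- which(mx <= 0)
  scl <- ifelse(mx > 0, mx, 1)
  out <- mat / scl
  if (length(bad)) out[bad, ] <- 0
  attr(out, "flagged_rows") <- bad
  out
}

#' Pairwise Spearman correlation between samples
#'
#' Rank correlation of occupancy profiles between every pair of samples
#' (columns), used to quantify how similar binding landscapes are across
#' genotypes and media.  Being rank-based it is invariant to any strictly
#' monotone per-sample transform.
#'
#' @param mat Numeric matrix, sites in rows and samples in columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
condition_correlation <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  stats::cor(mat, method = "spearman")
}

#' Paired Wilcoxon signed-rank test on per-site occupancy
#'
#' Tests whether occupancy differs systematically between two conditions
#' measured at the same sites.  Exact two-sided p-value when 25 or fewer
#' non-zero paired differences are present (and no ties in their absolute
#' values); otherwise the normal approximation with continuity correction.
#'
#' @param occ_a,occ_b Numeric vectors of equal length, paired by site.
#' @return The two-sided p-value.
#' @export
paired_occupancy_test <- function(occ_a, occ_b) {
  stopifnot(length(occ_a) == length(occ_b), length(occ_a) >= 1)
  d <- occ_a - occ_b
  d <- d[d != 0]
  if (length(d) == 0) return(1)  # identical vectors: no evidence of difference
  use_exact <- length(d) <= 25 && !anyDuplicated(abs(d))
  res <- stats::wilcox.test(d, exact = use_exact, correct = TRUE)
  unname(res$p.value)
}
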