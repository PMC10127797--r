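# Bayesian hierarchical models for the quantification data: Western-blot
# densitometry (protein levels with posterior difference probabilities),
# ChIP-qPCR enrichment (with Savage-Dickey log10 Bayes-factor tiers), and
# delta-delta-Cq expression effects.  All models share one likelihood
# family: normal on log-scale responses, cell means with weakly-informative
# zero-centred normal priors (scale 2.5 x data SD), an optional lineage
# random intercept, and a uniform prior on the residual SD.  Sampling is by
# Gibbs/Metropolis via JAGS; summaries are deterministic given the seed.

#' MCMC settings
#'
#' @param n_chains Number of chains (default 4).
#' @param n_iter Post-warm-up draws per chain (default 2000).
#' @param n_adapt Adaptation iterations (default 500).
#' @param n_burn Burn-in iterations (default 500).
#' @param seed Integer seed; chain c uses seed + c.
#' @return A list of class \code{"mcmc_config"}.
#' @export
mcmc_config <- function(n_chains = 4, n_iter = 2000, n_adapt = 500,
                        n_burn = 500, seed = 1) {
  stopifnot(n_chains >= 1, n_iter >= 100)
  structure(list(n_chains = n_chains, n_iter = n_iter, n_adapt = n_adapt,
                 n_burn = n_burn, seed = as.integer(seed)),
            class = "mcmc_config")
}

jags_cellmeans_model <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(mu[cell[i]] + b[lineage[i]], tau_res)
  }
  for (j in 1:J) { mu[j] ~ dnorm(0, prec_mu) }
  for (l in 1:K) { b[l] ~ dnorm(0, tau_lin) }
  tau_res <- pow(sigma_res, -2)
  sigma_res ~ dunif(sigma_lower, sigma_upper)
  tau_lin <- pow(sigma_lin, -2)
  sigma_lin ~ dunif(0, sigma_lin_upper)
}"

jags_cellmeans_model_nolineage <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(mu[cell[i]], tau_res)
  }
  for (j in 1:J) { mu[j] ~ dnorm(0, prec_mu) }
  tau_res <- pow(sigma_res, -2)
  sigma_res ~ dunif(sigma_lower, sigma_upper)
}"

split_rhat <- function(draws_by_chain) {
  # split-R-hat over a list of per-chain vectors
  halves <- unlist(lapply(draws_by_chain, function(x) {
    n <- floor(length(x) / 2)
    list(x[1:n], x[(n + 1):(2 * n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Fit the shared cell-means model.  y: response; cell: factor of cell ids;
# lineage: factor (collapsed to no random effect when < 2 levels).
# Returns draws matrix (iterations x cells), prior SD, convergence info.
fit_cell_means <- function(y, cell, lineage = NULL, mcmc = mcmc_config()) {
  stopifnot(length(y) == length(cell))
  cell <- factor(cell)
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y < 0.05) sd_y <- 0.05  # degenerate-data floor
  prior_sd <- 2.5 * max(sd_y, stats::sd(tapply(y, cell, mean)), na.rm = TRUE)
  use_lineage <- !is.null(lineage) && length(unique(lineage)) > 1
  # positive floor on the residual SD keeps the likelihood finite when the
  # data are exactly replicated (degenerate noiseless tables)
  data <- list(y = y, cell = as.integer(cell), N = length(y),
               J = nlevels(cell), prec_mu = 1 / prior_sd^2,
               sigma_lower = 0.005 * sd_y, sigma_upper = 5 * sd_y)
  model_str <- jags_cellmeans_model_nolineage
  if (use_lineage) {
    lineage <- factor(lineage)
    data$lineage <- as.integer(lineage)
    data$K <- nlevels(lineage)
    data$sigma_lin_upper <- 2.5 * sd_y
    model_str <- jags_cellmeans_model
  }
  inits <- lapply(seq_len(mcmc$n_chains), function(c) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = mcmc$seed + c)
  })
  jm <- rjags::jags.model(textConnection(model_str), data = data,
                          inits = inits, n.chains = mcmc$n_chains,
                          n.adapt = mcmc$n_adapt, quiet = TRUE)
  stats::update(jm, mcmc$n_burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, "mu", n.iter = mcmc$n_iter,
                              progress.bar = "none")
  draws <- do.call(rbind, lapply(samp, as.matrix))
  colnames(draws) <- levels(cell)
  rhat <- vapply(seq_len(ncol(draws)), function(j) {
    split_rhat(lapply(samp, function(ch) as.matrix(ch)[, j]))
  }, numeric(1))
  list(draws = draws, prior_sd = prior_sd, rhat = max(rhat),
       converged = max(rhat) <= 1.01, cells = levels(cell))
}

posterior_summary_row <- function(d, ref = NULL, prior_sd = NA,
                                  n_draws = length(d), seed = NA) {
  ci <- unname(stats::quantile(d, c(0.025, 0.975)))
  out <- data.frame(value = mean(d), ci.lo = ci[1], ci.hi = ci[2],
                    n_draws = n_draws, seed = seed)
  if (!is.null(ref)) {
    p_hi <- mean(d > ref)
    out$P_diff <- max(p_hi, 1 - p_hi)
    out$direction <- if (p_hi >= 0.5) "higher" else "lower"
  }
  out
}

#' Bayesian model for Western-blot protein levels
#'
#' Fits a hierarchical normal model to log density ratios
#' (`log(lrp_density / total_density)`): one mean per strain-by-medium-by-
#' phase cell, a random intercept per lineage, and residual noise across
#' biological replicates.  Reports, per cell, the posterior mean and 95%
#' credible interval of the relative protein level (linear scale, wild type
#' in the same medium and phase = 1) and `P_diff`, the posterior probability
#' of a difference versus wild type in the observed direction.
#'
#' @param table Data frame with columns strain, medium, phase, lineage,
#'   biorep, lrp_density, total_density (scar rows must be absent — the
#'   knockout has no band to quantify).
#' @param mcmc An [mcmc_config()].
#' @param reference Reference strain (default "WT").
#' @return Data frame of class \code{"posterior_summary"}: strain, medium,
#'   phase, value, ci.lo, ci.hi, P_diff, direction, n_draws, seed, plus
#'   attributes `rhat`, `converged`, `prior_sd`.
#' @export
fit_western_model <- function(table, mcmc = mcmc_config(),
                              reference = "WT") {
  req <- c("strain", "medium", "phase", "lineage", "biorep",
           "lrp_density", "total_density")
  stopifnot(all(req %in% names(table)))
  if (any(table$strain == "scar")) {
    stop("the scar knockout must be excluded from the Western model ",
         "(it has no regulator band)")
  }
  if (any(table$lrp_density <= 0) || any(table$total_density <= 0)) {
    stop("non-positive pixel densities cannot be log-transformed")
  }
  y <- log(table$lrp_density / table$total_density)
  cell <- interaction(table$strain, table$medium, table$phase, drop = TRUE,
                      sep = ":")
  lineage <- interaction(table$strain, table$lineage, drop = TRUE)
  fit <- fit_cell_means(y, cell, lineage, mcmc)
  cells <- strsplit(fit$cells, ":")
  out <- do.call(rbind, lapply(seq_along(fit$cells), function(j) {
    parts <- cells[[j]]
    ref_cell <- paste(reference, parts[2], parts[3], sep = ":")
    d <- fit$draws[, j]
    has_ref <- ref_cell %in% colnames(fit$draws) && parts[1] != reference
    # contrast on the log scale, reported as a linear-scale level vs WT
    dd <- if (has_ref) d - fit$draws[, ref_cell] else d * 0
    row <- posterior_summary_row(exp(dd), ref = if (has_ref) NULL else NULL,
                                 prior_sd = fit$prior_sd,
                                 n_draws = nrow(fit$draws), seed = mcmc$seed)
    if (has_ref) {
      p_hi <- mean(dd > 0)
      row$P_diff <- max(p_hi, 1 - p_hi)
      row$direction <- if (p_hi >= 0.5) "higher" else "lower"
    } else {
      row$P_diff <- NA_real_
      row$direction <- NA_character_
    }
    cbind(data.frame(strain = parts[1], medium = parts[2], phase = parts[3],
                     stringsAsFactors = FALSE), row)
  }))
  rownames(out) <- NULL
  structure(out, rhat = fit$rhat, converged = fit$converged,
            prior_sd = fit$prior_sd, class = c("posterior_summary",
                                               "data.frame"))
}

#' Bayesian model for ChIP-qPCR enrichment
#'
#' Per strain and biological replicate, forms
#' `dCq = Cq(IP) - Cq(input)` for every amplicon and subtracts the mean dCq
#' of the two control amplicons, giving a per-replicate log2 enrichment
#' (`-ddCq`).  A cell-means model per strain-by-amplicon then yields the
#' posterior log2 fold enrichment, its 95% credible interval, a
#' Savage-Dickey log10 Bayes factor against zero enrichment with
#' significance tiers (`*` 0.5-1, `**` 1-2, `***` >2), and the posterior
#' probability of a difference versus the reference strain (`sig.vs.wt`).
#'
#' @param cq_table Data frame: strain, amplicon, fraction ("IP"/"input"),
#'   biorep, cq (as from [simulate_qpcr()]).
#' @param controls Character vector of exactly two control amplicon ids.
#' @param mcmc An [mcmc_config()].
#' @param reference Reference strain (default "WT").
#' @return Data frame of class \code{"posterior_summary"}: strain, amplicon,
#'   value, ci.lo, ci.hi, log10_bf, tier, sig.vs.wt, direction, n_draws,
#'   seed.
#' @export
fit_chip_qpcr_model <- function(cq_table, controls, mcmc = mcmc_config(),
                                reference = "WT") {
  stopifnot(length(controls) == 2)
  missing_ctrl <- setdiff(controls, cq_table$amplicon)
  if (length(missing_ctrl)) {
    stop("control amplicon(s) missing from table: ",
         paste(missing_ctrl, collapse = ", "))
  }
  # per strain x amplicon x biorep: dCq = Cq(IP) - Cq(input)
  wide <- merge(
    cq_table[cq_table$fraction == "IP",
             c("strain", "amplicon", "biorep", "cq")],
    cq_table[cq_table$fraction == "input",
             c("strain", "amplicon", "biorep", "cq")],
    by = c("strain", "amplicon", "biorep"), suffixes = c("_ip", "_in"))
  wide$dcq <- wide$cq_ip - wide$cq_in
  ctrl <- wide[wide$amplicon %in% controls, ]
  ctrl_mean <- stats::aggregate(dcq ~ strain + biorep, ctrl, mean)
  names(ctrl_mean)[3] <- "ctrl_dcq"
  tgt <- wide[!(wide$amplicon %in% controls), ]
  tgt <- merge(tgt, ctrl_mean, by = c("strain", "biorep"))
  tgt$log2_enrichment <- -(tgt$dcq - tgt$ctrl_dcq)
  cell <- interaction(tgt$strain, tgt$amplicon, drop = TRUE, sep = ":")
  fit <- fit_cell_means(tgt$log2_enrichment, cell, lineage = NULL, mcmc)
  cells <- strsplit(fit$cells, ":")
  out <- do.call(rbind, lapply(seq_along(fit$cells), function(j) {
    parts <- cells[[j]]
    d <- fit$draws[, j]
    row <- posterior_summary_row(d, n_draws = nrow(fit$draws),
                                 seed = mcmc$seed)
    row$log10_bf <- bayes_factor(d, prior_sd = fit$prior_sd)
    row$tier <- bf_tier(row$log10_bf)
    ref_cell <- paste(reference, parts[2], sep = ":")
    if (parts[1] != reference && ref_cell %in% colnames(fit$draws)) {
      dd <- d - fit$draws[, ref_cell]
      p_hi <- mean(dd > 0)
      row$sig.vs.wt <- max(p_hi, 1 - p_hi)
      row$direction <- if (p_hi >= 0.5) "higher" else "lower"
    } else {
      row$sig.vs.wt <- NA_real_
      row$direction <- NA_character_
    }
    cbind(data.frame(strain = parts[1], amplicon = parts[2],
                     stringsAsFactors = FALSE), row)
  }))
  rownames(out) <- NULL
  structure(out, rhat = fit$rhat, converged = fit$converged,
            prior_sd = fit$prior_sd,
            class = c("posterior_summary", "data.frame"))
}

#' Bayesian delta-delta-Cq model for qRT-PCR expression
#'
#' Per genotype and replicate, `dCq = Cq(gene) - mean(Cq(references))`; the
#' model contrasts each mutant against the reference strain, reporting the
#' posterior `ddCq` effect on the log2 scale with the sign convention that
#' positive values mean higher expression in the mutant than in the
#' reference strain.
#'
#' @param qrt_table Data frame: strain, transcript, is_reference, biorep, cq
#'   (as from [simulate_qrt()]).
#' @param reference_transcripts Transcript ids of the reference set; default
#'   the `is_reference` column.
#' @param mcmc An [mcmc_config()].
#' @param reference Reference strain (default "WT").
#' @return Data frame of class \code{"posterior_summary"}: strain, gene,
#'   value (log2 effect vs reference strain), ci.lo, ci.hi, P_diff,
#'   direction, log10_bf, tier, n_draws, seed.
#' @export
fit_ddcq_model <- function(qrt_table, reference_transcripts = NULL,
                           mcmc = mcmc_config(), reference = "WT") {
  if (is.null(reference_transcripts)) {
    stopifnot("is_reference" %in% names(qrt_table))
    reference_transcripts <- unique(qrt_table$transcript[qrt_table$is_reference])
  }
  stopifnot(length(reference_transcripts) >= 1)
  refs <- qrt_table[qrt_table$transcript %in% reference_transcripts, ]
  ref_mean <- stats::aggregate(cq ~ strain + biorep, refs, mean)
  names(ref_mean)[3] <- "ref_cq"
  tgt <- qrt_table[!(qrt_table$transcript %in% reference_transcripts), ]
  tgt <- merge(tgt, ref_mean, by = c("strain", "biorep"))
  tgt$dcq <- tgt$cq - tgt$ref_cq
  cell <- interaction(tgt$strain, tgt$transcript, drop = TRUE, sep = ":")
  fit <- fit_cell_means(tgt$dcq, cell, lineage = NULL, mcmc)
  cells <- strsplit(fit$cells, ":")
  genes <- unique(vapply(cells, `[`, character(1), 2))
  out <- do.call(rbind, lapply(seq_along(fit$cells), function(j) {
    parts <- cells[[j]]
    if (parts[1] == reference) return(NULL)
    ref_cell <- paste(reference, parts[2], sep = ":")
    if (!(ref_cell %in% colnames(fit$draws))) return(NULL)
    # ddCq: negated so positive = higher expression in the mutant
    dd <- -(fit$draws[, j] - fit$draws[, ref_cell])
    row <- posterior_summary_row(dd, n_draws = nrow(fit$draws),
                                 seed = mcmc$seed)
    p_hi <- mean(dd > 0)
    row$P_diff <- max(p_hi, 1 - p_hi)
    row$direction <- if (p_hi >= 0.5) "higher" else "lower"
    row$log10_bf <- bayes_factor(dd, prior_sd = sqrt(2) * fit$prior_sd)
    row$tier <- bf_tier(row$log10_bf)
    cbind(data.frame(strain = parts[1], gene = parts[2],
                     stringsAsFactors = FALSE), row)
  }))
  rownames(out) <- NULL
  structure(out, rhat = fit$rhat, converged = fit$converged,
            prior_sd = fit$prior_sd,
            class = c("posterior_summary", "data.frame"))
}

#' Savage-Dickey log10 Bayes factor against a zero effect
#'
#' For a parameter with a zero-centred normal prior, the Bayes factor for a
#' nonzero effect is the prior density at zero divided by the posterior
#' density at zero (Savage-Dickey density ratio).  The posterior density at
#' zero is estimated from MCMC draws by a Gaussian kernel density; when the
#' draws lie far from zero the kernel density underflows and the Bayes
#' factor is capped at `log10_cap`.
#'
#' @param draws Posterior draws of the effect.
#' @param prior_sd SD of the zero-centred normal prior on the effect.
#' @param log10_cap Cap on |log10 BF| (default 6).
#' @return log10 Bayes factor (positive favours a nonzero effect).
#' @export
bayes_factor <- function(draws, prior_sd, log10_cap = 6) {
  stopifnot(prior_sd > 0, length(draws) > 10)
  prior_at_0 <- stats::dnorm(0, 0, prior_sd)
  dens <- stats::density(draws, n = 512,
                         from = min(c(draws, 0)) - stats::sd(draws),
                         to = max(c(draws, 0)) + stats::sd(draws))
  post_at_0 <- stats::approx(dens$x, dens$y, xout = 0)$y
  if (is.na(post_at_0) || post_at_0 <= 0) return(log10_cap)
  lb <- log10(prior_at_0) - log10(post_at_0)
  max(min(lb, log10_cap), -log10_cap)
}

bf_tier <- function(log10_bf) {
  if (log10_bf > 2) "***"
  else if (log10_bf > 1) "**"
  else if (log10_bf >= 0.5) "*"
  else "n.s."
}
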