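# Synthetic-data generator.  Emulates the statistical structure of a paired
# regulator/RNAP ChIP-seq study on a circular bacterial chromosome: planted
# primary binding sites with satellite secondary sites at kilobase spacing,
# genotype-specific leucine responses, regulator-coupled RNAP occupancy shifts
# at target transcription units, and log-normal densitometry / Cq noise.
# Every output is tied to a ground-truth record so downstream stages can be
# validated by parameter recovery.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Default per-genotype binding parameters
#'
#' One row per genotype: `min_binding_scale` is the occupancy scale in
#' minimal medium relative to wild type; `liv_binding_scale` multiplies it in
#' leucine-supplemented medium (before the per-site leucine-class factor);
#' `extra_secondary_rate` is the expected number of genotype-specific
#' satellite sites per primary site; `leucine_sensitive` says whether the
#' per-site leucine class (abrogated / reduced) applies in LIV.
#'
#' Defaults encode the study design: wild-type binding is abolished or
#' reduced by leucine, L136R binds slightly more strongly and barely senses
#' leucine, D114E gains extra local secondary sites in minimal medium, the
#' dimer-only dC11 variant and the scar knockout do not bind at all.
#'
#' @return A data frame keyed by genotype.
#' @export
default_genotype_params <- function() {
  data.frame(
    genotype = c("WT", "D114E", "L136R", "dC11", "scar"),
    min_binding_scale = c(1.0, 1.1, 1.2, 0.0, 0.0),
    liv_binding_scale = c(1.0, 1.0, 0.9, 0.0, 0.0),
    extra_secondary_rate = c(0.0, 1.0, 0.1, 0.0, 0.0),
    leucine_sensitive = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic study
#'
#' @param genome_length Circular replicon length in bases.
#' @param n_tus Number of transcription units to annotate.
#' @param bin_size Track bin width in bases.
#' @param n_primary_sites Number of planted primary regulator sites.
#' @param secondary_site_rate Probability that a primary site carries a
#'   shared satellite site (present in every binding genotype).
#' @param secondary_spacing Length-2 vector: satellite offsets from the
#'   primary centre are drawn uniformly in this range (bases, random sign).
#' @param peak_width Nominal footprint of one site in bases; enrichment is a
#'   Gaussian bump with SD `peak_width / 4`.
#' @param snr Peak height over mean background, in units of the background
#'   mean, for a site at occupancy scale 1.
#' @param genotype_params Data frame as from [default_genotype_params()].
#' @param rnap_effect_size Magnitude (log2 units) of the regulator-dependent
#'   RNAP occupancy change planted at bound transcription units.
#' @param noise_sd Multiplicative log-scale noise on per-site enrichment and
#'   per-replicate measurements.  Setting 0 switches the generator into a
#'   fully deterministic noiseless limit (flat background).
#' @param background_mean,background_size Mean and negative-binomial size of
#'   per-bin background coverage.
#' @param tss_bound_fraction Fraction of primary sites planted exactly at a
#'   TSS (these TUs become true direct targets).
#' @param abrogated_fraction Fraction of sites whose binding is fully
#'   abolished (rather than reduced) in leucine for sensitive genotypes.
#' @param reduced_liv_scale Residual occupancy scale in LIV for sites of the
#'   "reduced" leucine class.
#' @param seed Integer master seed; identical configs and seeds give
#'   identical outputs.
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(genome_length = 1e6, n_tus = 200, bin_size = 25,
                       n_primary_sites = 50, secondary_site_rate = 0.4,
                       secondary_spacing = c(1200, 2000), peak_width = 400,
                       snr = 5, genotype_params = default_genotype_params(),
                       rnap_effect_size = 1.5, noise_sd = 0.15,
                       background_mean = 50, background_size = 50,
                       tss_bound_fraction = 0.4, abrogated_fraction = 0.5,
                       reduced_liv_scale = 0.3, seed = 1) {
  stopifnot(genome_length >= 10 * n_primary_sites * peak_width,
            secondary_spacing[1] < secondary_spacing[2],
            bin_size >= 1, peak_width >= bin_size,
            snr >= 0, noise_sd >= 0, background_mean > 0,
            genome_length %% bin_size == 0,
            all(genotype_params$min_binding_scale >= 0),
            all(genotype_params$liv_binding_scale >= 0))
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %.0f bp circular genome, %d TUs, %d primary",
                     " sites, bin %d bp, snr %.1f, seed %d\n"),
              x$genome_length, x$n_tus, x$n_primary_sites, x$bin_size,
              x$snr, x$seed))
  invisible(x)
}

#' Simulate a transcription-unit annotation
#'
#' Places `n_tus` non-overlapping, randomly stranded transcription units on
#' the replicon, one TSS each at the strand-appropriate end.  Coordinates are
#' 0-based half-open.
#'
#' @param config A [sim_config()].
#' @return List with `tss` (data frame: tu_id, position, strand) and `tus`
#'   (data frame: tu_id, start, end, strand, gene).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_tus
  if (n == 0) {
    return(list(
      tss = data.frame(tu_id = character(0), position = integer(0),
                       strand = character(0), stringsAsFactors = FALSE),
      tus = data.frame(tu_id = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       gene = character(0), stringsAsFactors = FALSE)))
  }
  slot <- floor(config$genome_length / n)
  if (slot < 400) {
    stop("genome too small for ", n, " transcription units: each TU needs ",
         "at least a 400 bp slot, got ", slot, " bp; increase genome_length ",
         "or reduce n_tus")
  }
  with_seed(config$seed + 104729, {
    len <- round(stats::runif(n, 0.3, 0.8) * slot)
    off <- floor(stats::runif(n, 0, slot - len))
    start <- (seq_len(n) - 1L) * slot + off
    strand <- sample(c("+", "-"), n, replace = TRUE)
    tu_id <- sprintf("TU%04d", seq_len(n))
    tus <- data.frame(tu_id = tu_id, start = as.integer(start),
                      end = as.integer(start + len), strand = strand,
                      gene = sprintf("gene%04d", seq_len(n)),
                      stringsAsFactors = FALSE)
    tss <- data.frame(tu_id = tu_id,
                      position = as.integer(ifelse(strand == "+", tus$start,
                                                   tus$end - 1L)),
                      strand = strand, stringsAsFactors = FALSE)
    list(tss = tss, tus = tus)
  })
}

#' Plant ground-truth binding sites and effects
#'
#' Draws the latent state of the synthetic study: primary sites (a fraction
#' planted exactly at TSSs), shared satellite sites offset by
#' `secondary_spacing`, genotype-specific extra satellites, the leucine class
#' of every site, regulator-dependent RNAP effects at bound TUs, and the true
#' protein levels / qPCR enrichments used by the quantification generators.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()].
#' @return An object of class \code{"sim_truth"}: list with `sites` (data
#'   frame), `tu_effects` (data frame keyed by tu_id), `western_truth`,
#'   `qpcr_truth`, `qrt_truth`.
#' @export
simulate_truth <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$genome_length
  np <- config$n_primary_sites
  with_seed(config$seed + 15485863, {
    n_at_tss <- round(config$tss_bound_fraction * np)
    n_at_tss <- min(n_at_tss, nrow(annotation$tss))
    tss_pick <- if (n_at_tss > 0) {
      sort(sample(seq_len(nrow(annotation$tss)), n_at_tss))
    } else integer(0)
    centers <- numeric(0)
    tu_of <- character(0)
    if (n_at_tss > 0) {
      centers <- annotation$tss$position[tss_pick]
      tu_of <- annotation$tss$tu_id[tss_pick]
    }
    # remaining primaries uniform, kept >= 6 kb from all existing primaries
    # so satellite neighbourhoods do not collide
    min_sep <- 6000
    while (length(centers) < np) {
      cand <- floor(stats::runif(1, 0, L))
      d <- abs(cand - centers)
      d <- pmin(d, L - d)
      if (length(d) == 0 || min(d) >= min_sep) {
        centers <- c(centers, cand)
        tu_of <- c(tu_of, NA_character_)
      }
    }
    leu_class <- sample(c("abrogated", "reduced"), np, replace = TRUE,
                        prob = c(config$abrogated_fraction,
                                 1 - config$abrogated_fraction))
    half <- config$peak_width / 2
    sites <- data.frame(
      site_id = sprintf("P%03d", seq_len(np)),
      center = as.numeric(centers),
      role = "primary", primary_id = sprintf("P%03d", seq_len(np)),
      leucine_class = leu_class, genotype_specific = NA_character_,
      tu_id = tu_of, stringsAsFactors = FALSE)
    draw_offset <- function(k) {
      sign <- sample(c(-1, 1), k, replace = TRUE)
      sign * stats::runif(k, config$secondary_spacing[1],
                          config$secondary_spacing[2])
    }
    # shared satellites (present in every binding genotype)
    has_sat <- stats::runif(np) < config$secondary_site_rate
    if (any(has_sat)) {
      idx <- which(has_sat)
      sat <- data.frame(
        site_id = sprintf("S%03d", seq_along(idx)),
        center = (sites$center[idx] + draw_offset(length(idx))) %% L,
        role = "secondary", primary_id = sites$site_id[idx],
        leucine_class = sites$leucine_class[idx],
        genotype_specific = NA_character_, tu_id = NA_character_,
        stringsAsFactors = FALSE)
      sites <- rbind(sites, sat)
    }
    # genotype-specific extra satellites (e.g. D114E)
    gp <- config$genotype_params
    for (g in gp$genotype[gp$extra_secondary_rate > 0]) {
      rate <- gp$extra_secondary_rate[gp$genotype == g]
      nx <- stats::rpois(np, rate)
      if (sum(nx) == 0) next
      idx <- rep(seq_len(np), nx)
      ext <- data.frame(
        site_id = sprintf("X%s%03d", g, seq_along(idx)),
        center = (sites$center[idx] + draw_offset(length(idx))) %% L,
        role = "secondary", primary_id = sites$site_id[idx],
        leucine_class = sites$leucine_class[idx],
        genotype_specific = g, tu_id = NA_character_,
        stringsAsFactors = FALSE)
      sites <- rbind(sites, ext)
    }
    sites$start <- as.integer(round(sites$center - half) %% L)
    sites$end <- as.integer((round(sites$center - half) + 2 * half) %% L)
    rownames(sites) <- NULL

    # regulator-dependent RNAP effects at TUs hosting a primary site
    bound <- sites[sites$role == "primary" & !is.na(sites$tu_id), ]
    eff_sign <- sample(c(-1, 1), nrow(bound), replace = TRUE)
    tu_effects <- data.frame(
      tu_id = bound$tu_id, site_id = bound$site_id,
      leucine_class = bound$leucine_class,
      effect_min = eff_sign * config$rnap_effect_size,
      stringsAsFactors = FALSE)

    western_truth <- expand.grid(
      strain = c("WT", "D114E", "L136R", "dC11"),
      medium = c("Min", "LIV"), phase = c("Log", "Stat"),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    lv <- c(WT = 1.0, D114E = 1.3, L136R = 0.75, dC11 = 0.85)
    western_truth$level <- lv[western_truth$strain]
    western_truth$level[western_truth$strain == "dC11" &
                          western_truth$phase == "Stat"] <- 0.45
    qpcr_truth <- expand.grid(
      strain = c("WT", "Lrp5scr", "Peak3scr", "Secscr"),
      amplicon = c("Peak1", "Peak2", "Peak3", "Peak4",
                   "ctrl_cysG", "ctrl_mdoG"),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    enr <- matrix(c(  # rows: strains, cols: Peak1..4 (log2 IP enrichment)
      3.0, 3.0, 4.0, 3.0,   # WT
      2.8, 2.8, 2.0, 2.8,   # Lrp5 site scrambled: primary peak reduced
      1.5, 1.5, 0.0, 1.5,   # Peak3 scrambled: primary lost, satellites drop
      0.0, 0.0, 3.0, 0.0),  # secondaries scrambled: Peak3 mildly reduced
      nrow = 4, byrow = TRUE,
      dimnames = list(c("WT", "Lrp5scr", "Peak3scr", "Secscr"), NULL))
    qpcr_truth$log2_enrichment <- 0
    tgt <- grepl("^Peak", qpcr_truth$amplicon)
    qpcr_truth$log2_enrichment[tgt] <-
      enr[cbind(match(qpcr_truth$strain[tgt], rownames(enr)),
                as.integer(sub("Peak", "", qpcr_truth$amplicon[tgt])))]
    qrt_truth <- expand.grid(
      gene = c("ycgB", "dadA", "dadX"),
      strain = c("scar", "Lrp5scr", "Peak3scr", "Secscr"),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    dd <- matrix(c(  # log2 expression change vs WT
      1.0, 1.5, 1.5,    # scar: loses Lrp repression of all three
      0.6, 1.0, 1.0,    # Lrp5scr
      0.8, 1.2, 1.2,    # Peak3scr
      1.2, 0.2, 1.0),   # Secscr: ycgB and dadX respond, dadA barely
      nrow = 4, byrow = TRUE)
    qrt_truth$log2_change <- as.vector(t(dd))  # gene varies fastest
    structure(list(sites = sites, tu_effects = tu_effects,
                   western_truth = western_truth, qpcr_truth = qpcr_truth,
                   qrt_truth = qrt_truth),
              class = "sim_truth")
  })
}

genotype_row <- function(config, genotype) {
  gp <- config$genotype_params
  i <- match(genotype, gp$genotype)
  if (is.na(i)) stop("unknown genotype '", genotype, "'; known: ",
                     paste(gp$genotype, collapse = ", "))
  gp[i, ]
}

#' True per-site occupancy scale for a genotype and medium
#'
#' Combines the genotype's binding scales with the site's leucine class:
#' for leucine-sensitive genotypes in LIV, "abrogated" sites drop to 0 and
#' "reduced" sites to `reduced_liv_scale`; insensitive genotypes keep their
#' LIV scale at every site.  Genotype-specific satellites are 0 for other
#' genotypes; scar and dC11 are 0 everywhere.
#'
#' @param truth A [simulate_truth()] object.
#' @param config The matching [sim_config()].
#' @param genotype,medium Condition to evaluate.
#' @return Numeric vector of occupancy scales, aligned with `truth$sites`.
#' @export
site_occupancy_scale <- function(truth, config, genotype, medium) {
  g <- genotype_row(config, genotype)
  s <- truth$sites
  base <- rep(g$min_binding_scale, nrow(s))
  if (medium == "LIV") {
    base <- base * g$liv_binding_scale
    if (g$leucine_sensitive) {
      cls <- ifelse(s$leucine_class == "abrogated", 0, config$reduced_liv_scale)
      base <- base * cls
    }
  }
  base[!is.na(s$genotype_specific) & s$genotype_specific != genotype] <- 0
  base
}

#' True regulator-dependent RNAP log2 fold change per TU
#'
#' @inheritParams site_occupancy_scale
#' @return Data frame `tu_id`, `effect` (log2 units; 0 for unbound TUs is
#'   not listed — only TUs with planted effects appear).
#' @export
true_tu_effect <- function(truth, config, genotype, medium) {
  eff <- truth$tu_effects
  idx <- match(eff$site_id, truth$sites$site_id)
  scale <- site_occupancy_scale(truth, config, genotype, medium)[idx]
  data.frame(tu_id = eff$tu_id, effect = eff$effect_min * scale,
             stringsAsFactors = FALSE)
}

sample_seed_offset <- function(meta) {
  gi <- match(meta$genotype, c("WT", "D114E", "L136R", "dC11", "scar")) - 1L
  mi <- match(meta$medium, c("Min", "LIV")) - 1L
  pi_ <- match(meta$phase, c("Log", "Stat")) - 1L
  ai <- match(meta$assay, c("Lrp", "RNAP")) - 1L
  ((((gi * 2L + mi) * 2L + pi_) * 8L + (meta$lineage - 1L)) * 8L +
      (meta$biorep - 1L)) * 2L + ai
}

background_draw <- function(config, n_bins) {
  if (config$noise_sd == 0) {
    rep(config$background_mean, n_bins)
  } else {
    stats::rnbinom(n_bins, mu = config$background_mean,
                   size = config$background_size)
  }
}

# circular Gaussian bump added in place
add_bump <- function(values, center_bin, sd_bins, amp) {
  n <- length(values)
  w <- ceiling(4 * sd_bins)
  idx <- (center_bin - w):(center_bin + w)
  kern <- exp(-((idx - center_bin)^2) / (2 * sd_bins^2))
  idx <- ((idx - 1) %% n) + 1
  values[idx] <- values[idx] + amp * kern
  values
}

# shared multiplicative lineage factor (independently constructed strains
# differ slightly in overall ChIP efficiency)
lineage_factor <- function(config, genotype, lineage) {
  if (config$noise_sd == 0) return(1)
  gi <- match(genotype, c("WT", "D114E", "L136R", "dC11", "scar"))
  with_seed(config$seed + 32452843 + gi * 100 + lineage,
            exp(stats::rnorm(1, 0, config$noise_sd / 3)))
}

#' Simulate a regulator ChIP track and its matched input
#'
#' The input is pure background; the ChIP track adds a Gaussian enrichment
#' bump at every planted site, scaled by the genotype-by-medium occupancy
#' scale, the shared lineage factor, and per-site log-normal replicate noise.
#' Knockout (scar) and non-binding (dC11) samples have expected enrichment 0.
#'
#' @param config A [sim_config()].
#' @param truth A [simulate_truth()] object.
#' @param sample A [sample_meta()] with `assay = "Lrp"`.
#' @return List with `chip` and `input` raw [occupancy_track()]s.
#' @export
simulate_chip_tracks <- function(config, truth, sample) {
  stopifnot(inherits(sample, "sample_meta"))
  g <- genotype_row(config, sample$genotype)  # validates genotype
  n_bins <- config$genome_length / config$bin_size
  scales <- site_occupancy_scale(truth, config, sample$genotype, sample$medium)
  lf <- lineage_factor(config, sample$genotype, sample$lineage)
  with_seed(config$seed + 49979687 + sample_seed_offset(sample), {
    input <- background_draw(config, n_bins)
    chip <- background_draw(config, n_bins)
    sd_bins <- (config$peak_width / 4) / config$bin_size
    for (i in seq_len(nrow(truth$sites))) {
      if (scales[i] <= 0) next
      amp <- config$snr * config$background_mean * scales[i] * lf
      if (config$noise_sd > 0) amp <- amp * exp(stats::rnorm(1, 0, config$noise_sd))
      cb <- floor(truth$sites$center[i] / config$bin_size) + 1
      chip <- add_bump(chip, cb, sd_bins, amp)
    }
    list(chip = occupancy_track(chip, config$bin_size, meta = sample),
         input = occupancy_track(input, config$bin_size,
                                 meta = sample))
  })
}

#' Simulate an RNA-polymerase ChIP track and its matched input
#'
#' RNAP enrichment is uniform across each TU body at a baseline factor,
#' multiplied by `2^effect` where `effect` is the planted regulator-dependent
#' log2 change for this genotype and medium (0 in the scar strain).  With
#' `noise_sd = 0` the planted effect is recovered exactly by the TU-level
#' log-ratio statistic.
#'
#' @param config A [sim_config()].
#' @param truth A [simulate_truth()] object.
#' @param annotation Output of [simulate_annotation()].
#' @param sample A [sample_meta()] with `assay = "RNAP"`.
#' @param baseline_enrichment RNAP enrichment factor over background at TU
#'   bodies in the absence of regulation.
#' @return List with `chip` and `input` raw [occupancy_track()]s.
#' @export
simulate_rnap_tracks <- function(config, truth, annotation, sample,
                                 baseline_enrichment = 3) {
  stopifnot(inherits(sample, "sample_meta"))
  genotype_row(config, sample$genotype)
  n_bins <- config$genome_length / config$bin_size
  eff <- true_tu_effect(truth, config, sample$genotype, sample$medium)
  with_seed(config$seed + 67867967 + sample_seed_offset(sample), {
    input <- background_draw(config, n_bins)
    chip <- background_draw(config, n_bins)
    for (i in seq_len(nrow(annotation$tus))) {
      tu <- annotation$tus[i, ]
      e <- eff$effect[match(tu$tu_id, eff$tu_id)]
      if (is.na(e)) e <- 0
      b0 <- floor(tu$start / config$bin_size) + 1
      b1 <- ceiling(tu$end / config$bin_size)
      lvl <- config$background_mean * baseline_enrichment * 2^e
      if (config$noise_sd > 0) {
        lvl <- lvl * exp(stats::rnorm(1, 0, config$noise_sd))
        chip[b0:b1] <- stats::rnbinom(b1 - b0 + 1, mu = lvl,
                                      size = config$background_size)
      } else {
        chip[b0:b1] <- lvl
      }
    }
    list(chip = occupancy_track(chip, config$bin_size, meta = sample),
         input = occupancy_track(input, config$bin_size, meta = sample))
  })
}

#' Simulate a Western-blot densitometry table
#'
#' One row per strain, medium, phase, lineage and biological replicate, with
#' the regulator-band pixel density and the total-protein density.  Noise is
#' multiplicative log-normal; lineages share a small multiplicative factor.
#' The scar knockout is omitted (no band to quantify).
#'
#' @param truth A [simulate_truth()] object (uses `truth$western_truth`).
#' @param n_bioreps,n_lineages Replicate structure (defaults: two biological
#'   replicates of each of two lineages).
#' @param noise_sd Log-scale SD of replicate noise (0 gives exact ratios).
#' @param seed Integer seed.
#' @return Data frame with columns strain, medium, phase, lineage, biorep,
#'   lrp_density, total_density.
#' @export
simulate_western <- function(truth, n_bioreps = 2, n_lineages = 2,
                             noise_sd = 0.15, seed = 1) {
  wt <- truth$western_truth
  with_seed(seed + 86028121, {
    rows <- merge(wt, expand.grid(lineage = seq_len(n_lineages),
                                  biorep = seq_len(n_bioreps)))
    rows <- rows[order(rows$strain, rows$medium, rows$phase,
                       rows$lineage, rows$biorep), ]
    n <- nrow(rows)
    lin_fac <- exp(stats::rnorm(length(unique(rows$strain)) * n_lineages,
                                0, noise_sd / 3))
    names(lin_fac) <- as.vector(outer(unique(rows$strain),
                                      seq_len(n_lineages), paste, sep = "."))
    lf <- lin_fac[paste(rows$strain, rows$lineage, sep = ".")]
    rows$total_density <- 1000 * exp(stats::rnorm(n, 0, noise_sd / 2))
    rows$lrp_density <- rows$level * lf * rows$total_density *
      exp(stats::rnorm(n, 0, noise_sd))
    rownames(rows) <- NULL
    rows[, c("strain", "medium", "phase", "lineage", "biorep",
             "lrp_density", "total_density")]
  })
}

#' Simulate a ChIP-qPCR quantification-cycle table
#'
#' For every strain, amplicon and replicate, emits Cq values for the
#' immunoprecipitated (IP) and input fractions.  The IP fraction recovers a
#' constant share of unenriched material, so
#' `Cq(IP) - Cq(input) = ip_cost_log2 - log2(enrichment)`; with the two
#' control amplicons at enrichment 1 the double difference isolates the true
#' log2 enrichment.
#'
#' @param truth A [simulate_truth()] object (uses `truth$qpcr_truth`).
#' @param n_reps Replicates per strain and amplicon.
#' @param base_cq Baseline quantification cycle of unenriched input.
#' @param ip_cost_log2 log2 cost of the IP fraction at unenriched loci.
#' @param noise_sd SD of Cq measurement noise in cycles (0 = exact).
#' @param seed Integer seed.
#' @return Data frame: strain, amplicon, is_control, fraction, biorep, cq.
#' @export
simulate_qpcr <- function(truth, n_reps = 3, base_cq = 18, ip_cost_log2 = 4,
                          noise_sd = 0.15, seed = 1) {
  qt <- truth$qpcr_truth
  with_seed(seed + 92526413, {
    rows <- merge(qt, expand.grid(biorep = seq_len(n_reps),
                                  fraction = c("IP", "input"),
                                  stringsAsFactors = FALSE))
    rows <- rows[order(rows$strain, rows$amplicon, rows$fraction,
                       rows$biorep), ]
    n <- nrow(rows)
    ip <- rows$fraction == "IP"
    rows$cq <- base_cq + ifelse(ip, ip_cost_log2 - rows$log2_enrichment, 0) +
      stats::rnorm(n, 0, noise_sd)
    rows$is_control <- grepl("^ctrl_", rows$amplicon)
    rownames(rows) <- NULL
    rows[, c("strain", "amplicon", "is_control", "fraction", "biorep", "cq")]
  })
}

#' Simulate a qRT-PCR expression table
#'
#' Cq values for target genes and a set of reference transcripts across
#' genotypes, with planted log2 expression changes relative to wild type
#' (`truth$qrt_truth`).  Reference transcripts are unchanged across
#' genotypes.
#'
#' @param truth A [simulate_truth()] object.
#' @param n_reps Replicates per genotype and transcript.
#' @param reference_transcripts Names of the reference transcripts.
#' @param base_cq Baseline Cq.
#' @param noise_sd Cq noise SD in cycles.
#' @param seed Integer seed.
#' @return Data frame: strain, transcript, is_reference, biorep, cq.
#' @export
simulate_qrt <- function(truth, n_reps = 3,
                         reference_transcripts = c("ref1", "ref2", "ref3"),
                         base_cq = 20, noise_sd = 0.15, seed = 1) {
  qt <- truth$qrt_truth
  strains <- c("WT", unique(qt$strain))
  genes <- unique(qt$gene)
  with_seed(seed + 32462081, {
    grid <- expand.grid(strain = strains,
                        transcript = c(genes, reference_transcripts),
                        biorep = seq_len(n_reps),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    key <- paste(grid$strain, grid$transcript)
    chg <- qt$log2_change[match(key, paste(qt$strain, qt$gene))]
    chg[is.na(chg)] <- 0  # WT and reference transcripts
    grid$is_reference <- grid$transcript %in% reference_transcripts
    grid$cq <- base_cq - chg + stats::rnorm(nrow(grid), 0, noise_sd)
    grid <- grid[order(grid$strain, grid$transcript, grid$biorep), ]
    rownames(grid) <- NULL
    grid[, c("strain", "transcript", "is_reference", "biorep", "cq")]
  })
}
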