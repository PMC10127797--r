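# The synthetic-data generator: determinism, annotation geometry, planted
# enrichment per genotype, conservation, and the quantification tables.

test_that("simulate_annotation places disjoint in-bounds TUs deterministically", {
  cfg0 <- tiny_config(seed = 1)
  cfg0$n_tus <- 0L
  ann0 <- simulate_annotation(cfg0)
  expect_equal(nrow(ann0$tss), 0)
  expect_equal(nrow(ann0$tus), 0)

  cfg <- sim_config(genome_length = 5e5, n_tus = 50, seed = 1)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$tus), 50)
  expect_true(all(ann$tus$start >= 0 & ann$tus$end <= 5e5))
  # brute-force pairwise overlap scan
  for (i in 1:49) {
    for (j in (i + 1):50) {
      expect_true(ann$tus$end[i] <= ann$tus$start[j] ||
                    ann$tus$end[j] <= ann$tus$start[i])
    }
  }
  # TSS at the strand-appropriate end, inside the TU
  plus <- ann$tus$strand == "+"
  expect_equal(ann$tss$position[plus], ann$tus$start[plus])
  expect_equal(ann$tss$position[!plus], ann$tus$end[!plus] - 1L)
  # same config, same seed: identical output
  expect_identical(ann, simulate_annotation(cfg))
  # impossible sizing is rejected with a sizing message
  expect_error(simulate_annotation(sim_config(genome_length = 1e5,
                                              n_tus = 10000, bin_size = 25,
                                              n_primary_sites = 1,
                                              peak_width = 400)),
               "genome too small")
})

test_that("planted occupancy scales follow genotype and medium rules", {
  cfg <- tiny_config(seed = 5)
  ann <- simulate_annotation(cfg)
  tr <- simulate_truth(cfg, ann)
  # conservation: every genotype sees the configured number of primaries
  expect_equal(sum(tr$sites$role == "primary"), cfg$n_primary_sites)
  # scar has zero occupancy scale everywhere
  expect_true(all(site_occupancy_scale(tr, cfg, "scar", "Min") == 0))
  expect_true(all(site_occupancy_scale(tr, cfg, "dC11", "LIV") == 0))
  # WT in LIV: abrogated-class sites drop to exactly 0, reduced-class keep
  # the configured residual scale
  sc <- site_occupancy_scale(tr, cfg, "WT", "LIV")
  abro <- tr$sites$leucine_class == "abrogated" &
    is.na(tr$sites$genotype_specific)
  expect_true(all(sc[abro] == 0))
  redu <- tr$sites$leucine_class == "reduced" &
    is.na(tr$sites$genotype_specific)
  expect_true(all(sc[redu] == cfg$reduced_liv_scale))
  # L136R is leucine-insensitive: LIV scale is min x liv multiplier at all
  # of its sites
  scl <- site_occupancy_scale(tr, cfg, "L136R", "LIV")
  own <- is.na(tr$sites$genotype_specific) |
    tr$sites$genotype_specific == "L136R"
  expect_true(all(abs(scl[own] - 1.2 * 0.9) < 1e-12))
  # D114E-specific satellites have zero scale for WT
  xd <- !is.na(tr$sites$genotype_specific) &
    tr$sites$genotype_specific == "D114E"
  expect_true(all(site_occupancy_scale(tr, cfg, "WT", "Min")[xd] == 0))
  expect_error(simulate_chip_tracks(cfg, tr,
                                    structure(list(genotype = "XYZ",
                                                   medium = "Min",
                                                   phase = "Log",
                                                   lineage = 1L, biorep = 1L,
                                                   assay = "Lrp"),
                                              class = "sample_meta")),
               "unknown genotype")
})

test_that("D114E carries extra satellites at the configured rate", {
  # expectation over many primaries: extras per primary ~ Poisson(rate)
  cfg <- sim_config(genome_length = 2e6, n_primary_sites = 100, n_tus = 100,
                    seed = 8)
  tr <- simulate_truth(cfg, simulate_annotation(cfg))
  n_extra <- sum(!is.na(tr$sites$genotype_specific) &
                   tr$sites$genotype_specific == "D114E")
  rate <- 1.0  # default extra_secondary_rate for D114E
  expect_lt(abs(n_extra / 100 - rate), 3 * sqrt(rate / 100))
})

test_that("scar ChIP is unenriched and WT enrichment grows with snr", {
  cfg <- tiny_config(seed = 31)
  ann <- simulate_annotation(cfg)
  tr <- simulate_truth(cfg, ann)
  pair <- simulate_chip_tracks(cfg, tr, sample_meta("scar", "Min", "Log"))
  bins <- floor(tr$sites$center / cfg$bin_size) + 1
  diff_at_sites <- pair$chip$values[bins] - pair$input$values[bins]
  se <- sd(pair$chip$values) * sqrt(2 / length(bins))
  expect_lt(abs(mean(diff_at_sites)), 3 * se)
  # monotonicity: mean enrichment at planted sites increases with snr
  enr <- vapply(c(1, 3, 6), function(s) {
    cfg2 <- tiny_config(seed = 31, snr = s)
    tr2 <- simulate_truth(cfg2, ann)
    p <- simulate_chip_tracks(cfg2, tr2, sample_meta("WT", "Min", "Log"))
    b <- floor(tr2$sites$center / cfg2$bin_size) + 1
    mean(p$chip$values[b] - p$input$values[b])
  }, numeric(1))
  expect_true(all(diff(enr) > 0))
  # determinism
  p1 <- simulate_chip_tracks(cfg, tr, sample_meta("WT", "Min", "Log"))
  p2 <- simulate_chip_tracks(cfg, tr, sample_meta("WT", "Min", "Log"))
  expect_identical(p1$chip$values, p2$chip$values)
})

test_that("RNAP tracks carry the planted TU effects", {
  cfg <- tiny_config(seed = 41)
  cfg$noise_sd <- 0  # noiseless limit
  ann <- simulate_annotation(cfg)
  tr <- simulate_truth(cfg, ann)
  gp <- simulate_rnap_tracks(cfg, tr, ann,
                             sample_meta("WT", "Min", "Log", assay = "RNAP"))
  sp <- simulate_rnap_tracks(cfg, tr, ann,
                             sample_meta("scar", "Min", "Log", assay = "RNAP"))
  glr <- log_ratio(gp$chip, gp$input, pseudocount = 1e-9)
  slr <- log_ratio(sp$chip, sp$input, pseudocount = 1e-9)
  eff <- true_tu_effect(tr, cfg, "WT", "Min")
  for (k in seq_len(nrow(eff))) {
    tu <- ann$tus[ann$tus$tu_id == eff$tu_id[k], ]
    fc <- tu_log2fc(list(glr), list(slr), tu)
    expect_equal(fc$log2fc, eff$effect[k], tolerance = 1e-6)
  }
  # all-zero effects: genotype and scar TU signal indistinguishable
  cfg0 <- tiny_config(seed = 42, rnap_effect_size = 0)
  tr0 <- simulate_truth(cfg0, ann)
  g0 <- simulate_rnap_tracks(cfg0, tr0, ann,
                             sample_meta("WT", "Min", "Log", assay = "RNAP"))
  s0 <- simulate_rnap_tracks(cfg0, tr0, ann,
                             sample_meta("scar", "Min", "Log", assay = "RNAP"))
  fc0 <- vapply(seq_len(nrow(ann$tus)), function(i) {
    tu_log2fc(list(log_ratio(g0$chip, g0$input)),
              list(log_ratio(s0$chip, s0$input)), ann$tus[i, ])$log2fc
  }, numeric(1))
  expect_lt(abs(mean(fc0)), 0.1)  # no systematic genotype-vs-scar shift
})

test_that("western table has the replicate design and exact noiseless ratios", {
  cfg <- tiny_config(seed = 51)
  tr <- simulate_truth(cfg, simulate_annotation(cfg))
  tab <- simulate_western(tr, n_bioreps = 2, n_lineages = 2, seed = 2)
  expect_false(any(tab$strain == "scar"))
  counts <- table(tab$strain, tab$medium, tab$phase)
  expect_true(all(counts == 4))  # 2 lineages x 2 bioreps
  # zero noise: density ratio equals planted truth exactly
  tab0 <- simulate_western(tr, noise_sd = 0, seed = 2)
  ratio <- tab0$lrp_density / tab0$total_density
  truth <- merge(tab0, tr$western_truth)
  expect_equal(tab0$lrp_density / tab0$total_density,
               merge(tab0[, 1:5], tr$western_truth,
                     sort = FALSE)$level, tolerance = 1e-12)
  # fixed seed reruns identical
  expect_identical(simulate_western(tr, seed = 9), simulate_western(tr, seed = 9))
})

test_that("qPCR Cq arithmetic encodes enrichment in log2 units", {
  cfg <- tiny_config(seed = 61)
  tr <- simulate_truth(cfg, simulate_annotation(cfg))
  # zero noise: dCq(target) - dCq(control) = -log2(enrichment)
  cq <- simulate_qpcr(tr, noise_sd = 0, seed = 1)
  one <- function(strain, amp, frac) {
    cq$cq[cq$strain == strain & cq$amplicon == amp &
            cq$fraction == frac][1]
  }
  dcq <- function(strain, amp) one(strain, amp, "IP") - one(strain, amp, "input")
  # WT Peak3 is planted at 16x (log2 = 4)
  expect_equal(dcq("WT", "Peak3") - dcq("WT", "ctrl_cysG"), -4)
  # controls against each other: zero
  expect_equal(dcq("WT", "ctrl_cysG") - dcq("WT", "ctrl_mdoG"), 0)
  # an 8x enrichment gives exactly -3
  tr8 <- tr
  tr8$qpcr_truth$log2_enrichment[tr8$qpcr_truth$strain == "WT" &
                                   tr8$qpcr_truth$amplicon == "Peak1"] <- 3
  cq8 <- simulate_qpcr(tr8, noise_sd = 0, seed = 1)
  cq <- cq8
  expect_equal(dcq("WT", "Peak1") - dcq("WT", "ctrl_cysG"), -3)
})
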