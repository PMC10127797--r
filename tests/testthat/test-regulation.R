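# Binding-to-transcription: TSS overlap/enrichment, TU fold changes,
# direct targets, leucine-modulation score, the six-mode classifier,
# pileups, and clustering.

test_that("overlap_tss uses half-open intervals", {
  pk <- data.frame(start = 100, end = 200)
  tss <- data.frame(tu_id = c("a", "b", "c"),
                    position = c(100, 199, 200), strand = "+")
  ov <- overlap_tss(pk, tss)
  expect_setequal(ov$pairs$tu_id, c("a", "b"))  # start in, end out
  expect_equal(ov$fraction, 1)
  # fraction arithmetic: 35 of 208 peaks at a TSS
  pk208 <- data.frame(start = (0:207) * 1000, end = (0:207) * 1000 + 200)
  tss35 <- data.frame(tu_id = sprintf("t%d", 1:35),
                      position = (0:34) * 1000 + 100, strand = "+")
  ov2 <- overlap_tss(pk208, tss35)
  expect_equal(round(100 * ov2$fraction, 1), 16.8)
})

test_that("tss_enrichment detects planted promoter binding and has sane edges", {
  # peaks covering the whole replicon: observed = null = 1, p = 1
  pk_all <- data.frame(start = 0, end = 10000)
  tss <- data.frame(tu_id = "a", position = 5000, strand = "+")
  en <- tss_enrichment(pk_all, tss, 10000, n_perm = 99, seed = 1)
  expect_equal(en$observed, 1)
  expect_equal(en$p, 1)
  # no TSS: observed 0, p 1
  en0 <- tss_enrichment(pk_all, tss[0, ], 10000, n_perm = 99, seed = 1)
  expect_equal(en0$observed, 0)
  expect_equal(en0$p, 1)
  expect_error(tss_enrichment(pk_all, tss, 10000, n_perm = 0), "n_perm")
  # sim with peaks planted at TSSs is strongly enriched
  cfg <- tiny_config(seed = 111)
  ann <- simulate_annotation(cfg)
  tr <- simulate_truth(cfg, ann)
  pk <- call_peaks(simulate_scored_track(cfg, tr, sample_meta("WT", "Min", "Log")))
  en2 <- tss_enrichment(pk, ann$tss, cfg$genome_length, n_perm = 999, seed = 2)
  expect_lte(en2$p, 0.01)
})

test_that("diff_significance is calibrated against identity and powered", {
  set.seed(3)
  g <- matrix(rnorm(40), 10, 4)
  res_same <- diff_significance(g, g, n_perm = 199, seed = 1)
  expect_true(all(res_same$q > 0.9))  # identical groups: no signal
  # planted large effect, 4 vs 4
  s <- matrix(rnorm(40), 10, 4)
  g2 <- s + 3
  res <- diff_significance(g2, s, n_perm = 200, seed = 1)
  expect_true(all(res$q < 0.05))
  # BH properties: q >= p and q monotone in p
  mix <- diff_significance(rbind(g2[1:5, ], g[1:5, ]), rbind(s[1:5, ], g[1:5, ]),
                           n_perm = 100, seed = 2)
  expect_true(all(mix$q >= mix$p - 1e-12))
  ord <- order(mix$p)
  expect_true(all(diff(mix$q[ord]) >= -1e-12))
})

test_that("call_direct_targets needs both binding and a significant change", {
  changes <- list(Min = data.frame(tu_id = c("t1", "t2", "t3"),
                                   q = c(0.01, 0.5, 0.01)))
  # t1: bound + changed -> in; t2: bound, no change -> out;
  # t3: changed, unbound -> out (indirect)
  expect_equal(call_direct_targets(c("t1", "t2"), changes), "t1")
  # sim: planted direct targets are exactly the TUs with a primary site at
  # the TSS and a regulator-dependent effect
  cfg <- tiny_config(seed = 121)
  ann <- simulate_annotation(cfg)
  tr <- simulate_truth(cfg, ann)
  pk <- call_peaks(simulate_scored_track(cfg, tr, sample_meta("WT", "Min", "Log")))
  bound <- unique(overlap_tss(pk, ann$tss)$pairs$tu_id)
  reps <- lapply(1:4, function(b) {
    g <- simulate_rnap_tracks(cfg, tr, ann,
                              sample_meta("WT", "Min", "Log", 1, b, "RNAP"))
    s <- simulate_rnap_tracks(cfg, tr, ann,
                              sample_meta("scar", "Min", "Log", 1, b, "RNAP"))
    list(g = log_ratio(g$chip, g$input), s = log_ratio(s$chip, s$input))
  })
  tu_stat <- function(track, tu) {
    b0 <- floor(tu$start / track$bin_size) + 1
    mean(track$values[b0:ceiling(tu$end / track$bin_size)])
  }
  gmat <- t(vapply(seq_len(nrow(ann$tus)), function(i) {
    vapply(reps, function(r) tu_stat(r$g, ann$tus[i, ]), numeric(1))
  }, numeric(4)))
  smat <- t(vapply(seq_len(nrow(ann$tus)), function(i) {
    vapply(reps, function(r) tu_stat(r$s, ann$tus[i, ]), numeric(1))
  }, numeric(4)))
  sig <- diff_significance(gmat, smat, n_perm = 200, seed = 5)
  sig$tu_id <- ann$tus$tu_id
  hits <- call_direct_targets(bound, list(Min = sig))
  expect_setequal(hits, tr$tu_effects$tu_id)
})

test_that("leucine modulation score follows its sign convention", {
  expect_equal(leucine_modulation_score(2, 2), 0)
  expect_equal(leucine_modulation_score(-2, 0), -2)   # weakened repression
  expect_equal(leucine_modulation_score(1, 3), 2)     # strengthened activation
  # antisymmetry under swapping media at fixed Min-effect sign
  set.seed(4)
  a <- rnorm(20); b <- rnorm(20)
  s_ab <- leucine_modulation_score(a, b)
  s_ba <- (a - b) * sign(a)
  expect_equal(s_ab, -s_ba)
})

test_that("classifier labels all six constructed modes and the edge cases", {
  cm <- function(...) classify_mode(...)$mode
  se <- 0.1
  # independent: bound both, equal significant effects
  expect_equal(cm(TRUE, TRUE, 2, 2, se, se, 0.01, 0.01),
               "independent_activating")
  expect_equal(cm(TRUE, TRUE, -2, -2, se, se, 0.01, 0.01),
               "independent_repressing")
  # concerted: effect significantly larger in LIV
  expect_equal(cm(TRUE, TRUE, 1, 3, se, se, 0.01, 0.01),
               "concerted_activating")
  expect_equal(cm(TRUE, TRUE, -1, -3, se, se, 0.01, 0.01),
               "concerted_repressing")
  # reciprocal: binding and effect lost upon leucine addition
  expect_equal(cm(TRUE, FALSE, 2, 0, se, se, 0.01, 0.9),
               "reciprocal_activating")
  expect_equal(cm(TRUE, FALSE, -2, 0, se, se, 0.01, 0.9),
               "reciprocal_repressing")
  # magnitude reduction while still bound is also reciprocal
  expect_equal(cm(TRUE, TRUE, -2, -0.5, se, se, 0.01, 0.01),
               "reciprocal_repressing")
  # no significant effect anywhere: unclassified
  expect_equal(cm(TRUE, TRUE, 0.1, 0.1, se, se, 0.8, 0.7), "unclassified")
  # changed but unbound: unclassified (indirect)
  expect_equal(cm(FALSE, FALSE, 2, 2, se, se, 0.01, 0.01), "unclassified")
})

test_that("a leucine-inhibition-only generative model yields only reciprocal modes", {
  # build TU effects the way the generator does: LIV effect is the Min
  # effect shrunk by the residual binding scale (0 or 0.3)
  set.seed(6)
  modes <- vapply(1:50, function(i) {
    fc_min <- sample(c(-1, 1), 1) * runif(1, 1, 2)
    liv_scale <- sample(c(0, 0.3), 1)
    fc_liv <- fc_min * liv_scale
    classify_mode(bound_min = TRUE, bound_liv = liv_scale > 0,
                  fc_min = fc_min, fc_liv = fc_liv,
                  se_min = 0.1, se_liv = 0.1,
                  q_min = 0.001, q_liv = ifelse(liv_scale > 0, 0.02, 0.9))$mode
  }, character(1))
  expect_true(all(modes %in% c("reciprocal_activating",
                               "reciprocal_repressing")))
  expect_true(length(unique(modes)) == 2)
})

test_that("tss_pileup orients rows along transcription and wraps circularly", {
  v <- 1:40
  tr <- flat_track(v, bin_size = 10)
  tss <- data.frame(tu_id = c("p", "m"), position = c(200, 200),
                    strand = c("+", "-"))
  mat <- tss_pileup(tr, tss, half_width = 50)
  expect_equal(dim(mat), c(2, 11))
  expect_equal(mat["p", ], setNames(v[16:26], seq(-50, 50, 10)))
  expect_equal(mat["m", ], setNames(rev(v[16:26]), seq(-50, 50, 10)))
  # circular wrap at the origin
  tss0 <- data.frame(tu_id = "o", position = 0, strand = "+")
  m0 <- tss_pileup(tr, tss0, half_width = 20)
  expect_equal(unname(m0[1, ]), c(39, 40, 1, 2, 3))
  # a symmetric planted peak gives a near-symmetric row
  cfg <- tiny_config(seed = 131)
  ann <- simulate_annotation(cfg)
  tr2 <- simulate_truth(cfg, ann)
  st <- simulate_scored_track(cfg, tr2, sample_meta("WT", "Min", "Log"))
  prim <- tr2$sites[tr2$sites$role == "primary" & !is.na(tr2$sites$tu_id), ][1, ]
  tssx <- ann$tss[ann$tss$tu_id == prim$tu_id, ]
  row <- tss_pileup(st, tssx, half_width = 500)[1, ]
  expect_gt(cor(row, rev(row)), 0.8)
})

test_that("cluster_order reproduces hand-computed average-linkage merges", {
  m <- matrix(c(0, 1, 10, 11), ncol = 1)
  out <- cluster_order(m, "rows")
  hm <- out$tree$merge
  # the two tight pairs merge before the final join
  expect_equal(nrow(hm), 3)
  first_two <- list(sort(abs(hm[1, ])), sort(abs(hm[2, ])))
  expect_true(list(c(1, 2)) %in% first_two || all(first_two[[1]] == c(1, 2)))
  expect_true(any(vapply(first_two, function(x) all(x == c(1, 2)), logical(1))))
  expect_true(any(vapply(first_two, function(x) all(x == c(3, 4)), logical(1))))
  # average-linkage height of the final merge: mean pairwise distance
  expect_equal(max(out$tree$height), mean(c(10, 11, 9, 10)))
  # identical rows merge first
  m2 <- rbind(c(1, 1), c(5, 5), c(1, 1))
  out2 <- cluster_order(m2, "rows")
  expect_equal(sort(abs(out2$tree$merge[1, ])), c(1, 3))
  # permuting rows permutes leaves consistently
  set.seed(8)
  m3 <- matrix(rnorm(40), 10, 4)
  perm <- sample(10)
  o1 <- cluster_order(m3, "rows")$order
  o2 <- cluster_order(m3[perm, ], "rows")$order
  expect_setequal(perm[o2], seq_len(10))
  expect_equal(rank(match(perm[o2], o1)) %in% c(seq_len(10), rev(seq_len(10))),
               rep(TRUE, 10))
})
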