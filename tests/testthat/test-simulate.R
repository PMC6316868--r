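test_that("simulation is bit-reproducible from its seed", {
  g <- toy_genome(20000L)
  cfg <- sim_config(genome = g, segments = tibble::tibble(
    chrom = "chr1", start = 5000L, end = 7000L, copies = 8
  ), seed = 123)
  a <- simulate_pair(cfg)
  b <- simulate_pair(cfg)
  expect_identical(a$female$depth, b$female$depth)
  expect_identical(a$male$depth, b$male$depth)
  c <- simulate_pair(sim_config(genome = g, segments = cfg$segments, seed = 124))
  expect_false(identical(a$female$depth, c$female$depth))
})

test_that("simulated genome mean stays within 3 sd of the configured mean", {
  g <- toy_genome(1000000L)
  sim <- simulate_pair(sim_config(genome = g, mean_depth_male = 25, seed = 2))
  se <- sqrt(25 / 1e6)
  expect_lt(abs(track_mean_depth(sim$male) - 25), 3 * se)
  # negative binomial: same mean, larger spread
  simnb <- simulate_pair(sim_config(genome = toy_genome(200000L),
                                    noise = "negative_binomial",
                                    dispersion = 0.1, seed = 3))
  mu <- 15
  se_nb <- sqrt((mu + 0.1 * mu^2) / 200000)
  expect_lt(abs(track_mean_depth(simnb$female) - mu), 4 * se_nb)
  expect_gt(var(as.numeric(simnb$female$depth)), mu) # overdispersed
})

test_that("noise-free planted segments realize the (2 + c)/2 coverage model", {
  g <- toy_genome(500000L)
  segs <- tibble::tibble(chrom = "chr1", start = 100000L, end = 102000L,
                         copies = 8)
  cfg <- sim_config(genome = g, mean_depth_female = 16, mean_depth_male = 16,
                    segments = segs, noise = "none", seed = 1)
  sim <- simulate_pair(cfg)
  expect_true(all(sim$female$depth[100001:102000] == 16 * 5)) # (2+8)/2
  expect_true(all(sim$male$depth[100001:102000] == 16))
  s <- scr_table(sim$female, sim$male)
  infl <- 1 + 2000 * 4 / 500000
  expect_equal(s$scr[100001], 5 / infl, tolerance = 1e-12)
  bl <- estimate_copy_number(tidy(call_blocks(s)))
  expect_equal(bl$copies, 2 * 5 / infl - 2, tolerance = 1e-12)
})

test_that("decoys, dropouts and retrogenes shape coverage as configured", {
  g <- toy_genome(100000L)
  cfg <- sim_config(
    genome = g, mean_depth_female = 20, mean_depth_male = 20,
    a_duplications = tibble::tibble(chrom = "chr1", start = 10000L,
                                    end = 11000L),
    dropouts = tibble::tibble(chrom = "chr1", start = 30000L, end = 31000L,
                              retention = 0.4),
    retrogenes = tibble::tibble(
      chrom = "chr1", start = 50000L, end = 54000L,
      mode = c("true_retrogene"), copies = 10,
      exons = list(data.frame(start = c(50000L, 53000L),
                              end = c(50500L, 54000L)))
    ),
    noise = "none", seed = 6
  )
  sim <- simulate_pair(cfg)
  # female doubled over the A duplication, male untouched
  expect_true(all(sim$female$depth[10001:11000] == 40))
  expect_true(all(sim$male$depth[10001:11000] == 20))
  # dropout scales BOTH samples so the reference scaled coverage dips below 1
  expect_true(all(sim$male$depth[30001:31000] == 8))
  expect_true(all(sim$female$depth[30001:31000] == 8))
  # retrogene: exons elevated to (2+10)/2 = 6x baseline, introns untouched
  expect_true(all(sim$female$depth[50001:50500] == 120))
  expect_true(all(sim$female$depth[51001:52000] == 20))
  expect_true(all(sim$male$depth[50001:50500] == 20))
  # truth records everything planted
  expect_setequal(
    unique(sim$truth$type),
    c("a_duplication", "mappability_dropout", "retrogene", "retrogene_exon")
  )
})

test_that("dropout regions exercise the low-mappability copy estimator", {
  g <- toy_genome(100000L)
  cfg <- sim_config(
    genome = g, mean_depth_female = 20, mean_depth_male = 20,
    segments = tibble::tibble(chrom = "chr1", start = 40000L, end = 42000L,
                              copies = 12),
    dropouts = tibble::tibble(chrom = "chr1", start = 40000L, end = 42000L,
                              retention = 0.5),
    noise = "none", seed = 8
  )
  sim <- simulate_pair(cfg)
  s <- scr_table(sim$female, sim$male)
  bl <- estimate_copy_number(tidy(call_blocks(s)))
  expect_equal(nrow(bl), 1)
  expect_lt(bl$reference_scaled_mean, 1)
  expect_equal(bl$estimator, "female_scaled")
  # carrier scaled: 7 * 0.5 / inflation; estimate = 2 * that
  expect_equal(bl$copies, 2 * bl$carrier_scaled_mean)
})

test_that("overlapping planted segments are rejected", {
  g <- toy_genome(10000L)
  expect_error(sim_config(genome = g, segments = tibble::tibble(
    chrom = "chr1", start = c(100L, 500L), end = c(600L, 900L), copies = 4
  )), "disjoint")
  expect_error(sim_config(genome = g, segments = tibble::tibble(
    chrom = "chr1", start = 100L, end = 200L, copies = 0.5
  )), ">= 1")
})

test_that("random segment placement respects bounds, gaps and copy pool", {
  set.seed(10)
  g <- toy_genome(c(300000L, 300000L))
  segs <- plant_segments(g, n = 10, min_len = 1000, max_len = 5000,
                         copies = c(4, 8), min_gap = 2000)
  expect_equal(nrow(segs), 10)
  expect_true(all(segs$copies %in% c(4, 8)))
  expect_true(all(segs$end - segs$start >= 1000 & segs$end - segs$start <= 5000))
  for (ch in unique(segs$chrom)) {
    sc <- segs[segs$chrom == ch, ]
    if (nrow(sc) > 1) expect_true(all(sc$start[-1] - sc$end[-nrow(sc)] >= 2000))
  }
})

test_that("recovery scoring handles the degenerate cases", {
  truth <- tibble::tibble(chrom = "chr1", start = c(100L, 5000L),
                          end = c(1100L, 6000L), type = "b_segment",
                          copies = c(4, 8), retention = NA_real_)
  exact <- tibble::tibble(chrom = "chr1", start = c(100L, 5000L),
                          end = c(1100L, 6000L))
  ev <- evaluate_recovery(exact, truth)
  expect_equal(ev$metrics$sensitivity, 1)
  expect_equal(ev$metrics$precision, 1)
  expect_equal(ev$metrics$mean_breakpoint_error, 0)

  none <- tibble::tibble(chrom = character(), start = integer(),
                         end = integer())
  ev0 <- evaluate_recovery(none, truth)
  expect_equal(ev0$metrics$sensitivity, 0)
  expect_true(is.na(ev0$metrics$precision))

  half <- evaluate_recovery(exact[1, ], truth)
  expect_equal(half$metrics$sensitivity, 0.5)
})

test_that("pipeline recovers a realistically sized planted B chromosome", {
  # scaled-down study conditions with a self-consistent B fraction: the
  # planted B space (~102 kb) is ~5% of total coverage, as in the real
  # system, so genome-mean inflation stays small (I ~ 2.6%).
  g <- toy_genome(c(1000000L, 1000000L))
  segs <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(200000L, 600000L, 300000L, 700000L),
    end = c(203000L, 602000L, 301500L, 701000L),
    copies = c(4, 8, 16, 50)
  )
  cfg <- sim_config(genome = g, mean_depth_female = 15, mean_depth_male = 25,
                    segments = segs, seed = 7)
  sim <- simulate_pair(cfg)
  s <- scr_table(sim$female, sim$male)
  bl <- estimate_copy_number(tidy(call_blocks(s)))
  ev <- evaluate_recovery(bl, sim$truth)
  expect_equal(ev$metrics$sensitivity, 1)
  expect_lte(ev$metrics$mean_breakpoint_error, 300)
  expect_gte(ev$metrics$precision, 0.95)
  # copy estimates for segments >= 2 kb: within the estimator-switch
  # ambiguity (+2 copies when the reference block mean straddles 1) plus
  # a small inflation/noise margin
  big <- ev$per_segment[ev$per_segment$end - ev$per_segment$start >= 2000, ]
  expect_true(all(abs(big$est_copies - big$true_copies) <=
                    2.5 + 0.05 * big$true_copies))
  # called B space within 20% of the planted truth
  truth_b <- sum((segs$end - segs$start) * segs$copies)
  expect_lt(abs(sum(bl$b_space_bp) - truth_b) / truth_b, 0.2)
})

test_that("a control pair with nothing planted yields an empty call set", {
  g <- toy_genome(c(500000L, 500000L))
  sim <- simulate_pair(sim_config(genome = g, mean_depth_female = 15,
                                  mean_depth_male = 25, seed = 12))
  cl <- call_blocks(scr_table(sim$female, sim$male))
  fp <- sum(tidy(cl)$length)
  expect_lte(fp, 0.001 * genome_length(g))
})
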