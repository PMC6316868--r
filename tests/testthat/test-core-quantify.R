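test_that("a base is core iff covered in at least k samples", {
  # 13 samples; a base covered by 12 is core at k=12, one covered by 11 is not
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer())
  sets <- lapply(1:13, function(i) {
    rows <- list(empty)
    if (i <= 12) rows <- c(rows, list(tibble::tibble(
      chrom = "chr1", start = 100L, end = 200L)))
    if (i <= 11) rows <- c(rows, list(tibble::tibble(
      chrom = "chr1", start = 500L, end = 600L)))
    dplyr::bind_rows(rows)
  })
  core <- core_blocks(sets, k = 12)
  expect_equal(nrow(core), 1)
  expect_equal(core$start, 100L)
  expect_equal(core$end, 200L)
  expect_equal(core$support, 12L)
  expect_equal(nrow(core_blocks(sets, k = 13)), 0)
  expect_error(core_blocks(sets, k = 14), "between 1")
})

test_that("single-sample core is the identity; k=1 is union, k=N intersection", {
  one <- list(tibble::tibble(chrom = "chr1", start = c(10L, 400L),
                             end = c(60L, 450L)))
  core <- core_blocks(one, k = 1)
  expect_equal(core$start, c(10L, 400L))
  expect_equal(core$end, c(60L, 450L))

  set.seed(31)
  for (rep in 1:25) {
    N <- sample(2:5, 1)
    L <- sample(c(1000L, 5000L, 100000L), 1)
    sets <- lapply(1:N, function(i) random_blocks(L, sample(12, 1)))
    for (k in c(1, sample(N, 1), N)) {
      got <- core_blocks(sets, k)
      ora <- core_oracle(sets, k, L)
      expect_equal(got$start, ora$start, label = sprintf("rep %d k %d", rep, k))
      expect_equal(got$end, ora$end)
    }
    # monotone: increasing k never grows the footprint
    fp <- vapply(1:N, function(k) {
      co <- core_blocks(sets, k)
      if (nrow(co) == 0) 0 else sum(co$end - co$start)
    }, numeric(1))
    expect_true(all(diff(fp) <= 0))
  }
})

test_that("core intervals fragment at support changes in length but not bases", {
  # two staggered samples: union covered, only the middle at support 2
  sets <- list(
    tibble::tibble(chrom = "chr1", start = 0L, end = 1000L),
    tibble::tibble(chrom = "chr1", start = 600L, end = 1600L)
  )
  expect_equal(core_blocks(sets, 2)$start, 600L)
  expect_equal(core_blocks(sets, 2)$end, 1000L)
  u <- core_blocks(sets, 1)
  expect_equal(u$start, 0L)
  expect_equal(u$end, 1600L)
  expect_equal(u$support, 1L) # minimum support across the run
})

test_that("copy-number estimation switches regimes on reference coverage", {
  b <- tibble::tibble(
    chrom = "chr1", start = 0L, end = 1000L,
    block_scr = c(3, 1, 10, 0.5),
    carrier_scaled_mean = c(3, 1, 5, 0.25),
    reference_scaled_mean = c(1, 1.2, 0.5, 0.5)
  )
  est <- estimate_copy_number(b)
  # ratio regime at the calling threshold: SCR 3 -> 4 B-located copies
  expect_equal(est$copies[1], 4)
  expect_equal(est$estimator[1], "scr")
  # SCR 1 with reference >= 1 -> no excess -> 0 copies
  expect_equal(est$copies[2], 0)
  # low-mappability regime: carrier scaled mean 5 -> 10 copies
  expect_equal(est$copies[3], 10)
  expect_equal(est$estimator[3], "female_scaled")
  # clamped at zero, never negative
  expect_equal(est$copies[4], 0.5)
  est2 <- estimate_copy_number(dplyr::mutate(b, block_scr = 0.2,
                                             carrier_scaled_mean = 0,
                                             reference_scaled_mean = 2))
  expect_true(all(est2$copies == 0))
  # B space = length x copies, fractional copies kept unrounded
  expect_equal(est$b_space_bp[1], 4000)
})

test_that("noise-free simulated copy numbers invert exactly", {
  g <- toy_genome(200000L)
  segs <- tibble::tibble(chrom = "chr1", start = 50000L, end = 55000L,
                         copies = 8)
  cfg <- sim_config(genome = g, mean_depth_female = 20, mean_depth_male = 20,
                    segments = segs, noise = "none", seed = 1)
  sim <- simulate_pair(cfg)
  s <- scr_table(sim$female, sim$male)
  bl <- estimate_copy_number(tidy(call_blocks(s)))
  expect_equal(nrow(bl), 1)
  expect_equal(bl$start, 50000L)
  expect_equal(bl$end, 55000L)
  # genome-mean inflation from the planted segment itself: 5 kb at factor 5
  infl <- 1 + (5000 * (5 - 1)) / 200000
  expect_equal(bl$block_scr, 5 / infl, tolerance = 1e-12)
  expect_equal(bl$copies, 2 * 5 / infl - 2, tolerance = 1e-12)
})

test_that("quantification sums A space and copy-weighted B space", {
  b <- estimate_copy_number(tibble::tibble(
    chrom = "chr1", start = 0L, end = 1000L, block_scr = 6,
    carrier_scaled_mean = 6, reference_scaled_mean = 1
  ))
  q <- quantify_blocks(b)
  expect_equal(q$a_space_bp, 1000)
  expect_equal(q$b_space_bp, 10000) # 1 kb at 10 copies
  expect_true(is.na(q$core_pct_of_b))

  # core percent agrees with the printed-rounding arithmetic of a report row:
  # core 25.13 Mb of total 49.44 Mb in B space -> 50.84%
  blocks <- tibble::tibble(
    chrom = "chr1", start = 0L, end = 1000000L,
    block_scr = 25.72, carrier_scaled_mean = 25.72, reference_scaled_mean = 1
  )
  core_q <- tibble::tibble(
    chrom = "chr1", start = 0L, end = 500000L,
    block_scr = 26.13, carrier_scaled_mean = 26.13, reference_scaled_mean = 1
  )
  q2 <- quantify_blocks(estimate_copy_number(blocks),
                        estimate_copy_number(core_q))
  expect_equal(q2$b_space_bp / 1e6, 49.44, tolerance = 1e-9)
  expect_equal(q2$core_b_space_bp / 1e6, 25.13, tolerance = 1e-9)
  # agreement with the printed report value to printed rounding
  expect_equal(q2$core_pct_of_b, 50.84, tolerance = 5e-4)
})

test_that("quantifying an empty block set yields a zero report, not an error", {
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer())
  q <- quantify_blocks(empty)
  expect_equal(q$n_blocks, 0)
  expect_equal(q$a_space_bp, 0)
  expect_equal(q$b_space_bp, 0)
  expect_true(is.na(q$core_pct_of_b))
})

test_that("B-space totals are additive and invariant to chrom relabeling", {
  set.seed(9)
  mk <- function(chrom) estimate_copy_number(tibble::tibble(
    chrom = chrom, start = c(0L, 5000L), end = c(1000L, 7000L),
    block_scr = c(4, 9), carrier_scaled_mean = c(4, 9),
    reference_scaled_mean = 1
  ))
  a <- mk("chr1")
  b <- mk("chrZ")
  expect_equal(quantify_blocks(a)$b_space_bp, quantify_blocks(b)$b_space_bp)
  both <- dplyr::bind_rows(a, mk("chr2"))
  expect_equal(quantify_blocks(both)$b_space_bp, 2 * quantify_blocks(a)$b_space_bp)
})

test_that("block-size summaries match closed forms", {
  one <- tibble::tibble(chrom = "chr1", start = 0L, end = 800L)
  s1 <- summarize_blocks(one)
  expect_equal(s1$mean_bp, 800)
  expect_equal(s1$median_bp, 800)
  expect_equal(s1$max_bp, 800)
  expect_equal(s1$sd_bp, 0)

  three <- tibble::tibble(chrom = "chr1", start = c(0L, 2000L, 4000L),
                          end = c(501L, 3000L, 5499L))
  s3 <- summarize_blocks(three)
  expect_equal(s3$mean_bp, 1000)
  expect_equal(s3$median_bp, 1000)
  expect_equal(s3$max_bp, 1499)

  two <- tibble::tibble(chrom = "chr1", start = c(0L, 10000L),
                        end = c(600L, 11600L))
  expect_equal(summarize_blocks(two)$sd_bp, sqrt(500000), tolerance = 1e-12)
  expect_equal(round(summarize_blocks(two)$sd_bp, 1), 707.1)

  h <- block_length_histogram(three)
  expect_equal(h$length, c(501L, 1000L, 1499L))
  expect_equal(h$n, rep(1L, 3))
})
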