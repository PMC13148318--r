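test_that("overlap frequency counts each peak at most once", {
  blocks <- tibble::tibble(chrom = "chr1", start = c(100, 500), end = c(200, 600))
  expect_equal(overlap_frequency(
    tibble::tibble(chrom = "chr1", start = 1000, end = 1100), blocks), 0)
  # one peak spanning both blocks counts once
  expect_equal(overlap_frequency(
    tibble::tibble(chrom = "chr1", start = 150, end = 550), blocks), 1)
  withr::with_seed(44, {
    peaks <- random_intervals(1000, genome_len = 1e5, max_width = 800)
    blks <- random_intervals(30, genome_len = 1e5, max_width = 5000)
    expect_equal(overlap_frequency(peaks, blks), bf_count_overlapping(peaks, blks))
    # merge invariance of per-peak counting
    expect_equal(overlap_frequency(peaks, blks),
                 overlap_frequency(peaks, merge_intervals(blks)))
  })
})

test_that("peak density is count per merged megabase and merge-invariant", {
  peaks <- tibble::tibble(chrom = "chr1", start = (0:9) * 10000, end = (0:9) * 10000 + 500)
  blocks <- tibble::tibble(chrom = "chr1", start = 0, end = 2e6)
  expect_equal(peak_density(peaks, blocks), 5)
  # duplicating blocks leaves density unchanged (merged first)
  expect_equal(peak_density(peaks, dplyr::bind_rows(blocks, blocks)), 5)
  # splitting a block into abutting halves leaves density unchanged
  halves <- tibble::tibble(chrom = "chr1", start = c(0, 1e6), end = c(1e6, 2e6))
  expect_equal(peak_density(peaks, halves), 5)
  expect_error(peak_density(peaks, blocks[0, ]), class = "crenrich_data_error")
  withr::with_seed(45, {
    pk <- random_intervals(300, genome_len = 1e5)
    bl <- random_intervals(10, genome_len = 1e5, max_width = 8000)
    m <- merge_intervals(bl)
    expect_equal(peak_density(pk, bl),
                 bf_count_overlapping(pk, m) / (sum(m$end - m$start) / 1e6))
  })
})

test_that("empirical p follows the equal-or-greater definition exactly", {
  expect_equal(empirical_p(10, 1:10), 1 / 10)     # ties with the maximum count
  expect_equal(empirical_p(0, 1:10), 1)           # below every null value
  expect_equal(empirical_p(11, 1:10), 0)          # above every null value
  expect_equal(empirical_p(5, 1:10), 6 / 10)
  null1000 <- seq_len(1000)
  expect_equal(empirical_p(1000, null1000), 0.001)
  expect_equal(empirical_p(1001, null1000), 0)
  # adding a null value equal to the observed never decreases p
  expect_gte(empirical_p(5, c(1:10, 5)), empirical_p(5, 1:10) * 10 / 11)
  # attainable values are multiples of 1/N
  withr::with_seed(3, {
    nulls <- rpois(200, 5)
    p <- empirical_p(4, nulls)
    expect_true(abs(p * 200 - round(p * 200)) < 1e-12)
  })
})

test_that("run_enrichment computes both statistics against identical blocks", {
  blocks <- tibble::tibble(chrom = "chr1", start = c(1000, 9000), end = c(3000, 12000))
  peaks <- tibble::tibble(chrom = "chr1", start = c(1500, 2500, 20000), end = c(1600, 2600, 20100))
  bg <- list(
    peaks,                                                        # identical to observed
    tibble::tibble(chrom = "chr1", start = 50000, end = 50100)    # misses everything
  )
  res <- run_enrichment(peaks, blocks, bg)
  expect_s3_class(res, "cre_enrichment")
  r <- res$results
  expect_equal(r$observed[r$statistic == "overlap_frequency"], 2)
  expect_equal(r$observed[r$statistic == "peak_density"], 2 / 0.005)
  # degenerate null: peaks equal to one background set, N = 1 -> p = 1
  res1 <- run_enrichment(peaks, blocks, list(peaks))
  expect_equal(res1$results$empirical_p, c(1, 1))
  # zero-overlap null reports p = 0 with the < 1/N bound
  res2 <- run_enrichment(peaks, blocks, bg[2])
  expect_equal(res2$results$empirical_p, c(0, 0))
  expect_match(res2$results$p_label[1], "^< 1")
  expect_error(run_enrichment(peaks, blocks, list()), class = "crenrich_data_error")
})

test_that("tidy, glance, and autoplot work on enrichment results", {
  blocks <- tibble::tibble(chrom = "chr1", start = 1000, end = 3000)
  peaks <- tibble::tibble(chrom = "chr1", start = c(1500, 5000), end = c(1600, 5100))
  bg <- replicate(5, tibble::tibble(chrom = "chr1", start = 8000, end = 8100),
                  simplify = FALSE)
  res <- run_enrichment(peaks, blocks, bg)
  td <- generics::tidy(res)
  expect_equal(nrow(td), 2)
  gl <- generics::glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_sets, 5)
  pl <- ggplot2::autoplot(res)
  expect_s3_class(pl, "ggplot")
})
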