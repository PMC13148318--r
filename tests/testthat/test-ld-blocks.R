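test_that("GWAS filtering is strictly below the threshold and order-preserving", {
  snps <- tibble::tibble(
    chrom = "chr1", pos = c(10, 20, 30), id = c("a", "b", "c"),
    p_value = c(1e-9, 5e-8, 4.9e-8), group = "EUR"
  )
  kept <- filter_gwas(snps, 5e-8)
  expect_equal(kept$id, c("a", "c"))
  expect_equal(nrow(filter_gwas(snps[0, ], 5e-8)), 0)
})

test_that("r-squared: perfect LD, coding-flip invariance, and the 2x2 table oracle", {
  expect_equal(hap_r2(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  expect_equal(hap_r2(c(0, 1, 0, 1), c(1, 0, 1, 0)), 1)
  x <- c(0, 0, 1, 1, 0, 1, 0, 1)
  y <- c(0, 1, 1, 1, 0, 0, 0, 1)
  expect_equal(hap_r2(x, y), bf_r2(x, y), tolerance = 1e-15)
  expect_equal(hap_r2(x, y), hap_r2(y, x))
  expect_equal(hap_r2(x, y), hap_r2(1 - x, y))
  expect_true(is.na(hap_r2(c(0, 0, 0, 0), c(0, 1, 0, 1))))
  withr::with_seed(5, {
    for (i in 1:100) {
      n <- sample(4:64, 1)
      a <- rbinom(n, 1, runif(1, 0.2, 0.8))
      b <- rbinom(n, 1, runif(1, 0.2, 0.8))
      expect_equal(hap_r2(a, b), bf_r2(a, b), tolerance = 1e-12)
    }
  })
})

test_that("proxy selection handles in-panel, flanked, and one-sided SNPs", {
  mk_panel <- function(pos) {
    hap_panel("chr1", pos, matrix(rep(c(0L, 1L), length(pos)), nrow = 2))
  }
  p <- mk_panel(c(900, 1000, 1100))
  pr <- select_proxies(1000, p)
  expect_equal(pr$down, 2)
  expect_equal(pr$up, 2)
  pr <- select_proxies(1000, mk_panel(c(800, 1200)))
  expect_equal(c(pr$down, pr$up), c(1, 2))
  pr <- select_proxies(1000, mk_panel(c(700, 800)))
  expect_equal(c(pr$down, pr$up), c(2, 2))
  expect_null(select_proxies(1e7, mk_panel(c(700, 800))))
})

test_that("build_block matches the exhaustive all-pairs oracle and is monotone in r2_min", {
  withr::with_seed(21, {
    for (trial in 1:10) {
      # procedurally constructed 20-variant panels with correlated structure
      n_hap <- 30
      founders <- rbinom(20, 1, 0.5)
      alleles <- sapply(seq_len(20), function(j) {
        copy <- rbinom(n_hap, 1, runif(1, 0.3, 1))
        ifelse(copy == 1, founders[j], rbinom(n_hap, 1, 0.5))
      })
      storage.mode(alleles) <- "integer"
      positions <- sort(sample(1000:40000, 20))
      panel <- hap_panel("chr1", positions, alleles)
      snp <- tibble::tibble(chrom = "chr1", pos = positions[sample(20, 1)],
                            id = "s", p_value = 1e-10, group = "EUR")
      blk <- build_block(snp, panel, ld_params(window = 5e5, r2_min = 0.8))
      oracle <- bf_block_bounds(snp$pos, positions, alleles, 5e5, 0.8)
      expect_equal(c(blk$start, blk$end), unname(oracle))
      # monotone: a stricter r2_min yields a sub-interval
      blk95 <- build_block(snp, panel, ld_params(window = 5e5, r2_min = 0.95))
      expect_true(blk95$start >= blk$start && blk95$end <= blk$end)
    }
  })
})

test_that("degenerate block cases behave as declared", {
  # only proxies linked (all other variants independent at n large)
  withr::with_seed(33, {
    alleles <- cbind(
      rbinom(200, 1, 0.5), rbinom(200, 1, 0.5), rbinom(200, 1, 0.5)
    )
    storage.mode(alleles) <- "integer"
    panel <- hap_panel("chr1", c(1000, 5000, 9000), alleles)
    snp <- tibble::tibble(chrom = "chr1", pos = 5000, id = "s",
                          p_value = 1e-10, group = "EUR")
    blk <- build_block(snp, panel, ld_params(window = 4000, r2_min = 0.8))
    # proxies coincide with the SNP itself: degenerate single-variant block
    expect_equal(c(blk$start, blk$end), c(4999, 5000))
  })
  # no proxy in window: degenerate 1-bp block with warning, or dropped
  far <- hap_panel("chr1", c(1e6), matrix(c(0L, 1L), nrow = 2))
  snp <- tibble::tibble(chrom = "chr1", pos = 100, id = "s",
                        p_value = 1e-10, group = "EUR")
  expect_warning(blk <- build_block(snp, far, ld_params()), "degenerate")
  expect_equal(c(blk$start, blk$end), c(99, 100))
  expect_warning(blk2 <- build_block(snp, far, ld_params(), on_no_proxy = "drop"),
                 "dropped")
  expect_equal(nrow(blk2), 0)
})

test_that("merge_blocks pools provenance, keeps abutting blocks apart, and is idempotent", {
  blocks <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(0, 50, 200, 0), end = c(100, 200, 300, 50),
    source_snps = c("a", "b", "c", "d"), group = c("EUR", "AFR", "EUR", "EUR")
  )
  m <- merge_blocks(blocks)
  expect_equal(nrow(m), 3)
  expect_equal(m$source_snps[1], "a;b")
  expect_equal(m$group[1], "AFR;EUR")
  # abutting half-open blocks do not merge
  expect_equal(m$start[m$chrom == "chr1"], c(0, 200))
  expect_equal(merge_blocks(m), m)
  expect_equal(covered_bases(blocks), sum(m$end - m$start))
})

test_that("per-group blocks pool into one merged set", {
  cfg <- small_sim_cfg(panel = list(n_haplotypes = 60, groups = c("EUR", "AFR")))
  g <- simulate_genome(cfg, 13)
  pan <- simulate_panels(cfg, g$layout, 13)
  tb <- simulate_trait_blocks(cfg, pan$segments, g$layout, 13)
  gwas <- simulate_gwas(cfg, pan, tb, 13)
  sig <- filter_gwas(gwas)
  blocks <- build_ld_blocks(sig, pan$panels, ld_params())
  expect_true(nrow(blocks) >= 1)
  expect_true(all(blocks$end > blocks$start))
  # merged outputs are pairwise non-overlapping
  if (nrow(blocks) > 1) {
    same <- blocks$chrom[-1] == blocks$chrom[-nrow(blocks)]
    expect_true(all(blocks$start[-1][same] >= blocks$end[-nrow(blocks)][same]))
  }
  # every significant SNP id appears in the provenance
  ids <- unlist(strsplit(blocks$source_snps, ";"))
  expect_true(all(sig$id %in% ids))
})
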