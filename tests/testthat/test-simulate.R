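test_that("generators are pure functions of (config, seed)", {
  cfg <- small_sim_cfg()
  a <- simulate_genome(cfg, 42)
  b <- simulate_genome(cfg, 42)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$genes, b$genes)
  c <- simulate_genome(cfg, 43)
  expect_false(identical(as.character(a$genome), as.character(c$genome)))
  pa <- simulate_panels(cfg, a$layout, 42)
  pb <- simulate_panels(cfg, a$layout, 42)
  expect_identical(pa$panels$EUR$chr1$alleles, pb$panels$EUR$chr1$alleles)
  ga <- simulate_gwas(cfg, pa, NULL, 42)
  gb <- simulate_gwas(cfg, pa, NULL, 42)
  expect_identical(ga, gb)
  # written files are byte-identical across runs
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_all(cfg, seed = 4, out_dir = d1)
  simulate_all(cfg, seed = 4, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("genome-wide GC tracks the Beta parameters and zero genes mean intergenic", {
  cfg <- small_sim_cfg(genome = list(n_chrom = 1, chrom_length = 2e5,
                                     gc_shape1 = 50, gc_shape2 = 50,
                                     genes_per_chrom = 0))
  g <- simulate_genome(cfg, 2)
  whole <- gc_content(tibble::tibble(chrom = "chr1", start = 0, end = 2e5), g$genome)
  expect_lt(abs(whole - 0.5), 0.02)
  expect_equal(nrow(g$genes), 0)
  ann <- annotate_intervals(tibble::tibble(chrom = "chr1", start = c(0, 1e5),
                                           end = c(500, 1e5 + 500)), g$genes)
  expect_true(all(as.character(ann$annotation) == "intergenic"))
})

test_that("panel LD matches the mosaic model limits", {
  base <- list(genome = list(n_chrom = 1, chrom_length = 6e4, genes_per_chrom = 0),
               gwas = list(n_snps = 10, frac_significant = 0.5))
  mean_r2 <- function(panel, seg, within = TRUE) {
    pos <- panel$positions
    seg_of <- findInterval(pos - 1, c(seg$start[1], seg$end))
    pairs <- utils::combn(seq_along(pos), 2)
    keep <- if (within) seg_of[pairs[1, ]] == seg_of[pairs[2, ]] else
      seg_of[pairs[1, ]] != seg_of[pairs[2, ]]
    pairs <- pairs[, keep, drop = FALSE]
    if (ncol(pairs) > 300) pairs <- pairs[, seq_len(300)]
    vals <- vapply(seq_len(ncol(pairs)), function(k) {
      hap_r2(panel$alleles[, pairs[1, k]], panel$alleles[, pairs[2, k]])
    }, numeric(1))
    vals[!is.na(vals)]
  }
  # rho = 1: every within-segment pair is in perfect LD
  cfg1 <- do.call(sim_config, c(base, list(panel = list(
    n_haplotypes = 40, rho = 1, groups = "EUR", segment_length = 2e4
  ))))
  lay <- genome_layout("chr1", 6e4)
  p1 <- simulate_panels(cfg1, lay, 3)
  expect_true(all(abs(mean_r2(p1$panels$EUR$chr1, p1$segments) - 1) < 1e-12))
  # rho = 0: independence baseline, within ~ across ~ 1/n_haplotypes
  cfg0 <- do.call(sim_config, c(base, list(panel = list(
    n_haplotypes = 100, rho = 0, groups = "EUR", segment_length = 2e4
  ))))
  p0 <- simulate_panels(cfg0, lay, 3)
  w0 <- mean(mean_r2(p0$panels$EUR$chr1, p0$segments, TRUE))
  a0 <- mean(mean_r2(p0$panels$EUR$chr1, p0$segments, FALSE))
  expect_lt(abs(w0 - a0), 0.02)
  expect_lt(w0, 0.05)
  # rho = 0.95, 200 haplotypes: median within-segment r2 above the 0.8 threshold
  cfg95 <- do.call(sim_config, c(base, list(panel = list(
    n_haplotypes = 200, rho = 0.95, groups = "EUR", segment_length = 2e4
  ))))
  p95 <- simulate_panels(cfg95, lay, 3)
  expect_gt(median(mean_r2(p95$panels$EUR$chr1, p95$segments, TRUE)), 0.8)
  expect_lt(mean(mean_r2(p95$panels$EUR$chr1, p95$segments, FALSE)), 0.1)
})

test_that("GWAS tables carry the planted significance counts", {
  cfg <- small_sim_cfg(gwas = list(n_snps = 2400, frac_significant = 1687 / 2400))
  g <- simulate_genome(cfg, 12)
  pan <- simulate_panels(cfg, g$layout, 12)
  gw <- simulate_gwas(cfg, pan, NULL, 12)
  expect_equal(nrow(gw), 2400)
  expect_equal(nrow(filter_gwas(gw, 5e-8)), 1687)
  cfg0 <- small_sim_cfg(gwas = list(n_snps = 100, frac_significant = 0))
  gw0 <- simulate_gwas(cfg0, pan, NULL, 12)
  expect_equal(nrow(filter_gwas(gw0, 5e-8)), 0)
})

test_that("peak placement matches the two-level density closed form", {
  cfg <- small_sim_cfg(peaks = list(n_peaks = 2000, lambda = 5, width = 500))
  lay <- genome_layout(c("chr1", "chr2"), c(5e5, 5e5))
  blocks <- tibble::tibble(chrom = c("chr1", "chr2"),
                           start = c(1e5, 3e5), end = c(1.1e5, 3.1e5))
  # blocks are 2% of the genome
  q <- 5 * 0.02 / (5 * 0.02 + 0.98)
  in_frac <- replicate(10, {
    pk <- simulate_peaks(cfg, lay, blocks, sample.int(1e6, 1))
    attr(pk, "n_in_block") / nrow(pk)
  })
  sd_bin <- sqrt(q * (1 - q) / 2000)
  expect_lt(abs(mean(in_frac) - q), 3 * sd_bin)
  # lambda = 1: in-block fraction ~ block genome fraction
  cfg1 <- small_sim_cfg(peaks = list(n_peaks = 2000, lambda = 1, width = 500))
  pk1 <- simulate_peaks(cfg1, lay, blocks, 7)
  expect_lt(abs(attr(pk1, "n_in_block") / 2000 - 0.02), 3 * sqrt(0.02 * 0.98 / 2000))
  # peaks clipped to chromosome ends remain valid
  expect_true(all(pk1$end <= 5e5 & pk1$start >= 0 & pk1$end > pk1$start))
})

test_that("projection scores recover planted class proportions exactly", {
  cfg <- small_sim_cfg(dars = list(n_dars = 360))
  g <- simulate_genome(cfg, 14)
  src <- simulate_dars(cfg, g$layout, 14, "source")
  tgt <- simulate_dars(cfg, g$layout, 14, "target")
  pj <- simulate_projections(cfg, src, tgt, g$layout, 14)
  got <- as.character(classify_conservation(pj$projections$score))
  expect_identical(got, pj$truth$class)
  # largest-remainder allocation: planted proportions exact up to rounding
  props <- table(pj$truth$class)[c("direct", "indirect", "nonconserved")] / 360
  target <- cfg$projections$proportions
  expect_true(all(abs(props - target) <= 1 / 360 + 1e-9))
  # all-direct degenerate mixture
  cfg_d <- small_sim_cfg(projections = list(
    proportions = c(direct = 1, indirect = 0, nonconserved = 0),
    func_rate = c(ectoderm = 0.44, mesenchyme = 0.10)
  ))
  pj_d <- simulate_projections(cfg_d, src[1:50, ], tgt, g$layout, 3)
  expect_true(all(pj_d$truth$class == "direct"))
})

test_that("invalid configurations are rejected up front", {
  expect_error(sim_config(projections = list(
    proportions = c(direct = 0.6, indirect = 0.6, nonconserved = 0.2)
  )), class = "crenrich_config_error")
  expect_error(sim_config(panel = list(rho = 1.5)), class = "crenrich_config_error")
  expect_error(sim_config(peaks = list(lambda = -1)), class = "crenrich_config_error")
  expect_error(sim_config(genome = list(n_chrom = 1, chrom_length = 2e4,
                                        genes_per_chrom = 50)) |>
                 simulate_genome(1), class = "crenrich_config_error")
})
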