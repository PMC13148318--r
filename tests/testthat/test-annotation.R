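test_that("tiles partition every chromosome exactly", {
  layout <- genome_layout(c("chr1", "chr2"), c(1250, 1000))
  t <- tile_genome(layout, 500)
  expect_equal(t$start[t$chrom == "chr1"], c(0, 500, 1000))
  expect_equal(t$end[t$chrom == "chr1"], c(500, 1000, 1250))
  expect_equal(t$width[3], 250)
  # conservation and the closed-form count on random layouts
  withr::with_seed(2, {
    for (i in 1:5) {
      lens <- sample(1000:9999, 3)
      w <- sample(c(100, 250, 500), 1)
      lay <- genome_layout(paste0("c", 1:3), lens)
      tt <- tile_genome(lay, w)
      agg <- tapply(tt$width, tt$chrom, sum)[lay$chrom]
      expect_equal(as.numeric(agg), as.numeric(lens), ignore_attr = TRUE)
      expect_equal(nrow(tt), sum(ceiling(lens / w)))
      # no gaps, no overlaps
      for (ch in lay$chrom) {
        d <- tt[tt$chrom == ch, ]
        expect_equal(d$start[-1], d$end[-nrow(d)])
      }
    }
  })
})

test_that("GC content follows the stated ambiguity rules and a per-base oracle", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "GCGCATGCNNacgtNNNN"))
  expect_equal(gc_content(data.frame(chrom = "chr1", start = 0, end = 4), genome), 1)
  expect_equal(gc_content(data.frame(chrom = "chr1", start = 4, end = 10), genome), 0.5)
  expect_true(is.na(gc_content(data.frame(chrom = "chr1", start = 14, end = 18), genome)))
  # lower case counts
  expect_equal(gc_content(data.frame(chrom = "chr1", start = 10, end = 14), genome), 0.5)
  expect_error(gc_content(data.frame(chrom = "chr1", start = 10, end = 50), genome),
               class = "crenrich_data_error")
  withr::with_seed(31, {
    letters_pool <- c("A", "C", "G", "T", "N")
    seqs <- paste(sample(letters_pool, 5000, replace = TRUE, prob = c(.3, .2, .2, .25, .05)),
                  collapse = "")
    genome <- Biostrings::DNAStringSet(c(chrX = seqs))
    for (i in 1:20) {
      s <- sample(0:4500, 1)
      iv <- data.frame(chrom = "chrX", start = s, end = s + 500)
      chars <- strsplit(substr(seqs, s + 1, s + 500), "")[[1]]
      oracle <- sum(chars %in% c("G", "C")) / sum(chars %in% c("A", "C", "G", "T"))
      expect_identical(gc_content(iv, genome), oracle)
    }
  })
})

test_that("annotation uses any-overlap with the fixed priority order", {
  genes <- toy_genes()
  layout <- genome_layout("chr1", 40000)
  ann1 <- function(s, e) {
    as.character(annotate_intervals(
      data.frame(chrom = "chr1", start = s, end = e), genes, layout = layout
    )$annotation)
  }
  expect_equal(ann1(30000, 30500), "intergenic")      # gene desert
  expect_equal(ann1(4900, 5100), "promoter")          # spans TSS: promoter beats utr5/exon
  expect_equal(ann1(5300, 5400), "utr5")              # inside 5'UTR (and exon): utr5 wins
  expect_equal(ann1(5900, 6100), "exon")              # exon/intron boundary: exon wins
  expect_equal(ann1(6500, 6600), "intron")            # between exons
  expect_equal(ann1(9800, 9900), "utr3")
  # minus-strand gene: promoter sits right of the transcript end
  expect_equal(ann1(24100, 24500), "promoter")
  expect_equal(ann1(23850, 23900), "promoter")  # 5'UTR shadowed by promoter window
  expect_equal(ann1(23500, 23600), "utr5")
})

test_that("annotation equals the per-base exhaustive oracle on random intervals", {
  genes <- toy_genes()
  layout <- genome_layout("chr1", 40000)
  withr::with_seed(17, {
    for (i in 1:60) {
      s <- sample(0:39500, 1)
      w <- sample(c(50, 200, 500), 1)
      iv <- data.frame(chrom = "chr1", start = s, end = s + w)
      got <- as.character(annotate_intervals(iv, genes, layout = layout)$annotation)
      expect_equal(got, bf_annotate_one(iv, genes, layout = layout),
                   info = sprintf("interval [%d,%d)", s, s + w))
    }
  })
})

test_that("strata combine GC bin and annotation and partition the regions", {
  expect_equal(assign_stratum(0.42, "exon"), "gc05|exon")
  expect_equal(assign_stratum(1, "promoter"), "gc10|promoter")
  expect_equal(assign_stratum(0, "intron"), "gc01|intron")
  expect_true(is.na(assign_stratum(NA_real_, "exon")))
  withr::with_seed(8, {
    gc <- runif(200)
    ann <- sample(c("promoter", "exon", "intron", "intergenic"), 200, replace = TRUE)
    st <- assign_stratum(gc, ann, 10)
    # each region in exactly one stratum, consistent with its gc bin
    expect_equal(length(st), 200)
    expect_false(any(is.na(st)))
    bins <- as.integer(sub("^gc(\\d+)\\|.*$", "\\1", st))
    expect_true(all(bins == pmin(floor(gc * 10), 9) + 1))
    expect_true(all(sub("^gc\\d+\\|", "", st) == ann))
  })
})

test_that("annotate_regions attaches gc, annotation and stratum on simulated data", {
  cfg <- small_sim_cfg()
  g <- simulate_genome(cfg, 4)
  tiles <- tile_genome(g$layout, 500)
  ann <- annotate_regions(tiles, g$genome, g$genes)
  expect_named(ann, c("chrom", "start", "end", "width", "gc", "annotation", "stratum"))
  expect_false(any(is.na(ann$gc)))
  expect_true(all(levels(ann$annotation) == c("promoter", "utr5", "utr3",
                                              "exon", "intron", "intergenic")))
  # every class is realizable on the synthetic gene model
  expect_true(all(c("promoter", "exon", "intron", "intergenic") %in%
                    as.character(unique(ann$annotation))))
})
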