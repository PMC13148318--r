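# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's own code paths.

# O(n*m) double-loop overlap count: how many queries touch >= 1 subject
bf_count_overlapping <- function(query, subject) {
  hits <- 0L
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(subject))) {
      if (query$chrom[i] == subject$chrom[j] &&
          query$start[i] < subject$end[j] &&
          subject$start[j] < query$end[i]) {
        hits <- hits + 1L
        break
      }
    }
  }
  hits
}

# r-squared via the explicit 2x2 haplotype-count table
bf_r2 <- function(x, y) {
  n <- length(x)
  n11 <- sum(x == 1 & y == 1)
  n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1)
  px <- (n11 + n10) / n
  py <- (n11 + n01) / n
  if (px %in% c(0, 1) || py %in% c(0, 1)) return(NA_real_)
  d <- n11 / n - px * py
  d^2 / (px * (1 - px) * py * (1 - py))
}

# exhaustive LD-block oracle: all-pairs r2 scan over every panel variant
bf_block_bounds <- function(snp_pos, positions, alleles, window = 5e5, r2_min = 0.8) {
  half <- window / 2
  inside <- which(positions >= snp_pos - half & positions <= snp_pos + half)
  if (length(inside) == 0) return(NULL)
  below <- inside[positions[inside] <= snp_pos]
  above <- inside[positions[inside] >= snp_pos]
  down <- if (length(below) > 0) below[length(below)] else above[1]
  up <- if (length(above) > 0) above[1] else below[length(below)]
  linked <- vapply(inside, function(v) {
    r2d <- bf_r2(alleles[, v], alleles[, down])
    r2u <- bf_r2(alleles[, v], alleles[, up])
    (!is.na(r2d) && r2d >= r2_min) || (!is.na(r2u) && r2u >= r2_min)
  }, logical(1))
  linked[match(c(down, up), inside)] <- TRUE
  lp <- positions[inside][linked]
  c(start = min(lp) - 1, end = max(lp))
}

# uniform random interval table
random_intervals <- function(n, chroms = c("chrA", "chrB"), genome_len = 1e5,
                             max_width = 2000) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- floor(runif(n, 0, genome_len - max_width))
  width <- pmax(1, floor(runif(n, 1, max_width)))
  tibble::tibble(chrom = chrom, start = start, end = start + width)
}

# hand-built two-gene model covering every annotation class
toy_genes <- function() {
  tibble::tribble(
    ~chrom, ~start, ~end,  ~strand, ~type,             ~gene_id,
    "chr1", 5000,   10000, "+",     "gene",            "gA",
    "chr1", 5000,   10000, "+",     "mRNA",            "gA",
    "chr1", 5000,   6000,  "+",     "exon",            "gA",
    "chr1", 8000,   10000, "+",     "exon",            "gA",
    "chr1", 5000,   5600,  "+",     "five_prime_UTR",  "gA",
    "chr1", 9700,   10000, "+",     "three_prime_UTR", "gA",
    "chr1", 20000,  24000, "-",     "gene",            "gB",
    "chr1", 20000,  24000, "-",     "mRNA",            "gB",
    "chr1", 20000,  21000, "-",     "exon",            "gB",
    "chr1", 23000,  24000, "-",     "exon",            "gB",
    "chr1", 23400,  24000, "-",     "five_prime_UTR",  "gB",
    "chr1", 20000,  20300, "-",     "three_prime_UTR", "gB"
  )
}

# per-base exhaustive labelling followed by priority reduction
bf_annotate_one <- function(interval, features, promoter_up = 2000,
                            promoter_down = 200, layout = NULL) {
  classes <- crenrich::annotation_features(features, promoter_up, promoter_down, layout)
  priority <- c("promoter", "utr5", "utr3", "exon", "intron", "intergenic")
  bases <- seq(interval$start, interval$end - 1)
  labels <- vapply(bases, function(b) {
    covering <- classes$class[classes$chrom == interval$chrom &
                                classes$start <= b & classes$end > b]
    if (length(covering) == 0) "intergenic"
    else priority[min(match(covering, priority))]
  }, character(1))
  priority[min(match(labels, priority))]
}

# small deterministic genome fixture shared across tests
small_sim_cfg <- function(...) {
  base <- list(
    genome = list(n_chrom = 2, chrom_length = 1e5, genes_per_chrom = 5),
    panel = list(n_haplotypes = 40, groups = "EUR"),
    gwas = list(n_snps = 120, frac_significant = 0.5),
    peaks = list(n_peaks = 120),
    dars = list(n_dars = 120)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    base[[nm]] <- utils::modifyList(
      if (is.null(base[[nm]])) list() else base[[nm]],
      overrides[[nm]]
    )
  }
  do.call(crenrich::sim_config, base)
}
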