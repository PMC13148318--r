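#' Configuration of the synthetic-data generator
#'
#' Defaults define the study conditions the simulations run under: a
#' small two-chromosome genome with Beta-distributed per-kilobase GC and
#' a gene model realising every annotation class; a 200-haplotype panel
#' with block-structured LD (segment-mosaic model, within-segment
#' inheritance probability `rho = 0.95`); a GWAS table of 2400 SNP
#' records of which 1687 are genome-wide significant; peak sets with a
#' planted enrichment factor `lambda = 5` inside trait blocks covering 2%
#' of the genome; and projection scores drawn from the
#' 14.3% / 41.1% / 44.4% direct/indirect/nonconserved mixture with
#' tissue-specific functional-conservation rates of 0.44 (ectoderm) and
#' 0.10 (mesenchyme).
#'
#' @param ... Named overrides of the default sections, merged recursively
#'   (e.g. `sim_config(peaks = list(lambda = 1))`).
#' @return A nested named list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    genome = list(
      n_chrom = 2, chrom_length = 4e5, gc_shape1 = 42, gc_shape2 = 58,
      gc_window = 1000, genes_per_chrom = 12, gene_length = c(3000, 8000),
      n_exons = c(2, 5), utr5_length = 150, utr3_length = 300
    ),
    panel = list(
      n_haplotypes = 200, snp_spacing = 500, segment_length = 2e4,
      rho = 0.95, groups = c("EUR", "AFR")
    ),
    gwas = list(n_snps = 2400, frac_significant = 1687 / 2400),
    peaks = list(n_peaks = 500, width = 500, lambda = 5, block_fraction = 0.02),
    dars = list(
      n_dars = 400, width = 500,
      populations = c(ect1 = "ectoderm", ect2 = "ectoderm",
                      mes1 = "mesenchyme", mes2 = "mesenchyme")
    ),
    projections = list(
      proportions = c(direct = 0.143, indirect = 0.411, nonconserved = 0.444),
      func_rate = c(ectoderm = 0.44, mesenchyme = 0.10),
      identity_retention = 0.8,
      direct_min = 0.98, indirect_min = 0.84,
      bridges = c("human", "opossum")
    )
  )
  validate_sim_config(utils::modifyList(cfg, list(...)))
}

validate_sim_config <- function(cfg) {
  g <- cfg$genome
  if (!is_number(g$n_chrom) || g$n_chrom < 1) abort_config("genome$n_chrom must be >= 1")
  if (any(g$chrom_length <= 0)) abort_config("genome$chrom_length must be positive")
  p <- cfg$panel
  check_prob(p$rho, "panel$rho")
  if (!is_number(p$n_haplotypes) || p$n_haplotypes < 2 || p$n_haplotypes %% 2 != 0) {
    abort_config("panel$n_haplotypes must be an even number >= 2")
  }
  check_prob(cfg$gwas$frac_significant, "gwas$frac_significant")
  if (!is_number(cfg$peaks$lambda) || cfg$peaks$lambda < 0) {
    abort_config("peaks$lambda must be >= 0")
  }
  check_prob(cfg$peaks$block_fraction, "peaks$block_fraction")
  pr <- cfg$projections$proportions
  if (abs(sum(pr) - 1) > 0.01) {
    abort_config("projections$proportions must sum to 1")
  }
  for (nm in names(pr)) check_prob(pr[[nm]], paste0("projections$proportions$", nm))
  # tolerate rounded published-style proportions; renormalise exactly
  cfg$projections$proportions <- pr / sum(pr)
  check_prob(cfg$projections$identity_retention, "projections$identity_retention")
  p_cons <- sum(pr[c("direct", "indirect")])
  bad <- cfg$projections$func_rate > p_cons
  if (any(bad)) {
    abort_config(sprintf(
      "projections$func_rate cannot exceed the conserved proportion (%.3f)", p_cons
    ))
  }
  cfg
}

#' Simulate a genome with genes and heterogeneous GC
#'
#' Random sequence whose per-window GC is drawn from a Beta distribution,
#' with bases i.i.d. within each window given the window GC.  Genes are
#' placed uniformly without overlap, each with a TSS, exons, and 5'/3'
#' UTRs, so every annotation class is realizable.  A pure function of
#' (config, seed).
#'
#' @param cfg A [sim_config()] list (its `genome` section is used).
#' @param seed Integer seed.
#' @return A list: `layout` ([genome_layout()]), `genome`
#'   (`DNAStringSet`), `genes` (feature tibble as in
#'   [read_gene_features()]), `gc_windows` (per-window GC draws).
#' @export
simulate_genome <- function(cfg, seed = 1) {
  g <- cfg$genome
  lens <- rep_len(g$chrom_length, g$n_chrom)
  layout <- genome_layout(sprintf("chr%d", seq_len(g$n_chrom)), lens)
  with_seed(derive_seed(seed, "genome"), {
    seqs <- character(nrow(layout))
    gcw <- list()
    for (i in seq_len(nrow(layout))) {
      len <- layout$length[i]
      starts <- seq(0, len - 1, by = g$gc_window)
      widths <- pmin(starts + g$gc_window, len) - starts
      gc <- stats::rbeta(length(starts), g$gc_shape1, g$gc_shape2)
      chunks <- vapply(seq_along(starts), function(w) {
        paste(sample(c("A", "C", "G", "T"), widths[w], replace = TRUE,
                     prob = c((1 - gc[w]) / 2, gc[w] / 2, gc[w] / 2, (1 - gc[w]) / 2)),
              collapse = "")
      }, character(1))
      seqs[i] <- paste(chunks, collapse = "")
      gcw[[i]] <- tibble(chrom = layout$chrom[i], start = as.double(starts),
                         end = starts + widths, gc = gc)
    }
    genes <- simulate_gene_features(g, layout)
    list(
      layout = layout,
      genome = Biostrings::DNAStringSet(stats::setNames(seqs, layout$chrom)),
      genes = genes,
      gc_windows = dplyr::bind_rows(gcw)
    )
  })
}

# place non-overlapping genes and expand them into feature rows
simulate_gene_features <- function(g, layout) {
  rows <- list()
  gid <- 0L
  for (i in seq_len(nrow(layout))) {
    len <- layout$length[i]
    n_genes <- rep_len(g$genes_per_chrom, nrow(layout))[i]
    if (n_genes == 0) next
    if (n_genes * max(g$gene_length) > 0.8 * len) {
      abort_config("gene demand exceeds genome capacity")
    }
    p_start <- double(0)
    p_end <- double(0)
    tries <- 0
    while (length(p_start) < n_genes) {
      tries <- tries + 1
      if (tries > 200 * n_genes) abort_config("unable to place genes without overlap")
      glen <- round(stats::runif(1, g$gene_length[1], g$gene_length[2]))
      s <- floor(stats::runif(1, 0, len - glen))
      if (all(s + glen <= p_start | s >= p_end)) {
        p_start <- c(p_start, s)
        p_end <- c(p_end, s + glen)
      }
    }
    o <- order(p_start)
    placed <- tibble(chrom = layout$chrom[i], start = p_start[o], end = p_end[o])
    for (j in seq_len(nrow(placed))) {
      gid <- gid + 1L
      id <- sprintf("gene%03d", gid)
      strand <- sample(c("+", "-"), 1)
      s <- placed$start[j]
      e <- placed$end[j]
      n_ex <- sample(seq(g$n_exons[1], g$n_exons[2]), 1)
      # alternate exon/intron segments, first and last segments are exons
      n_seg <- 2 * n_ex - 1
      repeat {
        cuts <- sort(sample(seq(s + 1, e - 1), n_seg - 1))
        bounds <- c(s, cuts, e)
        if (all(diff(bounds) >= 50)) break
      }
      ex_idx <- seq(1, n_seg, by = 2)
      exons <- tibble(
        chrom = placed$chrom[j],
        start = bounds[ex_idx], end = bounds[ex_idx + 1],
        strand = strand, type = "exon", gene_id = id
      )
      first_ex <- exons[which.min(exons$start), ]
      last_ex <- exons[which.max(exons$start), ]
      if (strand == "+") {
        utr5 <- tibble(chrom = first_ex$chrom, start = first_ex$start,
                       end = first_ex$start + min(g$utr5_length, first_ex$end - first_ex$start),
                       strand = strand, type = "five_prime_UTR", gene_id = id)
        utr3 <- tibble(chrom = last_ex$chrom,
                       start = last_ex$end - min(g$utr3_length, last_ex$end - last_ex$start),
                       end = last_ex$end, strand = strand,
                       type = "three_prime_UTR", gene_id = id)
      } else {
        utr5 <- tibble(chrom = last_ex$chrom,
                       start = last_ex$end - min(g$utr5_length, last_ex$end - last_ex$start),
                       end = last_ex$end, strand = strand,
                       type = "five_prime_UTR", gene_id = id)
        utr3 <- tibble(chrom = first_ex$chrom, start = first_ex$start,
                       end = first_ex$start + min(g$utr3_length, first_ex$end - first_ex$start),
                       strand = strand, type = "three_prime_UTR", gene_id = id)
      }
      gene_rows <- tibble(
        chrom = placed$chrom[j], start = s, end = e, strand = strand,
        type = c("gene", "mRNA"), gene_id = id
      )
      rows[[length(rows) + 1]] <- dplyr::bind_rows(gene_rows, exons, utr5, utr3)
    }
  }
  if (length(rows) == 0) {
    return(tibble(chrom = character(), start = double(), end = double(),
                  strand = character(), type = character(), gene_id = character()))
  }
  dplyr::bind_rows(rows)
}

# shared variant positions and latent LD segments for all population groups
simulate_panel_sites <- function(p, layout, seed) {
  with_seed(derive_seed(seed, "sites"), {
    pos <- list()
    seg <- list()
    for (i in seq_len(nrow(layout))) {
      len <- layout$length[i]
      gaps <- stats::rexp(ceiling(2 * len / p$snp_spacing), rate = 1 / p$snp_spacing)
      pp <- unique(pmax(1, round(cumsum(gaps))))
      pp <- pp[pp <= len]
      pos[[i]] <- tibble(chrom = layout$chrom[i], pos = as.double(pp))
      cuts <- cumsum(stats::rexp(ceiling(3 * len / p$segment_length),
                                 rate = 1 / p$segment_length))
      cuts <- round(cuts[cuts < len])
      bounds <- unique(c(0, cuts, len))
      seg[[i]] <- tibble(
        chrom = layout$chrom[i],
        start = bounds[-length(bounds)], end = bounds[-1]
      )
    }
    seg <- dplyr::bind_rows(seg)
    seg$segment_id <- sprintf("seg%04d", seq_len(nrow(seg)))
    list(positions = dplyr::bind_rows(pos), segments = seg)
  })
}

#' Simulate haplotype panels with block-structured LD
#'
#' Segment-mosaic model: each chromosome is partitioned into latent LD
#' segments (exponential lengths, mean `panel$segment_length`).  Per
#' segment, two complementary ancestral haplotypes are drawn; each
#' present-day haplotype inherits one of them for the whole segment with
#' probability `rho` (orientation Bernoulli(1/2)) and otherwise draws
#' i.i.d. alleles.  Within a segment the expected r-squared between
#' segregating variants is approximately `rho^2`; across segment
#' boundaries it is approximately 0, so at the default `rho = 0.95` the
#' r-squared >= 0.8 block procedure recovers the latent segments.
#' Variant positions and segments are shared across population groups;
#' alleles are drawn independently per group.
#'
#' @param cfg A [sim_config()] list (its `panel` section is used).
#' @param layout A [genome_layout()].
#' @param seed Integer seed.
#' @param groups Population group labels (default from the config).
#' @return A list: `panels` -- `list(group -> list(chrom -> hap_panel))`
#'   -- and `segments`, the latent segment tibble (`chrom`, `start`,
#'   `end`, `segment_id`).
#' @export
simulate_panels <- function(cfg, layout, seed = 1, groups = cfg$panel$groups) {
  p <- cfg$panel
  sites <- simulate_panel_sites(p, layout, seed)
  panels <- lapply(stats::setNames(groups, groups), function(grp) {
    with_seed(derive_seed(seed, "alleles", grp), {
      per_chrom <- lapply(stats::setNames(layout$chrom, layout$chrom), function(ch) {
        pp <- sites$positions$pos[sites$positions$chrom == ch]
        seg <- sites$segments[sites$segments$chrom == ch, ]
        nh <- p$n_haplotypes
        m <- matrix(0L, nrow = nh, ncol = length(pp))
        for (k in seq_len(nrow(seg))) {
          j <- which(pp - 1 >= seg$start[k] & pp - 1 < seg$end[k])
          nj <- length(j)
          if (nj == 0) next
          f <- stats::rbinom(nj, 1, 0.5)
          inherit <- stats::rbinom(nh, 1, p$rho) == 1
          orient <- stats::rbinom(nh, 1, 0.5) == 1
          block <- matrix(stats::rbinom(nh * nj, 1, 0.5), nh, nj)
          if (any(inherit & orient)) {
            block[inherit & orient, ] <- matrix(f, sum(inherit & orient), nj, byrow = TRUE)
          }
          if (any(inherit & !orient)) {
            block[inherit & !orient, ] <- matrix(1L - f, sum(inherit & !orient), nj, byrow = TRUE)
          }
          m[, j] <- block
        }
        hap_panel(ch, pp, m)
      })
      per_chrom
    })
  })
  list(panels = panels, segments = sites$segments)
}

#' @rdname simulate_panels
#' @export
simulate_panel <- function(cfg, layout, seed = 1) {
  out <- simulate_panels(cfg, layout, seed, groups = cfg$panel$groups[1])
  list(panels = out$panels[[1]], segments = out$segments)
}

#' Choose trait blocks among the latent LD segments
#'
#' Randomly selects latent segments until they cover at least
#' `peaks$block_fraction` of the genome; these designated blocks carry
#' the planted peak enrichment and the significant GWAS SNPs.
#'
#' @param cfg A [sim_config()] list.
#' @param segments Latent segment tibble from [simulate_panels()].
#' @param layout A [genome_layout()].
#' @param seed Integer seed.
#' @return A tibble of trait-block intervals (a subset of `segments`).
#' @export
simulate_trait_blocks <- function(cfg, segments, layout, seed = 1) {
  target <- cfg$peaks$block_fraction * sum(layout$length)
  with_seed(derive_seed(seed, "trait_blocks"), {
    ord <- sample.int(nrow(segments))
    cum <- cumsum(segments$end[ord] - segments$start[ord])
    k <- which(cum >= target)
    take <- ord[seq_len(if (length(k) > 0) k[1] else length(ord))]
    out <- segments[sort(take), ]
    dplyr::arrange(out, .data$chrom, .data$start)
  })
}

#' Simulate a GWAS SNP table with planted significance counts
#'
#' Draws SNP records at panel variant positions (with replacement, as
#' several studies can report the same locus).  Exactly
#' `round(n_snps * frac_significant)` records receive p-values strictly
#' below 5e-8 and are placed inside the trait blocks; the remainder
#' receive non-significant p-values anywhere on the panel.  Group labels
#' are assigned round-robin over the configured populations.
#'
#' @param cfg A [sim_config()] list.
#' @param panels Output of [simulate_panels()] (positions are taken from
#'   the first group).
#' @param trait_blocks Trait-block intervals (or `NULL`: significant SNPs
#'   are placed anywhere).
#' @param seed Integer seed.
#' @return A SNP table tibble (`chrom`, `pos`, `id`, `p_value`, `group`).
#' @export
simulate_gwas <- function(cfg, panels, trait_blocks = NULL, seed = 1) {
  first_group <- panels$panels[[1]]
  sites <- dplyr::bind_rows(lapply(first_group, function(p) {
    tibble(chrom = p$chrom, pos = p$positions)
  }))
  n <- cfg$gwas$n_snps
  n_sig <- round(n * cfg$gwas$frac_significant)
  groups <- cfg$panel$groups
  log_thresh <- log10(5e-8)
  with_seed(derive_seed(seed, "gwas"), {
    sig_sites <- sites
    if (!is.null(trait_blocks) && nrow(trait_blocks) > 0) {
      inside <- overlaps_any(
        tibble(chrom = sites$chrom, start = sites$pos - 1, end = sites$pos),
        trait_blocks
      )
      if (any(inside)) sig_sites <- sites[inside, ]
    }
    si <- sample.int(nrow(sig_sites), n_sig, replace = TRUE)
    oi <- sample.int(nrow(sites), n - n_sig, replace = TRUE)
    out <- tibble(
      chrom = c(sig_sites$chrom[si], sites$chrom[oi]),
      pos = c(sig_sites$pos[si], sites$pos[oi]),
      id = sprintf("rs%06d", seq_len(n)),
      p_value = c(10^stats::runif(n_sig, -15, log_thresh - 1e-6),
                  10^stats::runif(n - n_sig, log_thresh + 1e-6, 0)),
      group = rep_len(groups, n)
    )
    out[sample.int(n), ]
  })
}

# sample k positions uniformly over the bases of an interval set
sample_positions_in <- function(intervals, k) {
  w <- intervals$end - intervals$start
  cw <- cumsum(w)
  u <- stats::runif(k, 0, cw[length(cw)])
  i <- findInterval(u, cw, left.open = TRUE) + 1L
  offs <- u - c(0, cw)[i]
  tibble(chrom = intervals$chrom[i],
         pos = pmin(floor(intervals$start[i] + offs), intervals$end[i] - 1))
}

#' Simulate peaks with planted enrichment inside trait blocks
#'
#' Peak start positions follow a two-level density: a baseline rate
#' outside the trait blocks and `lambda` times the baseline inside, so
#' the expected in-block fraction of peaks is
#' `lambda * b / (lambda * b + 1 - b)` for block genome-fraction `b`.
#' Peak widths come from the configured distribution (default: fixed
#' 500 bp, the background tile width); peaks are clipped at chromosome
#' ends.
#'
#' @param cfg A [sim_config()] list.
#' @param layout A [genome_layout()].
#' @param trait_blocks Trait-block intervals (may be empty: pure
#'   baseline).
#' @param seed Integer seed.
#' @return A peak tibble (`chrom`, `start`, `end`, `name`) with attribute
#'   `"n_in_block"`, the planted number of in-block peak starts.
#' @export
simulate_peaks <- function(cfg, layout, trait_blocks = NULL, seed = 1) {
  n <- cfg$peaks$n_peaks
  w <- cfg$peaks$width
  lambda <- cfg$peaks$lambda
  genome_all <- tibble(chrom = layout$chrom, start = 0, end = layout$length)
  blocks <- if (is.null(trait_blocks)) genome_all[0, ] else merge_intervals(trait_blocks)
  with_seed(derive_seed(seed, "peaks"), {
    if (nrow(blocks) == 0) {
      starts <- sample_positions_in(genome_all, n)
      n_in <- 0L
    } else {
      b_len <- sum(blocks$end - blocks$start)
      g_len <- sum(layout$length)
      p_in <- lambda * b_len / (lambda * b_len + (g_len - b_len))
      n_in <- stats::rbinom(1, n, p_in)
      outside <- dplyr::bind_rows(lapply(seq_len(nrow(layout)), function(i) {
        m <- blocks[blocks$chrom == layout$chrom[i], ]
        bounds_s <- c(0, m$end)
        bounds_e <- c(m$start, layout$length[i])
        keep <- bounds_e > bounds_s
        tibble(chrom = layout$chrom[i], start = bounds_s[keep], end = bounds_e[keep])
      }))
      starts <- dplyr::bind_rows(
        sample_positions_in(blocks, n_in),
        sample_positions_in(outside, n - n_in)
      )
    }
    len <- stats::setNames(layout$length, layout$chrom)
    out <- tibble(
      chrom = starts$chrom,
      start = pmin(starts$pos, len[starts$chrom] - 1),
      end = pmin(starts$pos + w, len[starts$chrom])
    )
    out <- out[sample.int(n), ]
    out$name <- sprintf("peak%05d", seq_len(n))
    attr(out, "n_in_block") <- n_in
    out
  })
}

#' Simulate DAR sets for two species
#'
#' Uniformly placed fixed-width regions with distinct coordinates, each
#' labelled with a cell population and its tissue class (ectoderm or
#' mesenchyme) from the configured population map.
#'
#' @param cfg A [sim_config()] list.
#' @param layout A [genome_layout()] for the species.
#' @param seed Integer seed.
#' @param species Label used in the seed substream (e.g. `"source"`).
#' @return A DAR tibble: `chrom`, `start`, `end`, `dar_id`, `population`,
#'   `tissue`.
#' @export
simulate_dars <- function(cfg, layout, seed = 1, species = "source") {
  n <- cfg$dars$n_dars
  w <- cfg$dars$width
  popmap <- cfg$dars$populations
  with_seed(derive_seed(seed, "dars", species), {
    per_chrom <- stats::rmultinom(1, n, layout$length / sum(layout$length))[, 1]
    out <- dplyr::bind_rows(lapply(seq_len(nrow(layout)), function(i) {
      k <- per_chrom[i]
      if (k == 0) return(NULL)
      # non-overlapping placement (DAR sets are disjoint peak calls):
      # sample width-spaced grid positions without replacement
      grid <- seq(0, layout$length[i] - w, by = w)
      if (k > length(grid)) abort_config("DAR demand exceeds genome capacity")
      starts <- sort(sample(grid, k, replace = FALSE))
      tibble(chrom = layout$chrom[i], start = as.double(starts),
             end = as.double(starts + w))
    }))
    out <- out[sample.int(nrow(out)), ]
    out$dar_id <- region_id(out)
    out$population <- sample(names(popmap), nrow(out), replace = TRUE)
    out$tissue <- unname(popmap[out$population])
    out
  })
}

#' Simulate projection scores and target coordinates for source DARs
#'
#' Class labels follow the configured proportions by largest-remainder
#' allocation (so planted proportions are exact up to rounding), with
#' scores uniform within each class band.  Conserved DARs receive target
#' coordinates; with tissue-dependent probability
#' `func_rate\[tissue\] / P(conserved)` the target overlaps a target-species
#' DAR (chosen same-tissue with probability `identity_retention`),
#' otherwise it lands in DAR-free target sequence.  Nonconserved DARs
#' carry no target.
#'
#' @param cfg A [sim_config()] list.
#' @param dars_source Source DAR tibble ([simulate_dars()]).
#' @param dars_target Target DAR tibble.
#' @param layout_target [genome_layout()] of the target species.
#' @param seed Integer seed.
#' @return A list: `projections` (projection table keyed by `region_id` =
#'   source `dar_id`) and `truth` (per-region planted `class`,
#'   `planted_hit`, `planted_same_tissue`).
#' @export
simulate_projections <- function(cfg, dars_source, dars_target, layout_target,
                                 seed = 1) {
  pj <- cfg$projections
  n <- nrow(dars_source)
  props <- pj$proportions[CONSERVATION_CLASSES]
  # largest-remainder allocation of class counts
  raw <- props * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  p_cons <- sum(props[c("direct", "indirect")])
  tgt_merged <- merge_intervals(dars_target)
  tgt_free <- dplyr::bind_rows(lapply(seq_len(nrow(layout_target)), function(i) {
    m <- tgt_merged[tgt_merged$chrom == layout_target$chrom[i], ]
    bs <- c(0, m$end)
    be <- c(m$start, layout_target$length[i])
    keep <- be - bs > cfg$dars$width + 2
    tibble(chrom = layout_target$chrom[i], start = bs[keep] + 1, end = be[keep] - cfg$dars$width - 1)
  }))
  with_seed(derive_seed(seed, "projections"), {
    classes <- sample(rep(CONSERVATION_CLASSES, times = cnt))
    score <- numeric(n)
    d <- classes == "direct"
    ind <- classes == "indirect"
    nc <- classes == "nonconserved"
    score[d] <- stats::runif(sum(d), pj$direct_min + 1e-6, 1)
    score[ind] <- stats::runif(sum(ind), pj$indirect_min + 1e-6, pj$direct_min)
    score[nc] <- stats::runif(sum(nc), 0, pj$indirect_min)
    conserved <- d | ind
    hit_prob <- pj$func_rate[dars_source$tissue] / p_cons
    hit <- conserved & stats::runif(n) < hit_prob
    t_chrom <- rep(NA_character_, n)
    t_start <- rep(NA_real_, n)
    t_end <- rep(NA_real_, n)
    same_tissue <- rep(NA, n)
    w <- cfg$dars$width
    len_t <- stats::setNames(layout_target$length, layout_target$chrom)
    for (i in which(hit)) {
      same <- stats::runif(1) < pj$identity_retention
      pool <- dars_target[
        if (same) dars_target$tissue == dars_source$tissue[i]
        else dars_target$tissue != dars_source$tissue[i], ]
      if (nrow(pool) == 0) pool <- dars_target
      dar <- pool[sample.int(nrow(pool), 1), ]
      # target roughly centred on the anchor DAR (jitter <= w/4), so the
      # anchor is always the best-overlapping target DAR
      s <- round(stats::runif(1, dar$start - w / 4, dar$start + w / 4))
      s <- max(0, min(s, len_t[dar$chrom] - w))
      if (s >= dar$end || s + w <= dar$start) s <- dar$start
      t_chrom[i] <- dar$chrom
      t_start[i] <- s
      t_end[i] <- s + w
      same_tissue[i] <- dar$tissue == dars_source$tissue[i]
    }
    miss <- which(conserved & !hit)
    if (length(miss) > 0) {
      if (nrow(tgt_free) == 0) abort_data("no DAR-free target sequence to place misses")
      ps <- sample_positions_in(tgt_free, length(miss))
      t_chrom[miss] <- ps$chrom
      t_start[miss] <- ps$pos
      t_end[miss] <- ps$pos + w
    }
    projections <- tibble(
      region_id = dars_source$dar_id,
      chrom = dars_source$chrom, start = dars_source$start, end = dars_source$end,
      score = score,
      target_chrom = t_chrom, target_start = t_start, target_end = t_end,
      bridge = ifelse(classes == "indirect",
                      sample(pj$bridges, n, replace = TRUE), NA_character_)
    )
    truth <- tibble(
      region_id = dars_source$dar_id,
      class = classes,
      planted_hit = unname(hit),
      planted_same_tissue = same_tissue
    )
    list(projections = projections, truth = truth)
  })
}

#' Simulate every pipeline input
#'
#' Runs all generators under named substreams of one master seed and,
#' optionally, writes the standard input files (FASTA, GFF3, one phased
#' VCF per group, TSV/BED tables, and sidecar truth tables) to a
#' directory.
#'
#' @param cfg A [sim_config()] list.
#' @param seed Master seed.
#' @param out_dir Optional output directory (created if needed).
#' @return A list with `layout`, `genome`, `genes`, `gc_windows`,
#'   `panels`, `segments`, `trait_blocks`, `gwas`, `peaks`,
#'   `dars_source`, `dars_target`, `projections`, `truth`, and (when
#'   written) `files`.
#' @export
simulate_all <- function(cfg = sim_config(), seed = 1, out_dir = NULL) {
  cfg <- validate_sim_config(cfg)
  gen <- simulate_genome(cfg, seed)
  pan <- simulate_panels(cfg, gen$layout, seed)
  blocks <- simulate_trait_blocks(cfg, pan$segments, gen$layout, seed)
  gwas <- simulate_gwas(cfg, pan, blocks, seed)
  peaks <- simulate_peaks(cfg, gen$layout, blocks, seed)
  dars_source <- simulate_dars(cfg, gen$layout, seed, "source")
  dars_target <- simulate_dars(cfg, gen$layout, seed, "target")
  proj <- simulate_projections(cfg, dars_source, dars_target, gen$layout, seed)
  out <- list(
    layout = gen$layout, genome = gen$genome, genes = gen$genes,
    gc_windows = gen$gc_windows, panels = pan$panels, segments = pan$segments,
    trait_blocks = blocks, gwas = gwas, peaks = peaks,
    dars_source = dars_source, dars_target = dars_target,
    projections = proj$projections, truth = proj$truth
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(out_dir, x)
    Biostrings::writeXStringSet(gen$genome, fp("genome.fa"))
    write_gene_features(gen$genes, fp("genes.gff3"))
    for (grp in names(pan$panels)) {
      write_phased_vcf(unname(pan$panels[[grp]]), fp(sprintf("panel_%s.vcf", grp)))
    }
    write_snp_table(gwas, fp("gwas.tsv"))
    write_bed(peaks, fp("peaks.bed"))
    dar_bed <- function(d) {
      stats::setNames(d[, c("chrom", "start", "end", "population")],
                      c("chrom", "start", "end", "name"))
    }
    write_bed(dar_bed(dars_source), fp("dars_source.bed"))
    write_bed(dar_bed(dars_target), fp("dars_target.bed"))
    write_projection_table(proj$projections, fp("projections.tsv"))
    write_bed(blocks[, c("chrom", "start", "end")], fp("trait_blocks.bed"))
    readr::write_tsv(pan$segments, fp("segments.tsv"))
    readr::write_tsv(proj$truth, fp("truth_projections.tsv"))
    truth_counts <- tibble(
      key = c("n_gwas_snps", "n_significant", "n_peaks", "n_peaks_in_block",
              "trait_block_bp", "genome_bp"),
      value = c(nrow(gwas), sum(gwas$p_value < 5e-8), nrow(peaks),
                attr(peaks, "n_in_block"), covered_bases(blocks),
                sum(gen$layout$length))
    )
    readr::write_tsv(truth_counts, fp("truth.tsv"))
    out$files <- list.files(out_dir, full.names = TRUE)
  }
  out
}
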