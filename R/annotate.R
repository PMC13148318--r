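ANNOTATION_CLASSES <- c("promoter", "utr5", "utr3", "exon", "intron", "intergenic")

#' Tile a genome into fixed-width segments
#'
#' Per chromosome, consecutive non-overlapping half-open tiles
#' `[0, w), [w, 2w), ...`; a terminal partial tile is kept, with its true
#' (smaller) width recorded.  Tiles partition each chromosome exactly.
#'
#' @param layout A [genome_layout()] tibble.
#' @param tile_width Tile width in bp (default 500, the background unit of
#'   the matched sampler).
#' @return A tibble with `chrom`, `start`, `end`, `width`.
#' @examples
#' tile_genome(genome_layout("chr1", 1250), 500)
#' @export
tile_genome <- function(layout, tile_width = 500) {
  if (!is_number(tile_width) || tile_width <= 0) {
    abort_config("`tile_width` must be a positive number")
  }
  out <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    starts <- seq(0, len - 1, by = tile_width)
    tibble(
      chrom = layout$chrom[i],
      start = as.double(starts),
      end = pmin(starts + tile_width, len)
    )
  })
  out <- dplyr::bind_rows(out)
  out$width <- out$end - out$start
  out
}

#' GC content of intervals
#'
#' `(G + C) / (A + C + G + T)` over each interval, case-insensitive;
#' ambiguous bases (N etc.) are excluded from both numerator and
#' denominator.  An all-ambiguous interval has undefined GC (`NA`).
#'
#' @param x An interval table.
#' @param genome A named `DNAStringSet` covering the intervals.
#' @return Numeric vector of GC fractions (or `NA`) along the rows of `x`.
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chr1 = "ATGCNN"))
#' gc_content(data.frame(chrom = "chr1", start = 0, end = 6), genome)  # 0.5
#' @export
gc_content <- function(x, genome) {
  x <- as_intervals(x)
  out <- rep(NA_real_, nrow(x))
  for (ch in unique(x$chrom)) {
    if (!ch %in% names(genome)) {
      abort_data(sprintf("chromosome %s not present in the genome sequence", ch))
    }
    seq <- genome[[ch]]
    idx <- which(x$chrom == ch)
    if (any(x$end[idx] > length(seq))) {
      abort_data(sprintf("interval extends beyond the end of %s", ch))
    }
    v <- Biostrings::Views(seq, start = x$start[idx] + 1L, end = x$end[idx])
    counts <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    denom <- rowSums(counts)
    gc <- (counts[, "G"] + counts[, "C"]) / denom
    gc[denom == 0] <- NA_real_
    out[idx] <- gc
  }
  out
}

#' Annotation feature intervals from a gene model
#'
#' Expands a gene-feature table into per-class interval sets used by
#' [annotate_intervals()]: strand-aware promoter windows around each TSS,
#' 5'/3' UTRs, exons, and introns (transcript span minus exons).
#'
#' @param features A gene-feature tibble (see [read_gene_features()]).
#' @param promoter_up,promoter_down Promoter window upstream/downstream of
#'   the TSS in bp (defaults 2000 and 200), applied strand-aware.
#' @param layout Optional [genome_layout()] used to clip promoter windows
#'   at chromosome ends.
#' @return A tibble with `class`, `chrom`, `start`, `end`.
#' @export
annotation_features <- function(features, promoter_up = 2000, promoter_down = 200,
                                layout = NULL) {
  f <- as_tibble(features)
  tx <- f[f$type %in% c("mRNA", "gene"), ]
  tx <- tx[!duplicated(tx$gene_id), ]
  exons <- f[f$type == "exon", ]
  out <- list()
  if (nrow(tx) > 0) {
    plus <- tx$strand != "-"
    # 0-based position of the first transcribed base
    tss <- ifelse(plus, tx$start, tx$end - 1)
    prom <- tibble(
      class = "promoter",
      chrom = tx$chrom,
      start = ifelse(plus, tss - promoter_up, tss - promoter_down + 1),
      end = ifelse(plus, tss + promoter_down, tss + promoter_up + 1)
    )
    prom$start <- pmax(prom$start, 0)
    if (!is.null(layout)) {
      len <- stats::setNames(layout$length, layout$chrom)
      prom$end <- pmin(prom$end, len[prom$chrom])
    }
    out$promoter <- prom[prom$end > prom$start, ]
  }
  add_class <- function(d, class) {
    d <- as_tibble(d[, c("chrom", "start", "end")])
    if (nrow(d) == 0) return(NULL)
    d$class <- class
    d[, c("class", "chrom", "start", "end")]
  }
  out$utr5 <- add_class(f[f$type == "five_prime_UTR", ], "utr5")
  out$utr3 <- add_class(f[f$type == "three_prime_UTR", ], "utr3")
  out$exon <- add_class(exons, "exon")
  # introns: per gene, transcript span minus exon union
  if (nrow(tx) > 0 && nrow(exons) > 0) {
    introns <- lapply(seq_len(nrow(tx)), function(i) {
      ex <- exons[exons$gene_id == tx$gene_id[i], ]
      if (nrow(ex) == 0) {
        return(tibble(chrom = tx$chrom[i], start = tx$start[i], end = tx$end[i]))
      }
      m <- merge_intervals(ex)
      gaps_start <- c(tx$start[i], m$end)
      gaps_end <- c(m$start, tx$end[i])
      keep <- gaps_end > gaps_start
      tibble(chrom = tx$chrom[i], start = gaps_start[keep], end = gaps_end[keep])
    })
    introns <- dplyr::bind_rows(introns)
    out$intron <- add_class(introns, "intron")
  }
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble(class = character(), chrom = character(),
                  start = double(), end = double())
  }
  out
}

#' Assign one annotation class per interval
#'
#' Any-overlap with a fixed priority: an interval takes the
#' highest-priority class whose features it overlaps by at least one base,
#' with priority `promoter > utr5 > utr3 > exon > intron > intergenic`.
#' Intervals overlapping no feature are `intergenic`.
#'
#' @param x An interval table.
#' @param features Either a gene-feature tibble (expanded internally via
#'   [annotation_features()]) or a pre-expanded class-interval tibble.
#' @param promoter_up,promoter_down,layout Passed to
#'   [annotation_features()] when `features` is a gene-feature tibble.
#' @return `x` with an added `annotation` factor column.
#' @export
annotate_intervals <- function(x, features, promoter_up = 2000,
                               promoter_down = 200, layout = NULL) {
  x <- as_intervals(x)
  if (!"class" %in% names(features)) {
    features <- annotation_features(features, promoter_up, promoter_down, layout)
  }
  ann <- rep(NA_character_, nrow(x))
  for (cl in setdiff(ANNOTATION_CLASSES, "intergenic")) {
    fs <- features[features$class == cl, ]
    if (nrow(fs) == 0) next
    todo <- is.na(ann)
    if (!any(todo)) break
    hit <- overlaps_any(x[todo, ], fs)
    ann[which(todo)[hit]] <- cl
  }
  ann[is.na(ann)] <- "intergenic"
  x$annotation <- factor(ann, levels = ANNOTATION_CLASSES)
  x
}

#' Assign sampling strata from GC and annotation
#'
#' The stratum is the pair (GC bin, annotation class) with `gc_bins`
#' equal-width bins on \[0, 1\]; GC exactly 1 falls in the top bin.
#' Undefined GC yields the excluded sentinel stratum (`NA`).
#'
#' @param gc Numeric GC fractions (may contain `NA`).
#' @param annotation Annotation class vector.
#' @param gc_bins Number of equal-width GC bins (default 10).
#' @return Character stratum ids of the form `"gc03|exon"` (`NA` for
#'   undefined GC).
#' @examples
#' assign_stratum(c(0.42, 1), c("exon", "promoter"))
#' @export
assign_stratum <- function(gc, annotation, gc_bins = 10) {
  if (!is_number(gc_bins) || gc_bins < 1) abort_config("`gc_bins` must be >= 1")
  if (any(!is.na(gc) & (gc < 0 | gc > 1))) abort_data("gc fractions must lie in [0, 1]")
  bin <- pmin(floor(gc * gc_bins), gc_bins - 1) + 1L
  out <- sprintf("gc%02d|%s", bin, as.character(annotation))
  out[is.na(gc)] <- NA_character_
  out
}

#' Annotate regions with GC, annotation class, and stratum
#'
#' Convenience wrapper chaining [gc_content()], [annotate_intervals()] and
#' [assign_stratum()]: the standard preparation of both foreground peaks
#' and background tiles for matched sampling.
#'
#' @param x An interval table (tiles or peaks).
#' @param genome A named `DNAStringSet`.
#' @param features Gene features (see [annotate_intervals()]).
#' @param gc_bins Number of GC bins (default 10).
#' @param promoter_up,promoter_down Promoter window (bp).
#' @return `x` with added `gc`, `annotation`, `stratum` columns.
#' @export
annotate_regions <- function(x, genome, features, gc_bins = 10,
                             promoter_up = 2000, promoter_down = 200) {
  layout <- genome_layout(names(genome), Biostrings::width(genome))
  x <- annotate_intervals(as_intervals(x), features, promoter_up, promoter_down, layout)
  x$gc <- gc_content(x, genome)
  x$stratum <- assign_stratum(x$gc, x$annotation, gc_bins)
  x[, c(setdiff(names(x), c("gc", "annotation", "stratum")),
        "gc", "annotation", "stratum")]
}
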