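#' Overlap frequency of peaks with LD blocks
#'
#' The number of peaks intersecting, partially or fully, any block; each
#' peak is counted at most once, so the statistic is invariant to merging
#' or splitting the blocks.
#'
#' @param peaks,blocks Interval tables.
#' @return A single integer.
#' @export
overlap_frequency <- function(peaks, blocks) {
  count_overlapping(peaks, blocks)
}

#' Peak density within LD blocks
#'
#' Overlapping-peak count per megabase of merged block length (the
#' default), or, with `mode = "bp_ratio"`, the fraction of merged-block
#' bases covered by peaks.  Blocks are merged before the length
#' computation, so duplicated or split blocks leave the density unchanged.
#'
#' @param peaks,blocks Interval tables.
#' @param mode `"count_per_mb"` (default) or `"bp_ratio"`.
#' @return A non-negative number.
#' @examples
#' peaks <- data.frame(chrom = "chr1", start = (0:9) * 1000, end = (0:9) * 1000 + 500)
#' blocks <- data.frame(chrom = "chr1", start = 0, end = 2e6)
#' peak_density(peaks, blocks)  # 5 peaks per Mb
#' @export
peak_density <- function(peaks, blocks, mode = c("count_per_mb", "bp_ratio")) {
  mode <- match.arg(mode)
  m <- merge_intervals(blocks)
  total <- sum(m$end - m$start)
  if (total <= 0) abort_data("blocks have zero total length")
  if (mode == "count_per_mb") {
    overlap_frequency(peaks, m) / (total / 1e6)
  } else {
    p <- merge_intervals(peaks)
    inter <- 0
    for (ch in unique(m$chrom)) {
      pm <- p[p$chrom == ch, ]
      mm <- m[m$chrom == ch, ]
      if (nrow(pm) == 0) next
      for (i in seq_len(nrow(mm))) {
        inter <- inter + sum(pmax(0, pmin(pm$end, mm$end[i]) - pmax(pm$start, mm$start[i])))
      }
    }
    inter / total
  }
}

#' Empirical permutation p-value
#'
#' The proportion of background (null) statistics equal to or greater
#' than the observed value: `p = #\{null >= observed\} / N`, with no
#' add-one correction, so attainable values are `0, 1/N, ..., 1`.  A
#' reported 0 is accompanied by the resolution bound `< 1/N` in printed
#' summaries.
#'
#' @param observed Observed statistic.
#' @param null_values Vector of the statistic on the background sets.
#' @return A number in \[0, 1\].
#' @examples
#' empirical_p(10, c(1:10))   # the maximum null ties: 1/10
#' empirical_p(11, c(1:10))   # 0, reported as "< 0.1"
#' @export
empirical_p <- function(observed, null_values) {
  if (length(null_values) == 0) abort_data("null_values must be non-empty")
  mean(null_values >= observed)
}

p_label <- function(p, n) {
  if (p == 0) sprintf("< %s", format(1 / n)) else format(p)
}

#' Peak enrichment in LD blocks against matched background sets
#'
#' Computes both enrichment statistics -- overlap frequency and peak
#' density -- on the observed peaks and on every background set against
#' the same blocks, with one-sided (enrichment-direction) empirical
#' p-values and fold estimates (`observed / mean(null)`).
#'
#' @param peaks Observed peak intervals.
#' @param blocks LD-block intervals.
#' @param background_sets Background sets: the object returned by
#'   [sample_background()], its long `sets` tibble (with a `set` column),
#'   or a list of interval tables.
#' @param density_mode Passed to [peak_density()].
#' @return A `cre_enrichment` object: a list with `results` (one row per
#'   statistic: `statistic`, `observed`, `null_mean`, `null_sd`, `fold`,
#'   `empirical_p`, `p_label`, `n_sets`) and `null` (per-set statistics).
#'   Supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
run_enrichment <- function(peaks, blocks, background_sets,
                           density_mode = c("count_per_mb", "bp_ratio")) {
  density_mode <- match.arg(density_mode)
  peaks <- as_intervals(peaks, "peaks")
  m <- merge_intervals(blocks)
  if (nrow(m) == 0) abort_data("no blocks supplied")
  if (is.list(background_sets) && !is.data.frame(background_sets) &&
      !is.null(background_sets$sets)) {
    background_sets <- background_sets$sets
  }
  if (is.data.frame(background_sets)) {
    if (!"set" %in% names(background_sets)) {
      abort_data("a background-set tibble must have a `set` column")
    }
    background_sets <- split(
      as_intervals(background_sets[, c("chrom", "start", "end")],
                   "background_sets"),
      background_sets$set
    )
  }
  n_sets <- length(background_sets)
  if (n_sets == 0) abort_data("at least one background set is required")
  total_mb <- sum(m$end - m$start) / 1e6
  stat_of <- function(x) {
    cnt <- sum(overlaps_any_merged(x, m))
    c(overlap_frequency = cnt,
      peak_density = if (density_mode == "count_per_mb") cnt / total_mb
                     else peak_density(x, m, "bp_ratio"))
  }
  obs <- stat_of(peaks)
  nulls <- vapply(background_sets, stat_of, numeric(2))
  null_tbl <- tibble(
    set = seq_len(n_sets),
    overlap_frequency = nulls["overlap_frequency", ],
    peak_density = nulls["peak_density", ]
  )
  results <- dplyr::bind_rows(lapply(
    c("overlap_frequency", "peak_density"),
    function(s) {
      nv <- nulls[s, ]
      p <- empirical_p(obs[[s]], nv)
      mu <- mean(nv)
      tibble(
        statistic = s, observed = unname(obs[[s]]), null_mean = mu,
        null_sd = stats::sd(nv),
        fold = if (mu > 0) unname(obs[[s]]) / mu else NA_real_,
        empirical_p = p, p_label = p_label(p, n_sets),
        n_sets = n_sets
      )
    }
  ))
  structure(list(results = results, null = null_tbl), class = "cre_enrichment")
}

#' @export
print.cre_enrichment <- function(x, ...) {
  cat(sprintf("<cre_enrichment> %d background sets\n", x$results$n_sets[1]))
  r <- x$results
  for (i in seq_len(nrow(r))) {
    cat(sprintf(
      "  %-18s observed %.4g  null %.4g +/- %.3g  fold %.3g  empirical P %s\n",
      r$statistic[i], r$observed[i], r$null_mean[i], r$null_sd[i],
      r$fold[i], r$p_label[i]
    ))
  }
  invisible(x)
}
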