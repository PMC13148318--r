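#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an enrichment result
#'
#' @param x A `cre_enrichment` object from [run_enrichment()].
#' @param ... Unused.
#' @return One row per statistic: observed value, null mean/sd, fold,
#'   empirical p.
#' @method tidy cre_enrichment
#' @export
tidy.cre_enrichment <- function(x, ...) {
  x$results
}

#' One-row summary of an enrichment result
#'
#' @param x A `cre_enrichment` object.
#' @param ... Unused.
#' @return A one-row tibble with both statistics' folds and p-values.
#' @method glance cre_enrichment
#' @export
glance.cre_enrichment <- function(x, ...) {
  r <- x$results
  tibble(
    n_sets = r$n_sets[1],
    overlap_observed = r$observed[r$statistic == "overlap_frequency"],
    overlap_fold = r$fold[r$statistic == "overlap_frequency"],
    overlap_p = r$empirical_p[r$statistic == "overlap_frequency"],
    density_observed = r$observed[r$statistic == "peak_density"],
    density_fold = r$fold[r$statistic == "peak_density"],
    density_p = r$empirical_p[r$statistic == "peak_density"]
  )
}

#' Null-distribution plot for an enrichment result
#'
#' Histograms of the background-set statistics with the observed value
#' marked, one facet per statistic.
#'
#' @param object A `cre_enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cre_enrichment
#' @export
autoplot.cre_enrichment <- function(object, ...) {
  null_long <- tidyr::pivot_longer(object$null, -"set",
                                   names_to = "statistic", values_to = "value")
  obs <- object$results[, c("statistic", "observed", "p_label")]
  ggplot2::ggplot(null_long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey35") +
    ggplot2::geom_vline(data = obs, ggplot2::aes(xintercept = .data$observed),
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(
      x = "statistic on matched background sets",
      y = "background sets",
      title = "Observed enrichment vs matched background",
      subtitle = paste(sprintf("%s: empirical P %s", obs$statistic, obs$p_label),
                       collapse = "; ")
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of conservation classes
#'
#' @param per_dar Output of [functional_conservation()] (or any tibble
#'   with a `class` column).
#' @return A ggplot object.
#' @export
plot_conservation_classes <- function(per_dar) {
  d <- dplyr::count(as_tibble(per_dar), .data$class)
  d$fraction <- d$n / sum(d$n)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "regions",
                  title = "Cross-species conservation classes") +
    ggplot2::theme_minimal()
}
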