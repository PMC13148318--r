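CONSERVATION_CLASSES <- c("direct", "indirect", "nonconserved")

#' Classify projection scores into conservation classes
#'
#' Synteny projection scores are classified as directly conserved
#' (`score > direct_min`), indirectly conserved
#' (`direct_min >= score > indirect_min`) or nonconserved
#' (`score <= indirect_min`).  Exact-boundary scores fall in the lower
#' class, consistent with the strict inequalities of the thresholds; the
#' classes partition \[0, 1\] and the mapping is monotone in the score.
#'
#' @param score Numeric projection scores in \[0, 1\].
#' @param direct_min Direct-conservation threshold (default 0.98).
#' @param indirect_min Indirect-conservation threshold (default 0.84).
#' @return A factor with levels `direct`, `indirect`, `nonconserved`.
#' @examples
#' classify_conservation(c(0.99, 0.9, 0.84))
#' @export
classify_conservation <- function(score, direct_min = 0.98, indirect_min = 0.84) {
  if (any(is.na(score) | score < 0 | score > 1)) {
    abort_data("projection scores must lie in [0, 1]")
  }
  if (indirect_min >= direct_min) {
    abort_config("`indirect_min` must be below `direct_min`")
  }
  out <- ifelse(score > direct_min, "direct",
                ifelse(score > indirect_min, "indirect", "nonconserved"))
  factor(out, levels = CONSERVATION_CLASSES)
}

#' Add conservation classes to a projection table
#'
#' @param projections A projection table (see [read_projection_table()]).
#' @param direct_min,indirect_min Thresholds, as in
#'   [classify_conservation()].
#' @return The table with an added `class` factor column.
#' @export
classify_projections <- function(projections, direct_min = 0.98, indirect_min = 0.84) {
  projections <- as_tibble(projections)
  projections$class <- classify_conservation(projections$score, direct_min, indirect_min)
  projections
}

#' Call functional conservation of DARs across species
#'
#' A source differentially accessible region (DAR) is functionally
#' conserved iff (i) its projection is conserved (direct or indirect),
#' (ii) the projection carries target coordinates, and (iii) the target
#' interval overlaps at least one base of a DAR in the target species --
#' irrespective of cell-type correspondence.  The conservation gate is
#' applied first: a nonconserved projection never yields a call, even if
#' its coordinates happen to overlap a target DAR.  Source DARs without a
#' projection record are counted as nonconserved (logged).
#'
#' The best-overlapping target DAR (largest overlap, ties to the leftmost
#' target) is recorded for identity-retention analysis.
#'
#' @param dars_source Source-species DAR table: intervals plus
#'   `population` and `tissue` columns (see [simulate_dars()] for the
#'   expected shape); row ids are taken from a `dar_id` column or derived
#'   from coordinates.
#' @param projections Projection table keyed by `region_id` matching the
#'   source DAR ids.
#' @param dars_target Target-species DAR table (same shape).
#' @param direct_min,indirect_min Classification thresholds.
#' @return Per-DAR tibble: source columns plus `class`, `has_target`,
#'   `target_hit`, `functionally_conserved`, and matched-target columns
#'   (`match_population`, `match_tissue`, `same_tissue`).
#' @export
functional_conservation <- function(dars_source, projections, dars_target,
                                    direct_min = 0.98, indirect_min = 0.84) {
  src <- as_intervals(dars_source, "dars_source")
  tgt <- as_intervals(dars_target, "dars_target")
  if (!"dar_id" %in% names(src)) src$dar_id <- region_id(src)
  proj <- classify_projections(as_tibble(projections), direct_min, indirect_min)
  idx <- match(src$dar_id, proj$region_id)
  n_missing <- sum(is.na(idx))
  if (n_missing > 0) {
    inform(sprintf(
      "functional_conservation: %d source DAR(s) without a projection record; counted as nonconserved",
      n_missing
    ))
  }
  src$class <- factor(
    ifelse(is.na(idx), "nonconserved", as.character(proj$class[idx])),
    levels = CONSERVATION_CLASSES
  )
  src$score <- proj$score[idx]
  t_chrom <- proj$target_chrom[idx]
  t_start <- proj$target_start[idx]
  t_end <- proj$target_end[idx]
  src$has_target <- !is.na(t_chrom) & !is.na(t_start) & !is.na(t_end)
  src$target_hit <- FALSE
  src$match_population <- NA_character_
  src$match_tissue <- NA_character_
  conserved <- src$class %in% c("direct", "indirect")
  cand <- which(conserved & src$has_target)
  if (length(cand) > 0 && nrow(tgt) > 0) {
    for (i in cand) {
      same <- tgt$chrom == t_chrom[i] & tgt$start < t_end[i] & tgt$end > t_start[i]
      if (!any(same)) next
      hits <- tgt[same, ]
      ov <- pmin(hits$end, t_end[i]) - pmax(hits$start, t_start[i])
      best <- order(-ov, hits$chrom, hits$start)[1]
      src$target_hit[i] <- TRUE
      if ("population" %in% names(hits)) {
        src$match_population[i] <- as.character(hits$population[best])
      }
      if ("tissue" %in% names(hits)) {
        src$match_tissue[i] <- as.character(hits$tissue[best])
      }
    }
  }
  src$functionally_conserved <- conserved & src$has_target & src$target_hit
  if ("tissue" %in% names(src)) {
    src$same_tissue <- ifelse(src$functionally_conserved,
                              src$match_tissue == src$tissue, NA)
  }
  src
}

#' Per-population conservation summary
#'
#' @param per_dar Output of [functional_conservation()].
#' @param by Grouping column (default `population`).
#' @return A tibble of counts and rates per group.
#' @export
conservation_summary <- function(per_dar, by = "population") {
  dplyr::summarise(
    dplyr::group_by(as_tibble(per_dar), dplyr::across(dplyr::all_of(by))),
    n = dplyr::n(),
    n_conserved = sum(.data$functionally_conserved),
    rate = .data$n_conserved / .data$n,
    .groups = "drop"
  )
}

#' Cell-type identity retention of conserved DARs
#'
#' Among functionally conserved source DARs, the fraction whose
#' best-overlapping target DAR shares the source tissue class.
#'
#' @param per_dar Output of [functional_conservation()].
#' @return A number in \[0, 1\], or `NA` (with a message) when no DAR is
#'   functionally conserved.
#' @export
identity_retention <- function(per_dar) {
  per_dar <- as_tibble(per_dar)
  fc <- per_dar[per_dar$functionally_conserved, ]
  if (nrow(fc) == 0) {
    inform("identity_retention: no functionally conserved DARs; not applicable")
    return(NA_real_)
  }
  mean(fc$match_tissue == fc$tissue)
}

#' Ectoderm vs mesenchyme conservation-rate ratio
#'
#' The ratio of per-tissue functional-conservation rates,
#' `(conserved/total in ectoderm) / (conserved/total in mesenchyme)`,
#' with a two-sided Fisher exact test on the 2x2 conserved-by-tissue
#' table.  A zero mesenchyme rate gives an infinite ratio (the table is
#' still attached).
#'
#' @param per_dar Output of [functional_conservation()] with a `tissue`
#'   column using the labels `ectoderm` and `mesenchyme`.
#' @return A one-row tibble: `ratio`, `p_value`, and the four cell counts
#'   (`ect_conserved`, `ect_total`, `mes_conserved`, `mes_total`); the
#'   2x2 table is attached as attribute `"table"`.
#' @examples
#' d <- tibble::tibble(
#'   chrom = "chr1", start = 0, end = 1,
#'   tissue = rep(c("ectoderm", "mesenchyme"), each = 100),
#'   functionally_conserved = c(rep(TRUE, 44), rep(FALSE, 56),
#'                              rep(TRUE, 10), rep(FALSE, 90))
#' )
#' tissue_rate_ratio(d)  # ratio 4.4
#' @export
tissue_rate_ratio <- function(per_dar) {
  per_dar <- as_tibble(per_dar)
  if (!all(c("tissue", "functionally_conserved") %in% names(per_dar))) {
    abort_data("per_dar must carry `tissue` and `functionally_conserved` columns")
  }
  ect <- per_dar$tissue == "ectoderm"
  mes <- per_dar$tissue == "mesenchyme"
  if (!any(ect) || !any(mes)) {
    abort_data("both tissue classes (ectoderm, mesenchyme) must be represented")
  }
  tab <- matrix(
    c(sum(per_dar$functionally_conserved[ect]), sum(!per_dar$functionally_conserved[ect]),
      sum(per_dar$functionally_conserved[mes]), sum(!per_dar$functionally_conserved[mes])),
    nrow = 2, dimnames = list(c("conserved", "not"), c("ectoderm", "mesenchyme"))
  )
  rate_e <- tab[1, 1] / sum(tab[, 1])
  rate_m <- tab[1, 2] / sum(tab[, 2])
  ratio <- if (rate_m == 0) Inf else rate_e / rate_m
  p <- stats::fisher.test(tab)$p.value
  out <- tibble(
    ratio = ratio, p_value = p,
    ect_conserved = tab[1, 1], ect_total = sum(tab[, 1]),
    mes_conserved = tab[1, 2], mes_total = sum(tab[, 2])
  )
  attr(out, "table") <- tab
  out
}
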