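#' Build the per-stratum background pool
#'
#' Groups annotated genome tiles by stratum and, by default, removes
#' tiles overlapping any foreground peak so the null cannot contain the
#' signal itself.  Tiles with undefined GC (sentinel stratum) are
#' excluded and counted.
#'
#' @param tiles Annotated tiles (see [annotate_regions()]); must carry a
#'   `stratum` column.
#' @param foreground Foreground peak intervals.
#' @param exclude_overlapping Drop tiles overlapping the foreground
#'   (default `TRUE`).
#' @return A tibble of eligible tiles with an `exclusion` attribute
#'   (named counts of tiles dropped by reason).
#' @export
build_pool <- function(tiles, foreground, exclude_overlapping = TRUE) {
  tiles <- as_tibble(tiles)
  if (!"stratum" %in% names(tiles)) {
    abort_data("tiles must be annotated with a `stratum` column (see annotate_regions())")
  }
  n0 <- nrow(tiles)
  undefined <- is.na(tiles$stratum)
  tiles <- tiles[!undefined, ]
  n_overlap <- 0L
  if (exclude_overlapping && nrow(foreground) > 0 && nrow(tiles) > 0) {
    hit <- overlaps_any(tiles, foreground)
    n_overlap <- sum(hit)
    tiles <- tiles[!hit, ]
  }
  attr(tiles, "exclusion") <- c(undefined_gc = sum(undefined),
                                foreground_overlap = n_overlap)
  tiles
}

# candidate strata for a depleted stratum, in deterministic fallback order:
# first the same annotation at increasing GC-bin distance (lower bin wins
# ties), then the same GC bin at increasing annotation-priority distance,
# then everything else by (annotation distance, bin distance).
fallback_order <- function(stratum, all_strata, gc_bins) {
  parse <- function(s) {
    m <- regmatches(s, regexec("^gc([0-9]+)\\|(.+)$", s))
    list(bin = as.integer(vapply(m, `[[`, character(1), 2)),
         ann = vapply(m, `[[`, character(1), 3))
  }
  s0 <- parse(stratum)
  ss <- parse(all_strata)
  bin_d <- abs(ss$bin - s0$bin)
  ann_d <- abs(match(ss$ann, ANNOTATION_CLASSES) - match(s0$ann, ANNOTATION_CLASSES))
  tier <- ifelse(bin_d == 0 & ann_d == 0, 0L,
                 ifelse(ann_d == 0, 1L, ifelse(bin_d == 0, 2L, 3L)))
  all_strata[order(tier, ann_d, bin_d, ss$bin, ss$ann)]
}

#' Sample matched background region sets
#'
#' Draws `n_sets` background sets from the pool by stratified sampling
#' without replacement: within each set, every (GC bin x annotation)
#' stratum contributes exactly as many regions as the foreground has in
#' that stratum, drawn uniformly without replacement.  When a stratum is
#' exhausted the sampler borrows deterministically from the nearest GC
#' bin with the same annotation, then from the same GC bin with
#' priority-adjacent annotation, logging every substitution; a set always
#' reaches the full foreground size.  Sets are drawn independently with
#' per-set seeds derived from (`seed`, set index), so any single set is
#' reproducible on its own.
#'
#' @param foreground Annotated foreground peaks (must carry `stratum`).
#' @param pool Eligible annotated tiles (see [build_pool()]).
#' @param n_sets Number of background sets (default 1000).
#' @param seed Master seed (integer).
#' @return A list with `sets` (a long tibble: `set`, `chrom`, `start`,
#'   `end`, `stratum`, `fallback`) and `manifest` (per-set tibble: `set`,
#'   `seed`, `n_fallback`).
#' @export
sample_background <- function(foreground, pool, n_sets = 1000, seed = 1) {
  foreground <- as_tibble(foreground)
  pool <- as_tibble(pool)
  if (!"stratum" %in% names(foreground) || !"stratum" %in% names(pool)) {
    abort_data("foreground and pool must carry a `stratum` column")
  }
  if (!is_number(n_sets) || n_sets < 1) abort_config("`n_sets` must be >= 1")
  n_fg <- nrow(foreground)
  if (nrow(pool) < n_fg) {
    demand <- table(foreground$stratum, useNA = "ifany")
    supply <- table(factor(pool$stratum, levels = names(demand)))
    diag <- paste(sprintf("%s: need %d, have %d", names(demand),
                          as.integer(demand), as.integer(supply)),
                  collapse = "; ")
    abort_data(sprintf(
      "background pool (%d tiles) smaller than the foreground (%d regions); per-stratum demand vs supply: %s",
      nrow(pool), n_fg, diag
    ))
  }
  fg_strata <- as.character(foreground$stratum)
  fg_strata[is.na(fg_strata)] <- "unstratified"
  need <- table(fg_strata)
  need <- need[order(names(need))]
  pool_strata <- as.character(pool$stratum)
  pool_by_stratum <- split(seq_len(nrow(pool)), pool_strata)
  all_strata <- names(pool_by_stratum)
  gc_bins <- max(as.integer(sub("^gc([0-9]+)\\|.*$", "\\1", all_strata)), 1L)
  fb_orders <- lapply(stats::setNames(names(need), names(need)), function(s) {
    if (s == "unstratified" || !grepl("^gc", s)) return(all_strata)
    fallback_order(s, all_strata, gc_bins)
  })
  set_seeds <- vapply(seq_len(n_sets), function(i) derive_seed(seed, "bgset", i),
                      integer(1))
  sets <- vector("list", n_sets)
  n_fallback <- integer(n_sets)
  for (si in seq_len(n_sets)) {
    chosen <- integer(0)
    fb <- logical(0)
    used <- logical(nrow(pool))
    nfb <- 0L
    with_seed(set_seeds[si], {
      for (s in names(need)) {
        k <- as.integer(need[[s]])
        own <- pool_by_stratum[[s]]
        own <- own[!used[own]]
        take <- own[sample.int(length(own), min(k, length(own)))]
        used[take] <- TRUE
        chosen <- c(chosen, take)
        fb <- c(fb, rep(FALSE, length(take)))
        short <- k - length(take)
        if (short > 0) {
          for (alt in fb_orders[[s]]) {
            if (short == 0) break
            if (alt == s) next
            cand <- pool_by_stratum[[alt]]
            cand <- cand[!used[cand]]
            if (length(cand) == 0) next
            take2 <- cand[sample.int(length(cand), min(short, length(cand)))]
            used[take2] <- TRUE
            chosen <- c(chosen, take2)
            fb <- c(fb, rep(TRUE, length(take2)))
            nfb <- nfb + length(take2)
            short <- short - length(take2)
          }
          if (short > 0) {
            abort_data(sprintf(
              "stratum %s cannot be filled even with fallback in set %d", s, si
            ))
          }
        }
      }
    })
    n_fallback[si] <- nfb
    d <- pool[chosen, c("chrom", "start", "end", "stratum")]
    d$set <- si
    d$fallback <- fb
    sets[[si]] <- d
  }
  sets <- dplyr::bind_rows(sets)[, c("set", "chrom", "start", "end", "stratum", "fallback")]
  total_fb <- sum(n_fallback)
  if (total_fb > 0) {
    inform(sprintf("sample_background: %d substitution(s) via stratum fallback across %d set(s)",
                   total_fb, sum(n_fallback > 0)))
  }
  list(
    sets = sets,
    manifest = tibble(set = seq_len(n_sets), seed = set_seeds,
                      n_fallback = n_fallback)
  )
}
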