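#' Parameters of the LD-block procedure
#'
#' @param p_threshold GWAS significance cutoff; only SNPs with
#'   `p_value < p_threshold` seed blocks (default the genome-wide
#'   significance convention, 5e-8).
#' @param window Total search window around each SNP in bp (default
#'   500 kb); variants within `pos +/- window/2` are considered.
#' @param r2_min Haplotype r-squared at or above which a variant joins the
#'   block (default 0.8).
#' @return A named list of validated parameters.
#' @examples
#' ld_params(window = 2e5)
#' @export
ld_params <- function(p_threshold = 5e-8, window = 5e5, r2_min = 0.8) {
  check_prob(p_threshold, "p_threshold", lo_open = TRUE, hi_open = TRUE)
  if (!is_number(window) || window <= 0) abort_config("`window` must be a positive number")
  check_prob(r2_min, "r2_min", lo_open = TRUE)
  list(p_threshold = p_threshold, window = window, r2_min = r2_min)
}

#' Filter a GWAS SNP table to genome-wide significance
#'
#' Keeps exactly the records with `p_value` strictly below the threshold,
#' preserving input order.
#'
#' @param snps A SNP table (see [read_snp_table()]).
#' @param p_threshold Significance cutoff (default 5e-8).
#' @return The filtered tibble.
#' @examples
#' snps <- tibble::tibble(
#'   chrom = "chr1", pos = c(10, 20, 30), id = c("a", "b", "c"),
#'   p_value = c(1e-9, 5e-8, 4.9e-8), group = "EUR"
#' )
#' filter_gwas(snps)  # keeps a and c: the cutoff is strict
#' @export
filter_gwas <- function(snps, p_threshold = 5e-8) {
  snps <- validate_snp_table(snps)
  dplyr::filter(snps, .data$p_value < p_threshold)
}

#' Haplotype r-squared between two biallelic variants
#'
#' With allele frequencies `p_x = mean(x)`, `p_y = mean(y)` and haplotype
#' frequency `p_xy = mean(x * y)`, the LD coefficient is
#' `D = p_xy - p_x * p_y` and `r2 = D^2 / (p_x (1 - p_x) p_y (1 - p_y))`.
#' Symmetric and invariant to flipping the allele coding of either vector.
#'
#' @param x,y Equal-length 0/1 allele vectors across the same haplotypes.
#' @return r-squared in \[0, 1\], or `NA` when either variant is
#'   monomorphic (undefined LD; callers treat `NA` as "not linked").
#' @examples
#' hap_r2(c(0, 1, 0, 1), c(1, 0, 1, 0))  # coding flip: still 1
#' @export
hap_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort_data("allele vectors must have equal length >= 2")
  }
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) {
    abort_data("allele vectors must contain only 0 and 1")
  }
  px <- mean(x)
  py <- mean(y)
  if (px %in% c(0, 1) || py %in% c(0, 1)) return(NA_real_)
  d <- mean(x * y) - px * py
  d^2 / (px * (1 - px) * py * (1 - py))
}

# vectorised r2 of every column of `alleles` against one column index j;
# monomorphic columns (or a monomorphic anchor) give NA
r2_against <- function(alleles, j) {
  y <- alleles[, j]
  p <- colMeans(alleles)
  py <- p[j]
  if (py %in% c(0, 1)) return(rep(NA_real_, ncol(alleles)))
  pxy <- colMeans(alleles * y)
  d <- pxy - p * py
  out <- d^2 / (p * (1 - p) * py * (1 - py))
  out[p %in% c(0, 1)] <- NA_real_
  out
}

#' Select proxy variants for a GWAS SNP
#'
#' GWAS SNPs absent from the haplotype panel are represented by the
#' nearest panel variants: `down` is the closest variant at or below the
#' SNP position, `up` the closest at or above it.  A SNP present in the
#' panel is its own proxy on both sides; if only one side has a variant
#' within the window, that variant serves as both proxies.
#'
#' @param snp_pos 1-based SNP position.
#' @param panel A [hap_panel()] on the SNP's chromosome.
#' @param window Total window size in bp (search spans `pos +/- window/2`).
#' @return A list with integer column indices `down` and `up`, or `NULL`
#'   when no panel variant lies within the window (no-proxy signal).
#' @export
select_proxies <- function(snp_pos, panel, window = 5e5) {
  half <- window / 2
  pos <- panel$positions
  inside <- which(pos >= snp_pos - half & pos <= snp_pos + half)
  if (length(inside) == 0) return(NULL)
  below <- inside[pos[inside] <= snp_pos]
  above <- inside[pos[inside] >= snp_pos]
  down <- if (length(below) > 0) below[length(below)] else NULL
  up <- if (length(above) > 0) above[1] else NULL
  if (is.null(down)) down <- up
  if (is.null(up)) up <- down
  list(down = down, up = up)
}

#' Build the LD block around one GWAS SNP
#'
#' Every panel variant within the window is marked linked when its
#' r-squared with either proxy reaches `r2_min` (proxies are always
#' linked: r-squared with self is 1).  The block spans from the most
#' upstream to the most downstream linked variant, reported 0-based
#' half-open.  A SNP with no proxy in the window yields a degenerate 1-bp
#' block at the SNP position with a warning (or is dropped when
#' `on_no_proxy = "drop"`).
#'
#' @param snp One SNP-table row (`chrom`, `pos`, `id`, `group`).
#' @param panel A [hap_panel()] on the SNP's chromosome.
#' @param params An [ld_params()] list.
#' @param on_no_proxy `"degenerate"` (default) or `"drop"`.
#' @return A one-row block tibble (`chrom`, `start`, `end`, `source_snps`,
#'   `proxy_down`, `proxy_up`, `group`), or a zero-row tibble when dropped.
#' @export
build_block <- function(snp, panel, params = ld_params(),
                        on_no_proxy = c("degenerate", "drop")) {
  on_no_proxy <- match.arg(on_no_proxy)
  snp <- as_tibble(snp)[1, ]
  if (!is.null(panel$chrom) && nzchar(panel$chrom) && n_variants(panel) > 0 &&
      panel$chrom != snp$chrom) {
    abort_data(sprintf("panel is on %s but SNP %s is on %s",
                       panel$chrom, snp$id, snp$chrom))
  }
  empty <- tibble(
    chrom = character(), start = double(), end = double(),
    source_snps = character(), proxy_down = character(),
    proxy_up = character(), group = character()
  )
  prox <- if (n_variants(panel) > 0) {
    select_proxies(snp$pos, panel, params$window)
  } else {
    NULL
  }
  if (is.null(prox)) {
    if (on_no_proxy == "drop") {
      warn(sprintf("no panel proxy within the window for SNP %s; dropped", snp$id))
      return(empty)
    }
    warn(sprintf(
      "no panel proxy within the window for SNP %s; emitting a degenerate 1-bp block",
      snp$id
    ))
    return(tibble(
      chrom = snp$chrom, start = snp$pos - 1, end = snp$pos,
      source_snps = snp$id, proxy_down = NA_character_,
      proxy_up = NA_character_, group = snp$group
    ))
  }
  half <- params$window / 2
  inside <- which(panel$positions >= snp$pos - half & panel$positions <= snp$pos + half)
  sub <- panel$alleles[, inside, drop = FALSE]
  d_local <- match(prox$down, inside)
  u_local <- match(prox$up, inside)
  r2d <- r2_against(sub, d_local)
  r2u <- r2_against(sub, u_local)
  linked <- (!is.na(r2d) & r2d >= params$r2_min) |
    (!is.na(r2u) & r2u >= params$r2_min)
  linked[c(d_local, u_local)] <- TRUE
  lp <- panel$positions[inside][linked]
  tibble(
    chrom = snp$chrom, start = min(lp) - 1, end = max(lp),
    source_snps = snp$id,
    proxy_down = panel$ids[prox$down], proxy_up = panel$ids[prox$up],
    group = snp$group
  )
}

#' Merge overlapping LD blocks
#'
#' Sorts blocks by position and merges any genuinely overlapping spans
#' (abutting half-open blocks stay separate), pooling the provenance: the
#' merged block's `source_snps` is the semicolon-joined union over its
#' inputs, and `group` the union of population labels.  Idempotent; total
#' covered bases are conserved.
#'
#' @param blocks A block tibble as produced by [build_block()] (only
#'   `chrom`, `start`, `end` are required).
#' @return A merged block tibble sorted by (`chrom`, `start`).
#' @export
merge_blocks <- function(blocks) {
  blocks <- as_intervals(blocks, "blocks")
  if (nrow(blocks) == 0) return(blocks)
  if (!"source_snps" %in% names(blocks)) blocks$source_snps <- NA_character_
  if (!"group" %in% names(blocks)) blocks$group <- NA_character_
  blocks <- blocks[order(blocks$chrom, blocks$start, blocks$end), ]
  join_unique <- function(x) {
    u <- unique(unlist(strsplit(x[!is.na(x)], ";", fixed = TRUE)))
    if (length(u) == 0) NA_character_ else paste(sort(u), collapse = ";")
  }
  parts <- split(blocks, blocks$chrom)
  out <- lapply(parts, function(d) {
    n <- nrow(d)
    cme <- cummax(d$end)
    g <- cumsum(c(TRUE, d$start[-1] >= cme[-n]))
    dplyr::summarise(
      dplyr::group_by(d, grp = g),
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      source_snps = join_unique(.data$source_snps),
      group = join_unique(.data$group),
      .groups = "drop"
    )[, c("chrom", "start", "end", "source_snps", "group")]
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$chrom, .data$start)
}

#' Build merged LD blocks for a filtered GWAS SNP table
#'
#' Runs [build_block()] for every SNP using the haplotype panel of the
#' SNP's population group and chromosome, then merges the pooled block
#' list across groups with [merge_blocks()].  Blocks for SNPs sharing a
#' (group, chromosome, position) are computed once.
#'
#' @param snps A (typically already significance-filtered) SNP table.
#' @param panels Panels keyed by group then chromosome:
#'   `list(EUR = list(chr1 = <hap_panel>, ...), ...)`.  A bare
#'   [hap_panel()] is accepted when there is a single group and chromosome.
#' @param params An [ld_params()] list.
#' @param on_no_proxy Passed to [build_block()].
#' @return A merged block tibble.
#' @export
build_ld_blocks <- function(snps, panels, params = ld_params(),
                            on_no_proxy = c("degenerate", "drop")) {
  on_no_proxy <- match.arg(on_no_proxy)
  snps <- validate_snp_table(snps)
  if (inherits(panels, "hap_panel")) {
    panels <- stats::setNames(
      list(stats::setNames(list(panels), panels$chrom)),
      unique(snps$group)[1]
    )
  }
  key <- paste(snps$group, snps$chrom, snps$pos, sep = "\r")
  first <- !duplicated(key)
  blocks <- vector("list", sum(first))
  idx <- which(first)
  for (k in seq_along(idx)) {
    i <- idx[k]
    gp <- panels[[snps$group[i]]]
    if (is.null(gp)) {
      abort_data(sprintf("no haplotype panel for group %s", snps$group[i]))
    }
    panel <- gp[[snps$chrom[i]]]
    if (is.null(panel)) {
      panel <- hap_panel(snps$chrom[i], double(), matrix(integer(), 2, 0))
    }
    blocks[[k]] <- build_block(snps[i, ], panel, params, on_no_proxy)
  }
  # re-attach source ids of duplicate-position SNPs before merging
  rows <- lapply(seq_len(nrow(snps)), function(i) {
    b <- blocks[[match(key[i], key[idx])]]
    if (nrow(b) == 0) return(b)
    b$source_snps <- snps$id[i]
    b
  })
  pooled <- dplyr::bind_rows(rows)
  if (nrow(pooled) == 0) {
    return(tibble(
      chrom = character(), start = double(), end = double(),
      source_snps = character(), group = character()
    ))
  }
  merge_blocks(pooled)
}
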