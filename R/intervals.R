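#' Genomic intervals as tibbles
#'
#' All coordinates in this package are 0-based, half-open (BED convention):
#' an interval covers bases `start, start+1, ..., end-1`.  An interval table
#' is any data frame with character `chrom` and numeric `start < end`
#' columns; extra columns are carried along untouched.  `as_intervals()`
#' validates and normalises such a table.
#'
#' @param x A data frame with columns `chrom`, `start`, `end`.
#' @param arg Name used in error messages.
#' @return A tibble with validated `chrom`, `start`, `end` (integer-valued
#'   doubles) and any additional columns of `x`.
#' @examples
#' as_intervals(data.frame(chrom = "chr1", start = 100, end = 600))
#' @export
as_intervals <- function(x, arg = "x") {
  if (!is.data.frame(x)) {
    abort_data(sprintf("`%s` must be a data frame of intervals", arg))
  }
  miss <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(miss) > 0) {
    abort_data(sprintf(
      "`%s` is missing interval column(s): %s", arg, paste(miss, collapse = ", ")
    ))
  }
  x <- as_tibble(x)
  x$chrom <- as.character(x$chrom)
  x$start <- as.double(x$start)
  x$end <- as.double(x$end)
  bad <- which(is.na(x$chrom) | !nzchar(x$chrom) | is.na(x$start) |
                 is.na(x$end) | x$start < 0 | x$end <= x$start)
  if (length(bad) > 0) {
    abort_data(sprintf(
      "`%s` has %d invalid interval(s) (need non-empty chrom, 0 <= start < end); first at row %d",
      arg, length(bad), bad[1]
    ))
  }
  x
}

#' Genome layout
#'
#' An ordered table of chromosome names and lengths.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Positive integer-valued vector of chromosome lengths (bp).
#' @return A tibble with columns `chrom`, `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.double(length)
  if (anyDuplicated(chrom)) abort_data("chromosome names must be unique")
  if (any(!nzchar(chrom)) || any(is.na(length)) || any(length <= 0)) {
    abort_data("chromosome names must be non-empty and lengths positive")
  }
  tibble(chrom = chrom, length = length)
}

#' Do two intervals overlap?
#'
#' Half-open semantics: intervals overlap iff they are on the same
#' chromosome and share at least one base, so abutting intervals
#' (`a$end == b$start`) do not overlap.  Vectorised elementwise over rows.
#'
#' @param a,b Interval tables (recycled to a common length).
#' @return Logical vector.
#' @examples
#' a <- data.frame(chrom = "chr1", start = 0, end = 10)
#' b <- data.frame(chrom = "chr1", start = 10, end = 20)
#' interval_overlaps(a, b)  # FALSE: abutting
#' @export
interval_overlaps <- function(a, b) {
  a <- as_intervals(a, "a")
  b <- as_intervals(b, "b")
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  a$chrom[ai] == b$chrom[bi] & a$start[ai] < b$end[bi] & b$start[bi] < a$end[ai]
}

#' Which query intervals overlap any subject interval?
#'
#' `overlaps_any()` flags, for each query interval, whether it overlaps at
#' least one base of at least one subject interval; `count_overlapping()`
#' counts the flagged queries.  Implemented as a `findInterval()` sweep over
#' the merged subject set, so it is O((n+m) log m) and safe to call inside
#' permutation loops.
#'
#' @param query,subject Interval tables.
#' @return `overlaps_any()`: a logical vector along `query`;
#'   `count_overlapping()`: a single integer.
#' @examples
#' peaks <- data.frame(chrom = "chr1", start = c(0, 50), end = c(10, 60))
#' blocks <- data.frame(chrom = "chr1", start = 5, end = 55)
#' overlaps_any(peaks, blocks)
#' count_overlapping(peaks, blocks)
#' @export
overlaps_any <- function(query, subject) {
  q <- as_intervals(query, "query")
  s <- merge_intervals(subject)
  overlaps_any_merged(q, s)
}

# internal fast path: `q` validated, `s` already merged and sorted
overlaps_any_merged <- function(q, s) {
  out <- logical(nrow(q))
  if (nrow(s) == 0 || nrow(q) == 0) return(out)
  for (ch in unique(q$chrom)) {
    qi <- which(q$chrom == ch)
    si <- s$chrom == ch
    if (!any(si)) next
    st <- s$start[si]
    en <- s$end[si]
    # first merged subject whose end is strictly right of the query start
    cand <- findInterval(q$start[qi], en) + 1L
    hit <- cand <= length(st) & st[pmin(cand, length(st))] < q$end[qi]
    out[qi] <- hit
  }
  out
}

#' @rdname overlaps_any
#' @export
count_overlapping <- function(query, subject) {
  sum(overlaps_any(query, subject))
}

#' Merge overlapping intervals
#'
#' Sort-and-sweep union of an interval set.  Only genuinely overlapping
#' intervals are merged; abutting half-open intervals are kept separate.
#' Extra columns are dropped.
#'
#' @param x An interval table.
#' @return A tibble of disjoint intervals sorted by (`chrom`, `start`),
#'   covering exactly the same bases as `x`.
#' @examples
#' merge_intervals(data.frame(
#'   chrom = "chr1", start = c(0, 50, 100), end = c(100, 200, 200)
#' ))
#' @export
merge_intervals <- function(x) {
  x <- as_intervals(x)
  if (nrow(x) == 0) return(tibble(chrom = character(), start = double(), end = double()))
  o <- order(x$chrom, x$start, x$end)
  ch <- x$chrom[o]
  s <- x$start[o]
  e <- x$end[o]
  n <- length(s)
  # cummax with per-chromosome reset: offset each chromosome into its own
  # coordinate band so an earlier chromosome can never dominate a later one
  ci <- match(ch, unique(ch))
  big <- max(e) + 1
  cme <- cummax(e + ci * big) - ci * big
  new_grp <- c(TRUE, ch[-1] != ch[-n] | s[-1] >= cme[-n])
  first <- which(new_grp)
  last <- c(first[-1] - 1L, n)
  tibble(chrom = ch[first], start = s[first], end = cme[last])
}

#' Total bases covered by an interval set
#'
#' @param x An interval table.
#' @return Number of distinct bases covered (overlaps counted once).
#' @export
covered_bases <- function(x) {
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

# internal: clip intervals to [0, chrom length]; drops rows emptied by clipping
clip_to_layout <- function(x, layout) {
  x <- as_intervals(x)
  len <- stats::setNames(layout$length, layout$chrom)
  if (any(!x$chrom %in% layout$chrom)) {
    abort_data("interval on a chromosome absent from the genome layout")
  }
  x$start <- pmax(x$start, 0)
  x$end <- pmin(x$end, len[x$chrom])
  x[x$end > x$start, , drop = FALSE]
}

# internal: stable region identifier used to key projection tables
region_id <- function(x) {
  x <- as_intervals(x)
  sprintf("%s:%d-%d", x$chrom, as.integer(x$start), as.integer(x$end))
}
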