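#' Read a BED3+ file
#'
#' Line-oriented reader for tab-separated BED with at least three columns.
#' Track/browser/comment lines are skipped.  Coordinates are kept in the
#' native 0-based half-open convention.  Malformed lines raise a parse
#' error naming the offending line number, and inverted coordinates a
#' validation error, so bad inputs fail loudly rather than silently.
#'
#' @param path Path to a BED file.
#' @return A tibble with `chrom`, `start`, `end`, and, when present,
#'   `name` (column 4) and `score` (column 5); input order preserved.
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t600\tpeak1", p)
#' read_bed(p)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("BED file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(chrom = character(), start = double(), end = double()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort_parse(sprintf(
      "malformed BED line %d in %s: fewer than 3 tab-separated fields",
      idx[which(nf < 3)[1]], path
    ))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.double(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.double(vapply(fields, `[[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort_parse(sprintf(
      "malformed BED line %d in %s: non-numeric coordinates", idx[bad[1]], path
    ))
  }
  inv <- which(end <= start | start < 0)
  if (length(inv) > 0) {
    abort_data(sprintf(
      "invalid interval on BED line %d in %s: need 0 <= start < end",
      idx[inv[1]], path
    ))
  }
  out <- tibble(chrom = chrom, start = start, end = end)
  if (all(nf >= 4)) out$name <- vapply(fields, `[[`, character(1), 4)
  if (all(nf >= 5)) {
    out$score <- suppressWarnings(as.double(vapply(fields, `[[`, character(1), 5)))
  }
  out
}

#' Write intervals as BED
#'
#' @param x An interval table; optional `name` and `score` columns become
#'   BED columns 4 and 5.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- as_intervals(x)
  cols <- c(
    sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start), as.integer(x$end))
  )
  if ("name" %in% names(x)) {
    cols <- paste0(cols, "\t", as.character(x$name))
    if ("score" %in% names(x)) {
      cols <- paste0(cols, "\t", format(x$score, trim = TRUE, scientific = FALSE))
    }
  }
  writeLines(cols, path)
  invisible(path)
}

#' Read / write a GWAS SNP table
#'
#' Tab-separated with a header and columns `chrom`, `pos` (1-based, VCF
#' convention), `id`, `p_value`, `group` (superpopulation label).
#'
#' @param path Path to the TSV file.
#' @return A tibble with the five columns above.
#' @export
read_snp_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), pos = readr::col_double(),
    id = readr::col_character(), p_value = readr::col_double(),
    group = readr::col_character()
  ))
  validate_snp_table(x)
}

validate_snp_table <- function(x) {
  miss <- setdiff(c("chrom", "pos", "id", "p_value", "group"), names(x))
  if (length(miss) > 0) {
    abort_data(sprintf("SNP table missing column(s): %s", paste(miss, collapse = ", ")))
  }
  bad <- which(is.na(x$pos) | x$pos < 1 | is.na(x$p_value) |
                 x$p_value <= 0 | x$p_value > 1)
  if (length(bad) > 0) {
    abort_data(sprintf(
      "SNP table has %d invalid row(s) (need pos >= 1 and 0 < p_value <= 1); first at row %d",
      length(bad), bad[1]
    ))
  }
  as_tibble(x)
}

#' @rdname read_snp_table
#' @param x A SNP table.
#' @export
write_snp_table <- function(x, path) {
  readr::write_tsv(validate_snp_table(x), path)
  invisible(path)
}

#' Read / write a projection-score table
#'
#' Tab-separated with a header; one row per projected source region:
#' `region_id`, source `chrom`/`start`/`end`, `score` in \[0, 1\], target
#' `target_chrom`/`target_start`/`target_end` (NA when the projection has
#' no target coordinates), and optional `bridge` species label.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the columns above.
#' @export
read_projection_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    region_id = readr::col_character(), chrom = readr::col_character(),
    start = readr::col_double(), end = readr::col_double(),
    score = readr::col_double(), target_chrom = readr::col_character(),
    target_start = readr::col_double(), target_end = readr::col_double(),
    .default = readr::col_character()
  ))
  if (any(is.na(x$score) | x$score < 0 | x$score > 1)) {
    abort_data("projection scores must lie in [0, 1]")
  }
  x
}

#' @rdname read_projection_table
#' @param x A projection table.
#' @export
write_projection_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A named `Biostrings::DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Genome layout from sequences
#'
#' @param genome A named `DNAStringSet` (or the path to a FASTA file).
#' @return A [genome_layout()] tibble.
#' @export
layout_from_genome <- function(genome) {
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  genome_layout(names(genome), Biostrings::width(genome))
}

# ---- GFF3 gene models -------------------------------------------------------

#' Read gene features from GFF3
#'
#' Imports a GFF3 file and returns the gene-model features the annotator
#' consumes: `gene`, `mRNA`, `exon`, `five_prime_UTR`, `three_prime_UTR`
#' records with a shared `gene_id`.  GFF3's 1-based inclusive coordinates
#' are converted to 0-based half-open on read.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with `chrom`, `start`, `end`, `strand`, `type`,
#'   `gene_id`.
#' @export
read_gene_features <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in%
    c("gene", "mRNA", "exon", "five_prime_UTR", "three_prime_UTR")
  gr <- gr[keep]
  ids <- as.character(gr$ID %||% rep(NA_character_, length(gr)))
  parent <- vapply(
    as.list(gr$Parent %||% replicate(length(gr), character(0), simplify = FALSE)),
    function(p) if (length(p) > 0) p[[1]] else NA_character_, character(1)
  )
  # gene rows carry ID = <gene>, mRNA rows ID = <gene>.t1, children Parent = <gene>.t1
  gene_id <- ifelse(is.na(parent), ids, sub("\\.t[0-9]+$", "", parent))
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.double(GenomicRanges::start(gr)) - 1,
    end = as.double(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = gene_id
  )
}

#' Write gene features as GFF3
#'
#' Inverse of [read_gene_features()]; coordinates converted back to the
#' 1-based inclusive GFF3 convention on write.
#'
#' @param features A gene-feature tibble (see [read_gene_features()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_features <- function(features, path) {
  f <- as_tibble(features)
  f <- f[order(f$chrom, f$gene_id, f$start,
               match(f$type, c("gene", "mRNA", "exon", "five_prime_UTR", "three_prime_UTR"))), ]
  gr <- GenomicRanges::GRanges(
    seqnames = f$chrom,
    ranges = IRanges::IRanges(start = as.integer(f$start) + 1L, end = as.integer(f$end)),
    strand = f$strand
  )
  tx <- paste0(f$gene_id, ".t1")
  gr$source <- "crenrich"
  gr$type <- f$type
  gr$ID <- ifelse(f$type == "gene", f$gene_id,
                  ifelse(f$type == "mRNA", tx, NA_character_))
  parent <- ifelse(f$type == "gene", NA_character_,
                   ifelse(f$type == "mRNA", f$gene_id, tx))
  gr$Parent <- S4Vectors::List(lapply(parent, function(p) if (is.na(p)) character(0) else p))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
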