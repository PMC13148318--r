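#' Haplotype panels
#'
#' A haplotype panel is a phased, biallelic allele matrix on a single
#' chromosome: one row per haplotype (two per diploid sample), one column
#' per variant, entries in \{0, 1\}, with strictly increasing 1-based
#' variant positions.  It is the substrate for haplotype r-squared.
#'
#' @param chrom Chromosome name.
#' @param positions Strictly increasing 1-based variant positions.
#' @param alleles Integer matrix (haplotypes x variants) of 0/1 alleles.
#' @param ids Variant identifiers (defaults to `chrom:pos`).
#' @return An object of class `hap_panel`.
#' @export
hap_panel <- function(chrom, positions, alleles, ids = NULL) {
  positions <- as.double(positions)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (ncol(alleles) != length(positions)) {
    abort_data("alleles must have one column per variant position")
  }
  if (length(positions) > 1 && any(diff(positions) <= 0)) {
    abort_data("variant positions must be strictly increasing")
  }
  if (nrow(alleles) < 2 && ncol(alleles) > 0) {
    abort_data("a haplotype panel needs at least 2 haplotypes")
  }
  if (length(alleles) > 0 && !all(alleles %in% c(0L, 1L))) {
    abort_data("panel alleles must be 0 or 1")
  }
  if (is.null(ids)) ids <- sprintf("%s:%d", chrom, as.integer(positions))
  structure(
    list(chrom = as.character(chrom), positions = positions,
         ids = as.character(ids), alleles = alleles),
    class = "hap_panel"
  )
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf(
    "<hap_panel> %s: %d haplotypes x %d variants (%s..%s)\n",
    x$chrom, nrow(x$alleles), length(x$positions),
    if (length(x$positions)) format(min(x$positions)) else "-",
    if (length(x$positions)) format(max(x$positions)) else "-"
  ))
  invisible(x)
}

#' Number of variants / haplotypes in a panel
#' @param panel A [hap_panel()].
#' @return Integer count.
#' @export
n_variants <- function(panel) length(panel$positions)

#' @rdname n_variants
#' @export
n_haplotypes <- function(panel) nrow(panel$alleles)

#' Read phased haplotypes from a VCF
#'
#' Retains only biallelic SNP records (single-base REF and ALT), with
#' FILTER in `keep_filter`, whose genotypes are phased (`|`-separated) and
#' non-missing in every sample.  Each diploid sample contributes two
#' haplotype rows.  Records failing any filter are dropped and the dropped
#' counts reported via a message.
#'
#' @param path Path to a VCF (>= 4.1) with GT.
#' @param region Optional interval table row (0-based half-open) restricting
#'   the panel to one chromosome span.
#' @param keep_filter FILTER values accepted (default `PASS` and `.`).
#' @return A [hap_panel()]; zero variants signal an empty panel (the caller
#'   decides how to proceed).
#' @export
read_phased_vcf <- function(path, region = NULL, keep_filter = c("PASS", ".")) {
  if (!file.exists(path)) abort_data(sprintf("VCF file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(hap_panel(if (!is.null(region)) region$chrom[1] else "", double(), matrix(integer(), 2, 0)))
  }
  pos <- as.double(fix$POS)
  chrom <- as.character(fix$CHROM)
  keep <- rep(TRUE, nrow(fix))
  dropped <- c(region = 0L, multiallelic_or_indel = 0L, filter = 0L, unphased_or_missing = 0L)
  if (!is.null(region)) {
    region <- as_intervals(region, "region")[1, ]
    inside <- chrom == region$chrom & pos - 1 >= region$start & pos - 1 < region$end
    dropped["region"] <- sum(keep & !inside)
    keep <- keep & inside
  } else if (length(unique(chrom)) > 1) {
    abort_data("VCF spans multiple chromosomes; supply `region` to select one")
  }
  snp <- grepl("^[ACGT]$", fix$REF) & grepl("^[ACGT]$", fix$ALT)
  dropped["multiallelic_or_indel"] <- sum(keep & !snp)
  keep <- keep & snp
  filt <- is.na(fix$FILTER) | fix$FILTER %in% keep_filter
  dropped["filter"] <- sum(keep & !filt)
  keep <- keep & filt
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) abort_data("VCF has no GT field")
  phased <- matrix(grepl("^[01]\\|[01]$", gt), nrow = nrow(gt))
  all_phased <- rowSums(phased) == ncol(gt)
  dropped["unphased_or_missing"] <- sum(keep & !all_phased)
  keep <- keep & all_phased
  if (any(dropped > 0)) {
    inform(sprintf(
      "read_phased_vcf: dropped %d record(s) [%s]",
      sum(dropped), paste(sprintf("%s=%d", names(dropped), dropped), collapse = ", ")
    ))
  }
  if (!any(keep)) {
    return(hap_panel(if (!is.null(region)) region$chrom[1] else chrom[1],
                     double(), matrix(integer(), 2, 0)))
  }
  gt <- gt[keep, , drop = FALSE]
  a1 <- matrix(as.integer(substr(gt, 1, 1)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3, 3)), nrow = nrow(gt))
  # interleave: sample j -> haplotype rows 2j-1, 2j
  nh <- 2L * ncol(gt)
  alleles <- matrix(0L, nrow = nh, ncol = nrow(gt))
  alleles[seq(1, nh, by = 2), ] <- t(a1)
  alleles[seq(2, nh, by = 2), ] <- t(a2)
  o <- order(pos[keep])
  hap_panel(
    chrom = chrom[keep][1],
    positions = pos[keep][o],
    alleles = alleles[, o, drop = FALSE],
    ids = ifelse(is.na(fix$ID[keep][o]) | fix$ID[keep][o] == ".",
                 sprintf("%s:%d", chrom[keep][o], as.integer(pos[keep][o])),
                 fix$ID[keep][o])
  )
}

#' Write a haplotype panel as a phased VCF
#'
#' Minimal VCFv4.2 text writer for generator output: biallelic SNP records
#' with phased GT only.  Several panels (one per chromosome) sharing the
#' same haplotypes can be concatenated into one file.
#'
#' @param panels A [hap_panel()] or list of panels (one per chromosome).
#' @param path Output path (plain text).
#' @param sample_prefix Prefix for generated sample names.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panels, path, sample_prefix = "S") {
  if (inherits(panels, "hap_panel")) panels <- list(panels)
  nh <- nrow(panels[[1]]$alleles)
  if (nh %% 2 != 0) abort_data("panel must have an even number of haplotypes to form diploid samples")
  samples <- sprintf("%s%04d", sample_prefix, seq_len(nh / 2))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", samples),
          collapse = "\t")
  )
  body <- unlist(lapply(panels, function(p) {
    if (n_variants(p) == 0) return(character(0))
    a1 <- p$alleles[seq(1, nh, by = 2), , drop = FALSE]
    a2 <- p$alleles[seq(2, nh, by = 2), , drop = FALSE]
    gts <- matrix(paste0(a1, "|", a2), nrow = nrow(a1))
    gt_str <- apply(gts, 2, paste, collapse = "\t")
    paste(p$chrom, as.integer(p$positions), p$ids, "A", "G", ".", "PASS", ".", "GT",
          gt_str, sep = "\t")
  }))
  writeLines(c(header, body), path)
  invisible(path)
}
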