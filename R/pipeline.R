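#' Pipeline configuration
#'
#' One nested configuration drives the whole pipeline; all the headline
#' procedure parameters (significance 5e-8, 500-kb window, r-squared 0.8,
#' 500-bp tiles, number of background sets, conservation thresholds
#' 0.98 / 0.84) are surfaced as named keys.  Values can be overridden
#' programmatically or loaded from a YAML file with [read_config()].
#'
#' @param ... Named overrides merged recursively into the defaults.
#' @return A validated nested list with sections `sim`, `ld`,
#'   `background`, `enrichment`, `conservation`.
#' @export
cre_config <- function(...) {
  cfg <- list(
    sim = sim_config(),
    ld = list(p_threshold = 5e-8, window = 5e5, r2_min = 0.8,
              on_no_proxy = "degenerate"),
    # exclude_overlapping defaults off here: on the desk-scale synthetic
    # genome the enriched foreground covers most in-block tiles, and
    # excluding them would empty the very strata the null needs.  On
    # genome-scale data (where peaks cover a few percent of the tiles)
    # build_pool's own default of TRUE is the better choice.
    background = list(n_sets = 200, gc_bins = 10, tile_width = 500,
                      exclude_overlapping = FALSE,
                      promoter_up = 2000, promoter_down = 200),
    enrichment = list(density_mode = "count_per_mb"),
    conservation = list(direct_min = 0.98, indirect_min = 0.84)
  )
  validate_config(utils::modifyList(cfg, list(...)))
}

#' @rdname cre_config
#' @param path Path to a YAML configuration file whose keys mirror the
#'   defaults.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
  validate_config(utils::modifyList(cre_config(), yaml::read_yaml(path)))
}

validate_config <- function(cfg) {
  bad <- setdiff(names(cfg), c("sim", "ld", "background", "enrichment", "conservation"))
  if (length(bad) > 0) {
    abort_config(sprintf("unknown config section(s): %s", paste(bad, collapse = ", ")))
  }
  cfg$sim <- validate_sim_config(cfg$sim)
  ld_params(cfg$ld$p_threshold, cfg$ld$window, cfg$ld$r2_min)
  if (!cfg$ld$on_no_proxy %in% c("degenerate", "drop")) {
    abort_config("ld$on_no_proxy must be 'degenerate' or 'drop'")
  }
  b <- cfg$background
  if (!is_number(b$n_sets) || b$n_sets < 1) abort_config("background$n_sets must be >= 1")
  if (!is_number(b$gc_bins) || b$gc_bins < 1) abort_config("background$gc_bins must be >= 1")
  if (!is_number(b$tile_width) || b$tile_width <= 0) {
    abort_config("background$tile_width must be positive")
  }
  if (!cfg$enrichment$density_mode %in% c("count_per_mb", "bp_ratio")) {
    abort_config("enrichment$density_mode must be 'count_per_mb' or 'bp_ratio'")
  }
  check_prob(cfg$conservation$direct_min, "conservation$direct_min")
  check_prob(cfg$conservation$indirect_min, "conservation$indirect_min")
  if (cfg$conservation$indirect_min >= cfg$conservation$direct_min) {
    abort_config("conservation$indirect_min must be below conservation$direct_min")
  }
  cfg
}

write_result_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  path
}

#' Run the full pipeline on synthetic inputs
#'
#' Executes the stages in dependency order -- simulate, GWAS filtering,
#' LD-block construction, genome tiling + annotation, matched background
#' sampling, permutation enrichment, conservation classification -- with
#' every stage reading and writing plain-text files under `out_dir`, and
#' writes a JSON run manifest with per-file MD5 digests.  A rerun with
#' the same config and seed reproduces identical result files.
#'
#' @param config A [cre_config()] list.
#' @param out_dir Output directory.
#' @param seed Master seed; every stage derives its own substream from it.
#' @return A list with the in-memory stage results (`blocks`,
#'   `enrichment`, `conservation`, ...) and the `manifest`.
#' @export
run_pipeline <- function(config = cre_config(), out_dir = tempfile("cre_run_"),
                         seed = 1) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(out_dir, x)
  manifest <- list(
    package = "crenrich",
    version = as.character(utils::packageVersion("crenrich")),
    seed = seed, config = config, started = format(Sys.time(), tz = "UTC"),
    stages = character(0)
  )
  write_manifest <- function(status) {
    manifest$status <- status
    manifest$finished <- format(Sys.time(), tz = "UTC")
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[!grepl("manifest\\.json$", files)]
    manifest$files <- lapply(
      stats::setNames(files, basename(files)),
      function(f) unname(tools::md5sum(f))
    )
    jsonlite::write_json(manifest, fp("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    manifest
  }
  result <- tryCatch({
      # ---- simulate -------------------------------------------------------
      sim <- simulate_all(config$sim, seed = seed, out_dir = out_dir)
      manifest$stages <- c(manifest$stages, "simulate")

      # ---- ld blocks ------------------------------------------------------
      params <- ld_params(config$ld$p_threshold, config$ld$window, config$ld$r2_min)
      gwas <- read_snp_table(fp("gwas.tsv"))
      sig <- filter_gwas(gwas, params$p_threshold)
      panels <- lapply(
        stats::setNames(names(sim$panels), names(sim$panels)),
        function(grp) {
          vcf <- fp(sprintf("panel_%s.vcf", grp))
          lapply(
            stats::setNames(sim$layout$chrom, sim$layout$chrom),
            function(ch) read_phased_vcf(
              vcf,
              region = tibble(chrom = ch, start = 0,
                              end = sim$layout$length[sim$layout$chrom == ch])
            )
          )
        }
      )
      blocks <- build_ld_blocks(sig, panels, params,
                                on_no_proxy = config$ld$on_no_proxy)
      bed <- blocks[, c("chrom", "start", "end")]
      bed$name <- blocks$source_snps
      write_bed(bed, fp("ld_blocks.bed"))
      write_result_tsv(blocks, fp("ld_blocks.tsv"))
      manifest$stages <- c(manifest$stages, "ld_blocks")

      # ---- annotate -------------------------------------------------------
      genome <- read_genome_fasta(fp("genome.fa"))
      genes <- read_gene_features(fp("genes.gff3"))
      bcfg <- config$background
      tiles <- annotate_regions(
        tile_genome(layout_from_genome(genome), bcfg$tile_width),
        genome, genes, gc_bins = bcfg$gc_bins,
        promoter_up = bcfg$promoter_up, promoter_down = bcfg$promoter_down
      )
      peaks <- annotate_regions(
        read_bed(fp("peaks.bed")), genome, genes, gc_bins = bcfg$gc_bins,
        promoter_up = bcfg$promoter_up, promoter_down = bcfg$promoter_down
      )
      write_result_tsv(tiles, fp("tiles_annotated.tsv"))
      write_result_tsv(peaks, fp("peaks_annotated.tsv"))
      manifest$stages <- c(manifest$stages, "annotate")

      # ---- background sampling -------------------------------------------
      pool <- build_pool(tiles, peaks, bcfg$exclude_overlapping)
      bg <- sample_background(peaks, pool, n_sets = bcfg$n_sets,
                              seed = derive_seed(seed, "background"))
      write_result_tsv(bg$manifest, fp("background_manifest.tsv"))
      manifest$stages <- c(manifest$stages, "background")

      # ---- enrichment -----------------------------------------------------
      enr <- run_enrichment(peaks, blocks, bg,
                            density_mode = config$enrichment$density_mode)
      write_result_tsv(enr$results, fp("enrichment.tsv"))
      write_result_tsv(enr$null, fp("enrichment_null.tsv"))
      manifest$stages <- c(manifest$stages, "enrichment")

      # ---- conservation ---------------------------------------------------
      proj <- read_projection_table(fp("projections.tsv"))
      per_dar <- functional_conservation(
        sim$dars_source, proj, sim$dars_target,
        direct_min = config$conservation$direct_min,
        indirect_min = config$conservation$indirect_min
      )
      cons_summary <- conservation_summary(per_dar)
      ratio <- tissue_rate_ratio(per_dar)
      retention <- identity_retention(per_dar)
      class_tbl <- dplyr::count(per_dar, .data$class, name = "n")
      class_tbl$fraction <- class_tbl$n / sum(class_tbl$n)
      write_result_tsv(per_dar, fp("conservation_per_dar.tsv"))
      write_result_tsv(cons_summary, fp("conservation_summary.tsv"))
      write_result_tsv(ratio, fp("tissue_rate_ratio.tsv"))
      write_result_tsv(class_tbl, fp("conservation_classes.tsv"))
      manifest$stages <- c(manifest$stages, "conservation")

      list(
        out_dir = out_dir, sim = sim, gwas_significant = sig, blocks = blocks,
        tiles = tiles, peaks = peaks, background = bg, enrichment = enr,
        conservation = list(per_dar = per_dar, summary = cons_summary,
                            tissue_rate_ratio = ratio,
                            identity_retention = retention,
                            classes = class_tbl)
      )
  }, error = function(e) {
    manifest$error <<- conditionMessage(e)
    write_manifest("failed")
    abort(sprintf("pipeline failed %s: %s",
                  if (length(manifest$stages) > 0) {
                    paste0("after stage '", manifest$stages[length(manifest$stages)], "'")
                  } else "at stage 'simulate'",
                  conditionMessage(e)),
          class = "crenrich_pipeline_error")
  })
  result$manifest <- write_manifest("ok")
  result
}
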