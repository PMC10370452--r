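#' Pipeline configuration
#'
#' Collects the inputs and thresholds of the full scan-and-association
#' analysis. Defaults are the standard settings of the analysis: 10%
#' missingness, MAF > 0.05 for nSL, the intermediate DAF window
#' `[0.15, 0.50]` with 4% empirical-p bins, component-p removal above 0.5,
#' a top-5% composite significance rule, a 1% empirical threshold for
#' single-statistic scans, LD pruning at r^2 > 0.8 and five genotype PCs.
#'
#' @param vcf path to a phased VCF.
#' @param population_map path to the `sample_id<TAB>population` map (or a
#'   data frame).
#' @param focal,sister,outgroup population labels per role.
#' @param phenotype_table optional TSV (or data frame) with columns
#'   `sample_id`, `sex`, `phenotype` and optional `PC1..PCk`.
#' @param exclusion_list optional path to (or character vector of) sample
#'   ids to drop before any analysis, e.g. relatives.
#' @param ancestral optional TSV (or data frame) `site_id`, `ancestral`
#'   base; when `NULL` the REF allele is taken as ancestral.
#' @param target_site site id tested for association (default: skipped
#'   unless a phenotype table is given; then required).
#' @param log_phenotype log-transform the phenotype before fitting?
#' @param site_max,sample_max,maf_min,daf_range,bin_width,p_max,top_fraction,alpha,r2_max,n_pcs,norm_bin_width
#'   analysis thresholds (see Description).
#' @param seed integer seed for any stochastic step.
#' @param out_dir output directory for [run_pipeline()].
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, population_map, focal, sister, outgroup,
                            phenotype_table = NULL, exclusion_list = NULL,
                            ancestral = NULL, target_site = NULL,
                            log_phenotype = TRUE,
                            site_max = 0.10, sample_max = 0.10,
                            maf_min = 0.05, daf_range = c(0.15, 0.50),
                            bin_width = 0.04, p_max = 0.5,
                            top_fraction = 0.05, alpha = 0.01,
                            r2_max = 0.8, n_pcs = 5L,
                            norm_bin_width = 0.02,
                            seed = 1L, out_dir = tempfile("sweepscan_run_")) {
  stopifnot(top_fraction > 0, top_fraction < 1, alpha > 0, alpha < 1,
            bin_width > 0, daf_range[1] < daf_range[2])
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$daf_range)) args$daf_range <- as.numeric(args$daf_range)
  do.call(pipeline_config, args)
}

#' Run the full selection-scan and association pipeline
#'
#' QC (exclusion list, missingness, polarization), per-site frequencies,
#' PBS, nSL and XP-nSL scans with normalization and 1% empirical
#' thresholds, the composite test, and — when a phenotype table and target
#' site are configured — additive and dominant association fits. Each
#' stage writes a TSV into `config$out_dir`; a JSON manifest records input
#' checksums, per-stage row counts, the package version and the seed. The
#' run is deterministic given inputs and seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the result tables and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  write_tsv <- function(df, name) {
    utils::write.table(df, out(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    nrow(df)
  }

  x <- read_phased_vcf(config$vcf)
  if (!is.null(config$exclusion_list)) {
    excl <- if (file.exists(config$exclusion_list[1]) &&
                length(config$exclusion_list) == 1) {
      readLines(config$exclusion_list)
    } else config$exclusion_list
    x <- hap_subset(x, samples = !(x$sample_id %in% excl))
  }
  x <- missingness_filter(x, config$site_max, config$sample_max)
  anc <- config$ancestral
  if (is.null(anc)) {
    anc <- tibble(site_id = x$site_id, ancestral = x$ref)
  } else if (!is.data.frame(anc)) {
    anc <- utils::read.table(anc, sep = "\t", header = TRUE,
                             colClasses = "character")
  }
  x <- polarize(x, anc)

  partition <- read_population_map(config$population_map,
                                   focal = config$focal,
                                   sister = config$sister,
                                   outgroup = config$outgroup)
  mapped <- x$sample_id %in% partition$sample_id
  if (!all(mapped)) x <- hap_subset(x, samples = mapped)
  check_partition_covers(x, partition)

  rows <- list()
  freqs <- site_frequencies(x, partition)
  rows$site_frequencies <- write_tsv(freqs, "site_frequencies.tsv")

  pbs_tbl <- pbs_scan(x, partition, freqs = freqs)
  pbs_thr <- empirical_threshold(pbs_tbl$pbs, config$alpha)
  rows$pbs <- write_tsv(dplyr::mutate(pbs_tbl, significant =
    !is.na(.data$pbs) & .data$pbs > pbs_thr), "pbs.tsv")

  nsl_tbl <- nsl_scan(x, partition, "focal", maf_min = config$maf_min)
  nsl_tbl <- normalize_scores(nsl_tbl, score = "nsl", freq = "daf",
                              mode = "bins",
                              bin_width = config$norm_bin_width)
  rows$nsl <- write_tsv(nsl_tbl, "nsl.tsv")

  xp_tbl <- xpnsl_scan(x, partition, "focal", "sister")
  xp_tbl <- normalize_scores(xp_tbl, score = "xpnsl", mode = "genomewide")
  xp_thr <- empirical_threshold(xp_tbl$norm, config$alpha)
  rows$xpnsl <- write_tsv(dplyr::mutate(xp_tbl, significant =
    !is.na(.data$norm) & .data$norm > xp_thr), "xpnsl.tsv")

  comp <- composite_scan(x, partition, maf_min = config$maf_min,
                         norm_bin_width = config$norm_bin_width,
                         daf_range = config$daf_range,
                         bin_width = config$bin_width,
                         p_max = config$p_max,
                         top_fraction = config$top_fraction)
  rows$composite <- write_tsv(comp, "composite.tsv")

  assoc <- NULL
  if (!is.null(config$phenotype_table)) {
    if (is.null(config$target_site)) {
      abort("a phenotype table requires `target_site` in the config.")
    }
    ph <- config$phenotype_table
    if (!is.data.frame(ph)) {
      ph <- utils::read.table(ph, sep = "\t", header = TRUE)
    }
    dos_all <- hap_dosage(x)
    site <- match(config$target_site, x$site_id)
    if (is.na(site)) abort(sprintf("target site '%s' not in matrix.", config$target_site))
    pruned <- ld_prune(dos_all, r2_max = config$r2_max)
    pc_cols <- grep("^PC[0-9]+$", names(ph), value = TRUE)
    if (!length(pc_cols)) {
      pcs <- compute_pcs(dos_all[, pruned, drop = FALSE], k = config$n_pcs)
      ph <- dplyr::inner_join(ph, pcs, by = "sample_id")
      pc_cols <- paste0("PC", seq_len(config$n_pcs))
    }
    ## minor-allele additive dosage at the target site
    add <- dos_all[, site]
    daf_t <- mean(add, na.rm = TRUE) / 2
    if (daf_t > 0.5) add <- 2 - add
    df <- dplyr::inner_join(ph, tibble(sample_id = rownames(dos_all),
                                       add = add),
                            by = "sample_id")
    df$dom <- as.integer(df$add > 0)
    df$y <- if (config$log_phenotype) log(df$phenotype) else df$phenotype
    fits <- list(
      additive = fit_association(df, "y", "add",
                                 covariates = c("sex", pc_cols),
                                 model = "additive"),
      dominant = fit_association(dplyr::mutate(df, add = NULL),
                                 "y", "dom",
                                 covariates = c("sex", pc_cols),
                                 model = "dominant")
    )
    assoc <- purrr::map_dfr(fits, glance)
    rows$association <- write_tsv(assoc, "association.tsv")
  }

  inputs <- purrr::compact(list(vcf = config$vcf,
                                population_map = config$population_map,
                                phenotype_table = config$phenotype_table))
  inputs <- inputs[vapply(inputs, is.character, logical(1))]
  manifest <- list(
    package = "sweepscan",
    version = as.character(utils::packageVersion("sweepscan")),
    seed = config$seed,
    input_md5 = as.list(tools::md5sum(unlist(inputs))),
    rows = rows,
    thresholds = list(pbs_1pct = pbs_thr, xpnsl_1pct = xp_thr)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  cfg <- config
  cfg$phenotype_table <- if (is.character(cfg$phenotype_table)) cfg$phenotype_table
  class(cfg) <- NULL
  yaml::write_yaml(purrr::compact(cfg[vapply(cfg, function(v)
    is.character(v) || is.numeric(v) || is.logical(v), logical(1))]),
    out("config.yaml"))

  invisible(list(frequencies = freqs, pbs = pbs_tbl, nsl = nsl_tbl,
                 xpnsl = xp_tbl, composite = comp, association = assoc,
                 manifest = manifest, out_dir = config$out_dir))
}
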