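## Reproducible simulation studies validating each stage of the pipeline.
## These are the package's own calibration experiments: they regenerate
## their inputs from the simulators and measure operating characteristics
## (power, false-flag rate, estimator recovery) at desk scale.

#' Neutral background panel for composite scans
#'
#' Simulates `panel_size` neutral replicate regions and returns their
#' pooled [composite_records()], the desk-scale stand-in for the
#' genome-wide empirical reference distribution against which a query
#' locus is ranked.
#'
#' @param panel_size number of neutral regions.
#' @param params a [sim_params()] template; `s` is forced to 0.
#' @return a list of per-region record tibbles, suitable for
#'   [composite_scan()]'s `background` argument.
#' @export
neutral_panel <- function(panel_size = 8, params = sim_params()) {
  params$s <- 0
  params$condition_daf <- NULL
  params$seed <- NULL
  purrr::map(seq_len(panel_size), function(i) {
    sim <- wright_fisher_sim(params)
    composite_records(sim$haps, sim$partition)
  })
}

#' Sweep detection power of the composite test
#'
#' Simulates `n_sweep` selective-sweep replicates (focal-population DAF
#' conditioned into the intermediate window), runs the composite test for
#' each against a shared neutral background panel, and reports how often
#' the sweep site itself is flagged, together with the flag rate among
#' neutral background sites.
#'
#' @param n_sweep number of sweep replicates.
#' @param panel_size neutral background regions in the reference panel.
#' @param params a [sim_params()] template for the sweep replicates
#'   (default: `s = 0.05` at the package's standard region design).
#' @param norm_bin_width nSL normalization bin width (default 0.10, the
#'   region-scale choice).
#' @param top_fraction composite significance fraction (default 0.05).
#' @param seed RNG seed for the whole study.
#' @return a list: `replicates` (per-replicate tibble), `detection_rate`,
#'   `neutral_flag_rate`.
#' @export
sweep_power_study <- function(n_sweep = 50, panel_size = 8,
                              params = sim_params(s = 0.05,
                                                  condition_daf = c(0.15, 0.50)),
                              norm_bin_width = 0.10, top_fraction = 0.05,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  panel <- neutral_panel(panel_size, params)
  params$seed <- NULL
  reps <- purrr::map_dfr(seq_len(n_sweep), function(r) {
    sim <- wright_fisher_sim(params)
    comp <- suppressWarnings(
      composite_scan(sim$haps, sim$partition,
                     norm_bin_width = norm_bin_width,
                     background = panel, top_fraction = top_fraction)
    )
    q <- comp[comp$region == "query", ]
    focal_row <- q[sim$focal_site, ]
    bg <- comp$region == "background" & !comp$removed
    tibble(
      rep = r,
      focal_daf = sim$focal_daf,
      attempts = sim$attempts,
      focal_flagged = isTRUE(focal_row$significant),
      focal_hmp = focal_row$hmp,
      neutral_flag_rate = mean(comp$significant[bg])
    )
  })
  list(
    replicates = reps,
    detection_rate = mean(reps$focal_flagged),
    neutral_flag_rate = mean(reps$neutral_flag_rate)
  )
}

#' Composite-test calibration on neutral data
#'
#' Pools several neutral simulated regions, runs the composite test, and
#' returns the composite table for calibration checks: within each DAF
#' bin the empirical p-values are rank multiples `k/N`, and the flagged
#' fraction among retained sites equals the configured tail fraction up
#' to tie inflation.
#'
#' @param n_regions neutral regions pooled.
#' @param params a [sim_params()] template; `s` forced to 0.
#' @param norm_bin_width,top_fraction analysis settings (region-scale
#'   defaults).
#' @param seed RNG seed.
#' @return the pooled [composite_test()] table.
#' @export
composite_calibration_study <- function(n_regions = 3,
                                        params = sim_params(),
                                        norm_bin_width = 0.10,
                                        top_fraction = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  regions <- neutral_panel(n_regions, params)
  rec <- dplyr::bind_rows(regions)
  rec <- normalize_scores(rec, score = "nsl", freq = "daf", mode = "bins",
                          bin_width = norm_bin_width)
  rec$abs_nsl <- abs(rec$norm)
  rec <- dplyr::select(rec, -"nsl", -"norm", -"freq_bin")
  suppressWarnings(composite_test(rec, top_fraction = top_fraction))
}

#' Association-model recovery study
#'
#' Repeatedly simulates a cohort (minor-allele dosage, sex, log-scale
#' phenotype with additive genotype effect `beta_g`) and fits the
#' additive model with sex as covariate, measuring estimator bias,
#' confidence-interval coverage and, under `beta_g = 0`, type-I error.
#'
#' @param n_reps replicates.
#' @param n cohort size per replicate.
#' @param beta_g true additive effect on the log scale.
#' @param maf minor allele frequency of the simulated variant.
#' @param beta_sex,sigma sex effect and residual sd (log scale).
#' @param seed RNG seed.
#' @return a list: `fits` (per-replicate tibble with `beta_hat`,
#'   `ci_low`, `ci_high`, `p`), `mean_beta`, `mc_se` (Monte-Carlo
#'   standard error of the mean), `coverage` (CI coverage of `beta_g`),
#'   `reject_rate` (fraction with p < 0.05).
#' @export
association_recovery_study <- function(n_reps = 200, n = 290,
                                       beta_g = 0.20, maf = 0.09,
                                       beta_sex = 0.37, sigma = 0.6,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fits <- purrr::map_dfr(seq_len(n_reps), function(r) {
    dos <- rbinom(n, 2, maf)
    while (var(dos) == 0) dos <- rbinom(n, 2, maf)
    ph <- simulate_phenotypes(dos, beta_g = beta_g, beta_sex = beta_sex,
                              sigma = sigma)
    ph$log_pheno <- log(ph$phenotype)
    fit <- fit_association(ph, "log_pheno", "dosage", covariates = "sex")
    tibble(rep = r, beta_hat = fit$beta, ci_low = fit$ci_low,
           ci_high = fit$ci_high, p = fit$p_value)
  })
  list(
    fits = fits,
    mean_beta = mean(fits$beta_hat),
    mc_se = sd(fits$beta_hat) / sqrt(n_reps),
    coverage = mean(fits$ci_low <= beta_g & fits$ci_high >= beta_g),
    reject_rate = mean(fits$p < 0.05)
  )
}
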