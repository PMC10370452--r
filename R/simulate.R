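#' Simulation parameters
#'
#' Bundles the knobs of the forward Wright-Fisher simulator and the
#' phenotype generator with validated defaults. Time is in discrete
#' generations; splits are given in generations before present. The
#' default deme size, selection strength and sample sizes describe a small
#' three-population design (focal / sister / outgroup) with an optional
#' additive sweep at a central focal site.
#'
#' @param seed integer RNG seed (`NULL` to use the current RNG state).
#' @param n_deme diploid population size per deme.
#' @param n_sites number of segregating-site positions on the simulated
#'   region grid.
#' @param mu per-site, per-generation mutation (allele-flip) probability.
#' @param rho per-adjacent-site, per-gamete crossover probability.
#' @param t_burnin generations the ancestral deme evolves before the first
#'   split.
#' @param t_split_outgroup,t_split_sister generations before present at
#'   which the outgroup and then the sister population split off.
#' @param s,h selection coefficient and dominance of the derived allele at
#'   the focal site in the focal deme (fitness 1, 1 + hs, 1 + 2s);
#'   selection acts from the sister split onward.
#' @param sweep_init_freq frequency at which the focal derived allele
#'   arises in the focal deme at the sister split (single origin: its
#'   initial copies share one donor haplotype).
#' @param condition_daf optional closed interval; replicates are redrawn
#'   until the sampled focal-population DAF at the focal site lands inside
#'   it (rejection conditioning).
#' @param max_attempts redraw budget for segregation / DAF conditioning.
#' @param sample_sizes named diploid sample sizes
#'   (`c(focal = , sister = , outgroup = )`).
#' @param beta_g,beta_sex,sigma phenotype model: additive genotype effect
#'   on the log scale, sex effect, and residual standard deviation.
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(seed = NULL,
                       n_deme = 500L, n_sites = 500L,
                       mu = 2e-5, rho = 2e-4,
                       t_burnin = 80L, t_split_outgroup = 120L,
                       t_split_sister = 60L,
                       s = 0, h = 1, sweep_init_freq = 0.02,
                       condition_daf = NULL, max_attempts = 30L,
                       sample_sizes = c(focal = 46L, sister = 112L,
                                        outgroup = 48L),
                       beta_g = 0.20, beta_sex = 0.37, sigma = 0.6) {
  stopifnot(n_deme >= 2, n_sites >= 2, mu >= 0, mu <= 1, rho >= 0, rho <= 1,
            t_burnin >= 0, t_split_outgroup > t_split_sister,
            t_split_sister >= 1, h >= 0, h <= 1,
            sweep_init_freq > 0, sweep_init_freq < 1,
            all(sample_sizes >= 2), all(sample_sizes <= n_deme),
            sigma > 0)
  if (!is.null(condition_daf)) {
    stopifnot(length(condition_daf) == 2, condition_daf[1] < condition_daf[2])
  }
  structure(as.list(environment()), class = "sim_params")
}

#' Balding-Nichols allele-frequency and genotype simulator
#'
#' Draws, per site, an ancestral frequency `p0` uniform on `p0_range`,
#' then per population a frequency
#' `p_k ~ Beta(p0 (1-F)/F, (1-p0)(1-F)/F)` and diploid genotype counts
#' from Hardy-Weinberg proportions. Under this model the expected
#' Weir-Cockerham FST between populations equals `F`, which makes it the
#' calibration substrate for the FST/PBS estimators.
#'
#' @param f divergence parameter per population (vector; `F = 0` gives
#'   `p_k = p0` exactly).
#' @param n diploid sample size per population.
#' @param n_sites number of independent sites.
#' @param p0_range range of the uniform ancestral-frequency distribution.
#' @param seed optional RNG seed.
#' @return a tibble in the [site_frequencies()] schema (`site_id`,
#'   `population`, `derived_count`, `n_called`, `daf`, `maf`, `n_geno`,
#'   `p_geno`, `het_count`) plus the latent frequencies `p0` and `p_pop`.
#' @export
balding_nichols <- function(f = c(0.1, 0.1), n = c(100L, 100L),
                            n_sites = 5000L, p0_range = c(0.05, 0.95),
                            seed = NULL) {
  stopifnot(length(f) == length(n), all(f >= 0), all(f < 1), all(n >= 1))
  if (!is.null(seed)) set.seed(seed)
  p0 <- runif(n_sites, p0_range[1], p0_range[2])
  site_id <- sprintf("bn%05d", seq_len(n_sites))
  purrr::map_dfr(seq_along(f), function(k) {
    pk <- if (f[k] == 0) p0 else {
      rbeta(n_sites, p0 * (1 - f[k]) / f[k], (1 - p0) * (1 - f[k]) / f[k])
    }
    ## diploid genotype counts under HWE: (aa, Aa, AA) per site
    gc <- vapply(pk, function(p) {
      as.vector(stats::rmultinom(1, n[k], c((1 - p)^2, 2 * p * (1 - p), p^2)))
    }, numeric(3))
    het <- gc[2, ]
    der <- gc[2, ] + 2 * gc[3, ]
    tibble(
      site_id = site_id, population = paste0("pop", k),
      derived_count = der, n_called = 2 * n[k],
      daf = der / (2 * n[k]), maf = pmin(der, 2 * n[k] - der) / (2 * n[k]),
      n_geno = n[k], p_geno = der / (2 * n[k]), het_count = het,
      p0 = p0, p_pop = pk
    )
  })
}

## One Wright-Fisher generation for a deme of L x 2N haplotypes.
## Fitness 1 / 1+hs / 1+2s by focal-site genotype when s != 0.
wf_generation <- function(pop, mu, rho, s = 0, h = 0.5, focal = NULL) {
  l <- nrow(pop)
  n <- ncol(pop) %/% 2L
  w <- rep(1, n)
  if (s != 0 && !is.null(focal)) {
    dos <- pop[focal, 2 * seq_len(n) - 1L] + pop[focal, 2 * seq_len(n)]
    w <- 1 + s * ifelse(dos == 2L, 2, ifelse(dos == 1L, h, 0))
  }
  par <- sample.int(n, 2L * n, replace = TRUE, prob = w)
  a <- pop[, 2L * par - 1L, drop = FALSE]
  b <- pop[, 2L * par, drop = FALSE]
  start <- rbinom(2L * n, 1L, 0.5)
  nx <- rpois(2L * n, rho * (l - 1))
  child <- a
  plain_b <- start == 1L & nx == 0L
  child[, plain_b] <- b[, plain_b, drop = FALSE]
  for (g in which(nx > 0L)) {
    bp <- sample.int(l - 1L, nx[g], replace = TRUE)
    cum <- cumsum(c(0L, tabulate(bp, l - 1L)))
    use_b <- (start[g] + cum) %% 2L == 1L
    child[use_b, g] <- b[use_b, g]
  }
  if (mu > 0) {
    nm <- rbinom(1L, l * 2L * n, mu)
    if (nm > 0L) {
      pos <- sample.int(l * 2L * n, nm)
      child[pos] <- 1L - child[pos]
    }
  }
  child
}

wf_evolve <- function(pop, t, mu, rho, s = 0, h = 0.5, focal = NULL) {
  for (g in seq_len(t)) pop <- wf_generation(pop, mu, rho, s, h, focal)
  pop
}

#' Forward Wright-Fisher simulation of three diverged populations
#'
#' Simulates discrete non-overlapping generations of `n_deme` diploids: an
#' ancestral deme evolves for `t_burnin` generations, the outgroup splits
#' `t_split_outgroup` generations before present, the sister population
#' `t_split_sister` generations before present, and from the sister split
#' onward the derived allele at the central focal site is selected in the
#' focal deme with coefficient `s` and dominance `h`. Gametes recombine
#' with a Poisson number of crossovers (mean `rho * (L - 1)`, positions
#' uniform on adjacent-site boundaries) and alleles flip site-wise with
#' probability `mu` (re-mutation allowed). Founding haplotypes draw each
#' site's derived frequency from a `1/x`-shaped spectrum so the region
#' starts with a realistic DAF distribution. The focal derived allele
#' arises in the focal deme at the sister split, at frequency
#' `sweep_init_freq` on a single donor haplotype background. Output is
#' polarized by construction (ancestral = founding state).
#'
#' Replicates whose sampled focal-population DAF misses `condition_daf`
#' (including loss of the focal allele) are redrawn, up to `max_attempts`
#' times.
#'
#' @param params a [sim_params()] object.
#' @return a list of class `wf_sim`: `haps` (combined [hap_matrix()] over
#'   the three sampled populations), `partition` (a `pop_partition` with
#'   roles focal/sister/outgroup), `focal_site` (site index),
#'   `focal_daf` (sampled focal-population DAF at the focal site),
#'   `attempts`, and `params`.
#' @export
wright_fisher_sim <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  p <- params
  l <- p$n_sites
  focal <- as.integer(ceiling(l / 2))
  for (attempt in seq_len(p$max_attempts)) {
    res <- wf_one_replicate(p, l, focal)
    if (!is.null(res)) {
      res$attempts <- attempt
      if (attempt > 1) {
        inform(sprintf("focal-site conditioning met after %d attempt(s).", attempt))
      }
      return(res)
    }
  }
  abort(paste("focal allele lost (or conditioning never met) in every attempt;",
              "raise `s`, `n_deme` or `max_attempts`."))
}

wf_one_replicate <- function(p, l, focal) {
  two_n <- 2L * p$n_deme
  ## founding spectrum ~ 1/x on [0.05, 0.95]; the focal site is
  ## monomorphic ancestral until the sweep allele arises at onset
  pf <- 0.05 * (0.95 / 0.05)^runif(l)
  pf[focal] <- 0
  anc <- matrix(rbinom(l * two_n, 1L, rep(pf, two_n)), nrow = l)

  anc <- wf_evolve(anc, p$t_burnin, p$mu, p$rho)
  deme_ab <- anc
  deme_c <- anc
  t_mid <- p$t_split_outgroup - p$t_split_sister
  deme_ab <- wf_evolve(deme_ab, t_mid, p$mu, p$rho)
  deme_c <- wf_evolve(deme_c, t_mid, p$mu, p$rho)
  ## the derived allele arises once in the focal deme at the sister split:
  ## its initial copies share one donor haplotype (identity by descent)
  deme_a <- deme_ab
  k <- max(2L, round(two_n * p$sweep_init_freq))
  carriers <- sample.int(two_n, k)
  deme_a[, carriers] <- deme_a[, carriers[1]]
  deme_a[focal, carriers] <- 1L
  deme_a <- wf_evolve(deme_a, p$t_split_sister, p$mu, p$rho,
                      s = p$s, h = p$h, focal = focal)
  deme_b <- wf_evolve(deme_ab, p$t_split_sister, p$mu, p$rho)
  deme_c <- wf_evolve(deme_c, p$t_split_sister, p$mu, p$rho)

  demes <- list(focal = deme_a, sister = deme_b, outgroup = deme_c)
  prefixes <- c(focal = "FOC", sister = "SIS", outgroup = "OUT")
  cols <- list(); ids <- character(0); pops <- character(0)
  for (nm in names(demes)) {
    take <- sort(sample.int(p$n_deme, p$sample_sizes[[nm]]))
    cols[[nm]] <- demes[[nm]][, sample_hap_cols(take), drop = FALSE]
    ids <- c(ids, sprintf("%s%03d", prefixes[[nm]], seq_len(p$sample_sizes[[nm]])))
    pops <- c(pops, rep(nm, p$sample_sizes[[nm]]))
  }
  alleles <- do.call(cbind, cols)
  fa <- alleles[focal, seq_len(2L * p$sample_sizes[["focal"]])]
  focal_daf <- mean(fa)
  if (!is.null(p$condition_daf) &&
      (focal_daf < p$condition_daf[1] || focal_daf > p$condition_daf[2])) {
    return(NULL)
  }
  haps <- hap_matrix(alleles, chrom = "sim1", pos = seq_len(l) * 1000L,
                     sample_id = ids, polarized = TRUE)
  partition <- pop_partition(tibble(sample_id = ids, population = pops),
                             focal = "focal", sister = "sister",
                             outgroup = "outgroup")
  list(haps = haps, partition = partition, focal_site = focal,
       focal_daf = focal_daf, params = p)
}

#' Simulate phenotypes with an additive genotype effect
#'
#' Generates `log(y) = beta_g * dosage + beta_sex * sex + pcs %*% gamma +
#' e`, `e ~ N(0, sigma^2)`, with sex drawn Bernoulli(0.5), and returns the
#' *raw* phenotype `exp(log y)` so a downstream log transform is
#' exercised. Defaults mirror a log-scale exhaled-NO-like trait: additive
#' effect 0.20 per minor allele, a sex difference of 0.37, residual sd
#' 0.6.
#'
#' @param dosage named numeric vector of per-sample genotype dosages.
#' @param beta_g,beta_sex,sigma effect sizes and residual sd (log scale).
#' @param pcs optional matrix/data frame of per-sample covariates
#'   (e.g. PCs) with `gamma` their effects.
#' @param gamma numeric effects for the columns of `pcs`.
#' @param seed optional RNG seed.
#' @return tibble: `sample_id`, `sex` (0/1), `phenotype` (raw scale),
#'   `dosage`.
#' @export
simulate_phenotypes <- function(dosage, beta_g = 0.20, beta_sex = 0.37,
                                sigma = 0.6, pcs = NULL, gamma = NULL,
                                seed = NULL) {
  if (sigma <= 0) abort("`sigma` must be positive.")
  if (!is.null(seed)) set.seed(seed)
  n <- length(dosage)
  ids <- names(dosage) %||% paste0("S", seq_len(n))
  sex <- rbinom(n, 1L, 0.5)
  eta <- beta_g * dosage + beta_sex * sex
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    stopifnot(nrow(pcs) == n, length(gamma) == ncol(pcs))
    eta <- eta + as.vector(pcs %*% gamma)
  }
  y <- eta + rnorm(n, 0, sigma)
  tibble(sample_id = ids, sex = sex, phenotype = exp(y), dosage = dosage)
}
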