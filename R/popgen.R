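#' Per-site, per-population allele frequency table
#'
#' Counts derived alleles, called alleles, genotype-complete diploids and
#' heterozygotes for every site in every population. Allele frequencies
#' (`daf`) use called-allele counting: missing haplotype alleles are
#' excluded from the denominator. The genotype-based columns (`n_geno`,
#' `p_geno`, `het_count`) count only samples with both haplotypes called;
#' they feed the Weir-Cockerham variance components, which are defined on
#' diploid individuals.
#'
#' @param x a polarized [hap_matrix()].
#' @param partition a `pop_partition` (see [read_population_map()]).
#' @return a tibble with one row per site x population: `chrom`, `pos`,
#'   `site_id`, `population`, `derived_count`, `n_called`, `daf`, `maf`,
#'   `n_geno`, `p_geno`, `het_count`.
#' @export
site_frequencies <- function(x, partition) {
  if (!x$polarized) abort("matrix must be polarized before computing frequencies.")
  pops <- unique(partition$population)
  purrr::map_dfr(pops, function(pp) {
    idx <- pop_samples(x, partition, pp)
    a <- x$alleles[, sample_hap_cols(idx), drop = FALSE]
    derived <- rowSums(a == 1L, na.rm = TRUE)
    called <- rowSums(!is.na(a))
    odd <- a[, seq(1L, ncol(a), by = 2L), drop = FALSE]
    even <- a[, seq(2L, ncol(a), by = 2L), drop = FALSE]
    both <- !is.na(odd) & !is.na(even)
    n_geno <- rowSums(both)
    het <- rowSums(both & odd != even, na.rm = TRUE)
    d_geno <- rowSums((odd + even) * both, na.rm = TRUE)
    daf <- ifelse(called > 0, derived / called, NA_real_)
    tibble(
      chrom = x$chrom, pos = x$pos, site_id = x$site_id, population = pp,
      derived_count = derived, n_called = called,
      daf = daf, maf = pmin(daf, 1 - daf),
      n_geno = n_geno,
      p_geno = ifelse(n_geno > 0, d_geno / (2 * n_geno), NA_real_),
      het_count = het
    )
  })
}

#' Per-site Weir-Cockerham FST between two populations
#'
#' Computes the 1984 variance components: `a` (among populations), `b`
#' (among individuals within populations) and `c` (within individuals) from
#' per-population diploid sample sizes, allele frequencies and heterozygote
#' frequencies, and the per-site ratio estimator `fst_raw = a/(a+b+c)`.
#' Negative estimates are clamped to 0 and values above 1 to 1 in `fst`.
#' Sites monomorphic across the pooled pair (`a+b+c = 0`) take the
#' no-differentiation limit `fst = 0` with `fst_raw = NA`; sites where
#' either population has fewer than two genotype-complete diploids are
#' undefined.
#'
#' @param freqs a tibble from [site_frequencies()] (or any tibble with
#'   columns `site_id`, `population`, `n_geno`, `p_geno`, `het_count`; the
#'   simulators emit this schema directly).
#' @param pop_x,pop_y the two population labels.
#' @return per-site tibble: `site_id` (plus `chrom`/`pos` when present),
#'   `a`, `b`, `c`, `fst_raw`, `fst`, `defined`.
#' @export
wc_fst <- function(freqs, pop_x, pop_y) {
  for (pp in c(pop_x, pop_y)) {
    if (!pp %in% freqs$population) abort(sprintf("unknown population label '%s'.", pp))
  }
  fx <- freqs[freqs$population == pop_x, ]
  fy <- freqs[freqs$population == pop_y, ]
  fy <- fy[match(fx$site_id, fy$site_id), ]
  n1 <- fx$n_geno; n2 <- fy$n_geno
  p1 <- fx$p_geno; p2 <- fy$p_geno
  h1 <- ifelse(n1 > 0, fx$het_count / n1, NA_real_)
  h2 <- ifelse(n2 > 0, fy$het_count / n2, NA_real_)

  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar # r - 1 = 1
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)

  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  denom <- a + b + cc
  enough <- n1 >= 2 & n2 >= 2 & is.finite(denom)
  ## a+b+c = 0 happens when the site is monomorphic across the pooled
  ## pair: no differentiation is estimable, and the natural limit is 0
  mono_pair <- enough & denom == 0
  defined <- enough & !is.na(denom)
  fst_raw <- ifelse(defined & denom != 0, a / denom, NA_real_)
  out <- tibble(
    site_id = fx$site_id,
    a = a, b = b, c = cc,
    fst_raw = fst_raw,
    fst = ifelse(mono_pair, 0, pmin(pmax(fst_raw, 0), 1)),
    defined = defined
  )
  if (all(c("chrom", "pos") %in% names(fx))) {
    out <- dplyr::bind_cols(fx[c("chrom", "pos")], out)
  }
  out
}

#' Multi-site Weir-Cockerham FST summary
#'
#' The standard way to combine per-site estimates across loci: the ratio
#' of summed variance components `sum(a) / sum(a + b + c)` over defined
#' sites. Unlike the unweighted mean of per-site ratios — which is biased
#' downward because noisy per-site denominators enter each ratio — this
#' weighted estimator recovers the model divergence parameter in
#' calibration simulations.
#'
#' @param fst_tbl output of [wc_fst()].
#' @return a single FST estimate.
#' @export
wc_fst_global <- function(fst_tbl) {
  d <- fst_tbl[fst_tbl$defined, ]
  if (!nrow(d)) abort("no defined sites.")
  sum(d$a) / sum(d$a + d$b + d$c)
}

#' Population branch statistic
#'
#' Transforms pairwise FST values into branch lengths
#' `T = -ln(1 - fst)` and returns the focal-population branch length
#' `PBS = (T_ab + T_ac - T_bc) / 2` for focal population A against sister B
#' and outgroup C. FST is clamped to `[0, 1 - eps]` before the log so the
#' branch length stays finite; a site undefined in any pair gives `NA`.
#'
#' @param fst_ab,fst_ac,fst_bc numeric vectors of pairwise FST, aligned by
#'   site.
#' @param eps cap keeping `1 - fst` away from zero (default `1e-12`).
#' @return a tibble `t_ab`, `t_ac`, `t_bc`, `pbs`.
#' @export
pbs <- function(fst_ab, fst_ac, fst_bc, eps = 1e-12) {
  n <- length(fst_ab)
  if (length(fst_ac) != n || length(fst_bc) != n) {
    abort("FST vectors must have equal length.")
  }
  branch <- function(f) -log(1 - pmin(pmax(f, 0), 1 - eps))
  t_ab <- branch(fst_ab); t_ac <- branch(fst_ac); t_bc <- branch(fst_bc)
  tibble(t_ab = t_ab, t_ac = t_ac, t_bc = t_bc,
         pbs = (t_ab + t_ac - t_bc) / 2)
}

#' PBS scan over a haplotype matrix
#'
#' Convenience wrapper: computes per-site frequencies, the three pairwise
#' Weir-Cockerham FST series for the focal / sister / outgroup roles, and
#' PBS for the focal population.
#'
#' @param x a polarized [hap_matrix()].
#' @param partition a `pop_partition` with all three roles assigned.
#' @param freqs optionally, a precomputed [site_frequencies()] table.
#' @return per-site tibble: `chrom`, `pos`, `site_id`, `daf_focal`,
#'   `fst_ab`, `fst_ac`, `fst_bc`, `pbs`.
#' @export
pbs_scan <- function(x, partition, freqs = NULL) {
  roles <- attr(partition, "roles")
  if (!all(c("focal", "sister", "outgroup") %in% names(roles))) {
    abort("partition must assign focal, sister and outgroup roles.")
  }
  if (is.null(freqs)) freqs <- site_frequencies(x, partition)
  ab <- wc_fst(freqs, roles[["focal"]], roles[["sister"]])
  ac <- wc_fst(freqs, roles[["focal"]], roles[["outgroup"]])
  bc <- wc_fst(freqs, roles[["sister"]], roles[["outgroup"]])
  p <- pbs(ab$fst, ac$fst, bc$fst)
  n_undef <- sum(!(ab$defined & ac$defined & bc$defined))
  if (n_undef > 0) {
    inform(sprintf("%d site(s) undefined in at least one pairwise FST.", n_undef))
  }
  daf_focal <- freqs$daf[freqs$population == roles[["focal"]]]
  tibble(
    chrom = x$chrom, pos = x$pos, site_id = x$site_id,
    daf_focal = daf_focal,
    fst_ab = ab$fst, fst_ac = ac$fst, fst_bc = bc$fst,
    pbs = p$pbs
  )
}

#' Upper-tail empirical significance threshold
#'
#' Returns the smallest observed value `v` such that the fraction of values
#' strictly greater than `v` is at most `alpha` — the empirical
#' `(1 - alpha)` quantile used for genome-wide significance calls.
#'
#' @param values finite statistic values.
#' @param alpha upper tail fraction (e.g. 0.01).
#' @return a single threshold value.
#' @export
empirical_threshold <- function(values, alpha) {
  values <- values[is.finite(values)]
  if (!length(values)) abort("no finite values supplied.")
  stopifnot(alpha > 0, alpha < 1)
  u <- sort(unique(values))
  n <- length(values)
  n_gt <- n - cumsum(tabulate(match(values, u), nbins = length(u)))
  u[match(TRUE, n_gt / n <= alpha)]
}
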