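# Independent oracles and fixture builders. Each oracle is a deliberately
# naive transcription (scalar loops, no shared code with the package
# internals) so agreement is informative.

# Weir & Cockerham (1984) two-population variance components, scalar form.
# n: diploid counts; p: allele frequencies; het: heterozygote frequencies.
oracle_wc <- function(n1, p1, het1, n2, p2, het2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * het1 + n2 * het2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       fst = if (a + b + cc == 0) NA_real_ else a / (a + b + cc))
}

# Shared length of one haplotype pair at a focal site: explicit left/right
# walk. Missing alleles match anything.
oracle_sl_pair <- function(alleles, i, j, f) {
  agrees <- function(s) {
    x <- alleles[s, i]; y <- alleles[s, j]
    is.na(x) || is.na(y) || x == y
  }
  if (!agrees(f)) return(0)
  lo <- f
  while (lo > 1 && agrees(lo - 1)) lo <- lo - 1
  hi <- f
  while (hi < nrow(alleles) && agrees(hi + 1)) hi <- hi + 1
  hi - lo + 1
}

oracle_mean_sl <- function(alleles, hap_set, f) {
  if (length(hap_set) < 2) return(NA_real_)
  tot <- 0; np <- 0
  for (ii in seq_along(hap_set)) {
    for (jj in seq_along(hap_set)) {
      if (jj <= ii) next
      tot <- tot + oracle_sl_pair(alleles, hap_set[ii], hap_set[jj], f)
      np <- np + 1
    }
  }
  tot / np
}

oracle_nsl <- function(alleles, f) {
  anc <- which(!is.na(alleles[f, ]) & alleles[f, ] == 0)
  der <- which(!is.na(alleles[f, ]) & alleles[f, ] == 1)
  if (length(anc) < 2 || length(der) < 2) return(NA_real_)
  log(oracle_mean_sl(alleles, anc, f) / oracle_mean_sl(alleles, der, f))
}

random_hap_matrix <- function(n_sites, n_samples, miss_rate = 0,
                              freq_range = c(0.1, 0.9)) {
  p <- runif(n_sites, freq_range[1], freq_range[2])
  a <- matrix(rbinom(n_sites * 2 * n_samples, 1, rep(p, 2 * n_samples)),
              nrow = n_sites)
  if (miss_rate > 0) {
    a[runif(length(a)) < miss_rate] <- NA_integer_
  }
  hap_matrix(a, chrom = "chr1", pos = seq_len(n_sites) * 100L,
             polarized = TRUE)
}

# Minimal phased VCF text for toy cases.
toy_vcf <- function(path, gt_rows, samples = c("S1", "S2"),
                    chrom = "chr1", pos = NULL, ref = "A", alt = "G",
                    extra_rows = character(0)) {
  n <- length(gt_rows)
  if (is.null(pos)) pos <- seq_len(n) * 10L
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(n), function(i) {
    paste(c(chrom, pos[i], ".", ref, alt, ".", "PASS", ".", "GT",
            gt_rows[[i]]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body, extra_rows), path)
  path
}

# A small three-population simulated data set shared across tests.
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- sim_params(seed = 400, n_deme = 120L, n_sites = 80L,
                      sample_sizes = c(focal = 15L, sister = 15L,
                                       outgroup = 15L))
      cache <<- suppressMessages(wright_fisher_sim(p))
    }
    cache
  }
})
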