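#' Phased haplotype matrix
#'
#' The substrate of every scan statistic: a sites x haplotypes matrix of
#' binary alleles from phased diploid genotypes. Before polarization allele
#' 1 means ALT; after [polarize()] it means derived. Haplotypes `2k - 1` and
#' `2k` belong to diploid sample `k`. Missing alleles are `NA`.
#'
#' @param alleles integer matrix, `n_sites x n_haplotypes`, values 0/1/`NA`.
#' @param chrom chromosome label per site (recycled if length 1).
#' @param pos physical 1-based position per site, strictly increasing within
#'   a chromosome.
#' @param site_id variant identifier per site (rsID or `chrom:pos`).
#' @param ref,alt reference / alternate allele base per site.
#' @param sample_id one id per diploid sample (`n_haplotypes / 2`).
#' @param polarized logical flag: has allele 1 been recoded to mean derived?
#'
#' @return An object of class `hap_matrix`.
#' @seealso [read_phased_vcf()], [polarize()], [missingness_filter()]
#' @export
hap_matrix <- function(alleles, chrom, pos, site_id = NULL, ref = NULL,
                       alt = NULL, sample_id = NULL, polarized = FALSE) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n_sites <- nrow(alleles)
  n_hap <- ncol(alleles)
  if (n_hap %% 2L != 0L) {
    abort("`alleles` must have an even number of haplotype columns (diploids).")
  }
  if (!all(alleles %in% c(0L, 1L) | is.na(alleles))) {
    abort("allele values must be 0, 1 or NA.")
  }
  chrom <- rep_len(as.character(chrom), n_sites)
  pos <- as.integer(pos)
  if (length(pos) != n_sites) abort("`pos` must have one entry per site.")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0)) {
      abort(sprintf("positions must be strictly increasing within chromosome %s.", ch))
    }
  }
  if (is.null(site_id)) site_id <- paste0(chrom, ":", pos)
  if (is.null(ref)) ref <- rep("A", n_sites)
  if (is.null(alt)) alt <- rep("G", n_sites)
  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(n_hap %/% 2L))
  if (length(sample_id) != n_hap %/% 2L) {
    abort("`sample_id` must have one entry per diploid sample.")
  }
  structure(
    list(
      alleles = alleles,
      chrom = chrom,
      pos = pos,
      site_id = as.character(site_id),
      ref = as.character(ref),
      alt = as.character(alt),
      sample_id = as.character(sample_id),
      polarized = isTRUE(polarized)
    ),
    class = "hap_matrix"
  )
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf(
    "<hap_matrix> %d sites x %d haplotypes (%d samples), %s\n",
    n_sites(x), n_haplotypes(x), n_samples(x),
    if (x$polarized) "polarized (1 = derived)" else "unpolarized (1 = ALT)"
  ))
  miss <- mean(is.na(x$alleles))
  cat(sprintf("  chrom %s, pos %d-%d, %.2f%% missing\n",
              paste(unique(x$chrom), collapse = ","),
              min(x$pos), max(x$pos), 100 * miss))
  invisible(x)
}

#' @rdname hap_matrix
#' @param x a `hap_matrix`.
#' @export
n_sites <- function(x) nrow(x$alleles)

#' @rdname hap_matrix
#' @export
n_haplotypes <- function(x) ncol(x$alleles)

#' @rdname hap_matrix
#' @export
n_samples <- function(x) ncol(x$alleles) %/% 2L

#' Subset a haplotype matrix by site and/or sample
#'
#' @param x a `hap_matrix`.
#' @param sites integer or logical index over sites.
#' @param samples integer or logical index over diploid samples (both
#'   haplotypes of a sample are kept or dropped together).
#' @return a `hap_matrix`.
#' @export
hap_subset <- function(x, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(x))
  if (is.null(samples)) samples <- seq_len(n_samples(x))
  sites <- seq_len(n_sites(x))[sites]
  samples <- seq_len(n_samples(x))[samples]
  hap_cols <- as.vector(rbind(2L * samples - 1L, 2L * samples))
  hap_matrix(
    x$alleles[sites, hap_cols, drop = FALSE],
    chrom = x$chrom[sites], pos = x$pos[sites], site_id = x$site_id[sites],
    ref = x$ref[sites], alt = x$alt[sites],
    sample_id = x$sample_id[samples], polarized = x$polarized
  )
}

#' Haplotype columns belonging to a set of samples
#' @noRd
sample_hap_cols <- function(sample_idx) {
  as.vector(rbind(2L * sample_idx - 1L, 2L * sample_idx))
}

#' Per-sample diploid dosages from a haplotype matrix
#'
#' Sums the two haplotype alleles of each sample. A sample with either
#' haplotype missing at a site gets `NA` there.
#'
#' @param x a `hap_matrix`.
#' @return integer matrix, samples x sites, entries 0/1/2/`NA`;
#'   column names are site ids, row names sample ids.
#' @export
hap_dosage <- function(x) {
  a <- x$alleles
  odd <- a[, seq(1L, ncol(a), by = 2L), drop = FALSE]
  even <- a[, seq(2L, ncol(a), by = 2L), drop = FALSE]
  d <- t(odd + even)
  dimnames(d) <- list(x$sample_id, x$site_id)
  d
}

#' @method as_tibble hap_matrix
#' @export
as_tibble.hap_matrix <- function(x, ...) {
  tibble(
    chrom = x$chrom, pos = x$pos, site_id = x$site_id,
    ref = x$ref, alt = x$alt,
    alt_count = rowSums(x$alleles == 1L, na.rm = TRUE),
    called = rowSums(!is.na(x$alleles))
  )
}
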