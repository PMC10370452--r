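## Shared-haplotype-length engine.
##
## For an unordered haplotype pair (i, j), SL at focal site f is the number
## of sites in the maximal contiguous run containing f over which i and j
## carry identical alleles; the run extends to the first mismatch on each
## side or the matrix edge, the focal site itself is counted, and a pair
## that mismatches at f has SL = 0 (no identity run contains f). A site at
## which either haplotype is missing never breaks a run (treated as a
## match) but still counts toward its length.

## Per-site pair-set accumulators for one haplotype set: sums and pair
## counts of SL over (all, both-ancestral, both-derived) pairs. Chunked
## over pairs to bound memory at ~chunk x n_sites doubles.
sl_pair_stats <- function(a, chunk = 20000L) {
  l <- nrow(a); h <- ncol(a)
  if (h < 2L) return(NULL)
  pr <- which(upper.tri(matrix(0, h, h)), arr.ind = TRUE)
  ii <- pr[, 1]; jj <- pr[, 2]
  np <- length(ii)
  zero <- numeric(l)
  acc <- list(sum_all = zero, n_all = zero, sum_anc = zero, n_anc = zero,
              sum_der = zero, n_der = zero)
  for (st in seq(1L, np, by = chunk)) {
    en <- min(st + chunk - 1L, np)
    a1 <- a[, ii[st:en], drop = FALSE]
    a2 <- a[, jj[st:en], drop = FALSE]
    m <- a1 != a2
    m[is.na(m)] <- FALSE
    p <- ncol(m)
    ## prev[f,]: index of last mismatch at or before f (0 if none);
    ## nxt[f,]: first mismatch at or after f (l + 1 if none)
    prev <- matrix(0L, l, p)
    run <- rep(0L, p)
    for (f in seq_len(l)) {
      run <- ifelse(m[f, ], f, run)
      prev[f, ] <- run
    }
    nxt <- matrix(l + 1L, l, p)
    run <- rep(l + 1L, p)
    for (f in rev(seq_len(l))) {
      run <- ifelse(m[f, ], f, run)
      nxt[f, ] <- run
    }
    sl <- nxt - prev - 1L
    sl[m] <- 0L
    d1 <- a1 == 1L & !is.na(a1); d2 <- a2 == 1L & !is.na(a2)
    c1 <- a1 == 0L & !is.na(a1); c2 <- a2 == 0L & !is.na(a2)
    both_der <- d1 & d2
    both_anc <- c1 & c2
    acc$sum_all <- acc$sum_all + rowSums(sl)
    acc$n_all <- acc$n_all + p
    acc$sum_anc <- acc$sum_anc + rowSums(sl * both_anc)
    acc$n_anc <- acc$n_anc + rowSums(both_anc)
    acc$sum_der <- acc$sum_der + rowSums(sl * both_der)
    acc$n_der <- acc$n_der + rowSums(both_der)
  }
  acc
}

#' Mean pairwise shared-haplotype length at a focal site
#'
#' Averages SL (shared length in segregating sites, see Details) over all
#' unordered pairs of the given haplotypes. With fewer than two haplotypes
#' the statistic is undefined and `NA` is returned.
#'
#' @details SL for a pair at a focal site is the length, in matrix sites,
#' of the maximal contiguous run of identical alleles containing the focal
#' site; runs truncate at the matrix edges, missing alleles match anything,
#' and a pair differing at the focal site scores 0.
#'
#' @param x a [hap_matrix()].
#' @param focal_site site index (1-based row of the matrix).
#' @param haplotypes integer vector of haplotype column indices
#'   (default: all).
#' @return mean SL, a single number `>= 0`.
#' @export
pairwise_sl <- function(x, focal_site, haplotypes = NULL) {
  if (is.null(haplotypes)) haplotypes <- seq_len(n_haplotypes(x))
  if (length(haplotypes) < 2L) return(NA_real_)
  acc <- sl_pair_stats(x$alleles[, haplotypes, drop = FALSE])
  acc$sum_all[focal_site] / acc$n_all[focal_site]
}

#' nSL scan within one population
#'
#' For every site with minor allele frequency above `maf_min` and at least
#' two ancestral and two derived carrier haplotypes, computes the mean
#' pairwise shared length among ancestral carriers (`sl_anc`) and among
#' derived carriers (`sl_der`) and the raw statistic
#' `nsl = ln(sl_anc / sl_der)`. Unusually long derived haplotypes — the
#' footprint of a sweep on the derived allele — give large negative raw
#' scores under this orientation; the composite test uses the absolute
#' normalized score, so the orientation does not affect significance calls.
#'
#' @param x a polarized [hap_matrix()].
#' @param partition optional `pop_partition`; with `population`, restricts
#'   the scan to that population's haplotypes.
#' @param population population label or role name (requires `partition`).
#' @param maf_min minor allele frequency cutoff (strict, default 0.05).
#' @return per-site tibble: `chrom`, `pos`, `site_id`, `daf`, `maf`,
#'   `n_anc`, `n_der`, `sl_anc`, `sl_der`, `nsl`, `defined`.
#' @export
nsl_scan <- function(x, partition = NULL, population = NULL, maf_min = 0.05) {
  if (!x$polarized) abort("matrix must be polarized for nSL (needs derived alleles).")
  cols <- if (is.null(partition)) {
    seq_len(n_haplotypes(x))
  } else {
    sample_hap_cols(pop_samples(x, partition, population %||% "focal"))
  }
  a <- x$alleles[, cols, drop = FALSE]
  acc <- sl_pair_stats(a)
  der <- rowSums(a == 1L, na.rm = TRUE)
  called <- rowSums(!is.na(a))
  daf <- ifelse(called > 0, der / called, NA_real_)
  maf <- pmin(daf, 1 - daf)
  n_der_hap <- der
  n_anc_hap <- rowSums(a == 0L, na.rm = TRUE)
  sl_anc <- ifelse(acc$n_anc > 0, acc$sum_anc / acc$n_anc, NA_real_)
  sl_der <- ifelse(acc$n_der > 0, acc$sum_der / acc$n_der, NA_real_)
  ok <- !is.na(maf) & maf > maf_min & n_anc_hap >= 2L & n_der_hap >= 2L &
    !is.na(sl_anc) & !is.na(sl_der) & sl_anc > 0 & sl_der > 0
  tibble(
    chrom = x$chrom, pos = x$pos, site_id = x$site_id,
    daf = daf, maf = maf,
    n_anc = n_anc_hap, n_der = n_der_hap,
    sl_anc = sl_anc, sl_der = sl_der,
    nsl = ifelse(ok, log(sl_anc / sl_der), NA_real_),
    defined = ok
  )
}

#' XP-nSL scan between two populations
#'
#' Per site, averages SL over *all* within-population haplotype pairs (no
#' conditioning on the focal allele) in each population and reports
#' `xpnsl = ln(sl_pop1 / sl_pop2)`. Positive values indicate longer shared
#' haplotypes — candidate selection — in `pop1`.
#'
#' @param x a polarized [hap_matrix()] holding both populations.
#' @param partition a `pop_partition`.
#' @param pop1,pop2 population labels or role names (defaults: focal,
#'   sister).
#' @return per-site tibble: `chrom`, `pos`, `site_id`, `daf_pop1`,
#'   `sl_pop1`, `sl_pop2`, `xpnsl`, `defined`.
#' @export
xpnsl_scan <- function(x, partition, pop1 = "focal", pop2 = "sister") {
  if (!x$polarized) abort("matrix must be polarized.")
  sl_of <- function(pp) {
    a <- x$alleles[, sample_hap_cols(pop_samples(x, partition, pp)), drop = FALSE]
    if (ncol(a) < 2L) abort(sprintf("population '%s' needs >= 2 haplotypes.", pp))
    acc <- sl_pair_stats(a)
    list(sl = acc$sum_all / acc$n_all, a = a)
  }
  s1 <- sl_of(pop1); s2 <- sl_of(pop2)
  called <- rowSums(!is.na(s1$a))
  daf1 <- ifelse(called > 0, rowSums(s1$a == 1L, na.rm = TRUE) / called, NA_real_)
  ok <- s1$sl > 0 & s2$sl > 0
  tibble(
    chrom = x$chrom, pos = x$pos, site_id = x$site_id,
    daf_pop1 = daf1,
    sl_pop1 = s1$sl, sl_pop2 = s2$sl,
    xpnsl = ifelse(ok, log(s1$sl / s2$sl), NA_real_),
    defined = ok
  )
}

#' Normalize scan scores within allele-frequency bins
#'
#' Standardizes a raw score column to zero mean and unit (population)
#' standard deviation, either within equal-width frequency bins (the convention for
#' nSL, which has a strong frequency dependence) or over all defined scores
#' at once (`mode = "genomewide"`, the convention for XP-nSL). Bins with
#' fewer than `min_bin` defined scores, or zero variance, leave their
#' scores undefined.
#'
#' @param scores a tibble holding raw scores (e.g. from [nsl_scan()]).
#' @param score,freq column names of the raw score and of the allele
#'   frequency used for binning (ignored for genome-wide mode).
#' @param mode `"bins"` or `"genomewide"`.
#' @param bin_width frequency bin width (default 0.02). For region-scale
#'   data with few hundred sites, widen (e.g. 0.10) so each bin holds
#'   enough scores to estimate its mean and sd.
#' @param min_bin minimum defined scores per bin (default 2).
#' @return `scores` with added columns `freq_bin` (integer id, `NA` outside
#'   any bin) and `norm` (standardized score).
#' @export
normalize_scores <- function(scores, score = "nsl", freq = "daf",
                             mode = c("bins", "genomewide"),
                             bin_width = 0.02, min_bin = 2L) {
  mode <- match.arg(mode)
  stopifnot(bin_width > 0)
  s <- scores[[score]]
  if (mode == "genomewide") {
    bin <- ifelse(is.na(s), NA_integer_, 0L)
  } else {
    f <- scores[[freq]]
    bin <- as.integer(pmin(floor(f / bin_width), ceiling(1 / bin_width) - 1L))
    bin[is.na(s) | is.na(f)] <- NA_integer_
  }
  out <- dplyr::mutate(scores, freq_bin = bin)
  pop_sd <- function(v) {
    v <- v[!is.na(v)]
    sqrt(mean((v - mean(v))^2))
  }
  grp <- dplyr::group_by(out, .data$freq_bin)
  out <- dplyr::ungroup(dplyr::mutate(
    grp,
    .n_def = sum(!is.na(.data[[score]])),
    .mu = mean(.data[[score]], na.rm = TRUE),
    .sd = pop_sd(.data[[score]]),
    norm = ifelse(
      is.na(.data$freq_bin) | .data$.n_def < min_bin |
        is.na(.data$.sd) | .data$.sd == 0,
      NA_real_,
      (.data[[score]] - .data$.mu) / .data$.sd
    )
  ))
  n_dropped <- sum(!is.na(out[[score]]) & is.na(out$norm))
  if (n_dropped > 0) {
    inform(sprintf("%d score(s) left undefined by bin normalization.", n_dropped))
  }
  dplyr::select(out, -".n_def", -".mu", -".sd")
}
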