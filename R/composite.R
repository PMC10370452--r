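#' Assign derived-allele-frequency bins
#'
#' Bins are left-closed / right-open intervals of width `bin_width`
#' starting at `range_low`; the final (possibly truncated) bin is closed at
#' `range_high`. DAF outside `[range_low, range_high]` gets no bin (`NA`).
#'
#' @param daf derived allele frequencies in `[0, 1]`.
#' @param bin_width bin width (default 0.04, i.e. 4% DAF bins).
#' @param range_low,range_high binned interval (defaults 0.15 and 0.50).
#' @return integer bin ids starting at 0, `NA` outside the range.
#' @export
assign_daf_bins <- function(daf, bin_width = 0.04, range_low = 0.15,
                            range_high = 0.50) {
  if (bin_width <= 0) abort("`bin_width` must be positive.")
  n_bins <- ceiling((range_high - range_low) / bin_width - 1e-9)
  b <- floor((daf - range_low) / bin_width + 1e-9)
  b <- as.integer(pmin(b, n_bins - 1L)) # closed right edge of final bin
  b[is.na(daf) | daf < range_low | daf > range_high] <- NA_integer_
  b
}

#' Flag sites outside the intermediate-DAF window
#'
#' The composite test targets beneficial alleles at intermediate derived
#' allele frequency; sites with DAF outside the closed interval
#' `[low, high]` are flagged removed (reason `"daf_outside"`).
#'
#' @param records a tibble with a `daf` column.
#' @param low,high closed interval bounds (defaults 0.15, 0.50).
#' @return `records` with logical `removed` and character `removed_reason`
#'   columns added (or updated: existing removal flags are kept).
#' @export
intermediate_daf_filter <- function(records, low = 0.15, high = 0.50) {
  if (low >= high) abort("`low` must be less than `high`.")
  if (!"removed" %in% names(records)) {
    records$removed <- FALSE
    records$removed_reason <- NA_character_
  }
  out_of_window <- !records$removed & (is.na(records$daf) |
    records$daf < low | records$daf > high)
  records$removed_reason[out_of_window] <- "daf_outside"
  records$removed[out_of_window] <- TRUE
  records
}

#' Bin-wise upper-tail empirical p-values
#'
#' Within each bin, `p_i = #\{j in bin: s_j >= s_i\} / N_bin` (the site
#' itself included, ties share the larger p), so p-values lie in
#' `[1/N_bin, 1]`. A singleton bin gives p = 1.
#'
#' @param statistic per-site statistic values (larger = more extreme).
#' @param bins integer bin ids from [assign_daf_bins()]; `NA` bin or `NA`
#'   statistic yields `NA` p.
#' @return numeric p-values aligned with `statistic`.
#' @export
empirical_pvalues <- function(statistic, bins) {
  if (length(statistic) != length(bins)) abort("lengths differ.")
  p <- rep(NA_real_, length(statistic))
  ok <- !is.na(bins) & !is.na(statistic)
  for (b in unique(bins[ok])) {
    i <- which(ok & bins == b)
    s <- statistic[i]
    n <- length(s)
    p[i] <- (n - rank(s, ties.method = "min") + 1) / n
  }
  p
}

#' Harmonic mean p-value of two dependent tests
#'
#' `hmp = (w1 + w2) / (w1/p1 + w2/p2)`; with equal weights this is
#' `2 p1 p2 / (p1 + p2)`, which always lies between `min(p1, p2)` and
#' `max(p1, p2)`. The harmonic mean p-value is only reliable when the
#' component p-values are below 0.5, so pairs where either p exceeds
#' `p_max` return `NA` (the site is to be removed, not combined).
#'
#' @param p1,p2 p-values in `(0, 1]`.
#' @param weights two non-negative weights summing to 1.
#' @param p_max component p-value ceiling (default 0.5; set to 1 to
#'   disable).
#' @return merged p-values; `NA` where a component is `NA` or exceeds
#'   `p_max`.
#' @export
hmp_combine <- function(p1, p2, weights = c(0.5, 0.5), p_max = 0.5) {
  stopifnot(length(weights) == 2, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-9)
  if (any(p1 <= 0 | p1 > 1, na.rm = TRUE) || any(p2 <= 0 | p2 > 1, na.rm = TRUE)) {
    abort("p-values must lie in (0, 1].")
  }
  hmp <- (weights[1] + weights[2]) / (weights[1] / p1 + weights[2] / p2)
  hmp[is.na(p1) | is.na(p2) | p1 > p_max | p2 > p_max] <- NA_real_
  hmp
}

#' Flag the top fraction of most extreme merged p-values
#'
#' Flags the `ceiling(fraction * N)` smallest `hmp` values among
#' non-removed sites as significant; ties at the cutoff are all included
#' (with a warning when that inflates the count).
#'
#' @param records a tibble with `hmp` and `removed` columns.
#' @param fraction tail fraction (default 0.05).
#' @return `records` with a logical `significant` column.
#' @export
top_fraction_significant <- function(records, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  keep <- !records$removed & !is.na(records$hmp)
  if (!any(keep)) abort("no non-removed sites with a merged p-value.")
  h <- records$hmp[keep]
  k <- ceiling(fraction * length(h))
  cutoff <- sort(h)[k]
  sig <- keep & records$hmp <= cutoff
  if (sum(sig) > k) {
    warn(sprintf("ties at the cutoff: %d sites flagged for a target of %d.",
                 sum(sig), k))
  }
  records$significant <- sig
  records
}

#' Composite selection test on per-site records
#'
#' The composite pipeline on an already-assembled per-site table: restrict
#' to intermediate DAF, assign DAF bins, convert PBS and \\|normalized
#' nSL\\| to bin-wise empirical p-values, remove sites where either p
#' exceeds `p_max`, merge the rest with the harmonic mean p-value, and
#' flag the top `top_fraction` as significant.
#'
#' @param records tibble with columns `daf`, `pbs`, `abs_nsl` (absolute
#'   normalized nSL), plus any identifier columns which are carried
#'   through.
#' @param daf_range closed intermediate-DAF window (default
#'   `c(0.15, 0.50)`).
#' @param bin_width empirical-p DAF bin width (default 0.04).
#' @param p_max component p-value removal threshold (default 0.5).
#' @param top_fraction significant tail fraction (default 0.05).
#' @param weights HMP weights (default equal).
#' @return `records` with added columns `daf_bin`, `p_pbs`, `p_nsl`,
#'   `hmp`, `removed`, `removed_reason`, `significant`.
#' @export
composite_test <- function(records, daf_range = c(0.15, 0.50),
                           bin_width = 0.04, p_max = 0.5,
                           top_fraction = 0.05, weights = c(0.5, 0.5)) {
  req <- c("daf", "pbs", "abs_nsl")
  if (!all(req %in% names(records))) {
    abort(sprintf("records must have columns %s.", paste(req, collapse = ", ")))
  }
  records$removed <- FALSE
  records$removed_reason <- NA_character_
  undef <- is.na(records$pbs) | is.na(records$abs_nsl)
  records$removed_reason[undef] <- "undefined_stat"
  records$removed[undef] <- TRUE
  records <- intermediate_daf_filter(records, daf_range[1], daf_range[2])
  records$daf_bin <- assign_daf_bins(records$daf, bin_width,
                                     daf_range[1], daf_range[2])
  records$daf_bin[records$removed] <- NA_integer_
  records$p_pbs <- empirical_pvalues(ifelse(records$removed, NA, records$pbs),
                                     records$daf_bin)
  records$p_nsl <- empirical_pvalues(ifelse(records$removed, NA, records$abs_nsl),
                                     records$daf_bin)
  records$hmp <- hmp_combine(records$p_pbs, records$p_nsl,
                             weights = weights, p_max = p_max)
  p_big <- !records$removed & !is.na(records$p_pbs) & !is.na(records$p_nsl) &
    (records$p_pbs > p_max | records$p_nsl > p_max)
  records$removed_reason[p_big] <- "p_above_half"
  records$removed[p_big] <- TRUE
  if (!any(!records$removed & !is.na(records$hmp))) {
    warn("no sites retained by the composite filters; nothing flagged.")
    records$significant <- FALSE
    return(records)
  }
  top_fraction_significant(records, top_fraction)
}

#' Raw per-site records for the composite test
#'
#' Computes, for one region, the per-site focal DAF, PBS, and raw
#' (unnormalized) nSL. Records from several regions can be row-bound
#' before normalization and testing, emulating the genome-wide empirical
#' reference the composite test assumes: a scanned locus should be ranked
#' against a predominantly neutral background, not only against its own
#' linked sites.
#'
#' @param x a polarized [hap_matrix()].
#' @param partition a `pop_partition` with all three roles.
#' @param maf_min nSL minor-allele-frequency cutoff (default 0.05).
#' @return per-site tibble: `chrom`, `pos`, `site_id`, `daf`, `pbs`,
#'   `nsl` (raw).
#' @export
composite_records <- function(x, partition, maf_min = 0.05) {
  pbs_tbl <- pbs_scan(x, partition)
  nsl_tbl <- nsl_scan(x, partition, "focal", maf_min = maf_min)
  dplyr::bind_cols(
    dplyr::select(pbs_tbl, "chrom", "pos", "site_id", daf = "daf_focal", "pbs"),
    dplyr::select(nsl_tbl, "nsl")
  )
}

#' Composite selection scan from haplotype matrices
#'
#' End-to-end wrapper: PBS scan for the focal/sister/outgroup roles, nSL
#' scan within the focal population normalized in frequency bins, then
#' [composite_test()] on the merged per-site table. `background` supplies
#' additional regions (e.g. neutral simulations or other loci) whose
#' records are pooled into the normalization and empirical-p reference —
#' the desk-scale stand-in for a genome-wide empirical distribution.
#'
#' @param x a polarized [hap_matrix()].
#' @param partition a `pop_partition` with all three roles.
#' @param maf_min nSL minor-allele-frequency cutoff (default 0.05).
#' @param norm_bin_width nSL normalization bin width passed to
#'   [normalize_scores()] (default 0.02; widen for region-scale data).
#' @param background optional list of `list(x = , partition = )` regions
#'   (or precomputed [composite_records()] tibbles) pooled into the
#'   reference.
#' @param ... further arguments to [composite_test()].
#' @return the [composite_test()] table with `chrom`, `pos`, `site_id`,
#'   `region`, `daf`, `pbs`, `abs_nsl` columns; `region` is `"query"` for
#'   sites of `x` and `"background"` otherwise.
#' @export
composite_scan <- function(x, partition, maf_min = 0.05,
                           norm_bin_width = 0.02, background = NULL, ...) {
  rec <- composite_records(x, partition, maf_min = maf_min)
  rec$region <- "query"
  for (bg in background %||% list()) {
    br <- if (is.data.frame(bg)) bg else {
      composite_records(bg$x, bg$partition, maf_min = maf_min)
    }
    br$region <- "background"
    rec <- dplyr::bind_rows(rec, br)
  }
  rec <- normalize_scores(rec, score = "nsl", freq = "daf",
                          mode = "bins", bin_width = norm_bin_width)
  rec$abs_nsl <- abs(rec$norm)
  rec <- dplyr::select(rec, -"nsl", -"norm", -"freq_bin")
  composite_test(rec, ...)
}
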