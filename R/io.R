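#' Read a phased VCF into a haplotype matrix
#'
#' Parses biallelic SNVs from a (plain or bgzipped) VCF 4.x file with phased
#' GT fields. Multi-allelic and indel records are skipped with a warning;
#' an unphased separator (`/`) at a retained site is an error, except the
#' fully missing genotype `./.` which is read as two missing alleles.
#'
#' @param path VCF file path.
#' @param region optional `"chrom:start-end"` restriction (1-based,
#'   inclusive).
#' @return a [hap_matrix()] with 0 = REF, 1 = ALT, `polarized = FALSE`.
#' @export
read_phased_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  id <- fix[, "ID"]
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]

  keep <- rep(TRUE, length(pos))
  snv <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!snv)) {
    warn(sprintf("skipping %d non-biallelic-SNV record(s).", sum(!snv)))
    keep <- keep & snv
  }
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) abort("`region` must look like 'chr:start-end'.")
    keep <- keep & chrom == m[2] & pos >= as.integer(m[3]) & pos <= as.integer(m[4])
    if (!any(keep)) abort(sprintf("region %s contains no retained sites.", region))
  }
  if (!any(keep)) abort("no biallelic SNV records retained from VCF.")

  gt <- v@gt[keep, -1, drop = FALSE]
  sample_id <- colnames(gt)
  fmt <- v@gt[keep, 1]
  gt_field <- vapply(seq_len(nrow(gt)), function(i) {
    j <- match("GT", strsplit(fmt[i], ":", fixed = TRUE)[[1]])
    if (is.na(j)) abort("VCF record without GT field.")
    j
  }, integer(1))

  n_sites <- nrow(gt)
  n_hap <- 2L * length(sample_id)
  alleles <- matrix(NA_integer_, n_sites, n_hap)
  for (i in seq_len(n_sites)) {
    raw <- gt[i, ]
    calls <- rep(NA_character_, length(raw))
    ok_raw <- !is.na(raw)
    calls[ok_raw] <- vapply(strsplit(raw[ok_raw], ":", fixed = TRUE),
                            `[`, character(1), gt_field[i])
    miss <- is.na(calls) | calls %in% c("./.", ".")
    bad <- !miss & !grepl("^[01.]\\|[01.]$", calls)
    if (any(bad)) {
      abort(sprintf(
        "unphased or malformed GT '%s' at site %s for sample %s.",
        calls[which(bad)[1]], id_or_pos(id, chrom, pos, keep)[i],
        sample_id[which(bad)[1]]
      ))
    }
    a <- matrix(NA_integer_, 2L, length(calls))
    a[, !miss] <- vapply(strsplit(calls[!miss], "|", fixed = TRUE),
                         function(x) suppressWarnings(as.integer(x)),
                         integer(2))
    alleles[i, ] <- as.vector(a)
  }

  idk <- id_or_pos(id, chrom, pos, keep)
  hap_matrix(alleles, chrom = chrom[keep], pos = pos[keep], site_id = idk,
             ref = ref[keep], alt = alt[keep], sample_id = sample_id,
             polarized = FALSE)
}

id_or_pos <- function(id, chrom, pos, keep) {
  out <- id[keep]
  blank <- is.na(out) | out == "."
  out[blank] <- paste0(chrom[keep][blank], ":", pos[keep][blank])
  out
}

#' Write a haplotype matrix as a phased GT-only VCF
#'
#' Emits a minimal plain-text VCF 4.2 with phased GT fields and an `AA`
#' (ancestral allele) INFO tag. Round-trips through [read_phased_vcf()]
#' bit-exactly on the genotype columns.
#'
#' @param x a [hap_matrix()].
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(x, path) {
  if (anyDuplicated(paste(x$chrom, x$pos))) {
    abort("position collision: duplicated chrom:pos among sites.")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral Allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$sample_id), collapse = "\t")
  ), con)
  if (n_sites(x) == 0L) return(invisible(path))
  ## if polarized, allele 1 is derived so AA = ref; writing is in REF/ALT space
  a <- x$alleles
  ch <- ifelse(is.na(a), ".", as.character(a))
  odd <- ch[, seq(1L, ncol(ch), by = 2L), drop = FALSE]
  even <- ch[, seq(2L, ncol(ch), by = 2L), drop = FALSE]
  gt <- matrix(paste(odd, even, sep = "|"), nrow = nrow(a))
  gt[gt == ".|."] <- "./."
  aa <- if (x$polarized) x$ref else "."
  lines <- paste(x$chrom, x$pos, x$site_id, x$ref, x$alt, ".", "PASS",
                 ifelse(aa == ".", ".", paste0("AA=", aa)), "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Polarize alleles against an ancestral-allele table
#'
#' Recodes alleles so 1 means derived. Sites whose ancestral base equals
#' REF are unchanged; sites whose ancestral base equals ALT are bit-flipped
#' (missing stays missing, REF/ALT labels swapped). Sites with unknown or
#' mismatching ancestral state are dropped with a message.
#'
#' @param x a [hap_matrix()] with `polarized = FALSE`.
#' @param ancestral a data frame with columns `site_id` and `ancestral`
#'   (allele base), or a named character vector `site_id -> base`.
#' @return a polarized [hap_matrix()].
#' @export
polarize <- function(x, ancestral) {
  if (x$polarized) abort("matrix is already polarized.")
  if (is.data.frame(ancestral)) {
    aa <- setNames(as.character(ancestral$ancestral), ancestral$site_id)
  } else {
    aa <- ancestral
  }
  anc <- unname(aa[x$site_id])
  is_ref <- !is.na(anc) & anc == x$ref
  is_alt <- !is.na(anc) & anc == x$alt
  drop <- !(is_ref | is_alt)
  if (any(drop)) {
    inform(sprintf("dropping %d site(s) with unknown or mismatching ancestral allele.",
                   sum(drop)))
  }
  keep <- which(!drop)
  a <- x$alleles[keep, , drop = FALSE]
  flip <- is_alt[keep]
  a[flip, ] <- 1L - a[flip, , drop = FALSE]
  ref <- x$ref[keep]; alt <- x$alt[keep]
  tmp <- ref[flip]; ref[flip] <- alt[flip]; alt[flip] <- tmp
  hap_matrix(a, chrom = x$chrom[keep], pos = x$pos[keep],
             site_id = x$site_id[keep], ref = ref, alt = alt,
             sample_id = x$sample_id, polarized = TRUE)
}

#' Missingness quality control
#'
#' Removes samples, then sites, whose fraction of missing alleles exceeds
#' the thresholds (defaults 10% each). Samples are filtered
#' first so that high-missingness individuals do not inflate per-site
#' missingness.
#'
#' @param x a [hap_matrix()].
#' @param site_max,sample_max maximum tolerated missing fraction.
#' @return a filtered [hap_matrix()]; the removed ids are attached as
#'   attributes `removed_samples` and `removed_sites`.
#' @export
missingness_filter <- function(x, site_max = 0.10, sample_max = 0.10) {
  stopifnot(site_max >= 0, site_max <= 1, sample_max >= 0, sample_max <= 1)
  miss <- is.na(x$alleles)
  samp_frac <- vapply(seq_len(n_samples(x)), function(k) {
    mean(miss[, c(2L * k - 1L, 2L * k)])
  }, numeric(1))
  keep_samp <- samp_frac <= sample_max
  if (!any(keep_samp)) abort("missingness filter removed every sample.")
  y <- hap_subset(x, samples = keep_samp)
  site_frac <- rowMeans(is.na(y$alleles))
  keep_site <- site_frac <= site_max
  out <- hap_subset(y, sites = keep_site)
  removed_samples <- x$sample_id[!keep_samp]
  removed_sites <- y$site_id[!keep_site]
  if (length(removed_samples) || length(removed_sites)) {
    inform(sprintf("missingness filter removed %d sample(s) and %d site(s).",
                   length(removed_samples), length(removed_sites)))
  }
  attr(out, "removed_samples") <- removed_samples
  attr(out, "removed_sites") <- removed_sites
  out
}

#' Read a sample-to-population map
#'
#' Reads a two-column tab-separated file (`sample_id<TAB>population`, no
#' header) and assigns the focal / sister / outgroup roles used by the PBS
#' and cross-population statistics.
#'
#' @param path TSV path, or a data frame with columns `sample_id`,
#'   `population`.
#' @param focal,sister,outgroup population labels taking each role.
#' @return a tibble (`sample_id`, `population`) of class `pop_partition`
#'   with a `roles` attribute.
#' @export
read_population_map <- function(path, focal, sister = NULL, outgroup = NULL) {
  if (is.data.frame(path)) {
    df <- path[c("sample_id", "population")]
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("sample_id", "population"),
                            colClasses = "character")
  }
  if (anyDuplicated(df$sample_id)) {
    abort(sprintf("duplicated sample id(s) in population map: %s",
                  paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", ")))
  }
  pop_partition(df, focal = focal, sister = sister, outgroup = outgroup)
}

#' @rdname read_population_map
#' @param df data frame with columns `sample_id`, `population`.
#' @export
pop_partition <- function(df, focal, sister = NULL, outgroup = NULL) {
  roles <- c(focal = focal, sister = sister, outgroup = outgroup)
  missing_lab <- setdiff(roles, df$population)
  if (length(missing_lab)) {
    abort(sprintf("role label(s) absent from population map: %s",
                  paste(missing_lab, collapse = ", ")))
  }
  out <- tibble(sample_id = as.character(df$sample_id),
                population = as.character(df$population))
  structure(out, roles = roles, class = c("pop_partition", class(out)))
}

#' Sample indices of one population within a haplotype matrix
#'
#' @param x a [hap_matrix()].
#' @param partition a `pop_partition`.
#' @param population a population label, or a role name
#'   (`"focal"`, `"sister"`, `"outgroup"`).
#' @return integer vector of diploid sample indices into `x`.
#' @export
pop_samples <- function(x, partition, population) {
  roles <- attr(partition, "roles")
  if (population %in% names(roles)) population <- roles[[population]]
  if (!population %in% partition$population) {
    abort(sprintf("unknown population label '%s'.", population))
  }
  ids <- partition$sample_id[partition$population == population]
  idx <- match(intersect(x$sample_id, ids), x$sample_id)
  if (!length(idx)) abort(sprintf("population '%s' has no samples in the matrix.", population))
  sort(idx)
}

check_partition_covers <- function(x, partition) {
  unmapped <- setdiff(x$sample_id, partition$sample_id)
  if (length(unmapped)) {
    abort(sprintf("sample(s) missing from population map: %s",
                  paste(unmapped, collapse = ", ")))
  }
  invisible(TRUE)
}
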