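#' Encode diploid genotypes as model dosages
#'
#' Codes genotypes for the minor allele: under the additive model the
#' minor-allele count (0/1/2), under the dominant model a carrier
#' indicator (0/1). Missing genotypes code to `NA` (samples are dropped at
#' fit time: complete-case analysis).
#'
#' @param genotypes character vector of genotypes like `"A/G"` or `"A|G"`
#'   (`NA` or `"./."` for missing), or a two-column character matrix of
#'   alleles.
#' @param model `"additive"` or `"dominant"`.
#' @param minor the minor allele base; by default determined from the
#'   analyzed cohort (ties broken alphabetically).
#' @return integer dosages with the minor allele as attribute `minor`.
#' @export
encode_genotype <- function(genotypes, model = c("additive", "dominant"),
                            minor = NULL) {
  model <- match.arg(model)
  if (is.matrix(genotypes)) {
    al <- genotypes
  } else {
    gs <- ifelse(is.na(genotypes) | genotypes %in% c("./.", ".|."),
                 NA_character_, genotypes)
    al <- t(vapply(strsplit(gs, "[/|]"), function(x) {
      if (length(x) == 2) x else c(NA_character_, NA_character_)
    }, character(2)))
  }
  counts <- sort(table(al), decreasing = FALSE)
  if (length(counts) < 2) abort("monomorphic site: no association possible.")
  if (length(counts) > 2) abort("more than two alleles observed.")
  if (is.null(minor)) {
    minor <- if (counts[1] < counts[2]) names(counts)[1] else
      sort(names(counts))[1]
  }
  if (!minor %in% names(counts)) abort(sprintf("allele '%s' not observed.", minor))
  d <- rowSums(al == minor)
  d[is.na(al[, 1]) | is.na(al[, 2])] <- NA_integer_
  d <- as.integer(d)
  if (model == "dominant") d <- as.integer(d > 0L)
  attr(d, "minor") <- minor
  d
}

#' Greedy windowed LD pruning
#'
#' Slides a window of `window` sites advanced by `step`; within each
#' window, while any retained pair has squared Pearson correlation of
#' dosages above `r2_max`, the later site of the offending pair is
#' removed.
#'
#' @param dosage numeric matrix, samples x sites (entries 0/1/2, `NA`
#'   allowed: correlations use pairwise complete observations).
#' @param r2_max squared-correlation threshold (default 0.8).
#' @param window,step window size and advance in sites (defaults 50, 5).
#' @return integer indices of retained sites.
#' @export
ld_prune <- function(dosage, r2_max = 0.8, window = 50L, step = 5L) {
  if (window < 2) abort("`window` must be at least 2 sites.")
  m <- ncol(dosage)
  keep <- rep(TRUE, m)
  starts <- seq(1L, max(1L, m - 1L), by = step)
  for (st in starts) {
    en <- min(st + window - 1L, m)
    repeat {
      idx <- which(keep[st:en]) + st - 1L
      if (length(idx) < 2) break
      r <- suppressWarnings(cor(dosage[, idx, drop = FALSE],
                                use = "pairwise.complete.obs"))
      r[is.na(r)] <- 0
      r2 <- r^2
      r2[lower.tri(r2, diag = TRUE)] <- 0
      hit <- which(r2 > r2_max, arr.ind = TRUE)
      if (nrow(hit) == 0) break
      ## drop the later site of the first offending pair
      keep[idx[max(hit[1, ])]] <- FALSE
    }
  }
  which(keep)
}

#' Genotype principal components
#'
#' Standard PCA on a dosage matrix: each site is centered by `2 p` and
#' scaled by `sqrt(2 p (1 - p))` with `p` the sample allele frequency;
#' missing dosages are mean-imputed; zero-variance sites are excluded. The
#' per-sample coordinates are the top-`k` principal component scores, with
#' each component's sign fixed so its largest-magnitude site loading is
#' positive.
#'
#' @param dosage numeric matrix, samples x sites (0/1/2 with `NA`).
#' @param k number of components (default 5).
#' @return tibble `sample_id`, `PC1` .. `PCk`.
#' @export
compute_pcs <- function(dosage, k = 5L) {
  n <- nrow(dosage)
  p <- colMeans(dosage, na.rm = TRUE) / 2
  keep <- is.finite(p) & p > 0 & p < 1
  x <- dosage[, keep, drop = FALSE]
  p <- p[keep]
  x <- sweep(x, 2, 2 * p)
  x[is.na(x)] <- 0
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  if (k >= min(dim(x))) abort("`k` must be below min(n samples, n polymorphic sites).")
  sv <- svd(x, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sv$u %*% diag(sv$d[seq_len(k)] * flip, nrow = k)
  colnames(scores) <- paste0("PC", seq_len(k))
  ids <- rownames(dosage) %||% paste0("S", seq_len(n))
  dplyr::bind_cols(tibble(sample_id = ids), as_tibble(scores))
}

#' Covariate-adjusted genotype-phenotype linear model
#'
#' Ordinary least squares of a (pre-transformed) phenotype on genotype
#' dosage plus covariates, complete cases only. The reported effect is the
#' dosage coefficient with a t-based confidence interval at the residual
#' degrees of freedom, a two-sided Wald p-value, and the full-model R^2.
#'
#' @param data a data frame holding all variables.
#' @param phenotype,dosage column names (strings) of the response and the
#'   coded genotype.
#' @param covariates character vector of covariate column names (e.g.
#'   `c("sex", "PC1", ..., "PC5")`); `NULL` for none.
#' @param model label recorded in the result (`"additive"` or
#'   `"dominant"`; the coding itself comes from [encode_genotype()]).
#' @param conf_level confidence level (default 0.95).
#' @return an object of class `assoc_fit`; see [tidy.assoc_fit()],
#'   [glance.assoc_fit()], [as_tibble.assoc_fit()].
#' @export
fit_association <- function(data, phenotype, dosage, covariates = NULL,
                            model = "additive", conf_level = 0.95) {
  vars <- c(phenotype, dosage, covariates)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    abort(sprintf("column(s) not in data: %s", paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(data[vars])
  df <- df[complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n <= length(vars) + 1L) abort("too few complete cases for the model.")
  if (var(df[[dosage]]) == 0) abort("monomorphic dosage: no association possible.")
  fml <- stats::reformulate(c(sprintf("`%s`", dosage),
                              sprintf("`%s`", covariates)),
                            response = sprintf("`%s`", phenotype))
  fit <- lm(fml, data = df)
  aliased <- is.na(coef(fit))
  if (any(aliased)) {
    abort(sprintf("rank-deficient design; collinear column(s): %s",
                  paste(names(coef(fit))[aliased], collapse = ", ")))
  }
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  r2 <- if (var(df[[phenotype]]) == 0) 0 else sm$r.squared
  term <- sprintf("`%s`", dosage)
  row <- if (term %in% rownames(co)) term else dosage
  beta <- co[row, "Estimate"]
  se <- co[row, "Std. Error"]
  dfres <- fit$df.residual
  tq <- qt(1 - (1 - conf_level) / 2, dfres)
  structure(
    list(
      fit = fit, model = model, dosage = dosage, phenotype = phenotype,
      covariates = covariates, n = n,
      beta = beta, se = se,
      ci_low = beta - tq * se, ci_high = beta + tq * se,
      p_value = co[row, "Pr(>|t|)"],
      r_squared = r2,
      conf_level = conf_level
    ),
    class = "assoc_fit"
  )
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("<assoc_fit> %s model, n = %d\n", x$model, x$n))
  cat(sprintf("  beta = %.3f [%d%% CI %.3f to %.3f], p = %.3g, R2 = %.3f\n",
              x$beta, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$p_value, x$r_squared))
  invisible(x)
}

#' Tidy an association fit
#'
#' @param x an `assoc_fit`.
#' @param ... unused.
#' @return one row per model term: `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy assoc_fit
#' @export
tidy.assoc_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble(
    term = gsub("`", "", rownames(co)),
    estimate = co[, "Estimate"],
    std.error = co[, "Std. Error"],
    statistic = co[, "t value"],
    p.value = co[, "Pr(>|t|)"]
  )
}

#' One-row model summary of an association fit
#'
#' @param x an `assoc_fit`.
#' @param ... unused.
#' @return tibble: `model`, `beta`, `se`, `ci_low`, `ci_high`, `p.value`,
#'   `r.squared`, `n`.
#' @method glance assoc_fit
#' @export
glance.assoc_fit <- function(x, ...) {
  tibble(
    model = x$model, beta = x$beta, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high,
    p.value = x$p_value, r.squared = x$r_squared, n = x$n
  )
}

#' @method as_tibble assoc_fit
#' @export
as_tibble.assoc_fit <- function(x, ...) glance(x)
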