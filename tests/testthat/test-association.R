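test_that("genotype encoding codes the minor allele under both models", {
  g <- c("A/A", "A/G", "G/G", "A/A", "A/A")
  expect_equal(as.integer(encode_genotype(g, "additive")), c(0L, 1L, 2L, 0L, 0L))
  expect_equal(as.integer(encode_genotype(g, "dominant")), c(0L, 1L, 1L, 0L, 0L))
  expect_equal(attr(encode_genotype(g), "minor"), "G")

  # missing genotype -> NA dosage
  g2 <- c("A/A", NA, "./.", "A|G")
  expect_equal(as.integer(encode_genotype(g2, "additive")),
               c(0L, NA, NA, 1L))

  # flipping which allele is minor maps additive dosage d -> 2 - d
  d_g <- encode_genotype(g, "additive", minor = "G")
  d_a <- encode_genotype(g, "additive", minor = "A")
  expect_equal(as.integer(d_a), 2L - as.integer(d_g))

  expect_error(encode_genotype(rep("A/A", 4)), "monomorphic")
  expect_error(encode_genotype(c("A/A", "A/G", "C/G")), "more than two")
})

test_that("LD pruning removes one of each over-correlated pair and no more", {
  withr::local_seed(171)
  base <- rbinom(60, 2, 0.4)
  dosage <- cbind(base, base, rbinom(60, 2, 0.4))
  colnames(dosage) <- NULL
  kept <- ld_prune(dosage, r2_max = 0.8, window = 10, step = 5)
  expect_equal(kept, c(1L, 3L))

  # orthogonal dosages survive intact
  d2 <- matrix(rbinom(600, 2, 0.5), nrow = 100)
  r <- cor(d2)^2; r[lower.tri(r, diag = TRUE)] <- 0
  stopifnot(max(r) < 0.8) # fixture sanity
  expect_equal(ld_prune(d2, 0.8, window = 6, step = 2), 1:6)

  expect_error(ld_prune(d2, 0.8, window = 1), "at least 2")

  # post-condition: no surviving pair within a window exceeds the threshold
  for (rep in 1:10) {
    p <- runif(20, 0.2, 0.8)
    d <- sapply(p, function(pp) rbinom(40, 2, pp))
    d[, 5] <- d[, 4]          # plant perfect LD
    d[, 12] <- 2 - d[, 11]
    kept <- ld_prune(d, r2_max = 0.5, window = 8, step = 4)
    for (w_start in seq(1, 19, by = 4)) {
      idx <- kept[kept >= w_start & kept <= min(w_start + 7, 20)]
      if (length(idx) < 2) next
      r2 <- suppressWarnings(cor(d[, idx, drop = FALSE]))^2
      r2[lower.tri(r2, diag = TRUE)] <- 0
      r2[is.na(r2)] <- 0
      expect_lte(max(r2), 0.5)
    }
  }
})

test_that("genotype PCs separate simulated populations and are orthogonal", {
  withr::local_seed(181)
  # two diverged populations, 40 samples each, 150 sites
  p1 <- rbeta(150, 2, 2); p2 <- pmin(pmax(p1 + rnorm(150, 0, 0.25), 0.02), 0.98)
  d <- rbind(sapply(p1, function(p) rbinom(40, 2, p)),
             sapply(p2, function(p) rbinom(40, 2, p)))
  rownames(d) <- paste0("S", 1:80)
  pcs <- compute_pcs(d, k = 5)
  lab <- rep(c(1, 2), each = 40)
  # PC1 separates the populations: between-group difference dominates
  expect_gt(abs(mean(pcs$PC1[lab == 1]) - mean(pcs$PC1[lab == 2])),
            2 * (sd(pcs$PC1[lab == 1]) + sd(pcs$PC1[lab == 2])) / 2)
  # scores orthogonal
  g <- crossprod(as.matrix(pcs[, -1]))
  expect_equal(g[upper.tri(g)], rep(0, 10), tolerance = 1e-8)

  # constant sites are excluded rather than propagating NaN
  d2 <- cbind(d, 1L)
  expect_silent(pcs2 <- compute_pcs(d2, k = 3))
  expect_false(any(is.na(pcs2$PC1)))

  expect_error(compute_pcs(d[1:4, 1:4], k = 4), "below min")
})

test_that("the association fit matches closed-form OLS and degenerate cases", {
  withr::local_seed(191)
  n <- 80
  df <- tibble::tibble(
    y = rnorm(n), dosage = rbinom(n, 2, 0.3), sex = rbinom(n, 1, 0.5),
    z = rnorm(n)
  )
  fit <- fit_association(df, "y", "dosage", covariates = c("sex", "z"))
  X <- cbind(1, df$dosage, df$sex, df$z)
  beta_hat <- solve(crossprod(X), crossprod(X, df$y))
  expect_equal(fit$beta, beta_hat[2], tolerance = 1e-10)
  res <- df$y - X %*% beta_hat
  sigma2 <- sum(res^2) / (n - 4)
  se <- sqrt(sigma2 * solve(crossprod(X))[2, 2])
  expect_equal(fit$se, se, tolerance = 1e-10)
  expect_equal(fit$ci_low, fit$beta - qt(0.975, n - 4) * se, tolerance = 1e-10)

  # phenotype identical to dosage: beta = 1, R^2 = 1
  fit1 <- fit_association(tibble::tibble(y = df$dosage, dosage = df$dosage),
                          "y", "dosage")
  expect_equal(fit1$beta, 1, tolerance = 1e-12)
  expect_equal(fit1$r_squared, 1, tolerance = 1e-12)

  # constant phenotype: beta = 0, R^2 = 0
  fit0 <- fit_association(tibble::tibble(y = rep(2, n), dosage = df$dosage),
                          "y", "dosage")
  expect_equal(fit0$beta, 0, tolerance = 1e-12)
  expect_equal(fit0$r_squared, 0)

  # adding a covariate orthogonal to dosage and phenotype leaves beta alone
  q <- qr.Q(qr(cbind(df$y, df$dosage, 1, rnorm(n))))[, 4]
  df$orth <- q
  fit2 <- fit_association(df, "y", "dosage", covariates = "orth")
  fit3 <- fit_association(df, "y", "dosage")
  expect_equal(fit2$beta, fit3$beta, tolerance = 1e-10)

  # collinear design errors and names the column
  df$dup <- df$dosage
  expect_error(fit_association(df, "y", "dosage", covariates = "dup"),
               "collinear.*dup")
  # monomorphic dosage
  expect_error(fit_association(tibble::tibble(y = df$y, dosage = 1), "y",
                               "dosage"), "monomorphic")
})

test_that("tidy and glance expose the model in broom shape", {
  withr::local_seed(201)
  df <- tibble::tibble(y = rnorm(50), dosage = rbinom(50, 2, 0.3),
                       sex = rbinom(50, 1, 0.5))
  fit <- fit_association(df, "y", "dosage", covariates = "sex",
                         model = "additive")
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", "dosage", "sex"))
  expect_true(all(c("estimate", "std.error", "statistic", "p.value") %in%
                    names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$beta, fit$beta)
  expect_equal(gl$n, 50L)
  expect_equal(gl$model, "additive")
  expect_s3_class(tibble::as_tibble(fit), "tbl_df")
})

test_that("phenotype simulation recovers its generative slope as noise vanishes", {
  withr::local_seed(211)
  dos <- rbinom(200, 2, 0.2)
  names(dos) <- paste0("S", 1:200)
  ph <- simulate_phenotypes(dos, beta_g = 0.2, beta_sex = 0, sigma = 1e-10)
  expect_equal(log(ph$phenotype), 0.2 * dos, tolerance = 1e-6,
               ignore_attr = TRUE)
  # the pipeline's log transform recovers the linear predictor plus noise
  ph2 <- simulate_phenotypes(dos, beta_g = 0.2, beta_sex = 0.4, sigma = 0.5)
  resid <- log(ph2$phenotype) - 0.2 * dos - 0.4 * ph2$sex
  expect_lt(abs(mean(resid)), 0.15)
  expect_equal(sd(resid), 0.5, tolerance = 0.15)
  expect_error(simulate_phenotypes(dos, sigma = 0), "positive")
})
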