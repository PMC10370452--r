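test_that("pairwise shared length reproduces hand-traced runs", {
  # two identical haplotypes over 7 sites: SL = 7 at any focal index
  a <- matrix(rep(c(0L, 1L, 0L, 0L, 1L, 1L, 0L), 2), ncol = 2)
  x <- hap_matrix(a, chrom = "1", pos = 1:7, polarized = TRUE)
  for (f in 1:7) expect_equal(pairwise_sl(x, f), 7)

  # 01100 vs 01101, focal site 3: shared run is sites 1-4 -> SL = 4
  a <- cbind(c(0L, 1L, 1L, 0L, 0L), c(0L, 1L, 1L, 0L, 1L))
  x <- hap_matrix(a, chrom = "1", pos = 1:5, polarized = TRUE)
  expect_equal(pairwise_sl(x, 3), 4)
  # at the mismatching site itself the pair shares no run
  expect_equal(pairwise_sl(x, 5), 0)
  # fewer than two haplotypes: undefined, not an error
  expect_true(is.na(pairwise_sl(x, 3, haplotypes = 1L)))

  # a missing allele neither breaks nor shortens a run
  a[4, 1] <- NA_integer_
  x <- hap_matrix(a, chrom = "1", pos = 1:5, polarized = TRUE)
  expect_equal(pairwise_sl(x, 3), 4)
})

test_that("locality: sites beyond every mismatch boundary do not affect SL", {
  withr::local_seed(61)
  x <- random_hap_matrix(20, 6)
  base <- pairwise_sl(x, 10)
  # perturb the outermost sites after planting a universal mismatch ring
  y <- x
  y$alleles[3, ] <- rep(c(0L, 1L), length.out = 12)   # breaks every pair
  y$alleles[17, ] <- rep(c(0L, 1L), length.out = 12)
  before <- pairwise_sl(y, 10)
  y$alleles[1, ] <- 1L - y$alleles[1, ]
  y$alleles[20, ] <- 1L - y$alleles[20, ]
  expect_equal(pairwise_sl(y, 10), before)
})

test_that("nSL matches the exhaustive pair-enumeration oracle", {
  withr::local_seed(71)
  checked <- 0
  for (rep in 1:60) {
    x <- random_hap_matrix(sample(10:40, 1), sample(3:6, 1))
    tbl <- nsl_scan(x)
    f <- sample(which(tbl$defined), size = min(3, sum(tbl$defined)))
    for (s in f) {
      expect_equal(tbl$nsl[s], oracle_nsl(x$alleles, s), tolerance = 1e-12)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)
})

test_that("nSL is zero under mirror symmetry and antisymmetric under relabeling", {
  # ancestral and derived carrier sets with identical internal structure
  block <- cbind(c(0L, 0L, 1L, 0L), c(0L, 1L, 1L, 0L))
  a <- rbind(cbind(block, block),
             c(0L, 0L, 1L, 1L))  # focal site: two anc, two der
  x <- hap_matrix(a, chrom = "1", pos = 1:5, polarized = TRUE)
  tbl <- nsl_scan(x, maf_min = 0.3)
  expect_equal(tbl$nsl[5], 0)

  withr::local_seed(81)
  x <- random_hap_matrix(25, 5)
  tbl <- nsl_scan(x)
  y <- x
  f <- which(tbl$defined)[1]
  y$alleles[f, ] <- 1L - y$alleles[f, ]
  tbl2 <- nsl_scan(y)
  expect_equal(tbl2$nsl[f], -tbl$nsl[f], tolerance = 1e-12)
})

test_that("XP-nSL matches the oracle, is zero for identical populations and antisymmetric", {
  withr::local_seed(91)
  # identical haplotype sets in the two populations
  half <- matrix(rbinom(20 * 6, 1, 0.4), nrow = 20)
  x <- hap_matrix(cbind(half, half), chrom = "1", pos = seq_len(20) * 5L,
                  polarized = TRUE)
  part <- pop_partition(data.frame(sample_id = x$sample_id,
                                   population = rep(c("P1", "P2"), each = 3)),
                        focal = "P1", sister = "P2")
  tbl <- xpnsl_scan(x, part, "P1", "P2")
  expect_equal(tbl$xpnsl[tbl$defined], rep(0, sum(tbl$defined)))

  for (rep in 1:20) {
    x <- random_hap_matrix(30, 6)
    part <- pop_partition(data.frame(sample_id = x$sample_id,
                                     population = rep(c("P1", "P2"), each = 3)),
                          focal = "P1", sister = "P2")
    t12 <- xpnsl_scan(x, part, "P1", "P2")
    t21 <- xpnsl_scan(x, part, "P2", "P1")
    expect_equal(t12$xpnsl, -t21$xpnsl, tolerance = 1e-12)
    f <- sample(which(t12$defined), 2)
    h1 <- 1:6; h2 <- 7:12
    for (s in f) {
      o <- log(oracle_mean_sl(x$alleles, h1, s) /
                 oracle_mean_sl(x$alleles, h2, s))
      expect_equal(t12$xpnsl[s], o, tolerance = 1e-12)
    }
  }
})

test_that("bin normalization standardizes each bin and flags degenerate bins", {
  # single bin with scores {-1, 1}: already standardized
  tbl <- tibble::tibble(nsl = c(-1, 1), daf = c(0.3, 0.31))
  out <- normalize_scores(tbl, mode = "genomewide")
  expect_equal(out$norm, c(-1, 1))

  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  withr::local_seed(101)
  tbl <- tibble::tibble(nsl = rnorm(300), daf = runif(300, 0.02, 0.98))
  out <- normalize_scores(tbl, bin_width = 0.1)
  grp <- split(out$norm, out$freq_bin)
  for (g in grp) {
    g <- g[!is.na(g)]
    if (length(g) >= 2) {
      expect_equal(mean(g), 0, tolerance = 1e-12)
      expect_equal(pop_sd(g), 1, tolerance = 1e-12)
    }
  }
  # per-bin loop oracle
  bins <- floor(tbl$daf / 0.1)
  oracle <- rep(NA_real_, 300)
  for (b in unique(bins)) {
    i <- which(bins == b)
    oracle[i] <- (tbl$nsl[i] - mean(tbl$nsl[i])) / pop_sd(tbl$nsl[i])
  }
  expect_equal(out$norm, oracle, tolerance = 1e-12)

  # singleton bin -> undefined; zero-variance bin -> undefined
  tbl <- tibble::tibble(nsl = c(0.5, 1, 1), daf = c(0.05, 0.5, 0.52))
  out <- suppressMessages(normalize_scores(tbl, bin_width = 0.1))
  expect_true(is.na(out$norm[1]))
  expect_true(all(is.na(out$norm[2:3])))
})

test_that("normalized nSL scores have unit spread within frequency bins on simulated data", {
  sim <- shared_sim()
  tbl <- nsl_scan(sim$haps, sim$partition, "focal")
  out <- suppressMessages(normalize_scores(tbl, bin_width = 0.2))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  for (g in split(out$norm, out$freq_bin)) {
    g <- g[!is.na(g)]
    if (length(g) >= 2) {
      expect_equal(mean(g), 0, tolerance = 1e-10)
      expect_equal(pop_sd(g), 1, tolerance = 1e-10)
    }
  }
  # SL means stay within [1, n_sites] for allele-conditioned pair sets
  def <- tbl[tbl$defined, ]
  expect_true(all(def$sl_anc >= 1 & def$sl_anc <= n_sites(sim$haps)))
  expect_true(all(def$sl_der >= 1 & def$sl_der <= n_sites(sim$haps)))
})
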