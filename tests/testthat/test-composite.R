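test_that("DAF bin edges are left-closed, right-open, final bin closed", {
  expect_equal(assign_daf_bins(c(0.15, 0.189, 0.19)), c(0L, 0L, 1L))
  expect_equal(assign_daf_bins(0.50), 8L)          # truncated final bin
  expect_equal(assign_daf_bins(c(0.149, 0.501)), c(NA_integer_, NA_integer_))
  expect_error(assign_daf_bins(0.2, bin_width = 0), "positive")

  # brute-force interval search on random DAFs
  withr::local_seed(111)
  daf <- runif(500)
  got <- assign_daf_bins(daf)
  breaks <- seq(0.15, 0.47, by = 0.04)
  for (i in seq_along(daf)) {
    if (daf[i] < 0.15 || daf[i] > 0.50) {
      expect_true(is.na(got[i]))
    } else {
      expect_equal(got[i], max(which(daf[i] >= breaks - 1e-9)) - 1L)
    }
  }
})

test_that("the intermediate-DAF window is closed at both printed bounds", {
  rec <- tibble::tibble(daf = c(0.15, 0.50, 0.149, 0.501, NA))
  out <- intermediate_daf_filter(rec)
  expect_equal(out$removed, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(out$removed_reason[3], "daf_outside")
  expect_error(intermediate_daf_filter(rec, 0.5, 0.2), "less than")
})

test_that("bin-wise empirical p-values follow the >= rank rule with shared ties", {
  expect_equal(empirical_pvalues(c(3, 2, 1), c(0L, 0L, 0L)),
               c(1 / 3, 2 / 3, 1))
  expect_equal(empirical_pvalues(c(2, 2), c(0L, 0L)), c(1, 1))
  expect_equal(empirical_pvalues(5, 0L), 1)  # singleton bin
  expect_true(is.na(empirical_pvalues(c(1, 2), c(0L, NA))[2]))

  # without ties, per-bin p-values are a permutation of k/N
  withr::local_seed(121)
  for (rep in 1:20) {
    s <- rnorm(60)
    b <- sample(0:2, 60, replace = TRUE)
    p <- empirical_pvalues(s, b)
    for (bb in 0:2) {
      i <- b == bb
      expect_equal(sort(p[i]), seq_len(sum(i)) / sum(i))
    }
  }
})

test_that("harmonic-mean merging matches its closed form and removal rule", {
  expect_equal(hmp_combine(0.01, 0.04), 0.016)
  grid <- c(0.001, 0.01, 0.05, 0.2, 0.5)
  expect_equal(hmp_combine(grid, grid), grid)
  expect_true(is.na(hmp_combine(0.6, 0.01)))
  expect_true(is.na(hmp_combine(0.01, 0.51)))
  expect_error(hmp_combine(0, 0.1), "0, 1")
  expect_error(hmp_combine(0.1, 1.2), "0, 1")

  # min(p1, p2) <= hmp <= max(p1, p2); monotone in each argument
  withr::local_seed(131)
  p1 <- runif(200, 0.001, 0.5); p2 <- runif(200, 0.001, 0.5)
  h <- hmp_combine(p1, p2)
  expect_true(all(h >= pmin(p1, p2) & h <= pmax(p1, p2)))
  h2 <- hmp_combine(p1 * 0.9, p2)
  expect_true(all(h2 < h))

  # unequal weights
  expect_equal(hmp_combine(0.01, 0.04, weights = c(0.8, 0.2)),
               1 / (0.8 / 0.01 + 0.2 / 0.04))
})

test_that("top-fraction flagging matches a sort-based oracle including ties", {
  rec <- tibble::tibble(hmp = (1:100) / 100, removed = FALSE)
  out <- top_fraction_significant(rec, 0.05)
  expect_equal(sum(out$significant), 5L)
  expect_true(all(which(out$significant) == 1:5))

  rec <- tibble::tibble(hmp = rep(0.2, 10), removed = FALSE)
  expect_warning(out <- top_fraction_significant(rec, 0.05), "ties")
  expect_true(all(out$significant))

  withr::local_seed(141)
  for (rep in 1:20) {
    h <- sample(round(runif(50), 2), 50, replace = TRUE)
    rec <- tibble::tibble(hmp = h, removed = runif(50) < 0.2)
    out <- suppressWarnings(top_fraction_significant(rec, 0.1))
    keep <- !rec$removed
    k <- ceiling(0.1 * sum(keep))
    cutoff <- sort(h[keep])[k]
    expect_equal(out$significant, keep & h <= cutoff)
  }

  expect_error(top_fraction_significant(
    tibble::tibble(hmp = NA_real_, removed = TRUE), 0.05), "non-removed")
})

test_that("composite_test wires filters, p-values and flags together deterministically", {
  withr::local_seed(151)
  rec <- tibble::tibble(
    site_id = sprintf("s%03d", 1:200),
    daf = runif(200, 0.05, 0.6),
    pbs = rexp(200, 10),
    abs_nsl = abs(rnorm(200))
  )
  out1 <- suppressWarnings(composite_test(rec))
  out2 <- suppressWarnings(composite_test(rec))
  expect_identical(out1, out2)

  # significant implies not removed; p-values in (0, 1]
  expect_true(all(!out1$removed[out1$significant]))
  ok <- !is.na(out1$p_pbs)
  expect_true(all(out1$p_pbs[ok] > 0 & out1$p_pbs[ok] <= 1))
  # hmp defined only when both component ps <= 0.5
  both <- !is.na(out1$hmp)
  expect_true(all(out1$p_pbs[both] <= 0.5 & out1$p_nsl[both] <= 0.5))
  # removal reasons are exhaustive
  expect_true(all(out1$removed_reason[out1$removed] %in%
                    c("daf_outside", "undefined_stat", "p_above_half")))

  # undefined statistics are removed, not combined
  rec$pbs[1] <- NA
  out <- suppressWarnings(composite_test(rec))
  expect_true(out$removed[1])
  expect_equal(out$removed_reason[1], "undefined_stat")

  # empty retained set reports cleanly
  rec2 <- tibble::tibble(daf = c(0.01, 0.9), pbs = c(1, 2), abs_nsl = c(1, 2))
  expect_warning(out <- composite_test(rec2), "no sites retained")
  expect_false(any(out$significant))
})

test_that("the p > 0.5 removal never reorders the surviving sites", {
  withr::local_seed(161)
  rec <- tibble::tibble(
    daf = runif(300, 0.15, 0.50),
    pbs = rexp(300, 5),
    abs_nsl = abs(rnorm(300))
  )
  strict <- suppressWarnings(composite_test(rec, p_max = 0.5))
  loose <- suppressWarnings(composite_test(rec, p_max = 1))
  keep <- !strict$removed
  expect_equal(order(strict$hmp[keep]), order(loose$hmp[keep]))
})

test_that("composite_scan flags a fraction close to the target on simulated data", {
  sim <- shared_sim()
  comp <- suppressMessages(suppressWarnings(
    composite_scan(sim$haps, sim$partition, norm_bin_width = 0.2,
                   top_fraction = 0.10)))
  expect_equal(nrow(comp), n_sites(sim$haps))
  retained <- sum(!comp$removed)
  if (retained > 0) {
    expect_gte(sum(comp$significant), ceiling(0.10 * retained))
  }
})
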