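test_that("summaries reproduce constants and brute-force order statistics", {
  s <- summariseDescriptors(c(7, 7, 7))
  expect_equal(s$mean, 7)
  expect_equal(s$sd, 0)
  expect_equal(c(s$p50, s$p75, s$p90), c(7, 7, 7))

  x <- as.numeric(1:100)
  s2 <- summariseDescriptors(x)
  expect_equal(s2$p50, type6Quantile(x, 0.5))
  expect_equal(s2$p75, type6Quantile(x, 0.75))
  expect_equal(s2$p90, type6Quantile(x, 0.9))
  expect_true(s2$p50 <= s2$p75 && s2$p75 <= s2$p90)

  # permutation invariance
  set.seed(5)
  y <- rnorm(57)
  expect_equal(as.data.frame(summariseDescriptors(y)),
               as.data.frame(summariseDescriptors(sample(y))))
  expect_error(summariseDescriptors(numeric()), "no non-missing")
})

test_that("squared correlation is exact on lines and vanishes on noise", {
  x <- 1:20
  expect_equal(pearsonR2(x, 2 * x + 1), 1)
  expect_error(pearsonR2(x, rep(3, 20)), "zero variance")
  set.seed(99)
  expect_lt(pearsonR2(rnorm(1e4), rnorm(1e4)), 0.01)
})

test_that("Tukey-Kramer HSD flags clear separations and not identical groups", {
  same <- tukeyKramerHSD(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  # groups identical in mean -> no significant pair
  expect_false(any(same$significant))

  set.seed(21)
  g <- rep(c("lo", "hi"), each = 50)
  v <- c(rnorm(50, 0), rnorm(50, 10))
  res <- tukeyKramerHSD(v, g)
  expect_true(all(res$significant))
  expect_true(all(res$p_adj >= 0 & res$p_adj <= 1))
})

test_that("HSD is symmetric in group order and matches stats::TukeyHSD", {
  set.seed(33)
  v <- rnorm(60, rep(c(0, 0.8, 1.6), each = 20))
  g <- rep(c("a", "b", "c"), each = 20)
  mine <- tukeyKramerHSD(v, g)
  ref <- TukeyHSD(aov(v ~ g))$g
  # match on p-values pair by pair
  refP <- ref[paste0(mine$group2, "-", mine$group1), "p adj"]
  expect_equal(mine$p_adj, unname(refP), tolerance = 1e-8)
  # permuting input order changes nothing
  ord <- sample(length(v))
  mine2 <- tukeyKramerHSD(v[ord], g[ord])
  expect_equal(mine$p_adj, mine2$p_adj)
})

test_that("HSD decisions agree with a permutation oracle on small groups", {
  v <- c(4.1, 5.2, 4.8, 6.0, 5.5, 7.9, 8.3, 7.4, 2.2, 2.9, 3.4)
  g <- rep(c("a", "b", "c"), c(5, 3, 3))
  mine <- tukeyKramerHSD(v, g)
  set.seed(8)
  perm <- permutationMaxQ(v, g, B = 5000)
  # family-wise: permutation p of the max-q statistic vs the smallest
  # adjusted p-value; both should agree on rejection at alpha = 0.05
  expect_equal(min(mine$p_adj) < 0.05, perm$pvalue < 0.05)
  expect_equal(min(mine$p_adj), perm$pvalue, tolerance = 0.05)
})

test_that("degenerate groups are pooled without crashing", {
  v <- c(1, 1, 5, 6, 7)
  g <- c("a", "a", "b", "b", "b")
  expect_silent(res <- tukeyKramerHSD(v, g))
  expect_equal(nrow(res), 1L)
})

test_that("temporal binning counts fails and conserves totals", {
  lib <- cachedLibrary()
  rec <- drugRecords(lib)
  planted <- provenance(lib)$planted
  tr <- temporalTrend(rec$approval_year, planted$fail)
  expect_equal(sum(tr$n), nCompounds(lib))
  expect_equal(sum(tr$n_fails), sum(planted$fail))
  byBin <- tapply(planted$fail, planted$period, sum)
  expect_equal(tr$n_fails, as.vector(byBin[tr$period]))

  # all-pass set: 0 percent everywhere
  tr0 <- temporalTrend(rec$approval_year, rep(FALSE, nCompounds(lib)))
  expect_true(all(tr0$fail_pct == 0))

  # merging the two later bins conserves counts
  merged <- temporalTrend(rec$approval_year, planted$fail,
    bins = list(`2000-2009` = c(2000L, 2009L),
                `2010-2022` = c(2010L, 2022L)))
  expect_equal(merged$n_fails[2], sum(tr$n_fails[2:3]))

  expect_error(temporalTrend(c(1999L, 2005L), c(TRUE, FALSE)), "1999")
})

test_that("planted per-bin fail rates are recovered within binomial error", {
  lib <- cachedLibrary()
  rec <- drugRecords(lib)
  d <- cachedDescriptors()
  lip <- lipinskiAssess(d)
  tr <- temporalTrend(rec$approval_year, lip$fails)
  spec <- provenance(lib)$spec
  for (b in seq_len(nrow(tr))) {
    p <- spec$binFailRates[tr$period[b]]
    half <- 3 * sqrt(p * (1 - p) / tr$n[b])
    expect_lt(abs(tr$n_fails[b] / tr$n[b] - p), half + 1e-12,
              label = paste("bin", tr$period[b]))
  }
})

test_that("subset comparison separates real partitions but not coin flips", {
  d <- cachedDescriptors()
  lip <- lipinskiAssess(d)
  res <- subsetCompare(d, ifelse(lip$fails, "fail", "pass"), "mwt")
  expect_true(res$comparison$significant)
  means <- setNames(res$summary$mean, res$summary$subset)
  expect_gt(means["fail"], means["pass"])

  # random labels: mostly no significance across seeded replicates
  hits <- 0L
  set.seed(202)
  for (r in 1:100) {
    flip <- sample(c("x", "y"), nrow(d), replace = TRUE)
    cmp <- subsetCompare(d, flip, "mwt")
    hits <- hits + any(cmp$comparison$significant)
  }
  expect_lte(hits, 12L)  # ~alpha = 0.05, with binomial slack

  expect_warning(
    subsetCompare(d, c("solo", rep("rest", nrow(d) - 1L)), "mwt"),
    "fewer than 2")
})
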