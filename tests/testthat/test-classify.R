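test_that("rule-of-5 assessment applies strict inequalities", {
  # typical full-set means: compliant
  a <- lipinskiAssess(data.frame(mwt = 432, clogp = 3.4, hbd = 2, hba = 6))
  expect_equal(a$violation_count, 0L)
  expect_false(a$fails)
  # fail-subset means: two violations
  b <- lipinskiAssess(data.frame(mwt = 656, clogp = 5.7, hbd = 2, hba = 9))
  expect_true(b$over_mwt && b$over_clogp)
  expect_equal(b$violation_count, 2L)
  expect_true(b$fails)
  # boundary values do not violate
  c_ <- lipinskiAssess(data.frame(mwt = 500, clogp = 5, hbd = 5, hba = 10))
  expect_equal(c_$violation_count, 0L)
})

test_that("raising any descriptor never decreases the violation count", {
  set.seed(42)
  for (r in 1:50) {
    base <- data.frame(mwt = runif(1, 100, 900), clogp = runif(1, -2, 9),
                       hbd = sample(0:8, 1), hba = sample(0:14, 1))
    v0 <- lipinskiAssess(base)$violation_count
    for (col in names(base)) {
      up <- base
      up[[col]] <- up[[col]] + runif(1, 0, 300)
      expect_gte(lipinskiAssess(up)$violation_count, v0)
    }
  }
})

test_that("macrocycle calls match the fixtures and are not fooled by fused rings", {
  expect_true(isMacrocycle("C1CCCCCCCCCCC1"))        # 12-ring
  expect_false(isMacrocycle("C1CCCCC1"))             # cyclohexane
  expect_false(isMacrocycle("c1ccc2ccccc2c1"))       # naphthalene perimeter
  expect_false(isMacrocycle("C1CCCCCCCCCC1"))        # 11-ring, below cutoff
  expect_true(isMacrocycle("O=C1CCCCCCCCCCCO1"))     # macrolactone
})

test_that("smallest-ring search agrees with brute-force cycle enumeration", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(4:14, 1)
    edges <- randomMoleculeGraph(n, extra = sample(1:3, 1))
    expect_equal(drugspace:::maxSmallestRingSize(edges, n),
                 bruteMaxSmallestRing(edges, n),
                 label = paste("graph rep", rep))
  }
})

test_that("ionisation classes match fixtures and partition every input", {
  ic <- ionisationClass(c("CC(=O)O", "CCN", "CCO", "NCC(=O)O",
                          "NCCS(=O)(=O)O", "CC(=O)Nc1ccccc1"))
  expect_equal(as.character(ic$net_class),
               c("monoacid", "monobase", "neutral", "zwitterion",
                 "zwitterion", "neutral"))
  expect_equal(ic$acid_groups[1], 1L)
  expect_equal(ic$base_groups[2], 1L)
  # amides and anilines are not basic
  expect_equal(ionisationClass("CC(=O)NC")$base_groups, 0L)
  expect_equal(ionisationClass("Nc1ccccc1")$base_groups, 0L)
  # every compound in a library gets exactly one class
  lib <- cachedLibrary()
  cls <- ionisationClass(lib)$net_class
  expect_false(anyNA(cls))
})

test_that("percentile rules are order statistics of the analysis set", {
  # constant dataset: thresholds equal the constant
  const <- data.frame(mwt = rep(300, 10), clogp = rep(2, 10),
                      hbd = rep(1, 10), hba = rep(4, 10))
  r <- derivePercentileRules(const)
  expect_equal(r$threshold, c(300, 2, 1, 4))

  # 1..10 at the 90th percentile under the (n+1)p rule: 9.9
  d <- data.frame(mwt = 1:10, clogp = 1:10, hbd = 1:10, hba = 1:10)
  r2 <- derivePercentileRules(d)
  expect_equal(r2$threshold, rep(9.9, 4))

  # random data against the independent order-statistics oracle
  set.seed(11)
  rnd <- data.frame(mwt = runif(37, 100, 900), clogp = rnorm(37, 3, 2),
                    hbd = rpois(37, 2), hba = rpois(37, 6))
  for (p in c(50, 75, 90)) {
    rp <- derivePercentileRules(rnd, percentile = p)
    for (i in seq_len(nrow(rp))) {
      expect_equal(rp$threshold[i],
                   type6Quantile(rnd[[rp$descriptor[i]]], p / 100))
    }
  }
  expect_error(derivePercentileRules(rnd[0, ]), "at least 2")
})
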