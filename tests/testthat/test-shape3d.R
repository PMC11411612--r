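test_that("principal moments match hand-evaluated point-mass systems", {
  # two unit masses at (+-1, 0, 0): I = (0, 2, 2)
  expect_equal(momentsOfInertia(rbind(c(1, 0, 0), c(-1, 0, 0)), c(1, 1)),
               c(0, 2, 2))
  # four unit masses at (+-1, +-1, 0): I = (4, 4, 8)
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  expect_equal(momentsOfInertia(sq, rep(1, 4)), c(4, 4, 8))
  # a single point mass anywhere: all moments zero
  expect_equal(momentsOfInertia(matrix(c(3, -2, 7), 1), 5), c(0, 0, 0))
  expect_error(momentsOfInertia(matrix(0, 1, 3), 0), "mass")
})

test_that("moments are invariant under rigid motions to 1e-8", {
  set.seed(19)
  coords <- matrix(rnorm(30, sd = 2), ncol = 3)
  masses <- runif(10, 1, 19)
  ref <- momentsOfInertia(coords, masses)
  for (r in 1:10) {
    rot <- randomRotation()
    shift <- matrix(rnorm(3, sd = 50), nrow(coords), 3, byrow = TRUE)
    moved <- coords %*% rot + shift
    expect_equal(momentsOfInertia(moved, masses), ref, tolerance = 1e-8)
  }
})

test_that("NPR ratios hit the triangle vertices and reject degenerate input", {
  expect_equal(unname(nprRatios(c(0, 2, 2))), c(0, 1))       # rod
  expect_equal(unname(nprRatios(c(4, 4, 8))), c(0.5, 0.5))   # disc
  expect_equal(unname(nprRatios(c(8, 8, 8))), c(1, 1))       # sphere
  expect_error(nprRatios(c(0, 0, 0)), "undefined")
  expect_error(nprRatios(c(3, 2, 1)), "sorted")
})

test_that("Boltzmann weights and averages behave as closed forms demand", {
  kB <- 0.0019872041
  expect_equal(boltzmannAverage(5, 123), 5)                # single conformer
  expect_equal(boltzmannAverage(c(1, 3), c(7, 7)), 2)      # uniform weights
  # energy gap of kB * 300 * ln 2 makes the weights 2:1 -> average 1/3
  gap <- kB * 300 * log(2)
  expect_equal(boltzmannAverage(c(0, 1), c(0, gap)), 1 / 3)

  w <- boltzmannWeights(c(0, 1, 5), 300)
  expect_equal(sum(w), 1)
  expect_true(all(diff(w) <= 0))
  expect_error(boltzmannAverage(c(1, 2), 1), "length")
  expect_error(boltzmannAverage(numeric(), numeric()), "empty")
})

test_that("temperature limits select the minimum conformer or the plain mean", {
  vals <- c(0.2, 0.5, 0.9)
  en <- c(3, 1, 7)
  expect_equal(boltzmannAverage(vals, en, temperature = 0), 0.5)
  expect_equal(boltzmannAverage(vals, en, temperature = Inf), mean(vals))
  # monotone approach: very low T ~ minimum, very high T ~ mean
  expect_equal(boltzmannAverage(vals, en, temperature = 1e-3), 0.5,
               tolerance = 1e-9)
  expect_equal(boltzmannAverage(vals, en, temperature = 1e9), mean(vals),
               tolerance = 1e-4)
})

test_that("ensemble shape summaries stay inside the PMI triangle", {
  opt <- .cache$aspirinOptimised
  if (is.null(opt)) {
    opt <- optimiseEnsemble(
      generateEnsemble("CC(=O)Oc1ccccc1C(=O)O", id = "aspirin", seed = 7))
  }
  per <- conformerShapes(opt)
  expect_true(all(per$i1 <= per$i2 & per$i2 <= per$i3))
  expect_true(all(per$npr1 + per$npr2 >= 1 - 1e-9))
  expect_true(all(per$npr1 <= per$npr2 & per$npr2 <= 1 + 1e-9))
  sh <- shapeDescriptors(opt)
  expect_gte(sh$npr1_boltz + sh$npr2_boltz, 1)
  expect_true(sh$npr1_boltz >= min(per$npr1) && sh$npr1_boltz <= max(per$npr1))
  expect_equal(sh$n_conformers, nConformers(opt))
})
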