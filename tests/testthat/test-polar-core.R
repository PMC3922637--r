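test_that("area weights follow the polar Jacobian and sum to 1", {
  g <- makePolarGrid(4, 2)
  w <- areaWeights(g)
  expect_equal(dim(w), c(2, 4))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # closed-form annulus areas: inner band (0.5^2 - 0) / 4 angles = 1/16,
  # outer band (1 - 0.25) / 4 = 3/16
  expect_equal(unname(w[1, ]), rep(1 / 16, 4))
  expect_equal(unname(w[2, ]), rep(3 / 16, 4))

  for (dims in list(c(4, 2), c(7, 5), c(64, 32), c(128, 12))) {
    w <- areaWeights(makePolarGrid(dims[1], dims[2]))
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_true(all(w > 0))
    expect_true(all(diff(w) >= 0))  # nondecreasing with radius
  }

  expect_error(makePolarGrid(3, 2), "nTheta")
  expect_error(makePolarGrid(4, 1), "nRadial")
})

test_that("the 17 segments partition the disc", {
  model <- segmentModel17()
  for (dims in list(c(64, 32), c(24, 8))) {
    g <- makePolarGrid(dims[1], dims[2])
    sm <- segmentMap(g, model)
    expect_false(anyNA(sm))
    expect_setequal(unique(as.vector(sm)), 1:17)
    expect_equal(sum(segmentAreaWeights(g, model)), 1, tolerance = 1e-9)
  }

  g <- makePolarGrid(64, 32)
  # apex convention: innermost band maps to segment 17 at every angle
  for (i in c(1, 17, 40, 64))
    expect_identical(segmentOf(g, c(i, 1)), 17L)
  # anchor check: just above 0 degrees, outermost band, lies in the basal
  # anterolateral segment (6), whose interval is [0, 60)
  expect_identical(segmentOf(g, c(1, 32)), 6L)
  # 90 degrees basal -> basal anterior (1); 90 degrees apical -> 13
  i90 <- 17  # centre 92.8 degrees
  expect_identical(segmentOf(g, c(i90, 32)), 1L)
  expect_identical(segmentOf(g, c(i90, 12)), 13L)

  expect_error(segmentOf(g, c(0, 1)), "out of range")
  expect_error(segmentOf(g, c(1, 33)), "out of range")
})

test_that("normalization is idempotent, scale-invariant and correct", {
  m <- polarMap(matrix(c(50, 200, 10, 80, 30, 60, 20, 90), 2, 4))
  n1 <- normalizeUptake(m)
  expect_equal(max(mapValues(n1)), 100)
  expect_equal(mapValues(n1)[1, 1], 25)   # {50, 200} -> {25, 100}
  expect_true(isNormalized(n1))

  # idempotent
  expect_equal(mapValues(normalizeUptake(n1)), mapValues(n1))
  # scale invariance
  scaled <- polarMap(mapValues(m) * 7.3)
  expect_equal(mapValues(normalizeUptake(scaled)), mapValues(n1))
  # constant map -> constant 100
  const <- normalizeUptake(polarMap(matrix(42, 3, 8)))
  expect_true(all(mapValues(const) == 100))
  # all-zero map is degenerate
  expect_error(normalizeUptake(polarMap(matrix(0, 3, 8))), "degenerate")
})

test_that("difference maps subtract stress from rest with sign symmetry", {
  g <- makePolarGrid(8, 4)
  rest <- normalizeUptake(polarMap(matrix(100, 4, 8), g, "rest"))
  sv <- matrix(100, 4, 8); sv[2, 3] <- 40
  stress <- normalizeUptake(polarMap(sv, g, "stress"))

  d <- differenceMap(stress, rest)
  expect_identical(mapPhase(d), "difference")
  expect_equal(mapValues(d)[2, 3], 60)
  expect_equal(sum(mapValues(d) != 0), 1L)

  # identical inputs -> all zeros; antisymmetry
  expect_true(all(mapValues(differenceMap(stress, stress)) == 0))
  expect_equal(mapValues(differenceMap(rest, stress)),
               -mapValues(differenceMap(stress, rest)))

  other <- normalizeUptake(polarMap(matrix(100, 5, 8), makePolarGrid(8, 5), "rest"))
  expect_error(differenceMap(stress, other), "grid mismatch")
})

test_that("maps validate their invariants", {
  expect_error(polarMap(matrix(-1, 4, 8), phase = "stress"), "nonnegative")
  expect_error(polarMap(matrix(NaN, 4, 8)), "finite")
  expect_silent(polarMap(matrix(-5, 4, 8), phase = "difference"))
})
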