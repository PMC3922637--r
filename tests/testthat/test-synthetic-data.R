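test_that("noise-free simulation honours severity and reversibility", {
  # severity 0: both maps flat at baseline
  st <- simulateStudy(grid64, defectSpec(90, 0.7, 40, 0.2, 0, 1), 0, seed = 1)
  expect_true(all(mapValues(st$stress) == 100))
  expect_true(all(mapValues(st$rest) == 100))
  expect_equal(st$truth$trueExtentPercent, 0)

  # fully reversible: rest flat, difference positive exactly on the profile
  st <- simulateStudy(grid64, sectorDefect(0.6, 1), 0, seed = 1)
  expect_true(all(mapValues(st$rest) == 100))
  d <- mapValues(differenceMap(normalizeUptake(st$stress),
                               normalizeUptake(st$rest)))
  expect_true(all(d[st$truth$reversibleMask] > 0))

  # pure scar: stress and rest identical reductions
  st <- simulateStudy(grid64, sectorDefect(0.6, 0), 0, seed = 1)
  expect_equal(mapValues(st$stress), mapValues(st$rest))
  expect_equal(sum(st$truth$reversibleMask), 0L)
})

test_that("ground-truth extent matches the closed-form sector-annulus area", {
  # 90-degree sector over r in [0.5, 1]: 100 * (90/360) * (1 - 0.25) = 18.75
  st <- simulateStudy(grid64, sectorDefect(), 0, seed = 1)
  expect_equal(st$truth$trueExtentPercent, 18.75, tolerance = 1e-12)
  # and the mask-weight summation agrees with extentPercent
  expect_equal(extentPercent(list(st$truth$reversibleMask), grid64), 18.75)

  # other specs whose edges align with cell boundaries agree within one
  # cell's weight
  oneCellPct <- 100 * max(areaWeights(grid64))
  for (case in list(c(180, 0.5, 90, 0.25), c(0, 0.625, 28.125, 0.125))) {
    d <- defectSpec(case[1], case[2], case[3], case[4], 0.7, 1)
    st <- simulateStudy(grid64, d, 0, seed = 1)
    analytic <- 100 * (2 * case[3] / 360) *
      ((case[2] + case[4])^2 - (case[2] - case[4])^2)
    expect_lte(abs(st$truth$trueExtentPercent - analytic), oneCellPct)
  }
})

test_that("simulation is seed-deterministic and truth masks nest", {
  a <- simulateStudy(grid64, sectorDefect(), 0.05, seed = 7)
  b <- simulateStudy(grid64, sectorDefect(), 0.05, seed = 7)
  expect_identical(mapValues(a$stress), mapValues(b$stress))
  expect_identical(mapValues(a$rest), mapValues(b$rest))
  c <- simulateStudy(grid64, sectorDefect(), 0.05, seed = 8)
  expect_false(identical(mapValues(a$stress), mapValues(c$stress)))

  # containment of reversible in stress-defect mask for random specs
  set.seed(11)
  for (i in 1:10) {
    d <- randomDefect(reversibility = runif(1, 0.1, 1))
    st <- simulateStudy(grid64, d, 0, seed = i)
    expect_true(all(st$truth$stressDefectMask[st$truth$reversibleMask]))
  }
})

test_that("defect specs outside the disc or unit ranges are rejected", {
  expect_error(defectSpec(0, 0.9, 30, 0.3, 0.5, 1), "beyond the disc")
  expect_error(defectSpec(0, 0.5, 30, 0.2, 1.2, 1), "severity")
  expect_error(defectSpec(0, 0.5, -30, 0.2, 0.5, 1), "half widths")
})

test_that("rater panels follow the two-way random-effects model", {
  # no rater or error variance: identical columns, downstream ICC 1
  p <- simulateRaterPanel(10, 4, patientSd = 10, raterSd = 0, errorSd = 0,
                          grandMean = 30, seed = 1)
  v <- panelValues(p)
  expect_true(all(apply(v, 1, function(r) diff(range(r)) == 0)))
  expect_equal(iccTwoWayRandom(p)@icc, 1)

  # no patient variance: ICC near 0 at large n
  p0 <- simulateRaterPanel(400, 6, patientSd = 0, raterSd = 5, errorSd = 5,
                           grandMean = 50, seed = 2)
  expect_lt(iccTwoWayRandom(p0)@icc, 0.05)

  # determinism and clipping report
  p1 <- simulateRaterPanel(25, 11, 15, 5, 5, 20, seed = 3)
  p2 <- simulateRaterPanel(25, 11, 15, 5, 5, 20, seed = 3)
  expect_identical(panelValues(p1), panelValues(p2))
  expect_true(all(panelValues(p1) >= 0 & panelValues(p1) <= 100))
  expect_gte(nClipped(p1), 0L)
})

test_that("Monte-Carlo ICC recovery matches the implied closed form", {
  # implied ICC = 225 / (225 + 25 + 25) = 0.818...
  iccs <- vapply(1:50, function(s)
    iccTwoWayRandom(simulateRaterPanel(200, 11, 15, 5, 5, 20,
                                       seed = s))@icc, numeric(1))
  expect_lt(abs(mean(iccs) - 225 / 275), 0.08)
})
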