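test_that("column summaries reproduce the packaged per-program statistics", {
  t1 <- table1Fixture()
  expect_equal(nrow(t1), 25L)

  s <- columnSummary(t1$exini_extent)
  expect_equal(round(s$mean, 1), 17.0)
  expect_equal(round(s$sd, 1), 14.6)
  expect_equal(s$median, 16)
  expect_equal(c(s$min, s$max), c(0, 59))

  s <- columnSummary(t1$ect_extent)
  expect_equal(s$median, 11)
  expect_equal(c(s$min, s$max), c(0, 37))

  # degenerate single-value column
  s1 <- columnSummary(5)
  expect_true(s1$zeroVariance)
  expect_equal(s1$sd, 0)
  expect_equal(s1$median, 5)
  expect_error(columnSummary(numeric(0)), "at least one")
})

test_that("ICC matches an independent mean-squares oracle", {
  # fixed small panels, oracle computed from textbook sums of squares
  panels <- list(
    matrix(c(9, 6, 8, 7, 10, 6, 3, 8, 2, 8, 2, 4), 4, 3),
    matrix(c(1, 2, 3, 4, 5, 2, 3, 4, 5, 6, 1, 3, 3, 5, 5), 5, 3),
    matrix(runif(24, 0, 50), 6, 4)
  )
  set.seed(99)
  panels[[3]] <- matrix(runif(24, 0, 50), 6, 4)
  for (v in panels) {
    r <- iccTwoWayRandom(v)
    expect_equal(r@icc, anovaICCOracle(v), tolerance = 1e-9)
    expect_lte(r@ciLow, r@icc)
    expect_gte(r@ciHigh, r@icc)
  }

  # identical observers, patients differ -> ICC 1
  v <- matrix(rep(c(10, 20, 30, 40), 3), 4, 3)
  expect_equal(iccTwoWayRandom(v)@icc, 1)

  # constant panel -> degenerate flag, CI [1, 1]
  rconst <- iccTwoWayRandom(matrix(7, 4, 3))
  expect_true(rconst@degenerate)
  expect_equal(c(rconst@ciLow, rconst@ciHigh), c(1, 1))
})

test_that("ICC is invariant to location-scale changes and hurt by noise", {
  set.seed(3)
  v <- panelValues(simulateRaterPanel(30, 6, 12, 4, 4, 30, seed = 3))
  base <- iccTwoWayRandom(v)@icc
  expect_equal(iccTwoWayRandom(v + 17)@icc, base, tolerance = 1e-12)
  expect_equal(iccTwoWayRandom(v * 2.5)@icc, base, tolerance = 1e-12)

  # additive i.i.d. noise lowers ICC in expectation
  set.seed(4)
  noisy <- vapply(1:50, function(i)
    iccTwoWayRandom(v + matrix(rnorm(length(v), 0, 6), nrow(v)))@icc,
    numeric(1))
  expect_lt(mean(noisy), base)
})

test_that("REML variance components agree with method of moments", {
  skip_if_not_installed("lme4")
  p <- simulateRaterPanel(40, 8, 12, 4, 5, 25, seed = 6)
  a <- iccTwoWayRandom(p, method = "anova")
  r <- iccTwoWayRandom(p, method = "reml")
  expect_equal(r@icc, a@icc, tolerance = 0.02)
})

test_that("between-observer SD recovers the observer component", {
  # identical observers -> 0
  v <- matrix(rep(c(10, 20, 30, 40), 3), 4, 3)
  expect_equal(as.numeric(betweenObserverSD(v)), 0)

  # exact offsets (-5, 0, +5), no error: component estimate is 5
  base <- c(10, 25, 40, 15)
  v <- cbind(base - 5, base, base + 5)
  obs <- betweenObserverSD(v)
  expect_equal(as.numeric(obs), 5, tolerance = 1e-12)
  expect_equal(attr(obs, "sdOfObserverMeans"), 5, tolerance = 1e-12)

  # Monte-Carlo recovery of rater_sd 6 at 200 x 11
  ests <- vapply(1:50, function(s)
    as.numeric(betweenObserverSD(simulateRaterPanel(200, 11, 15, 6, 5, 30,
                                                    seed = s))),
    numeric(1))
  expect_lt(abs(mean(ests) - 6), 1.5)
})

test_that("Bland-Altman reports bias, limits and attainable-difference bounds", {
  x <- c(10, 20, 30, 40, 50)
  same <- blandAltman(x, x)
  expect_equal(same@bias, 0)
  expect_equal(same@loaHigh - same@loaLow, 0)

  shifted <- blandAltman(x, x + 3)
  expect_equal(shifted@bias, 3)
  expect_equal(c(shifted@loaLow, shifted@loaHigh), c(3, 3))

  # d = {-2, 0, 2}: SD = 2, limits at +/- 3.92
  ba <- blandAltman(c(10, 20, 30), c(8, 20, 32))
  expect_equal(ba@bias, 0)
  expect_equal(ba@loaHigh, 1.96 * 2)
  expect_equal(ba@loaLow, -1.96 * 2)

  # no value below -reference is attainable (extents are nonnegative)
  expect_equal(ba@maxDiffLower, -c(10, 20, 30))
  expect_equal(ba@maxDiffUpper, 100 - c(10, 20, 30))

  expect_error(blandAltman(1:3, 1:4), "equal length")
})

test_that("exact Wilcoxon p-values match full sign-pattern enumeration", {
  # n = 5 strictly positive differences: two-sided p = 2/32
  r <- wilcoxonSignedRank(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))
  expect_equal(r$p.value, 0.0625)
  expect_true(r$exact)

  # random integer data (with ties and zeros) for all n <= 10
  set.seed(12)
  for (n in 3:10) {
    for (rep in 1:5) {
      x <- sample(0:6, n, replace = TRUE)
      y <- sample(0:6, n, replace = TRUE)
      if (all(x == y)) next
      ours <- wilcoxonSignedRank(x, y, mode = "exact")
      expect_equal(ours$p.value, wilcoxonEnumOracle(x, y), tolerance = 1e-12)
    }
  }

  # identical vectors: nothing to test
  r0 <- wilcoxonSignedRank(1:4, 1:4)
  expect_true(r0$noTest)
  expect_equal(r0$p.value, 1)
})

test_that("normal approximation tracks the exact Wilcoxon p", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    pe <- wilcoxonSignedRank(x, y, mode = "exact")$p.value
    pa <- wilcoxonSignedRank(x, y, mode = "approx")$p.value
    expect_lte(abs(pe - pa), 0.02)
  }
})

test_that("balanced method contrasts equal paired mean differences", {
  set.seed(8)
  n <- 12
  a <- runif(n, 0, 40)
  long <- data.frame(
    patient = rep(sprintf("p%02d", 1:n), 2),
    method = rep(c("A", "B"), each = n),
    value = c(a, a + 5))
  mc <- methodContrast(long)
  expect_equal(nrow(mc), 1L)
  expect_equal(mc$estimate, -5)
  expect_lt(mc$p.value, 1e-10)

  # permuted deviations with the same mean -> contrast 0
  dev <- a - mean(a)
  long2 <- data.frame(
    patient = rep(sprintf("p%02d", 1:n), 2),
    method = rep(c("A", "B"), each = n),
    value = c(mean(a) + dev, mean(a) + sample(dev)))
  expect_equal(methodContrast(long2)$estimate, 0, tolerance = 1e-12)

  # algebraic identity: contrast == mean(A) - mean(B) on random data
  long3 <- data.frame(
    patient = rep(sprintf("p%02d", 1:n), 3),
    method = rep(c("A", "B", "C"), each = n),
    value = runif(3 * n, 0, 50))
  mc3 <- methodContrast(long3)
  expect_equal(nrow(mc3), 3L)
  wide <- matrix(long3$value, n)
  expect_equal(mc3$estimate[mc3$methodA == "A" & mc3$methodB == "B"],
               mean(wide[, 1]) - mean(wide[, 2]), tolerance = 1e-12)

  # unbalanced designs are refused
  expect_error(methodContrast(long[-1, ]), "unsupported design")
})

test_that("a suggested-delineation second read raises the ICC", {
  wins <- 0L
  for (s in 1:50) {
    first <- simulateRaterPanel(25, 11, patientSd = 12, raterSd = 6,
                                errorSd = 6, grandMean = 20, seed = s)
    ref <- rowMeans(panelValues(first))  # common suggestion per patient
    second <- simulateSecondRead(first, ref, weight = 0.5)
    if (iccTwoWayRandom(second)@icc > iccTwoWayRandom(first)@icc)
      wins <- wins + 1L
  }
  expect_gte(wins, 45L)
})
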