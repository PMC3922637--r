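test_that("seed detection matches an exhaustive local-minimum scan", {
  # constant map: no seeds
  flat <- normalizeUptake(polarMap(matrix(100, 32, 64), grid64))
  expect_equal(nrow(findSeeds(flat)), 0L)

  # exhaustive oracle: scan every cell against its 8-neighbourhood with
  # angular wrap and one-sided radial edges
  scanOracle <- function(v, thr) {
    hits <- NULL
    nR <- nrow(v); nT <- ncol(v)
    for (j in 1:nR) for (i in 1:nT) {
      if (v[j, i] >= thr) next
      ok <- TRUE
      for (dj in -1:1) for (di in -1:1) {
        if (di == 0 && dj == 0) next
        jj <- j + dj
        if (jj < 1 || jj > nR) next
        ii <- ((i + di - 1) %% nT) + 1
        if (v[jj, ii] <= v[j, i]) ok <- FALSE
      }
      if (ok) hits <- rbind(hits, c(i, j))
    }
    hits
  }

  # one smooth dip (soft profile, no flat core -> unique strict minimum)
  st <- simulateStudy(grid64, defectSpec(120, 0.6, 20, 0.1, 0.6, 1, 0.2),
                      0, seed = 1)
  sn <- normalizeUptake(st$stress)
  seeds <- findSeeds(sn, 70)
  oracle <- scanOracle(mapValues(sn), 70)
  expect_equal(nrow(seeds), 1L)
  expect_equal(nrow(seeds), nrow(oracle))
  expect_true(all(seeds == oracle))

  # two well-separated dips
  st2 <- simulateStudy(grid64, list(
    defectSpec(60, 0.6, 20, 0.1, 0.6, 1, 0.2),
    defectSpec(240, 0.6, 20, 0.1, 0.5, 1, 0.2)), 0, seed = 1)
  sn2 <- normalizeUptake(st2$stress)
  seeds2 <- findSeeds(sn2, 70)
  oracle2 <- scanOracle(mapValues(sn2), 70)
  expect_equal(nrow(seeds2), 2L)
  expect_equal(nrow(seeds2), nrow(oracle2))
  expect_true(all(seeds2 == oracle2))

  # plateau: flat-bottomed dip collapses to a single centroid seed
  v <- matrix(100, 32, 64)
  v[14:16, 20:23] <- 40
  seeds3 <- findSeeds(normalizeUptake(polarMap(v, grid64)), 70)
  expect_equal(nrow(seeds3), 1L)
  expect_equal(unname(seeds3[1, ]), c(21, 15))  # centroid cell (rounded)
})

test_that("active contours recover sharp defects and descend in energy", {
  st <- simulateStudy(grid64, defectSpec(90, 0.7, 40, 0.2, 0.6, 1, 0.01),
                      0, seed = 1)
  sn <- normalizeUptake(st$stress)
  seeds <- findSeeds(sn, 70)
  expect_equal(nrow(seeds), 1L)
  ct <- fitActiveContour(sn, seeds[1, ])
  m <- rasterizeContour(ct, grid64)
  expect_gte(dice(m, st$truth$stressDefectMask), 0.85)

  # final energy never exceeds initial energy
  tr <- energyTrace(ct)
  expect_lte(tr[length(tr)], tr[1])

  expect_error(fitActiveContour(sn, c(5, 0.2)), "boundary")
})

test_that("energy descent and seed containment hold over random studies", {
  set.seed(42)
  for (i in 1:20) {
    st <- simulateStudy(grid64, randomDefect(), runif(1, 0, 0.05), seed = i)
    sn <- normalizeUptake(st$stress)
    seeds <- findSeeds(sn, 70)
    if (!nrow(seeds)) next
    ct <- fitActiveContour(sn, seeds[1, ])
    expect_true(all(diff(energyTrace(ct)) <= 1e-9))
    # seed lies inside the final polygon
    m <- rasterizeContour(ct, grid64)
    expect_true(m[seeds[1, "r"], seeds[1, "theta"]])
    expect_gte(nrow(contourVertices(ct)), 8)
  }
})

test_that("stage 1 merges overlapping regions and drops specks", {
  flat <- polarMap(matrix(100, 32, 64), grid64)
  expect_length(delineateStressDefects(normalizeUptake(flat)), 0)

  # two disjoint defects -> two regions
  st <- simulateStudy(grid64, list(
    defectSpec(60, 0.6, 30, 0.15, 0.6, 1),
    defectSpec(240, 0.6, 30, 0.15, 0.7, 1)), 0, seed = 1)
  regs <- delineateStressDefects(normalizeUptake(st$stress))
  expect_length(regs, 2)

  # moved to overlap -> a single merged region
  st2 <- simulateStudy(grid64, list(
    defectSpec(80, 0.6, 30, 0.15, 0.6, 1),
    defectSpec(110, 0.6, 30, 0.15, 0.7, 1)), 0, seed = 1)
  regs2 <- delineateStressDefects(normalizeUptake(st2$stress))
  expect_length(regs2, 1)

  # masks pairwise disjoint after merging
  if (length(regs) > 1) {
    overlap <- regionMask(regs[[1]]) & regionMask(regs[[2]])
    expect_equal(sum(overlap), 0L)
  }
})

test_that("stage 2 extracts reversible regions inside stress defects", {
  st <- simulateStudy(grid64, sectorDefect(0.6, 1), 0, seed = 1)
  sn <- normalizeUptake(st$stress); rn <- normalizeUptake(st$rest)
  sd1 <- delineateStressDefects(sn)
  d <- differenceMap(sn, rn)

  # all-zero difference image -> empty list
  zero <- differenceMap(sn, sn)
  expect_length(extractReversible(sd1, zero), 0)

  # fully reversible defect: one region, high Dice against truth
  rev <- extractReversible(sd1, d)
  expect_length(rev, 1)
  expect_gte(dice(regionMask(rev[[1]]), st$truth$reversibleMask), 0.85)
  expect_identical(regionKind(rev[[1]]), "difference_defect")

  # pure scar -> no difference defects
  scar <- simulateStudy(grid64, sectorDefect(0.6, 0), 0, seed = 1)
  snS <- normalizeUptake(scar$stress)
  sdS <- delineateStressDefects(snS)
  dS <- differenceMap(snS, normalizeUptake(scar$rest))
  expect_length(extractReversible(sdS, dS), 0)
})

test_that("the full pipeline is deterministic, contained and sign-aware", {
  st <- simulateStudy(grid64, sectorDefect(), 0.02, seed = 1)
  r1 <- delineate(st$stress, st$rest)
  r2 <- delineate(st$stress, st$rest)
  expect_identical(unionMask(r1$differenceDefects, grid64),
                   unionMask(r2$differenceDefects, grid64))

  # containment: difference defects inside the union of stress defects
  su <- unionMask(r1$stressDefects, grid64)
  du <- unionMask(r1$differenceDefects, grid64)
  expect_true(all(su[du]))

  # recovered extent close to the truth
  expect_lt(abs(r1$extentPercent - st$truth$trueExtentPercent), 3)

  # swapping stress and rest: difference nonpositive -> nothing reversible
  swapped <- delineate(st$rest, st$stress)
  expect_length(swapped$differenceDefects, 0)
})

test_that("estimated reversible extent is monotone in reversibility", {
  exts <- vapply(seq(0, 1, by = 0.25), function(rev) {
    st <- simulateStudy(grid64, sectorDefect(0.6, rev), 0, seed = 1)
    delineate(st$stress, st$rest)$extentPercent
  }, numeric(1))
  expect_true(all(diff(exts) >= 0))
  expect_equal(exts[1], 0)
})
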