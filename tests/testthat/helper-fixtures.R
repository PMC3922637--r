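# Shared fixtures: everything is generated in code at test time.

grid64 <- makePolarGrid(64, 32)

# A quarter-circle sector over the outer half of the disc: closed-form
# area fraction (90/360) * (1^2 - 0.5^2) = 0.1875.
sectorDefect <- function(severity = 0.6, reversibility = 1,
                         edgeSoftness = 0.05) {
  defectSpec(90, 0.75, 45, 0.25, severity, reversibility, edgeSoftness)
}

# Random in-disc defect under the study conditions used throughout the
# tests: extent roughly 5-40% of LV, severity 0.5-0.8.
randomDefect <- function(severity = runif(1, 0.5, 0.8),
                         reversibility = 1) {
  ext <- runif(1, 5, 40)
  cr <- runif(1, 0.45, 0.7)
  hwt <- runif(1, 30, 75)
  hwr <- ext / 100 * 360 / (2 * hwt) / (4 * cr)
  hwr <- min(max(hwr, 0.08), 0.98 - cr)
  defectSpec(runif(1, 0, 360), cr, hwt, hwr, severity, reversibility)
}

unionMask <- function(regions, grid) {
  if (!length(regions)) return(matrix(FALSE, nRadial(grid), nTheta(grid)))
  Reduce(`|`, lapply(regions, regionMask))
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Independent two-way ANOVA mean-squares oracle, written from the
# textbook sums of squares (no shared code with the package internals).
anovaICCOracle <- function(v) {
  n <- nrow(v); k <- ncol(v)
  gm <- mean(v)
  ssTotal <- sum((v - gm)^2)
  ssRow <- sum(k * (rowMeans(v) - gm)^2)
  ssCol <- sum(n * (colMeans(v) - gm)^2)
  ssErr <- ssTotal - ssRow - ssCol
  msr <- ssRow / (n - 1); msc <- ssCol / (k - 1)
  mse <- ssErr / ((n - 1) * (k - 1))
  vp <- max((msr - mse) / k, 0)
  vo <- max((msc - mse) / n, 0)
  vp / (vp + vo + mse)
}

# Exhaustive Wilcoxon signed-rank oracle: enumerate all 2^m sign patterns.
wilcoxonEnumOracle <- function(x, y) {
  d <- (x - y)[x != y]
  m <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  allW <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  pLo <- mean(allW <= W + 1e-9)
  pHi <- mean(allW >= W - 1e-9)
  min(1, 2 * min(pLo, pHi))
}
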