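#' Column summary statistics
#'
#' Mean, sample SD (n - 1 denominator), median (middle order statistic,
#' average of the middle two for even n), minimum and maximum -
#' the descriptive layer used for per-program extent columns.  A single
#' observation has no sample SD; it is reported as 0 with
#' \code{zeroVariance = TRUE}.
#'
#' @param x numeric vector, length >= 1.
#' @return List with \code{n}, \code{mean}, \code{sd}, \code{median},
#'   \code{min}, \code{max}, \code{zeroVariance}.
#' @export
columnSummary <- function(x) {
  if (!length(x) || !is.numeric(x)) stop("need at least one numeric value")
  if (anyNA(x)) stop("missing values not allowed")
  list(n = length(x), mean = mean(x),
       sd = if (length(x) > 1L) stats::sd(x) else 0,
       median = stats::median(x), min = min(x), max = max(x),
       zeroVariance = length(x) == 1L)
}

## Two-way crossed ANOVA mean squares for a complete patients x observers
## panel, plus method-of-moments variance components (truncated at 0).
.twoWayComponents <- function(v) {
  n <- nrow(v); k <- ncol(v)
  gm <- mean(v)
  rm <- rowMeans(v); cm <- colMeans(v)
  msr <- k * sum((rm - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  resid <- v - outer(rm, rep(1, k)) - outer(rep(1, n), cm) + gm
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  list(n = n, k = k, msr = msr, msc = msc, mse = mse,
       varP = max((msr - mse) / k, 0),
       varO = max((msc - mse) / n, 0),
       varE = mse)
}

#' Two-way random-effects intraclass correlation
#'
#' Single-rater, absolute-agreement ICC from a two-way random-effects model
#' with patients and observers as random effects: the ANOVA mean squares
#' give method-of-moments variance components \eqn{\sigma^2_p = (MS_p -
#' MS_e)/k}, \eqn{\sigma^2_o = (MS_o - MS_e)/n}, \eqn{\sigma^2_e = MS_e}
#' (negative estimates truncated to 0), and \eqn{ICC = \sigma^2_p /
#' (\sigma^2_p + \sigma^2_o + \sigma^2_e)}.  The 95 percent confidence
#' interval is the F-based interval for the single-rater two-way
#' random-effects ICC (Satterthwaite degrees of freedom for the
#' denominator).  A REML fit of the same model is available via
#' \code{method = "reml"} (requires \pkg{lme4}); the interval is always
#' F-based.
#'
#' @param panel a \linkS4class{RaterPanel} or a complete numeric matrix
#'   (patients x observers).
#' @param alpha 1 - confidence level (default 0.05 for 95 percent CI).
#' @param method \code{"anova"} (method of moments, default) or
#'   \code{"reml"}.
#' @return An \linkS4class{ICCResult}.
#' @references Shrout & Fleiss (1979) Psychol Bull 86:420;
#'   McGraw & Wong (1996) Psychol Methods 1:30.
#' @export
iccTwoWayRandom <- function(panel, alpha = 0.05,
                            method = c("anova", "reml")) {
  method <- match.arg(method)
  v <- if (is(panel, "RaterPanel")) panel@values else as.matrix(panel)
  if (nrow(v) < 2L || ncol(v) < 2L || anyNA(v))
    stop("need a complete panel with >= 2 patients and >= 2 observers")
  cmp <- .twoWayComponents(v)

  if (cmp$varP + cmp$varO + cmp$varE <= 1e-12) {
    ## constant panel: no variance at all; agreement is perfect by
    ## convention, flagged degenerate
    return(new("ICCResult", icc = 1, ciLow = 1, ciHigh = 1,
               varPatient = 0, varObserver = 0, varError = 0,
               degenerate = TRUE))
  }

  if (method == "reml") {
    if (!requireNamespace("lme4", quietly = TRUE))
      stop("method = 'reml' requires the lme4 package")
    long <- data.frame(value = as.vector(v),
                       patient = factor(rep(seq_len(cmp$n), cmp$k)),
                       observer = factor(rep(seq_len(cmp$k), each = cmp$n)))
    fit <- lme4::lmer(value ~ 1 + (1 | patient) + (1 | observer),
                      data = long,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    vc <- as.data.frame(lme4::VarCorr(fit))
    cmp$varP <- vc$vcov[vc$grp == "patient"]
    cmp$varO <- vc$vcov[vc$grp == "observer"]
    cmp$varE <- vc$vcov[vc$grp == "Residual"]
  }

  icc <- cmp$varP / (cmp$varP + cmp$varO + cmp$varE)
  n <- cmp$n; k <- cmp$k
  msr <- cmp$msr; msc <- cmp$msc; mse <- cmp$mse

  if (mse <= 1e-12 && msc <= 1e-12) {
    ## observers identical: perfect agreement given patient variance
    ciLow <- icc; ciHigh <- icc
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    if (!is.finite(a)) { a <- 0; b <- 1 }   # icc == 1 guard
    vdf <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, vdf)
    fu <- stats::qf(1 - alpha / 2, vdf, n - 1)
    ciLow <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    ciHigh <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
    ciLow <- max(min(ciLow, icc), -1)
    ciHigh <- min(max(ciHigh, icc), 1)
  }
  new("ICCResult", icc = icc, ciLow = ciLow, ciHigh = ciHigh,
      varPatient = cmp$varP, varObserver = cmp$varO, varError = cmp$varE,
      degenerate = FALSE)
}

#' Between-observer standard deviation
#'
#' The square root of the observer variance component \eqn{\sigma^2_o} from
#' the two-way random-effects decomposition (method of moments, truncated
#' at 0).  The SD of the observer column means - a population-style
#' alternative reading of "SD between observers" - is attached as attribute
#' \code{"sdOfObserverMeans"}.
#'
#' @param panel a \linkS4class{RaterPanel} or complete numeric matrix.
#' @return Between-observer SD in percentage points.
#' @export
betweenObserverSD <- function(panel) {
  v <- if (is(panel, "RaterPanel")) panel@values else as.matrix(panel)
  if (nrow(v) < 2L || ncol(v) < 2L || anyNA(v))
    stop("need a complete panel with >= 2 patients and >= 2 observers")
  cmp <- .twoWayComponents(v)
  out <- sqrt(cmp$varO)
  attr(out, "sdOfObserverMeans") <- stats::sd(colMeans(v))
  out
}

#' Bland-Altman agreement between two methods
#'
#' Differences \code{test - reference} with mean bias and limits of
#' agreement bias +/- 1.96 x sample SD, plus the per-point boundary of the
#' maximum possible difference: extents lie in \[0, 100\], so for a
#' reference value x no difference below -x (or above 100 - x) is
#' attainable; that bound appears as the diagonal limit line in the plots.
#'
#' @param reference,test numeric vectors of equal length >= 2;
#'   \code{reference} is the reference method.
#' @return A \linkS4class{BlandAltmanResult}.
#' @export
blandAltman <- function(reference, test) {
  if (length(reference) != length(test))
    stop("reference and test must have equal length")
  if (length(reference) < 2L) stop("need at least 2 paired values")
  d <- test - reference
  bias <- mean(d)
  s <- stats::sd(d)
  new("BlandAltmanResult", bias = bias,
      loaLow = bias - 1.96 * s, loaHigh = bias + 1.96 * s,
      differences = d, means = (reference + test) / 2,
      maxDiffLower = -reference, maxDiffUpper = 100 - reference)
}

#' Wilcoxon signed-rank test for paired data
#'
#' Zero differences are dropped; tied absolute differences receive
#' midranks.  The statistic is W = sum of the ranks of the positive
#' differences.  With \code{mode = "exact"} (the default for up to 20
#' nonzero pairs) the two-sided p-value comes from the exact permutation
#' distribution over all sign assignments, computed by convolution over the
#' doubled (integer) midranks, which is valid under ties; otherwise a
#' normal approximation with continuity correction and midrank variance
#' \eqn{\sum r_i^2 / 4} is used.  When every difference is zero there is
#' nothing to test: the result carries \code{noTest = TRUE} and p = 1.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param mode \code{"auto"}, \code{"exact"} or \code{"approx"}.
#' @return List with \code{statistic} (W), \code{p.value}, \code{n}
#'   (nonzero pairs), \code{exact}, \code{noTest}.
#' @examples
#' wilcoxonSignedRank(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 5))$p.value  # 0.0625
#' @export
wilcoxonSignedRank <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L)
    return(list(statistic = NA_real_, p.value = 1, n = 0L, exact = NA,
                noTest = TRUE))
  r <- rank(abs(d))          # midranks for ties
  W <- sum(r[d > 0])
  useExact <- mode == "exact" || (mode == "auto" && m <= 20L)
  if (useExact) {
    r2 <- as.integer(round(2 * r))   # doubled midranks are integers
    total <- sum(r2)
    ## counts over the exact distribution of 2W by subset convolution
    counts <- numeric(total + 1L)
    counts[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(total + 1L - ri)])
      counts <- counts + shifted
    }
    w2 <- as.integer(round(2 * W))
    pLo <- sum(counts[seq_len(w2 + 1L)]) / 2^m
    pHi <- sum(counts[(w2 + 1L):(total + 1L)]) / 2^m
    p <- min(1, 2 * min(pLo, pHi))
    list(statistic = W, p.value = p, n = m, exact = TRUE, noTest = FALSE)
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    cc <- if (W == mu) 0 else 0.5 * sign(W - mu)
    z <- (W - mu - cc) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(statistic = W, p.value = p, n = m, exact = FALSE, noTest = FALSE)
  }
}

#' Pairwise method contrasts on a balanced complete design
#'
#' For every pair of methods, the fixed-effect contrast of a linear mixed
#' model with method (and observer, if present) as fixed effects and
#' patients as random effects reduces, on a complete balanced design, to
#' the paired mean difference across patients; the returned p-value is the
#' paired t-test on those differences.  Unbalanced input is refused rather
#' than silently approximated.
#'
#' @param data data.frame with columns \code{patient}, \code{method},
#'   \code{value}: every method observed exactly once on every patient.
#' @return data.frame with one row per ordered method pair: \code{methodA},
#'   \code{methodB}, \code{estimate} (mean of A - B), \code{p.value}.
#' @export
methodContrast <- function(data) {
  stopifnot(all(c("patient", "method", "value") %in% names(data)))
  tab <- table(data$patient, data$method)
  if (any(tab != 1L))
    stop("unsupported design: every method must be observed exactly once ",
         "per patient (complete balanced design)")
  methods <- sort(unique(as.character(data$method)))
  wide <- stats::reshape(
    data[, c("patient", "method", "value")], direction = "wide",
    idvar = "patient", timevar = "method")
  out <- NULL
  for (a in seq_along(methods)) for (b in seq_along(methods)) {
    if (a >= b) next
    va <- wide[[paste0("value.", methods[a])]]
    vb <- wide[[paste0("value.", methods[b])]]
    d <- va - vb
    p <- if (stats::sd(d) == 0) {
      if (mean(d) == 0) 1 else 0
    } else stats::t.test(d)$p.value
    out <- rbind(out, data.frame(methodA = methods[a], methodB = methods[b],
                                 estimate = mean(d), p.value = p,
                                 stringsAsFactors = FALSE))
  }
  out
}
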