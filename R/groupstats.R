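#' @include AllClasses.R
NULL

#' One-sample t test with Cohen's d
#'
#' Either from raw per-subject values or from summary statistics
#' (mean/SD/n), as when recomputing printed results. For a one-sample test
#' d = mean/SD = t/sqrt(n).
#'
#' @param x per-subject values; or supply \code{mean}, \code{sd}, \code{n}.
#' @param mu null value (default 0).
#' @param mean,sd,n summary statistics (used when \code{x} is missing).
#' @param tail \code{"greater"} (default, signal > 0), \code{"less"} or
#'   \code{"two.sided"}.
#' @return list with \code{t}, \code{df}, \code{p}, \code{d}.
#' @examples
#' oneSampleT(mean = 0.152, sd = 0.087, n = 15)  # t = 6.77, d = 1.75
#' @export
oneSampleT <- function(x = NULL, mu = 0, mean = NULL, sd = NULL, n = NULL,
                       tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  if (!is.null(x)) {
    stopifnot(length(x) >= 2, all(is.finite(x)))
    mean <- base::mean(x); sd <- stats::sd(x); n <- length(x)
  }
  stopifnot(n >= 2)
  if (sd == 0) stop("zero standard deviation: t undefined")
  t <- (mean - mu) / (sd / sqrt(n))
  df <- n - 1
  p <- switch(tail,
    greater = stats::pt(t, df, lower.tail = FALSE),
    less = stats::pt(t, df),
    two.sided = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
  list(t = t, df = df, p = p, d = (mean - mu) / sd)
}

#' Electrode-wise paired contrast with Bonferroni correction
#'
#' Paired t test per electrode on the difference A - B across matched
#' subjects (the standard > scrambled contrast), one-tailed, with p-values
#' multiplied by \code{nComparisons} (capped at 1) and thresholded at
#' \code{alpha}.
#'
#' @param topoA,topoB subjects x electrodes matrices of summed responses
#'   (uV); identical dimnames required.
#' @param nComparisons Bonferroni multiplier (default: number of
#'   electrodes).
#' @param alpha significance level after correction (default 0.05).
#' @return data.frame with electrode, t, df, p, p_bonf, d, significant.
#' @export
pairedTContrast <- function(topoA, topoB, nComparisons = ncol(topoA),
                            alpha = 0.05) {
  topoA <- as.matrix(topoA); topoB <- as.matrix(topoB)
  if (!identical(dim(topoA), dim(topoB)))
    stop("matrices must be subject- and electrode-matched")
  if (!is.null(colnames(topoA)) && !is.null(colnames(topoB)) &&
      !identical(colnames(topoA), colnames(topoB)))
    stop("electrode sets differ")
  n <- nrow(topoA)
  if (n < 2) stop("need at least 2 subjects")
  d <- topoA - topoB
  m <- colMeans(d)
  s <- apply(d, 2L, stats::sd)
  ## identical conditions give a zero difference with zero SD: t = 0
  t <- ifelse(s == 0, ifelse(m == 0, 0, sign(m) * Inf), m / (s / sqrt(n)))
  p <- stats::pt(t, n - 1, lower.tail = FALSE)
  pb <- pmin(p * nComparisons, 1)
  data.frame(
    electrode = if (is.null(colnames(topoA)))
      paste0("e", seq_along(m)) else colnames(topoA),
    t = t, df = n - 1, p = p, p_bonf = pb, d = m / s,
    significant = pb < alpha,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Average a topography over a region of interest
#'
#' @param topo named per-channel values (uV), e.g.
#'   \code{\link{summedAmplitude}} output.
#' @param roi character electrode labels; all must be present.
#' @return scalar mean.
#' @export
roiAverage <- function(topo, roi) {
  if (!all(roi %in% names(topo)))
    stop("ROI labels missing from topography: ",
         paste(setdiff(roi, names(topo)), collapse = ", "))
  mean(topo[roi])
}

#' The right superior-temporal voice ROI
#'
#' Electrodes isolated by the standard > scrambled contrast: TP8h, CP6,
#' C6, T8.
#' @return character vector of labels.
#' @export
roiVoice <- function() c("TP8h", "CP6", "C6", "T8")

#' Spearman rank correlation
#'
#' Tie-aware rank correlation with a two-tailed p-value
#' (\code{stats::cor.test}).
#'
#' @param x,y per-subject scalars, n >= 4.
#' @return list with \code{rho} and \code{p}; constant input gives
#'   \code{NA} with a warning.
#' @export
spearmanRho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Welch's two-sample t test
#'
#' From summary statistics (the form printed in papers) or from raw
#' samples; the Welch-Satterthwaite degrees of freedom are returned.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @param x,y alternatively, raw samples (overrides summaries).
#' @param tail \code{"two.sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @examples
#' welchT(223.5, 7.1, 16, 220.6, 1.85, 16)  # df = 17.03
#' @export
welchT <- function(mean1, sd1, n1, mean2, sd2, n2, x = NULL, y = NULL,
                   tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  if (!is.null(x) && !is.null(y)) {
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0 || sd2 > 0)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- switch(tail,
    two.sided = 2 * stats::pt(abs(t), df, lower.tail = FALSE),
    greater = stats::pt(t, df, lower.tail = FALSE),
    less = stats::pt(t, df))
  list(t = t, df = df, p = p)
}

#' Mann-Whitney U test
#'
#' Exact for small tie-free samples, normal approximation otherwise
#' (\code{stats::wilcox.test}). Both the U statistic of the first sample
#' and the rank-sum W convention are reported, since software conventions
#' differ.
#'
#' @param x,y samples.
#' @return list with \code{U}, \code{W} (rank sum of \code{x}), \code{p}
#'   (two-tailed).
#' @export
mannWhitneyU <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x)
  exact <- n1 <= 20 && length(y) <= 20 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact))
  U <- unname(wt$statistic)
  list(U = U, W = U + n1 * (n1 + 1) / 2, p = wt$p.value)
}

#' Single-pass 3-SD outlier exclusion
#'
#' Excludes values deviating more than \code{k} standard deviations from
#' the group mean, with mean and SD computed once on the full set (no
#' iteration).
#'
#' @param values numeric vector, n >= 3.
#' @param k SD multiple (default 3).
#' @return list with \code{kept} values and \code{excluded} indices.
#' @export
outlier3SD <- function(values, k = 3) {
  stopifnot(length(values) >= 3)
  m <- mean(values); s <- stats::sd(values)
  out <- which(abs(values - m) > k * s)
  list(kept = if (length(out)) values[-out] else values, excluded = out)
}
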