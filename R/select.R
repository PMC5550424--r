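#' ROSE feature selection: Recognition of Outliers by Sampling Ends
#'
#' For each probe the sample intensities are sorted ascending; an ordinary
#' least-squares trend line is fitted to the middle third of the sorted
#' profile (ranks `ceiling(n/3)+1 ... floor(2n/3)`); the third and
#' antepenultimate order statistics serve as fixed cutoff points (chosen to
#' accommodate group sizes >= 3). The deviations of the observed intensities
#' from the trend at those cutoffs,
#' `d_low = yhat(3) - x(3)` and `d_high = x(n-2) - yhat(n-2)`,
#' measure exclusive under-/over-expression in a small subgroup. With
#' `D = max(d_low, d_high)`, `mode = "band"` selects probes with
#' `t_min < D <= t_max` (each published analysis lists a lower and an upper
#' threshold), and `mode = "lower"` selects `D > t_min` only.
#'
#' Unlike a variance or IQR filter, a probe expressed exclusively in a
#' subgroup smaller than ~1/8 of the cohort still scores highly, while a
#' probe that is merely noisy across all samples does not: a constant probe
#' and a perfect linear gradient both give D = 0.
#'
#' @param x Numeric matrix, probes x samples (log2 scale), >= 9 samples.
#' @param t_min Lower deviation threshold (log2 units), exclusive.
#' @param t_max Upper deviation threshold (log2 units), inclusive
#'   (default `Inf`).
#' @param mode `"band"` (default) or `"lower"`.
#' @return Data frame of class `rose_result`: probe, d_low, d_high, deviation,
#'   slope, intercept, selected.
#' @export
rose_select <- function(x, t_min, t_max = Inf, mode = c("band", "lower")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(x), is.numeric(x))
  n <- ncol(x)
  if (n < 9) stop("ROSE needs >= 9 samples so thirds and cutoffs are defined", call. = FALSE)
  s <- t(apply(x, 1, sort))
  i1 <- ceiling(n / 3) + 1L
  i2 <- floor(2 * n / 3)
  ranks <- i1:i2
  rbar <- mean(ranks)
  denom <- sum((ranks - rbar)^2)
  mid <- s[, ranks, drop = FALSE]
  mbar <- rowMeans(mid)
  slope <- as.vector(mid %*% (ranks - rbar)) / denom
  intercept <- mbar - slope * rbar
  yhat_lo <- intercept + slope * 3
  yhat_hi <- intercept + slope * (n - 2)
  d_low <- yhat_lo - s[, 3]
  d_high <- s[, n - 2] - yhat_hi
  dev <- pmax(d_low, d_high)
  selected <- if (mode == "band") dev > t_min & dev <= t_max else dev > t_min
  out <- data.frame(probe = rownames(x), d_low = d_low, d_high = d_high,
                    deviation = dev, slope = slope, intercept = intercept,
                    selected = selected, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("rose_result", "data.frame")
  out
}

#' Top-n probe selection by a spread statistic
#'
#' Standard comparator filters: variance, interquartile range, or coefficient
#' of variation (s.d./mean). Ties are broken by probe id; zero-mean probes
#' have an undefined CV and are excluded with a warning.
#'
#' @param x Numeric matrix, probes x samples.
#' @param statistic `"variance"`, `"iqr"`, or `"cv"`.
#' @param n_top Number of probes to return (`<= nrow(x)`).
#' @return Character vector of selected probe ids, best first.
#' @export
variance_filter <- function(x, statistic = c("variance", "iqr", "cv"), n_top) {
  statistic <- match.arg(statistic)
  stopifnot(is.matrix(x), n_top <= nrow(x))
  stat <- switch(statistic,
                 variance = row_vars(x),
                 iqr = apply(x, 1, stats::IQR),
                 cv = {
                   mu <- rowMeans(x)
                   cv <- sqrt(row_vars(x)) / mu
                   if (any(mu == 0)) {
                     warning(sum(mu == 0), " zero-mean probe(s) excluded (undefined CV)")
                     cv[mu == 0] <- -Inf
                   }
                   cv
                 })
  ids <- rownames(x)
  keep <- is.finite(stat)
  ord <- order(-stat[keep], ids[keep])
  utils::head(ids[keep][ord], n_top)
}
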