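#' Single-sample pathway activity by combined z-score
#'
#' Each member gene is z-score transformed across samples; a sample's score
#' aggregates the member z-scores as `sum(z) / sqrt(m)`, so under
#' independence the null score is standard normal regardless of set size.
#' Zero-variance genes contribute z = 0 (flagged); members absent from the
#' matrix are dropped with a message.
#'
#' @param x Numeric matrix, genes x samples (>= 2 samples).
#' @param gene_set Character vector of member genes.
#' @return Named numeric vector of per-sample scores; attribute `m` holds the
#'   number of members used.
#' @export
pathway_activity <- function(x, gene_set) {
  stopifnot(is.matrix(x))
  if (ncol(x) < 2) stop("need >= 2 samples for z-scores", call. = FALSE)
  present <- intersect(gene_set, rownames(x))
  if (length(present) < 1) stop("no gene-set member in the matrix", call. = FALSE)
  absent <- length(setdiff(gene_set, present))
  if (absent > 0) message(absent, " gene(s) absent from the matrix dropped")
  sub <- x[present, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- sqrt(row_vars(sub))
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " zero-variance gene(s): z set to 0")
    sdv[sdv == 0] <- Inf
  }
  z <- (sub - mu) / sdv
  score <- colSums(z) / sqrt(length(present))
  attr(score, "m") <- length(present)
  score
}

#' Linear signature score
#'
#' `score = sum(w_i * x_i)` over the coefficient table's features matched by
#' id in the matrix (the form of published leukemia stem-cell scores such as
#' LSC17).
#'
#' @param x Numeric matrix, features x samples.
#' @param coefficients Data frame with columns `feature` and `weight`.
#' @return Named numeric vector of per-sample scores; attribute `n_matched`
#'   reports how many features matched.
#' @export
linear_score <- function(x, coefficients) {
  stopifnot(is.matrix(x), all(c("feature", "weight") %in% colnames(coefficients)))
  matched <- coefficients[coefficients$feature %in% rownames(x), , drop = FALSE]
  if (nrow(matched) == 0) stop("no signature feature matched the matrix", call. = FALSE)
  w <- matched$weight
  score <- as.vector(t(x[matched$feature, , drop = FALSE]) %*% w)
  names(score) <- colnames(x)
  attr(score, "n_matched") <- nrow(matched)
  score
}

#' Median split of signature scores
#'
#' Samples are labeled `"high"` iff their score is strictly above the cohort
#' median, `"low"` otherwise (so in odd cohorts the median sample itself is
#' low).
#'
#' @param scores Named numeric vector.
#' @return Named character vector of "high"/"low" labels.
#' @export
median_split <- function(scores) {
  med <- stats::median(scores)
  stats::setNames(ifelse(scores > med, "high", "low"), names(scores))
}

#' TMM scaling factors for a count matrix
#'
#' Trimmed mean of M-values: the reference is the sample whose upper quartile
#' is closest to the mean upper quartile; per sample, log2 expression ratios
#' (M) versus the reference after library-size division are doubly trimmed by
#' M (30%) and by average log abundance A (5%), the factor is 2 to the
#' precision-weighted mean M, and factors are rescaled to geometric mean 1.
#' Delegates to [edgeR::calcNormFactors()].
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param trim_M M-value trim fraction (default 0.30).
#' @param trim_A A-value trim fraction (default 0.05).
#' @return Named numeric vector of per-sample scaling factors.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "), call. = FALSE)
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_M, sumTrim = trim_A)
  stats::setNames(f, colnames(counts))
}

#' Two-group k-means stratification on signature features
#'
#' Features are z-scored per gene (unscaled genes would dominate by
#' variance), then k-means with `restarts` random starts picks the partition
#' with minimal within-cluster sum of squares. Cluster labels are oriented
#' deterministically: label 1 is the cluster with the higher mean signature
#' expression (on the unscaled matrix).
#'
#' @param x Numeric matrix restricted to the signature features
#'   (features x samples).
#' @param k Number of clusters (default 2).
#' @param restarts Random restarts (default 50).
#' @param seed Integer seed.
#' @param scale Z-score features first (default TRUE).
#' @return Named integer vector of cluster labels (1 = high-expression
#'   cluster).
#' @export
kmeans_stratify <- function(x, k = 2, restarts = 50, seed = 1L, scale = TRUE) {
  stopifnot(is.matrix(x))
  if (k > ncol(x)) stop("k exceeds the number of samples", call. = FALSE)
  xs <- x
  if (scale) {
    sdv <- sqrt(row_vars(x))
    sdv[sdv == 0] <- 1
    xs <- (x - rowMeans(x)) / sdv
  }
  set.seed(seed)
  km <- stats::kmeans(t(xs), centers = k, nstart = restarts, iter.max = 100)
  labels <- km$cluster
  means <- vapply(seq_len(k), function(cl) {
    mean(x[, labels == cl, drop = FALSE])
  }, numeric(1))
  relabel <- order(-means)            # cluster with highest mean -> label 1
  out <- match(labels, relabel)
  stats::setNames(out, colnames(x))
}

#' Kaplan-Meier product-limit curves per stratum
#'
#' Product-limit estimator via [survival::survfit()]; censored times do not
#' step the curve, and ties are handled events-before-censoring.
#'
#' @param cohort Data frame with columns `time` (>= 0), `event` (0/1), and
#'   optionally `stratum`.
#' @return Data frame of class `km_curve`: stratum, time, n_risk, n_event,
#'   n_censor, survival.
#' @export
km_curve <- function(cohort) {
  stopifnot(all(c("time", "event") %in% colnames(cohort)))
  if (any(cohort$time < 0)) stop("negative survival time", call. = FALSE)
  if (!"stratum" %in% colnames(cohort)) cohort$stratum <- "all"
  fit <- survival::survfit(survival::Surv(time, event) ~ stratum, data = cohort)
  sm <- summary(fit, censored = TRUE)
  strat <- if (is.null(sm$strata)) rep("all", length(sm$time)) else
    sub("^stratum=", "", as.character(sm$strata))
  out <- data.frame(stratum = strat, time = sm$time, n_risk = sm$n.risk,
                    n_event = sm$n.event, n_censor = sm$n.censor,
                    survival = sm$surv, stringsAsFactors = FALSE)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Log-rank test between strata
#'
#' Standard log-rank: at each distinct event time, observed versus expected
#' events per stratum under the hypergeometric null, chi-square with
#' (strata - 1) degrees of freedom. Delegates to [survival::survdiff()].
#'
#' @param cohort Data frame with columns `time`, `event`, `stratum`.
#' @return List: `chisq`, `df`, `p`.
#' @export
logrank_test <- function(cohort) {
  stopifnot(all(c("time", "event", "stratum") %in% colnames(cohort)))
  if (length(unique(cohort$stratum)) < 2) stop("need >= 2 strata", call. = FALSE)
  if (sum(cohort$event) == 0) stop("no events: log-rank test undefined", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ stratum, data = cohort)
  df <- length(sd$n) - 1
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}
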