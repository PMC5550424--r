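#' Read a probes-by-samples expression matrix from TSV
#'
#' Expects a header row of sample ids with the first column holding feature
#' ids. Missing or non-numeric cells are rejected (all downstream statistics
#' assume complete matrices), as are duplicate feature or sample ids.
#'
#' @param path TSV file path.
#' @param value_kind Either `"log2"` (intensities) or `"counts"`.
#' @return Numeric matrix (features x samples) with a `value_kind` attribute.
#' @export
read_matrix <- function(path, value_kind = c("log2", "counts")) {
  value_kind <- match.arg(value_kind)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("matrix file needs an id column and >= 1 sample column", call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "), call. = FALSE)
  }
  body <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric or missing value at row %d (feature '%s'), column '%s'",
                 bad[1, 1], ids[bad[1, 1]], samples[bad[1, 2]]), call. = FALSE)
  }
  dimnames(num) <- list(ids, samples)
  attr(num, "value_kind") <- value_kind
  num
}

#' Quantile-normalize a log2 expression matrix
#'
#' Forces every column to the same distribution: the per-rank mean of the
#' input columns' sorted values. Ties within a column receive the mean of the
#' tied ranks' reference values. Delegates to [limma::normalizeQuantiles()].
#'
#' @param x Numeric matrix, features x samples.
#' @return Matrix of the same dimensions.
#' @export
quantile_normalize <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (ncol(x) < 2) {
    warning("single sample: quantile normalization is the identity")
    return(x)
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Batch-adjust a matrix with parametric empirical-Bayes location-scale shrinkage
#'
#' Wraps the parametric ComBat algorithm ([sva::ComBat()]): features are
#' standardized, per-batch location and scale parameters are estimated and
#' shrunk towards normal / inverse-gamma priors, then back-transformed so the
#' per-feature grand mean and pooled variance are preserved. Biological group
#' labels, when supplied, are protected as model covariates (default on).
#'
#' @param x Numeric matrix, features x samples.
#' @param batch Character/factor batch label per sample.
#' @param group Optional biological group label per sample to protect.
#' @param protect_group Include `group` as a covariate (default TRUE).
#' @return Adjusted matrix of the same dimensions. A single batch returns the
#'   input unchanged; a batch with one sample is an error; a group confined
#'   entirely to one batch triggers a warning and the covariates are dropped.
#' @export
combat_adjust <- function(x, batch, group = NULL, protect_group = TRUE) {
  stopifnot(is.matrix(x), length(batch) == ncol(x))
  batch <- as.character(batch)
  if (length(unique(batch)) < 2) return(x)
  sizes <- table(batch)
  if (any(sizes < 2)) {
    stop("batch(es) with a single sample: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  mod <- NULL
  if (!is.null(group) && protect_group) {
    tab <- table(as.character(group), batch)
    confounded <- rownames(tab)[rowSums(tab > 0) == 1]
    if (length(confounded) > 0 && length(unique(group)) > 1) {
      warning("group(s) confined to a single batch (",
              paste(confounded, collapse = ", "),
              "); proceeding without covariate protection")
    } else if (length(unique(group)) > 1) {
      mod <- stats::model.matrix(~factor(group))
    }
  }
  out <- sva::ComBat(dat = x, batch = batch, mod = mod,
                     par.prior = TRUE, prior.plots = FALSE)
  dimnames(out) <- dimnames(x)
  out
}

#' Collapse probes to genes by the most variable probe
#'
#' For genes measured by several probes, the probe with maximal variance
#' across samples is kept verbatim; ties go to the lexicographically smallest
#' probe id. Probes without an annotation are dropped (count reported).
#'
#' @param x Numeric matrix, probes x samples.
#' @param annotation Data frame with columns `probe` and `gene`.
#' @return Matrix with one row per gene (rownames = gene symbols) and a
#'   `probe` attribute naming the retained probe per gene.
#' @export
collapse_to_genes <- function(x, annotation) {
  stopifnot(is.matrix(x), all(c("probe", "gene") %in% colnames(annotation)))
  ann <- annotation[!is.na(annotation$gene) & annotation$gene != "", , drop = FALSE]
  ann <- ann[ann$probe %in% rownames(x), , drop = FALSE]
  dropped <- nrow(x) - length(unique(ann$probe))
  if (dropped > 0) message(dropped, " unannotated probe(s) dropped")
  v <- row_vars(x[ann$probe, , drop = FALSE])
  ord <- order(ann$gene, -v, ann$probe)
  keep <- ann[ord, ][!duplicated(ann$gene[ord]), , drop = FALSE]
  out <- x[keep$probe, , drop = FALSE]
  rownames(out) <- keep$gene
  attr(out, "probe") <- stats::setNames(keep$probe, keep$gene)
  out
}

row_vars <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

#' Fit a Gaussian background model to the low end of a matrix
#'
#' Probes are ranked by their mean intensity and the lowest `low_fraction`
#' of probes is taken; the background mean `mu0` is the mode of a Gaussian
#' kernel-density fit (Silverman bandwidth) to those probes' intensity values
#' (pooled over samples, so the model lives on the same scale the expression
#' call compares against), and `sigma0` is the mirrored half-sample s.d. of
#' values at or below the mode, which resists contamination by the expressed
#' component.
#'
#' @param x Numeric matrix with >= 100 features.
#' @param low_fraction Fraction of lowest-mean features used (default 0.15).
#' @param k_sd Multiplier stored for the expression threshold (default 3).
#' @return List of class `background_model`: `mu0`, `sigma0`, `low_fraction`,
#'   `k_sd`, `threshold = mu0 + k_sd * sigma0`.
#' @export
fit_background <- function(x, low_fraction = 0.15, k_sd = 3) {
  stopifnot(is.matrix(x))
  if (nrow(x) < 100) stop("need >= 100 features for a stable background fit", call. = FALSE)
  stopifnot(low_fraction > 0, low_fraction <= 1)
  m <- rowMeans(x)
  cutoff <- stats::quantile(m, low_fraction, names = FALSE)
  sub <- as.vector(x[m <= cutoff, , drop = FALSE])
  if (stats::var(sub) == 0) {
    warning("degenerate background subset (zero variance); sigma0 = 0")
    mu0 <- sub[[1]]
    sigma0 <- 0
  } else {
    d <- stats::density(sub, bw = "nrd0")
    mu0 <- d$x[which.max(d$y)]
    below <- sub[sub <= mu0]
    sigma0 <- if (length(below) == 0) 0 else sqrt(mean((below - mu0)^2))
    if (sigma0 == 0) warning("degenerate lower half-sample; sigma0 = 0")
  }
  structure(list(mu0 = mu0, sigma0 = sigma0, low_fraction = low_fraction,
                 k_sd = k_sd, threshold = mu0 + k_sd * sigma0),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("Gaussian background model: mu0 = %.3f, sigma0 = %.3f (lowest %.0f%% of features)\n",
              x$mu0, x$sigma0, 100 * x$low_fraction))
  cat(sprintf("expression threshold mu0 + %g sd = %.3f\n", x$k_sd, x$threshold))
  invisible(x)
}

#' Call expressed features against a background model
#'
#' A feature is expressed iff its signal exceeds `mu0 + k_sd * sigma0` in
#' strictly more than `min_arrays` samples.
#'
#' @param x Numeric matrix, features x samples.
#' @param bg A [fit_background()] model.
#' @param k_sd Threshold multiplier (default 3).
#' @param min_arrays Minimum exceedance count, exclusive (default 4: a
#'   feature needs more than four arrays above threshold).
#' @return Named logical vector, one entry per feature.
#' @export
call_expressed <- function(x, bg, k_sd = 3, min_arrays = 4) {
  stopifnot(is.matrix(x), inherits(bg, "background_model"))
  if (min_arrays >= ncol(x)) {
    warning("min_arrays >= number of samples: no feature can be called expressed")
  }
  thr <- bg$mu0 + k_sd * bg$sigma0
  rowSums(x > thr) > min_arrays
}

#' Correlation-of-correlations concordance between two platforms
#'
#' For each platform, Pearson correlations of all unordered sample pairs are
#' computed; the coefficient is the Pearson correlation between the two
#' pair-correlation vectors. Features may differ between platforms; the
#' sample sets must agree.
#'
#' @param a,b Numeric matrices (features x samples) over the same samples.
#' @return The concordance coefficient (scalar).
#' @export
correlation_of_correlations <- function(a, b) {
  stopifnot(is.matrix(a), is.matrix(b))
  if (ncol(a) < 3) stop("need >= 3 samples", call. = FALSE)
  if (!is.null(colnames(a)) && !is.null(colnames(b))) {
    if (!setequal(colnames(a), colnames(b))) stop("sample sets differ", call. = FALSE)
    b <- b[, colnames(a), drop = FALSE]
  } else if (ncol(a) != ncol(b)) {
    stop("sample sets differ", call. = FALSE)
  }
  ra <- stats::cor(a)
  rb <- stats::cor(b)
  ut <- upper.tri(ra)
  stats::cor(ra[ut], rb[ut])
}
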