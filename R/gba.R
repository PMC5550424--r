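#' Read a gene-set collection from a GMT file
#'
#' Tab-separated lines: set name, description, member genes. Members are
#' de-duplicated within each set.
#'
#' @param path GMT file.
#' @return Named list of member-gene character vectors; descriptions are kept
#'   in the `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(structure(list(), description = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("GMT parse error at line ", which(nf < 3)[1],
         ": fewer than 3 tab-separated fields", call. = FALSE)
  }
  nms <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nms
  structure(sets, description = stats::setNames(
    vapply(fields, `[`, character(1), 2), nms))
}

#' Filter gene sets by effective size within a universe
#'
#' Memberships are intersected with the universe first; sets smaller than
#' `min_size` or larger than `max_size` genes are then removed (bounds
#' inclusive: sizes of exactly 15 and 300 are kept under the defaults).
#'
#' @param collection Named list of member vectors.
#' @param universe Character vector of genes present in the matrix.
#' @param min_size,max_size Inclusive effective-size bounds (defaults 15/300).
#' @return Filtered collection with members restricted to the universe.
#' @export
filter_genesets <- function(collection, universe, min_size = 15, max_size = 300) {
  trimmed <- lapply(collection, function(m) intersect(m, universe))
  sz <- lengths(trimmed)
  trimmed[sz >= min_size & sz <= max_size]
}

#' Correlation-ranked gene list for a query ncRNA
#'
#' Pearson correlation of every coding gene against the query profile; the
#' values form the ranked list whose mean and (n-1) s.d. parameterize the
#' PAGE null. Constant coding genes get r = 0 and are flagged rather than
#' removed, preserving a fixed universe across queries.
#'
#' @param query Numeric vector (the ncRNA profile across samples).
#' @param coding Numeric matrix, coding genes x samples (same sample order).
#' @return List of class `ranked_list`: `r` (named), `mu`, `sigma`,
#'   `flagged` (constant genes).
#' @export
correlation_rank <- function(query, coding) {
  stopifnot(is.matrix(coding), length(query) == ncol(coding))
  if (length(query) < 3) stop("need >= 3 samples", call. = FALSE)
  if (stats::var(query) == 0) stop("constant query profile: correlation undefined", call. = FALSE)
  suppressWarnings(r <- as.vector(stats::cor(t(coding), query)))
  names(r) <- rownames(coding)
  flagged <- names(r)[is.na(r)]
  r[is.na(r)] <- 0
  structure(list(r = r, mu = mean(r), sigma = stats::sd(r), flagged = flagged),
            class = "ranked_list")
}

#' Parametric gene-set enrichment (PAGE) z-test on a ranked list
#'
#' With `Sm` the mean list value over the set's `m` members (after universe
#' intersection) and `mu`, `sigma` the list mean and s.d., the statistic is
#' `Z = (Sm - mu) * sqrt(m) / sigma`, referred to the standard normal
#' (two-sided p). The normal reference is what makes PAGE fast relative to
#' permutation GSEA.
#'
#' @param ranked A [correlation_rank()] result (or list with `r`, `mu`,
#'   `sigma`).
#' @param gene_set Character vector of member genes.
#' @return Named numeric vector: m, Sm, Z, p.
#' @export
page_test <- function(ranked, gene_set) {
  members <- intersect(gene_set, names(ranked$r))
  m <- length(members)
  if (m < 1) stop("no gene-set member in the universe", call. = FALSE)
  if (ranked$sigma == 0) stop("degenerate ranked list (sigma = 0)", call. = FALSE)
  sm <- mean(ranked$r[members])
  z <- (sm - ranked$mu) * sqrt(m) / ranked$sigma
  c(m = m, Sm = sm, Z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Guilt-by-association table for a panel of query ncRNAs
#'
#' For each query: correlation-ranked list against the coding matrix, PAGE
#' z-test per gene set, then Benjamini-Hochberg FDR across sets. The FDR
#' family is per query by default (associations are reported per ncRNA); a
#' global family over all (query, set) pairs is available.
#'
#' @param queries Numeric matrix of query profiles (queries x samples), or a
#'   character vector of row names to take from `coding_plus` — see
#'   `query_matrix`.
#' @param coding Numeric matrix, coding genes x samples.
#' @param collection Gene-set collection (pre-filtered with
#'   [filter_genesets()]).
#' @param fdr_max Significance threshold on the FDR (default 0.01).
#' @param fdr_family `"per_query"` (default) or `"global"`.
#' @return Data frame: query, set, m, Sm, Z, p, fdr, significant.
#' @export
associate_all <- function(queries, coding, collection, fdr_max = 0.01,
                          fdr_family = c("per_query", "global")) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(is.matrix(coding))
  if (is.null(dim(queries))) queries <- matrix(queries, nrow = 1,
                                               dimnames = list("query", NULL))
  if (length(collection) == 0) {
    return(data.frame(query = character(0), set = character(0), m = integer(0),
                      Sm = numeric(0), Z = numeric(0), p = numeric(0),
                      fdr = numeric(0), significant = logical(0)))
  }
  rows <- list()
  for (q in rownames(queries)) {
    ranked <- correlation_rank(queries[q, ], coding)
    res <- t(vapply(collection, function(gs) page_test(ranked, gs), numeric(4)))
    df <- data.frame(query = q, set = rownames(res), m = as.integer(res[, "m"]),
                     Sm = res[, "Sm"], Z = res[, "Z"], p = res[, "p"],
                     stringsAsFactors = FALSE)
    if (fdr_family == "per_query") df$fdr <- bh_adjust(df$p)
    rows[[q]] <- df
  }
  out <- do.call(rbind, rows)
  if (fdr_family == "global") out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr < fdr_max
  rownames(out) <- NULL
  out
}

#' Enrichment-map edge table between significant gene sets
#'
#' Nodes are the gene sets significant for one query at the stated nominal-p
#' and FDR thresholds; edges connect set pairs whose overlap coefficient
#' `|A n B| / min(|A|, |B|)` exceeds `edge_min`. Edge sign is the product of
#' the two sets' association directions (sign of Z).
#'
#' @param assoc Association table from [associate_all()].
#' @param collection Gene-set collection (members define overlaps).
#' @param query Query ncRNA to export.
#' @param p_max Nominal-p node threshold (default 0.001).
#' @param fdr_max FDR node threshold (default 0.05).
#' @param edge_min Minimum overlap coefficient for an edge (default 0.25).
#' @return Data frame: source, target, similarity, sign.
#' @export
geneset_similarity <- function(assoc, collection, query, p_max = 0.001,
                               fdr_max = 0.05, edge_min = 0.25) {
  a <- assoc[assoc$query == query & assoc$p < p_max & assoc$fdr < fdr_max, ,
             drop = FALSE]
  nodes <- a$set
  sgn <- stats::setNames(sign(a$Z), a$set)
  edges <- list()
  if (length(nodes) >= 2) {
    for (i in seq_along(nodes)) {
      for (j in seq_along(nodes)) {
        if (j <= i) next
        A <- collection[[nodes[i]]]
        B <- collection[[nodes[j]]]
        oc <- length(intersect(A, B)) / min(length(A), length(B))
        if (oc > edge_min) {
          edges[[length(edges) + 1L]] <- data.frame(
            source = nodes[i], target = nodes[j], similarity = oc,
            sign = unname(sgn[nodes[i]] * sgn[nodes[j]]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(edges) == 0) {
    return(data.frame(source = character(0), target = character(0),
                      similarity = numeric(0), sign = numeric(0)))
  }
  do.call(rbind, edges)
}

#' Overlap coefficient between two sets
#'
#' `|A n B| / min(|A|, |B|)`.
#'
#' @param a,b Character vectors.
#' @return Scalar in \[0, 1\].
#' @export
overlap_coefficient <- function(a, b) {
  length(intersect(a, b)) / min(length(unique(a)), length(unique(b)))
}
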