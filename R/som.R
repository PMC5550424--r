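#' Train a batch self-organizing map over genes
#'
#' Every gene is assigned to a representative metagene (the prototype of one
#' grid unit); units with similar profiles sit close on the grid, so
#' co-expressed genes form contiguous regions. Training is batch mode for
#' determinism: per epoch, each gene is assigned to its best-matching unit
#' (nearest prototype by Euclidean distance) and every prototype is replaced
#' by the Gaussian-neighborhood-weighted mean of the assigned genes. The
#' neighborhood radius decays linearly from `max(rows, cols)/2` to 1 over the
#' epochs. Genes are centered and variance-scaled per gene before training;
#' zero-variance genes are centered only.
#'
#' @param x Numeric matrix, genes x samples.
#' @param rows,cols Grid dimensions (default 30 x 30).
#' @param epochs Number of batch epochs (>= 1).
#' @param seed Integer seed (prototype initialization); training is
#'   bit-reproducible given the seed.
#' @param scale Center/scale genes before training (default TRUE).
#' @param radius Optional explicit per-epoch neighborhood radius schedule
#'   (length `epochs`); overrides the linear decay.
#' @return List of class `som_model`: `rows`, `cols`, `grid` (unit, row, col),
#'   `prototypes` (units x samples metagene matrix), `mapping` (named integer,
#'   gene -> unit), `qe` (per-epoch quantization error, mean gene-to-BMU
#'   Euclidean distance), `radius` (per-epoch neighborhood radius), `seed`.
#' @export
train_som <- function(x, rows = 30, cols = 30, epochs = 20, seed = 1L,
                      scale = TRUE, radius = NULL) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  n_units <- rows * cols
  if (nrow(x) < n_units) {
    warning("fewer genes (", nrow(x), ") than grid units (", n_units, ")")
  }
  xs <- x
  if (scale) {
    mu <- rowMeans(x)
    sdv <- sqrt(row_vars(x))
    sdv[sdv == 0] <- 1
    xs <- (x - mu) / sdv
  }
  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))[, c("row", "col")]
  grid$unit <- seq_len(n_units)
  gd2 <- as.matrix(stats::dist(grid[, c("row", "col")]))^2  # squared grid distance

  set.seed(seed)
  init_idx <- sample.int(nrow(xs), n_units, replace = nrow(xs) < n_units)
  w <- xs[init_idx, , drop = FALSE]
  rownames(w) <- sprintf("u%04d", seq_len(n_units))

  if (is.null(radius)) {
    r_max <- max(rows, cols) / 2
    radius <- if (epochs == 1) 1 else r_max + (1 - r_max) * (seq_len(epochs) - 1) / (epochs - 1)
    radius <- pmax(radius, 1)
  } else {
    stopifnot(length(radius) == epochs, all(radius > 0))
  }
  qe <- numeric(epochs)
  x2 <- rowSums(xs^2)
  for (e in seq_len(epochs)) {
    w2 <- rowSums(w^2)
    # squared distances gene x unit via expansion
    d2 <- outer(x2, w2, "+") - 2 * tcrossprod(xs, w)
    bmu <- max.col(-d2, ties.method = "first")
    h <- exp(-gd2 / (2 * radius[e]^2))
    sums <- matrix(0, n_units, ncol(xs))
    tmp <- rowsum(xs, bmu)
    sums[as.integer(rownames(tmp)), ] <- tmp
    cnts <- tabulate(bmu, nbins = n_units)
    num <- h %*% sums
    den <- as.vector(h %*% cnts)
    w_new <- num / den
    w_new[den == 0, ] <- w[den == 0, ]
    w <- w_new
    rownames(w) <- sprintf("u%04d", seq_len(n_units))
    # quantization error on the updated prototypes
    w2 <- rowSums(w^2)
    d2 <- outer(x2, w2, "+") - 2 * tcrossprod(xs, w)
    d2[d2 < 0] <- 0
    bmu <- max.col(-d2, ties.method = "first")
    qe[e] <- mean(sqrt(d2[cbind(seq_len(nrow(xs)), bmu)]))
  }
  colnames(w) <- colnames(x)
  structure(list(rows = rows, cols = cols, grid = grid,
                 prototypes = w,
                 mapping = stats::setNames(bmu, rownames(x)),
                 qe = qe, radius = radius, epochs = epochs, seed = seed),
            class = "som_model")
}

#' Per-group expression portraits on the SOM grid
#'
#' For each group and unit: the mean prototype value over the group's samples
#' minus the grand mean over all samples (centered portrait). Portraits
#' weighted by group sizes therefore sum to zero at every unit.
#'
#' @param model A [train_som()] model.
#' @param groups Character/factor group label per sample (in the column order
#'   of the training matrix / named by sample id).
#' @return Numeric matrix, units x groups.
#' @export
group_portraits <- function(model, groups) {
  stopifnot(inherits(model, "som_model"))
  p <- model$prototypes
  if (!is.null(names(groups))) {
    if (!all(colnames(p) %in% names(groups))) {
      stop("unknown sample label(s): ",
           paste(setdiff(colnames(p), names(groups)), collapse = ", "), call. = FALSE)
    }
    groups <- groups[colnames(p)]
  }
  if (length(groups) != ncol(p)) stop("one group label per sample required", call. = FALSE)
  grand <- rowMeans(p)
  lv <- unique(as.character(groups))
  out <- vapply(lv, function(g) {
    rowMeans(p[, groups == g, drop = FALSE]) - grand
  }, numeric(nrow(p)))
  rownames(out) <- rownames(p)
  out
}

#' Detect group overexpression spots on the SOM grid
#'
#' Units whose portrait value lies strictly above the global quantile
#' threshold (computed over all groups' portraits; `quantile = 0` disables
#' thresholding) are candidates; 8-connected components of candidate units
#' within one group map form spots; spots smaller than `min_units` are
#' discarded. Member genes are the genes assigned to the spot's units.
#'
#' @param model A [train_som()] model.
#' @param portraits Matrix from [group_portraits()].
#' @param quantile Global quantile defining the threshold (default 0.98).
#' @param min_units Minimum units per spot (default 2).
#' @return List of class `spot_set`; each element has `id`, `group`, `units`
#'   (unit indices), `genes`. The `summary` attribute tabulates spots.
#' @export
detect_spots <- function(model, portraits, quantile = 0.98, min_units = 2) {
  stopifnot(inherits(model, "som_model"))
  thr <- stats::quantile(portraits, quantile, names = FALSE)
  spots <- list()
  for (g in colnames(portraits)) {
    pass <- if (quantile <= 0) seq_len(nrow(portraits)) else
      which(portraits[, g] > thr)
    if (length(pass) == 0) next
    comp <- grid_components(pass, model$rows, model$cols)
    k <- 0L
    for (units in comp) {
      if (length(units) < min_units) next
      k <- k + 1L
      genes <- names(model$mapping)[model$mapping %in% units]
      spots[[paste0(g, ".", k)]] <- list(id = paste0(g, ".", k), group = g,
                                         units = units, genes = genes)
    }
  }
  class(spots) <- "spot_set"
  spots
}

# 8-connected components among `units` (indices on a rows x cols grid laid
# out row-major: unit = (row-1)*cols + col).
grid_components <- function(units, rows, cols) {
  r <- (units - 1L) %/% cols + 1L
  cc <- (units - 1L) %% cols + 1L
  n <- length(units)
  lab <- integer(n)
  comp <- list()
  for (i in seq_len(n)) {
    if (lab[i] != 0L) next
    id <- length(comp) + 1L
    queue <- i
    lab[i] <- id
    members <- integer(0)
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      members <- c(members, units[j])
      nb <- which(lab == 0L & abs(r - r[j]) <= 1 & abs(cc - cc[j]) <= 1)
      lab[nb] <- id
      queue <- c(queue, nb)
    }
    comp[[id]] <- sort(members)
  }
  comp
}

#' Spot-metagene matrix
#'
#' Entry (sample, spot) = mean prototype value over the spot's units for that
#' sample: the metagene summary used for sample trees.
#'
#' @param model A [train_som()] model.
#' @param spots A [detect_spots()] result.
#' @return Numeric matrix, samples x spots.
#' @export
spot_metagene_matrix <- function(model, spots) {
  stopifnot(inherits(model, "som_model"), length(spots) > 0)
  out <- vapply(spots, function(sp) {
    colMeans(model$prototypes[sp$units, , drop = FALSE])
  }, numeric(ncol(model$prototypes)))
  rownames(out) <- colnames(model$prototypes)
  colnames(out) <- vapply(spots, `[[`, character(1), "id")
  out
}

#' Neighbor-joining sample tree from a metagene matrix
#'
#' Saitou-Nei neighbor joining ([ape::nj()]) on the sample-sample Euclidean
#' distance matrix. Negative branch lengths (an NJ artifact on non-additive
#' distances) are clamped to zero with the deficit transferred to the sister
#' edge, preserving path lengths through the parent node.
#'
#' @param m Numeric matrix, samples x features (e.g. spot metagenes), >= 3
#'   samples with unique row names; alternatively a precomputed
#'   [stats::dist()] object.
#' @param distance Distance metric passed to [stats::dist()] (ignored when
#'   `m` is already a distance object).
#' @return Newick string (unrooted, with branch lengths); the `phylo` object
#'   is attached as attribute `tree`.
#' @export
nj_tree <- function(m, distance = "euclidean") {
  if (inherits(m, "dist")) {
    d <- m
    labs <- attr(d, "Labels")
    if (attr(d, "Size") < 3) stop("need >= 3 samples", call. = FALSE)
    if (is.null(labs) || anyDuplicated(labs)) {
      stop("duplicate or missing sample ids", call. = FALSE)
    }
  } else {
    stopifnot(is.matrix(m))
    if (nrow(m) < 3) stop("need >= 3 samples", call. = FALSE)
    if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
      stop("duplicate or missing sample ids", call. = FALSE)
    }
    d <- stats::dist(m, method = distance)
  }
  tr <- ape::nj(d)
  tr <- clamp_negative_edges(tr)
  nwk <- ape::write.tree(tr)
  attr(nwk, "tree") <- tr
  nwk
}

# Set negative edge lengths to 0, moving the deficit onto a sister edge
# (another edge sharing the same parent node) so root-to-tip distances
# through that node are preserved where possible.
clamp_negative_edges <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0) break
    e <- neg[1]
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sisters <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sisters) > 0) {
      tr$edge.length[sisters[1]] <- tr$edge.length[sisters[1]] + deficit
    }
  }
  tr
}
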