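make_toy_model <- function(prototypes, rows, cols, mapping = NULL) {
  n_units <- rows * cols
  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows))[, c("row", "col")]
  grid$unit <- seq_len(n_units)
  if (is.null(mapping)) mapping <- stats::setNames(integer(0), character(0))
  structure(list(rows = rows, cols = cols, grid = grid,
                 prototypes = prototypes, mapping = mapping,
                 qe = NA, radius = NA, epochs = 0, seed = 0),
            class = "som_model")
}

test_that("SOM training is deterministic and maps identical genes together", {
  set.seed(3)
  x <- matrix(rnorm(120 * 8), 120, 8,
              dimnames = list(sprintf("g%03d", 1:120), paste0("s", 1:8)))
  x["g002", ] <- x["g001", ]
  m1 <- train_som(x, rows = 4, cols = 4, epochs = 10, seed = 5)
  m2 <- train_som(x, rows = 4, cols = 4, epochs = 10, seed = 5)
  expect_identical(m1, m2)
  expect_equal(m1$mapping[["g001"]], m1$mapping[["g002"]])
  expect_error(train_som(x, epochs = 0), "epochs")
})

test_that("a 1x1 grid collapses to the mean profile", {
  x <- matrix(c(1, 2, 3, 5, 6, 7), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:3)))
  m <- suppressWarnings(train_som(x, rows = 1, cols = 1, epochs = 3, seed = 1,
                                  scale = FALSE))
  expect_equal(unname(m$prototypes[1, ]), unname(colMeans(x)))
  expect_true(all(m$mapping == 1))
})

test_that("quantization error is non-increasing at fixed neighborhood radius", {
  set.seed(8)
  x <- matrix(rnorm(300 * 10), 300, 10,
              dimnames = list(sprintf("g%03d", 1:300), paste0("s", 1:10)))
  for (r in c(3, 1.5, 1)) {
    m <- train_som(x, rows = 5, cols = 5, epochs = 8, seed = 2,
                   radius = rep(r, 8))
    expect_true(all(diff(m$qe) <= 1e-8), label = paste("radius", r))
  }
  # default decaying schedule still ends better than it starts
  md <- train_som(x, rows = 5, cols = 5, epochs = 12, seed = 2)
  expect_lt(md$qe[12], md$qe[1])
})

test_that("group portraits are centered contrasts of the prototypes", {
  p <- matrix(0, 4, 4, dimnames = list(paste0("u", 1:4), c("a1", "a2", "b1", "b2")))
  p[1, ] <- c(3, 3, 1, 1)   # +c in group A on unit 1, c = 2
  p[2, ] <- c(1, 1, 3, 3)
  m <- make_toy_model(p, 2, 2)
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  port <- group_portraits(m, groups)
  expect_equal(unname(port[1, ]), c(A = 1, B = -1), ignore_attr = TRUE)
  expect_equal(unname(port[2, ]), c(-1, 1))
  # one group holding all samples: identically zero portrait
  port1 <- group_portraits(m, c(a1 = "all", a2 = "all", b1 = "all", b2 = "all"))
  expect_true(all(port1 == 0))
  # size-weighted portraits sum to the zero map
  sizes <- table(groups)[colnames(port)]
  expect_lt(max(abs(port %*% as.numeric(sizes))), 1e-12)
  expect_error(group_portraits(m, c(a1 = "A", a2 = "A", b1 = "B")), "label")
})

test_that("spot detection finds connected components above the global quantile", {
  # 6x6 grid, one group; a 3x3 block of high units
  p <- matrix(0, 36, 2, dimnames = list(sprintf("u%02d", 1:36), c("s1", "s2")))
  m <- make_toy_model(p, 6, 6,
                      mapping = stats::setNames(c(8L, 9L, 15L), c("gA", "gB", "gC")))
  port <- matrix(0, 36, 1, dimnames = list(rownames(p), "grp"))
  block <- as.vector(outer(c(2, 3, 4), (c(2, 3, 4) - 1) * 6, "+"))  # rows 2-4, cols 2-4
  port[block, 1] <- 5
  spots <- detect_spots(m, port, quantile = 0.6, min_units = 2)
  expect_length(spots, 1)
  expect_setequal(spots[[1]]$units, block)
  expect_setequal(spots[[1]]$genes, c("gA", "gB", "gC"))
  # a single high unit is dropped under min_units = 2
  port2 <- matrix(0, 36, 1, dimnames = list(rownames(p), "grp"))
  port2[14, 1] <- 5
  expect_length(detect_spots(m, port2, quantile = 0.9, min_units = 2), 0)
  # quantile 0: every unit passes and the grid forms one spot per group
  spots0 <- detect_spots(m, port, quantile = 0, min_units = 2)
  expect_length(spots0, 1)
  expect_length(spots0[[1]]$units, 36)
})

test_that("spot detection sees grid geometry, not unit labels", {
  # two diagonal-touching units are 8-connected
  p <- matrix(0, 16, 1, dimnames = list(sprintf("u%02d", 1:16), "s1"))
  m <- make_toy_model(p, 4, 4)
  port <- matrix(0, 16, 1, dimnames = list(rownames(p), "g"))
  port[c(1, 6), 1] <- 5    # (1,1) and (2,2): diagonal neighbors
  spots <- detect_spots(m, port, quantile = 0.9, min_units = 2)
  expect_length(spots, 1)
  expect_setequal(spots[[1]]$units, c(1, 6))
  port[c(1, 6), 1] <- 0
  port[c(1, 11), 1] <- 5   # (1,1) and (3,3): not adjacent
  expect_length(detect_spots(m, port, quantile = 0.9, min_units = 2), 0)
})

test_that("spot metagenes average the member prototypes", {
  p <- matrix(c(1, 2, 3,
                5, 6, 7,
                9, 10, 11,
                0, 0, 0), 4, 3, byrow = TRUE,
              dimnames = list(paste0("u", 1:4), paste0("s", 1:3)))
  m <- make_toy_model(p, 2, 2)
  spots <- list(sp1 = list(id = "g.1", group = "g", units = c(1L, 2L), genes = character(0)),
                sp2 = list(id = "g.2", group = "g", units = 3L, genes = character(0)),
                sp3 = list(id = "g.3", group = "g", units = c(1L, 2L), genes = character(0)))
  class(spots) <- "spot_set"
  sm <- spot_metagene_matrix(m, spots)
  expect_equal(unname(sm[, "g.1"]), c(3, 4, 5))        # hand-computed means
  expect_equal(unname(sm[, "g.2"]), c(9, 10, 11))      # single unit = prototype
  expect_equal(sm[, "g.1"], sm[, "g.3"], ignore_attr = TRUE)  # identical spots
})

test_that("neighbor joining recovers additive topologies and clamps negatives", {
  d <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  nwk <- nj_tree(stats::as.dist(d))
  tr <- attr(nwk, "tree")
  expect_equal(nj_split(tr), c("A", "B"))
  expect_true(all(tr$edge.length >= 0))
  # total path length A-B preserved by the additive fit
  coph <- ape::cophenetic.phylo(tr)
  expect_equal(coph["A", "B"], 2, tolerance = 1e-9)
  # 3 taxa: forced star topology with the closed-form three-point branch lengths
  d3 <- matrix(c(0, 3, 5, 3, 0, 4, 5, 4, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  nwk3 <- nj_tree(stats::as.dist(d3))
  tr3 <- attr(nwk3, "tree")
  coph3 <- ape::cophenetic.phylo(tr3)
  expect_equal(coph3["x", "y"], 3, tolerance = 1e-9)
  expect_equal(coph3["x", "z"], 5, tolerance = 1e-9)
  expect_equal(coph3["y", "z"], 4, tolerance = 1e-9)
  # duplicate sample ids are rejected
  mm <- matrix(rnorm(12), 3, 4, dimnames = list(c("a", "a", "b"), NULL))
  expect_error(nj_tree(mm), "duplicate")
})

test_that("neighbor joining is consistent on simulated additive tree metrics", {
  set.seed(19)
  ok <- 0
  for (i in 1:20) {
    tr <- ape::rtree(6, rooted = FALSE, br = function(n) runif(n, 0.5, 2))
    d <- ape::cophenetic.phylo(tr)
    nwk <- nj_tree(stats::as.dist(d))
    got <- attr(nwk, "tree")
    if (ape::dist.topo(ape::unroot(tr), ape::unroot(got)) == 0) ok <- ok + 1
  }
  expect_equal(ok, 20)
})

test_that("sample trees recover a planted two-pair lineage structure", {
  # 4 lineages as two pairs of similar lineages: fingerprints shared within
  # a pair plus pair-specific offsets
  recovered <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n_per <- 3
    groups <- rep(c("A1", "A2", "B1", "B2"), each = n_per)
    n <- length(groups)
    pair <- ifelse(groups %in% c("A1", "A2"), "A", "B")
    x <- matrix(rnorm(300 * n, 8, 0.5), 300, n,
                dimnames = list(sprintf("g%03d", 1:300), sprintf("s%02d", 1:n)))
    x[1:60, pair == "A"] <- x[1:60, pair == "A"] + 4        # pair-level block
    x[61:120, pair == "B"] <- x[61:120, pair == "B"] + 4
    for (gi in seq_along(unique(groups))) {                  # lineage blocks
      g <- unique(groups)[gi]
      rows <- 120 + (gi - 1) * 30 + 1:30
      x[rows, groups == g] <- x[rows, groups == g] + 2
    }
    som <- train_som(x, rows = 6, cols = 6, epochs = 10, seed = seed)
    port <- group_portraits(som, stats::setNames(groups, colnames(x)))
    spots <- detect_spots(som, port, quantile = 0.75, min_units = 2)
    sm <- spot_metagene_matrix(som, spots)
    centroids <- rowsum(sm, groups) / n_per
    nwk <- nj_tree(centroids)
    split <- nj_split(attr(nwk, "tree"))
    if (identical(split, c("A1", "A2")) || identical(split, c("B1", "B2"))) {
      recovered <- recovered + 1
    }
  }
  expect_gte(recovered, 9)
})
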