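test_that("read_matrix validates structure and rejects missing values", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe\ts1\ts2", "p1\t1\t2", "p2\t3\t4"), tmp)
  x <- read_matrix(tmp)
  expect_equal(dim(x), c(2, 2))
  expect_equal(unname(x["p2", "s2"]), 4)

  writeLines(c("probe\ts1\ts2", "p1\t1\t2", "p1\t3\t4"), tmp)
  expect_error(read_matrix(tmp), "p1")

  writeLines(c("probe\ts1\ts2", "p1\t1\tNA", "p2\t3\t4"), tmp)
  expect_error(read_matrix(tmp), "row 1.*column 's2'")

  writeLines(c("probe\ts1\ts2", "p1\t1\t2", "p2\tx\t4"), tmp)
  expect_error(read_matrix(tmp), "p2")
})

test_that("quantile normalization matches the per-rank-mean oracle", {
  x <- cbind(a = c(1, 3), b = c(2, 6))
  q <- quantile_normalize(x)
  expect_equal(unname(q[, "a"]), c(1.5, 4.5))
  expect_equal(unname(q[, "b"]), c(1.5, 4.5))
})

test_that("quantile normalization is idempotent and equalizes distributions", {
  set.seed(1)
  x <- matrix(rnorm(500, 8, 2), 100, 5,
              dimnames = list(sprintf("p%03d", 1:100), paste0("s", 1:5)))
  q <- quantile_normalize(x)
  for (j in 2:5) expect_equal(sort(q[, j]), sort(q[, 1]), ignore_attr = TRUE)
  expect_equal(quantile_normalize(q), q)
  # identical columns are a fixed point
  y <- matrix(rep(sort(rnorm(50)), 3), 50, 3,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:3)))
  expect_equal(quantile_normalize(y), y)
  expect_warning(z <- quantile_normalize(x[, 1, drop = FALSE]), "single sample")
  expect_equal(z, x[, 1, drop = FALSE])
})

test_that("combat adjustment removes a planted batch shift", {
  set.seed(9)
  a <- matrix(rnorm(50 * 50, 8, 1), 50, 50)
  x <- cbind(a, a + 2)  # batch 2 = shifted copy, delta = 2
  dimnames(x) <- list(sprintf("f%02d", 1:50), paste0("s", 1:100))
  batch <- rep(c("b1", "b2"), each = 50)
  xa <- suppressMessages(combat_adjust(x, batch))
  before <- rowMeans(x[, batch == "b2"]) - rowMeans(x[, batch == "b1"])
  after <- rowMeans(xa[, batch == "b2"]) - rowMeans(xa[, batch == "b1"])
  expect_lt(mean(abs(after)), 0.1 * 2)          # shift largely removed
  expect_lt(mean(abs(after)), 0.1 * mean(abs(before)))
  # per-feature grand mean preserved
  expect_lt(max(abs(rowMeans(xa) - rowMeans(x))), 0.05)
})

test_that("combat adjustment is mild when batches share a distribution", {
  set.seed(3)
  x <- matrix(rnorm(1000 * 20, 8, 1), 1000, 20,
              dimnames = list(sprintf("f%04d", 1:1000), paste0("s", 1:20)))
  batch <- rep(c("b1", "b2"), each = 10)
  xa <- suppressMessages(combat_adjust(x, batch))
  expect_lt(mean(abs(xa - x)), 0.25)
})

test_that("combat handles degenerate designs per contract", {
  x <- matrix(rnorm(40), 4, 10, dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
  expect_identical(combat_adjust(x, rep("b1", 10)), x)
  expect_error(combat_adjust(x, c(rep("b1", 9), "b2")), "single sample")
  grp <- rep(c("g1", "g2"), each = 5)
  batch <- rep(c("b1", "b2"), each = 5)   # confounded
  expect_warning(suppressMessages(combat_adjust(x, batch, group = grp)),
                 "confined to a single batch")
})

test_that("combat commutes with feature reordering", {
  set.seed(4)
  x <- matrix(rnorm(200 * 12, 8, 1), 200, 12,
              dimnames = list(sprintf("f%03d", 1:200), paste0("s", 1:12)))
  x[, 7:12] <- x[, 7:12] + 1
  batch <- rep(c("b1", "b2"), each = 6)
  perm <- sample(nrow(x))
  a <- suppressMessages(combat_adjust(x, batch))[perm, ]
  b <- suppressMessages(combat_adjust(x[perm, ], batch))
  expect_equal(a, b)
})

test_that("probe-to-gene collapse keeps the most variable probe", {
  x <- rbind(p1 = c(1, 2, 3, 4), p2 = c(0, 2, 4, 6), p3 = c(5, 5, 5, 5))
  colnames(x) <- paste0("s", 1:4)
  ann <- data.frame(probe = c("p1", "p2", "p3"), gene = c("G1", "G1", "G2"))
  out <- collapse_to_genes(x, ann)
  expect_equal(rownames(out), c("G1", "G2"))
  expect_equal(unname(attr(out, "probe")["G1"]), "p2")   # var 20/3 beats 5/3
  expect_equal(unname(out["G2", ]), c(5, 5, 5, 5))       # single probe verbatim
  # tie broken by smaller probe id
  x2 <- rbind(pa = c(1, 2), pz = c(2, 1), extra = c(0, 0))
  colnames(x2) <- c("s1", "s2")
  ann2 <- data.frame(probe = c("pz", "pa"), gene = c("G", "G"))
  out2 <- suppressMessages(collapse_to_genes(x2, ann2))
  expect_equal(unname(attr(out2, "probe")["G"]), "pa")
  # unannotated probes dropped with a message
  expect_message(collapse_to_genes(x2, ann2), "1 unannotated")
})

test_that("background model recovers a planted low Gaussian peak", {
  set.seed(31)
  n_feat <- 10000
  truth_expressed <- c(rep(FALSE, 1500), rep(TRUE, 8500))
  x <- matrix(0, n_feat, 10, dimnames = list(sprintf("p%05d", 1:n_feat),
                                             paste0("s", 1:10)))
  x[!truth_expressed, ] <- rnorm(1500 * 10, 6, 0.5)
  x[truth_expressed, ] <- rnorm(8500 * 10, 12, 1)
  bg <- fit_background(x)
  expect_gt(bg$mu0, 5.8); expect_lt(bg$mu0, 6.2)
  expect_gt(bg$sigma0, 0.35); expect_lt(bg$sigma0, 0.65)
  # low_fraction = 1 on a pure Gaussian: KDE mode is consistent for the mean
  y <- matrix(rnorm(5000, 6, 0.5), 5000, 1,
              dimnames = list(sprintf("p%04d", 1:5000), "s1"))
  bg1 <- fit_background(y, low_fraction = 1)
  expect_lt(abs(bg1$mu0 - 6), 0.2)
  # constant matrix degenerates cleanly
  z <- matrix(3, 200, 4, dimnames = list(sprintf("p%03d", 1:200), paste0("s", 1:4)))
  expect_warning(bgc <- fit_background(z), "zero variance")
  expect_equal(bgc$mu0, 3); expect_equal(bgc$sigma0, 0)
  expect_error(fit_background(z[1:50, ]), ">= 100 features")
})

test_that("expressed calling uses a strict more-than-min_arrays rule", {
  bg <- structure(list(mu0 = 6, sigma0 = 0.5, low_fraction = 0.15,
                       k_sd = 3, threshold = 7.5), class = "background_model")
  x <- matrix(6, 3, 20, dimnames = list(c("at4", "at5", "never"), paste0("s", 1:20)))
  x["at4", 1:4] <- 12
  x["at5", 1:5] <- 12
  ex <- call_expressed(x, bg)
  expect_false(ex[["at4"]])   # exactly 4 arrays is not "more than four"
  expect_true(ex[["at5"]])
  expect_false(ex[["never"]])
  expect_warning(allf <- call_expressed(x, bg, min_arrays = 20), "min_arrays")
  expect_false(any(allf))
})

test_that("expressed calling is monotone in k_sd and accurate on a planted mixture", {
  set.seed(13)
  n <- 20
  truth_expressed <- c(rep(FALSE, 1500), rep(TRUE, 8500))
  x <- matrix(0, 10000, n, dimnames = list(sprintf("p%05d", 1:10000),
                                           paste0("s", 1:n)))
  x[!truth_expressed, ] <- rnorm(1500 * n, 6, 0.5)
  x[truth_expressed, ] <- rnorm(8500 * n, 12, 1)
  bg <- fit_background(x)
  ex <- call_expressed(x, bg)
  expect_gte(mean(ex[truth_expressed]), 0.95)
  expect_lte(mean(ex[!truth_expressed]), 0.01)
  for (k in c(1, 2, 4, 6)) {
    lo <- call_expressed(x, bg, k_sd = k)
    hi <- call_expressed(x, bg, k_sd = k + 1)
    expect_true(all(lo | !hi))   # raising k_sd never adds expressed features
  }
})

test_that("correlation of correlations measures cross-platform concordance", {
  set.seed(6)
  a <- matrix(rnorm(200 * 8, 8, 1), 200, 8,
              dimnames = list(sprintf("p%03d", 1:200), paste0("s", 1:8)))
  expect_equal(correlation_of_correlations(a, a), 1.0)
  expect_equal(correlation_of_correlations(a, a[sample(nrow(a)), ]), 1.0)
  expect_error(correlation_of_correlations(a[, 1:2], a[, 1:2]), ">= 3 samples")
  # independent platforms: near-zero coefficient on average
  cc <- replicate(50, {
    m1 <- matrix(rnorm(100 * 10), 100, 10, dimnames = list(NULL, paste0("s", 1:10)))
    m2 <- matrix(rnorm(100 * 10), 100, 10, dimnames = list(NULL, paste0("s", 1:10)))
    correlation_of_correlations(m1, m2)
  })
  expect_lt(abs(mean(cc)), 0.1)
})
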