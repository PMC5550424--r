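# Independent oracles used across tests. These are deliberately naive
# implementations kept separate from the package code paths they check.

# Brute-force Hamming scan: all (transcript, offset, mismatches) occurrences
# of `probe` in each sequence of `seqs` with at most max_mismatch
# substitutions. Offsets 0-based.
brute_force_scan <- function(probe, seqs, max_mismatch = 1) {
  pl <- nchar(probe)
  pchars <- strsplit(probe, "")[[1]]
  rows <- list()
  for (tid in names(seqs)) {
    tchars <- strsplit(seqs[[tid]], "")[[1]]
    tl <- length(tchars)
    if (tl < pl) next
    for (s in seq_len(tl - pl + 1)) {
      mm <- sum(tchars[s:(s + pl - 1)] != pchars)
      if (mm <= max_mismatch) {
        rows[[length(rows) + 1L]] <- data.frame(
          transcript = tid, offset = s - 1L, mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(transcript = character(0), offset = integer(0),
                      mismatches = integer(0)))
  }
  do.call(rbind, rows)
}

# First-principles log-rank statistic for two groups: hypergeometric moments
# at each distinct event time.
logrank_oracle <- function(time, event, group) {
  g1 <- unique(group)[1]
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (tt in times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Least-squares branch-length fit of a 4-taxon unrooted topology to a
# distance matrix; returns the residual sum of squares. Topology given as a
# split, e.g. c("A","B") meaning AB|CD.
ls_topology_sse <- function(d, pair) {
  taxa <- rownames(d)
  other <- setdiff(taxa, pair)
  # branch order: a (pair[1]), b (pair[2]), c (other[1]), dd (other[2]), e (internal)
  combs <- t(combn(taxa, 2))
  design <- matrix(0, nrow(combs), 5,
                   dimnames = list(NULL, c(pair, other, "internal")))
  y <- numeric(nrow(combs))
  for (i in seq_len(nrow(combs))) {
    u <- combs[i, 1]; v <- combs[i, 2]
    design[i, u] <- 1
    design[i, v] <- 1
    same_side <- (u %in% pair) == (v %in% pair)
    if (!same_side) design[i, "internal"] <- 1
    y[i] <- d[u, v]
  }
  fit <- stats::lm.fit(design, y)
  sum(fit$residuals^2)
}

# Best 4-taxon topology by brute-force least squares over the 3 splits;
# returns the winning split as a sorted character pair.
ls_best_split <- function(d) {
  taxa <- sort(rownames(d))
  splits <- list(c(taxa[1], taxa[2]), c(taxa[1], taxa[3]), c(taxa[1], taxa[4]))
  sse <- vapply(splits, function(p) ls_topology_sse(d, p), numeric(1))
  sort(splits[[which.min(sse)]])
}

# Split containing taxon 1 read off an unrooted 4-taxon phylo tree.
nj_split <- function(tree) {
  tree <- ape::unroot(tree)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  for (p in parts) {
    if (length(p) == 2) {
      pair <- labs[p]
      if (labs[1] %in% pair) return(sort(pair))
      return(sort(setdiff(labs, pair)))
    }
  }
  # star / unresolved
  NA_character_
}

# Mean fingerprint precision/recall of a fingerprint call table against a
# synthetic truth table.
fingerprint_accuracy <- function(called, truth) {
  is_fp <- grepl("^fingerprint:", truth$role)
  key_true <- paste(truth$probe[is_fp], sub("fingerprint:", "", truth$role[is_fp]))
  hit <- called[called$call == "fingerprint", ]
  key_called <- paste(hit$feature, hit$group)
  tp <- sum(key_called %in% key_true)
  list(precision = if (nrow(hit) == 0) NA_real_ else tp / nrow(hit),
       recall = tp / length(key_true))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}
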