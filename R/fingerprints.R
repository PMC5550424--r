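#' Empirical-Bayes moderated two-sample t-statistics
#'
#' Per feature, the pooled two-group residual variance `s^2` (df `dg`) is
#' shrunk towards a global prior: the prior degrees of freedom `d0` and prior
#' variance `s0^2` are estimated by matching the first two moments of
#' `log s^2` to a scaled-F distribution (closed form via digamma/trigamma
#' inversion), giving the posterior variance
#' `s_tilde^2 = (d0 s0^2 + dg s^2) / (d0 + dg)`. The moderated statistic
#' `t = dmean / (s_tilde sqrt(1/ng + 1/nh))` follows a t-distribution with
#' `d0 + dg` degrees of freedom; p-values are Benjamini-Hochberg adjusted
#' over features.
#'
#' With `pool = "global"` the residual variance is pooled within every group
#' of the design (df `N - K`) rather than the two contrasted groups only.
#'
#' @param x Numeric matrix, features x samples.
#' @param groups Group label per sample.
#' @param g,h The two groups to contrast (log2-FC is mean(g) - mean(h)).
#' @param pool `"pairwise"` (default) or `"global"` residual pooling.
#' @param prior_df Optional fixed prior degrees of freedom `d0`; `0` turns
#'   shrinkage off (ordinary t), `Inf` shrinks every variance to `s0^2`.
#'   Default `NULL` estimates `d0` from the data.
#' @return Data frame: feature, lfc, s2, t, df_total, p, adj_p; attributes
#'   `d0` and `s02` carry the prior.
#' @export
moderated_t <- function(x, groups, g, h, pool = c("pairwise", "global"),
                        prior_df = NULL) {
  pool <- match.arg(pool)
  stopifnot(is.matrix(x), length(groups) == ncol(x))
  groups <- as.character(groups)
  ig <- which(groups == g)
  ih <- which(groups == h)
  if (length(ig) < 2 || length(ih) < 2) {
    stop("both groups need >= 2 samples", call. = FALSE)
  }
  ng <- length(ig); nh <- length(ih)
  mg <- rowMeans(x[, ig, drop = FALSE])
  mh <- rowMeans(x[, ih, drop = FALSE])
  lfc <- mg - mh
  if (pool == "pairwise") {
    vg <- row_vars(x[, ig, drop = FALSE])
    vh <- row_vars(x[, ih, drop = FALSE])
    dg <- ng + nh - 2
    s2 <- ((ng - 1) * vg + (nh - 1) * vh) / dg
  } else {
    lv <- unique(groups)
    ss <- 0
    for (gr in lv) {
      idx <- which(groups == gr)
      if (length(idx) < 2) next
      ss <- ss + (length(idx) - 1) * row_vars(x[, idx, drop = FALSE])
    }
    dg <- sum(vapply(lv, function(gr) max(sum(groups == gr) - 1, 0), numeric(1)))
    s2 <- ss / dg
  }
  prior <- fit_f_prior(s2, dg)
  d0 <- if (is.null(prior_df)) prior$d0 else prior_df
  s02 <- prior$s02
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + dg * s2) / (d0 + dg)
  se <- sqrt(s2_post * (1 / ng + 1 / nh))
  t <- ifelse(se == 0, 0, lfc / se)
  df_total <- d0 + dg
  p <- 2 * stats::pt(-abs(t), df = df_total)
  p[se == 0 & lfc == 0] <- 1
  out <- data.frame(feature = rownames(x), lfc = lfc, s2 = s2, t = t,
                    df_total = df_total, p = p, adj_p = bh_adjust(p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

# Moment-matching fit of the scaled-F prior for sample variances s2 with
# df residual degrees of freedom: returns prior df d0 and prior variance s02.
# evar <= 0 means no excess dispersion in log s2 beyond chi-square sampling
# noise; the prior df is then infinite and every variance shrinks to s02.
fit_f_prior <- function(s2, df) {
  z <- log(pmax(s2, 1e-300))
  e <- z - digamma(df / 2) + log(df / 2)
  n <- length(z)
  evar <- stats::var(e) * (n - 1) / n - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s02 = exp(mean(e))))
  }
  half_d0 <- trigamma_inverse(evar)
  if (!is.finite(half_d0)) return(list(d0 = Inf, s02 = exp(mean(e))))
  d0 <- 2 * half_d0
  s02 <- exp(mean(e) + digamma(half_d0) - log(half_d0))
  list(d0 = d0, s02 = s02)
}

# Solve trigamma(y) = x for y > 0 by Newton iteration on 1/trigamma,
# which is nearly linear in y (convergence tolerance 1e-8).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values with monotone enforcement, capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' All one-vs-each-lineage moderated-t contrasts
#'
#' Computes [moderated_t()] for every ordered pair of groups (reusing each
#' unordered pair: swapping direction negates log2-FC and t and leaves p
#' unchanged).
#'
#' @inheritParams moderated_t
#' @return Long data frame: feature, group, other, lfc, t, p, adj_p.
#' @export
fingerprint_contrasts <- function(x, groups, pool = c("pairwise", "global")) {
  pool <- match.arg(pool)
  lv <- unique(as.character(groups))
  out <- list()
  for (i in seq_along(lv)) {
    for (j in seq_along(lv)) {
      if (j <= i) next
      ct <- moderated_t(x, groups, lv[i], lv[j], pool = pool)
      out[[length(out) + 1L]] <- data.frame(
        feature = ct$feature, group = lv[i], other = lv[j],
        lfc = ct$lfc, t = ct$t, p = ct$p, adj_p = ct$adj_p,
        stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        feature = ct$feature, group = lv[j], other = lv[i],
        lfc = -ct$lfc, t = -ct$t, p = ct$p, adj_p = ct$adj_p,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call lineage fingerprint and anti-fingerprint features
#'
#' A feature is a fingerprint of group *g* iff, against every other group,
#' the moderated-t contrast has adjusted p < `adj_p_max` and log2-FC >
#' `lfc_min`, AND the feature's SOM unit lies inside one of group *g*'s
#' overexpression spots. Anti-fingerprints mirror the thresholds with
#' reversed sign (log2-FC < -`lfc_min` in every contrast); no spot criterion
#' is applied to them since no underexpression spots are defined.
#'
#' Spot membership is implemented as unit membership of the feature in the
#' group's spot — a per-feature property; no per-gene enrichment test is
#' performed.
#'
#' @param contrasts Long contrast table from [fingerprint_contrasts()],
#'   covering every ordered group pair.
#' @param mapping Named integer gene -> SOM unit (from a `som_model`), or a
#'   `som_model`.
#' @param spots A [detect_spots()] result.
#' @param adj_p_max Adjusted-p threshold, exclusive (default 0.05).
#' @param lfc_min log2-FC threshold, exclusive (default 1).
#' @return Data frame: feature, group, min_lfc, max_adj_p, in_spot, call
#'   (fingerprint / anti-fingerprint / none).
#' @export
call_fingerprints <- function(contrasts, mapping, spots,
                              adj_p_max = 0.05, lfc_min = 1) {
  if (inherits(mapping, "som_model")) mapping <- mapping$mapping
  lv <- unique(contrasts$group)
  need <- expand.grid(group = lv, other = lv, stringsAsFactors = FALSE)
  need <- need[need$group != need$other, ]
  have <- unique(contrasts[, c("group", "other")])
  miss <- setdiff(paste(need$group, need$other, sep = " vs "),
                  paste(have$group, have$other, sep = " vs "))
  if (length(miss) > 0) {
    stop("missing contrast(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  spot_units <- lapply(stats::setNames(nm = lv), function(g) {
    u <- unlist(lapply(spots, function(sp) if (sp$group == g) sp$units))
    unique(u)
  })
  key <- interaction(contrasts$feature, contrasts$group, drop = TRUE)
  min_lfc <- tapply(contrasts$lfc, key, min)
  max_adj <- tapply(contrasts$adj_p, key, max)
  max_lfc <- tapply(contrasts$lfc, key, max)
  # feature ids may themselves contain "."; rebuild names from the table
  first <- !duplicated(key)
  feat <- contrasts$feature[first][match(names(min_lfc), as.character(key[first]))]
  grp <- contrasts$group[first][match(names(min_lfc), as.character(key[first]))]
  in_spot <- mapply(function(f, g) {
    u <- mapping[f]
    !is.na(u) && u %in% spot_units[[g]]
  }, feat, grp)
  is_fp <- max_adj < adj_p_max & min_lfc > lfc_min & in_spot
  is_anti <- max_adj < adj_p_max & max_lfc < -lfc_min
  call <- ifelse(is_fp, "fingerprint", ifelse(is_anti, "anti-fingerprint", "none"))
  out <- data.frame(feature = feat, group = grp,
                    min_lfc = as.numeric(min_lfc), max_adj_p = as.numeric(max_adj),
                    in_spot = as.logical(in_spot), call = call,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$group, out$feature), ]
}
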