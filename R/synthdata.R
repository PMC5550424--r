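#' Configuration for a synthetic lineage expression cohort
#'
#' Describes a probes-by-samples log2-intensity cohort with the statistical
#' structure a lineage atlas assumes: a population of pure-background probes
#' forming a low Gaussian peak, broadly expressed ("housekeeping") probes with
#' lognormal baseline intensities (Gaussian on the log2 scale), planted
#' lineage-specific fingerprint probes expressed only in one group, and
#' latent-factor co-regulated probe sets in which designated non-coding RNA
#' queries share a factor with a block of coding genes.
#'
#' Defaults emulate a blood-cell atlas: 12 lineages with three to eight
#' donors each.
#'
#' @param n_groups Number of lineage groups.
#' @param samples_per_group Integer vector of samples per group (each >= 3).
#'   Defaults to sizes between 3 and 8 recycled over `n_groups`.
#' @param n_probes Total number of probes.
#' @param frac_background Fraction of probes that are pure background noise.
#' @param background_mean,background_sd Background peak location/spread
#'   (log2-intensity units).
#' @param expressed_mean,expressed_sd Expressed baseline location/spread
#'   (log2-intensity units); baselines are Gaussian on the log2 scale.
#' @param noise_sd Within-probe residual noise s.d. (log2 units).
#' @param fingerprint_per_group Number of fingerprint probes planted per group.
#' @param effect_size Planted fingerprint effect (log2 fold-change units),
#'   the in-group minus out-group mean difference. Must be > 0 unless
#'   explicitly exploring the null (0 is allowed).
#' @param n_latent_sets Number of latent-factor co-regulation sets.
#' @param latent_set_size Coding members per latent set.
#' @param latent_loading Loading of members and query on the shared factor,
#'   in \[0, 1\]; pairwise member correlation is `latent_loading^2`.
#' @param n_decoy_sets Number of decoy gene sets (size-matched, no loading)
#'   emitted by [gen_geneset_truth()].
#' @param seed Integer seed; all generators are pure functions of the config.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_groups = 12,
                         samples_per_group = NULL,
                         n_probes = 4000,
                         frac_background = 0.30,
                         background_mean = 6, background_sd = 0.5,
                         expressed_mean = 10, expressed_sd = 1,
                         noise_sd = 0.5,
                         fingerprint_per_group = 20,
                         effect_size = 4,
                         n_latent_sets = 5,
                         latent_set_size = 30,
                         latent_loading = 0.9,
                         n_decoy_sets = 5,
                         seed = 1L) {
  if (is.null(samples_per_group)) {
    sizes <- c(3L, 3L, 3L, 4L, 4L, 5L, 5L, 6L, 6L, 7L, 8L, 8L)
    samples_per_group <- rep_len(sizes, n_groups)
  }
  cfg <- list(n_groups = as.integer(n_groups),
              samples_per_group = as.integer(samples_per_group),
              n_probes = as.integer(n_probes),
              frac_background = frac_background,
              background_mean = background_mean, background_sd = background_sd,
              expressed_mean = expressed_mean, expressed_sd = expressed_sd,
              noise_sd = noise_sd,
              fingerprint_per_group = as.integer(fingerprint_per_group),
              effect_size = effect_size,
              n_latent_sets = as.integer(n_latent_sets),
              latent_set_size = as.integer(latent_set_size),
              latent_loading = latent_loading,
              n_decoy_sets = as.integer(n_decoy_sets),
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid synth_config field '", field, "': ", msg, call. = FALSE)
  }
  chk(cfg$n_groups >= 1, "n_groups", "must be >= 1")
  chk(length(cfg$samples_per_group) == cfg$n_groups, "samples_per_group",
      "length must equal n_groups")
  chk(all(cfg$samples_per_group >= 3), "samples_per_group",
      "each group needs >= 3 samples")
  chk(cfg$n_probes >= 1, "n_probes", "must be >= 1")
  chk(cfg$frac_background >= 0 && cfg$frac_background <= 1, "frac_background",
      "must lie in [0, 1]")
  chk(cfg$effect_size >= 0, "effect_size", "must be >= 0")
  chk(cfg$background_sd >= 0, "background_sd", "must be >= 0")
  chk(cfg$fingerprint_per_group >= 0, "fingerprint_per_group", "must be >= 0")
  chk(cfg$n_latent_sets >= 0, "n_latent_sets", "must be >= 0")
  chk(cfg$latent_loading >= 0 && cfg$latent_loading <= 1, "latent_loading",
      "must lie in [0, 1]")
  n_special <- round(cfg$frac_background * cfg$n_probes) +
    cfg$n_groups * cfg$fingerprint_per_group +
    cfg$n_latent_sets * (cfg$latent_set_size + 1L)
  chk(n_special <= cfg$n_probes, "n_probes",
      "too small for the requested background/fingerprint/latent probes")
  invisible(cfg)
}

# Deterministic layout of probe roles: blocks of background, per-group
# fingerprints, latent members + one ncRNA query per set, then housekeeping.
synth_layout <- function(cfg) {
  n_bg <- round(cfg$frac_background * cfg$n_probes)
  groups <- sprintf("g%02d", seq_len(cfg$n_groups))
  role <- character(cfg$n_probes)
  biotype <- rep("coding", cfg$n_probes)
  i <- 0L
  if (n_bg > 0) {
    role[i + seq_len(n_bg)] <- "background"
    i <- i + n_bg
  }
  for (g in groups) {
    if (cfg$fingerprint_per_group > 0) {
      role[i + seq_len(cfg$fingerprint_per_group)] <- paste0("fingerprint:", g)
      i <- i + cfg$fingerprint_per_group
    }
  }
  if (cfg$n_latent_sets > 0) {
    for (s in seq_len(cfg$n_latent_sets)) {
      role[i + seq_len(cfg$latent_set_size)] <- paste0("latent:set", s)
      i <- i + cfg$latent_set_size
      role[i + 1L] <- paste0("latent:set", s)
      biotype[i + 1L] <- "ncRNA"
      i <- i + 1L
    }
  }
  if (i < cfg$n_probes) role[(i + 1L):cfg$n_probes] <- "housekeeping"
  probe <- sprintf("probe_%05d", seq_len(cfg$n_probes))
  probe[biotype == "ncRNA"] <- sprintf("query_set%d", seq_len(sum(biotype == "ncRNA")))
  samples <- unlist(lapply(seq_len(cfg$n_groups), function(k) {
    sprintf("%s_s%d", groups[k], seq_len(cfg$samples_per_group[k]))
  }))
  sample_group <- rep(groups, cfg$samples_per_group)
  list(probe = probe, role = role, biotype = biotype, groups = groups,
       samples = samples, sample_group = sample_group)
}

#' Generate a synthetic lineage expression matrix with a truth table
#'
#' Draws a probes-by-samples log2-intensity matrix under [synth_config()]:
#' background probes are `N(background_mean, background_sd^2)` in all samples;
#' fingerprint probes of group *g* sit at `background_mean + effect_size`
#' (with `background_sd` noise) in group-*g* samples and at background level
#' elsewhere, so the planted mean log2 fold-change equals `effect_size`
#' exactly; housekeeping probes get a probe-specific Gaussian log2 baseline;
#' latent-set probes follow the unit-variance factor model
#' `x = loading * f + sqrt(1 - loading^2) * eps` scaled by `expressed_sd`.
#' Deterministic given the config (seed included).
#'
#' @param config A [synth_config()].
#' @return List with `matrix` (probes x samples), `samples` (data frame:
#'   sample, group, batch), and `truth` (data frame: probe, role, gene,
#'   biotype) in which every probe and sample appears exactly once.
#' @export
gen_lineage_matrix <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  lay <- synth_layout(config)
  n <- length(lay$samples)
  set.seed(config$seed)
  x <- matrix(0, nrow = config$n_probes, ncol = n,
              dimnames = list(lay$probe, lay$samples))

  is_bg <- lay$role == "background"
  if (any(is_bg)) {
    x[is_bg, ] <- rnorm(sum(is_bg) * n, config$background_mean, config$background_sd)
  }
  is_hk <- lay$role == "housekeeping"
  if (any(is_hk)) {
    base <- rnorm(sum(is_hk), config$expressed_mean, config$expressed_sd)
    x[is_hk, ] <- base + rnorm(sum(is_hk) * n, 0, config$noise_sd)
  }
  for (g in lay$groups) {
    idx <- lay$role == paste0("fingerprint:", g)
    if (!any(idx)) next
    in_g <- lay$sample_group == g
    x[idx, ] <- rnorm(sum(idx) * n, config$background_mean, config$background_sd)
    x[idx, in_g] <- x[idx, in_g] + config$effect_size
  }
  if (config$n_latent_sets > 0) {
    lam <- config$latent_loading
    for (s in seq_len(config$n_latent_sets)) {
      idx <- lay$role == paste0("latent:set", s)
      f <- rnorm(n)
      eps <- matrix(rnorm(sum(idx) * n), nrow = sum(idx))
      z <- lam * matrix(f, nrow = sum(idx), ncol = n, byrow = TRUE) +
        sqrt(1 - lam^2) * eps
      x[idx, ] <- config$expressed_mean + config$expressed_sd * z
    }
  }
  truth <- data.frame(probe = lay$probe, role = lay$role,
                      gene = lay$probe, biotype = lay$biotype,
                      stringsAsFactors = FALSE)
  samples <- data.frame(sample = lay$samples, group = lay$sample_group,
                        batch = "b1", stringsAsFactors = FALSE)
  list(matrix = x, samples = samples, truth = truth)
}

#' Generate gene-set truth matching the latent structure of a synthetic cohort
#'
#' Emits a GMT-serializable collection in which each latent set's member
#' genes (and its designated query ncRNA, listed separately in the truth
#' table) load on the same latent factor as in [gen_lineage_matrix()] under
#' the identical config, plus size-matched decoy sets drawn from housekeeping
#' probes with no factor loading.
#'
#' @param config A [synth_config()] with `n_latent_sets >= 1`.
#' @return List with `collection` (named list of member-gene vectors),
#'   `queries` (named character: set -> query ncRNA id), and `truth`
#'   (data frame: set, type in latent/decoy, query).
#' @export
gen_geneset_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  if (config$n_latent_sets < 1) stop("n_latent_sets must be >= 1", call. = FALSE)
  lay <- synth_layout(config)
  collection <- list()
  queries <- character(0)
  for (s in seq_len(config$n_latent_sets)) {
    idx <- lay$role == paste0("latent:set", s)
    members <- lay$probe[idx & lay$biotype == "coding"]
    q <- lay$probe[idx & lay$biotype == "ncRNA"]
    nm <- sprintf("latent_set%d", s)
    collection[[nm]] <- members
    queries[nm] <- q
  }
  hk <- lay$probe[lay$role == "housekeeping"]
  set.seed(config$seed + 1000L)
  for (d in seq_len(config$n_decoy_sets)) {
    nm <- sprintf("decoy_set%d", d)
    collection[[nm]] <- sample(hk, config$latent_set_size)
  }
  truth <- data.frame(set = names(collection),
                      type = rep(c("latent", "decoy"),
                                 c(config$n_latent_sets, config$n_decoy_sets)),
                      query = c(unname(queries), rep(NA, config$n_decoy_sets)),
                      stringsAsFactors = FALSE)
  list(collection = collection, queries = queries, truth = truth)
}

#' Configuration for a synthetic AML survival cohort
#'
#' @param n_patients Number of patients (>= 10). Default 171 emulates a
#'   consortium-scale AML cohort.
#' @param baseline_hazard Events per time unit for a patient with score 0.
#' @param hazard_coefficient Log-hazard per unit stemness score (beta).
#' @param censor_time_max Upper bound of the uniform censoring time.
#' @param signature_size Number of signature genes driven by the score.
#' @param n_noise_genes Additional genes unrelated to the score.
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 171,
                          baseline_hazard = 0.1,
                          hazard_coefficient = 1,
                          censor_time_max = 20,
                          signature_size = 17,
                          n_noise_genes = 200,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              baseline_hazard = baseline_hazard,
              hazard_coefficient = hazard_coefficient,
              censor_time_max = censor_time_max,
              signature_size = as.integer(signature_size),
              n_noise_genes = as.integer(n_noise_genes),
              seed = as.integer(seed))
  if (cfg$n_patients < 10) stop("invalid cohort_config field 'n_patients': must be >= 10", call. = FALSE)
  if (cfg$baseline_hazard <= 0) stop("invalid cohort_config field 'baseline_hazard': must be > 0", call. = FALSE)
  if (cfg$censor_time_max <= 0) stop("invalid cohort_config field 'censor_time_max': must be > 0", call. = FALSE)
  class(cfg) <- "cohort_config"
  cfg
}

#' Generate a synthetic AML cohort with score-driven survival
#'
#' Per-patient stemness score `s ~ N(0,1)` drives the expression of
#' `signature_size` genes (`x = mean + s + noise`); event times are
#' exponential with rate `baseline_hazard * exp(beta * s)` and censored at an
#' independent `Uniform(0, censor_time_max)` time, giving a closed-form
#' group hazard ratio for recovery tests.
#'
#' @param config A [cohort_config()].
#' @return List with `matrix` (genes x patients, log2 scale), `survival`
#'   (data frame: sample, time, event), and `truth` (data frame: sample,
#'   score).
#' @export
gen_aml_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("pt%03d", seq_len(n))
  s <- rnorm(n)
  sig_genes <- sprintf("sig_gene%02d", seq_len(config$signature_size))
  noise_genes <- sprintf("noise_gene%03d", seq_len(config$n_noise_genes))
  x_sig <- matrix(10 + rep(s, each = config$signature_size) +
                    rnorm(config$signature_size * n, 0, 0.5),
                  nrow = config$signature_size)
  x_noise <- matrix(rnorm(config$n_noise_genes * n, 10, 1),
                    nrow = config$n_noise_genes)
  x <- rbind(x_sig, x_noise)
  dimnames(x) <- list(c(sig_genes, noise_genes), ids)
  rate <- config$baseline_hazard * exp(config$hazard_coefficient * s)
  t_event <- rexp(n, rate)
  t_cens <- runif(n, 0, config$censor_time_max)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  surv <- data.frame(sample = ids, time = time, event = event,
                     stringsAsFactors = FALSE)
  truth <- data.frame(sample = ids, score = s, stringsAsFactors = FALSE)
  list(matrix = x, survival = surv, truth = truth)
}

#' Generate a synthetic count matrix for scaling-normalization tests
#'
#' Poisson draws from lognormal per-gene means with specified library-size
#' multipliers; an optional fraction of genes is differentially expressed
#' (fold change applied) in designated samples.
#'
#' @param n_genes Number of genes.
#' @param lib_multipliers Per-sample library-size multipliers.
#' @param de_frac Fraction of genes differentially expressed.
#' @param de_fold Fold change applied to DE genes.
#' @param de_sample Index of the sample carrying the DE genes.
#' @param mean_log Mean of the log-normal gene mean distribution (natural log).
#' @param sd_log S.d. of the log-normal gene mean distribution.
#' @param seed Integer seed.
#' @return List with `counts` (genes x samples integer matrix) and `de_genes`
#'   (character vector of planted DE genes).
#' @export
gen_count_matrix <- function(n_genes = 5000, lib_multipliers = c(1, 3),
                             de_frac = 0, de_fold = 16, de_sample = 1L,
                             mean_log = 3, sd_log = 1, seed = 1L) {
  set.seed(seed)
  mu <- exp(rnorm(n_genes, mean_log, sd_log))
  n_s <- length(lib_multipliers)
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  lambda <- outer(mu, lib_multipliers)
  de_genes <- character(0)
  if (de_frac > 0) {
    n_de <- round(de_frac * n_genes)
    de_idx <- seq_len(n_de)
    lambda[de_idx, de_sample] <- lambda[de_idx, de_sample] * de_fold
    de_genes <- genes[de_idx]
  }
  counts <- matrix(rpois(n_genes * n_s, lambda), nrow = n_genes,
                   dimnames = list(genes, sprintf("s%d", seq_len(n_s))))
  list(counts = counts, de_genes = de_genes)
}

#' Write synthetic fixtures to disk
#'
#' Serializes a full synthetic study (lineage matrix, sample annotation,
#' probe annotation, gene sets, AML cohort matrix and survival table, truth
#' tables) as plain-text files re-readable by the pipeline's readers.
#' Idempotent: re-running with the same configs rewrites identical files.
#'
#' @param output_dir Directory (created if absent).
#' @param config A [synth_config()].
#' @param cohort A [cohort_config()].
#' @return Data frame manifest: file, path, seed.
#' @export
write_fixtures <- function(output_dir, config = synth_config(),
                           cohort = cohort_config()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(output_dir)) stop("cannot create directory: ", output_dir, call. = FALSE)
  lin <- gen_lineage_matrix(config)
  gs <- gen_geneset_truth(config)
  aml <- gen_aml_cohort(cohort)

  path <- function(f) file.path(output_dir, f)
  wr <- function(df, f, rn = FALSE) {
    utils::write.table(df, path(f), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)
  }
  wm <- function(m, f) {
    df <- data.frame(probe = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path(f), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  wm(round(lin$matrix, 6), "expression.tsv")
  wr(lin$samples, "samples.tsv")
  wr(lin$truth[, c("probe", "gene", "biotype")], "annotation.tsv")
  wr(lin$truth, "truth_probes.tsv")
  gmt <- vapply(names(gs$collection), function(nm) {
    paste(c(nm, "synthetic", gs$collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(gmt, path("genesets.gmt"))
  wr(gs$truth, "truth_sets.tsv")
  wm(round(aml$matrix, 6), "cohort_expression.tsv")
  wr(aml$survival, "survival.tsv")
  wr(aml$truth, "truth_cohort.tsv")

  files <- c("expression.tsv", "samples.tsv", "annotation.tsv",
             "truth_probes.tsv", "genesets.gmt", "truth_sets.tsv",
             "cohort_expression.tsv", "survival.tsv", "truth_cohort.tsv")
  manifest <- data.frame(file = files,
                         path = vapply(files, path, character(1)),
                         seed = c(rep(config$seed, 6), rep(cohort$seed, 3)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, path("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}
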