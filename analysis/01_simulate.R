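#!/usr/bin/env Rscript
# Step 01 — simulate the study data.
#
# Writes a synthetic lineage atlas (12 blood-cell lineages, 3-8 donors each,
# planted fingerprint probes, latent-factor co-regulated ncRNA/gene-set
# structure) and a synthetic AML survival cohort whose hazard is driven by a
# planted stemness score. All downstream steps read these files.

library(lincscope)

out_dir <- "results/fixtures"
cfg <- synth_config(seed = 20260919L)
cohort <- cohort_config(seed = 20260919L)

manifest <- write_fixtures(out_dir, cfg, cohort)
cat("Wrote", nrow(manifest), "fixture files to", out_dir, "\n")

lin <- gen_lineage_matrix(cfg)
cat(sprintf("Atlas: %d probes x %d samples in %d lineages (group sizes %s)\n",
            nrow(lin$matrix), ncol(lin$matrix), cfg$n_groups,
            paste(cfg$samples_per_group, collapse = "/")))
cat(sprintf("Planted: %d fingerprint probes, %d latent sets, %.0f%% background\n",
            cfg$n_groups * cfg$fingerprint_per_group, cfg$n_latent_sets,
            100 * cfg$frac_background))
aml <- gen_aml_cohort(cohort)
cat(sprintf("AML cohort: %d patients, %d events (%.0f%% censored)\n",
            nrow(aml$survival), sum(aml$survival$event),
            100 * mean(aml$survival$event == 0)))
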