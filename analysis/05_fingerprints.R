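#!/usr/bin/env Rscript
# Step 05 — lineage fingerprint calling.
#
# Moderated-t contrasts of every lineage against every other lineage on the
# ROSE-selected probes; a probe is a lineage fingerprint iff all contrasts
# pass adjusted P < 0.05 and log2-FC > 1 AND its SOM unit lies in that
# lineage's overexpression spot. The SOM is retrained with the step-04 seed
# (batch training is deterministic), so both steps see the same map.

library(lincscope)

out_dir <- "results/fingerprints"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

x <- read_matrix("results/preprocess/expression_qnorm.tsv")
sel_ids <- readLines("results/select/selected_probes.txt")
samples <- read.delim("results/fixtures/samples.tsv")
groups <- setNames(samples$group, samples$sample)
n_groups <- length(unique(groups))
sel <- x[sel_ids, ]

som <- train_som(sel, rows = 10, cols = 10, epochs = 20, seed = 20260919L)
port <- group_portraits(som, groups)
spots <- detect_spots(som, port, quantile = 1 - 1 / n_groups, min_units = 2)

contrasts <- fingerprint_contrasts(sel, groups)
write.table(contrasts, file.path(out_dir, "contrasts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
called <- call_fingerprints(contrasts, som, spots)
write.table(called, file.path(out_dir, "fingerprint_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

n_fp <- sum(called$call == "fingerprint")
n_anti <- sum(called$call == "anti-fingerprint")
cat(sprintf("Called %d fingerprints and %d anti-fingerprint assignments\n",
            n_fp, n_anti))

truth <- read.delim("results/fixtures/truth_probes.tsv")
is_fp <- grepl("^fingerprint:", truth$role)
key_true <- paste(truth$probe[is_fp], sub("fingerprint:", "", truth$role[is_fp]))
hit <- called[called$call == "fingerprint", ]
tp <- sum(paste(hit$feature, hit$group) %in% key_true)
cat(sprintf("Against the planted truth: precision %.3f, recall %.3f\n",
            tp / max(nrow(hit), 1), tp / length(key_true)))
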