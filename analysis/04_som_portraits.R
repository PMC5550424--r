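#!/usr/bin/env Rscript
# Step 04 — SOM expression portraits, spots, and the lineage tree.
#
# Trains a batch SOM on the ROSE-selected probes, derives per-lineage
# centered portraits, detects 8-connected overexpression spots, computes
# spot metagenes, and reconstructs the lineage tree by neighbor joining on
# lineage centroids of the spot-metagene matrix.

library(lincscope)

out_dir <- "results/som"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

x <- read_matrix("results/preprocess/expression_qnorm.tsv")
sel_ids <- readLines("results/select/selected_probes.txt")
samples <- read.delim("results/fixtures/samples.tsv")
groups <- setNames(samples$group, samples$sample)
n_groups <- length(unique(groups))

som <- train_som(x[sel_ids, ], rows = 10, cols = 10, epochs = 20,
                 seed = 20260919L)
cat(sprintf("SOM %dx%d on %d probes: quantization error %.3f -> %.3f over %d epochs\n",
            som$rows, som$cols, length(sel_ids),
            som$qe[1], som$qe[som$epochs], som$epochs))

port <- group_portraits(som, groups)
long <- data.frame(group = rep(colnames(port), each = nrow(port)),
                   row = som$grid$row, col = som$grid$col,
                   value = as.vector(port))
write.table(long, file.path(out_dir, "portraits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

spots <- detect_spots(som, port, quantile = 1 - 1 / n_groups, min_units = 2)
spot_df <- do.call(rbind, lapply(spots, function(sp) {
  data.frame(spot = sp$id, group = sp$group, n_units = length(sp$units),
             n_genes = length(sp$genes))
}))
write.table(spot_df, file.path(out_dir, "spots.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("Detected %d overexpression spots covering %d lineages\n",
            length(spots), length(unique(spot_df$group))))

sm <- spot_metagene_matrix(som, spots)
write.table(data.frame(sample = rownames(sm), round(sm, 5), check.names = FALSE),
            file.path(out_dir, "spot_metagenes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

centroids <- rowsum(sm, groups[rownames(sm)]) /
  as.vector(table(groups[rownames(sm)]))
nwk <- nj_tree(centroids)
writeLines(nwk, file.path(out_dir, "lineage_tree.nwk"))
cat("Lineage tree:", substr(nwk, 1, 70), "...\n")

mapping_df <- data.frame(gene = names(som$mapping), unit = som$mapping)
write.table(mapping_df, file.path(out_dir, "gene_units.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
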