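#!/usr/bin/env Rscript
# Morph markers: a 1000-tree random forest classifies the replicate
# samples by morph; genes are ranked by mean decrease in Gini impurity
# and the top 30 are reported with both importance scores, then checked
# against the planted marker genes.

suppressPackageStartupMessages(library(aphidcoex))

expr <- read_expression_matrix("results/data/matrix.tsv",
                               "results/data/meta.tsv")
truth <- jsonlite::read_json("results/data/truth.json",
                             simplifyVector = TRUE)

rk <- rank_markers(expr, label = "morph", n_trees = 1000, seed = 1)
top <- top_markers(rk, 30)
planted <- unlist(truth$marker_genes)
cat("top 30 genes by mean decrease Gini (planted markers marked *):\n")
shown <- rk[rk$rank_gini <= 30, ]
cat(sprintf("  %2d. %s%s gini %.2f, accuracy %.2f\n", shown$rank_gini,
            shown$gene_id, ifelse(shown$gene_id %in% planted, "*", " "),
            shown$mean_decrease_gini, shown$mean_decrease_accuracy),
    sep = "")
cat(sprintf("planted markers recovered in the top 30: %d/%d\n",
            sum(planted %in% top), length(planted)))

write.table(rk, "results/markers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/markers.tsv\n")
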