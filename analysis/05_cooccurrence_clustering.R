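#!/usr/bin/env Rscript
# Stage 5: gene-phenotype co-occurrence and clustering.
#
# Counts sentence-level co-occurrence between mined genes and the phenotype
# keywords, verifies against ground truth, reports per-phenotype totals and
# top genes, selects genes hitting >= 2 phenotypes at frequency >= 7,
# normalizes each selected gene's row to [0, 1], clusters rows by
# complete-linkage on Euclidean distance, and exports the bipartite graph
# and the leaf-ordered heatmap matrix. The "metastasis" keyword is part of
# the counting lexicon but excluded from the four-phenotype figure exports.

suppressPackageStartupMessages(library(hccmine))
suppressPackageStartupMessages(library(jsonlite))

data_dir <- "results/data"
out_dir <- "results"
lexicon <- load_lexicon(file.path(data_dir, "lexicon.tsv"))
corp <- parse_medline(file.path(data_dir, "main.medline"), label = "MAIN")
mentions <- mine_corpus(corp, lexicon)

cm <- count_cooccurrence(corp, mentions)
write_cooccurrence_tsv(cm, file.path(out_dir, "cooccurrence.tsv"))

truth <- read_json(file.path(data_dir, "ground_truth.json"),
                   simplifyVector = TRUE)
tc <- as.matrix(truth$main$true_cooccurrence)
rownames(tc) <- rownames(truth$main$true_cooccurrence)
stopifnot(all(unclass(cm) == tc[rownames(cm), colnames(cm)]))
message("co-occurrence matrix matches the generator ground truth exactly")

totals <- sort(phenotype_totals(cm), decreasing = TRUE)
message("phenotype totals (sentence co-occurrences):")
for (p in names(totals)) message(sprintf("  %-13s %d", p, totals[[p]]))
tops <- top_gene_per_phenotype(cm)
message("most frequent gene per phenotype:")
for (i in seq_len(nrow(tops))) {
  message(sprintf("  %-13s %s (freq = %d)", tops$phenotype[i],
                  tops$symbol[i], tops$count[i]))
}

# four-phenotype view: drop the generic "metastasis" anchor
keep <- setdiff(colnames(cm), "metastasis")
cm4 <- structure(unclass(cm)[, keep, drop = FALSE],
                 class = "cooccurrence_matrix")
export_bipartite_gexf(cm4, file.path(out_dir, "cooccurrence_bipartite.gexf"))

genes <- multi_phenotype_genes(cm4, min_phenotypes = 2, min_freq = 7)
message(sprintf("multi-phenotype genes (freq >= 7 on >= 2 phenotypes): %s",
                paste(genes, collapse = ", ")))
write.table(data.frame(symbol = genes),
            file.path(out_dir, "multi_phenotype_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

if (length(genes) >= 2) {
  norm <- linear_normalize(unclass(cm4)[genes, , drop = FALSE])
  tree <- hierarchical_cluster(norm)
  export_heatmap_data(norm, tree, file.path(out_dir, "heatmap_clustered.tsv"))
  message(sprintf("clustered %d genes; leaf order: %s", length(genes),
                  paste(leaf_order(tree), collapse = ", ")))
} else {
  message("fewer than 2 multi-phenotype genes; clustering skipped")
}
message("wrote cooccurrence artifacts under results/")
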