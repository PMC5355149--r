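#!/usr/bin/env Rscript
# Stage 1: build the synthetic study inputs.
#
# The pipeline mines three literature arms (a main HCC-metastasis arm and
# two etiology arms, HBV and HCV). No public corpus ships with the package,
# so this driver generates seeded MEDLINE corpora with planted gene mention
# and gene-phenotype co-occurrence structure, plus the gene lexicon, a GMT
# gene-set collection, and an experimental PPI edge list. Ground truth is
# saved alongside so later stages can verify their counts.

suppressPackageStartupMessages(library(hccmine))
suppressPackageStartupMessages(library(jsonlite))

seed <- 20260930L
data_dir <- "results/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

lex_path <- file.path(data_dir, "lexicon.tsv")
generate_lexicon(20, 2, seed = seed, path = lex_path)
lexicon <- load_lexicon(lex_path)
message(sprintf("lexicon: %d genes, %d aliases", nrow(lexicon$entries),
                nrow(lexicon$alias_table)))

# four designated multi-phenotype genes with distinct phenotype profiles
# (rates well above the downstream selection threshold), plus one
# single-phenotype gene that must not pass the >= 2 phenotype rule
pair_rates <- data.frame(
  gene = c("GENE1", "GENE1", "GENE2", "GENE2", "GENE3", "GENE3",
           "GENE4", "GENE4", "GENE5"),
  phenotype = c("invasion", "migration", "adhesion", "angiogenesis",
                "invasion", "migration", "adhesion", "invasion",
                "invasion"),
  rate = c(0.06, 0.06, 0.06, 0.06, 0.04, 0.025, 0.025, 0.02, 0.03),
  stringsAsFactors = FALSE)

# each etiology arm writes about its own sub-vocabulary so the partition
# has shared and arm-specific genes: HBV papers cover GENE1-GENE15, HCV
# papers GENE1-GENE8 plus GENE16-GENE18
sub_lexicon <- function(path, genes) {
  lines <- readLines(path)
  keep <- c(1L, 1L + which(load_lexicon(path)$entries$symbol %in% genes))
  load_lexicon(paste(lines[keep], collapse = "\n"))
}
arms <- list(
  main = list(n = 200, seed = seed + 1L, lexicon = lexicon,
              pairs = pair_rates),
  hbv = list(n = 120, seed = seed + 2L,
             lexicon = sub_lexicon(lex_path, sprintf("GENE%d", 1:15)),
             pairs = pair_rates),
  hcv = list(n = 60, seed = seed + 3L,
             lexicon = sub_lexicon(lex_path, sprintf("GENE%d", c(1:8, 16:18))),
             pairs = pair_rates[pair_rates$gene %in% sprintf("GENE%d", 1:8), ]))
truths <- list()
for (nm in names(arms)) {
  spec <- corpus_spec(n_abstracts = arms[[nm]]$n, gene_mention_rate = 0.02,
                      pair_rates = arms[[nm]]$pairs,
                      lexicon = arms[[nm]]$lexicon,
                      seed = arms[[nm]]$seed)
  g <- generate_corpus(spec, label = toupper(nm))
  writeLines(g$medline, file.path(data_dir, paste0(nm, ".medline")),
             useBytes = TRUE)
  truths[[nm]] <- list(
    true_frequencies = as.list(g$truth$true_frequencies),
    true_cooccurrence = as.data.frame(g$truth$true_cooccurrence),
    planted_multiphenotype_genes = g$truth$planted_multiphenotype_genes,
    n_sentences = g$truth$n_sentences)
  message(sprintf("arm %-4s: %d abstracts, %d sentences, %d genes with mentions",
                  nm, arms[[nm]]$n, g$truth$n_sentences,
                  length(g$truth$true_frequencies)))
}
write_json(truths, file.path(data_dir, "ground_truth.json"),
           auto_unbox = TRUE, digits = NA, pretty = TRUE)

gmt <- generate_gmt(list(n_sets = 8, set_size_range = c(4, 8),
                         universe = lexicon$entries$symbol),
                    enriched_query = c("GENE1", "GENE2", "GENE3", "GENE4",
                                       "GENE5"),
                    seed = seed + 4L, path = file.path(data_dir, "pathways.gmt"))
message("GMT collection: 8 sets over the 20-gene universe (SET1 enriched)")

ppi <- generate_ppi(20, n_hub = 3, hub_degree_boost = 6, seed = seed + 5L,
                    base_p = 0.12, n_predicted = 10,
                    path = file.path(data_dir, "ppi_edges.tsv"))
message(sprintf("PPI edge list: %d rows (10 predicted decoys), planted hubs: %s",
                nrow(ppi$edges), paste(ppi$planted_hubs, collapse = ", ")))
message("inputs written to ", data_dir)
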