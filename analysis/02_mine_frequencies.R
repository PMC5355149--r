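#!/usr/bin/env Rscript
# Stage 2: mine gene mentions and analyse frequencies.
#
# Parses the three MEDLINE arms, runs dictionary NER over every sentence
# (titles included), counts once-per-sentence gene frequencies, ranks the
# top 20 for the main arm, verifies counts against the generator's ground
# truth, and partitions the two etiology arms into shared/unique gene sets
# with corpus-size normalization of the smaller arm.

suppressPackageStartupMessages(library(hccmine))
suppressPackageStartupMessages(library(jsonlite))

data_dir <- "results/data"
out_dir <- "results"
lexicon <- load_lexicon(file.path(data_dir, "lexicon.tsv"))
truth <- read_json(file.path(data_dir, "ground_truth.json"),
                   simplifyVector = TRUE)

arms <- list(main = "MAIN", hbv = "HBV", hcv = "HCV")
corpora <- list(); freqs <- list()
for (nm in names(arms)) {
  corpora[[nm]] <- parse_medline(file.path(data_dir, paste0(nm, ".medline")),
                                 label = arms[[nm]])
  mentions <- mine_corpus(corpora[[nm]], lexicon)
  freqs[[nm]] <- count_frequencies(mentions, corpora[[nm]])
  message(sprintf("arm %-4s: %d abstracts, %d mention events, %d genes",
                  nm, corpora[[nm]]$n_papers, nrow(mentions),
                  nrow(freqs[[nm]])))
}

# verify mined frequencies against recorded ground truth (main arm)
tf <- unlist(truth$main$true_frequencies)
got <- setNames(freqs$main$count, freqs$main$symbol)
stopifnot(setequal(names(tf), names(got)),
          all(got[names(tf)] == tf))
message("main-arm frequencies match the generator ground truth exactly")

top <- top_n(freqs$main, 20)
write_frequency_tsv(frequency_table(top, corpus_label = "MAIN"),
                    file.path(out_dir, "frequency_top20.tsv"))
message("top mined genes:")
for (i in seq_len(min(5, nrow(top)))) {
  message(sprintf("  %-8s %d sentences", top$symbol[i], top$count[i]))
}

# etiology comparison: partition, low-frequency cut, corpus-size scaling
part <- partition_sets(freqs$hbv$symbol, freqs$hcv$symbol)
factor <- normalization_factor(corpora$hbv$n_papers, corpora$hcv$n_papers)
message(sprintf("partition: %d shared, %d HBV-only, %d HCV-only (union %d)",
                length(part$shared), length(part$a_only),
                length(part$b_only),
                length(part$shared) + length(part$a_only) +
                  length(part$b_only)))
message(sprintf("normalization factor (%d vs %d papers): x%.3f",
                corpora$hbv$n_papers, corpora$hcv$n_papers, factor))

hbv_only <- filter_min_freq(freqs$hbv, 5)
hcv_only <- filter_min_freq(freqs$hcv, 5)
hbv_only <- as.data.frame(hbv_only)[hbv_only$symbol %in% part$a_only, ]
hcv_only <- as.data.frame(hcv_only)[hcv_only$symbol %in% part$b_only, ]
sections <- rbind(
  data.frame(set = rep("shared", length(part$shared)),
             symbol = part$shared,
             count = setNames(freqs$hbv$count, freqs$hbv$symbol)[part$shared],
             normalized_count = NA_real_),
  if (nrow(hbv_only) > 0)
    data.frame(set = "HBV_only", symbol = hbv_only$symbol,
               count = hbv_only$count, normalized_count = hbv_only$count),
  if (nrow(hcv_only) > 0)
    data.frame(set = "HCV_only", symbol = hcv_only$symbol,
               count = hcv_only$count,
               normalized_count = hcv_only$count * factor))
write.table(sections, file.path(out_dir, "etiology_partition.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote frequency_top20.tsv and etiology_partition.tsv under results/")
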