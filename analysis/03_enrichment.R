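#!/usr/bin/env Rscript
# Stage 3: gene-set over-representation analysis.
#
# Runs the one-sided hypergeometric test of the mined gene lists (main arm
# plus the etiology-specific sets) against the GMT collection, using the
# lexicon vocabulary present in the collection as the universe. Raw p is
# filtered at 0.05; BH-adjusted p travels along for reporting.

suppressPackageStartupMessages(library(hccmine))

data_dir <- "results/data"
out_dir <- "results"
lexicon <- load_lexicon(file.path(data_dir, "lexicon.tsv"))

collection_all <- load_gmt(file.path(data_dir, "pathways.gmt"))
universe <- intersect(lexicon$entries$symbol,
                      unique(unlist(collection_all$sets)))
collection <- suppressWarnings(
  load_gmt(file.path(data_dir, "pathways.gmt"), universe = universe))
message(sprintf("collection: %d sets, universe %d of %d lexicon genes",
                length(collection$sets), length(collection$universe),
                nrow(lexicon$entries)))

part <- read.delim(file.path(out_dir, "etiology_partition.tsv"))
freqs <- read_frequency_tsv(file.path(out_dir, "frequency_top20.tsv"))
# main query: the strongly mined genes (sentence frequency >= 30)
queries <- list(main = freqs$symbol[freqs$count >= 30],
                hbv_only = part$symbol[part$set == "HBV_only"],
                hcv_only = part$symbol[part$set == "HCV_only"])

for (nm in names(queries)) {
  q <- intersect(queries[[nm]], collection$universe)
  if (length(q) == 0L) {
    message(sprintf("%s: no query genes inside the universe; skipping", nm))
    next
  }
  res <- hypergeometric_enrichment(q, collection)
  sig <- filter_significant(res, 0.05)
  write_enrichment_tsv(res, file.path(out_dir,
                                      sprintf("enrichment_%s.tsv", nm)))
  message(sprintf("%s: %d/%d sets significant at raw p <= 0.05", nm,
                  nrow(sig), nrow(res)))
  if (nrow(sig) > 0) {
    message(sprintf("  top set %s: overlap %d/%d, p = %.3g (BH %.3g)",
                    sig$set_name[1], sig$overlap_count[1], sig$set_size[1],
                    sig$p_value[1], sig$adjusted_p[1]))
  }
}
message("wrote enrichment_*.tsv under results/")
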