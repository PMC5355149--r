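#!/usr/bin/env Rscript
# Stage 4: induced protein-protein interaction network.
#
# Loads the experimental edge list (predicted rows are dropped), induces
# the subnetwork over the mined main-arm genes only (no neighbours),
# removes self-loops and isolates, ranks nodes by degree, and exports the
# network as GEXF.

suppressPackageStartupMessages(library(hccmine))

data_dir <- "results/data"
out_dir <- "results"

edges <- load_edges(file.path(data_dir, "ppi_edges.tsv"))
message(sprintf("edge list: %d experimental undirected pairs after filtering",
                nrow(edges)))

query <- read_frequency_tsv(file.path(out_dir, "frequency_top20.tsv"))$symbol
net <- build_induced_network(edges, query)
message(sprintf("induced network: %d nodes, %d edges (handshake check: %s)",
                length(net$nodes), nrow(net$edges),
                sum(degree_ranking(net)$degree) == 2 * nrow(net$edges)))

ranking <- degree_ranking(net, 20)
write.table(ranking, file.path(out_dir, "degree_top20.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("highest-degree nodes (candidate hubs):")
for (i in seq_len(min(5, nrow(ranking)))) {
  message(sprintf("  %-8s degree %d", ranking$symbol[i], ranking$degree[i]))
}

export_network_gexf(net, file.path(out_dir, "ppi_network.gexf"))
message("wrote degree_top20.tsv and ppi_network.gexf under results/")
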