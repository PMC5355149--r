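#' Build a pipeline configuration
#'
#' Collects the input paths, labels and thresholds for the end-to-end
#' analysis: the main corpus arm plus two etiology arms, the gene lexicon,
#' the phenotype lexicon, a GMT collection, and the PPI edge list. The
#' default thresholds are the ones the analysis is built around: low
#' frequency cut 5, co-occurrence threshold 7 with >= 2 phenotypes,
#' enrichment alpha 0.05, rankings of length 20.
#'
#' @param corpus_main,corpus_a,corpus_b Paths to MEDLINE files (main arm and
#'   the two etiology arms).
#' @param label_main,label_a,label_b Arm labels.
#' @param lexicon_path Gene lexicon TSV.
#' @param phenotype_path Phenotype lexicon TSV, or `NULL` for the default
#'   five-term lexicon.
#' @param gmt_path GMT gene-set collection.
#' @param edge_path PPI edge-list TSV.
#' @param output_dir Directory receiving all artifacts.
#' @param min_freq Low-frequency cut for the etiology comparison.
#' @param cooc_min_freq Per-phenotype co-occurrence threshold.
#' @param min_phenotypes Minimum phenotypes for the multi-phenotype list.
#' @param alpha Enrichment significance level in (0, 1].
#' @param top_n Length of frequency and degree rankings.
#' @param cluster_exclude Phenotype label(s) excluded from the
#'   four-phenotype co-occurrence figure and clustering (default
#'   "metastasis").
#' @param seed Integer seed recorded in the manifest.
#' @return A `pipeline_config` list (not yet validated).
#' @export
pipeline_config <- function(corpus_main, corpus_a, corpus_b,
                            lexicon_path, gmt_path, edge_path, output_dir,
                            label_main = "HCC", label_a = "HBV",
                            label_b = "HCV", phenotype_path = NULL,
                            min_freq = 5, cooc_min_freq = 7,
                            min_phenotypes = 2, alpha = 0.05, top_n = 20,
                            cluster_exclude = "metastasis", seed = 1) {
  structure(list(corpus_main = corpus_main, corpus_a = corpus_a,
                 corpus_b = corpus_b, label_main = label_main,
                 label_a = label_a, label_b = label_b,
                 lexicon_path = lexicon_path,
                 phenotype_path = phenotype_path, gmt_path = gmt_path,
                 edge_path = edge_path, output_dir = output_dir,
                 min_freq = min_freq, cooc_min_freq = cooc_min_freq,
                 min_phenotypes = min_phenotypes, alpha = alpha,
                 top_n = top_n, cluster_exclude = cluster_exclude,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are the [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Validate a pipeline configuration
#'
#' Checks every referenced input path and every threshold, collecting all
#' violations into a single error so a broken config is reported at once.
#'
#' @param config A [pipeline_config()].
#' @return The config, invisibly, when valid.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  errs <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)

  for (f in c("corpus_main", "corpus_a", "corpus_b", "lexicon_path",
              "gmt_path", "edge_path")) {
    p <- config[[f]]
    need(is.character(p) && length(p) == 1L && nzchar(p),
         sprintf("%s: missing path", f))
    if (is.character(p) && length(p) == 1L && nzchar(p)) {
      need(file.exists(p), sprintf("%s: file not found: %s", f, p))
    }
  }
  if (!is.null(config$phenotype_path)) {
    need(file.exists(config$phenotype_path),
         sprintf("phenotype_path: file not found: %s", config$phenotype_path))
  }
  need(is.character(config$output_dir) && nzchar(config$output_dir),
       "output_dir: missing")
  for (f in c("min_freq", "cooc_min_freq", "min_phenotypes", "top_n")) {
    need(is.numeric(config[[f]]) && config[[f]] >= 0,
         sprintf("%s: must be a non-negative number", f))
  }
  need(is.numeric(config$min_phenotypes) && config$min_phenotypes >= 1,
       "min_phenotypes: must be >= 1")
  need(is.numeric(config$top_n) && config$top_n >= 1, "top_n: must be >= 1")
  need(is.numeric(config$alpha) && config$alpha > 0 && config$alpha <= 1,
       "alpha: must lie in (0, 1]")
  if (length(errs) > 0L) {
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(config)
}

#' Run the end-to-end literature-mining pipeline
#'
#' Stage order: mine each arm, frequency tables and top-N ranking, etiology
#' partition with corpus-size normalization, per-arm enrichment,
#' gene-phenotype co-occurrence with bipartite export, multi-phenotype gene
#' selection and complete-linkage clustering, induced PPI network with
#' degree ranking, and a JSON run manifest. Any stage failure aborts with
#' the stage name after writing a partial manifest recording the completed
#' stages. Outputs are pure functions of the inputs and config: a rerun
#' writes byte-identical artifacts.
#'
#' @param config A validated [pipeline_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, ...)

  manifest <- list(
    package = "hccmine",
    version = as.character(utils::packageVersion("hccmine")),
    seed = config$seed,
    thresholds = list(min_freq = config$min_freq,
                      cooc_min_freq = config$cooc_min_freq,
                      min_phenotypes = config$min_phenotypes,
                      alpha = config$alpha, top_n = config$top_n),
    stages = list())
  completed <- character(0)
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages_completed <- completed
      manifest$failed_stage <- name
      jsonlite::write_json(manifest, pth("manifest_partial.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    completed <<- c(completed, name)
    res
  }
  lexicon <- NULL; phen <- NULL
  arms <- list(); freqs <- list(); mentions <- list()

  run_stage("load_inputs", function() {
    lexicon <<- load_lexicon(config$lexicon_path)
    phen <<- if (is.null(config$phenotype_path)) default_phenotypes() else
      load_phenotypes(config$phenotype_path)
    NULL
  })

  run_stage("mine", function() {
    arms <<- list(main = parse_medline(config$corpus_main, config$label_main),
                  a = parse_medline(config$corpus_a, config$label_a),
                  b = parse_medline(config$corpus_b, config$label_b))
    mentions <<- lapply(arms, mine_corpus, lexicon = lexicon)
    NULL
  })

  run_stage("frequency", function() {
    freqs <<- mapply(count_frequencies, mentions, arms, SIMPLIFY = FALSE)
    ranked <- top_n(freqs$main, config$top_n)
    utils::write.table(ranked, pth("frequency_top.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    NULL
  })

  partition <- NULL
  run_stage("partition_normalize", function() {
    partition <<- partition_sets(freqs$a$symbol, freqs$b$symbol)
    fa <- filter_min_freq(freqs$a, config$min_freq)
    fb <- filter_min_freq(freqs$b, config$min_freq)
    # scale the smaller arm onto the larger arm's corpus size
    if (arms$a$n_papers >= arms$b$n_papers) {
      factor_b <- normalization_factor(arms$a$n_papers, arms$b$n_papers)
      factor_a <- 1
    } else {
      factor_a <- normalization_factor(arms$b$n_papers, arms$a$n_papers)
      factor_b <- 1
    }
    section <- function(set_label, symbols, tab, factor) {
      tab <- as.data.frame(tab)
      tab <- tab[tab$symbol %in% symbols, , drop = FALSE]
      if (nrow(tab) == 0L) {
        return(data.frame(set = character(0), symbol = character(0),
                          count = numeric(0), normalized_count = numeric(0)))
      }
      data.frame(set = set_label, symbol = tab$symbol, count = tab$count,
                 normalized_count = tab$count * factor,
                 stringsAsFactors = FALSE)
    }
    part_tab <- rbind(
      section("shared", partition$shared, as.data.frame(freqs$a), 1),
      section(paste0(config$label_a, "_only"), partition$a_only, fa, factor_a),
      section(paste0(config$label_b, "_only"), partition$b_only, fb, factor_b))
    utils::write.table(part_tab, pth("partition.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$stages$partition <<- list(
      shared = length(partition$shared), a_only = length(partition$a_only),
      b_only = length(partition$b_only),
      union = length(partition$shared) + length(partition$a_only) +
        length(partition$b_only),
      factor_a = factor_a, factor_b = factor_b)
    NULL
  })

  run_stage("enrichment", function() {
    gmt_members <- load_gmt(config$gmt_path)
    universe <- intersect(lexicon$entries$symbol,
                          unique(unlist(gmt_members$sets)))
    collection <- suppressWarnings(load_gmt(config$gmt_path,
                                            universe = universe))
    queries <- list(main = freqs$main$symbol,
                    a_only = partition$a_only, b_only = partition$b_only)
    for (nm in names(queries)) {
      q <- intersect(queries[[nm]], collection$universe)
      res <- if (length(q) == 0L) {
        data.frame(set_name = character(0), overlap_count = integer(0),
                   query_size = integer(0), set_size = integer(0),
                   universe_size = integer(0), p_value = numeric(0),
                   adjusted_p = numeric(0))
      } else {
        filter_significant(hypergeometric_enrichment(q, collection),
                           config$alpha)
      }
      write_enrichment_tsv(res, pth(sprintf("enrichment_%s.tsv", nm)))
      manifest$stages$enrichment[[nm]] <<-
        list(query_size = length(q), significant = nrow(res))
    }
    NULL
  })

  cooc <- NULL
  run_stage("cooccurrence", function() {
    cooc <<- count_cooccurrence(arms$main, mentions$main, phen)
    write_cooccurrence_tsv(cooc, pth("cooccurrence.tsv"))
    keep <- setdiff(colnames(cooc), config$cluster_exclude)
    sub <- unclass(cooc)[, keep, drop = FALSE]
    export_bipartite_gexf(structure(sub, class = "cooccurrence_matrix"),
                          pth("cooccurrence_bipartite.gexf"))
    manifest$stages$cooccurrence <<- list(
      genes = nrow(cooc), phenotype_totals = as.list(phenotype_totals(cooc)))
    NULL
  })

  run_stage("clustering", function() {
    keep <- setdiff(colnames(cooc), config$cluster_exclude)
    sub <- unclass(cooc)[, keep, drop = FALSE]
    genes <- multi_phenotype_genes(structure(sub, class = "cooccurrence_matrix"),
                                   min_phenotypes = config$min_phenotypes,
                                   min_freq = config$cooc_min_freq)
    utils::write.table(data.frame(symbol = genes),
                       pth("multi_phenotype_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (length(genes) >= 2L) {
      mat <- sub[genes, , drop = FALSE]
      norm <- linear_normalize(mat)
      tree <- hierarchical_cluster(norm)
      export_heatmap_data(norm, tree, pth("heatmap_clustered.tsv"))
    } else {
      # too few multi-phenotype genes to cluster: emit an empty heatmap
      utils::write.table(
        data.frame(symbol = character(0)), pth("heatmap_clustered.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$stages$clustering <<- list(multi_phenotype_genes = length(genes))
    NULL
  })

  run_stage("network", function() {
    edges <- load_edges(config$edge_path)
    query <- freqs$main$symbol
    if (length(query) == 0L || nrow(edges) == 0L) {
      net <- NULL
      ranked <- data.frame(symbol = character(0), degree = integer(0))
      write_gexf(data.frame(id = character(0), label = character(0)),
                 data.frame(source = character(0), target = character(0)),
                 pth("ppi_network.gexf"))
    } else {
      net <- build_induced_network(edges, query)
      ranked <- degree_ranking(net, config$top_n)
      export_network_gexf(net, pth("ppi_network.gexf"))
    }
    utils::write.table(ranked, pth("degree_ranking.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$stages$network <<- list(
      nodes = if (is.null(net)) 0L else length(net$nodes),
      edges = if (is.null(net)) 0L else nrow(net$edges))
    NULL
  })

  manifest$stages$mine <- list(
    n_papers = lapply(arms, function(a) a$n_papers),
    n_mentions = lapply(mentions, nrow),
    n_genes = lapply(freqs, nrow))
  manifest$stages_completed <- completed
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
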