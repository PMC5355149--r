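# Seeded generators for every input the pipeline consumes: abstract corpora
# with planted mention/co-occurrence structure, alias lexicons, GMT
# collections, and PPI edge lists. Ground truth is recorded during
# generation (from the realized token placements, not the Bernoulli draws),
# so oracle tests stay independent of the mining code path.

#' Specification for a synthetic abstract corpus
#'
#' Defines the planted structure of a generated corpus: per-sentence gene
#' mention probabilities, joint gene-phenotype planting rates, and how often
#' a mention is rendered with a non-canonical alias. The defaults emulate a
#' small literature arm (200 short abstracts over a 20-gene vocabulary) that
#' runs through the whole pipeline in seconds.
#'
#' @param n_abstracts Number of abstracts.
#' @param sentences_range Integer range (lo, hi) of sentences per abstract.
#' @param gene_mention_rate Per-sentence probability that each gene is
#'   mentioned independently of any phenotype.
#' @param pair_rates Data.frame with columns `gene`, `phenotype`, `rate`:
#'   per-sentence probability that the pair is planted jointly in the
#'   sentence. Realized marginals always dominate the joint rate, since a
#'   pair plant inserts both tokens.
#' @param alias_usage Probability that a planted mention uses a
#'   non-canonical alias instead of the canonical symbol.
#' @param lexicon A [load_lexicon()] result naming the gene vocabulary;
#'   default a [generate_lexicon()] of 20 genes.
#' @param phenotypes A [phenotype_lexicon()]; default the five cascade terms.
#' @param seed Integer seed; generation is a pure function of spec + seed.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_abstracts = 200, sentences_range = c(3, 6),
                        gene_mention_rate = 0.05, pair_rates = NULL,
                        alias_usage = 0.3,
                        lexicon = load_lexicon(generate_lexicon(20, 2, seed = seed)),
                        phenotypes = default_phenotypes(), seed = 1) {
  stopifnot(n_abstracts >= 0, length(sentences_range) == 2L,
            sentences_range[1] >= 1, sentences_range[2] >= sentences_range[1],
            gene_mention_rate >= 0, gene_mention_rate <= 1,
            alias_usage >= 0, alias_usage <= 1)
  if (is.null(pair_rates)) {
    pair_rates <- data.frame(gene = character(0), phenotype = character(0),
                             rate = numeric(0), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(pair_rates),
            all(c("gene", "phenotype", "rate") %in% names(pair_rates)))
  if (any(pair_rates$rate < 0 | pair_rates$rate > 1)) {
    stop("inconsistent pair rates: probabilities must lie in [0, 1]")
  }
  if (anyDuplicated(pair_rates[, c("gene", "phenotype")])) {
    stop("inconsistent pair rates: duplicate (gene, phenotype) rows")
  }
  bad_g <- setdiff(pair_rates$gene, lexicon$entries$symbol)
  bad_p <- setdiff(pair_rates$phenotype, phenotypes$label)
  if (length(bad_g) > 0L || length(bad_p) > 0L) {
    stop("pair rates reference unknown symbols: ",
         paste(c(bad_g, bad_p), collapse = ", "))
  }
  structure(list(n_abstracts = n_abstracts,
                 sentences_range = as.integer(sentences_range),
                 gene_mention_rate = gene_mention_rate,
                 pair_rates = pair_rates, alias_usage = alias_usage,
                 lexicon = lexicon, phenotypes = phenotypes,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

# sentence templates; none contains internal [.?!], splitter abbreviations,
# uppercase-after-space pitfalls, lexicon aliases or phenotype words
corpus_templates <- function() {
  list(carrier = c(
    "Expression of %s was assessed in liver tumour specimens.",
    "We observed that %s showed marked changes in this cohort.",
    "Analysis suggested that %s may act together during tumour progression.",
    "Levels of %s were compared between the two patient groups.",
    "These data indicate that %s deserve further functional study."),
    filler = c(
      "Patients were followed for two years after resection.",
      "Clinical records were reviewed retrospectively.",
      "Samples were processed under a standardized protocol.",
      "Statistical tests were two-sided throughout the study.",
      "The cohort comprised adults from a single referral centre."))
}

#' Generate a synthetic MEDLINE corpus with recorded ground truth
#'
#' Each sentence embeds the sampled gene aliases and phenotype words in
#' neutral template prose. Ground-truth tallies (sentence incidence per
#' gene, sentence co-occurrence per gene-phenotype pair) are recorded from
#' the realized token placements during generation. Identical seeds give
#' byte-identical output.
#'
#' @param spec A [corpus_spec()].
#' @param label Corpus label.
#' @return List with `medline` (flat-file text), `truth` (list:
#'   `true_frequencies` named vector, `true_cooccurrence` gene x phenotype
#'   matrix, `planted_multiphenotype_genes`, `n_sentences`), and `corpus`
#'   (the parsed [corpus()], for convenience).
#' @export
generate_corpus <- function(spec, label = "synthetic") {
  stopifnot(inherits(spec, "corpus_spec"))
  lex <- spec$lexicon
  genes <- lex$entries$symbol
  phen <- spec$phenotypes$label
  # non-canonical aliases per gene, for alias_usage draws
  alias_pool <- lapply(genes, function(g) {
    a <- lex$alias_table$alias[lex$alias_table$symbol == g]
    setdiff(a, g)
  })
  names(alias_pool) <- genes
  pr <- spec$pair_rates
  tmpl <- corpus_templates()

  truth_freq <- stats::setNames(integer(length(genes)), genes)
  truth_cooc <- matrix(0L, nrow = length(genes), ncol = length(phen),
                       dimnames = list(genes, phen))
  n_sentences <- 0L

  blocks <- with_rng_seed(spec$seed, {
    lapply(seq_len(spec$n_abstracts), function(a) {
      n_sent <- sample_int_range(spec$sentences_range[1],
                                 spec$sentences_range[2])
      sents <- character(n_sent)
      for (s in seq_len(n_sent)) {
        g_present <- character(0); p_present <- character(0)
        if (nrow(pr) > 0L) {
          planted <- stats::runif(nrow(pr)) < pr$rate
          g_present <- pr$gene[planted]
          p_present <- pr$phenotype[planted]
        }
        g_present <- unique(c(g_present,
                              genes[stats::runif(length(genes)) <
                                      spec$gene_mention_rate]))
        p_present <- unique(p_present)

        # bookkeeping from realized presence, shared with nothing downstream
        truth_freq[g_present] <<- truth_freq[g_present] + 1L
        if (length(g_present) > 0L && length(p_present) > 0L) {
          truth_cooc[g_present, p_present] <<-
            truth_cooc[g_present, p_present] + 1L
        }
        n_sentences <<- n_sentences + 1L

        tokens <- vapply(g_present, function(g) {
          pool <- alias_pool[[g]]
          if (length(pool) > 0L && stats::runif(1) < spec$alias_usage) {
            sample(pool, 1L)
          } else g
        }, character(1))
        tokens <- c(tokens, p_present)
        if (length(tokens) == 0L) {
          sents[s] <- sample(tmpl$filler, 1L)
        } else {
          sents[s] <- sprintf(sample(tmpl$carrier, 1L),
                              paste(sample(tokens), collapse = " and "))
        }
      }
      sprintf("PMID- %d\nTI  - Synthetic abstract %d on liver tumour biology\nAB  - %s",
              10000L + a, a, paste(sents, collapse = " "))
    })
  })

  multi <- character(0)
  if (nrow(pr) > 0L) {
    per_gene <- table(pr$gene[pr$rate > 0])
    multi <- sort(names(per_gene)[per_gene >= 2L])
  }
  truth_freq <- truth_freq[truth_freq > 0L]
  medline <- paste(unlist(blocks), collapse = "\n\n")
  list(medline = medline,
       truth = list(true_frequencies = truth_freq,
                    true_cooccurrence = truth_cooc,
                    planted_multiphenotype_genes = multi,
                    n_sentences = n_sentences),
       corpus = parse_medline(medline, label = label))
}

#' Generate a synthetic gene lexicon TSV
#'
#' Symbols `GENE1..GENEn`, each with `aliases_per_gene` distinct synthetic
#' aliases (all >= 4 characters, so they match case-insensitively); no
#' ambiguous aliases by construction. Identical seeds give identical files.
#'
#' @param n_genes Number of genes (>= 1).
#' @param aliases_per_gene Non-canonical aliases per gene.
#' @param seed Integer seed.
#' @param path Optional path to write the TSV to.
#' @return The TSV content as a string (invisibly when written to `path`).
#' @export
generate_lexicon <- function(n_genes, aliases_per_gene = 2, seed = 1,
                             path = NULL) {
  stopifnot(n_genes >= 1, aliases_per_gene >= 0)
  rows <- with_rng_seed(seed, {
    vapply(seq_len(n_genes), function(i) {
      sym <- sprintf("GENE%d", i)
      aliases <- if (aliases_per_gene > 0) {
        vapply(seq_len(aliases_per_gene), function(j) {
          sprintf("%s%sX%d", sym, paste(sample(LETTERS, 2), collapse = ""), j)
        }, character(1))
      } else character(0)
      sprintf("%s\t%d\tsynthetic gene %d\t%s", sym, 100000L + i, i,
              paste(aliases, collapse = "|"))
    }, character(1))
  })
  text <- paste(c("symbol\tgene_id\tdescription\taliases", rows),
                collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path, useBytes = TRUE)
    return(invisible(text))
  }
  text
}

#' Generate a synthetic experimental PPI edge list
#'
#' Random graph over `GENE1..GENEn` in which `n_hub` designated hub nodes
#' receive elevated attachment probability (`base_p * hub_degree_boost`,
#' capped at 1). All emitted rows carry an experimental evidence tag; a few
#' predicted decoy rows can be added to exercise the evidence filter.
#'
#' @param n_nodes Number of nodes.
#' @param n_hub Number of planted hubs (the first `n_hub` symbols).
#' @param hub_degree_boost Attachment multiplier for hub-incident pairs;
#'   at `boost >= 1 / base_p` every hub connects to every other node.
#' @param seed Integer seed.
#' @param base_p Baseline edge probability between non-hub pairs.
#' @param n_predicted Number of non-experimental decoy rows appended.
#' @param path Optional path to write the TSV to.
#' @return List with `tsv` (text), `edges` (data.frame), `planted_hubs`.
#' @export
generate_ppi <- function(n_nodes, n_hub = 0, hub_degree_boost = 1, seed = 1,
                         base_p = 0.1, n_predicted = 0, path = NULL) {
  stopifnot(n_nodes >= 2, n_hub >= 0, n_hub <= n_nodes,
            hub_degree_boost >= 0, base_p >= 0, base_p <= 1)
  symbols <- sprintf("GENE%d", seq_len(n_nodes))
  hubs <- symbols[seq_len(n_hub)]
  pairs <- utils::combn(symbols, 2)
  out <- with_rng_seed(seed, {
    p_edge <- ifelse(pairs[1, ] %in% hubs | pairs[2, ] %in% hubs,
                     pmin(1, base_p * hub_degree_boost), base_p)
    keep <- stats::runif(ncol(pairs)) < p_edge
    edges <- data.frame(interactorA = pairs[1, keep],
                        interactorB = pairs[2, keep],
                        source = "synthetic", evidence = "experimental",
                        stringsAsFactors = FALSE)
    if (n_predicted > 0L) {
      decoy_idx <- sample(ncol(pairs), min(n_predicted, ncol(pairs)))
      edges <- rbind(edges, data.frame(
        interactorA = pairs[1, decoy_idx], interactorB = pairs[2, decoy_idx],
        source = "synthetic", evidence = "predicted",
        stringsAsFactors = FALSE))
    }
    edges
  })
  lines <- c("interactorA\tinteractorB\tsource\tevidence",
             sprintf("%s\t%s\t%s\t%s", out$interactorA, out$interactorB,
                     out$source, out$evidence))
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) writeLines(text, path, useBytes = TRUE)
  list(tsv = text, edges = out, planted_hubs = hubs)
}

#' Generate a synthetic GMT gene-set collection
#'
#' In enrichment mode one designated set (`SET1`) is drawn mostly from the
#' supplied query, so the hypergeometric test must rank it first. Without
#' `enriched_query` the collection is a calibration-mode draw: independent
#' random sets for null-uniformity checks. Set and universe sizes default
#' large so the null p-value distribution is fine-grained.
#'
#' @param collection_spec List with `n_sets`, `set_size_range` (lo, hi) and
#'   either `universe` (symbols) or `universe_size` (GENE1..GENEk used).
#' @param enriched_query Optional character vector of query symbols.
#' @param seed Integer seed.
#' @param signal_fraction Fraction of the designated set drawn from the
#'   query in enrichment mode.
#' @param path Optional path to write the GMT to.
#' @return List with `gmt` (text), `universe`, and
#'   `expected_significant` (`"SET1"` in enrichment mode, else NULL).
#' @export
generate_gmt <- function(collection_spec = list(n_sets = 20,
                                                set_size_range = c(800, 1200),
                                                universe_size = 5000),
                         enriched_query = NULL, seed = 1,
                         signal_fraction = 0.8, path = NULL) {
  cs <- collection_spec
  stopifnot(cs$n_sets >= 1, length(cs$set_size_range) == 2L)
  universe <- if (!is.null(cs[["universe"]])) as.character(cs[["universe"]]) else
    sprintf("GENE%d", seq_len(cs[["universe_size"]]))
  stopifnot(cs$set_size_range[2] <= length(universe))
  if (!is.null(enriched_query)) {
    enriched_query <- intersect(unique(enriched_query), universe)
    stopifnot(length(enriched_query) > 0L)
  }
  lines <- with_rng_seed(seed, {
    vapply(seq_len(cs$n_sets), function(i) {
      size <- sample_int_range(cs$set_size_range[1], cs$set_size_range[2])
      if (i == 1L && !is.null(enriched_query)) {
        n_sig <- min(length(enriched_query), max(1L, round(size * signal_fraction)))
        members <- c(sample(enriched_query, n_sig),
                     sample(setdiff(universe, enriched_query),
                            max(0L, size - n_sig)))
      } else {
        members <- sample(universe, size)
      }
      paste(c(sprintf("SET%d", i), sprintf("synthetic set %d", i),
              sort(unique(members))), collapse = "\t")
    }, character(1))
  })
  text <- paste(lines, collapse = "\n")
  if (!is.null(path)) writeLines(text, path, useBytes = TRUE)
  list(gmt = text, universe = universe,
       expected_significant = if (is.null(enriched_query)) NULL else "SET1")
}
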