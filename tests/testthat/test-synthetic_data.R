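small_pair_rates <- function() {
  data.frame(gene = c("GENE1", "GENE1", "GENE2", "GENE2", "GENE3"),
             phenotype = c("invasion", "migration", "adhesion",
                           "angiogenesis", "invasion"),
             rate = c(0.10, 0.09, 0.08, 0.08, 0.09),
             stringsAsFactors = FALSE)
}

test_that("generators are pure functions of spec and seed", {
  s1 <- corpus_spec(n_abstracts = 30, pair_rates = small_pair_rates(),
                    seed = 5)
  expect_identical(generate_corpus(s1)$medline, generate_corpus(s1)$medline)
  expect_identical(generate_lexicon(6, 2, seed = 9),
                   generate_lexicon(6, 2, seed = 9))
  expect_identical(generate_ppi(15, 2, 10, seed = 9)$tsv,
                   generate_ppi(15, 2, 10, seed = 9)$tsv)
  expect_identical(generate_gmt(list(n_sets = 4, set_size_range = c(5, 10),
                                     universe_size = 50), seed = 9)$gmt,
                   generate_gmt(list(n_sets = 4, set_size_range = c(5, 10),
                                     universe_size = 50), seed = 9)$gmt)
  # different seeds differ
  s2 <- corpus_spec(n_abstracts = 30, pair_rates = small_pair_rates(),
                    seed = 6)
  expect_false(identical(generate_corpus(s1)$medline,
                         generate_corpus(s2)$medline))
})

test_that("zero rates give a corpus without mentions or truth", {
  spec <- corpus_spec(n_abstracts = 10, gene_mention_rate = 0, seed = 2)
  g <- generate_corpus(spec)
  expect_length(g$truth$true_frequencies, 0L)
  expect_equal(sum(g$truth$true_cooccurrence), 0L)
  expect_equal(nrow(mine_corpus(g$corpus, spec$lexicon)), 0L)
})

test_that("invalid pair rates are rejected", {
  expect_error(corpus_spec(pair_rates = data.frame(
    gene = "GENE1", phenotype = "invasion", rate = 1.2), seed = 1),
    "inconsistent pair rates")
  expect_error(corpus_spec(pair_rates = data.frame(
    gene = c("GENE1", "GENE1"), phenotype = c("invasion", "invasion"),
    rate = c(0.1, 0.2)), seed = 1), "duplicate")
  expect_error(corpus_spec(pair_rates = data.frame(
    gene = "NOPE", phenotype = "invasion", rate = 0.1), seed = 1),
    "unknown symbols")
})

test_that("a planted pair recovers near its expected rate and exactly matches truth", {
  pr <- data.frame(gene = "GENE7", phenotype = "invasion", rate = 0.5,
                   stringsAsFactors = FALSE)
  spec <- corpus_spec(n_abstracts = 100, sentences_range = c(4, 4),
                      gene_mention_rate = 0.02, pair_rates = pr, seed = 17)
  g <- generate_corpus(spec)                     # 400 sentences
  expect_equal(g$truth$n_sentences, 400L)
  m <- mine_corpus(g$corpus, spec$lexicon)
  cm <- count_cooccurrence(g$corpus, m, spec$phenotypes)
  got <- cm["GENE7", "invasion"]
  # binomial bound: within 3 sd of 400 * 0.5
  expect_lt(abs(got - 200), 3 * sqrt(400 * 0.25) + 10)
  # and exactly equal to the recorded ground truth
  expect_equal(got, g$truth$true_cooccurrence["GENE7", "invasion"])
})

test_that("generated lexicons validate and have the declared shape", {
  txt <- generate_lexicon(5, 2, seed = 3)
  lex <- load_lexicon(txt)
  expect_equal(nrow(lex$entries), 5L)
  # 5 canonicals + 10 distinct non-canonical aliases
  expect_equal(nrow(lex$alias_table), 15L)
  expect_true(all(nchar(lex$alias_table$alias) >= 4L))
})

test_that("full pipeline counting reproduces generator ground truth exactly", {
  for (seed in 1:3) {
    spec <- corpus_spec(n_abstracts = 60, pair_rates = small_pair_rates(),
                        seed = seed)
    g <- generate_corpus(spec)
    m <- mine_corpus(g$corpus, spec$lexicon)
    ft <- count_frequencies(m, g$corpus)
    truth <- g$truth$true_frequencies
    expect_equal(stats::setNames(ft$count, ft$symbol)[sort(names(truth))],
                 truth[sort(names(truth))] + 0)
    cm <- count_cooccurrence(g$corpus, m, spec$phenotypes)
    tc <- g$truth$true_cooccurrence[rownames(cm), colnames(cm), drop = FALSE]
    expect_equal(unclass(cm) + 0, tc + 0)
  }
})

test_that("hub boost of 1 gives no systematic hub rank enrichment", {
  # across seeds, the 2 designated 'hubs' should land in the top 2 degree
  # ranks at roughly the chance rate, not systematically
  n_top <- 0L; n_seeds <- 50L
  for (s in seq_len(n_seeds)) {
    gen <- generate_ppi(12, n_hub = 2, hub_degree_boost = 1, seed = s,
                        base_p = 0.3)
    net <- build_induced_network(gen$edges |>
                                   (\(e) data.frame(a = e$interactorA,
                                                    b = e$interactorB,
                                                    source = e$source,
                                                    evidence = e$evidence))(),
                                 sprintf("GENE%d", 1:12))
    top2 <- degree_ranking(net, 2)$symbol
    n_top <- n_top + sum(gen$planted_hubs %in% top2)
  }
  # chance expectation ~ n_seeds * 2 * (2/12); systematic planting would
  # push this toward 2 * n_seeds
  expect_lt(n_top, n_seeds)
})

test_that("GMT generator enrichment mode beats every background set", {
  universe <- sprintf("GENE%d", 1:300)
  q <- sprintf("GENE%d", 1:30)
  gen <- generate_gmt(list(n_sets = 6, set_size_range = c(15, 30),
                           universe = universe),
                      enriched_query = q, seed = 4)
  coll <- load_gmt(gen$gmt, universe = gen$universe)
  res <- hypergeometric_enrichment(q, coll)
  expect_equal(res$set_name[1], "SET1")
  expect_lt(res$p_value[1], min(res$p_value[-1]))
})
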