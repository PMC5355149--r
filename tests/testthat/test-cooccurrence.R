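cooc_fixture <- function(sentences) {
  corp <- corpus(list(abstract_record("1", abstract = paste0(
    paste(sentences, collapse = ". "), "."))))
  lex <- demo_lexicon()
  list(corpus = corp, lexicon = lex, mentions = mine_corpus(corp, lex))
}

test_that("a pair counts once per sentence regardless of repetition", {
  fx <- cooc_fixture("VEGFA and VEGFA induce angiogenesis and angiogenesis")
  m <- count_cooccurrence(fx$corpus, fx$mentions)
  expect_equal(m["VEGFA", "angiogenesis"], 1L)
  expect_equal(sum(unclass(m)), 1L)
})

test_that("a gene without a phenotype word contributes nothing", {
  fx <- cooc_fixture("MMP9 was strongly expressed in tissue")
  m <- count_cooccurrence(fx$corpus, fx$mentions)
  expect_equal(sum(unclass(m)), 0L)
  expect_true("MMP9" %in% rownames(m))
})

test_that("phenotype matching is whole-word and case-insensitive", {
  fx <- cooc_fixture(c("MMP9 drove Invasion here",
                       "MMP2 looked invasive there"))
  m <- count_cooccurrence(fx$corpus, fx$mentions)
  expect_equal(m["MMP9", "invasion"], 1L)   # case-insensitive
  expect_equal(sum(unclass(m)["MMP2", ]), 0L)  # no stemming: "invasive"
})

test_that("counts match the brute-force nested-loop oracle", {
  lex <- demo_lexicon()
  phen <- default_phenotypes()
  pool <- c(lex$alias_table$alias, phen$label, "cells", "grew", "slowly",
            "liver", "samples", "the")
  set.seed(51)
  for (i in 1:25) {
    sents <- replicate(sample(3:10, 1),
                       paste(sample(pool, sample(2:8, 1), replace = TRUE),
                             collapse = " "))
    corp <- corpus(lapply(seq_along(sents), function(j)
      abstract_record(as.character(j), abstract = paste0(sents[j], "."))))
    m <- count_cooccurrence(corp, mine_corpus(corp, lex), phen)
    want <- oracle_cooccurrence(corp, lex, phen)
    expect_equal(unclass(m)[rownames(want), colnames(want), drop = FALSE] + 0,
                 want + 0)
  }
})

test_that("entries never exceed either token's sentence support", {
  lex <- demo_lexicon()
  phen <- default_phenotypes()
  pool <- c(lex$alias_table$alias, phen$label, "and", "rose")
  set.seed(52)
  for (i in 1:10) {
    sents <- replicate(8, paste(sample(pool, 5, replace = TRUE),
                                collapse = " "))
    corp <- corpus(lapply(seq_along(sents), function(j)
      abstract_record(as.character(j), abstract = paste0(sents[j], "."))))
    mm <- mine_corpus(corp, lex)
    m <- count_cooccurrence(corp, mm, phen)
    gene_support <- table(unique(mm[, c("pmid", "sentence_index", "symbol")])$symbol)
    all_sents <- unlist(lapply(corp$records, `[[`, "sentences"))
    for (p in colnames(m)) {
      p_support <- sum(vapply(all_sents, function(s)
        oracle_phenotype_in_sentence(s, p), logical(1)))
      for (g in rownames(m)) {
        expect_lte(m[g, p], min(gene_support[[g]], p_support))
      }
    }
  }
})

test_that("phenotype totals equal independent column sums", {
  m <- structure(matrix(c(0L, 5L, 2L, 0L, 1L, 3L), nrow = 3,
                        dimnames = list(c("A", "B", "C"), c("p1", "p2"))),
                 class = "cooccurrence_matrix")
  expect_equal(phenotype_totals(m), c(p1 = 7, p2 = 4))
  z <- structure(matrix(0L, 2, 2, dimnames = list(c("A", "B"), c("x", "y"))),
                 class = "cooccurrence_matrix")
  expect_equal(unname(phenotype_totals(z)), c(0, 0))
  set.seed(53)
  r <- matrix(rpois(12, 3), 4, 3, dimnames = list(letters[1:4], LETTERS[1:3]))
  expect_equal(phenotype_totals(r),
               vapply(as.data.frame(r), sum, numeric(1)))
})

test_that("top gene per phenotype takes the argmax with lexicographic ties", {
  m <- structure(matrix(c(64L, 12L, 3L, 3L, 0L, 0L), nrow = 2, byrow = FALSE,
                        dimnames = list(c("CDH1", "PTK2"),
                                        c("adhesion", "migration", "invasion"))),
                 class = "cooccurrence_matrix")
  # adhesion column: CDH1 64, PTK2 12
  top <- top_gene_per_phenotype(m)
  expect_equal(top$symbol[top$phenotype == "adhesion"], "CDH1")
  expect_equal(top$count[top$phenotype == "adhesion"], 64)
  # tie at 3 in migration resolves to the lexicographically first symbol
  expect_equal(top$symbol[top$phenotype == "migration"], "CDH1")
  # all-zero invasion column is absent
  expect_false("invasion" %in% top$phenotype)
})

test_that("multi-phenotype selection applies both thresholds", {
  m <- structure(matrix(c(10L, 10L, 8L, 0L, 3L, 0L), nrow = 2,
                        dimnames = list(c("g1", "g2"),
                                        c("invasion", "migration", "adhesion"))),
                 class = "cooccurrence_matrix")
  # g1: invasion 10, migration 8, adhesion 3 -> retained at defaults
  # g2: invasion 10 only -> excluded
  expect_equal(multi_phenotype_genes(m), "g1")
  # min_freq 0 with min_phenotypes 1 keeps any gene with a nonzero entry
  expect_setequal(multi_phenotype_genes(m, 1, 0), c("g1", "g2"))
})

test_that("multi-phenotype selection is monotone in both thresholds", {
  set.seed(54)
  for (i in 1:20) {
    m <- structure(matrix(rpois(24, 4), 6, 4,
                          dimnames = list(paste0("g", 1:6), paste0("p", 1:4))),
                   class = "cooccurrence_matrix")
    base <- multi_phenotype_genes(m, 2, 3)
    expect_true(all(multi_phenotype_genes(m, 2, 5) %in% base))
    expect_true(all(multi_phenotype_genes(m, 3, 3) %in% base))
  }
})

test_that("bipartite GEXF export round-trips weights and sizes", {
  m <- structure(matrix(c(5L, 3L), nrow = 2,
                        dimnames = list(c("MMP9", "VEGFA"), "invasion")),
                 class = "cooccurrence_matrix")
  path <- withr::local_tempfile(fileext = ".gexf")
  export_bipartite_gexf(m, path)
  g <- read_gexf(path)
  expect_equal(nrow(g$nodes), 3L)
  expect_equal(nrow(g$edges), 2L)
  expect_equal(g$nodes$n_genes[g$nodes$id == "invasion"], 2)
  expect_setequal(g$edges$weight, c(5, 3))

  z <- structure(matrix(0L, 2, 1, dimnames = list(c("A", "B"), "invasion")),
                 class = "cooccurrence_matrix")
  export_bipartite_gexf(z, path)
  gz <- read_gexf(path)
  expect_equal(nrow(gz$edges), 0L)
  expect_equal(nrow(gz$nodes), 0L)
  export_bipartite_gexf(z, path, include_isolated = TRUE)
  expect_equal(nrow(read_gexf(path)$nodes), 3L)
})

test_that("co-occurrence matrices round-trip through TSV", {
  m <- structure(matrix(c(1L, 0L, 4L, 2L), 2,
                        dimnames = list(c("g1", "g2"), c("invasion", "adhesion"))),
                 class = "cooccurrence_matrix")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cooccurrence_tsv(m, path)
  back <- read_cooccurrence_tsv(path)
  expect_equal(unclass(back) + 0, unclass(m) + 0,
               ignore_attr = FALSE)
})
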