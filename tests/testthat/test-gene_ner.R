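test_that("lexicon loads with self-aliases and reports ambiguity", {
  lex <- demo_lexicon()
  expect_s3_class(lex, "gene_lexicon")
  at <- lex$alias_table
  expect_equal(at$symbol[at$alias == "E-cadherin"], "CDH1")
  expect_equal(at$symbol[at$alias == "FAK"], "PTK2")
  expect_true(all(lex$entries$symbol %in% at$alias))  # symbol is own alias
  # ambiguous alias fails the load naming the colliding canonicals
  bad <- paste("symbol\tgene_id\tdescription\taliases",
               "TP53\t7157\ttumor protein p53\tp53",
               "TP63\t8626\ttumor protein p63\tp53", sep = "\n")
  expect_error(load_lexicon(bad), "ambiguous.*p53.*TP53.*TP63")
  # ambiguity detection is case-folded
  bad2 <- paste("symbol\tgene_id\tdescription\taliases",
                "AAAA\t1\tx\tshared-alias",
                "BBBB\t2\ty\tSHARED-ALIAS", sep = "\n")
  expect_error(load_lexicon(bad2), "ambiguous")
  expect_error(load_lexicon("symbol\tgene_id\tdescription\taliases"),
               "no entries")
})

test_that("the shipped illustrative lexicon and phenotype list validate", {
  lex <- load_lexicon(system.file("extdata", "hcc_lexicon.tsv",
                                  package = "hccmine"))
  expect_gt(nrow(lex$entries), 30L)
  expect_equal(lex$alias_table$symbol[lex$alias_table$alias == "E-cadherin"],
               "CDH1")
  expect_equal(lex$alias_table$symbol[lex$alias_table$alias == "p53"], "TP53")
  phen <- load_phenotypes(system.file("extdata", "phenotypes.tsv",
                                      package = "hccmine"))
  expect_setequal(phen$label, c("metastasis", "adhesion", "migration",
                                "invasion", "angiogenesis"))
  # plural surface form of metastasis matches; "metastatic" does not
  corp <- corpus(list(abstract_record("1",
    abstract = "TP53 loss drove metastases. MET was metastatic here.")))
  cm <- count_cooccurrence(corp, mine_corpus(corp, lex), phen)
  expect_equal(cm["TP53", "metastasis"], 1L)
  expect_equal(cm["MET", "metastasis"], 0L)
})

test_that("alias matching normalizes mentions to canonical symbols", {
  lex <- demo_lexicon()
  m <- find_gene_mentions("E-cadherin loss enhances migration", lex)
  expect_equal(m$symbol, "CDH1")
  expect_equal(m$matched_text, "E-cadherin")
  # half-open 0-based span maps back onto the sentence text
  s <- "E-cadherin loss enhances migration"
  expect_equal(substr(s, m$start + 1, m$end), m$matched_text)

  # parenthesised synonym counts as its own mention
  m2 <- find_gene_mentions("CD147 (BSG) was elevated", lex)
  expect_equal(m2$symbol, c("BSG", "BSG"))

  m3 <- find_gene_mentions("MMP2 and MMP9 degrade matrix", lex)
  expect_equal(sort(m3$symbol), c("MMP2", "MMP9"))
  # "MMP" alone is not in the lexicon
  expect_equal(nrow(find_gene_mentions("MMP levels rose", lex)), 0L)
})

test_that("case rule: short aliases exact-case, long aliases case-insensitive", {
  lex <- demo_lexicon()
  expect_equal(nrow(find_gene_mentions("they met yesterday", lex)), 0L)
  expect_equal(find_gene_mentions("MET was amplified", lex)$symbol, "MET")
  expect_equal(find_gene_mentions("e-cadherin fell", lex)$symbol, "CDH1")
  expect_equal(find_gene_mentions("vegf-a rose", lex)$symbol, "VEGFA")
})

test_that("word boundaries respect hyphens as word characters", {
  lex <- demo_lexicon()
  # embedded in a longer token: no match
  expect_equal(nrow(find_gene_mentions("proMMP2 was cleaved", lex)), 0L)
  expect_equal(nrow(find_gene_mentions("anti-E-cadherin antibody", lex)), 0L)
  # punctuation boundaries do match
  expect_equal(find_gene_mentions("levels of MMP2, rose", lex)$symbol, "MMP2")
})

test_that("mine_corpus fills pmid and 0-based sentence_index", {
  lex <- demo_lexicon()
  corp <- suppressWarnings(parse_medline(demo_medline_text()))
  ev <- mine_corpus(corp, lex)
  expect_true(all(ev$pmid %in% c("101", "102")))
  # title of record 101 holds an E-cadherin mention at sentence 0
  expect_true(any(ev$pmid == "101" & ev$sentence_index == 0 &
                    ev$symbol == "CDH1"))
  # spans check out against their sentences
  for (i in seq_len(nrow(ev))) {
    rec <- corp$records[[match(ev$pmid[i], c("101", "102"))]]
    sent <- rec$sentences[ev$sentence_index[i] + 1L]
    expect_equal(substr(sent, ev$start[i] + 1L, ev$end[i]),
                 ev$matched_text[i])
  }
  expect_equal(nrow(mine_corpus(corpus(list()), lex)), 0L)
})

test_that("returned mentions never overlap within a sentence", {
  lex <- demo_lexicon()
  set.seed(21)
  for (i in 1:50) {
    s <- random_sentence(lex)
    m <- find_gene_mentions(s, lex)
    if (nrow(m) >= 2L) {
      m <- m[order(m$start), ]
      expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
    }
  }
})

test_that("matching equals the brute-force leftmost-longest oracle", {
  lex <- demo_lexicon()
  set.seed(31)
  n_checked <- 0L
  for (i in 1:120) {
    s <- random_sentence(lex)
    if (nchar(s) > 200) next
    got <- find_gene_mentions(s, lex)
    want <- oracle_find_mentions(s, lex)
    expect_equal(got$symbol, want$symbol)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 100L)
})
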