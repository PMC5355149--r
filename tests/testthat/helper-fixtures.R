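# Shared fixtures and independent brute-force oracles. The oracles never
# call the implementation's scanning/counting internals: they re-derive the
# same quantities from first principles so equivalence tests are two-route.

demo_lexicon_text <- function() {
  paste(
    "symbol\tgene_id\tdescription\taliases",
    "VEGFA\t7422\tvascular endothelial growth factor A\tVEGF-A",
    "CDH1\t999\tcadherin 1\tE-cadherin|ECAD",
    "PTK2\t5747\tprotein tyrosine kinase 2\tFAK",
    "BSG\t682\tbasigin\tCD147",
    "MMP2\t4313\tmatrix metallopeptidase 2\t",
    "MMP9\t4318\tmatrix metallopeptidase 9\t",
    "MET\t4233\tMET proto-oncogene\t",
    sep = "\n")
}

demo_lexicon <- function() load_lexicon(demo_lexicon_text())

demo_medline_text <- function() {
  paste(
    "PMID- 101",
    "TI  - E-cadherin loss in liver cancer",
    "AB  - CDH1 suppressed migration. VEGFA and MMP9 promoted invasion",
    "      and angiogenesis. CD147 (BSG) was elevated.",
    "",
    "PMID- 102",
    "TI  - A report without gene content",
    "AB  - Patients were followed for two years. FAK signalling increased adhesion.",
    sep = "\n")
}

# --- independent oracle: dictionary matching ------------------------------

oracle_word_char <- function(ch) {
  nzchar(ch) && grepl("^[A-Za-z0-9-]$", ch)
}

# try every alias at every position, then leftmost-longest by repeated
# selection (min start, then max end)
oracle_find_mentions <- function(sentence, lexicon) {
  at <- lexicon$alias_table
  cand <- list()
  n <- nchar(sentence)
  for (k in seq_len(nrow(at))) {
    alias <- at$alias[k]
    la <- nchar(alias)
    if (la > n) next
    for (i in seq_len(n - la + 1L)) {
      piece <- substr(sentence, i, i + la - 1L)
      hit <- if (at$case_sensitive[k]) piece == alias else
        tolower(piece) == tolower(alias)
      if (!hit) next
      left_ok <- i == 1L || !oracle_word_char(substr(sentence, i - 1L, i - 1L))
      right_ok <- i + la - 1L == n ||
        !oracle_word_char(substr(sentence, i + la, i + la))
      if (left_ok && right_ok) {
        cand[[length(cand) + 1L]] <-
          list(start = i, end = i + la - 1L, symbol = at$symbol[k])
      }
    }
  }
  picked <- list()
  while (length(cand) > 0L) {
    starts <- vapply(cand, `[[`, numeric(1), "start")
    ends <- vapply(cand, `[[`, numeric(1), "end")
    sel <- which(starts == min(starts))
    sel <- sel[which.max(ends[sel])]
    picked[[length(picked) + 1L]] <- cand[[sel]]
    s <- cand[[sel]]$start; e <- cand[[sel]]$end
    cand <- Filter(function(c) c$start > e || c$end < s, cand)
  }
  if (length(picked) == 0L) {
    return(data.frame(symbol = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  out <- data.frame(symbol = vapply(picked, `[[`, character(1), "symbol"),
                    start = vapply(picked, `[[`, numeric(1), "start") - 1L,
                    end = vapply(picked, `[[`, numeric(1), "end"),
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

# --- independent oracle: per-sentence set-union tallies -------------------

oracle_count_frequencies <- function(mentions) {
  tally <- new.env()
  seen <- character(0)
  for (i in seq_len(nrow(mentions))) {
    key <- paste(mentions$pmid[i], mentions$sentence_index[i],
                 mentions$symbol[i], sep = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    sym <- mentions$symbol[i]
    tally[[sym]] <- (if (is.null(tally[[sym]])) 0L else tally[[sym]]) + 1L
  }
  syms <- ls(tally)
  stats::setNames(vapply(syms, function(s) tally[[s]], integer(1)), syms)
}

# phenotype word presence by tokenization on non-alphanumerics
oracle_phenotype_in_sentence <- function(sentence, forms) {
  toks <- tolower(strsplit(sentence, "[^[:alnum:]]+")[[1]])
  any(tolower(forms) %in% toks)
}

oracle_cooccurrence <- function(corpus, lexicon, phen_lex) {
  genes <- character(0)
  pairs <- list()
  for (r in corpus$records) {
    for (s in seq_along(r$sentences)) {
      sent <- r$sentences[s]
      g <- unique(oracle_find_mentions(sent, lexicon)$symbol)
      genes <- union(genes, g)
      if (length(g) == 0L) next
      for (j in seq_len(nrow(phen_lex))) {
        if (oracle_phenotype_in_sentence(sent, phen_lex$surface_forms[[j]])) {
          for (gg in g) {
            key <- paste(gg, phen_lex$label[j], sep = "|")
            pairs[[key]] <- (if (is.null(pairs[[key]])) 0L else pairs[[key]]) + 1L
          }
        }
      }
    }
  }
  m <- matrix(0L, nrow = length(sort(genes)), ncol = nrow(phen_lex),
              dimnames = list(sort(genes), phen_lex$label))
  for (key in names(pairs)) {
    gp <- strsplit(key, "|", fixed = TRUE)[[1]]
    m[gp[1], gp[2]] <- pairs[[key]]
  }
  m
}

# --- independent oracle: hypergeometric tail by enumeration ---------------

# P(overlap >= k) when drawing n from a universe of N with K marked,
# by exhaustive enumeration of all C(N, n) draws (N <= 12)
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked) >= k)
  mean(hits)
}

# --- independent oracle: degree by adjacency scan -------------------------

oracle_degrees <- function(edge_df) {
  nodes <- sort(unique(c(edge_df$a, edge_df$b)))
  vapply(stats::setNames(nodes, nodes), function(v) {
    nb <- unique(c(edge_df$b[edge_df$a == v], edge_df$a[edge_df$b == v]))
    length(setdiff(nb, v))
  }, integer(1))
}

# random sentence built from lexicon aliases, phenotype words and filler,
# for NER property tests
random_sentence <- function(lexicon, max_tokens = 12) {
  fill <- c("the", "cells", "showed", "strong", "signal", "in", "liver",
            "tissue", "and", "tumor", "growth", "was", "reduced")
  pool <- c(lexicon$alias_table$alias, fill, fill)
  n <- sample(seq_len(max_tokens), 1)
  paste(sample(pool, n, replace = TRUE), collapse = " ")
}
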