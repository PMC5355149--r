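#' Default phenotype lexicon
#'
#' The five metastasis-cascade keywords used as co-occurrence anchors.
#' "metastasis" itself is part of the default lexicon but is excluded from
#' the four-phenotype co-occurrence figures by the default pipeline config.
#'
#' @return A `phenotype_lexicon`: data.frame with `label` and `surface_forms`
#'   (list column of exact word forms; matching is case-insensitive,
#'   whole-word, with no stemming, so "invasion" does not match "invasive").
#' @export
default_phenotypes <- function() {
  labels <- c("metastasis", "adhesion", "migration", "invasion", "angiogenesis")
  phenotype_lexicon(data.frame(label = labels,
                               surface_forms = labels,
                               stringsAsFactors = FALSE))
}

#' Construct or validate a phenotype lexicon
#'
#' @param df Data.frame with `label` (unique) and `surface_forms` (either a
#'   list column of character vectors or a pipe-separated string column).
#' @return A `phenotype_lexicon`.
#' @export
phenotype_lexicon <- function(df) {
  stopifnot(is.data.frame(df), all(c("label", "surface_forms") %in% names(df)))
  if (anyDuplicated(df$label)) stop("duplicate phenotype labels")
  forms <- df$surface_forms
  if (!is.list(forms)) {
    forms <- lapply(strsplit(as.character(forms), "|", fixed = TRUE),
                    function(x) trimws(x[nzchar(trimws(x))]))
  }
  if (any(lengths(forms) == 0L)) stop("phenotype with no surface forms")
  out <- data.frame(label = df$label, stringsAsFactors = FALSE)
  out$surface_forms <- forms
  structure(out, class = c("phenotype_lexicon", "data.frame"))
}

#' Read a phenotype lexicon from 2-column TSV
#'
#' @param stream Path or content of a TSV with columns `label` and
#'   `surface_forms` (pipe-separated).
#' @return A `phenotype_lexicon`.
#' @export
load_phenotypes <- function(stream) {
  text <- read_text_input(stream)
  df <- utils::read.delim(text = text, stringsAsFactors = FALSE)
  phenotype_lexicon(df)
}

# Which sentences contain each phenotype? Case-insensitive whole-word match
# on any surface form. Returns a logical matrix [sentence x phenotype].
phenotype_presence <- function(sentences, phen_lex) {
  stopifnot(inherits(phen_lex, "phenotype_lexicon"))
  pres <- matrix(FALSE, nrow = length(sentences), ncol = nrow(phen_lex),
                 dimnames = list(NULL, phen_lex$label))
  for (j in seq_len(nrow(phen_lex))) {
    for (form in phen_lex$surface_forms[[j]]) {
      pat <- paste0("(?i)(?<![[:alnum:]])",
                    gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", form),
                    "(?![[:alnum:]])")
      pres[, j] <- pres[, j] | grepl(pat, sentences, perl = TRUE)
    }
  }
  pres
}

#' Count sentence-level gene-phenotype co-occurrence
#'
#' For each sentence, every (gene, phenotype) pair present contributes
#' exactly 1, no matter how often either token repeats within the sentence
#' (the once-per-sentence rule). The matrix aggregates over all sentences of
#' all records.
#'
#' @param corpus A [corpus()].
#' @param mentions Mention events from [mine_corpus()] on that corpus.
#' @param phenotype_lexicon A [phenotype_lexicon()]; default the five
#'   metastasis-cascade terms.
#' @return A `cooccurrence_matrix`: integer matrix, genes (sorted symbols
#'   with at least one mention) x phenotypes (lexicon order).
#' @export
count_cooccurrence <- function(corpus, mentions,
                               phenotype_lexicon = default_phenotypes()) {
  stopifnot(inherits(corpus, "corpus"), is.data.frame(mentions))
  phen <- phenotype_lexicon
  genes <- sort(unique(mentions$symbol))
  m <- matrix(0L, nrow = length(genes), ncol = nrow(phen),
              dimnames = list(genes, phen$label))
  if (length(genes) == 0L) return(structure(m, class = "cooccurrence_matrix"))

  sent_text <- character(0); sent_key <- character(0)
  for (r in corpus$records) {
    k <- length(r$sentences)
    if (k == 0L) next
    sent_text <- c(sent_text, r$sentences)
    sent_key <- c(sent_key, paste(r$pmid, seq_len(k) - 1L, sep = "\r"))
  }
  pres <- phenotype_presence(sent_text, phen)

  mkey <- paste(mentions$pmid, mentions$sentence_index, sep = "\r")
  genes_by_sentence <- lapply(split(mentions$symbol, mkey), unique)
  for (key in names(genes_by_sentence)) {
    s <- match(key, sent_key)
    if (is.na(s)) stop("mention refers to a sentence absent from the corpus")
    p_idx <- which(pres[s, ])
    if (length(p_idx) == 0L) next
    g_idx <- match(genes_by_sentence[[key]], genes)
    m[g_idx, p_idx] <- m[g_idx, p_idx] + 1L
  }
  structure(m, class = "cooccurrence_matrix")
}

#' Column totals of a co-occurrence matrix
#'
#' Total co-occurrence frequency per phenotype (the quantity behind "the
#' mostly concerned phenotype").
#'
#' @param matrix A `cooccurrence_matrix` (or any gene x phenotype matrix).
#' @return Named numeric vector of column sums.
#' @export
phenotype_totals <- function(matrix) {
  colSums(unclass(matrix))
}

#' Most frequent gene per phenotype
#'
#' Argmax of each column; ties broken lexicographically by symbol (rows are
#' stored sorted, so the first maximum wins). All-zero columns are reported
#' as absent.
#'
#' @param matrix A `cooccurrence_matrix`.
#' @return Data.frame `phenotype`, `symbol`, `count`, one row per phenotype
#'   with a nonzero column.
#' @export
top_gene_per_phenotype <- function(matrix) {
  m <- unclass(matrix)
  stopifnot(length(m) > 0L)
  rows <- lapply(colnames(m), function(p) {
    col <- m[, p]
    if (all(col == 0)) return(NULL)
    i <- which.max(col)  # rows sorted by symbol => first max is the tie rule
    data.frame(phenotype = p, symbol = rownames(m)[i], count = col[[i]],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(phenotype = character(0), symbol = character(0),
                      count = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genes co-occurring with multiple phenotypes
#'
#' A gene is retained when its co-occurrence count reaches the frequency
#' threshold for at least `min_phenotypes` distinct phenotypes. A phenotype
#' qualifies only with a nonzero count, so at `min_freq = 0` the rule reads
#' "any nonzero co-occurrence".
#'
#' @param matrix A `cooccurrence_matrix`.
#' @param min_phenotypes Minimum number of qualifying phenotypes (default 2).
#' @param min_freq Per-phenotype frequency threshold (default 7).
#' @return Sorted character vector of retained symbols.
#' @export
multi_phenotype_genes <- function(matrix, min_phenotypes = 2, min_freq = 7) {
  stopifnot(min_phenotypes >= 1, min_freq >= 0)
  m <- unclass(matrix)
  if (length(m) == 0L || nrow(m) == 0L) return(character(0))
  qualifies <- m >= max(min_freq, 1)
  sort(rownames(m)[rowSums(qualifies) >= min_phenotypes])
}

#' Write / read a co-occurrence matrix as TSV
#'
#' Genes as rows, phenotypes as columns, first column `symbol`.
#'
#' @param matrix A `cooccurrence_matrix`.
#' @param path Output path.
#' @export
write_cooccurrence_tsv <- function(matrix, path) {
  m <- unclass(matrix)
  df <- data.frame(symbol = rownames(m), m, check.names = FALSE,
                   row.names = NULL, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cooccurrence_tsv
#' @export
read_cooccurrence_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$symbol
  storage.mode(m) <- "double"
  structure(m, class = "cooccurrence_matrix")
}

#' Export the gene-phenotype co-occurrence graph as bipartite GEXF
#'
#' Gene and phenotype nodes; an edge per nonzero pair weighted by the
#' co-occurrence frequency. Each phenotype node carries an `n_genes`
#' attribute, the number of genes with nonzero co-occurrence (the circle
#' size in the bipartite figure). Zero-count pairs are omitted; nodes that
#' end up isolated are dropped unless `include_isolated = TRUE`.
#'
#' @param matrix A `cooccurrence_matrix`.
#' @param path Output path (.gexf).
#' @param include_isolated Keep nodes with no nonzero pair.
#' @return `path`, invisibly.
#' @export
export_bipartite_gexf <- function(matrix, path, include_isolated = FALSE) {
  m <- unclass(matrix)
  nz <- which(m > 0, arr.ind = TRUE)
  edges <- data.frame(source = rownames(m)[nz[, 1]],
                      target = colnames(m)[nz[, 2]],
                      weight = m[nz], stringsAsFactors = FALSE)
  gene_keep <- if (include_isolated) rownames(m) else
    rownames(m)[rowSums(m > 0) > 0]
  phen_keep <- if (include_isolated) colnames(m) else
    colnames(m)[colSums(m > 0) > 0]
  n_genes <- colSums(m > 0)

  nodes <- rbind(
    data.frame(id = gene_keep, label = gene_keep,
               type = rep("gene", length(gene_keep)),
               n_genes = rep(NA_real_, length(gene_keep)),
               stringsAsFactors = FALSE),
    data.frame(id = phen_keep, label = phen_keep,
               type = rep("phenotype", length(phen_keep)),
               n_genes = as.numeric(n_genes[phen_keep]),
               stringsAsFactors = FALSE))
  write_gexf(nodes, edges, path,
             node_attrs = c(type = "string", n_genes = "double"))
}
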