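#' Count gene frequencies in a corpus
#'
#' One counting semantics is used throughout the pipeline: a gene contributes
#' at most 1 to its count per sentence, however many times its aliases occur
#' there. A gene's frequency is therefore its sentence incidence across the
#' corpus. Zero-count genes are absent from the table.
#'
#' @param mentions Mention events from [mine_corpus()] on this corpus.
#' @param corpus The [corpus()] the mentions came from (supplies the label
#'   and paper count carried on the table).
#' @return A `frequency_table`: data.frame with columns `symbol`, `count`,
#'   ordered by descending count then symbol, with attributes `corpus_label`,
#'   `n_papers`, and `normalized = FALSE`.
#' @export
count_frequencies <- function(mentions, corpus) {
  stopifnot(inherits(corpus, "corpus"), is.data.frame(mentions))
  if (nrow(mentions) == 0L) {
    tab <- data.frame(symbol = character(0), count = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    key <- unique(mentions[, c("pmid", "sentence_index", "symbol")])
    cnt <- table(key$symbol)
    tab <- data.frame(symbol = names(cnt), count = as.numeric(cnt),
                      stringsAsFactors = FALSE)
  }
  frequency_table(tab, corpus_label = corpus$label, n_papers = corpus$n_papers)
}

#' Construct a frequency table
#'
#' @param df Data.frame with columns `symbol` and `count` (counts >= 1
#'   unless the table is flagged normalized).
#' @param corpus_label Corpus arm label.
#' @param n_papers Number of abstracts in the arm.
#' @param normalized Whether counts are corpus-size-scaled reals rather than
#'   integer sentence incidences.
#' @return A `frequency_table` ordered by descending count, ties by symbol.
#' @export
frequency_table <- function(df, corpus_label = "corpus", n_papers = NA_integer_,
                            normalized = FALSE) {
  stopifnot(is.data.frame(df), all(c("symbol", "count") %in% names(df)))
  df <- df[, c("symbol", "count")]
  if (anyDuplicated(df$symbol)) stop("duplicate symbols in frequency table")
  if (any(df$count <= 0)) stop("frequency table counts must be positive")
  df <- df[order(-df$count, df$symbol), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("frequency_table", "data.frame"),
            corpus_label = corpus_label, n_papers = n_papers,
            normalized = normalized)
}

#' Top-N ranking of a frequency table
#'
#' Descending by count; ties broken lexicographically by symbol (the
#' deterministic tie rule used for every ranking in this pipeline).
#'
#' @param table A [frequency_table()].
#' @param n Ranking length (>= 1); truncated to the table size.
#' @return Data.frame `symbol`, `count` of length `min(n, nrow(table))`.
#' @export
top_n <- function(table, n) {
  stopifnot(inherits(table, "frequency_table"), n >= 1)
  k <- min(as.integer(n), nrow(table))
  out <- as.data.frame(table)[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop low-frequency genes
#'
#' @param table A [frequency_table()].
#' @param min_freq Minimum count retained (default 5, the cut used when
#'   comparing etiology arms).
#' @return Filtered `frequency_table`.
#' @export
filter_min_freq <- function(table, min_freq = 5) {
  stopifnot(inherits(table, "frequency_table"), min_freq >= 0)
  out <- as.data.frame(table)[table$count >= min_freq, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(table),
            corpus_label = attr(table, "corpus_label"),
            n_papers = attr(table, "n_papers"),
            normalized = attr(table, "normalized"))
}

#' Corpus-size normalization factor
#'
#' Ratio of paper counts used to put the smaller literature arm on the scale
#' of the larger one (e.g. 262 HBV papers vs 136 HCV papers gives 1.926).
#' The reported factor is rounded to 3 decimals; keep full precision
#' internally by computing the ratio yourself if needed.
#'
#' @param n_papers_ref Paper count of the reference (larger) arm, >= 1.
#' @param n_papers_target Paper count of the arm being rescaled, >= 1.
#' @return `round(n_papers_ref / n_papers_target, 3)`.
#' @examples
#' normalization_factor(262, 136)  # 1.926
#' @export
normalization_factor <- function(n_papers_ref, n_papers_target) {
  stopifnot(is.numeric(n_papers_ref), is.numeric(n_papers_target))
  if (n_papers_target <= 0) stop("n_papers_target must be >= 1")
  if (n_papers_ref <= 0) stop("n_papers_ref must be >= 1")
  round(n_papers_ref / n_papers_target, 3)
}

#' Scale a frequency table by a normalization factor
#'
#' @param table A [frequency_table()].
#' @param factor Positive multiplier, typically from
#'   [normalization_factor()].
#' @return A `frequency_table` with real-valued counts and
#'   `normalized = TRUE`.
#' @export
apply_normalization <- function(table, factor) {
  stopifnot(inherits(table, "frequency_table"), factor > 0)
  out <- as.data.frame(table)
  out$count <- out$count * factor
  structure(out, class = class(table),
            corpus_label = attr(table, "corpus_label"),
            n_papers = attr(table, "n_papers"),
            normalized = TRUE)
}

#' Partition two gene sets into shared and arm-specific sets
#'
#' @param genes_a,genes_b Character vectors of symbols (e.g. the genes mined
#'   from the HBV and HCV arms).
#' @return A `gene_set_partition`: list with `shared`, `a_only`, `b_only`
#'   (sorted, pairwise disjoint; their sizes sum to `|A union B|`).
#' @export
partition_sets <- function(genes_a, genes_b) {
  a <- unique(as.character(genes_a))
  b <- unique(as.character(genes_b))
  structure(list(shared = sort(intersect(a, b)),
                 a_only = sort(setdiff(a, b)),
                 b_only = sort(setdiff(b, a))),
            class = "gene_set_partition")
}

#' @export
print.gene_set_partition <- function(x, ...) {
  cat(sprintf("<gene_set_partition: shared %d, a_only %d, b_only %d (union %d)>\n",
              length(x$shared), length(x$a_only), length(x$b_only),
              length(x$shared) + length(x$a_only) + length(x$b_only)))
  invisible(x)
}

#' Write a frequency table as 2-column TSV
#'
#' @param table A [frequency_table()].
#' @param path Output path.
#' @export
write_frequency_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a frequency table from 2-column TSV
#'
#' @param path Input path (columns `symbol`, `count`).
#' @param ... Passed to [frequency_table()].
#' @return A `frequency_table`.
#' @export
read_frequency_tsv <- function(path, ...) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  frequency_table(df, ...)
}
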