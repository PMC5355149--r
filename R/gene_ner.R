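#' Load a gene alias lexicon
#'
#' Reads a 4-column TSV (`symbol`, `gene_id`, `description`, `aliases` with
#' pipe-separated alias strings) into a validated dictionary used for gene
#' named-entity recognition. Every canonical symbol is also an alias of
#' itself. Aliases are many-to-one after case folding: an alias claimed by
#' two or more canonical symbols is ambiguous and fails the load, reporting
#' the colliding canonicals and their line numbers.
#'
#' @param stream Path to the TSV or its content as a string.
#' @return A `gene_lexicon`: list with `entries` (data.frame of symbol,
#'   gene_id, description, aliases) and `alias_table` (data.frame of alias,
#'   symbol, case_sensitive).
#' @export
load_lexicon <- function(stream) {
  text <- read_text_input(stream)
  df <- utils::read.delim(text = text, header = TRUE, sep = "\t",
                          quote = "", comment.char = "",
                          colClasses = "character", check.names = FALSE)
  required <- c("symbol", "gene_id", "description", "aliases")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("lexicon missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("lexicon has no entries")
  dup_sym <- unique(df$symbol[duplicated(df$symbol)])
  if (length(dup_sym) > 0L) {
    stop("duplicate canonical symbol(s): ", paste(dup_sym, collapse = ", "))
  }

  # alias table: each row's symbol plus its pipe-separated aliases,
  # carrying the 1-based data line number for error reporting
  alias_rows <- lapply(seq_len(nrow(df)), function(i) {
    extra <- strsplit(df$aliases[i], "|", fixed = TRUE)[[1]]
    extra <- trimws(extra[nzchar(trimws(extra))])
    data.frame(alias = unique(c(df$symbol[i], extra)),
               symbol = df$symbol[i], line = i + 1L,
               stringsAsFactors = FALSE)
  })
  at <- do.call(rbind, alias_rows)

  fold <- tolower(at$alias)
  collided <- split(seq_len(nrow(at)), fold)
  bad <- Filter(function(idx) length(unique(at$symbol[idx])) > 1L, collided)
  if (length(bad) > 0L) {
    msgs <- vapply(bad, function(idx) {
      sprintf("'%s' -> {%s} (lines %s)", at$alias[idx[1]],
              paste(unique(at$symbol[idx]), collapse = ", "),
              paste(unique(at$line[idx]), collapse = ", "))
    }, character(1))
    stop("ambiguous alias(es) in lexicon: ", paste(msgs, collapse = "; "))
  }
  # duplicates of the same (folded alias, symbol) pair collapse silently
  at <- at[!duplicated(paste(fold, at$symbol)), , drop = FALSE]
  rownames(at) <- NULL
  at$case_sensitive <- nchar(at$alias) < 4L

  structure(list(entries = df[, required],
                 alias_table = at[, c("alias", "symbol", "case_sensitive")]),
            class = "gene_lexicon")
}

#' @export
print.gene_lexicon <- function(x, ...) {
  cat(sprintf("<gene_lexicon: %d genes, %d aliases>\n",
              nrow(x$entries), nrow(x$alias_table)))
  invisible(x)
}

# Word-boundary test: a match must be delimited by the start/end of the
# text or a character that is neither alphanumeric nor "-" (hyphen is a
# word character inside aliases such as "E-cadherin").
is_word_char <- function(ch) grepl("^[[:alnum:]-]$", ch)

# Scan a character vector of sentences for all alias occurrences.
# Aliases of length >= 4 match case-insensitively; shorter aliases match
# case-sensitively (so "MET" does not fire on the verb "met").
# Returns a data.frame: sentence (index into `sentences`), start, end
# (1-based inclusive, internal coordinates), alias, symbol.
scan_alias_candidates <- function(sentences, lexicon) {
  stopifnot(inherits(lexicon, "gene_lexicon"))
  n <- length(sentences)
  if (n == 0L) {
    return(data.frame(sentence = integer(0), start = integer(0),
                      end = integer(0), alias = character(0),
                      symbol = character(0), stringsAsFactors = FALSE))
  }
  lowered <- tolower(sentences)
  at <- lexicon$alias_table
  out <- vector("list", nrow(at))
  for (k in seq_len(nrow(at))) {
    alias <- at$alias[k]
    if (at$case_sensitive[k]) {
      hits <- gregexpr(alias, sentences, fixed = TRUE)
    } else {
      hits <- gregexpr(tolower(alias), lowered, fixed = TRUE)
    }
    len <- nchar(alias)
    rows <- list(); nr <- 0L
    for (s in seq_len(n)) {
      pos <- hits[[s]]
      if (pos[1] == -1L) next
      for (p in as.integer(pos)) {
        e <- p + len - 1L
        ok_left <- p == 1L ||
          !is_word_char(substring(sentences[s], p - 1L, p - 1L))
        ok_right <- e == nchar(sentences[s]) ||
          !is_word_char(substring(sentences[s], e + 1L, e + 1L))
        if (ok_left && ok_right) {
          nr <- nr + 1L
          rows[[nr]] <- c(s, p, e)
        }
      }
    }
    if (nr > 0L) {
      m <- do.call(rbind, rows)
      out[[k]] <- data.frame(sentence = m[, 1], start = m[, 2], end = m[, 3],
                             alias = alias, symbol = at$symbol[k],
                             stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(sentence = integer(0), start = integer(0),
                      end = integer(0), alias = character(0),
                      symbol = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Leftmost-longest resolution of overlapping candidates within one sentence.
# Candidates: data.frame with start, end (1-based inclusive). Repeatedly take
# the candidate with the smallest start, longest span among those, then drop
# everything overlapping it.
resolve_leftmost_longest <- function(cand) {
  if (nrow(cand) == 0L) return(cand)
  cand <- cand[order(cand$start, -(cand$end - cand$start)), , drop = FALSE]
  keep <- logical(nrow(cand))
  last_end <- 0L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- cand$end[i]
    }
  }
  cand[keep, , drop = FALSE]
}

#' Find gene mentions in one sentence
#'
#' Dictionary NER: multi-pattern scan over every lexicon alias, word-boundary
#' constrained (hyphen counts as a word character), with overlapping
#' candidates resolved leftmost-longest and each surviving match normalized
#' to its canonical symbol. Mentions inside parentheses count.
#'
#' @param sentence One sentence (character scalar).
#' @param lexicon A [load_lexicon()] result.
#' @return Data.frame of mention events with columns `symbol` (canonical),
#'   `matched_text`, `start`, `end`; the span is half-open and 0-based, so
#'   `substr(sentence, start + 1, end)` equals `matched_text`.
#' @examples
#' lex <- load_lexicon(paste(
#'   "symbol\tgene_id\tdescription\taliases",
#'   "CDH1\t999\tcadherin 1\tE-cadherin|ECAD",
#'   sep = "\n"))
#' find_gene_mentions("E-cadherin loss enhances migration", lex)
#' @export
find_gene_mentions <- function(sentence, lexicon) {
  stopifnot(is.character(sentence), length(sentence) == 1L)
  cand <- scan_alias_candidates(sentence, lexicon)
  res <- resolve_leftmost_longest(cand)
  if (nrow(res) == 0L) {
    return(data.frame(symbol = character(0), matched_text = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(symbol = res$symbol,
             matched_text = substring(sentence, res$start, res$end),
             start = res$start - 1L,
             end = res$end,
             stringsAsFactors = FALSE)
}

#' Mine a whole corpus for gene mentions
#'
#' Runs dictionary NER over every sentence of every record (the title counts
#' as sentence 0 when present) and concatenates the mention events.
#'
#' @param corpus A [corpus()].
#' @param lexicon A [load_lexicon()] result.
#' @return Data.frame of mention events: `pmid`, `sentence_index` (0-based
#'   position in the record's sentence list), `symbol`, `matched_text`,
#'   `start`, `end` (half-open 0-based span within the sentence).
#' @export
mine_corpus <- function(corpus, lexicon) {
  stopifnot(inherits(corpus, "corpus"))
  sent_text <- character(0); sent_pmid <- character(0); sent_idx <- integer(0)
  for (r in corpus$records) {
    k <- length(r$sentences)
    if (k == 0L) next
    sent_text <- c(sent_text, r$sentences)
    sent_pmid <- c(sent_pmid, rep(r$pmid, k))
    sent_idx <- c(sent_idx, seq_len(k) - 1L)
  }
  empty <- data.frame(pmid = character(0), sentence_index = integer(0),
                      symbol = character(0), matched_text = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (length(sent_text) == 0L) return(empty)

  cand <- scan_alias_candidates(sent_text, lexicon)
  if (nrow(cand) == 0L) return(empty)
  parts <- lapply(split(cand, cand$sentence), resolve_leftmost_longest)
  res <- do.call(rbind, parts)
  res <- res[order(res$sentence, res$start), , drop = FALSE]
  data.frame(pmid = sent_pmid[res$sentence],
             sentence_index = sent_idx[res$sentence],
             symbol = res$symbol,
             matched_text = substring(sent_text[res$sentence],
                                      res$start, res$end),
             start = res$start - 1L,
             end = res$end,
             stringsAsFactors = FALSE)
}
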