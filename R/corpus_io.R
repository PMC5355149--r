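#' Default abbreviation list for sentence splitting
#'
#' Tokens whose trailing period never ends a sentence. User-extensible: pass a
#' modified vector to [split_sentences()] or store one per pipeline config.
#'
#' @return Character vector of abbreviations, each ending in a period.
#' @export
default_abbreviations <- function() {
  c("et al.", "Fig.", "Figs.", "e.g.", "i.e.", "vs.", "cf.", "ca.",
    "approx.", "no.", "No.", "Dr.", "St.")
}

#' Split prose into sentences
#'
#' Rule-based splitter: a boundary is a run of `.`, `?` or `!` followed by
#' whitespace and an uppercase letter or digit. Boundaries whose terminal
#' period closes a known abbreviation (e.g. "et al.", "Fig.") are suppressed.
#' Deterministic by construction; no trained model involved.
#'
#' @param text Character scalar of plain prose (UTF-8).
#' @param abbreviations Character vector of abbreviation strings ending in a
#'   period; defaults to [default_abbreviations()].
#' @return Character vector of sentences, each trimmed, never empty. An empty
#'   or whitespace-only `text` gives `character(0)`.
#' @examples
#' split_sentences("MMP9 promotes invasion. VEGFA drives angiogenesis.")
#' split_sentences("Cells (Fig. 2) migrated.")
#' @export
split_sentences <- function(text, abbreviations = default_abbreviations()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))

  # Candidate boundaries: terminal punctuation, then whitespace, then [A-Z0-9].
  cand <- gregexpr("[.?!]+(?=[[:space:]]+[A-Z0-9])", text, perl = TRUE)[[1]]
  if (cand[1] == -1L) return(trimws(text))
  ends <- as.integer(cand) + attr(cand, "match.length") - 1L

  keep <- vapply(ends, function(e) {
    !is_abbreviation_at(text, e, abbreviations)
  }, logical(1))
  ends <- ends[keep]
  if (length(ends) == 0L) return(trimws(text))

  starts <- c(1L, ends + 1L)
  stops <- c(ends, nchar(text))
  out <- trimws(substring(text, starts, stops))
  out[nzchar(out)]
}

# Does the punctuation run ending at position `end` close an abbreviation?
# The abbreviation must itself start at a word boundary (start of text or a
# non-alphanumeric character) so that e.g. "refig." does not match "Fig.".
is_abbreviation_at <- function(text, end, abbreviations) {
  for (ab in abbreviations) {
    n <- nchar(ab)
    if (end < n) next
    if (substring(text, end - n + 1L, end) != ab) next
    before <- end - n
    if (before == 0L || grepl("[^[:alnum:]]", substring(text, before, before))) {
      return(TRUE)
    }
  }
  FALSE
}

#' Construct an abstract record
#'
#' One PubMed abstract: the unit of mining. The title is carried as one
#' additional sentence preceding the abstract sentences, since gene mentions
#' in titles belong to the record as much as those in the abstract body.
#'
#' @param pmid Non-empty PMID string.
#' @param title Title text ("" if absent).
#' @param abstract Abstract text ("" if absent).
#' @param abbreviations Abbreviation list forwarded to [split_sentences()].
#' @return An `abstract_record`: list with `pmid`, `title`, `abstract`, and
#'   `sentences` (title sentence first, then abstract sentences).
#' @export
abstract_record <- function(pmid, title = "", abstract = "",
                            abbreviations = default_abbreviations()) {
  stopifnot(is.character(pmid), length(pmid) == 1L, nzchar(pmid))
  title <- if (is.na(title)) "" else title
  abstract <- if (is.na(abstract)) "" else abstract
  sentences <- character(0)
  if (nzchar(trimws(title))) sentences <- trimws(title)
  sentences <- c(sentences, split_sentences(abstract, abbreviations))
  structure(list(pmid = pmid, title = title, abstract = abstract,
                 sentences = sentences),
            class = "abstract_record")
}

#' Construct a corpus
#'
#' @param records List of [abstract_record()] objects with unique PMIDs.
#' @param label Corpus arm label (e.g. "HCC", "HBV", "HCV").
#' @return A `corpus`: list with `label`, `records`, `n_papers`.
#' @export
corpus <- function(records, label = "corpus") {
  stopifnot(is.list(records))
  pmids <- vapply(records, function(r) r$pmid, character(1))
  if (anyDuplicated(pmids)) {
    stop("duplicate PMID(s) in corpus: ",
         paste(unique(pmids[duplicated(pmids)]), collapse = ", "))
  }
  structure(list(label = label, records = records, n_papers = length(records)),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus '%s': %d abstracts, %d sentences>\n", x$label,
              x$n_papers, sum(vapply(x$records, function(r)
                length(r$sentences), integer(1)))))
  invisible(x)
}

#' Parse a MEDLINE flat-file corpus
#'
#' Reads the tagged MEDLINE export dialect (fields `PMID`, `TI`, `AB`;
#' continuation lines indented). One [abstract_record()] is produced per
#' `PMID` block. Records lacking an `AB` field get an empty abstract and a
#' warning. A block carrying fields before any `PMID` tag is a parse error
#' reported with the byte offset of the offending line.
#'
#' @param stream Path to a MEDLINE file, or the file content as a string.
#' @param label Corpus label.
#' @param abbreviations Forwarded to sentence splitting.
#' @return A [corpus()].
#' @export
parse_medline <- function(stream, label = "corpus",
                          abbreviations = default_abbreviations()) {
  text <- read_text_input(stream)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  # byte offset of the start of each line within the stream
  offsets <- c(0L, cumsum(nchar(lines, type = "bytes") + 1L))[seq_along(lines)]

  records <- list()
  cur <- NULL        # named list of fields for the current block
  cur_field <- NULL  # field tag receiving continuation lines

  flush_block <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur$PMID)) stop("internal: block without PMID reached flush")
    if (is.null(cur$AB)) {
      warning(sprintf("record PMID %s has no AB field; abstract set empty",
                      cur$PMID), call. = FALSE)
    }
    abstract_record(pmid = trimws(cur$PMID),
                    title = if (is.null(cur$TI)) "" else cur$TI,
                    abstract = if (is.null(cur$AB)) "" else cur$AB,
                    abbreviations = abbreviations)
  }

  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) {  # blank line ends a block
      if (!is.null(cur)) {
        records[[length(records) + 1L]] <- flush_block(cur)
        cur <- NULL; cur_field <- NULL
      }
      next
    }
    m <- regmatches(line, regexec("^([A-Z][A-Z0-9]{0,3})[[:space:]]*- ?(.*)$", line))[[1]]
    if (length(m) == 3L) {  # a new tagged field
      tag <- m[2]; value <- m[3]
      if (tag == "PMID") {
        if (!is.null(cur)) {  # block separated by a new PMID, not a blank line
          records[[length(records) + 1L]] <- flush_block(cur)
        }
        cur <- list(); cur_field <- NULL
      } else if (is.null(cur)) {
        stop(sprintf(
          "malformed MEDLINE block: field '%s' before any PMID tag at byte offset %d",
          tag, offsets[i]), call. = FALSE)
      }
      cur[[tag]] <- value
      cur_field <- tag
    } else if (grepl("^[[:space:]]", line)) {  # continuation line
      if (is.null(cur) || is.null(cur_field)) {
        stop(sprintf(
          "malformed MEDLINE block: continuation line outside any field at byte offset %d",
          offsets[i]), call. = FALSE)
      }
      cur[[cur_field]] <- paste(cur[[cur_field]], trimws(line))
    } else {
      stop(sprintf("malformed MEDLINE line at byte offset %d: %s",
                   offsets[i], substr(line, 1, 40)), call. = FALSE)
    }
  }
  if (!is.null(cur)) records[[length(records) + 1L]] <- flush_block(cur)
  corpus(records, label = label)
}

#' Write a corpus back to MEDLINE flat-file text
#'
#' Inverse of [parse_medline()] for the fields this pipeline consumes:
#' re-parsing the output recovers identical (pmid, title, abstract) triples.
#'
#' @param corpus A [corpus()].
#' @param path Optional output path; when `NULL` the text is returned.
#' @return The MEDLINE text, invisibly when written to `path`.
#' @export
write_medline <- function(corpus, path = NULL) {
  stopifnot(inherits(corpus, "corpus"))
  blocks <- vapply(corpus$records, function(r) {
    lines <- sprintf("PMID- %s", r$pmid)
    if (nzchar(r$title)) lines <- c(lines, sprintf("TI  - %s", r$title))
    if (nzchar(r$abstract)) lines <- c(lines, sprintf("AB  - %s", r$abstract))
    paste(lines, collapse = "\n")
  }, character(1))
  text <- paste(blocks, collapse = "\n\n")
  if (!is.null(path)) {
    writeLines(text, path, useBytes = TRUE)
    return(invisible(text))
  }
  text
}
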