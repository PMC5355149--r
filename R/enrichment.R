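#' Load a gene-set collection from GMT
#'
#' Standard GMT lines: set name, description, then tab-separated member
#' symbols. The universe defaults to the union of all members; when an
#' explicit universe is supplied, members outside it are dropped with a
#' warning. Sets left empty are rejected with a warning; duplicate set
#' names fail the load.
#'
#' @param stream Path to the GMT file or its content as a string.
#' @param universe Optional character vector of symbols defining the
#'   enrichment universe (typically the minable lexicon vocabulary).
#' @return A `gene_set_collection`: list with `sets` (named list of member
#'   vectors), `descriptions` (named character), and `universe`.
#' @export
load_gmt <- function(stream, universe = NULL) {
  text <- read_text_input(stream)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT input")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L) {
    stop("malformed GMT line(s): ", paste(bad, collapse = ", "))
  }
  names_ <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names_)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  }
  descr <- vapply(parts, `[[`, character(1), 2L)
  members <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(members) <- names_
  names(descr) <- names_

  if (is.null(universe)) {
    universe <- sort(unique(unlist(members)))
  } else {
    universe <- sort(unique(as.character(universe)))
    for (nm in names_) {
      outside <- setdiff(members[[nm]], universe)
      if (length(outside) > 0L) {
        warning(sprintf("set '%s': %d member(s) outside the universe dropped",
                        nm, length(outside)), call. = FALSE)
        members[[nm]] <- intersect(members[[nm]], universe)
      }
    }
  }
  empty <- names_[lengths(members) == 0L]
  if (length(empty) > 0L) {
    warning("rejecting empty gene set(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
    members <- members[setdiff(names_, empty)]
    descr <- descr[setdiff(names_, empty)]
  }
  if (length(members) == 0L) stop("no usable gene sets after validation")
  structure(list(sets = members, descriptions = descr, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection: %d sets, universe %d symbols>\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the p-value is the upper-tail hypergeometric
#' probability of drawing at least the observed overlap when `query_size`
#' symbols are sampled without replacement from a universe containing
#' `set_size` marked symbols (the classical one-sided over-representation
#' test). Benjamini-Hochberg adjusted p-values are computed across all sets
#' and reported alongside; results are sorted by ascending p, ties by set
#' name.
#'
#' @param query Character vector of query symbols; symbols outside the
#'   collection's universe are dropped with a warning.
#' @param collection A [load_gmt()] result.
#' @return Data.frame with `set_name`, `overlap_count`, `query_size`,
#'   `set_size`, `universe_size`, `p_value`, `adjusted_p`.
#' @export
hypergeometric_enrichment <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside) > 0L) {
    warning(sprintf("%d query symbol(s) outside the universe dropped",
                    length(outside)), call. = FALSE)
    query <- intersect(query, collection$universe)
  }
  if (length(query) == 0L) stop("query is empty after universe filtering")

  N <- length(collection$universe)
  n_q <- length(query)
  res <- lapply(names(collection$sets), function(nm) {
    members <- collection$sets[[nm]]
    K <- length(members)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, N - K, n_q, lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = k, query_size = n_q,
               set_size = K, universe_size = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter enrichment results at a significance threshold
#'
#' Retains results with raw `p_value <= alpha` (raw-p filtering, as common
#' in screening-style pathway analyses; the BH-adjusted p travels along for
#' reporting but is not used as the filter).
#'
#' @param results Output of [hypergeometric_enrichment()].
#' @param alpha Significance level in (0, 1]; default 0.05.
#' @return Filtered data.frame.
#' @export
filter_significant <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results), alpha > 0, alpha <= 1)
  out <- results[results$p_value <= alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write enrichment results as TSV
#'
#' @param results Output of [hypergeometric_enrichment()].
#' @param path Output path.
#' @export
write_enrichment_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
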