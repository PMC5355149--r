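#' Load a protein-protein interaction edge list
#'
#' Reads a TSV with at least two interactor columns and optional `source`
#' and `evidence` columns (a pre-exported table standing in for aggregated
#' interaction databases). Rows whose evidence is not experimental are
#' dropped, keeping only experimentally supported interactions; when no
#' evidence column exists all rows are treated as experimental. Duplicate
#' unordered pairs (including reversed A-B / B-A rows) collapse to a single
#' edge, keeping the first row's source tag.
#'
#' @param stream Path to the TSV or its content as a string.
#' @param header Whether the file has a header row naming the columns
#'   (`interactorA`, `interactorB`, `source`, `evidence`); without a header
#'   the first four columns are taken in that order.
#' @return Data.frame with `a`, `b` (canonically ordered so `a < b`),
#'   `source`, `evidence`.
#' @export
load_edges <- function(stream, header = TRUE) {
  text <- read_text_input(stream)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(a = character(0), b = character(0),
                      source = character(0), evidence = character(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  cols <- c("interactorA", "interactorB", "source", "evidence")
  if (header) {
    cols <- parts[[1]]
    start <- 2L
  }
  if (start > length(lines)) return(empty)
  body <- parts[start:length(parts)]
  short <- which(lengths(body) < 2L)
  if (length(short) > 0L) {
    stop(sprintf("edge row(s) with fewer than 2 columns at line(s): %s",
                 paste(short + start - 1L, collapse = ", ")))
  }
  get_col <- function(i, default = NA_character_) {
    vapply(body, function(p) if (length(p) >= i) p[[i]] else default,
           character(1))
  }
  src_i <- match("source", cols, nomatch = 3L)
  ev_i <- match("evidence", cols, nomatch = 4L)
  df <- data.frame(a = get_col(1L), b = get_col(2L),
                   source = get_col(src_i, "unknown"),
                   evidence = get_col(ev_i, "experimental"),
                   stringsAsFactors = FALSE)
  df$source[is.na(df$source)] <- "unknown"
  df$evidence[is.na(df$evidence)] <- "experimental"
  df <- df[tolower(df$evidence) == "experimental", , drop = FALSE]

  # canonical unordered pair, then dedupe
  swap <- df$a > df$b
  tmp <- df$a[swap]; df$a[swap] <- df$b[swap]; df$b[swap] <- tmp
  df <- df[!duplicated(paste(df$a, df$b, sep = "\r")), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build the induced interaction network over a query gene set
#'
#' Keeps only edges with both endpoints in `query_nodes` ("input nodes only,
#' excluding their neighbours"), removes self-loops, and drops nodes left
#' isolated, yielding an undirected simple graph.
#'
#' @param edges Edge data.frame from [load_edges()] (columns `a`, `b`,
#'   optionally `source`).
#' @param query_nodes Non-empty character vector of symbols.
#' @return An `interaction_network`: list with `graph` (igraph), `nodes`
#'   (sorted symbols) and `edges` (data.frame `a`, `b`, `source`).
#' @export
build_induced_network <- function(edges, query_nodes) {
  query_nodes <- unique(as.character(query_nodes))
  stopifnot(length(query_nodes) > 0L)
  keep <- edges$a %in% query_nodes & edges$b %in% query_nodes &
    edges$a != edges$b
  e <- edges[keep, , drop = FALSE]
  if (!"source" %in% names(e)) e$source <- "unknown"
  swap <- e$a > e$b
  tmp <- e$a[swap]; e$a[swap] <- e$b[swap]; e$b[swap] <- tmp
  e <- e[!duplicated(paste(e$a, e$b, sep = "\r")), , drop = FALSE]
  e <- e[order(e$a, e$b), , drop = FALSE]
  rownames(e) <- NULL
  nodes <- sort(unique(c(e$a, e$b)))  # isolated query nodes never appear
  g <- igraph::graph_from_data_frame(
    e[, c("a", "b")], directed = FALSE,
    vertices = if (length(nodes) > 0L) nodes else NULL)
  structure(list(graph = g, nodes = nodes, edges = e),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network: %d nodes, %d edges>\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Degree ranking of an interaction network
#'
#' Degree is the number of distinct interaction partners. Descending order,
#' ties broken lexicographically by symbol.
#'
#' @param network An [build_induced_network()] result.
#' @param n Ranking length; default the whole node set.
#' @return Data.frame `symbol`, `degree` of length `min(n, n_nodes)`.
#' @export
degree_ranking <- function(network, n = Inf) {
  stopifnot(inherits(network, "interaction_network"))
  if (length(network$nodes) == 0L) {
    return(data.frame(symbol = character(0), degree = integer(0),
                      stringsAsFactors = FALSE))
  }
  deg <- igraph::degree(network$graph)
  out <- data.frame(symbol = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$symbol), , drop = FALSE]
  k <- min(n, nrow(out))
  out <- out[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export an interaction network as GEXF 1.2
#'
#' Undirected graph with a `degree` attribute on every node.
#'
#' @param network An [build_induced_network()] result.
#' @param path Output path (.gexf).
#' @return `path`, invisibly.
#' @export
export_network_gexf <- function(network, path) {
  stopifnot(inherits(network, "interaction_network"))
  deg <- degree_ranking(network)
  nodes <- data.frame(id = deg$symbol, label = deg$symbol,
                      degree = deg$degree, stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- data.frame(source = network$edges$a, target = network$edges$b,
                      weight = rep(1, nrow(network$edges)),
                      stringsAsFactors = FALSE)
  write_gexf(nodes, edges, path, node_attrs = c(degree = "integer"))
}
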