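# GEXF 1.2 reading and writing (the dialect Gephi 0.8.x consumes).
# Writer is string-assembled for byte-stable output; reader uses xml2.

#' Write a graph as GEXF 1.2
#'
#' @param nodes Data.frame with `id`, `label`, plus any columns named in
#'   `node_attrs`.
#' @param edges Data.frame with `source`, `target` and optional `weight`.
#' @param path Output path.
#' @param node_attrs Named character vector mapping node column names to
#'   GEXF attribute types (`"string"`, `"double"`, `"integer"`).
#' @param mode `"static"` graph with the given default edge type.
#' @param defaultedgetype `"undirected"` (default) or `"directed"`.
#' @return `path`, invisibly.
#' @export
write_gexf <- function(nodes, edges, path, node_attrs = character(0),
                       mode = "static", defaultedgetype = "undirected") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con, useBytes = TRUE)

  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">')
  w('  <graph mode="%s" defaultedgetype="%s">', mode, defaultedgetype)

  if (length(node_attrs) > 0L) {
    w('    <attributes class="node">')
    for (i in seq_along(node_attrs)) {
      w('      <attribute id="%d" title="%s" type="%s"/>',
        i - 1L, xml_escape(names(node_attrs)[i]), node_attrs[[i]])
    }
    w('    </attributes>')
  }

  w('    <nodes>')
  for (i in seq_len(nrow(nodes))) {
    vals <- character(0)
    for (j in seq_along(node_attrs)) {
      v <- nodes[[names(node_attrs)[j]]][i]
      if (is.na(v)) next
      vals <- c(vals, sprintf('        <attvalue for="%d" value="%s"/>',
                              j - 1L, xml_escape(as.character(v))))
    }
    if (length(vals) > 0L) {
      w('      <node id="%s" label="%s">', xml_escape(nodes$id[i]),
        xml_escape(nodes$label[i]))
      w('%s', paste(c("      <attvalues>", vals, "      </attvalues>"),
                    collapse = "\n"))
      w('      </node>')
    } else {
      w('      <node id="%s" label="%s"/>', xml_escape(nodes$id[i]),
        xml_escape(nodes$label[i]))
    }
  }
  w('    </nodes>')

  w('    <edges>')
  if (nrow(edges) > 0L) {
    weight <- if ("weight" %in% names(edges)) edges$weight else
      rep(1, nrow(edges))
    for (i in seq_len(nrow(edges))) {
      w('      <edge id="%d" source="%s" target="%s" weight="%s"/>',
        i - 1L, xml_escape(edges$source[i]), xml_escape(edges$target[i]),
        fmt_num(weight[i]))
    }
  }
  w('    </edges>')
  w('  </graph>')
  w('</gexf>')
  invisible(path)
}

#' Read a GEXF file
#'
#' Recovers nodes (with attvalues) and weighted edges; used for round-trip
#' checks and for consuming the pipeline's own exports.
#'
#' @param path A GEXF file.
#' @return List with `nodes` (data.frame `id`, `label`, one column per node
#'   attribute) and `edges` (data.frame `source`, `target`, `weight`).
#' @export
read_gexf <- function(path) {
  doc <- xml2::read_xml(path)
  attr_nodes <- xml2::xml_find_all(
    doc, "//*[local-name()='attributes'][@class='node']/*[local-name()='attribute']")
  attr_ids <- xml2::xml_attr(attr_nodes, "id")
  attr_titles <- xml2::xml_attr(attr_nodes, "title")
  attr_types <- xml2::xml_attr(attr_nodes, "type")

  node_els <- xml2::xml_find_all(doc, "//*[local-name()='node']")
  nodes <- data.frame(id = xml2::xml_attr(node_els, "id"),
                      label = xml2::xml_attr(node_els, "label"),
                      stringsAsFactors = FALSE)
  for (k in seq_along(attr_ids)) {
    vals <- vapply(node_els, function(el) {
      v <- xml2::xml_find_first(
        el, sprintf(".//*[local-name()='attvalue'][@for='%s']", attr_ids[k]))
      if (inherits(v, "xml_missing")) NA_character_ else xml2::xml_attr(v, "value")
    }, character(1))
    if (attr_types[k] %in% c("double", "float", "integer", "long")) {
      vals <- as.numeric(vals)
    }
    nodes[[attr_titles[k]]] <- vals
  }

  edge_els <- xml2::xml_find_all(doc, "//*[local-name()='edge']")
  wt <- xml2::xml_attr(edge_els, "weight")
  edges <- data.frame(source = xml2::xml_attr(edge_els, "source"),
                      target = xml2::xml_attr(edge_els, "target"),
                      weight = ifelse(is.na(wt), 1, as.numeric(wt)),
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}
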