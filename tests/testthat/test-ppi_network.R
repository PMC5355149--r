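edge_text <- function(rows) {
  paste(c("interactorA\tinteractorB\tsource\tevidence", rows), collapse = "\n")
}

test_that("load_edges filters evidence and dedupes unordered pairs", {
  e <- load_edges(edge_text(c("A\tB\tdb1\texperimental",
                              "B\tC\tdb1\texperimental",
                              "C\tD\tdb2\texperimental",
                              "C\tE\tdb2\tpredicted")))
  expect_equal(nrow(e), 3L)
  expect_false(any(e$b == "E"))

  e2 <- load_edges(edge_text(c("A\tB\tdb1\texperimental",
                               "B\tA\tdb2\texperimental")))
  expect_equal(nrow(e2), 1L)
  expect_equal(e2[1, c("a", "b")], data.frame(a = "A", b = "B"))

  expect_equal(nrow(load_edges("interactorA\tinteractorB")), 0L)
  expect_error(load_edges(edge_text(c("A\tB\tdb\texperimental", "lonely"))),
               "line\\(s\\): 3")
  # without an evidence column every row counts as experimental
  e3 <- load_edges("x\ty\nA\tB", header = TRUE)
  expect_equal(nrow(e3), 1L)
})

test_that("induced network keeps query-internal edges only", {
  e <- load_edges(edge_text(c("A\tB\tdb\texperimental",
                              "B\tC\tdb\texperimental",
                              "C\tX\tdb\texperimental",
                              "C\tC\tdb\texperimental")))
  net <- build_induced_network(e, c("A", "B", "C", "D"))
  expect_setequal(net$nodes, c("A", "B", "C"))          # X out, D isolated
  expect_equal(nrow(net$edges), 2L)                     # self-loop C-C gone
  expect_false("X" %in% net$nodes)
  expect_false("D" %in% net$nodes)
})

test_that("degree ranking is descending with lexicographic ties", {
  tri <- load_edges(edge_text(c("A\tB\tdb\texperimental",
                                "B\tC\tdb\texperimental",
                                "A\tC\tdb\texperimental")))
  net <- build_induced_network(tri, c("A", "B", "C"))
  r <- degree_ranking(net)
  expect_equal(r$degree, c(2L, 2L, 2L))
  expect_equal(r$symbol, c("A", "B", "C"))

  star <- load_edges(edge_text(sprintf("H\tL%d\tdb\texperimental", 1:5)))
  net_star <- build_induced_network(star, c("H", paste0("L", 1:5)))
  rs <- degree_ranking(net_star, 2)
  expect_equal(rs$symbol[1], "H")
  expect_equal(rs$degree, c(5L, 1L))
})

test_that("degree ranking equals brute-force adjacency scanning", {
  set.seed(71)
  n_checked <- 0L
  for (i in 1:110) {
    n <- sample(5:30, 1)
    nodes <- paste0("N", seq_len(n))
    m <- sample(3:40, 1)
    rows <- sprintf("%s\t%s\tdb\texperimental",
                    sample(nodes, m, replace = TRUE),
                    sample(nodes, m, replace = TRUE))
    e <- load_edges(edge_text(rows))
    e <- e[e$a != e$b, , drop = FALSE]
    if (nrow(e) == 0L) next
    net <- build_induced_network(e, nodes)
    got <- degree_ranking(net)
    want <- oracle_degrees(net$edges)
    expect_equal(stats::setNames(got$degree, got$symbol)[names(want)], want)
    # handshake lemma on every built network
    expect_equal(sum(got$degree), 2L * nrow(net$edges))
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 100L)
})

test_that("induced-network construction is idempotent", {
  set.seed(72)
  for (i in 1:20) {
    nodes <- paste0("N", 1:12)
    rows <- sprintf("%s\t%s\tdb\texperimental",
                    sample(nodes, 20, replace = TRUE),
                    sample(nodes, 20, replace = TRUE))
    net <- build_induced_network(load_edges(edge_text(rows)), nodes)
    again <- build_induced_network(net$edges, net$nodes)
    expect_equal(again$nodes, net$nodes)
    expect_equal(again$edges[, c("a", "b")], net$edges[, c("a", "b")])
  }
})

test_that("removing a node never increases another's degree", {
  set.seed(73)
  for (i in 1:10) {
    nodes <- paste0("N", 1:10)
    rows <- sprintf("%s\t%s\tdb\texperimental",
                    sample(nodes, 25, replace = TRUE),
                    sample(nodes, 25, replace = TRUE))
    e <- load_edges(edge_text(rows))
    e <- e[e$a != e$b, , drop = FALSE]
    if (nrow(e) < 2L) next
    net <- build_induced_network(e, nodes)
    full <- stats::setNames(degree_ranking(net)$degree,
                            degree_ranking(net)$symbol)
    drop <- sample(net$nodes, 1)
    sub <- build_induced_network(e, setdiff(nodes, drop))
    red <- degree_ranking(sub)
    for (j in seq_len(nrow(red))) {
      expect_lte(red$degree[j], full[[red$symbol[j]]])
    }
  }
})

test_that("network GEXF export round-trips nodes, edges and degrees", {
  tri <- load_edges(edge_text(c("A\tB\tdb\texperimental",
                                "B\tC\tdb\texperimental",
                                "A\tC\tdb\texperimental")))
  net <- build_induced_network(tri, c("A", "B", "C"))
  path <- withr::local_tempfile(fileext = ".gexf")
  export_network_gexf(net, path)
  g <- read_gexf(path)
  expect_equal(nrow(g$nodes), 3L)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(g$nodes$degree, c(2, 2, 2))
  pairs_got <- sort(paste(pmin(g$edges$source, g$edges$target),
                          pmax(g$edges$source, g$edges$target)))
  pairs_want <- sort(paste(net$edges$a, net$edges$b))
  expect_equal(pairs_got, pairs_want)

  # empty network still writes valid GEXF
  write_gexf(data.frame(id = character(0), label = character(0)),
             data.frame(source = character(0), target = character(0)), path)
  ge <- read_gexf(path)
  expect_equal(nrow(ge$nodes), 0L)
  expect_equal(nrow(ge$edges), 0L)
})

test_that("planted hubs occupy the top ranks at extreme boost", {
  for (s in 1:5) {
    gen <- generate_ppi(30, n_hub = 3, hub_degree_boost = 1000, seed = s,
                        base_p = 0.05, n_predicted = 4)
    e <- load_edges(gen$tsv)
    expect_true(all(tolower(e$evidence) == "experimental"))
    net <- build_induced_network(e, sprintf("GENE%d", 1:30))
    top <- degree_ranking(net, 3)
    expect_setequal(top$symbol, gen$planted_hubs)
  }
})
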