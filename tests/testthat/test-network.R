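make_presence <- function(mat) {
  # severity matrix from a binary presence matrix
  storage.mode(mat) <- "integer"
  mat
}

test_that("edge retention keeps ceiling(quantile x candidates) edges", {
  # 5 items, all pairs co-occur with distinct weights: 10 candidate edges.
  n <- 40
  m <- matrix(0L, n, 5, dimnames = list(NULL, paste0("s", 1:5)))
  m[1:30, ] <- 1L                      # everyone shares a common block
  m[31:35, 1:2] <- 1L                  # extra weight for pair (1,2)
  net <- cooccurrence_network(m, node_min_prevalence = 0.1,
                              edge_quantile = 0.30)
  expect_identical(nrow(net$edges), 3L)  # ceiling(0.3 * 10) = 3
  net_all <- cooccurrence_network(m, node_min_prevalence = 0.1,
                                  edge_quantile = 1)
  expect_identical(nrow(net_all$edges), 10L)
})

test_that("three always-co-present symptoms form a complete triangle", {
  m <- make_presence(matrix(1, 10, 3, dimnames = list(NULL, c("a", "b", "c"))))
  net <- cooccurrence_network(m, node_min_prevalence = 0.5, edge_quantile = 1)
  expect_equal(net$metrics$density, 1)
  expect_equal(net$metrics$avg_clustering, 1)
  expect_equal(net$metrics$avg_degree, 2)
  expect_true(all(net$edges$weight == 10))
})

test_that("path and star metrics match closed forms", {
  g_path <- igraph::make_graph(~ a - b, b - c)
  m <- network_metrics(g_path)
  expect_equal(m$metrics$density, 2 / 3, tolerance = 1e-12)
  expect_equal(m$metrics$avg_degree, 4 / 3, tolerance = 1e-12)
  expect_equal(m$metrics$avg_clustering, 0)
  g_star <- igraph::make_star(5, mode = "undirected")
  igraph::V(g_star)$name <- c("hub", paste0("leaf", 1:4))
  ms <- network_metrics(g_star)
  btw <- setNames(ms$centrality$betweenness, ms$centrality$id)
  expect_equal(unname(btw["hub"]), 1)
  expect_equal(unname(btw[paste0("leaf", 1:4)]), rep(0, 4))
})

test_that("density and degree identities hold on generated networks", {
  ds <- generate_survey(default_generator_config(seed = 9))
  net <- cooccurrence_network(ds$symptoms, default_codebook())
  N <- nrow(net$nodes); E <- nrow(net$edges)
  expect_equal(net$metrics$density, 2 * E / (N * (N - 1)))
  expect_equal(net$metrics$avg_degree, 2 * E / N)
  # Co-occurrence cannot exceed either endpoint's occurrence count.
  cnt <- setNames(net$nodes$count, net$nodes$id)
  expect_true(all(net$edges$weight <=
                    pmin(cnt[net$edges$from], cnt[net$edges$to])))
  # No self-loops or duplicate edges.
  expect_true(igraph::is_simple(net$graph))
})

test_that("raising the edge quantile never drops a retained edge", {
  for (seed in c(2, 7, 21)) {
    ds <- generate_survey(default_generator_config(seed = seed))
    prev_keys <- character()
    for (q in c(0.1, 0.3, 0.5, 0.8, 1)) {
      net <- cooccurrence_network(ds$symptoms, default_codebook(),
                                  edge_quantile = q)
      keys <- paste(net$edges$from, net$edges$to)
      expect_true(all(prev_keys %in% keys))
      prev_keys <- keys
    }
  }
})

test_that("degenerate inputs yield an empty network with a warning", {
  m <- make_presence(matrix(0, 10, 3, dimnames = list(NULL, c("a", "b", "c"))))
  expect_warning(net <- cooccurrence_network(m, node_min_prevalence = 0.5),
                 "fewer than 2 candidate nodes")
  expect_identical(nrow(net$nodes), 0L)
  expect_null(net$metrics)
  expect_error(cooccurrence_network(make_presence(matrix(1, 5, 2,
                  dimnames = list(NULL, c("a", "b")))), edge_quantile = 1.5),
               "edge_quantile")
})

test_that("network export writes GraphML, edge list, and metrics", {
  m <- make_presence(matrix(1, 10, 3, dimnames = list(NULL, c("a", "b", "c"))))
  net <- cooccurrence_network(m, node_min_prevalence = 0.5, edge_quantile = 1)
  gml <- withr::local_tempfile(fileext = ".graphml")
  ecsv <- withr::local_tempfile(fileext = ".csv")
  mjson <- withr::local_tempfile(fileext = ".json")
  export_network(net, graphml = gml, edges_csv = ecsv, metrics_json = mjson,
                 layout_seed = 42)
  expect_true(file.size(gml) > 0)
  e <- read.csv(ecsv)
  expect_identical(names(e), c("source", "target", "weight"))
  expect_identical(nrow(e), 3L)
  mj <- jsonlite::fromJSON(mjson)
  expect_equal(mj$density, 1)
})
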