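test_that("gene_network collapses duplicates, drops self-loops, checks labels", {
  e <- data.frame(source = c("a", "a", "b", "c"),
                  target = c("b", "b", "b", "d"))
  net <- gene_network(e, node_types = c(a = "gene", b = "gene", c = "gene",
                                        d = "compound"))
  expect_equal(igraph::ecount(net), 2) # a->b dedup, b->b loop dropped
  expect_equal(sort(igraph::V(net)$name), c("a", "b", "c", "d"))
  expect_error(gene_network(e, node_types = c(a = "gene", b = "gene")),
               "unlabeled", class = "emtnet_input_error")
})

test_that("build_network unions pathways and removes compounds", {
  empty <- build_network(pathway_collection(list()))
  expect_equal(igraph::vcount(empty), 0)

  # two pathways sharing gene g: 4 + 3 gene nodes (1 shared), 3 + 2 edge
  # records (1 duplicated) -> 6 nodes, 4 unique edges
  p1 <- hand_pathway("p1", rbind(c("g", "x1"), c("x1", "x2"), c("x2", "x3")))
  p2 <- hand_pathway("p2", rbind(c("g", "y1"), c("g", "y1")),
                     extra_nodes = "y2")
  net <- build_network(pathway_collection(list(p1, p2)))
  expect_equal(igraph::vcount(net), 6)
  expect_equal(igraph::ecount(net), 4)

  # compound node of degree 2 -> node count -1, edge count -2 after removal
  p3 <- hand_pathway("p3", rbind(c("a", "cpd"), c("cpd", "b"), c("a", "b")),
                     compound_nodes = "cpd")
  with_cpd <- build_network(pathway_collection(list(p3)),
                            drop_compounds = FALSE)
  no_cpd <- build_network(pathway_collection(list(p3)))
  expect_equal(igraph::vcount(with_cpd) - igraph::vcount(no_cpd), 1)
  expect_equal(igraph::ecount(with_cpd) - igraph::ecount(no_cpd), 2)
})

test_that("build_network is a fixed point on its own edge list", {
  set.seed(4)
  rg <- random_digraph(15, 0.2, seed = 4)
  e <- igraph::as_data_frame(rg$net, what = "edges")
  rebuilt <- gene_network(
    data.frame(source = e$from, target = e$to, stringsAsFactors = FALSE),
    node_types = setNames(igraph::V(rg$net)$node_type,
                          igraph::V(rg$net)$name))
  expect_setequal(igraph::V(rebuilt)$name, igraph::V(rg$net)$name)
  expect_equal(igraph::ecount(rebuilt), igraph::ecount(rg$net))
})

test_that("main_component extracts the largest weak component with percent", {
  # connected graph: unchanged, 100.0%
  tri <- gene_network(data.frame(source = c("a", "b", "c"),
                                 target = c("b", "c", "a")))
  mc <- main_component(tri)
  expect_equal(igraph::vcount(mc), 3)
  expect_equal(attr(mc, "retained_percent"), 100.0)

  # components of sizes 7 and 3 -> 70.0%
  e7 <- data.frame(source = sprintf("a%d", 1:6), target = sprintf("a%d", 2:7))
  e3 <- data.frame(source = c("b1", "b2"), target = c("b2", "b3"))
  both <- gene_network(rbind(e7, e3))
  mc2 <- main_component(both)
  expect_equal(igraph::vcount(mc2), 7)
  expect_equal(attr(mc2, "retained_percent"), 70.0)
  expect_equal(igraph::components(mc2, mode = "weak")$no, 1)
  # maximality: every excluded node is disconnected from the component
  expect_setequal(igraph::V(mc2)$name, sprintf("a%d", 1:7))
  expect_warning(main_component(gene_network(NULL)), "empty")
})

test_that("node_metrics on hand-checkable graphs", {
  tri <- gene_network(data.frame(source = c("a", "b", "c"),
                                 target = c("b", "c", "a")))
  m <- node_metrics(tri)
  expect_equal(m$in_degree, rep(1, 3))
  expect_equal(m$out_degree, rep(1, 3))
  expect_equal(m$clustering_coefficient, rep(1, 3))

  # 5-node star with reciprocal edges: center CC 0, leaves degree 1+1
  leaves <- sprintf("l%d", 1:4)
  star <- gene_network(data.frame(source = c(rep("c", 4), leaves),
                                  target = c(leaves, rep("c", 4))))
  ms <- node_metrics(star)
  expect_equal(ms$clustering_coefficient[ms$node == "c"], 0)
  expect_equal(ms$total_degree[ms$node != "c"], rep(2, 4))
  expect_equal(ms$in_degree[ms$node != "c"], rep(1, 4))
})

test_that("degree sums and betweenness match oracles on random digraphs", {
  for (i in 1:10) {
    rg <- random_digraph(sample(8:20, 1), runif(1, 0.1, 0.3), seed = 100 + i)
    m <- node_metrics(rg$net)
    expect_equal(sum(m$in_degree), igraph::ecount(rg$net))
    expect_equal(sum(m$out_degree), igraph::ecount(rg$net))
    # order metrics rows to adjacency order before comparing
    b <- m$betweenness[match(rg$nodes, m$node)]
    expect_equal(b, oracle_betweenness(rg$adj), tolerance = 1e-9)
  }
})

test_that("topology_summary on hand-enumerated graphs", {
  # complete directed graph on 4 nodes
  pairs <- expand.grid(s = letters[1:4], t = letters[1:4],
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$s != pairs$t, ]
  k4 <- gene_network(data.frame(source = pairs$s, target = pairs$t))
  ts <- topology_summary(k4, fits = FALSE)
  expect_equal(ts$diameter, 1)
  expect_equal(ts$characteristic_path_length, 1.0)
  expect_equal(ts$n_shortest_paths, 12)
  expect_equal(ts$percent_shortest_paths, 100.0)

  # directed path a -> b -> c: 3 of 6 ordered pairs reachable, CPL 4/3
  pth <- gene_network(data.frame(source = c("a", "b"), target = c("b", "c")))
  tp <- topology_summary(pth, fits = FALSE)
  expect_equal(tp$n_shortest_paths, 3)
  expect_equal(tp$percent_shortest_paths, 50.0)
  expect_equal(tp$characteristic_path_length, 4 / 3)
  expect_equal(tp$diameter, 2)
  expect_error(topology_summary(gene_network(NULL)),
               class = "emtnet_input_error")
})

test_that("powerlaw_fit recovers exact laws and degenerate cases", {
  x <- c(1, 2, 4, 8, 16)
  fit <- powerlaw_fit(x, 10 * x^(-2))
  expect_equal(fit$gamma, -2, tolerance = 1e-12)
  expect_equal(fit$R, -1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  flat <- powerlaw_fit(x, rep(3, 5))
  expect_equal(flat$gamma, 0)
  expect_true(flat$ok)

  short <- powerlaw_fit(c(1, 2), c(1, 2))
  expect_false(short$ok)
  expect_true(is.na(short$gamma))
})

test_that("powerlaw_fit equals closed-form regression on random point sets", {
  set.seed(23)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    x <- sort(runif(n, 0.5, 50))
    y <- exp(runif(n, -2, 3))
    fit <- powerlaw_fit(x, y)
    o <- oracle_loglog_fit(x, y)
    expect_equal(fit$gamma, o$gamma, tolerance = 1e-9)
    expect_equal(fit$R, o$R, tolerance = 1e-9)
    expect_equal(fit$r_squared, o$r_squared, tolerance = 1e-9)
  }
})

test_that("synthetic scale-free networks look scale-free; ER does not", {
  sf <- generate_reference_network("scale_free", n = 400, param = 2, seed = 31)
  m <- node_metrics(sf)
  pts <- table(m$total_degree[m$total_degree > 0])
  fit <- powerlaw_fit(as.numeric(names(pts)), as.numeric(pts))
  expect_lt(fit$gamma, 0)
  expect_gt(fit$r_squared, 0.7)
})
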