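#' Construct a directed gene network
#'
#' Thin constructor around an [igraph::graph_from_data_frame()] directed
#' graph. Self-loops are removed and duplicate directed edges collapsed, so
#' the result is always a simple directed graph. Every node carries a
#' `node_type` vertex attribute (`"gene"` or `"compound"`).
#'
#' @param edges `data.frame` with columns `source`, `target` and optionally
#'   `interaction` (edge label, kept as an edge attribute).
#' @param node_types Named character vector mapping node id to type. Nodes
#'   referenced by edges but missing here raise a format error. Extra
#'   (isolated) nodes in `node_types` are added to the graph.
#' @param default_type Used only when `node_types` is `NULL`: all nodes get
#'   this type (default `"gene"`).
#' @return An `igraph` object, directed and simple, with vertex attribute
#'   `node_type`, classed additionally as `gene_network`.
#' @export
gene_network <- function(edges, node_types = NULL, default_type = "gene") {
  if (is.null(edges) || nrow(edges) == 0) {
    ids <- names(node_types) %||% character(0)
    g <- igraph::make_empty_graph(n = 0, directed = TRUE)
    if (length(ids))
      g <- igraph::add_vertices(g, length(ids), name = ids,
                                node_type = unname(node_types))
    class(g) <- c("gene_network", class(g))
    return(g)
  }
  if (!all(c("source", "target") %in% names(edges)))
    stop_input("edges must have 'source' and 'target' columns")
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  ids <- unique(c(edges$source, edges$target, names(node_types)))
  if (is.null(node_types)) {
    node_types <- stats::setNames(rep(default_type, length(ids)), ids)
  } else {
    missing_ids <- setdiff(unique(c(edges$source, edges$target)),
                           names(node_types))
    if (length(missing_ids))
      stop_input("edge references %d unlabeled node(s), e.g. '%s'",
                 length(missing_ids), missing_ids[1])
  }
  cols <- c("source", "target",
            if ("interaction" %in% names(edges)) "interaction")
  g <- igraph::graph_from_data_frame(
    edges[, cols, drop = FALSE], directed = TRUE,
    vertices = data.frame(name = ids, node_type = unname(node_types[ids]),
                          stringsAsFactors = FALSE))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = "first")
  class(g) <- c("gene_network", class(g))
  g
}

as_gene_network <- function(g) {
  if (!inherits(g, "gene_network")) class(g) <- c("gene_network", class(g))
  g
}

#' Merge enriched pathways into one gene-gene network
#'
#' Takes the union of all pathway edge lists (duplicate edges across pathways
#' collapse to one), then optionally removes compound-typed nodes together
#' with their incident edges, mirroring the convention of pathway-to-graph
#' conversion where chemical compounds are dropped to keep gene-gene
#' relations only.
#'
#' @param pathways A `pathway_collection` (see
#'   [generate_pathway_collection()] / [read_sif()]).
#' @param drop_compounds Remove `node_type == "compound"` nodes; default TRUE.
#' @return A `gene_network`.
#' @export
build_network <- function(pathways, drop_compounds = TRUE) {
  stopifnot(inherits(pathways, "pathway_collection"))
  if (length(pathways$pathways) == 0)
    return(gene_network(NULL, node_types = stats::setNames(character(0), character(0))))
  edges <- do.call(rbind, lapply(pathways$pathways, function(p) p$edges))
  types <- unlist(lapply(pathways$pathways, function(p) p$node_types))
  types <- types[!duplicated(names(types))]
  g <- gene_network(edges, node_types = types)
  if (drop_compounds) {
    drop <- igraph::V(g)[igraph::V(g)$node_type == "compound"]
    g <- as_gene_network(igraph::delete_vertices(g, drop))
  }
  g
}

#' Extract the main connected component
#'
#' The largest WEAKLY connected component of the directed network (ties
#' broken by smallest component index, i.e. deterministic). The retained
#' share of nodes is reported as a percentage rounded half-up to one decimal,
#' the convention used when quoting "main component" coverage.
#'
#' @param net A `gene_network`.
#' @return The induced subgraph (a `gene_network`) with attributes
#'   `retained_percent` (numeric, 1 decimal) and `n_total` (nodes in the
#'   input).
#' @export
main_component <- function(net) {
  n_total <- igraph::vcount(net)
  if (n_total == 0) {
    warning("main_component: empty network")
    attr(net, "retained_percent") <- NA_real_
    attr(net, "n_total") <- 0L
    return(net)
  }
  comp <- igraph::components(net, mode = "weak")
  biggest <- which.max(comp$csize)
  keep <- igraph::V(net)[comp$membership == biggest]
  sub <- as_gene_network(igraph::induced_subgraph(net, keep))
  attr(sub, "retained_percent") <- round_half_up1(100 * length(keep) / n_total)
  attr(sub, "n_total") <- n_total
  sub
}

#' Per-node topological metrics
#'
#' Degrees are computed on the directed simple graph; the clustering
#' coefficient on the underlying undirected simple graph (the headline
#' convention of desktop network-analysis tools), with nodes of undirected
#' degree < 2 assigned 0; betweenness is the exact directed, unnormalized
#' shortest-path betweenness.
#'
#' @param net A `gene_network`.
#' @return `data.frame`: `node`, `in_degree`, `out_degree`, `total_degree`,
#'   `undirected_degree`, `clustering_coefficient`, `betweenness`.
#' @export
node_metrics <- function(net) {
  und <- igraph::as_undirected(net, mode = "collapse")
  cc <- igraph::transitivity(und, type = "local", isolates = "zero")
  # igraph returns NaN for degree-1 nodes in some versions; force 0
  cc[!is.finite(cc)] <- 0
  data.frame(
    node = igraph::V(net)$name,
    in_degree = igraph::degree(net, mode = "in"),
    out_degree = igraph::degree(net, mode = "out"),
    total_degree = igraph::degree(net, mode = "all"),
    undirected_degree = igraph::degree(und),
    clustering_coefficient = cc,
    betweenness = igraph::betweenness(net, directed = TRUE, normalized = FALSE),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Least-squares power-law fit on log-log axes
#'
#' Fits `log10(y) ~ log10(x)` by ordinary least squares. `gamma` is the
#' slope (negative for decaying laws), `R` the Pearson correlation of the
#' log-log points and `r_squared = R^2`.
#'
#' @param x,y Positive numeric vectors (zero-count points must be excluded
#'   by the caller).
#' @return List of class `powerlaw_fit`: `gamma`, `R`, `r_squared`,
#'   `n_points`, `ok` (FALSE when fewer than 3 valid points, all estimates
#'   NA; or when x or y is constant, in which case `gamma` is 0 for constant
#'   y and `R`/`r_squared` are NA).
#' @export
powerlaw_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  valid <- is.finite(x) & is.finite(y) & x > 0 & y > 0
  x <- x[valid]; y <- y[valid]
  if (length(x) < 3)
    return(structure(list(gamma = NA_real_, R = NA_real_,
                          r_squared = NA_real_, n_points = length(x),
                          ok = FALSE), class = "powerlaw_fit"))
  lx <- log10(x); ly <- log10(y)
  if (stats::var(lx) == 0)
    return(structure(list(gamma = NA_real_, R = NA_real_,
                          r_squared = NA_real_, n_points = length(x),
                          ok = FALSE), class = "powerlaw_fit"))
  slope <- stats::cov(lx, ly) / stats::var(lx)
  if (stats::var(ly) == 0) {
    # constant y: flat law, correlation undefined
    return(structure(list(gamma = 0, R = NA_real_, r_squared = NA_real_,
                          n_points = length(x), ok = TRUE),
                     class = "powerlaw_fit"))
  }
  R <- stats::cor(lx, ly)
  structure(list(gamma = slope, R = R, r_squared = R^2,
                 n_points = length(x), ok = TRUE), class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  if (!x$ok) cat("powerlaw_fit: insufficient/degenerate points\n")
  else cat(sprintf("powerlaw_fit: gamma = %.4f, R = %.4f, R2 = %.4f (n = %d)\n",
                   x$gamma, if (is.na(x$R)) NaN else x$R,
                   if (is.na(x$r_squared)) NaN else x$r_squared, x$n_points))
  invisible(x)
}

# Degree-frequency points (k >= 1, count > 0), no binning.
degree_distribution_points <- function(degrees) {
  tb <- table(degrees[degrees > 0])
  list(k = as.numeric(names(tb)), count = as.numeric(tb))
}

# C(k): mean clustering coefficient among nodes of undirected degree k,
# for k >= 1 with at least one node and positive mean.
ck_points <- function(metrics) {
  keep <- metrics$undirected_degree >= 1
  m <- metrics[keep, , drop = FALSE]
  if (nrow(m) == 0) return(list(k = numeric(0), ck = numeric(0)))
  agg <- tapply(m$clustering_coefficient, m$undirected_degree, mean)
  k <- as.numeric(names(agg)); ck <- as.numeric(agg)
  pos <- ck > 0
  list(k = k[pos], ck = ck[pos])
}

#' Global topological panel
#'
#' Summary statistics of a directed gene network, following desktop network
#' analyzer conventions: weak connected components; diameter = longest finite
#' directed shortest path; shortest-path census = number of ordered reachable
#' pairs (u != v) with its percentage of all n(n-1) ordered pairs;
#' characteristic path length = mean distance over reachable ordered pairs;
#' average neighbors = mean undirected degree; power-law fits of the in- and
#' out-degree frequency distributions and of C(k) vs k.
#'
#' @param net A nonempty `gene_network`.
#' @param fits Compute the three power-law fits (default TRUE; turn off for
#'   speed in property tests).
#' @return List of class `topology_summary`.
#' @export
topology_summary <- function(net, fits = TRUE) {
  n <- igraph::vcount(net)
  if (n == 0) stop_input("topology_summary: empty network")
  metrics <- node_metrics(net)
  d <- igraph::distances(net, mode = "out")
  diag(d) <- Inf
  finite <- is.finite(d)
  n_paths <- sum(finite)
  cpl <- if (n_paths > 0) mean(d[finite]) else NA_real_
  diam <- if (n_paths > 0) max(d[finite]) else 0
  res <- list(
    n_nodes = n,
    n_edges = igraph::ecount(net),
    mean_clustering_coefficient = mean(metrics$clustering_coefficient),
    n_connected_components = igraph::components(net, mode = "weak")$no,
    diameter = diam,
    n_shortest_paths = n_paths,
    percent_shortest_paths =
      if (n > 1) round_half_up1(100 * n_paths / (n * (n - 1))) else 0,
    characteristic_path_length = cpl,
    avg_neighbors = mean(metrics$undirected_degree))
  if (fits) {
    din <- degree_distribution_points(metrics$in_degree)
    dout <- degree_distribution_points(metrics$out_degree)
    ck <- ck_points(metrics)
    res$degree_fit_in <- powerlaw_fit(din$k, din$count)
    res$degree_fit_out <- powerlaw_fit(dout$k, dout$count)
    res$ck_fit <- powerlaw_fit(ck$k, ck$ck)
  }
  structure(res, class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf("Number of nodes\t%d\n", x$n_nodes))
  cat(sprintf("Number of edges\t%d\n", x$n_edges))
  cat(sprintf("Clustering coefficient\t%.3f\n", x$mean_clustering_coefficient))
  cat(sprintf("Connected component\t%d\n", x$n_connected_components))
  cat(sprintf("Network diameter\t%g\n", x$diameter))
  cat(sprintf("Shortest paths\t%d (%.1f%%)\n", x$n_shortest_paths,
              x$percent_shortest_paths))
  cat(sprintf("Characteristic path length\t%.3f\n",
              x$characteristic_path_length))
  cat(sprintf("Avg. number of neighbors\t%.3f\n", x$avg_neighbors))
  if (!is.null(x$degree_fit_in)) {
    fmt <- function(f) if (isTRUE(f$ok))
      sprintf("gamma %.3f R %.3f R2 %.3f", f$gamma, f$R, f$r_squared)
      else "not fit"
    cat(sprintf("In-degree distribution\t%s\n", fmt(x$degree_fit_in)))
    cat(sprintf("Out-degree distribution\t%s\n", fmt(x$degree_fit_out)))
    cat(sprintf("C(k) vs k\t%s\n", fmt(x$ck_fit)))
  }
  invisible(x)
}
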