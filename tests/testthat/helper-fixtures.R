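# Shared in-code fixtures.

# Tiny two-condition study from explicit per-condition row values.
toy_study <- function(values_a, values_b, genes = NULL) {
  stopifnot(nrow(values_a) == nrow(values_b))
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values_a)))
  m <- cbind(values_a, values_b)
  rownames(m) <- genes
  expression_study(m, rep(c("a", "b"), c(ncol(values_a), ncol(values_b))))
}

# Hand-written de_table row set (bypasses the test; for call_degs etc.).
hand_de_table <- function(gene_id, log2fc, q_value, mean_a = 10,
                          mean_b = 10, inf_fc = FALSE, p_value = q_value) {
  df <- data.frame(gene_id = gene_id, mean_a = mean_a, mean_b = mean_b,
                   log2fc = log2fc, inf_fc = inf_fc, p_value = p_value,
                   q_value = q_value, row.names = NULL,
                   stringsAsFactors = FALSE)
  class(df) <- c("de_table", "data.frame")
  df
}

# Pathway record from an edge matrix (2 columns: source, target).
# extra_nodes: labeled members without edges (legal in SIF node tables).
hand_pathway <- function(id, edges, compound_nodes = character(0),
                         extra_nodes = character(0)) {
  e <- data.frame(source = edges[, 1], interaction = "i",
                  target = edges[, 2], stringsAsFactors = FALSE)
  nodes <- unique(c(e$source, e$target, extra_nodes))
  types <- setNames(ifelse(nodes %in% compound_nodes, "compound", "gene"),
                    nodes)
  list(id = id, name = id, edges = e, node_types = types)
}

# node_metrics-shaped table built by hand.
hand_metrics <- function(node, total_degree, betweenness = 0,
                         clustering_coefficient = 0) {
  data.frame(node = node, in_degree = 0L, out_degree = 0L,
             total_degree = total_degree,
             undirected_degree = total_degree,
             clustering_coefficient = clustering_coefficient,
             betweenness = betweenness,
             row.names = NULL, stringsAsFactors = FALSE)
}
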