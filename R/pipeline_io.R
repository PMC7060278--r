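#' Read / write an expression study as TSV
#'
#' Dialect: first column `gene_id`, one column per sample named
#' `<condition>_<replicate>`.
#'
#' @param study An [expression_study()].
#' @param path File path.
#' @return `write_expression_tsv()` returns `path` invisibly;
#'   `read_expression_tsv()` returns an [expression_study()].
#' @export
write_expression_tsv <- function(study, path) {
  stopifnot(inherits(study, "expression_study"))
  df <- data.frame(gene_id = study$genes, study$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop_io("no such file: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop_io("%s: first column must be gene_id", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  conditions <- sub("_[0-9]+$", "", colnames(m))
  expression_study(m, conditions)
}

#' Read / write pathway SIF files
#'
#' SIF dialect: `source <tab> interaction <tab> target`, one edge per line,
#' no header. Node types live in a companion TSV with header
#' `node_id <tab> node_type` (`gene` or `compound`).
#'
#' `read_sif()` reads one SIF file into a single-pathway
#' [pathway_collection()] fragment; `read_sif_dir()` reads every `*.sif` in a
#' directory (each file one pathway, sharing one node-type table).
#'
#' @param edges_or_net A pathway record's `edges` data.frame, or a
#'   `gene_network` (whose edge list is then written).
#' @param path SIF file path (for `read_sif_dir()`: a directory).
#' @param node_types_path Companion node-type TSV path; `NULL` in
#'   `read_sif()` types every node `"gene"`.
#' @param id Pathway id for the fragment; defaults to the file name.
#' @return `read_sif()`/`read_sif_dir()`: a `pathway_collection`.
#' @export
write_sif <- function(edges_or_net, path) {
  edges <- if (inherits(edges_or_net, "gene_network")) {
    e <- igraph::as_data_frame(edges_or_net, what = "edges")
    data.frame(source = e$from,
               interaction = if ("interaction" %in% names(e)) e$interaction
                             else "interacts",
               target = e$to, stringsAsFactors = FALSE)
  } else edges_or_net
  utils::write.table(edges[, c("source", "interaction", "target")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a node-type table
#' @param node_types Named character vector (node id -> type).
#' @param path Output TSV path.
#' @export
write_node_types <- function(node_types, path) {
  utils::write.table(
    data.frame(node_id = names(node_types), node_type = unname(node_types),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_node_types <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("node_id", "node_type") %in% names(df)))
    stop_io("%s: expected columns node_id, node_type", path)
  stats::setNames(df$node_type, df$node_id)
}

#' @rdname write_sif
#' @export
read_sif <- function(path, node_types_path = NULL, id = NULL) {
  if (!file.exists(path)) stop_io("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 3L)
  if (length(bad))
    stop_io("%s: malformed SIF line %d (need 3 tab-separated fields)",
            path, bad[1])
  edges <- data.frame(source = vapply(parts, `[[`, character(1), 1),
                      interaction = vapply(parts, `[[`, character(1), 2),
                      target = vapply(parts, `[[`, character(1), 3),
                      stringsAsFactors = FALSE)
  nodes <- unique(c(edges$source, edges$target))
  types <- if (is.null(node_types_path))
    stats::setNames(rep("gene", length(nodes)), nodes)
  else read_node_types(node_types_path)
  id <- id %||% sub("\\.sif$", "", basename(path))
  pathway_collection(list(list(id = id, name = id, edges = edges,
                               node_types = types[nodes])))
}

#' @rdname write_sif
#' @export
read_sif_dir <- function(path, node_types_path = NULL) {
  if (!dir.exists(path)) stop_io("no such directory: %s", path)
  files <- sort(list.files(path, pattern = "\\.sif$", full.names = TRUE))
  if (length(files) == 0) stop_io("no .sif files in %s", path)
  frags <- lapply(files, read_sif, node_types_path = node_types_path)
  pathway_collection(lapply(frags, function(f) f$pathways[[1]]))
}

#' Write a pathway collection as SIF files plus a node-type TSV
#'
#' @param collection A `pathway_collection`.
#' @param dir Output directory (created if missing). One `<id>.sif` per
#'   pathway plus `node_types.tsv`.
#' @export
write_pathway_collection <- function(collection, dir) {
  stopifnot(inherits(collection, "pathway_collection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_types <- character(0)
  for (p in collection$pathways) {
    write_sif(p$edges, file.path(dir, paste0(p$id, ".sif")))
    all_types <- c(all_types, p$node_types[setdiff(names(p$node_types),
                                                   names(all_types))])
  }
  write_node_types(all_types, file.path(dir, "node_types.tsv"))
  invisible(dir)
}

#' Read / write gene sets in GMT format
#'
#' GMT: one set per line, `set_id <tab> description <tab> member...`. A line
#' with no members is retained as an empty set with a warning.
#'
#' @param path File path.
#' @param universe Gene universe for the resulting collection; defaults to
#'   the union of all members.
#' @param sets Named list of member vectors (for writing).
#' @param descriptions Optional descriptions (for writing).
#' @return `read_gmt()`: a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop_io("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad))
    stop_io("%s: malformed GMT line %d (need at least id and description)",
            path, bad[1])
  ids <- vapply(parts, `[[`, character(1), 1)
  desc <- vapply(parts, `[[`, character(1), 2)
  members <- lapply(parts, function(p) if (length(p) > 2) p[-(1:2)]
                                       else character(0))
  empty <- vapply(members, length, integer(1)) == 0
  if (any(empty))
    warning(sprintf("read_gmt: %d set(s) with 0 members retained", sum(empty)))
  if (is.null(universe)) universe <- unique(unlist(members))
  gene_set_collection(stats::setNames(members, ids), universe,
                      descriptions = desc)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Cuffdiff-style differential table
#'
#' Accepts the `gene_exp.diff` dialect: tab-separated with a header row and
#' at least the columns `gene`, `value_1`, `value_2`, `log2(fold_change)`,
#' `p_value`, `q_value`. Extra columns are ignored with a warning listing
#' them. `inf`/`-inf` fold changes become the infinite-fold-change flag; for
#' those rows the numeric `log2fc` is recomputed with pseudocount 1 so
#' downstream sorting stays finite.
#'
#' @param path File path.
#' @return A `de_table` (see [simple_de_test()]).
#' @export
read_diff <- function(path) {
  if (!file.exists(path)) stop_io("no such file: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene", "value_1", "value_2", "log2(fold_change)", "p_value",
            "q_value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_io("%s: missing column(s): %s", path,
            paste(missing_cols, collapse = ", "))
  known <- c("test_id", need, "significant", "gene_id", "locus", "sample_1",
             "sample_2", "status", "test_stat")
  extra <- setdiff(names(df), known)
  if (length(extra))
    warning(sprintf("read_diff: ignoring column(s): %s",
                    paste(extra, collapse = ", ")))
  lfc_raw <- df[["log2(fold_change)"]]
  if (is.character(lfc_raw)) {
    lfc_raw <- gsub("(?i)^-?inf$", NA, lfc_raw, perl = TRUE)
    lfc_raw <- suppressWarnings(as.numeric(lfc_raw))
  }
  mean_a <- df$value_1; mean_b <- df$value_2
  inf_fc <- xor(mean_a == 0, mean_b == 0) & (mean_a > 0 | mean_b > 0)
  lfc <- ifelse(is.finite(lfc_raw) & !inf_fc, lfc_raw,
                log2((mean_b + 1) / (mean_a + 1)))
  out <- data.frame(gene_id = as.character(df$gene),
                    mean_a = mean_a, mean_b = mean_b, log2fc = lfc,
                    inf_fc = inf_fc, p_value = df$p_value,
                    q_value = df$q_value,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Write a table as TSV with stable column order
#' @param x A data.frame (e.g. `deg_table`, `controller_table`, enrichment
#'   table).
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Exactly one input route must be given: `synth` (a [synth_config()]) or
#' real-format paths (`expression_path` or `diff_path`, plus `sif_dir` and
#' optionally `gmt_path`).
#'
#' @param synth A [synth_config()] or `NULL`.
#' @param expression_path,diff_path,gmt_path,sif_dir,node_types_path Input
#'   file paths (real-input route).
#' @param q_max,fc_min DEG thresholds (defaults 0.05, 1).
#' @param go_q,kegg_q Enrichment q ceilings for the GO-style and
#'   pathway-style screens (defaults 0.01, 0.05).
#' @param bottleneck_k Bottleneck count (default 200).
#' @param hub_sd_multiplier Hub rule multiplier (default 1).
#' @param kde A [kde_config()].
#' @param min_fpkm,min_replicate_fraction Expression-filter settings.
#' @param n_pathways,mean_size,compound_fraction Synthetic pathway settings
#'   (synthetic route only).
#' @param out_dir Output directory.
#' @param seed Integer seed (drives pathway generation in the synthetic
#'   route).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = NULL, expression_path = NULL,
                            diff_path = NULL, gmt_path = NULL, sif_dir = NULL,
                            node_types_path = NULL,
                            q_max = 0.05, fc_min = 1.0, go_q = 0.01,
                            kegg_q = 0.05, bottleneck_k = 200,
                            hub_sd_multiplier = 1.0, kde = kde_config(),
                            min_fpkm = 0.1, min_replicate_fraction = 1.0,
                            n_pathways = 24, mean_size = 60,
                            compound_fraction = 0.1,
                            out_dir = NULL, seed = 1) {
  real <- !is.null(expression_path) || !is.null(diff_path)
  if (is.null(synth) == !real)
    stop_config("exactly one of synth config or real input paths required")
  if (!is.null(synth)) stopifnot(inherits(synth, "synth_config"))
  if (real && is.null(sif_dir))
    stop_config("real-input route requires sif_dir (pathway edge lists)")
  structure(list(synth = synth, expression_path = expression_path,
                 diff_path = diff_path, gmt_path = gmt_path,
                 sif_dir = sif_dir, node_types_path = node_types_path,
                 q_max = q_max, fc_min = fc_min, go_q = go_q, kegg_q = kegg_q,
                 bottleneck_k = bottleneck_k,
                 hub_sd_multiplier = hub_sd_multiplier, kde = kde,
                 min_fpkm = min_fpkm,
                 min_replicate_fraction = min_replicate_fraction,
                 n_pathways = n_pathways, mean_size = mean_size,
                 compound_fraction = compound_fraction,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Chains every stage: input (synthetic or files) -> expression filter and
#' Venn partition -> stand-in differential test (unless a precomputed diff
#' table is supplied) -> DEG calling -> pathway over-representation ->
#' network construction from enriched pathways -> main component -> node
#' metrics and topology panel -> hubs, bottlenecks, KDE local hubs ->
#' evidence integration. Every filtering stage logs its in/out counts via
#' `message()`. If `out_dir` is set, stage outputs are written there
#' (`expression.tsv` when synthetic, `degs.tsv`, `venn.tsv`,
#' `enrichment_pathways.tsv`, `network.sif`, `network_node_types.tsv`,
#' `network.graphml`, `topology.tsv`, `controllers.tsv`, `manifest.json`).
#'
#' @param cfg A [pipeline_config()].
#' @return A `run_manifest`: list with `config` echo, per-stage `counts`,
#'   `results` (the in-memory stage objects), `tool_version` and per-stage
#'   `wall_clock_s`. Identical config and seed give identical results and
#'   identical manifests up to the wall-clock fields.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timing <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timing[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  counts <- list()

  # --- stage 1: inputs -------------------------------------------------
  truth <- NULL; study <- NULL; det <- NULL
  if (!is.null(cfg$synth)) {
    gen <- generate_expression(cfg$synth)
    study <- gen$study; truth <- gen$truth
  } else if (!is.null(cfg$expression_path)) {
    study <- read_expression_tsv(cfg$expression_path)
  }
  if (!is.null(cfg$diff_path)) det <- read_diff(cfg$diff_path)
  counts$genes_in <- if (!is.null(study)) length(study$genes) else nrow(det)
  message(sprintf("input: %d genes", counts$genes_in))
  tick("input")

  # --- stage 2: expression filter + DEGs -------------------------------
  venn <- NULL
  if (!is.null(study)) {
    venn <- venn_partition(study, cfg$min_fpkm, cfg$min_replicate_fraction)
    counts$expressed <- counts$genes_in - length(venn$excluded)
    message(sprintf("expression filter: %d -> %d genes (common %d, specific %d/%d)",
                    counts$genes_in, counts$expressed, length(venn$common),
                    length(venn$specific_a), length(venn$specific_b)))
    if (is.null(det)) det <- simple_de_test(study)
  } else {
    counts$expressed <- nrow(det)
  }
  degs <- call_degs(det, q_max = cfg$q_max, fc_min = cfg$fc_min)
  ds <- deg_summary(degs)
  counts$degs_total <- ds$total
  counts$degs_up_in_a <- ds$up_in_a
  counts$degs_up_in_b <- ds$up_in_b
  counts$degs_exclusive_a <- ds$exclusive_a
  counts$degs_exclusive_b <- ds$exclusive_b
  message(sprintf("DEGs: %d total (%d up in a, %d up in b; %d/%d exclusive)",
                  ds$total, ds$up_in_a, ds$up_in_b, ds$exclusive_a,
                  ds$exclusive_b))
  tick("degs")

  # --- stage 3: pathways + enrichment ----------------------------------
  if (!is.null(cfg$synth)) {
    universe_genes <- if (!is.null(venn))
      setdiff(study$genes, venn$excluded) else degs$gene_id
    pathways <- generate_pathway_collection(
      n_pathways = cfg$n_pathways, genes = study$genes,
      mean_size = cfg$mean_size, compound_fraction = cfg$compound_fraction,
      seed = cfg$seed, hub_genes = truth$controller_genes,
      de_genes = names(truth$de_genes))
  } else {
    pathways <- read_sif_dir(cfg$sif_dir, cfg$node_types_path)
    universe_genes <- if (!is.null(venn))
      setdiff(study$genes, venn$excluded) else degs$gene_id
  }
  collection <- if (!is.null(cfg$gmt_path))
    read_gmt(cfg$gmt_path, universe = universe_genes)
  else
    suppressMessages(gene_set_collection(pathway_members(pathways),
                                         universe = universe_genes))
  deg_ids <- degs$gene_id[degs$is_deg]
  enr <- suppressMessages(enrich(deg_ids, collection,
                                 q_threshold = cfg$kegg_q))
  counts$enriched_sets <- sum(enr$enriched)
  enriched_ids <- enr$set_id[enr$enriched]
  message(sprintf("enrichment: %d / %d sets enriched at q <= %g",
                  counts$enriched_sets, nrow(enr), cfg$kegg_q))
  tick("enrichment")

  # --- stage 4: network + topology -------------------------------------
  pw_ids <- vapply(pathways$pathways, `[[`, character(1), "id")
  selected <- pathways
  if (length(enriched_ids) > 0) {
    selected <- pathway_collection(
      pathways$pathways[pw_ids %in% enriched_ids])
  } else {
    warning("no enriched pathway; building network from all pathways")
  }
  net <- build_network(selected, drop_compounds = TRUE)
  counts$network_nodes <- igraph::vcount(net)
  counts$network_edges <- igraph::ecount(net)
  mc <- main_component(net)
  counts$mc_nodes <- igraph::vcount(mc)
  counts$mc_percent <- attr(mc, "retained_percent")
  message(sprintf("network: %d nodes / %d edges; MC %d nodes (%.1f%%)",
                  counts$network_nodes, counts$network_edges,
                  counts$mc_nodes, counts$mc_percent))
  metrics <- node_metrics(mc)
  topo <- topology_summary(mc)
  tick("network")

  # --- stage 5: controllers --------------------------------------------
  hubs <- find_hubs(metrics, hub_rule(cfg$hub_sd_multiplier))
  bottlenecks <- suppressWarnings(find_bottlenecks(metrics,
                                                   cfg$bottleneck_k))
  local_hubs <- suppressWarnings(find_local_hubs(hubs, metrics, cfg$kde))
  controllers <- integrate_evidence(degs, hubs, bottlenecks, local_hubs)
  counts$hubs <- length(hubs)
  counts$bottlenecks <- length(bottlenecks)
  counts$local_hubs <- length(local_hubs)
  inter <- attr(controllers, "intersections")
  counts$hub_bottleneck <- inter$hub_bottleneck
  counts$controller_candidates <- inter$hub_bottleneck_deg
  message(sprintf("controllers: %d hubs, %d bottlenecks, %d local hubs -> %d hub-bottleneck-DEG candidates",
                  counts$hubs, counts$bottlenecks, counts$local_hubs,
                  counts$controller_candidates))
  tick("controllers")

  manifest <- structure(list(
    tool_version = as.character(utils::packageVersion("emtnetctrl")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("synth", "kde"))],
    synth = if (!is.null(cfg$synth)) unclass(cfg$synth),
    counts = counts,
    wall_clock_s = timing), class = "run_manifest")
  results <- list(study = study, truth = truth, venn = venn, degs = degs,
                  enrichment = enr, pathways = pathways, network = net,
                  main_component = mc, metrics = metrics, topology = topo,
                  hubs = hubs, bottlenecks = bottlenecks,
                  local_hubs = local_hubs, controllers = controllers,
                  manifest = manifest)

  if (!is.null(cfg$out_dir)) write_pipeline_outputs(results, cfg$out_dir)
  manifest$results <- results
  manifest
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  if (!is.null(res$study)) write_expression_tsv(res$study, p("expression.tsv"))
  if (!is.null(res$venn)) {
    v <- res$venn
    venn_df <- data.frame(
      gene = c(v$common, v$specific_a, v$specific_b, v$excluded),
      class = rep(c("common", "specific_a", "specific_b", "excluded"),
                  c(length(v$common), length(v$specific_a),
                    length(v$specific_b), length(v$excluded))),
      stringsAsFactors = FALSE)
    write_tsv(venn_df[order(venn_df$gene), ], p("venn.tsv"))
  }
  write_tsv(res$degs, p("degs.tsv"))
  write_tsv(res$enrichment, p("enrichment_pathways.tsv"))
  write_sif(res$network, p("network.sif"))
  write_node_types(
    stats::setNames(igraph::V(res$network)$node_type,
                    igraph::V(res$network)$name),
    p("network_node_types.tsv"))
  igraph::write_graph(res$network, p("network.graphml"), format = "graphml")
  topo <- res$topology
  topo_df <- data.frame(
    parameter = c("Number of nodes", "Number of edges",
                  "Clustering coefficient", "Connected component",
                  "Network diameter", "Shortest paths",
                  "Shortest paths percent", "Characteristic path length",
                  "Avg. number of neighbors",
                  "In-degree gamma", "In-degree R", "In-degree R2",
                  "Out-degree gamma", "Out-degree R", "Out-degree R2",
                  "C(k) gamma", "C(k) R", "C(k) R2"),
    value = c(topo$n_nodes, topo$n_edges,
              topo$mean_clustering_coefficient, topo$n_connected_components,
              topo$diameter, topo$n_shortest_paths,
              topo$percent_shortest_paths, topo$characteristic_path_length,
              topo$avg_neighbors,
              topo$degree_fit_in$gamma, topo$degree_fit_in$R,
              topo$degree_fit_in$r_squared,
              topo$degree_fit_out$gamma, topo$degree_fit_out$R,
              topo$degree_fit_out$r_squared,
              topo$ck_fit$gamma, topo$ck_fit$R, topo$ck_fit$r_squared),
    stringsAsFactors = FALSE)
  write_tsv(topo_df, p("topology.tsv"))
  write_tsv(res$controllers, p("controllers.tsv"))
  m <- res$manifest
  jsonlite::write_json(unclass(m), p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(out_dir)
}
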