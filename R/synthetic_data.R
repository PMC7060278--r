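#' Synthetic-study configuration
#'
#' Describes the generated two-condition expression study: negative-binomial
#' abundances on the FPKM scale with planted fold changes, planted
#' condition-exclusive genes (hard zeros in the other condition), and a
#' subset of DE genes designated ground-truth "controller" genes (these are
#' additionally wired as high-degree targets by
#' [generate_pathway_collection()]).
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per condition; default 3 (the typical
#'   replicated cell-culture design).
#' @param de_fraction Fraction of genes with a planted fold change, in
#'   `[0, 1]`.
#' @param effect_log2fc Planted `|log2 fold change|` for DE genes
#'   (direction random per gene).
#' @param exclusive_per_condition Genes expressed in exactly one condition
#'   (zero in every replicate of the other), per condition.
#' @param dispersion Negative-binomial overdispersion (`size = 1/dispersion`).
#' @param baseline_mean Baseline FPKM-scale mean.
#' @param n_controllers Number of controller genes planted among the DE
#'   genes; default 0.
#' @param seed Integer seed; identical configs (including seed) give
#'   byte-identical output.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_genes, n_replicates = 3, de_fraction = 0,
                         effect_log2fc = 0, exclusive_per_condition = 0,
                         dispersion = 0.1, baseline_mean = 100,
                         n_controllers = 0, seed = 1) {
  chk <- function(ok, msg, ...) if (!ok) stop_config(msg, ...)
  chk(is.numeric(n_genes) && n_genes >= 1 && n_genes == floor(n_genes),
      "n_genes must be a positive integer")
  chk(n_replicates >= 2 && n_replicates == floor(n_replicates),
      "n_replicates must be an integer >= 2")
  chk(de_fraction >= 0 && de_fraction <= 1, "de_fraction must be in [0, 1]")
  chk(effect_log2fc >= 0, "effect_log2fc must be >= 0")
  chk(exclusive_per_condition >= 0 &&
        exclusive_per_condition == floor(exclusive_per_condition),
      "exclusive_per_condition must be a nonnegative integer")
  chk(dispersion > 0, "dispersion must be > 0")
  chk(baseline_mean > 0, "baseline_mean must be > 0")
  n_de <- round(de_fraction * n_genes)
  chk(n_de + 2 * exclusive_per_condition <= n_genes,
      "violated: de_fraction*n_genes + 2*exclusive_per_condition <= n_genes (%d + %d > %d)",
      n_de, 2 * exclusive_per_condition, n_genes)
  chk(n_controllers >= 0 && n_controllers <= n_de,
      "n_controllers must be between 0 and the number of DE genes (%d)", n_de)
  structure(list(n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 de_fraction = de_fraction, effect_log2fc = effect_log2fc,
                 exclusive_per_condition = as.integer(exclusive_per_condition),
                 dispersion = dispersion, baseline_mean = baseline_mean,
                 n_controllers = as.integer(n_controllers),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Reference synthetic configuration
#'
#' The package's frozen "stated world" for end-to-end validation: 2000
#' genes, 3 replicates per condition, 10% DE at a strong planted effect
#' (|log2FC| = 4), 10 exclusive genes per condition, clonal-cell-culture
#' dispersion 0.02, baseline mean 150 FPKM, 20 planted controller genes.
#' See the methods vignette for the rationale behind each value.
#'
#' @param seed Integer seed.
#' @return A [synth_config()].
#' @export
reference_synth_config <- function(seed = 1) {
  synth_config(n_genes = 2000, n_replicates = 3, de_fraction = 0.1,
               effect_log2fc = 4, exclusive_per_condition = 10,
               dispersion = 0.02, baseline_mean = 150, n_controllers = 20,
               seed = seed)
}

#' Generate a synthetic two-condition expression study
#'
#' Draws negative-binomial abundances for two conditions (`"a"`, `"b"`) with
#' `n_replicates` each. DE genes have condition-b mean equal to the
#' condition-a mean times `2^(+/- effect_log2fc)`; exclusive genes are
#' expressed in one condition and hard-zero in every replicate of the other;
#' controller genes are the first `n_controllers` of the planted DE genes.
#'
#' @param config A [synth_config()].
#' @return List with `study` (an [expression_study()]) and `truth` (class
#'   `ground_truth`: `de_genes` named character vector gene -> direction
#'   (`"up_in_a"`/`"up_in_b"`), `exclusive_genes` list with elements `a` and
#'   `b`, `controller_genes` character vector).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  ng <- config$n_genes; nr <- config$n_replicates
  genes <- sprintf("g%05d", seq_len(ng))
  n_de <- round(config$de_fraction * ng)
  n_ex <- config$exclusive_per_condition
  special <- sample(genes, n_de + 2 * n_ex)
  de_genes <- special[seq_len(n_de)]
  ex_a <- special[n_de + seq_len(n_ex)]
  ex_b <- special[n_de + n_ex + seq_len(n_ex)]
  up_in_b <- if (n_de) sample(c(TRUE, FALSE), n_de, replace = TRUE) else logical(0)
  controllers <- de_genes[seq_len(config$n_controllers)]

  mu_a <- stats::setNames(rep(config$baseline_mean, ng), genes)
  mu_b <- mu_a
  mu_b[de_genes] <- mu_a[de_genes] * 2^(ifelse(up_in_b, 1, -1) *
                                          config$effect_log2fc)
  size <- 1 / config$dispersion
  draw <- function(mu) matrix(stats::rnbinom(ng * nr, mu = rep(mu, nr),
                                             size = size), ng, nr)
  A <- draw(mu_a); B <- draw(mu_b)
  rownames(A) <- rownames(B) <- genes
  A[ex_b, ] <- 0  # exclusive-to-b genes: silent in condition a
  B[ex_a, ] <- 0
  values <- cbind(A, B)
  colnames(values) <- c(paste0("a_", seq_len(nr)), paste0("b_", seq_len(nr)))
  study <- expression_study(values, rep(c("a", "b"), each = nr))
  dirs <- if (n_de) ifelse(up_in_b, "up_in_b", "up_in_a") else character(0)
  truth <- structure(list(
    de_genes = stats::setNames(dirs, de_genes),
    exclusive_genes = list(a = ex_a, b = ex_b),
    controller_genes = controllers), class = "ground_truth")
  list(study = study, truth = truth)
}

#' Construct a pathway collection
#'
#' @param pathways List of pathway records; each a list with `id`, `name`,
#'   `edges` (`data.frame` with `source`, `interaction`, `target`) and
#'   `node_types` (named character vector over the pathway's nodes, values
#'   `"gene"` or `"compound"`).
#' @return Object of class `pathway_collection`.
#' @export
pathway_collection <- function(pathways) {
  for (p in pathways) {
    stopifnot(all(c("id", "edges", "node_types") %in% names(p)))
    ends <- unique(c(p$edges$source, p$edges$target))
    bad <- setdiff(ends, names(p$node_types))
    if (length(bad))
      stop_input("pathway '%s': edge references unlabeled node '%s'",
                 p$id, bad[1])
  }
  structure(list(pathways = pathways), class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d pathway(s)\n", length(x$pathways)))
  invisible(x)
}

#' Gene members (non-compound nodes) of each pathway
#'
#' @param collection A `pathway_collection`.
#' @return Named list of character vectors.
#' @export
pathway_members <- function(collection) {
  stopifnot(inherits(collection, "pathway_collection"))
  stats::setNames(
    lapply(collection$pathways, function(p)
      names(p$node_types)[p$node_types == "gene"]),
    vapply(collection$pathways, `[[`, character(1), "id"))
}

# Random weakly-connected directed scaffold over `nodes`: a random
# arborescence (each node links to one earlier node) plus `extra` random
# directed edges, directions uniform.
random_pathway_edges <- function(nodes, extra_factor = 0.6) {
  n <- length(nodes)
  if (n < 2) return(data.frame(source = character(0),
                               interaction = character(0),
                               target = character(0),
                               stringsAsFactors = FALSE))
  from <- to <- character(0)
  for (i in 2:n) {
    j <- if (i == 2) 1L else sample.int(i - 1L, 1L)
    from <- c(from, nodes[j]); to <- c(to, nodes[i])
  }
  n_extra <- round(extra_factor * n)
  if (n_extra > 0) {
    s <- nodes[sample.int(n, n_extra, replace = TRUE)]
    t <- nodes[sample.int(n, n_extra, replace = TRUE)]
    keep <- s != t
    from <- c(from, s[keep]); to <- c(to, t[keep])
  }
  flip <- sample(c(TRUE, FALSE), length(from), replace = TRUE)
  data.frame(source = ifelse(flip, to, from),
             interaction = "interacts",
             target = ifelse(flip, from, to), stringsAsFactors = FALSE)
}

#' Generate a synthetic pathway collection
#'
#' Emulates a set of enriched signaling/metabolic pathways as directed edge
#' lists whose union graph has heavy-tailed degree structure. A fraction of
#' pathways (`enriched_fraction`) is "signal-bearing": their membership is
#' biased toward `de_genes` (sampling weight `de_weight`) and every
#' `hub_genes` entry is included and wired to each other member with
#' probability `hub_connect_prob` - giving planted controller genes high
#' degree and betweenness in the union graph. The remaining pathways sample
#' members uniformly. Optionally, a share of each pathway's nodes are
#' chemical compounds (dropped later by [build_network()]).
#'
#' @param n_pathways Number of pathways.
#' @param genes Gene-id universe (nonempty).
#' @param mean_size Mean number of gene members per pathway (Poisson,
#'   truncated at 3).
#' @param compound_fraction Fraction of each pathway's nodes that are
#'   compounds, in `[0, 1)`; default 0.
#' @param seed Integer seed.
#' @param hub_genes Gene ids to plant as high-degree targets (typically
#'   `truth$controller_genes`); default none.
#' @param de_genes Gene ids upweighted in signal-bearing pathway
#'   membership; default none.
#' @param de_weight Sampling weight multiplier for `de_genes`; default 6.
#' @param enriched_fraction Fraction of pathways that are signal-bearing;
#'   default 0.5.
#' @param hub_connect_prob Probability that a planted hub connects to any
#'   given co-member; default 0.5.
#' @return A [pathway_collection()]. Pathway ids are `pw01`, `pw02`, ...;
#'   the attribute `"signal_pathways"` lists the signal-bearing ids.
#' @export
generate_pathway_collection <- function(n_pathways, genes, mean_size,
                                        compound_fraction = 0, seed = 1,
                                        hub_genes = character(0),
                                        de_genes = character(0),
                                        de_weight = 6,
                                        enriched_fraction = 0.5,
                                        hub_connect_prob = 0.5) {
  if (length(genes) == 0) stop_input("empty gene universe")
  if (n_pathways < 1 || n_pathways != floor(n_pathways))
    stop_config("n_pathways must be a positive integer")
  if (compound_fraction < 0 || compound_fraction >= 1)
    stop_config("compound_fraction must be in [0, 1)")
  set.seed(seed)
  hub_genes <- intersect(hub_genes, genes)
  n_signal <- round(enriched_fraction * n_pathways)
  w <- stats::setNames(rep(1, length(genes)), genes)
  w[intersect(de_genes, genes)] <- de_weight
  pws <- lapply(seq_len(n_pathways), function(i) {
    signal <- i <= n_signal
    size <- max(3L, stats::rpois(1, mean_size))
    size <- min(size, length(genes))
    members <- if (signal)
      sample(genes, size, prob = w)
    else
      sample(genes, size)
    if (signal && length(hub_genes))
      members <- unique(c(members, hub_genes))
    n_cpd <- round(compound_fraction * length(members) /
                     (1 - compound_fraction))
    compounds <- if (n_cpd > 0) sprintf("cpd_p%02d_%03d", i, seq_len(n_cpd))
                 else character(0)
    nodes <- sample(c(members, compounds)) # shuffle so compounds mix in
    edges <- random_pathway_edges(nodes)
    if (signal && length(hub_genes)) {
      others <- setdiff(members, hub_genes)
      for (h in hub_genes) {
        tgt <- others[stats::runif(length(others)) < hub_connect_prob]
        if (length(tgt)) {
          flip <- sample(c(TRUE, FALSE), length(tgt), replace = TRUE)
          edges <- rbind(edges, data.frame(
            source = ifelse(flip, tgt, h), interaction = "interacts",
            target = ifelse(flip, h, tgt), stringsAsFactors = FALSE))
        }
      }
    }
    list(id = sprintf("pw%02d", i),
         name = sprintf("synthetic pathway %02d%s", i,
                        if (signal) " (signal)" else ""),
         edges = edges,
         node_types = stats::setNames(
           c(rep("gene", length(members)), rep("compound", length(compounds))),
           c(members, compounds)))
  })
  out <- pathway_collection(pws)
  attr(out, "signal_pathways") <- sprintf("pw%02d", seq_len(n_signal))
  out
}

#' Generate a reference network
#'
#' `model = "scale_free"`: preferential attachment starting from `param = m`
#' initial unconnected nodes; each subsequent node attaches to `m` distinct
#' existing nodes with probability proportional to degree + 1, giving
#' exactly `m * (n - m)` edges and a heavy-tailed degree distribution.
#' `model = "random"`: Erdos-Renyi with independent edge probability
#' `param = p`. Either way each edge receives a uniform random direction and
#' the result is a simple directed `gene_network`.
#'
#' @param model `"scale_free"` or `"random"`.
#' @param n Number of nodes (>= 3).
#' @param param Attachment count `m` (integer, `< n`) for `scale_free`;
#'   edge probability for `random`.
#' @param seed Integer seed.
#' @return A `gene_network` with `n` nodes, all typed `"gene"`.
#' @export
generate_reference_network <- function(model = c("scale_free", "random"),
                                       n, param, seed = 1) {
  model <- match.arg(model)
  if (n < 3) stop_input("n must be >= 3")
  set.seed(seed)
  nodes <- sprintf("n%04d", seq_len(n))
  if (model == "scale_free") {
    m <- param
    if (m < 1 || m != floor(m)) stop_input("param (m) must be a positive integer")
    if (m >= n) stop_input("param (m = %g) must be < n (%d)", m, n)
    deg <- rep(0, n)
    from <- integer(0); to <- integer(0)
    for (v in (m + 1):n) {
      tg <- sample.int(v - 1L, m, prob = deg[seq_len(v - 1L)] + 1)
      deg[tg] <- deg[tg] + 1L
      deg[v] <- deg[v] + m
      from <- c(from, rep(v, m)); to <- c(to, tg)
    }
  } else {
    p <- param
    if (p < 0 || p > 1) stop_input("param (p) must be in [0, 1]")
    pairs <- utils::combn(n, 2)
    keep <- stats::runif(ncol(pairs)) < p
    from <- pairs[1, keep]; to <- pairs[2, keep]
  }
  flip <- sample(c(TRUE, FALSE), length(from), replace = TRUE)
  edges <- data.frame(source = nodes[ifelse(flip, to, from)],
                      interaction = "interacts",
                      target = nodes[ifelse(flip, from, to)],
                      stringsAsFactors = FALSE)
  gene_network(edges,
               node_types = stats::setNames(rep("gene", n), nodes))
}
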