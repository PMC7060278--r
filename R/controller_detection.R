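#' Hub rule
#'
#' Hubs are nodes whose degree is at least `sd_multiplier` population
#' standard deviations above the network mean degree.
#'
#' @param sd_multiplier Positive real; default 1.
#' @param degree_kind Which degree: `"total"` (default), `"in"` or `"out"`.
#' @param degenerate What to return when the degree sd is 0 (regular graph):
#'   `"empty"` (default; "above the mean" cannot be met) or `"all"`.
#' @return List of class `hub_rule`.
#' @export
hub_rule <- function(sd_multiplier = 1.0, degree_kind = c("total", "in", "out"),
                     degenerate = c("empty", "all")) {
  if (!is.numeric(sd_multiplier) || sd_multiplier <= 0)
    stop_config("sd_multiplier must be > 0")
  structure(list(sd_multiplier = sd_multiplier,
                 degree_kind = match.arg(degree_kind),
                 degenerate = match.arg(degenerate)),
            class = "hub_rule")
}

hub_degrees <- function(metrics, degree_kind) {
  col <- switch(degree_kind, total = "total_degree", `in` = "in_degree",
                out = "out_degree")
  metrics[[col]]
}

#' Find hub nodes
#'
#' @param metrics A [node_metrics()] table (typically of the main component).
#' @param rule A [hub_rule()].
#' @return Character vector of hub node ids (possibly empty). Population
#'   (divide-by-n) standard deviation is used; threshold comparisons use
#'   `>=`.
#' @export
find_hubs <- function(metrics, rule = hub_rule()) {
  if (!is.data.frame(metrics) || nrow(metrics) == 0)
    stop_input("empty metrics table")
  stopifnot(inherits(rule, "hub_rule"))
  deg <- hub_degrees(metrics, rule$degree_kind)
  mu <- mean(deg)
  sigma <- sqrt(mean((deg - mu)^2))
  if (sigma == 0) {
    if (rule$degenerate == "all") return(metrics$node)
    return(character(0))
  }
  metrics$node[deg >= mu + rule$sd_multiplier * sigma]
}

#' Find bottleneck nodes
#'
#' The `k` nodes with highest betweenness centrality; ties broken by higher
#' total degree, then lexicographic node id (deterministic). When the
#' network has fewer than `k` nodes, all are returned with a warning.
#'
#' @param metrics A [node_metrics()] table.
#' @param k Number of bottlenecks; default 200.
#' @return Character vector of node ids, length `min(k, nrow(metrics))`.
#' @export
find_bottlenecks <- function(metrics, k = 200) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0 || k != floor(k))
    stop_config("k must be a positive integer")
  if (!is.data.frame(metrics) || nrow(metrics) == 0)
    stop_input("empty metrics table")
  if (nrow(metrics) < k) {
    warning(sprintf("find_bottlenecks: only %d nodes (< k = %d); returning all",
                    nrow(metrics), k))
    k <- nrow(metrics)
  }
  ord <- order(-metrics$betweenness, -metrics$total_degree, metrics$node)
  metrics$node[ord][seq_len(k)]
}

#' KDE configuration for local-hub detection
#'
#' The choice of features and the density cutoff are an explicit
#' reconstruction of an under-documented desktop-software step, exposed as
#' configuration: by default the two features are `log1p(total_degree)` and
#' the clustering coefficient, and a hub is "local" when its estimated
#' density is at or above the `density_quantile` quantile of hub densities
#' (dense-cluster membership).
#'
#' @param features Length-2 character vector naming metric columns; the
#'   special name `"log1p_total_degree"` means `log1p(total_degree)`.
#' @param bandwidth_rule `"scott"`, `"silverman"` or a fixed positive number
#'   (used for both axes).
#' @param density_quantile Quantile in (0, 1); default 0.5.
#' @return List of class `kde_config`.
#' @export
kde_config <- function(features = c("log1p_total_degree",
                                    "clustering_coefficient"),
                       bandwidth_rule = "scott",
                       density_quantile = 0.5) {
  if (length(features) != 2) stop_config("exactly two features required")
  if (is.character(bandwidth_rule)) {
    if (!bandwidth_rule %in% c("scott", "silverman"))
      stop_config("bandwidth_rule must be 'scott', 'silverman' or a number")
  } else if (!is.numeric(bandwidth_rule) || bandwidth_rule <= 0) {
    stop_config("fixed bandwidth must be positive")
  }
  if (!is.numeric(density_quantile) || density_quantile <= 0 ||
      density_quantile >= 1)
    stop_config("density_quantile must be in (0, 1)")
  structure(list(features = features, bandwidth_rule = bandwidth_rule,
                 density_quantile = density_quantile), class = "kde_config")
}

# Gaussian-product-kernel density of 2-column matrix `pts` evaluated at each
# of its own rows. Returns a vector of densities.
kde2_self_density <- function(pts, bandwidth_rule = "scott") {
  n <- nrow(pts)
  bw <- function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(0)
    # Scott and Silverman coincide for d = 2 Gaussian product kernels:
    # h_j = sigma_j * n^(-1/(d+4))
    s * n^(-1 / 6)
  }
  if (is.numeric(bandwidth_rule)) {
    hx <- hy <- bandwidth_rule
  } else {
    hx <- bw(pts[, 1]); hy <- bw(pts[, 2])
  }
  # Degenerate axes (zero spread) contribute no discrimination: drop them.
  kx <- if (hx > 0) outer(pts[, 1], pts[, 1], "-") / hx else NULL
  ky <- if (hy > 0) outer(pts[, 2], pts[, 2], "-") / hy else NULL
  if (is.null(kx) && is.null(ky)) return(rep(1, n)) # all points identical
  kmat <- matrix(1, n, n)
  if (!is.null(kx)) kmat <- kmat * stats::dnorm(kx) / hx
  if (!is.null(ky)) kmat <- kmat * stats::dnorm(ky) / hy
  rowMeans(kmat)
}

#' Find local hubs by kernel density estimation
#'
#' Estimates a 2-D Gaussian-product-kernel density over the hub nodes in
#' metric space and keeps hubs whose density is at or above the configured
#' quantile of hub densities: hubs sitting in dense clusters of similar hubs
#' ("local hubs"), as opposed to isolated outliers. With Scott/Silverman
#' bandwidths the selection is invariant to affine rescaling of either
#' feature. Fewer than 3 hubs yields an empty set with a warning (the
#' estimate would be meaningless).
#'
#' @param hubs Character vector of hub node ids (from [find_hubs()]).
#' @param metrics A [node_metrics()] table containing those nodes.
#' @param cfg A [kde_config()].
#' @return Character vector of local-hub ids; always a subset of `hubs`.
#' @export
find_local_hubs <- function(hubs, metrics, cfg = kde_config()) {
  stopifnot(inherits(cfg, "kde_config"))
  if (length(hubs) < 3) {
    warning("find_local_hubs: fewer than 3 hubs; returning empty set")
    return(character(0))
  }
  missing_ids <- setdiff(hubs, metrics$node)
  if (length(missing_ids))
    stop_input("%d hub(s) absent from metrics, e.g. '%s'",
               length(missing_ids), missing_ids[1])
  m <- metrics[match(hubs, metrics$node), , drop = FALSE]
  feat <- function(name) {
    if (name == "log1p_total_degree") return(log1p(m$total_degree))
    if (!name %in% names(m)) stop_config("unknown KDE feature '%s'", name)
    m[[name]]
  }
  pts <- cbind(feat(cfg$features[1]), feat(cfg$features[2]))
  dens <- kde2_self_density(pts, cfg$bandwidth_rule)
  cutoff <- stats::quantile(dens, cfg$density_quantile, names = FALSE)
  hubs[dens >= cutoff]
}

# Fixed feature order for the evidence-class label.
evidence_class_label <- function(is_bottleneck, is_hub, is_deg, is_kde,
                                 is_exclusive) {
  parts <- c("bottleneck", "hub", "DEG", "KDE", "exclusive")[
    c(is_bottleneck, is_hub, is_deg, is_kde, is_exclusive)]
  if (length(parts) == 0) "none" else paste(parts, collapse = "-")
}

#' Integrate topological and expression evidence
#'
#' Combines hub, bottleneck, local-hub and differential-expression evidence
#' into one table with a derived `evidence_class` label per gene (features
#' concatenated in the fixed order bottleneck, hub, DEG, KDE, exclusive).
#' Summary counts for the standard intersections are attached as the
#' `"intersections"` attribute.
#'
#' @param degs A `deg_table` from [call_degs()], or `NULL` for none.
#' @param hubs,bottlenecks,local_hubs Character vectors of gene ids.
#' @param direction Optionally restrict "DEG" evidence to one direction
#'   (`"up_in_a"`/`"up_in_b"`), matching hubs from a condition's network to
#'   that condition's over-expressed genes; default `NULL` uses all DEGs.
#' @return `data.frame` of class `controller_table`: `gene`, logical flags
#'   `is_hub`, `is_bottleneck`, `is_local_hub`, `is_deg`, `is_exclusive`,
#'   and `evidence_class`; one row per gene occurring in any evidence set,
#'   sorted by gene id.
#' @export
integrate_evidence <- function(degs, hubs, bottlenecks, local_hubs,
                               direction = NULL) {
  deg_genes <- character(0); excl_genes <- character(0)
  if (!is.null(degs)) {
    stopifnot(inherits(degs, "deg_table"))
    d <- degs[degs$is_deg, , drop = FALSE]
    if (!is.null(direction)) d <- d[d$direction == direction, , drop = FALSE]
    deg_genes <- d$gene_id
    excl_genes <- d$gene_id[d$is_exclusive]
  }
  genes <- sort(unique(c(hubs, bottlenecks, local_hubs, deg_genes)))
  out <- data.frame(
    gene = genes,
    is_hub = genes %in% hubs,
    is_bottleneck = genes %in% bottlenecks,
    is_local_hub = genes %in% local_hubs,
    is_deg = genes %in% deg_genes,
    is_exclusive = genes %in% excl_genes,
    row.names = NULL, stringsAsFactors = FALSE)
  out$evidence_class <- mapply(evidence_class_label, out$is_bottleneck,
                               out$is_hub, out$is_deg, out$is_local_hub,
                               out$is_exclusive)
  class(out) <- c("controller_table", "data.frame")
  attr(out, "intersections") <- list(
    hub_bottleneck = sum(out$is_hub & out$is_bottleneck),
    hub_deg = sum(out$is_hub & out$is_deg),
    bottleneck_deg = sum(out$is_bottleneck & out$is_deg),
    hub_bottleneck_deg = sum(out$is_hub & out$is_bottleneck & out$is_deg),
    hub_bottleneck_deg_kde = sum(out$is_hub & out$is_bottleneck &
                                   out$is_deg & out$is_local_hub))
  out
}
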