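#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (member gene ids). Names are
#'   set ids.
#' @param universe Character vector: the gene universe against which
#'   over-representation is judged (conventionally, all genes surviving the
#'   expression filter). Members outside the universe are dropped with a
#'   message reporting the count.
#' @param descriptions Optional character vector (same length as `sets`) of
#'   human-readable set names; defaults to the set ids.
#' @return Object of class `gene_set_collection`: list with `sets` (trimmed
#'   member lists), `descriptions`, `universe`.
#' @export
gene_set_collection <- function(sets, universe, descriptions = NULL) {
  if (length(universe) == 0) stop_input("empty gene universe")
  universe <- unique(as.character(universe))
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop_input("sets must have unique names (set ids)")
  if (is.null(descriptions)) descriptions <- names(sets)
  stopifnot(length(descriptions) == length(sets))
  dropped <- 0L
  trimmed <- lapply(sets, function(s) {
    s <- unique(as.character(s))
    keep <- s %in% universe
    dropped <<- dropped + sum(!keep)
    s[keep]
  })
  if (dropped > 0)
    message(sprintf("gene_set_collection: dropped %d member(s) outside the universe",
                    dropped))
  structure(list(sets = trimmed,
                 descriptions = stats::setNames(descriptions, names(sets)),
                 universe = universe),
            class = "gene_set_collection")
}

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` where `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` that contains `K` set members, the probability of seeing
#' at least `k` members. Identical to the one-sided (over-representation)
#' Fisher exact p-value on the corresponding 2x2 table. Computed via
#' `phyper()` (stable log-scale tail).
#'
#' @param k Observed overlap (vectorized).
#' @param K Set size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return p-values in `[0, 1]`.
#' @examples
#' hypergeom_tail(2, 3, 3, 10) # 22/120
#' @export
hypergeom_tail <- function(k, K, n, N) {
  r <- cbind(k = k, K = K, n = n, N = N) # recycles and validates lengths
  if (any(r != floor(r)) || any(r < 0))
    stop_input("k, K, n, N must be nonnegative integers")
  if (any(r[, "K"] > r[, "N"])) stop_input("violated: K <= N")
  if (any(r[, "n"] > r[, "N"])) stop_input("violated: n <= N")
  if (any(r[, "k"] > pmin(r[, "K"], r[, "n"])))
    stop_input("violated: k <= min(K, n)")
  unname(stats::phyper(r[, "k"] - 1, r[, "K"], r[, "N"] - r[, "K"], r[, "n"],
                       lower.tail = FALSE))
}

#' Multiplicity adjustment
#'
#' Benjamini-Hochberg step-up by default; `"bonferroni"` and `"none"` are
#' offered because the source toolchain's exact method is a convention, not a
#' contract. Output order matches input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method One of `"bh"`, `"bonferroni"`, `"none"`.
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p, method = c("bh", "bonferroni", "none")) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_input("p-values must lie in [0, 1]")
  switch(method,
         bh = stats::p.adjust(p, method = "BH"),
         bonferroni = stats::p.adjust(p, method = "bonferroni"),
         none = p)
}

#' Over-representation analysis
#'
#' Tests each set in the collection for enrichment of the query list via the
#' hypergeometric upper tail (one-sided Fisher), adjusts across sets, and
#' flags sets with `q_value <= q_threshold`. Two conventional presets:
#' `q_threshold = 0.01` for GO-style term screens and `0.05` for pathway
#' screens.
#'
#' @param query Character vector of gene ids. Genes outside the collection's
#'   universe are dropped with a message.
#' @param collection A [gene_set_collection()].
#' @param q_threshold Enrichment q-value ceiling; default 0.05.
#' @param method Adjustment method, see [bh_adjust()].
#' @return `data.frame` with one row per set: `set_id`, `name`, `k`, `K`,
#'   `n`, `N`, `p_value`, `q_value`, `enriched`; sorted by `q_value`, then
#'   `p_value`, then `set_id`.
#' @export
enrich <- function(query, collection, q_threshold = 0.05, method = "bh") {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (q_threshold <= 0 || q_threshold > 1)
    stop_config("q_threshold must be in (0, 1]")
  query <- unique(as.character(query))
  inside <- query %in% collection$universe
  if (any(!inside))
    message(sprintf("enrich: dropped %d query gene(s) outside the universe",
                    sum(!inside)))
  query <- query[inside]
  N <- length(collection$universe)
  n <- length(query)
  K <- vapply(collection$sets, length, integer(1))
  k <- vapply(collection$sets, function(s) sum(query %in% s), integer(1))
  p <- hypergeom_tail(k, K, n, N)
  q <- bh_adjust(p, method = method)
  out <- data.frame(set_id = names(collection$sets),
                    name = unname(collection$descriptions),
                    k = k, K = K, n = n, N = N,
                    p_value = unname(p), q_value = unname(q),
                    enriched = unname(q <= q_threshold),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$q_value, out$p_value, out$set_id), , drop = FALSE]
}
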