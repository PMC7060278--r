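#' Construct a two-condition expression study
#'
#' Container for a gene x sample abundance matrix on the FPKM scale with a
#' two-condition, replicated design. Row names are gene identifiers (opaque,
#' case-sensitive strings); columns are samples named
#' `<condition>_<replicate>`.
#'
#' @param values Nonnegative numeric matrix, genes in rows, samples in
#'   columns. Row names are required (gene ids).
#' @param conditions Character vector of length `ncol(values)` assigning each
#'   sample to one of exactly two condition labels.
#' @return An object of class `expression_study`: a list with elements
#'   `values` (the matrix), `genes`, `samples`, `conditions` (per-sample
#'   labels) and `condition_levels` (the two labels, in first-appearance
#'   order).
#' @examples
#' m <- matrix(c(5, 6, 4, 20, 22, 19), nrow = 1,
#'             dimnames = list("g1", NULL))
#' st <- expression_study(m, rep(c("ctrl", "emt"), each = 3))
#' st$condition_levels
#' @export
expression_study <- function(values, conditions) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("values must be a numeric matrix")
  if (is.null(rownames(values)))
    stop_input("values must have gene ids as row names")
  if (anyDuplicated(rownames(values)))
    stop_input("duplicate gene ids in expression matrix")
  if (any(!is.finite(values)) || any(values < 0))
    stop_input("abundances must be finite and nonnegative")
  conditions <- as.character(conditions)
  if (length(conditions) != ncol(values))
    stop_input("length(conditions) [%d] != number of samples [%d]",
               length(conditions), ncol(values))
  lev <- unique(conditions)
  if (length(lev) != 2L)
    stop_input("exactly two conditions required, got %d", length(lev))
  tab <- table(conditions)
  if (any(tab < 2L))
    stop_input("every condition needs >= 2 replicates (found %s)",
               paste(sprintf("%s: %d", names(tab), tab), collapse = ", "))
  if (is.null(colnames(values))) {
    rep_idx <- stats::ave(seq_along(conditions), conditions, FUN = seq_along)
    colnames(values) <- paste(conditions, rep_idx, sep = "_")
  }
  structure(list(values = values,
                 genes = rownames(values),
                 samples = colnames(values),
                 conditions = conditions,
                 condition_levels = lev),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d samples (%s)\n",
              length(x$genes), length(x$samples),
              paste(sprintf("%s n=%d", x$condition_levels,
                            tabulate(match(x$conditions, x$condition_levels))),
                    collapse = ", ")))
  invisible(x)
}

condition_cols <- function(study, condition) {
  lev <- study$condition_levels
  if (!condition %in% lev)
    stop_input("unknown condition '%s' (have: %s)", condition,
               paste(lev, collapse = ", "))
  which(study$conditions == condition)
}

#' Expression filter for one gene in one condition
#'
#' A gene counts as expressed in a condition when its abundance exceeds
#' `min_fpkm` in at least `ceiling(min_replicate_fraction * n_replicates)`
#' replicates of that condition. The defaults (0.1 FPKM in all replicates)
#' are a configurable stand-in for study-specific filtering rules.
#'
#' @param study An [expression_study()].
#' @param gene Gene id (must exist in the study).
#' @param condition Condition label.
#' @param min_fpkm Abundance threshold (strictly exceeded), default 0.1.
#' @param min_replicate_fraction Fraction of replicates required, in (0, 1];
#'   default 1 (all replicates).
#' @return Logical flag.
#' @export
is_expressed <- function(study, gene, condition, min_fpkm = 0.1,
                         min_replicate_fraction = 1.0) {
  if (!inherits(study, "expression_study")) stop_input("not an expression_study")
  if (!gene %in% study$genes) stop_input("unknown gene '%s'", gene)
  if (min_fpkm < 0) stop_config("min_fpkm must be >= 0")
  if (min_replicate_fraction <= 0 || min_replicate_fraction > 1)
    stop_config("min_replicate_fraction must be in (0, 1]")
  cols <- condition_cols(study, condition)
  v <- study$values[gene, cols]
  sum(v > min_fpkm) >= ceiling(min_replicate_fraction * length(cols))
}

# Vectorized expression flags: genes x 2 logical matrix (condition order =
# condition_levels).
expressed_flags <- function(study, min_fpkm = 0.1,
                            min_replicate_fraction = 1.0) {
  if (min_replicate_fraction <= 0 || min_replicate_fraction > 1)
    stop_config("min_replicate_fraction must be in (0, 1]")
  vapply(study$condition_levels, function(cond) {
    cols <- which(study$conditions == cond)
    need <- ceiling(min_replicate_fraction * length(cols))
    rowSums(study$values[, cols, drop = FALSE] > min_fpkm) >= need
  }, logical(length(study$genes)))
}

#' Partition genes into common / condition-specific / excluded sets
#'
#' Applies the expression filter per condition and classifies every gene as
#' expressed in both conditions (`common`), in exactly one (`specific_a`,
#' `specific_b`, in condition-level order), or in neither (`excluded`). The
#' four sets are pairwise disjoint and cover the gene universe.
#'
#' @inheritParams is_expressed
#' @return An object of class `venn_partition`: list with character vectors
#'   `common`, `specific_a`, `specific_b`, `excluded`, plus `conditions`
#'   naming which level is "a" and which "b".
#' @export
venn_partition <- function(study, min_fpkm = 0.1,
                           min_replicate_fraction = 1.0) {
  fl <- expressed_flags(study, min_fpkm, min_replicate_fraction)
  g <- study$genes
  structure(list(
    common = g[fl[, 1] & fl[, 2]],
    specific_a = g[fl[, 1] & !fl[, 2]],
    specific_b = g[!fl[, 1] & fl[, 2]],
    excluded = g[!fl[, 1] & !fl[, 2]],
    conditions = study$condition_levels), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf(paste0("venn_partition (a = %s, b = %s): common %d | ",
                     "specific_a %d | specific_b %d | excluded %d\n"),
              x$conditions[1], x$conditions[2], length(x$common),
              length(x$specific_a), length(x$specific_b), length(x$excluded)))
  invisible(x)
}

#' Stand-in per-gene differential test
#'
#' Equal-variance two-sample t test on `log2(FPKM + pseudocount)` per gene,
#' with Benjamini-Hochberg q-values. This is a deliberately simple stand-in
#' for a full RNA-seq differential pipeline: the downstream network analysis,
#' not the test, is the point. Fold change is
#' `log2((mean_b + pseudocount) / (mean_a + pseudocount))` on raw means;
#' genes whose raw mean is zero in exactly one condition are flagged
#' `inf_fc` (infinite fold change carried as a flag, never a sentinel
#' number).
#'
#' Degenerate variance (all 2n values identical after transform) yields
#' p = 1 when the group means agree and p = 0 when they differ.
#'
#' @param study An [expression_study()] with >= 2 replicates per condition.
#' @param pseudocount Added before the log2 transform and inside the fold
#'   change; default 1.
#' @return A `data.frame` of class `de_table`: `gene_id`, `mean_a`, `mean_b`
#'   (raw condition means), `log2fc`, `inf_fc` (logical), `p_value`,
#'   `q_value`. Condition "a"/"b" follow `study$condition_levels`.
#' @export
simple_de_test <- function(study, pseudocount = 1) {
  if (!inherits(study, "expression_study")) stop_input("not an expression_study")
  ca <- which(study$conditions == study$condition_levels[1])
  cb <- which(study$conditions == study$condition_levels[2])
  na <- length(ca); nb <- length(cb)
  A <- study$values[, ca, drop = FALSE]
  B <- study$values[, cb, drop = FALSE]
  la <- log2(A + pseudocount); lb <- log2(B + pseudocount)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1, stats::var); vb <- apply(lb, 1, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- (mb - ma) / se
  p <- 2 * stats::pt(-abs(tstat), df = na + nb - 2)
  zero_var <- sp2 == 0
  p[zero_var & ma == mb] <- 1
  p[zero_var & ma != mb] <- 0
  mean_a <- rowMeans(A); mean_b <- rowMeans(B)
  res <- data.frame(
    gene_id = study$genes,
    mean_a = mean_a, mean_b = mean_b,
    log2fc = log2((mean_b + pseudocount) / (mean_a + pseudocount)),
    inf_fc = xor(mean_a == 0, mean_b == 0) & (mean_a > 0 | mean_b > 0),
    p_value = p,
    q_value = bh_adjust(p),
    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("de_table", "data.frame")
  attr(res, "conditions") <- study$condition_levels
  res
}

#' Call differentially expressed genes
#'
#' Flags genes with `q_value <= q_max` and `|log2fc| >= fc_min` (boundary
#' values retained). Infinite-fold-change genes (raw mean zero in exactly one
#' condition) are always DEGs of the condition where they are expressed,
#' regardless of q: they are the "exclusive" genes.
#'
#' @param det A `de_table` from [simple_de_test()] or [read_diff()].
#' @param q_max q-value ceiling, in (0, 1]; default 0.05.
#' @param fc_min Minimum `|log2fc|`; default 1.
#' @return `det` with columns `is_deg` (logical), `direction`
#'   (`"up_in_a"`/`"up_in_b"`/`NA`), `is_exclusive` (logical) and
#'   `exclusive_condition` (`"a"`/`"b"`/`NA`) appended; class `deg_table`.
#' @export
call_degs <- function(det, q_max = 0.05, fc_min = 1.0) {
  if (!is.data.frame(det) || !all(c("gene_id", "log2fc", "q_value") %in% names(det)))
    stop_input("det must carry gene_id, log2fc, q_value")
  if (!is.numeric(q_max) || length(q_max) != 1 || q_max <= 0 || q_max > 1)
    stop_config("q_max must be in (0, 1]")
  if (fc_min < 0) stop_config("fc_min must be >= 0")
  inf_fc <- if ("inf_fc" %in% names(det)) det$inf_fc else
    !is.finite(det$log2fc)
  passes <- det$q_value <= q_max & abs(det$log2fc) >= fc_min
  is_deg <- (passes | inf_fc)
  up_b <- ifelse(inf_fc, det$mean_b > 0, det$log2fc > 0)
  out <- det
  out$is_deg <- is_deg
  out$direction <- ifelse(is_deg, ifelse(up_b, "up_in_b", "up_in_a"), NA)
  out$is_exclusive <- inf_fc
  out$exclusive_condition <- ifelse(inf_fc, ifelse(det$mean_b > 0, "b", "a"), NA)
  class(out) <- c("deg_table", "de_table", "data.frame")
  attr(out, "conditions") <- attr(det, "conditions")
  attr(out, "thresholds") <- c(q_max = q_max, fc_min = fc_min)
  out
}

#' Summarize a DEG table
#'
#' @param degs A `deg_table` from [call_degs()].
#' @return Named list of counts: `total` DEGs, `up_in_a`, `up_in_b`,
#'   `exclusive_a`, `exclusive_b`. `total == up_in_a + up_in_b` always.
#' @export
deg_summary <- function(degs) {
  stopifnot(inherits(degs, "deg_table"))
  d <- degs[degs$is_deg, , drop = FALSE]
  list(total = nrow(d),
       up_in_a = sum(d$direction == "up_in_a"),
       up_in_b = sum(d$direction == "up_in_b"),
       exclusive_a = sum(d$is_exclusive & d$exclusive_condition == "a"),
       exclusive_b = sum(d$is_exclusive & d$exclusive_condition == "b"))
}
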