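# Organ/tissue expression-atlas processing: row-centered log2
# normalization (so the heatmap scale is a log2 fold change around each
# gene's mean), hierarchical clustering of genes and samples, and expression
# similarity within duplicate pairs.

expr_matrix <- function(expr, gene_col = "gene_id") {
  expr <- as_tibble(expr)
  stopifnot(gene_col %in% names(expr))
  m <- as.matrix(expr[setdiff(names(expr), gene_col)])
  if (!is.numeric(m)) abort("expression values must be numeric")
  if (any(!is.finite(m))) abort("expression values must be finite")
  rownames(m) <- expr[[gene_col]]
  if (any(duplicated(rownames(m)))) abort("duplicate gene ids")
  m
}

#' Row-centered log2 normalization of an expression matrix
#'
#' Each signal is transformed as `log2(x + pseudocount)` and then centered on
#' the gene's mean across samples, so every value reads as a log2 fold change
#' relative to that gene's average expression; a constant gene maps to an
#' all-zero row.
#'
#' @param expr Tibble with a `gene_id` column and one numeric column per
#'   sample (non-negative signals).
#' @param pseudocount Added before the log (default 1).
#' @return A tibble of the same shape with transformed values.
#' @export
normalize_log2 <- function(expr, pseudocount = 1) {
  m <- expr_matrix(expr)
  if (any(m < 0)) abort("negative expression values")
  lg <- log2(m + pseudocount)
  centered <- lg - rowMeans(lg)
  dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(centered))
}

#' Hierarchical clustering of an expression matrix axis
#'
#' Agglomerative clustering (default Euclidean distance, average linkage)
#' of genes (rows) or samples (columns) via `stats::hclust`; `hclust`'s
#' merge order is deterministic for a given input order, and the tree itself
#' is invariant to input order up to relabeling.
#'
#' @param expr Expression tibble (typically [normalize_log2()] output).
#' @param axis `"genes"` or `"samples"`.
#' @param metric A `stats::dist` method (default `"euclidean"`).
#' @param linkage A `stats::hclust` method (default `"average"`).
#' @return A list of class `ccch_hclust`: `hclust` (the fitted tree),
#'   `order` (leaf labels in dendrogram order), `axis`.
#' @export
hcluster <- function(expr, axis = c("genes", "samples"),
                     metric = "euclidean", linkage = "average") {
  axis <- match.arg(axis)
  m <- expr_matrix(expr)
  if (axis == "samples") m <- t(m)
  if (nrow(m) < 2) abort("need at least 2 items to cluster")
  hc <- hclust(dist(m, method = metric), method = linkage)
  structure(list(hclust = hc, order = rownames(m)[hc$order], axis = axis),
            class = "ccch_hclust")
}

#' @export
print.ccch_hclust <- function(x, ...) {
  cat(sprintf("<ccch_hclust> %d %s, %s linkage\n",
              length(x$order), x$axis, x$hclust$method))
  invisible(x)
}

#' @method tidy ccch_hclust
#' @export
tidy.ccch_hclust <- function(x, ...) {
  h <- x$hclust
  tibble(step = seq_along(h$height), height = h$height,
         merge1 = h$merge[, 1], merge2 = h$merge[, 2])
}

#' @method glance ccch_hclust
#' @export
glance.ccch_hclust <- function(x, ...) {
  tibble(n_items = length(x$order), axis = x$axis,
         linkage = x$hclust$method, max_height = max(x$hclust$height))
}

#' Cluster an expression atlas into a heatmap-ready object
#'
#' Convenience wrapper: normalize, cluster both axes, and keep the leaf
#' orders, mirroring the usual clustered log2 fold change heatmap.
#'
#' @param expr Raw expression tibble (`gene_id` + sample columns).
#' @inheritParams normalize_log2
#' @inheritParams hcluster
#' @return A list of class `clustered_heatmap`: `values` (normalized
#'   tibble), `genes`, `samples` (both `ccch_hclust`).
#' @export
cluster_atlas <- function(expr, pseudocount = 1, metric = "euclidean",
                          linkage = "average") {
  values <- normalize_log2(expr, pseudocount)
  structure(list(values = values,
                 genes = hcluster(values, "genes", metric, linkage),
                 samples = hcluster(values, "samples", metric, linkage)),
            class = "clustered_heatmap")
}

#' @export
print.clustered_heatmap <- function(x, ...) {
  cat(sprintf("<clustered_heatmap> %d genes x %d samples\n",
              length(x$genes$order), length(x$samples$order)))
  invisible(x)
}

#' Expression similarity within duplicate gene pairs
#'
#' Pearson correlation of the two genes' normalized expression profiles
#' across samples; a pair is "similar" when `r >= threshold`. When `pairs`
#' carries a `selection` column, the per-class fraction of similar pairs is
#' attached as the `"summary"` attribute (the contrast between purifying and
#' diversifying pairs).
#'
#' @param expr Raw expression tibble (`gene_id` + sample columns).
#' @param pairs Tibble with `gene_a`, `gene_b` (optionally `selection`).
#' @param threshold Similarity threshold on `r` (default 0.8).
#' @param pseudocount Passed to [normalize_log2()].
#' @return `pairs` with `r` and `similar` columns; attribute `"summary"` is a
#'   tibble of `selection`, `n_pairs`, `n_similar`, `frac_similar` when a
#'   `selection` column is present.
#' @export
pair_expression_similarity <- function(expr, pairs, threshold = 0.8,
                                       pseudocount = 1) {
  norm <- normalize_log2(expr, pseudocount)
  m <- expr_matrix(norm)
  missing <- setdiff(c(pairs$gene_a, pairs$gene_b), rownames(m))
  if (length(missing)) abort(paste0("gene(s) absent from matrix: ",
                                    paste(missing, collapse = ", ")))
  r <- purrr::map2_dbl(pairs$gene_a, pairs$gene_b,
                       function(a, b) cor(m[a, ], m[b, ]))
  out <- mutate(pairs, r = r, similar = r >= threshold)
  if ("selection" %in% names(pairs)) {
    attr(out, "summary") <- out |>
      group_by(.data$selection) |>
      summarise(n_pairs = n(), n_similar = sum(.data$similar),
                frac_similar = mean(.data$similar), .groups = "drop")
  }
  out
}
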