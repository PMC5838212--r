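#' Hierarchical clustering of log2 normalized median counts
#'
#' Builds the matrix behind the enrichment heatmap: for each miRNA in
#' `subset` and each condition, the median normalized count across that
#' condition's replicate samples, log2-transformed after adding a
#' pseudocount. Rows (miRNAs) and columns (conditions) are clustered by
#' agglomerative hierarchical clustering (Euclidean distance, complete
#' linkage by default).
#'
#' @param m a [mirna_counts], normally in `quantile_normalized` state.
#' @param subset miRNA ids to cluster (nonempty).
#' @param pseudocount added before the log2 transform.
#' @param distance distance measure passed to [stats::dist()].
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return List with `matrix` (log2 medians, rows/columns in clustered leaf
#'   order), `row_hclust`, `col_hclust` (NULL when degenerate), `row_order`,
#'   `col_order` (leaf orders as ids).
#' @export
cluster_heatmap <- function(m, subset, pseudocount = 1,
                            distance = "euclidean", linkage = "complete") {
  stopifnot(inherits(m, "mirna_counts"))
  if (length(subset) == 0) stop("subset must be nonempty")
  endo <- endogenous_counts(m)
  missing <- setdiff(subset, rownames(endo))
  if (length(missing)) {
    stop("unknown miRNA id(s): ", paste(missing, collapse = ", "))
  }
  conds <- unique(m$condition)
  med <- sapply(conds, function(cc) {
    apply(endo[subset, m$condition == cc, drop = FALSE], 1, median)
  })
  med <- matrix(med, nrow = length(subset),
                dimnames = list(subset, conds))
  lmat <- log2(med + pseudocount)

  cluster_dim <- function(x) {
    if (nrow(x) < 2) return(list(hc = NULL, order = 1L))
    hc <- stats::hclust(stats::dist(x, method = distance), method = linkage)
    list(hc = hc, order = hc$order)
  }
  rows <- cluster_dim(lmat)
  cols <- cluster_dim(t(lmat))
  list(
    matrix = lmat[rows$order, cols$order, drop = FALSE],
    row_hclust = rows$hc,
    col_hclust = cols$hc,
    row_order = rownames(lmat)[rows$order],
    col_order = colnames(lmat)[cols$order]
  )
}
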