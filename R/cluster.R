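#' Log-transform and gene-center an expression matrix
#'
#' Applies `log2(x + 1)` then subtracts each gene's mean across cells,
#' the standard transformation ahead of PCA and correlation-based
#' clustering of normalized transcript counts.
#'
#' @param normalized genes x cells matrix of normalized counts
#' @return matrix of the same shape with zero row means
#' @export
transform_counts <- function(normalized) {
  y <- log2(as.matrix(normalized) + 1)
  sweep(y, 1L, rowMeans(y), "-")
}

#' Most variable genes
#'
#' Ranks genes by the variance of `log2(x + 1)`-transformed normalized
#' counts and returns the top `n`. Ties break lexicographically by gene
#' id so the selection is deterministic. Typical presets: 500 genes for
#' PCA, 100 for heatmaps/clustering.
#'
#' @param normalized genes x cells matrix of normalized counts
#' @param n number of genes to return
#' @return character vector of gene ids, most variable first
#' @export
variable_genes <- function(normalized, n = 500L) {
  stopifnot(n >= 1)
  y <- log2(as.matrix(normalized) + 1)
  v <- apply(y, 1L, stats::var)
  ids <- rownames(y) %||% as.character(seq_len(nrow(y)))
  ord <- order(-v, ids)
  head(ids[ord], n)
}

#' PCA over cells
#'
#' Exact PCA (singular value decomposition via `prcomp`, no randomized
#' solver) of cells over the supplied transformed matrix. Signs follow
#' a fixed convention — the largest-magnitude loading of each component
#' is positive — so results are reproducible across platforms.
#'
#' @param transformed genes x cells matrix from [transform_counts()]
#'   (already centered; no further centering is applied)
#' @param n_components number of components to keep
#' @return list(`scores` cells x k, `loadings` genes x k,
#'   `var_explained` fraction per component)
#' @export
run_pca <- function(transformed, n_components = 2L) {
  stopifnot(ncol(transformed) >= 2)
  k <- min(n_components, ncol(transformed) - 1L, nrow(transformed))
  p <- stats::prcomp(t(transformed), center = FALSE, rank. = k)
  flip <- apply(p$rotation, 2L, function(w) sign(w[which.max(abs(w))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2L, flip, "*")
  loadings <- sweep(p$rotation, 2L, flip, "*")
  list(scores = scores, loadings = loadings,
       var_explained = p$sdev^2 / sum(p$sdev^2))
}

#' Hierarchical clustering of cells with correlation distance
#'
#' Pairwise distance between cells is `1 - r` (Pearson correlation of
#' their transformed profiles); agglomeration uses average linkage. A
#' constant-profile cell has undefined correlation and is removed with
#' a warning before clustering.
#'
#' @param transformed genes x cells matrix
#' @param k number of clusters for the dendrogram cut (NULL = no cut)
#' @return list(`hclust`, `labels` named integer vector when `k` given,
#'   `dist` the distance matrix, `removed` cell names dropped)
#' @export
hcluster_cells <- function(transformed, k = NULL) {
  m <- as.matrix(transformed)
  const <- apply(m, 2L, function(x) stats::sd(x) == 0 || !is.finite(stats::sd(x)))
  removed <- colnames(m)[const]
  if (any(const)) {
    warning(sum(const), " constant-profile cell(s) removed before clustering")
    m <- m[, !const, drop = FALSE]
  }
  d <- stats::as.dist(1 - stats::cor(m))
  hc <- stats::hclust(d, method = "average")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(hclust = hc, labels = labels, dist = d, removed = removed)
}

#' Label clusters by marker-gene expression
#'
#' Each cluster receives the cell-type label whose marker set has the
#' highest mean normalized expression within the cluster (mean over the
#' set's genes and the cluster's cells); exact ties give "unresolved".
#' Marker sets must be disjoint.
#'
#' @param labels per-cell cluster assignment (named by cell)
#' @param normalized genes x cells normalized count matrix
#' @param marker_sets named list: cell type -> character vector of genes
#' @return named character vector: cluster id -> cell type
#' @examples
#' # marker_sets = list(beta = c("Ins1", "Ins2"), alpha = "Gcg",
#' #                    delta = "Sst", pp = "Ppy")
#' @export
label_clusters <- function(labels, normalized, marker_sets) {
  all_markers <- unlist(marker_sets)
  if (anyDuplicated(all_markers)) stop("marker sets must be disjoint")
  normalized <- as.matrix(normalized)
  clusters <- sort(unique(labels))
  out <- stats::setNames(character(length(clusters)), clusters)
  for (cl in clusters) {
    cells <- names(labels)[labels == cl] %||% which(labels == cl)
    score <- vapply(marker_sets, function(gs) {
      gs <- intersect(gs, rownames(normalized))
      if (length(gs) == 0L) return(NA_real_)
      mean(normalized[gs, cells, drop = FALSE])
    }, numeric(1))
    top <- which(score == max(score, na.rm = TRUE))
    out[as.character(cl)] <- if (length(top) == 1L) names(marker_sets)[top] else "unresolved"
  }
  out
}

#' Pairwise cell-cell Pearson correlation
#'
#' Correlates per-gene profiles between all cell pairs, either on
#' transcript (UMI-cluster) counts or on raw read counts — comparing
#' the two shows the UMI advantage: removing PCR-duplication noise
#' raises cell-cell correlation.
#'
#' @param counts genes x cells matrix (transcript or read counts)
#' @param log transform with log2(x+1) first (default TRUE)
#' @return correlation matrix (cells x cells)
#' @export
cell_pair_correlation <- function(counts, log = TRUE) {
  m <- as.matrix(counts)
  stopifnot(ncol(m) >= 2)
  if (log) m <- log2(m + 1)
  stats::cor(m)
}

#' Median of off-diagonal pairwise correlations
#'
#' @param cormat matrix from [cell_pair_correlation()]
#' @return median r over distinct cell pairs
#' @export
median_pair_r <- function(cormat) {
  stats::median(cormat[upper.tri(cormat)])
}
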