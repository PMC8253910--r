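#' Principal component analysis of samples
#'
#' PCA of a complete log2 matrix with samples as observations and proteins
#' as variables: protein columns are mean-centered and the singular value
#' decomposition taken; explained-variance fractions are the squared
#' singular values normalized to sum to one.
#'
#' @param matrix An [intensity_matrix()] (complete) or a plain complete
#'   proteins x samples numeric matrix.
#' @return A `pca_result` list: `scores` (samples x components),
#'   `loadings`, `explained_variance_fraction`, `sample_id`.
#' @export
pca <- function(matrix) {
  values <- if (inherits(matrix, "intensity_matrix")) matrix$values else matrix
  stopifnot(is.matrix(values))
  if (anyNA(values)) stop("matrix must be complete (impute first)",
                          call. = FALSE)
  if (ncol(values) < 2) stop("need at least 2 samples", call. = FALSE)
  X <- t(values)  # samples x proteins
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(scores = pc$x,
                 loadings = pc$rotation,
                 explained_variance_fraction = ev / sum(ev),
                 sample_id = rownames(X)),
            class = "pca_result")
}

#' Hierarchical clustering of proteins and samples with a k-cut
#'
#' Agglomerative clustering as used for expression heatmaps: per-protein
#' z-scored rows, Euclidean distance, average linkage (all configurable).
#' Protein clusters come from cutting the protein dendrogram into `k`
#' groups; cluster ids are renumbered 1..k in dendrogram order so they are
#' stable and contiguous. Samples are clustered on the same standardized
#' matrix.
#'
#' @param matrix Complete proteins x samples matrix (or
#'   [intensity_matrix()]), typically restricted to the DE proteins.
#' @param k Number of protein clusters (default 8, the number of distinct
#'   expression patterns noted in the emulated study).
#' @param distance Distance for [stats::dist()].
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param scale_rows Z-score each protein row first (default TRUE).
#' @return A `cluster_assignment` list: `cluster` (named integer vector),
#'   `protein_order`, `sample_order`, `k`, plus the two `hclust` trees.
#' @export
cluster_heatmap <- function(matrix, k = 8, distance = "euclidean",
                            linkage = "average", scale_rows = TRUE) {
  values <- if (inherits(matrix, "intensity_matrix")) matrix$values else matrix
  stopifnot(is.matrix(values), !anyNA(values))
  if (k > nrow(values)) stop("k exceeds the number of proteins",
                             call. = FALSE)
  Z <- if (scale_rows) {
    sds <- apply(values, 1, stats::sd)
    sds[sds == 0] <- 1
    (values - rowMeans(values)) / sds
  } else values
  hp <- stats::hclust(stats::dist(Z, method = distance), method = linkage)
  hs <- stats::hclust(stats::dist(t(Z), method = distance), method = linkage)
  raw <- stats::cutree(hp, k = k)
  # renumber clusters by first appearance along the dendrogram order
  first_seen <- unique(raw[hp$order])
  cluster <- match(raw, first_seen)
  names(cluster) <- rownames(values)
  structure(list(cluster = cluster,
                 protein_order = hp$order,
                 sample_order = hs$order,
                 k = k,
                 protein_tree = hp, sample_tree = hs),
            class = "cluster_assignment")
}

#' Per-cluster expression profiles by group and timepoint
#'
#' Summarizes all protein x sample values of each (cluster, group,
#' timepoint) stratum: median, first and third quartiles (type-7
#' quantiles) and the number of contributing values. Raw log2 values are
#' summarized (not the z-scores used for clustering). Empty strata are
#' reported with `NA` summaries and `n = 0`.
#'
#' @param matrix Complete proteins x samples matrix or
#'   [intensity_matrix()].
#' @param clusters A [cluster_heatmap()] assignment for the same proteins.
#' @param design The `sample_design` for the columns.
#' @return Data frame: `cluster`, `group`, `timepoint`, `median`, `q1`,
#'   `q3`, `n`.
#' @export
cluster_profiles <- function(matrix, clusters, design) {
  values <- if (inherits(matrix, "intensity_matrix")) matrix$values else matrix
  stopifnot(is.matrix(values), length(clusters$cluster) == nrow(values),
            all(c("group", "timepoint") %in% names(design)),
            ncol(values) == nrow(design))
  lv <- function(x) if (is.factor(x)) levels(x) else unique(as.character(x))
  out <- expand.grid(cluster = seq_len(clusters$k),
                     group = lv(design$group),
                     timepoint = lv(design$timepoint),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  stats_of <- function(v) {
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_, 0))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    c(q[2], q[1], q[3], length(v))
  }
  res <- t(apply(out, 1, function(row) {
    rows <- clusters$cluster == as.integer(row[["cluster"]])
    cols <- design$group == row[["group"]] &
      design$timepoint == row[["timepoint"]]
    stats_of(as.numeric(values[rows, cols, drop = FALSE]))
  }))
  out$median <- res[, 1]
  out$q1 <- res[, 2]
  out$q3 <- res[, 3]
  out$n <- as.integer(res[, 4])
  out
}
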