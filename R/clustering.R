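# Unsupervised structure of preprocessed spectra: PCA scores and
# Ward/Euclidean hierarchical clustering with dendrogram export.

#' Principal component decomposition of a spectra matrix
#'
#' Column-mean-centers `X` and decomposes it by singular value
#' decomposition. Scores are `U %*% S` (truncated); each loading vector is
#' signed so that its largest-magnitude element is positive, which makes
#' score plots stable across runs and platforms.
#'
#' @param X Numeric matrix, samples x points.
#' @param n_components Number of components to retain
#'   (`<= min(n-1, p)`).
#' @return An object of class `"ftir_pca"`: `scores` (n x k), `loadings`
#'   (p x k, orthonormal columns), `explained_variance_ratio` (length k) and
#'   `mean` (length p).
#' @export
pca_decompose <- function(X, n_components) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  k <- as.integer(n_components)
  if (k < 1L || k > min(n - 1L, p))
    stop(sprintf("`n_components` must be between 1 and %d", min(n - 1L, p)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = k, nv = k)
  V <- sv$v; U <- sv$u
  for (a in seq_len(k)) {
    j <- which.max(abs(V[, a]))
    if (V[j, a] < 0) { V[, a] <- -V[, a]; U[, a] <- -U[, a] }
  }
  scores <- U * rep(sv$d[seq_len(k)], each = n)
  rownames(scores) <- rownames(X)
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = V,
                 explained_variance_ratio = (sv$d^2 / sum(sv$d^2))[seq_len(k)],
                 mean = mu),
            class = "ftir_pca")
}

#' @export
print.ftir_pca <- function(x, ...) {
  cat(sprintf("<ftir_pca> %d samples, %d components; variance ratios: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.3f", x$explained_variance_ratio),
                    collapse = " ")))
  invisible(x)
}

#' Ward/Euclidean hierarchical clustering of spectra
#'
#' Agglomerates samples from their pairwise Euclidean distances under Ward's
#' minimum-variance criterion, with merge heights kept on the Euclidean (not
#' squared) scale — i.e. the Lance-Williams recurrence
#' `D(AB,C) = sqrt(((nA+nC) D_AC^2 + (nB+nC) D_BC^2 - nC D_AB^2) /
#' (nA+nB+nC))`, the "ward.D2" convention, under which the first merge of
#' two singletons happens at their plain Euclidean distance.
#'
#' @param X Numeric matrix, samples x points.
#' @param sample_ids Sample ids (unique); default rownames of `X`.
#' @return An object of class `"ftir_dendrogram"`: `merges` (data frame with
#'   columns `a`, `b`, `height`, `size`; negative entries in `a`/`b` denote
#'   leaves by index, positive entries earlier merges), `leaf_ids`, and the
#'   underlying `hclust` object.
#' @seealso [cut_dendrogram()], [export_newick()]
#' @export
hca_ward <- function(X, sample_ids = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("clustering needs at least 2 samples")
  if (is.null(sample_ids)) sample_ids <- rownames(X)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (length(sample_ids) != n) stop("`sample_ids` length must equal nrow(X)")
  hc <- stats::hclust(stats::dist(X, method = "euclidean"),
                      method = "ward.D2")
  hc$labels <- sample_ids
  size <- integer(n - 1L)
  for (i in seq_len(n - 1L)) {
    sz <- function(j) if (j < 0) 1L else size[j]
    size[i] <- sz(hc$merge[i, 1]) + sz(hc$merge[i, 2])
  }
  structure(list(merges = data.frame(a = hc$merge[, 1], b = hc$merge[, 2],
                                     height = hc$height, size = size),
                 leaf_ids = sample_ids, hclust = hc),
            class = "ftir_dendrogram")
}

#' @export
print.ftir_dendrogram <- function(x, ...) {
  cat(sprintf("<ftir_dendrogram> %d leaves, %d merges, max height %.4g\n",
              length(x$leaf_ids), nrow(x$merges), max(x$merges$height)))
  invisible(x)
}

#' @export
plot.ftir_dendrogram <- function(x, ...) {
  graphics::plot(x$hclust, xlab = "", sub = "", ...)
  invisible(x)
}

#' Cut a dendrogram into a fixed number of clusters
#'
#' Removes the `n_clusters - 1` highest merges and labels the resulting
#' groups deterministically: cluster 1 contains the sample with the smallest
#' index, and so on.
#'
#' @param d An `ftir_dendrogram`.
#' @param n_clusters Number of clusters, `1 <= n_clusters <= n`.
#' @return Named integer vector mapping sample id to cluster label.
#' @export
cut_dendrogram <- function(d, n_clusters) {
  if (!inherits(d, "ftir_dendrogram")) stop("`d` must be an ftir_dendrogram")
  n <- length(d$leaf_ids)
  k <- as.integer(n_clusters)
  if (k < 1L || k > n) stop("`n_clusters` must be between 1 and ", n)
  stats::cutree(d$hclust, k = k)
}

fmt_num <- function(x) sprintf("%.10g", x)

newick_label <- function(id) {
  if (grepl("[](),:;[[:space:]]", id)) gsub("'", "''", sprintf("'%s'", id))
  else id
}

#' Export a dendrogram as a Newick tree
#'
#' Builds an ultrametric Newick string: every leaf sits at height 0 and each
#' branch length is the parent merge height minus the child's height (a
#' leaf's branch equals the height of the merge that absorbs it), so all
#' root-to-leaf path lengths equal the final merge height.
#'
#' @param d An `ftir_dendrogram`.
#' @return A single Newick string terminated by `";"`.
#' @export
export_newick <- function(d) {
  if (!inherits(d, "ftir_dendrogram")) stop("`d` must be an ftir_dendrogram")
  m <- d$merges
  node <- function(j, parent_h) {
    if (j < 0)
      return(paste0(newick_label(d$leaf_ids[-j]), ":", fmt_num(parent_h)))
    h <- m$height[j]
    paste0("(", node(m$a[j], h), ",", node(m$b[j], h), "):",
           fmt_num(parent_h - h))
  }
  root <- nrow(m)
  h <- m$height[root]
  paste0("(", node(m$a[root], h), ",", node(m$b[root], h), ");")
}
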