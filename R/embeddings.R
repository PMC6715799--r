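#' PCA reduction of hidden features
#'
#' Projects mean-centered feature vectors onto their top principal
#' components; the standard first stage before t-SNE (256 -> 20 for the
#' sequence models, 80 -> 20 for the CNN features).
#'
#' @param features Numeric matrix (n points x feature width).
#' @param n_components Number of components to retain
#'   (<= min(n - 1, width)).
#' @return A list with `reduced` (n x n_components scores), `ratios`
#'   (non-increasing explained-variance ratios summing to <= 1), and
#'   `rotation` (the orthonormal component matrix).
#' @export
pca_reduce <- function(features, n_components) {
  features <- as.matrix(features)
  if (n_components > min(nrow(features), ncol(features))) {
    stop("n_components = ", n_components, " exceeds min(n_points, width) = ",
         min(nrow(features), ncol(features)))
  }
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  k <- min(n_components, ncol(pc$x))
  list(
    reduced = pc$x[, seq_len(k), drop = FALSE],
    ratios = (pc$sdev^2 / total_var)[seq_len(k)],
    rotation = pc$rotation[, seq_len(k), drop = FALSE]
  )
}

#' t-SNE embedding of reduced features
#'
#' Barnes-Hut t-SNE to 2 or 3 dimensions, deterministic for a fixed seed.
#'
#' @param reduced Numeric matrix (typically the PCA scores).
#' @param out_dim 2 or 3.
#' @param perplexity t-SNE perplexity; must satisfy
#'   `3 * perplexity < n_points - 1`.
#' @param seed Integer seed.
#' @param labels Optional per-point labels carried into the result.
#' @return An object of class `embedding_result` with `coordinates`
#'   (n x out_dim), `labels`, and `method_params`.
#' @export
tsne_embed <- function(reduced, out_dim = 2, perplexity = 30, seed = 1L,
                       labels = NULL) {
  reduced <- as.matrix(reduced)
  n <- nrow(reduced)
  if (!out_dim %in% c(2L, 3L)) stop("out_dim must be 2 or 3")
  if (perplexity >= n) stop("perplexity (", perplexity,
                            ") must be smaller than n_points (", n, ")")
  if (3 * perplexity >= n - 1) {
    stop("perplexity too large for ", n,
         " points; need 3 * perplexity < n - 1")
  }
  set.seed(seed)
  fit <- Rtsne::Rtsne(reduced, dims = out_dim, perplexity = perplexity,
                      pca = FALSE, check_duplicates = FALSE, verbose = FALSE)
  structure(
    list(coordinates = fit$Y, labels = labels,
         method_params = list(out_dim = out_dim, perplexity = perplexity,
                              seed = seed)),
    class = "embedding_result"
  )
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result: %d points in %d-D (perplexity %g)>\n",
              nrow(x$coordinates), ncol(x$coordinates),
              x$method_params$perplexity))
  invisible(x)
}

#' Silhouette-based cluster separability of an embedding
#'
#' Mean silhouette width over all points with Euclidean distance,
#' quantifying how conspicuously the labelled groups cluster in the
#' embedding. Points in singleton clusters contribute 0 by convention.
#'
#' @param coordinates Numeric matrix of embedded points.
#' @param labels Per-point labels (>= 2 distinct values).
#' @return Mean silhouette score in \[-1, 1\].
#' @export
cluster_separability <- function(coordinates, labels) {
  coordinates <- as.matrix(coordinates)
  stopifnot(nrow(coordinates) == length(labels))
  cl <- as.integer(factor(labels))
  if (length(unique(cl)) < 2L) {
    stop("need at least 2 distinct labels")
  }
  sil <- cluster::silhouette(cl, stats::dist(coordinates))
  # all-singleton partitions have no silhouette object; score 0 by convention
  if (!inherits(sil, "silhouette")) return(0)
  mean(sil[, "sil_width"])
}
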