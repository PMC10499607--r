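#' Aggregate cells into pseudocells
#'
#' Randomly selects a fraction of cells as seeds (round-half-up) and
#' builds a territory per seed from its `k` nearest neighbours (plus the
#' seed itself) in PCA space computed on the z-scaled expression of the
#' most variable genes. A cell claimed by several territories is assigned
#' to one of them uniformly at random. Expression is aggregated as the
#' arithmetic mean of territory members; accessibility as the mean of
#' binarized counts, hence a probability in `[0, 1]`.
#'
#' @param expr genes x cells log-normalized expression matrix.
#' @param access_counts peaks x cells accessibility count matrix.
#' @param n_pcs Number of principal components (default 20).
#' @param seed_fraction Fraction of cells used as seeds (default 0.3).
#' @param k Neighbours per territory (default 10).
#' @param seed Integer seed.
#' @param n_var_genes Number of most-variable genes entering PCA
#'   (default 2000; capped at the gene count).
#' @return A list with `map` (named list seed cell -> member indices),
#'   `paired` (the aggregated [paired_matrix()]) and `seed_cells`.
#' @export
make_pseudocells <- function(expr, access_counts, n_pcs = 20,
                             seed_fraction = 0.3, k = 10, seed = 1,
                             n_var_genes = 2000) {
  n <- ncol(expr)
  if (n < k + 1) stop("need at least k + 1 = ", k + 1, " cells")
  if (ncol(access_counts) != n) {
    stop("expression and accessibility must cover the same cells")
  }
  set.seed(seed)
  v <- apply(expr, 1, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_var_genes, nrow(expr)))]
  x <- t(expr[keep, , drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  x <- scale(x, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  n_pcs <- min(n_pcs, ncol(x), n - 1)
  pcs <- stats::prcomp(x, rank. = n_pcs, center = FALSE, scale. = FALSE)$x

  n_seeds <- floor(seed_fraction * n + 0.5)  # round half up
  n_seeds <- max(1, n_seeds)
  seeds <- sample.int(n, n_seeds)

  d <- as.matrix(stats::dist(pcs))
  territories <- lapply(seeds, function(s) {
    nn <- order(d[s, ])           # self first (distance 0)
    union(s, utils::head(setdiff(nn, s), k))
  })
  # resolve multi-territory cells uniformly at random
  claims <- data.frame(cell = unlist(territories),
                       terr = rep(seq_along(territories),
                                  lengths(territories)))
  claims <- claims[sample.int(nrow(claims)), ]
  claims <- claims[!duplicated(claims$cell), ]
  members <- split(claims$cell, claims$terr)

  terr_ids <- as.integer(names(members))
  seed_cells <- seeds[terr_ids]
  agg_expr <- vapply(members, function(m) {
    rowMeans(expr[, m, drop = FALSE])
  }, numeric(nrow(expr)))
  agg_access <- vapply(members, function(m) {
    rowMeans(access_counts[, m, drop = FALSE] > 0)
  }, numeric(nrow(access_counts)))
  if (is.null(colnames(expr))) {
    colnames(expr) <- paste0("cell", seq_len(n))
  }
  pc_names <- paste0("pseudocell_", colnames(expr)[seed_cells])
  colnames(agg_expr) <- colnames(agg_access) <- pc_names
  rownames(agg_expr) <- rownames(expr)
  rownames(agg_access) <- rownames(access_counts)

  map <- stats::setNames(members, pc_names)
  list(map = map,
       paired = paired_matrix(agg_expr, agg_access),
       seed_cells = colnames(expr)[seed_cells])
}

#' Latent semantic indexing of a peak-count matrix
#'
#' tf-idf transform (term frequency per observation, scaled by
#' `log(1 + N / df)`) followed by truncated SVD. The first component is
#' retained (no depth-component dropping).
#'
#' @param access_counts peaks x observations nonnegative count matrix.
#' @param n_components Number of singular vectors (default 20, capped at
#'   the matrix rank bound).
#' @return observations x n_components embedding (`V %*% diag(d)`), with
#'   the singular values as attribute `"d"`.
#' @export
lsi <- function(access_counts, n_components = 20) {
  x <- as.matrix(access_counts)
  if (all(x == 0)) stop("all-zero accessibility matrix")
  n <- ncol(x)
  csum <- colSums(x)
  csum[csum == 0] <- 1
  tf <- sweep(x, 2, csum, `/`)
  df <- rowSums(x > 0)
  idf <- log(1 + n / pmax(df, 1))
  tfidf <- tf * idf
  k <- min(n_components, nrow(x), n)
  sv <- svd(tfidf, nu = 0, nv = k)
  emb <- sv$v[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(emb) <- colnames(x)
  colnames(emb) <- paste0("LSI_", seq_len(k))
  attr(emb, "d") <- sv$d[seq_len(k)]
  emb
}

#' High-resolution Louvain clustering of an embedding
#'
#' Builds an unweighted symmetric k-nearest-neighbour graph (Euclidean)
#' and runs Louvain modularity optimization at the given resolution.
#'
#' @param embedding observations x dimensions matrix.
#' @param resolution Louvain resolution (default 100).
#' @param k Neighbours for the kNN graph (default 20, capped at n - 1).
#' @param seed Integer seed.
#' @return Integer vector of 0-based, contiguous cluster labels.
#' @export
cluster_high_resolution <- function(embedding, resolution = 100, k = 20,
                                    seed = 1) {
  n <- nrow(embedding)
  if (n < 2) stop("need at least 2 observations")
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(embedding))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nn <- order(d[i, ])
    nn <- setdiff(nn, i)[seq_len(k)]
    cbind(i, nn)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- igraph::membership(cl)
  as.integer(factor(labels)) - 1L
}

#' Summarize accessibility probabilities to cluster level
#'
#' @param access peaks x observations accessibility matrix.
#' @param labels Cluster label per observation.
#' @return peaks x clusters matrix of mean accessibility, columns named by
#'   cluster label.
#' @export
summarize_access_by_cluster <- function(access, labels) {
  if (length(labels) != ncol(access)) {
    stop("labels must have one entry per observation")
  }
  if (length(labels) == 0) stop("empty cluster label set")
  labs <- sort(unique(labels))
  out <- vapply(labs, function(l) {
    rowMeans(access[, labels == l, drop = FALSE])
  }, numeric(nrow(access)))
  out <- matrix(out, nrow = nrow(access),
                dimnames = list(rownames(access), as.character(labs)))
  out
}
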