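#' Combined co-expression/regulation score
#'
#' `s = r * sqrt(|beta|) + 1`, combining the expression correlation `r`
#' between two TFs with the magnitude of the regulatory coefficient
#' linking them.
#'
#' @param r Pearson correlation in `[-1, 1]`.
#' @param beta Regulatory coefficient (any real).
#' @return The combined score (vectorized).
#' @export
combined_score <- function(r, beta) {
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must be <= 1")
  r * sqrt(abs(beta)) + 1
}

#' TF-by-TF combined score matrix
#'
#' `S[i, j] = r[i, j] * sqrt(|beta[i, j]|) + 1`, where `r` is the Pearson
#' correlation of log-normalized TF expression across observations and
#' `beta[i, j]` the mean significant coefficient of TF `j` acting on TF
#' `i` (0 when no significant edge links them).
#'
#' @param grn A [infer_grn()] result.
#' @param expr genes x observations expression matrix covering the TFs.
#' @param tfs TFs to include (default: all GRN TFs present in `expr`).
#' @return A list with matrices `s`, `r`, `beta` over the TF set.
#' @export
tf_score_matrix <- function(grn, expr, tfs = NULL) {
  if (is.null(tfs)) tfs <- sort(unique(grn$edges$tf))
  tfs <- intersect(tfs, rownames(expr))
  if (length(tfs) < 2) stop("need at least 2 TFs with expression")
  r <- stats::cor(t(expr[tfs, , drop = FALSE]))
  r[is.na(r)] <- 0
  beta <- matrix(0, length(tfs), length(tfs), dimnames = list(tfs, tfs))
  e <- grn$edges[grn$edges$tf %in% tfs & grn$edges$target %in% tfs, ,
                 drop = FALSE]
  if (nrow(e)) {
    mb <- tapply(e$beta, list(e$target, e$tf), mean)
    beta[rownames(mb), colnames(mb)] <- ifelse(is.na(mb), 0, mb)
  }
  list(s = combined_score(r, beta), r = r, beta = beta)
}

#' Embed the TF network in two dimensions
#'
#' PCA on the rows of the combined-score matrix followed by UMAP on the
#' top principal components; deterministic under a fixed seed
#' (single-threaded). TFs with identical score rows are embedded once and
#' share coordinates (stochastic layout optimization would otherwise
#' scatter exact duplicates).
#'
#' @param s Square combined-score matrix (TF x TF).
#' @param n_pcs Principal components kept (default 20, capped).
#' @param seed Integer seed.
#' @param n_neighbors UMAP neighbourhood size (default 15, capped at
#'   n - 1).
#' @return TF x 2 coordinate matrix.
#' @export
embed_tf_network <- function(s, n_pcs = 20, seed = 1, n_neighbors = 15) {
  n <- nrow(s)
  if (n < 3) stop("need at least 3 TFs")
  if (stats::sd(as.numeric(s)) == 0) stop("constant score matrix")
  key <- apply(s, 1, paste, collapse = "\r")
  rep_idx <- match(key, key)           # first occurrence per distinct row
  uniq <- which(rep_idx == seq_len(n))
  if (length(uniq) < 3) stop("need at least 3 distinct TF profiles")
  n_pcs <- min(n_pcs, length(uniq) - 1, ncol(s))
  pcs <- stats::prcomp(s[uniq, , drop = FALSE], rank. = n_pcs)$x
  set.seed(seed)
  emb <- uwot::umap(pcs, n_neighbors = min(n_neighbors, length(uniq) - 1),
                    n_threads = 1, n_sgd_threads = 1)
  coords <- emb[match(rep_idx, uniq), , drop = FALSE]
  rownames(coords) <- rownames(s)
  colnames(coords) <- c("UMAP_1", "UMAP_2")
  coords
}

grn_tf_graph <- function(grn, tf_only = FALSE) {
  e <- grn$edges
  # collapse parallel region-mediated edges to one signed edge per pair
  key <- paste(e$tf, e$target)
  agg <- tapply(e$beta, key, mean)
  pairs <- do.call(rbind, strsplit(names(agg), " "))
  el <- data.frame(from = pairs[, 1], to = pairs[, 2],
                   beta = as.numeric(agg), stringsAsFactors = FALSE)
  if (tf_only) {
    tfs <- unique(e$tf)
    el <- el[el$to %in% tfs, , drop = FALSE]
    g <- igraph::graph_from_data_frame(el, directed = TRUE,
                                       vertices = data.frame(name = tfs))
  } else {
    g <- igraph::graph_from_data_frame(el, directed = TRUE)
  }
  g
}

#' PageRank centrality of TFs in the GRN
#'
#' PageRank on the directed TF -> target graph restricted to TF nodes
#' (edges into non-TF targets are dropped); scores sum to 1.
#'
#' @param grn A [infer_grn()] result with a nonempty edge set.
#' @param damping Damping factor (default 0.85).
#' @return Named numeric vector of PageRank scores over TFs.
#' @export
pagerank_centrality <- function(grn, damping = 0.85) {
  if (nrow(grn$edges) == 0) stop("GRN has no edges")
  g <- grn_tf_graph(grn, tf_only = TRUE)
  pr <- igraph::page_rank(g, damping = damping, directed = TRUE)$vector
  pr / sum(pr)
}

#' Predict knockout DE direction from GRN shortest paths
#'
#' For each DE gene reachable from `source_tf`, all unweighted shortest
#' paths are enumerated; each path's direction is the product of its edge
#' signs and the predicted effect of the source on the gene is the mode
#' over paths (ties are `"ambiguous"` and excluded from accuracy). Under
#' the knockout convention, net activation by the source predicts
#' down-regulation upon its loss, so a gene counts as correct when its
#' observed DE direction is the inverse of the predicted effect. DE-gene
#' enrichment in the first (direct) and second order (indirect)
#' neighbourhood of the source is tested with Fisher's exact test over the
#' GRN gene universe.
#'
#' @param grn A [infer_grn()] result.
#' @param source_tf The perturbed TF (must be in the GRN).
#' @param de_table Data frame with columns `gene` and `direction`
#'   (`"+"`/`"-"` or +1/-1), observed under source knockout.
#' @return A list with `predictions` (gene, predicted KO direction,
#'   observed, correct), `accuracy`, `unreachable`, `fisher_first`,
#'   `fisher_second` (p-values).
#' @export
predict_direction_by_paths <- function(grn, source_tf, de_table) {
  e <- grn$edges
  if (!source_tf %in% e$tf) stop("source TF not in GRN")
  dir_num <- function(d) {
    if (is.character(d)) ifelse(d == "+", 1, -1) else sign(d)
  }
  g <- grn_tf_graph(grn)
  sign_of <- function(path) {
    # product of edge signs along a vertex path
    ids <- igraph::get_edge_ids(g, rep(path, each = 2)[-c(1, 2 * length(path))])
    prod(sign(igraph::E(g)$beta[ids]))
  }
  genes <- as.character(de_table$gene)
  observed <- dir_num(de_table$direction)
  known <- genes %in% igraph::V(g)$name
  pred <- rep(NA_character_, length(genes))
  for (i in which(known)) {
    if (genes[i] == source_tf) next
    sp <- suppressWarnings(igraph::all_shortest_paths(
      g, from = source_tf, to = genes[i], mode = "out"))
    if (!length(sp$vpaths)) next
    signs <- vapply(sp$vpaths, function(p) sign_of(as.integer(p)), 0)
    n_pos <- sum(signs > 0)
    n_neg <- sum(signs < 0)
    effect <- if (n_pos == n_neg) 0 else sign(n_pos - n_neg)
    # KO inverts the net effect of the source
    pred[i] <- if (effect == 0) "ambiguous" else if (-effect > 0) "+" else "-"
  }
  reachable <- !is.na(pred)
  predictions <- data.frame(
    gene = genes, predicted = pred,
    observed = ifelse(observed > 0, "+", "-"),
    correct = !is.na(pred) & pred != "ambiguous" &
      pred == ifelse(observed > 0, "+", "-"),
    stringsAsFactors = FALSE)
  usable <- reachable & pred != "ambiguous"
  accuracy <- if (any(usable)) mean(predictions$correct[usable]) else NA_real_

  universe <- unique(c(e$tf, e$target))
  first <- unique(e$target[e$tf == source_tf])
  second <- unique(c(first, e$target[e$tf %in% intersect(first, e$tf)]))
  fisher_nb <- function(nb) {
    in_de <- universe %in% genes
    in_nb <- universe %in% nb
    stats::fisher.test(table(factor(in_de, c(FALSE, TRUE)),
                             factor(in_nb, c(FALSE, TRUE))))$p.value
  }
  list(predictions = predictions, accuracy = accuracy,
       unreachable = genes[!reachable],
       fisher_first = fisher_nb(first), fisher_second = fisher_nb(second))
}
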