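#' Rank-normalized transition scores
#'
#' Per terminal state, absorption probabilities are ranked (average ranks
#' for ties) and divided by the number of observations, giving scores in
#' (0, 1] that are invariant to any strictly monotone transform of each
#' column.
#'
#' @param absorption_probs observations x terminal-states matrix of
#'   probabilities in `[0, 1]`.
#' @return Matrix of the same shape with rank/N scores.
#' @export
transition_scores <- function(absorption_probs) {
  m <- as.matrix(absorption_probs)
  if (any(m < 0 | m > 1)) stop("absorption probabilities must be in [0, 1]")
  apply(m, 2, function(v) rank(v, ties.method = "average") / length(v))
}

#' Build the coarse fate graph over trajectory nodes
#'
#' Nodes (high-resolution clusters) are connected to their k nearest
#' neighbours in transition-score space (Euclidean over the terminal-state
#' score vectors); edges are kept only between nodes with connectivity
#' above the threshold and oriented from lower to higher pseudotime
#' (strict inequality; ties are dropped).
#'
#' @param scores nodes x terminal-states transition-score matrix (row
#'   names = node ids).
#' @param pseudotime Named numeric pseudotime per node.
#' @param connectivities Symmetric nonnegative node x node connectivity
#'   matrix.
#' @param k Nearest neighbours (default 30, capped at n - 1).
#' @param conn_threshold Connectivity threshold (default 0.2).
#' @return A list with `graph` (directed igraph), `scores`, `pseudotime`,
#'   `connectivities`.
#' @export
build_fate_graph <- function(scores, pseudotime, connectivities, k = 30,
                             conn_threshold = 0.2) {
  nodes <- rownames(scores)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(scores)))
  n <- length(nodes)
  pseudotime <- pseudotime[nodes]
  connectivities <- connectivities[nodes, nodes, drop = FALSE]
  k <- min(k, n - 1)
  d <- as.matrix(stats::dist(scores))
  edges <- NULL
  for (i in seq_len(n)) {
    nn <- setdiff(order(d[i, ]), i)[seq_len(k)]
    for (j in nn) {
      if (connectivities[i, j] <= conn_threshold) next
      if (pseudotime[i] < pseudotime[j]) {
        edges <- rbind(edges, c(i, j))
      } else if (pseudotime[j] < pseudotime[i]) {
        edges <- rbind(edges, c(j, i))
      }
      # equal pseudotimes: edge dropped
    }
  }
  g <- igraph::make_empty_graph(n, directed = TRUE)
  igraph::V(g)$name <- nodes
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, t(unique(edges)))
    g <- igraph::simplify(g)
  }
  list(graph = g, scores = scores, pseudotime = pseudotime,
       connectivities = connectivities)
}

# Auto tip per terminal state: node maximizing the product of the ranks of
# its transition score and its pseudotime.
auto_tips <- function(fate) {
  nodes <- rownames(fate$scores)
  pt_rank <- rank(fate$pseudotime)
  tips <- apply(fate$scores, 2, function(s) {
    nodes[which.max(rank(s) * pt_rank)]
  })
  tips
}

#' Assign branch identities by backward random walks
#'
#' From each tip, uniform random walks are performed along reversed edges
#' (backwards in pseudotime); walks stop early at nodes with no backward
#' edge. Per node, visitation frequencies from each tip decide the
#' identity: a single tip when its frequency exceeds `ratio` times the
#' next highest, otherwise the combination of all tips within `ratio` of
#' the top (multi-identity labels are renamed via `merge_map` when
#' provided, default: tip labels joined with `+`). Unreached nodes inherit
#' the label of their highest-connectivity neighbour; isolated unreached
#' nodes are `"unassigned"`.
#'
#' @param fate A [build_fate_graph()] result.
#' @param tips Named character vector (terminal state -> tip node), or
#'   `NULL` for automatic selection (node maximizing the product of
#'   transition-score and pseudotime ranks).
#' @param n_walks Walks per tip (default 10000).
#' @param walk_len Steps per walk (default 200).
#' @param ratio Dominance ratio (default 100).
#' @param merge_map Optional named character vector renaming multi-tip
#'   labels, keyed by the sorted tip states joined with `+` (e.g.
#'   `c("dorsal+ventral" = "telencephalon")`).
#' @param seed Integer seed.
#' @return Named character vector: node -> identity label.
#' @export
assign_branches <- function(fate, tips = NULL, n_walks = 10000,
                            walk_len = 200, ratio = 100, merge_map = NULL,
                            seed = 1) {
  g <- fate$graph
  nodes <- igraph::V(g)$name
  if (is.null(tips)) tips <- auto_tips(fate)
  states <- names(tips)
  if (is.null(states)) states <- colnames(fate$scores)
  set.seed(seed)
  # reversed adjacency: backward in pseudotime
  radj <- lapply(seq_along(nodes), function(i) {
    as.integer(igraph::neighbors(g, i, mode = "in"))
  })
  visits <- matrix(0, length(nodes), length(tips),
                   dimnames = list(nodes, states))
  for (ti in seq_along(tips)) {
    cur <- rep(match(tips[ti], nodes), n_walks)
    visits[, ti] <- visits[, ti] + tabulate(cur, length(nodes))
    for (step in seq_len(walk_len)) {
      alive <- which(!is.na(cur))
      if (!length(alive)) break
      nxt <- rep(NA_integer_, length(cur))
      for (u in unique(cur[alive])) {
        nb <- radj[[u]]
        at_u <- alive[cur[alive] == u]
        if (!length(nb)) next  # dead end: walks terminate
        nxt[at_u] <- nb[sample.int(length(nb), length(at_u), replace = TRUE)]
      }
      cur <- nxt
      alive <- which(!is.na(cur))
      if (length(alive)) {
        visits[, ti] <- visits[, ti] + tabulate(cur[alive], length(nodes))
      }
    }
  }
  labels <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  for (i in seq_along(nodes)) {
    f <- visits[i, ]
    if (all(f == 0)) next
    ord <- order(f, decreasing = TRUE)
    top <- f[ord[1]]
    if (length(f) == 1 || top > ratio * f[ord[2]]) {
      labels[i] <- states[ord[1]]
    } else {
      within <- states[f * ratio >= top & f > 0]
      key <- paste(sort(within), collapse = "+")
      labels[i] <- if (!is.null(merge_map) && key %in% names(merge_map)) {
        merge_map[[key]]
      } else {
        key
      }
    }
  }
  # unreached nodes inherit the highest-connectivity neighbour's label
  unreached <- which(is.na(labels))
  for (i in unreached) {
    conn <- fate$connectivities[i, ]
    conn[i] <- 0
    nb <- which(conn > 0 & !is.na(labels))
    labels[i] <- if (length(nb)) {
      labels[nb[which.max(conn[nb])]]
    } else {
      "unassigned"
    }
  }
  labels
}
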