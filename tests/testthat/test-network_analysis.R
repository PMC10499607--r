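toy_grn <- function(edges) {
  structure(list(edges = edges, all_edges = edges,
                 modules = regulokit:::tf_modules(edges)),
            class = "grn")
}

test_that("combined score evaluates the printed formula", {
  expect_equal(combined_score(0.5, 4), 2.0)
  expect_equal(combined_score(0, 123), 1.0)
  expect_equal(combined_score(-0.5, 1), 0.5)
  expect_error(combined_score(1.5, 1), "<= 1")
  # odd symmetry around 1 in r
  for (r in c(0.1, 0.4, 0.9)) {
    for (b in c(0.5, 2, 9)) {
      expect_equal(combined_score(r, b) + combined_score(-r, b), 2)
    }
  }
})

test_that("TF score matrix combines correlation with mean coefficients", {
  set.seed(71)
  expr <- matrix(runif(3 * 50), 3, 50,
                 dimnames = list(c("TF1", "TF2", "TF3"), NULL))
  edges <- data.frame(tf = c("TF1", "TF1"), region_id = c("R1", "R2"),
                      target = "TF2", beta = c(2, 4), pval = 1e-5,
                      fdr = 1e-4)
  sm <- tf_score_matrix(toy_grn(edges), expr,
                        tfs = c("TF1", "TF2", "TF3"))
  expect_equal(unname(sm$beta["TF2", "TF1"]), 3)  # mean(2, 4)
  r <- stats::cor(expr["TF2", ], expr["TF1", ])
  expect_equal(unname(sm$s["TF2", "TF1"]), r * sqrt(3) + 1)
  expect_equal(unname(sm$s["TF3", "TF1"]),
               stats::cor(expr["TF3", ], expr["TF1", ]) * 0 + 1)
})

test_that("TF network embedding is deterministic and respects duplicates", {
  set.seed(72)
  s <- matrix(rnorm(64), 8, 8, dimnames = list(paste0("T", 1:8),
                                               paste0("T", 1:8)))
  s[2, ] <- s[1, ]  # identical TF rows
  c1 <- embed_tf_network(s, seed = 4)
  c2 <- embed_tf_network(s, seed = 4)
  expect_identical(c1, c2)
  expect_equal(unname(c1[1, ]), unname(c1[2, ]))  # identical rows coincide
  expect_equal(dim(c1), c(8, 2))
  expect_error(embed_tf_network(matrix(1, 5, 5)), "constant")
  expect_error(embed_tf_network(s[1:2, 1:2]), "at least 3")
})

test_that("pagerank centrality matches symmetry and a power-iteration oracle", {
  sym <- toy_grn(data.frame(tf = c("A", "B"), region_id = c("R1", "R2"),
                            target = c("B", "A"), beta = 1, pval = 0,
                            fdr = 0))
  pr <- pagerank_centrality(sym)
  expect_equal(unname(pr), c(0.5, 0.5))

  star <- toy_grn(data.frame(tf = c("H", "H", "H", "A", "B", "C"),
                             region_id = paste0("R", 1:6),
                             target = c("A", "B", "C", "H", "H", "H"),
                             beta = 1, pval = 0, fdr = 0))
  prs <- pagerank_centrality(star)
  expect_true(prs["H"] > max(prs[c("A", "B", "C")]))
  expect_equal(sum(prs), 1, tolerance = 1e-12)

  # power-iteration oracle on a small directed graph where every node
  # regulates something (so the TF-restricted graph covers all 6 nodes)
  set.seed(73)
  nodes <- paste0("T", 1:6)
  repeat {
    el <- expand.grid(tf = nodes, target = nodes, stringsAsFactors = FALSE)
    el <- el[el$tf != el$target & runif(nrow(el)) < 0.4, ]
    if (setequal(unique(el$tf), nodes)) break
  }
  g <- toy_grn(data.frame(el, region_id = paste0("R", seq_len(nrow(el))),
                          beta = 1, pval = 0, fdr = 0))
  pr <- pagerank_centrality(g, damping = 0.85)
  A <- matrix(0, 6, 6, dimnames = list(nodes, nodes))
  A[cbind(el$tf, el$target)] <- 1
  out_deg <- rowSums(A)
  v <- rep(1 / 6, 6)
  for (i in 1:2000) {
    spread <- rep(0, 6)
    for (n in nodes) {
      if (out_deg[n] > 0) {
        spread <- spread + v[match(n, nodes)] * A[n, ] / out_deg[n]
      } else {
        spread <- spread + v[match(n, nodes)] / 6  # dangling node
      }
    }
    v <- 0.15 / 6 + 0.85 * spread
  }
  expect_equal(unname(pr[nodes]), unname(v / sum(v)), tolerance = 1e-8)
})

test_that("KO direction prediction follows shortest-path sign products", {
  # chain source -(+)-> A -(-)-> B: net repression, KO de-represses B
  chain <- toy_grn(data.frame(tf = c("S", "A"), region_id = c("R1", "R2"),
                              target = c("A", "B"), beta = c(2, -1),
                              pval = 0, fdr = 0))
  res <- predict_direction_by_paths(chain, "S",
                                    data.frame(gene = "B", direction = "+"))
  expect_equal(res$predictions$predicted, "+")
  expect_true(res$predictions$correct)
  expect_equal(res$accuracy, 1)

  # two equal-length paths with opposite products: ambiguous
  tie <- toy_grn(data.frame(tf = c("S", "S", "A", "C"),
                            region_id = paste0("R", 1:4),
                            target = c("A", "C", "B", "B"),
                            beta = c(1, 1, 1, -1), pval = 0, fdr = 0))
  res <- predict_direction_by_paths(tie, "S",
                                    data.frame(gene = "B", direction = "-"))
  expect_equal(res$predictions$predicted, "ambiguous")
  expect_true(is.na(res$accuracy))

  # unreachable genes are reported separately
  res <- predict_direction_by_paths(chain, "S",
                                    data.frame(gene = "Z", direction = "+"))
  expect_equal(res$unreachable, "Z")
})

test_that("path products match a brute-force BFS oracle on random graphs", {
  set.seed(74)
  for (rep in 1:3) {
    nodes <- paste0("N", 1:12)
    el <- expand.grid(tf = nodes, target = nodes, stringsAsFactors = FALSE)
    el <- el[el$tf != el$target & runif(nrow(el)) < 0.15, ]
    el$beta <- sample(c(-1, 1), nrow(el), TRUE) * runif(nrow(el), 0.5, 2)
    grn <- toy_grn(data.frame(el, region_id = paste0("R", seq_len(nrow(el))),
                              pval = 0, fdr = 0))
    src <- "N1"
    if (!src %in% el$tf) next
    de <- data.frame(gene = setdiff(nodes, src), direction = "+")
    res <- predict_direction_by_paths(grn, src, de)

    # oracle: enumerate all shortest paths by BFS layers
    adj <- split(seq_len(nrow(el)), el$tf)
    oracle_pred <- sapply(de$gene, function(gene) {
      dist <- stats::setNames(rep(Inf, 12), nodes)
      dist[src] <- 0
      frontier <- src
      while (length(frontier) && is.infinite(dist[gene])) {
        nxt <- character()
        for (u in frontier) {
          for (ei in adj[[u]]) {
            v <- el$target[ei]
            if (is.infinite(dist[v])) nxt <- union(nxt, v)
          }
        }
        for (v in nxt) dist[v] <- dist[frontier[1]] + 1
        frontier <- nxt
      }
      if (is.infinite(dist[gene])) return(NA_character_)
      # count sign products over all shortest paths by dynamic programming
      npos <- stats::setNames(rep(0, 12), nodes)
      nneg <- npos
      npos[src] <- 1
      for (d in seq_len(dist[gene])) {
        npos2 <- nneg2 <- stats::setNames(rep(0, 12), nodes)
        for (u in nodes[dist == d - 1]) {
          for (ei in adj[[u]]) {
            v <- el$target[ei]
            if (dist[v] == d) {
              if (el$beta[ei] > 0) {
                npos2[v] <- npos2[v] + npos[u]
                nneg2[v] <- nneg2[v] + nneg[u]
              } else {
                npos2[v] <- npos2[v] + nneg[u]
                nneg2[v] <- nneg2[v] + npos[u]
              }
            }
          }
        }
        npos <- npos2
        nneg <- nneg2
      }
      if (npos[gene] == nneg[gene]) return("ambiguous")
      if (npos[gene] > nneg[gene]) "-" else "+"  # KO inverts
    })
    got <- res$predictions$predicted
    want <- unname(oracle_pred)
    expect_equal(got, want)
  }
})
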