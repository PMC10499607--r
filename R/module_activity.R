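#' Gene module activity score
#'
#' Control-matched module score: pool genes are binned into `n_bins` by
#' average expression; for each module gene, `n_ctrl` control genes are
#' sampled (with replacement) from the non-module genes of its bin (the
#' nearest bin with non-module genes when its own has none); the score per
#' observation is the mean expression of module genes minus the mean
#' expression of the control genes. Excluding module genes from the
#' control draw keeps an additive shift of the module fully visible in the
#' score instead of being partly absorbed into its own controls.
#'
#' @param expr genes x observations expression matrix.
#' @param module_genes Genes in the module (subset of `pool_genes`).
#' @param pool_genes Background pool (default: all rows of `expr`);
#'   typically all genes included in GRN inference.
#' @param n_bins Expression bins (default 24).
#' @param n_ctrl Control genes sampled per module gene (default 100).
#' @param seed Integer seed.
#' @return Numeric score per observation.
#' @export
gene_module_score <- function(expr, module_genes, pool_genes = rownames(expr),
                              n_bins = 24, n_ctrl = 100, seed = 1) {
  if (length(module_genes) == 0) stop("module is empty")
  if (!all(module_genes %in% pool_genes)) {
    stop("module genes must be contained in the pool")
  }
  pool_genes <- intersect(pool_genes, rownames(expr))
  set.seed(seed)
  avg <- rowMeans(expr[pool_genes, , drop = FALSE])
  n_bins <- min(n_bins, length(unique(avg)))
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  names(bins) <- pool_genes
  non_module <- setdiff(pool_genes, module_genes)
  if (!length(non_module)) stop("pool has no non-module control genes")
  ctrl <- unlist(lapply(module_genes, function(g) {
    candidates <- non_module[bins[non_module] == bins[g]]
    if (!length(candidates)) {
      nearest <- non_module[order(abs(bins[non_module] - bins[g]))]
      candidates <- nearest[seq_len(min(10, length(nearest)))]
    }
    sample(candidates, n_ctrl, replace = TRUE)
  }))
  colMeans(expr[module_genes, , drop = FALSE]) -
    colMeans(expr[ctrl, , drop = FALSE])
}

#' Regulatory module accessibility deviation
#'
#' Background-matched deviation z-score: background region sets of the
#' same size are drawn from accessibility-matched quantile bins; the
#' deviation per observation is the observed module mean accessibility
#' minus the expectation over background draws, divided by the s.d. over
#' draws. A degenerate background s.d. yields z = 0.
#'
#' @param access regions x observations accessibility matrix.
#' @param module_regions Regions in the module.
#' @param background_draws Number of background sets (default 50).
#' @param n_bins Accessibility-matching quantile bins (default 10).
#' @param seed Integer seed.
#' @return Numeric deviation z per observation.
#' @export
regulatory_module_deviation <- function(access, module_regions,
                                        background_draws = 50, n_bins = 10,
                                        seed = 1) {
  if (length(module_regions) == 0) stop("module regions are empty")
  set.seed(seed)
  all_regions <- rownames(access)
  avg <- rowMeans(access)
  n_bins <- min(n_bins, length(unique(avg)))
  bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
              labels = FALSE)
  names(bins) <- all_regions
  obs <- colMeans(access[module_regions, , drop = FALSE])
  bg <- vapply(seq_len(background_draws), function(i) {
    draw <- vapply(module_regions, function(r) {
      sample(all_regions[bins == bins[r]], 1)
    }, "")
    colMeans(access[draw, , drop = FALSE])
  }, numeric(ncol(access)))
  mu <- rowMeans(bg)
  s <- apply(bg, 1, stats::sd)
  z <- ifelse(s > 0, (obs - mu) / s, 0)
  unname(z)
}

#' Variance in module activity explained by branch and pseudotime
#'
#' Three OLS fits — activity ~ branch, ~ pseudotime, ~ branch + pseudotime
#' — returning each model's R squared.
#'
#' @param activity Numeric activity per observation.
#' @param branch Branch label per observation (>= 2 levels).
#' @param pseudotime Numeric pseudotime per observation.
#' @return Named vector `c(branch = , pseudotime = , both = )`.
#' @export
variance_explained <- function(activity, branch, pseudotime) {
  if (length(activity) < 3) stop("need at least 3 observations")
  if (length(unique(branch)) < 2) stop("need at least 2 branches")
  if (stats::var(activity) == 0) {
    return(c(branch = 0, pseudotime = 0, both = 0))
  }
  df <- data.frame(y = activity, branch = factor(branch),
                   pseudotime = pseudotime)
  # suppressed: summary.lm warns on essentially perfect fits
  r2 <- function(f) {
    suppressWarnings(summary(stats::lm(f, data = df))$r.squared)
  }
  c(branch = r2(y ~ branch), pseudotime = r2(y ~ pseudotime),
    both = r2(y ~ branch + pseudotime))
}

#' Differential module activity between two branches
#'
#' Restricts to observations above the pseudotime quantile, runs a
#' two-sided Wilcoxon rank-sum test per module between the two branches,
#' BH-adjusts, and returns for each branch the `top_k` modules with
#' significantly higher activity there (FDR < `fdr`), ranked by mean
#' activity difference.
#'
#' @param activity modules x observations activity matrix.
#' @param branch Branch label per observation.
#' @param pseudotime Numeric pseudotime per observation.
#' @param branches The two branches to compare (default: the two most
#'   frequent labels).
#' @param quantile Pseudotime quantile cutoff (default 0.7, i.e. the top
#'   30%).
#' @param top_k Modules returned per branch (default 15).
#' @param fdr FDR threshold (default 0.05).
#' @return A data frame (module, up_branch, mean_diff, p, fdr, rank).
#' @export
differential_module_activity <- function(activity, branch, pseudotime,
                                         branches = NULL, quantile = 0.7,
                                         top_k = 15, fdr = 0.05) {
  if (is.null(branches)) {
    branches <- names(sort(table(branch), decreasing = TRUE))[1:2]
  }
  cut_pt <- stats::quantile(pseudotime, quantile, names = FALSE)
  keep <- pseudotime > cut_pt & branch %in% branches
  if (!any(keep & branch == branches[1]) ||
      !any(keep & branch == branches[2])) {
    stop("a branch is empty after the pseudotime restriction")
  }
  act <- activity[, keep, drop = FALSE]
  grp <- branch[keep]
  res <- do.call(rbind, lapply(seq_len(nrow(act)), function(m) {
    x <- act[m, grp == branches[1]]
    y <- act[m, grp == branches[2]]
    p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
    data.frame(module = rownames(act)[m], mean_diff = mean(x) - mean(y),
               p = p, stringsAsFactors = FALSE)
  }))
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  out <- list()
  for (i in 1:2) {
    sgn <- if (i == 1) 1 else -1
    up <- res[res$fdr < fdr & sgn * res$mean_diff > 0, , drop = FALSE]
    up <- up[order(-sgn * up$mean_diff), , drop = FALSE]
    up <- utils::head(up, top_k)
    if (nrow(up)) {
      up$up_branch <- branches[i]
      up$rank <- seq_len(nrow(up))
      out[[i]] <- up
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(module = character(), mean_diff = numeric(),
                      p = numeric(), fdr = numeric(),
                      up_branch = character(), rank = integer())
  }
  rownames(out) <- NULL
  out
}

#' Branch activation score of gene modules
#'
#' Per gene, the correlation between its expression and the branch
#' (absorption) probability across observations; per module, the mean of
#' its genes' correlations; across modules, the means are z-scored
#' (sample standard deviation, so two modules with means 1 and -1 score
#' +-1/sqrt(2)). Genes with constant expression have undefined correlation
#' and are skipped (and counted).
#'
#' @param expr genes x observations expression matrix.
#' @param modules Named list of gene vectors (one per module).
#' @param branch_prob Branch probability per observation, in `[0, 1]`.
#' @param method Correlation type: `"pearson"` (default) or `"spearman"`.
#' @return A list with `score` (z-scored module means), `module_mean`,
#'   `gene_cor` (named list) and `n_skipped` per module.
#' @export
branch_activation_score <- function(expr, modules, branch_prob,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (any(branch_prob < 0 | branch_prob > 1)) {
    stop("branch probabilities must lie in [0, 1]")
  }
  gene_cor <- lapply(modules, function(genes) {
    genes <- intersect(genes, rownames(expr))
    cors <- vapply(genes, function(g) {
      x <- as.numeric(expr[g, ])
      if (stats::sd(x) == 0) return(NA_real_)
      stats::cor(x, branch_prob, method = method)
    }, 0)
    cors
  })
  n_skipped <- vapply(gene_cor, function(v) sum(is.na(v)), 0L)
  module_mean <- vapply(gene_cor, function(v) mean(v, na.rm = TRUE), 0)
  mu <- mean(module_mean)
  s <- stats::sd(module_mean)
  score <- if (isTRUE(s > 0)) (module_mean - mu) / s else
    rep(0, length(module_mean))
  list(score = score, module_mean = module_mean, gene_cor = gene_cor,
       n_skipped = n_skipped)
}
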