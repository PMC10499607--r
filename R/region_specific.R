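#' Trimmed z-transformation of accessibility across clusters
#'
#' Per region, the per-cluster mean ATAC read depth is regressed out of the
#' accessibility probabilities (OLS), and residuals are z-transformed using
#' a trimmed mean and s.d. computed only over clusters whose residual lies
#' within the 5th-95th percentile band. A trimmed s.d. of 0 yields z = 0
#' with a degenerate flag.
#'
#' @param access_by_cluster regions x clusters matrix of accessibility
#'   probabilities (from [summarize_access_by_cluster()]).
#' @param covariate Per-cluster mean ATAC read count (regressed out).
#' @param trim Percentile band (default `c(0.05, 0.95)`).
#' @return A list with `z` (regions x clusters) and `degenerate` (logical
#'   per region).
#' @export
trimmed_z <- function(access_by_cluster, covariate,
                      trim = c(0.05, 0.95)) {
  x <- as.matrix(access_by_cluster)
  n_cl <- ncol(x)
  if (n_cl < 10) stop("need at least 10 clusters for percentile trimming")
  if (length(covariate) != n_cl) {
    stop("covariate must have one value per cluster")
  }
  design <- cbind(1, covariate)
  use_cov <- stats::var(covariate) > 0
  z <- matrix(0, nrow(x), n_cl, dimnames = dimnames(x))
  degenerate <- logical(nrow(x))
  for (r in seq_len(nrow(x))) {
    resid <- if (use_cov) {
      stats::lm.fit(design, x[r, ])$residuals
    } else {
      x[r, ] - mean(x[r, ])
    }
    band <- stats::quantile(resid, trim, names = FALSE)
    inband <- resid >= band[1] & resid <= band[2]
    m <- mean(resid[inband])
    s <- stats::sd(resid[inband])
    # residuals that are numerically zero (perfect regression) are degenerate
    if (!is.finite(s) || s < 1e-10 || max(abs(resid)) < 1e-10) {
      degenerate[r] <- TRUE
      z[r, ] <- 0
    } else {
      z[r, ] <- (resid - m) / s
    }
  }
  list(z = z, degenerate = degenerate)
}

#' Call accessibility outlier clusters from z-scores
#'
#' Close outliers: BH over `pnorm(z)` per region across clusters, flagged
#' at FDR < `fdr`. Open outliers: the same on `1 - pnorm(z)`.
#'
#' @param z regions x clusters z-score matrix (or [trimmed_z()] output).
#' @param fdr Outlier FDR threshold (default 0.01).
#' @return A list with matrices `p_close`, `p_open`, `fdr_close`,
#'   `fdr_open` and logical flag matrices `close`, `open`.
#' @export
call_outliers <- function(z, fdr = 0.01) {
  if (is.list(z)) z <- z$z
  p_close <- stats::pnorm(z)
  p_open <- 1 - p_close
  adj_rows <- function(p) {
    t(apply(p, 1, stats::p.adjust, method = "BH"))
  }
  fdr_close <- adj_rows(p_close)
  fdr_open <- adj_rows(p_open)
  list(p_close = p_close, p_open = p_open,
       fdr_close = fdr_close, fdr_open = fdr_open,
       close = fdr_close < fdr, open = fdr_open < fdr)
}

#' Clusters in which each region is accessible (step-wise rule)
#'
#' If a region has close outliers, it is accessible in all clusters except
#' those; otherwise, if it has open outliers, it is accessible only in
#' those; with no outliers at all it is accessible in every cluster.
#'
#' @param outliers Output of [call_outliers()].
#' @return Named list: per region, the character vector of accessible
#'   cluster names.
#' @export
accessible_clusters <- function(outliers) {
  cl_names <- colnames(outliers$close)
  if (is.null(cl_names)) cl_names <- as.character(seq_len(ncol(outliers$close)))
  out <- lapply(seq_len(nrow(outliers$close)), function(r) {
    cls <- outliers$close[r, ]
    opn <- outliers$open[r, ]
    if (any(cls)) {
      cl_names[!cls]
    } else if (any(opn)) {
      cl_names[opn]
    } else {
      cl_names
    }
  })
  names(out) <- rownames(outliers$close)
  out
}

#' Propagate cluster accessibility to metacells
#'
#' A metacell has a region accessible iff its cluster is in the region's
#' accessible-cluster set.
#'
#' @param accessible Output of [accessible_clusters()].
#' @param metacell_clusters Cluster label per metacell.
#' @return regions x metacells logical matrix.
#' @export
metacell_accessibility <- function(accessible, metacell_clusters) {
  mc <- as.character(metacell_clusters)
  out <- t(vapply(accessible, function(cls) mc %in% cls,
                  logical(length(mc))))
  rownames(out) <- names(accessible)
  out
}

#' Find regions significantly depleted of accessible metacells per branch
#'
#' Per (region, branch), a 2x2 table of metacells (in-branch vs not) x
#' (region accessible vs not) is tested with a two-sided chi-squared test
#' (no continuity correction); p-values are BH-adjusted across regions
#' within each branch. A region is called inaccessible in a branch iff
#' FDR < `fdr` AND odds ratio < `or_max`. Zero-margin tables get p = 1;
#' odds ratios use the Haldane-Anscombe 0.5 correction when any cell is 0.
#'
#' @param metacell_branch Branch label per metacell.
#' @param metacell_access regions x metacells logical matrix
#'   ([metacell_accessibility()]).
#' @param fdr FDR threshold (default 0.01).
#' @param or_max Odds-ratio threshold (default 0.5).
#' @return A data frame (region_id, branch, p, fdr, odds_ratio,
#'   inaccessible).
#' @export
region_depletion_test <- function(metacell_branch, metacell_access,
                                  fdr = 0.01, or_max = 0.5) {
  branches <- sort(unique(metacell_branch))
  if (length(branches) < 2) stop("need at least 2 branches")
  res <- list()
  for (b in branches) {
    inb <- metacell_branch == b
    p <- numeric(nrow(metacell_access))
    or <- numeric(nrow(metacell_access))
    for (r in seq_len(nrow(metacell_access))) {
      acc <- metacell_access[r, ]
      tab <- c(a = sum(inb & acc), b = sum(inb & !acc),
               c = sum(!inb & acc), d = sum(!inb & !acc))
      if (sum(tab[c("a", "b")]) == 0 || sum(tab[c("c", "d")]) == 0 ||
          sum(tab[c("a", "c")]) == 0 || sum(tab[c("b", "d")]) == 0) {
        p[r] <- 1
      } else {
        p[r] <- suppressWarnings(
          stats::chisq.test(matrix(tab, 2, byrow = TRUE),
                            correct = FALSE)$p.value)
      }
      if (any(tab == 0)) tab <- tab + 0.5
      or[r] <- (tab["a"] * tab["d"]) / (tab["b"] * tab["c"])
    }
    adj <- stats::p.adjust(p, method = "BH")
    res[[b]] <- data.frame(region_id = rownames(metacell_access),
                           branch = b, p = p, fdr = adj, odds_ratio = or,
                           inaccessible = adj < fdr & or < or_max,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out
}

#' Prune a GRN to one branch
#'
#' Drops edges mediated by regions called inaccessible in the branch, then
#' drops all edges of TFs detected (expression > 0) in fewer than
#' `tf_min_detect` of the branch's observations.
#'
#' @param grn A [infer_grn()] result.
#' @param inaccessible_regions Character vector of region ids inaccessible
#'   in this branch (e.g. from [region_depletion_test()]).
#' @param expr genes x observations expression matrix restricted to the
#'   branch.
#' @param tf_min_detect Detection-rate threshold (default 0.05).
#' @return A `grn` object with the pruned edge set and rebuilt modules.
#' @export
prune_grn_by_branch <- function(grn, inaccessible_regions, expr,
                                tf_min_detect = 0.05) {
  edges <- grn$edges
  edges <- edges[!edges$region_id %in% inaccessible_regions, , drop = FALSE]
  tfs <- unique(edges$tf)
  tfs_in <- intersect(tfs, rownames(expr))
  detect <- stats::setNames(rep(0, length(tfs)), tfs)
  detect[tfs_in] <- rowMeans(expr[tfs_in, , drop = FALSE] > 0)
  edges <- edges[detect[edges$tf] >= tf_min_detect, , drop = FALSE]
  rownames(edges) <- NULL
  out <- grn
  out$edges <- edges
  out$modules <- tf_modules(edges)
  out
}
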