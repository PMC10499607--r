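#' Build the interaction design matrix for one target gene
#'
#' One column per distinct (TF, region) pair such that the region is
#' assigned to the target and carries a binding site of the TF; the column
#' value per observation is the product of TF expression and region
#' accessibility, `e_tf * a_region`. Duplicate (TF, region) pairs (e.g.
#' several motif hits in one region) are collapsed. Terms whose TF equals
#' the target (self-loops) or is detected (expression > 0) in fewer than
#' `min_detect` of observations are dropped.
#'
#' @param target Target gene id (must be a row of the expression matrix).
#' @param pairs Data frame with columns `gene_id`, `region_id` from
#'   [assign_regions_to_genes()].
#' @param sites Binding-site table with columns `region_id`, `tf` (from
#'   [scan_regions()]).
#' @param data A [paired_matrix()].
#' @param min_detect Minimum TF detection fraction (default 0.05).
#' @param cluster_labels Optional per-observation cluster labels; when
#'   given, accessibility enters as the cluster-level mean broadcast to
#'   member observations.
#' @param region_map Optional named vector mapping region ids to the
#'   accessibility row (peak) ids covering them (see
#'   [map_regions_to_peaks()]); by default region ids index accessibility
#'   rows directly.
#' @return A list with `design` (observations x terms matrix), `terms`
#'   (data frame `tf`, `region_id`) and `no_model` (`TRUE` when no term
#'   survives; not an error).
#' @export
build_design <- function(target, pairs, sites, data, min_detect = 0.05,
                         cluster_labels = NULL, region_map = NULL) {
  expr <- data$expression
  if (!target %in% rownames(expr)) {
    stop("target ", target, " not present in expression matrix")
  }
  no_model <- list(design = NULL,
                   terms = data.frame(tf = character(),
                                      region_id = character()),
                   no_model = TRUE)
  regions <- unique(pairs$region_id[pairs$gene_id == target])
  s <- sites[sites$region_id %in% regions, c("tf", "region_id"), drop = FALSE]
  s <- unique(s)
  s <- s[s$tf != target & s$tf %in% rownames(expr), , drop = FALSE]
  s$access_id <- if (is.null(region_map)) {
    s$region_id
  } else {
    unname(region_map[s$region_id])
  }
  s <- s[!is.na(s$access_id) &
           s$access_id %in% rownames(data$accessibility), , drop = FALSE]
  # candidates covered by one peak share an accessibility profile: collapse
  s <- s[!duplicated(s[, c("tf", "access_id")]), , drop = FALSE]
  if (nrow(s) == 0) return(no_model)
  detect <- rowMeans(expr[unique(s$tf), , drop = FALSE] > 0)
  s <- s[detect[s$tf] >= min_detect, , drop = FALSE]
  if (nrow(s) == 0) return(no_model)

  access <- data$accessibility
  if (!is.null(cluster_labels)) {
    by_cluster <- summarize_access_by_cluster(access, cluster_labels)
    access <- by_cluster[, as.character(cluster_labels), drop = FALSE]
    rownames(access) <- rownames(data$accessibility)
  }
  design <- vapply(seq_len(nrow(s)), function(i) {
    as.numeric(expr[s$tf[i], ]) * as.numeric(access[s$access_id[i], ])
  }, numeric(ncol(expr)))
  design <- matrix(design, ncol = nrow(s))
  colnames(design) <- paste(s$tf, s$region_id, sep = "|")
  list(design = design,
       terms = data.frame(tf = s$tf, region_id = s$region_id,
                          stringsAsFactors = FALSE),
       no_model = FALSE)
}

#' Fit the per-target interaction regression
#'
#' The default method is ordinary least squares (Gaussian noise, identity
#' link) with an intercept; per-term p-values come from the two-sided
#' t-test on the coefficient, which equals the F-test comparing the full
#' model against the model without that term. Rank-deficient designs are
#' handled by dropping aliased columns (in term order) and reporting them.
#' Regularized alternatives (`ridge`, `lasso`, `elastic_net` via glmnet)
#' and gradient boosting (`gbm` via xgboost, if installed) return
#' coefficients or importances with `pval = NA`.
#'
#' @param y Response vector (target expression per observation).
#' @param design observations x terms matrix from [build_design()].
#' @param method Regression back-end.
#' @return A list with `coef` (data frame `term`, `beta`, `pval`),
#'   `intercept`, `r_squared`, `dropped` (aliased term names).
#' @export
fit_target_model <- function(y, design,
                             method = c("glm", "ridge", "lasso",
                                        "elastic_net", "gbm")) {
  method <- match.arg(method)
  if (is.null(design) || ncol(design) < 1) stop("design has no columns")
  terms <- colnames(design)
  if (method == "glm") {
    if (length(y) <= ncol(design) + 1) {
      stop("need more observations than terms + 1 for OLS")
    }
    fit <- stats::lm(y ~ ., data = data.frame(y = y, design,
                                              check.names = FALSE))
    cf <- stats::coef(fit)[-1]
    dropped <- terms[is.na(cf)]
    # suppressed: summary.lm warns on essentially perfect (noiseless) fits
    sm <- suppressWarnings(summary(fit))$coefficients
    kept <- terms[!is.na(cf)]
    rows <- match(paste0("`", kept, "`"), rownames(sm))
    rows[is.na(rows)] <- match(kept, rownames(sm))[is.na(rows)]
    coef_tab <- data.frame(term = kept, beta = sm[rows, 1],
                           pval = sm[rows, 4], stringsAsFactors = FALSE)
    rownames(coef_tab) <- NULL
    return(list(coef = coef_tab,
                intercept = unname(stats::coef(fit)[1]),
                r_squared = suppressWarnings(summary(fit))$r.squared,
                dropped = dropped))
  }
  if (method %in% c("ridge", "lasso", "elastic_net")) {
    alpha <- c(ridge = 0, lasso = 1, elastic_net = 0.5)[[method]]
    # glmnet needs >= 2 columns; pad with a zero column if necessary
    x <- design
    padded <- FALSE
    if (ncol(x) == 1) {
      x <- cbind(x, pad = 0)
      padded <- TRUE
    }
    cv <- glmnet::cv.glmnet(x, y, alpha = alpha,
                            nfolds = max(3, min(10, floor(length(y) / 3))))
    beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
    if (padded) beta <- beta[-3]
    return(list(coef = data.frame(term = terms, beta = beta[-1],
                                  pval = NA_real_, stringsAsFactors = FALSE),
                intercept = beta[1],
                r_squared = 1 - min(cv$cvm) / stats::var(y), dropped = character()))
  }
  if (!requireNamespace("xgboost", quietly = TRUE)) {
    stop("method 'gbm' requires the xgboost package")
  }
  bst <- xgboost::xgboost(data = design, label = y, nrounds = 50,
                          max_depth = 3, eta = 0.3, verbose = 0,
                          objective = "reg:squarederror", nthread = 1)
  imp <- xgboost::xgb.importance(model = bst)
  gain <- stats::setNames(rep(0, length(terms)), terms)
  gain[imp$Feature] <- imp$Gain
  pred <- stats::predict(bst, design)
  list(coef = data.frame(term = terms, beta = unname(gain),
                         pval = NA_real_, stringsAsFactors = FALSE),
       intercept = mean(y),
       r_squared = 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
       dropped = character())
}

#' Infer a gene regulatory network
#'
#' Fits the interaction regression for every target gene appearing in
#' `gene_pairs`, pools all coefficient p-values across all models into one
#' Benjamini-Hochberg correction, and retains edges with FDR below the
#' threshold. Per-TF modules are built from the retained edges, split by
#' coefficient sign.
#'
#' @param data A [paired_matrix()].
#' @param sites Binding-site table ([scan_regions()]).
#' @param gene_pairs Gene-region assignment ([assign_regions_to_genes()]).
#' @param fdr_threshold Edge FDR threshold (default 0.05).
#' @param method Regression back-end (see [fit_target_model()]); only
#'   `"glm"` produces p-values, other methods return all edges unfiltered
#'   with `fdr = NA`.
#' @param min_detect TF detection filter (default 0.05).
#' @param cluster_labels Optional accessibility cluster labels (see
#'   [build_design()]).
#' @param region_map Optional region id to accessibility (peak) row
#'   mapping (see [map_regions_to_peaks()]).
#' @param targets Restrict inference to these targets (default: all genes
#'   in `gene_pairs` present in the expression matrix).
#' @return An object of class `grn`: list with `edges` (significant edges:
#'   `tf`, `region_id`, `target`, `beta`, `pval`, `fdr`), `all_edges`,
#'   `fit_info` (per-target `n_terms`, `r_squared`), `modules` (per-TF
#'   positive/negative target and region sets) and `skipped` (targets with
#'   no model).
#' @export
infer_grn <- function(data, sites, gene_pairs, fdr_threshold = 0.05,
                      method = "glm", min_detect = 0.05,
                      cluster_labels = NULL, region_map = NULL,
                      targets = NULL) {
  if (is.null(targets)) {
    targets <- intersect(unique(gene_pairs$gene_id), rownames(data$expression))
  }
  edges <- list()
  fit_info <- list()
  skipped <- character()
  for (tg in targets) {
    dm <- build_design(tg, gene_pairs, sites, data, min_detect,
                       cluster_labels, region_map)
    if (dm$no_model) {
      skipped <- c(skipped, tg)
      next
    }
    fit <- fit_target_model(as.numeric(data$expression[tg, ]), dm$design,
                            method = method)
    keep <- match(fit$coef$term, colnames(dm$design))
    edges[[tg]] <- data.frame(tf = dm$terms$tf[keep],
                              region_id = dm$terms$region_id[keep],
                              target = tg, beta = fit$coef$beta,
                              pval = fit$coef$pval, stringsAsFactors = FALSE)
    fit_info[[tg]] <- data.frame(target = tg, n_terms = nrow(fit$coef),
                                 r_squared = fit$r_squared,
                                 stringsAsFactors = FALSE)
  }
  all_edges <- if (length(edges)) {
    do.call(rbind, c(edges, list(make.row.names = FALSE)))
  } else {
    data.frame(tf = character(), region_id = character(),
               target = character(), beta = numeric(), pval = numeric())
  }
  all_edges$fdr <- stats::p.adjust(all_edges$pval, method = "BH")
  sig <- if (method == "glm") {
    all_edges[!is.na(all_edges$fdr) & all_edges$fdr < fdr_threshold, ,
              drop = FALSE]
  } else {
    all_edges
  }
  rownames(sig) <- NULL
  structure(list(edges = sig, all_edges = all_edges,
                 fit_info = do.call(rbind, c(fit_info,
                                             list(make.row.names = FALSE))),
                 modules = tf_modules(sig), fdr_threshold = fdr_threshold,
                 skipped = skipped),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat("grn:", nrow(x$edges), "significant edges,",
      length(x$modules), "TF modules,",
      length(unique(x$edges$target)), "targets\n")
  invisible(x)
}

# Per-TF modules: positively/negatively regulated targets and regions,
# backed by significant edges split by coefficient sign.
tf_modules <- function(edges) {
  if (nrow(edges) == 0) return(list())
  lapply(split(edges, edges$tf), function(e) {
    list(tf = e$tf[1],
         positive_targets = sort(unique(e$target[e$beta > 0])),
         negative_targets = sort(unique(e$target[e$beta < 0])),
         positive_regions = sort(unique(e$region_id[e$beta > 0])),
         negative_regions = sort(unique(e$region_id[e$beta < 0])))
  })
}

#' TF activity within a branch
#'
#' Activity of a TF is the mean coefficient of its active edges multiplied
#' by its mean log-normalized expression over the branch observations; the
#' sign marks a mainly activating (+) or repressing (-) role there.
#'
#' @param grn A [infer_grn()] result, possibly branch-pruned.
#' @param expr genes x observations expression matrix restricted to the
#'   branch.
#' @return Named numeric vector over TFs with at least one active edge.
#' @export
tf_activity_in_branch <- function(grn, expr) {
  edges <- grn$edges
  edges <- edges[edges$tf %in% rownames(expr), , drop = FALSE]
  if (nrow(edges) == 0) return(stats::setNames(numeric(0), character(0)))
  mean_beta <- tapply(edges$beta, edges$tf, mean)
  mean_expr <- rowMeans(expr[names(mean_beta), , drop = FALSE])
  stats::setNames(as.numeric(mean_beta) * as.numeric(mean_expr),
                  names(mean_beta))
}

#' Write GRN edges as TSV
#' @param grn A `grn` object.
#' @param path Output path.
#' @param regions Optional [region_set()] to attach region coordinates.
#' @export
write_grn <- function(grn, path, regions = NULL) {
  edges <- grn$edges
  if (!is.null(regions)) {
    m <- match(edges$region_id, regions$region_id)
    edges$chrom <- regions$chrom[m]
    edges$start <- regions$start[m]
    edges$end <- regions$end[m]
  }
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
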