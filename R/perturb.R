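#' Assign guides to cells from bimodal UMI counts
#'
#' Fits a two-component Gaussian mixture (free variances) on natural-log
#' transformed nonzero UMI counts; entries with posterior probability of
#' at least 0.5 for the higher-mean component are assigned. Cells with
#' zero UMI for a guide never receive it. With fewer than 10 nonzero
#' counts the mixture is unidentifiable and a fixed ln-count threshold is
#' used instead, with a warning.
#'
#' @param umi_counts cells x guides matrix of nonnegative integer counts.
#' @param seed Integer seed.
#' @param fallback_ln_threshold ln-count cutoff used when the mixture
#'   cannot be fit (default `log(10)`).
#' @return Binary cells x guides assignment matrix.
#' @export
assign_guides <- function(umi_counts, seed = 1,
                          fallback_ln_threshold = log(10)) {
  counts <- as.matrix(umi_counts)
  nz <- which(counts > 0)
  if (!length(nz)) stop("no nonzero guide counts")
  x <- matrix(0L, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  lnc <- log(counts[nz])
  if (length(nz) < 10 || length(unique(lnc)) < 3) {
    warning("too few distinct nonzero counts for a mixture fit; ",
            "using fixed ln-count threshold ", signif(fallback_ln_threshold, 3))
    x[nz][lnc >= fallback_ln_threshold] <- 1L
    return(x)
  }
  set.seed(seed)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  fit <- tryCatch(
    mclust::Mclust(lnc, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("mixture fit failed; using fixed ln-count threshold")
    x[nz][lnc >= fallback_ln_threshold] <- 1L
    return(x)
  }
  hi <- which.max(fit$parameters$mean)
  x[nz][fit$z[, hi] >= 0.5] <- 1L
  x
}

#' Perturbation probability per cell and guide
#'
#' Fits a multi-response elastic-net regression of the most-variable
#' features on covariates plus binary guide assignments (shared
#' cross-validated lambda), then for each guide-carrying cell re-evaluates
#' the fit with that guide set to 0 and transforms the squared-error
#' difference into a probability:
#' `p = logistic((SSE_0 - SSE) / (2 * sigma^2))`, with `sigma^2` the mean
#' squared residual of the full fit. Cells without the guide get p = 0;
#' guides with fewer than `min_cells` carriers are reported as missing
#' (NA). Target-level probabilities take the maximum over the target's
#' guides.
#'
#' @param Y genes x cells log-normalized expression.
#' @param X cells x guides binary assignment matrix.
#' @param covariates Data frame of per-cell covariates (e.g. `n_features`,
#'   `sample`, `cell_type`); factors are expanded to dummies.
#' @param guide_map Optional data frame (guide, target) for target-level
#'   summarization.
#' @param n_var_features Most-variable features used (default 500).
#' @param alpha Elastic-net mixing (default 0.5).
#' @param min_cells Minimum carrier cells per guide (default 5).
#' @param seed Integer seed (cross-validation folds).
#' @return A list with `p` (cells x guides), `p_target` (cells x targets,
#'   or NULL without `guide_map`) and `sigma2`.
#' @export
perturbation_probability <- function(Y, X, covariates, guide_map = NULL,
                                     n_var_features = 500, alpha = 0.5,
                                     min_cells = 5, seed = 1) {
  X <- as.matrix(X)
  n_cells <- ncol(Y)
  if (nrow(X) != n_cells) stop("X must have one row per cell")
  v <- apply(Y, 1, stats::var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_var_features, nrow(Y)))]
  Yv <- t(Y[keep, , drop = FALSE])           # cells x features
  cov_mm <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  design <- cbind(cov_mm, X)
  guide_cols <- ncol(cov_mm) + seq_len(ncol(X))

  set.seed(seed)
  cv <- glmnet::cv.glmnet(design, Yv, family = "mgaussian", alpha = alpha,
                          standardize = TRUE,
                          nfolds = max(3, min(10, floor(n_cells / 50))))
  coefs <- stats::coef(cv, s = "lambda.min")
  W <- do.call(cbind, lapply(coefs, function(co) as.numeric(co)[-1]))
  intercepts <- vapply(coefs, function(co) as.numeric(co)[1], 0)
  fitted <- sweep(design %*% W, 2, intercepts, `+`)
  resid <- Yv - fitted
  sigma2 <- mean(resid^2)

  n_carrier <- colSums(X > 0)
  p <- matrix(0, n_cells, ncol(X), dimnames = dimnames(X))
  for (j in seq_len(ncol(X))) {
    if (n_carrier[j] < min_cells) {
      p[, j] <- NA_real_
      next
    }
    cells <- which(X[, j] > 0)
    w_j <- W[guide_cols[j], ]                # per-feature guide effect
    # zeroing the guide shifts each fitted value by -w_j:
    # SSE0 - SSE = sum_i (r_i + w_ij)^2 - r_i^2 = sum_i 2 r_i w_ij + w_ij^2
    delta <- as.numeric(resid[cells, , drop = FALSE] %*% (2 * w_j)) +
      sum(w_j^2)
    p[cells, j] <- stats::plogis(delta / (2 * sigma2))
  }
  p_target <- NULL
  if (!is.null(guide_map)) {
    targets <- unique(guide_map$target)
    p_target <- vapply(targets, function(tg) {
      g <- guide_map$guide[guide_map$target == tg]
      g <- intersect(g, colnames(p))
      apply(p[, g, drop = FALSE], 1, function(v) {
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
      })
    }, numeric(n_cells))
    colnames(p_target) <- targets
  }
  list(p = p, p_target = p_target, sigma2 = sigma2)
}

#' Transcriptomic knockout effects from perturbation probabilities
#'
#' Per gene, an OLS fit on the stated covariates plus all target
#' perturbation-probability columns; each target coefficient is tested
#' with the single-coefficient F-test (ANOVA) and all p-values are pooled
#' into one BH correction. Collinear covariate columns are dropped
#' (aliased) and logged.
#'
#' @param Y genes x cells log-normalized expression.
#' @param p_target cells x targets perturbation probabilities (NA columns
#'   are skipped).
#' @param covariates Data frame of per-cell covariates.
#' @param fdr DE threshold on the adjusted p-value (default 1e-4).
#' @return A list with `table` (gene, target, coefficient, pval, fdr, de)
#'   and `aliased` (dropped design columns).
#' @export
ko_transcriptomic_effects <- function(Y, p_target, covariates, fdr = 1e-4) {
  usable <- colnames(p_target)[colSums(is.na(p_target)) == 0]
  pt <- p_target[, usable, drop = FALSE]
  cov_mm <- stats::model.matrix(~ ., data = covariates)
  design <- cbind(cov_mm, pt)
  qrd <- qr(design)
  aliased <- character()
  if (qrd$rank < ncol(design)) {
    keep <- qrd$pivot[seq_len(qrd$rank)]
    aliased <- colnames(design)[-keep]
    design <- design[, keep, drop = FALSE]
    qrd <- qr(design)
    usable <- intersect(usable, colnames(design))
  }
  n <- nrow(design)
  df_res <- n - qrd$rank
  Yt <- t(Y)                                  # cells x genes
  coefs <- qr.coef(qrd, Yt)
  resid <- qr.resid(qrd, Yt)
  rss <- colSums(resid^2)
  sigma2 <- rss / df_res
  xtx_inv <- chol2inv(qr.R(qrd))
  rownames(xtx_inv) <- colnames(xtx_inv) <- colnames(design)
  rows <- lapply(usable, function(tg) {
    se <- sqrt(sigma2 * xtx_inv[tg, tg])
    tstat <- coefs[tg, ] / se
    pv <- 2 * stats::pt(abs(tstat), df_res, lower.tail = FALSE)
    pv[se == 0 | !is.finite(tstat)] <- 1
    data.frame(gene = rownames(Y), target = tg,
               coefficient = coefs[tg, ], pval = pv,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tab$fdr <- stats::p.adjust(tab$pval, method = "BH")
  tab$de <- tab$fdr < fdr
  list(table = tab, aliased = aliased)
}

#' Cochran-Mantel-Haenszel test for stratified 2x2 tables
#'
#' Classical CMH chi-squared statistic (1 df, no continuity correction).
#' Strata with fewer than 2 observations are ignored; if no stratum is
#' informative, p = 1.
#'
#' @param tables 2x2xK array of nonnegative counts (or a 2x2 matrix for
#'   K = 1).
#' @return A list with `statistic` and `p`.
#' @export
cmh_test <- function(tables) {
  if (is.matrix(tables)) tables <- array(tables, c(2, 2, 1))
  stopifnot(dim(tables)[1] == 2, dim(tables)[2] == 2)
  num <- 0
  den <- 0
  for (k in seq_len(dim(tables)[3])) {
    t2 <- tables[, , k]
    n <- sum(t2)
    if (n < 2) next
    row1 <- sum(t2[1, ])
    col1 <- sum(t2[, 1])
    e <- row1 * col1 / n
    v <- row1 * (n - row1) * col1 * (n - col1) / (n^2 * (n - 1))
    num <- num + (t2[1, 1] - e)
    den <- den + v
  }
  if (den == 0) return(list(statistic = 0, p = 1))
  stat <- num^2 / den
  list(statistic = unname(stat),
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Log odds ratio of target enrichment in a branch
#'
#' `LOR = ln[(N_target,branch / N_target,other) /
#' (N_other,branch / N_other,other)]`; when any count is 0, 0.5 is added
#' to all four (Haldane-Anscombe).
#'
#' @param n_tb,n_to,n_ob,n_oo Counts: target-in-branch, target-elsewhere,
#'   others-in-branch, others-elsewhere.
#' @return The log odds ratio (natural log).
#' @export
log_odds_ratio <- function(n_tb, n_to, n_ob, n_oo) {
  counts <- c(n_tb, n_to, n_ob, n_oo)
  if (any(counts == 0)) counts <- counts + 0.5
  log((counts[1] / counts[2]) / (counts[3] / counts[4]))
}

#' Compositional enrichment of screen targets per branch
#'
#' Per gRNA and branch, association between guide carriage and branch
#' membership is tested with the organoid-stratified CMH test and, per
#' organoid, with Fisher's exact test (both BH-adjusted across all tests
#' of their kind). Filter 1 keeps gRNAs whose per-organoid enrichment is
#' significant (Fisher FDR < `fdr_organoid`) in more than one organoid
#' with a consistent direction. Filter 2 keeps gRNAs whose effect (same
#' branch, same direction) is matched at CMH FDR < `fdr_confirm` by at
#' least one other gRNA of the same target. Surviving gRNAs are pooled per
#' target and the log odds ratio of each (target, branch) enrichment is
#' computed, with the per-target maximum across branches as the
#' composition-change measure.
#'
#' @param X cells x guides binary assignment matrix.
#' @param branch Branch label per cell.
#' @param organoid Organoid id per cell.
#' @param guide_map Data frame (guide, target).
#' @param fdr_organoid Filter-1 per-organoid FDR threshold (default 0.05).
#' @param fdr_confirm Filter-2 cross-guide FDR threshold (default 0.01).
#' @return A list with `guide_table` (per guide x branch: CMH p/FDR,
#'   direction, filter flags), `target_table` (per target x branch: counts,
#'   LOR, CMH FDR), `max_lor` (named per-target maximum LOR) and
#'   `kept_guides`.
#' @export
composition_enrichment <- function(X, branch, organoid, guide_map,
                                   fdr_organoid = 0.05, fdr_confirm = 0.01) {
  organoids <- sort(unique(organoid))
  if (length(organoids) < 2) {
    stop("need at least 2 organoids for the consistency filter")
  }
  branches <- sort(unique(branch))
  guides <- colnames(X)
  grid <- expand.grid(guide = guides, branch = branches,
                      stringsAsFactors = FALSE)
  cmh_p <- numeric(nrow(grid))
  direction <- numeric(nrow(grid))
  fisher_p <- matrix(NA_real_, nrow(grid), length(organoids),
                     dimnames = list(NULL, organoids))
  fisher_dir <- matrix(0, nrow(grid), length(organoids))
  for (i in seq_len(nrow(grid))) {
    has_g <- X[, grid$guide[i]] > 0
    in_b <- branch == grid$branch[i]
    tabs <- array(0, c(2, 2, length(organoids)))
    for (k in seq_along(organoids)) {
      o <- organoid == organoids[k]
      t2 <- matrix(c(sum(o & has_g & in_b), sum(o & has_g & !in_b),
                     sum(o & !has_g & in_b), sum(o & !has_g & !in_b)),
                   2, 2, byrow = TRUE)
      tabs[, , k] <- t2
      if (sum(t2) > 0) {
        ft <- stats::fisher.test(t2)
        fisher_p[i, k] <- ft$p.value
        fisher_dir[i, k] <- sign(log_odds_ratio(t2[1, 1], t2[1, 2],
                                                t2[2, 1], t2[2, 2]))
      }
    }
    cmh_p[i] <- cmh_test(tabs)$p
    tot <- apply(tabs, c(1, 2), sum)
    direction[i] <- sign(log_odds_ratio(tot[1, 1], tot[1, 2],
                                        tot[2, 1], tot[2, 2]))
  }
  cmh_fdr <- stats::p.adjust(cmh_p, method = "BH")
  fisher_fdr <- matrix(stats::p.adjust(fisher_p, method = "BH"),
                       nrow(grid), dimnames = dimnames(fisher_p))

  # filter 1: significant in >1 organoid, consistent direction, per guide
  pass1_bybranch <- vapply(seq_len(nrow(grid)), function(i) {
    sig <- which(fisher_fdr[i, ] < fdr_organoid)
    length(sig) > 1 && length(unique(fisher_dir[i, sig])) == 1
  }, FALSE)
  guide_pass1 <- tapply(pass1_bybranch, grid$guide, any)

  # filter 2: same effect (branch + direction) in another guide of the
  # same target at the confirmation FDR
  grid$target <- guide_map$target[match(grid$guide, guide_map$guide)]
  sig2 <- cmh_fdr < fdr_confirm
  pass2 <- vapply(seq_len(nrow(grid)), function(i) {
    if (!sig2[i]) return(FALSE)
    mates <- grid$target == grid$target[i] & grid$guide != grid$guide[i] &
      grid$branch == grid$branch[i]
    any(sig2[mates] & direction[mates] == direction[i])
  }, FALSE)
  guide_pass2 <- tapply(pass2, grid$guide, any)

  kept <- guides[guide_pass1[guides] & guide_pass2[guides]]
  guide_table <- data.frame(grid, cmh_p = cmh_p, cmh_fdr = cmh_fdr,
                            direction = direction,
                            pass_organoid = pass1_bybranch,
                            pass_confirm = pass2,
                            kept = grid$guide %in% kept,
                            stringsAsFactors = FALSE)

  # pooled target-level counts and LOR over kept guides
  targets <- unique(guide_map$target[guide_map$guide %in% kept])
  rows <- list()
  for (tg in targets) {
    g <- intersect(guide_map$guide[guide_map$target == tg], kept)
    has_t <- rowSums(X[, g, drop = FALSE] > 0) > 0
    for (b in branches) {
      in_b <- branch == b
      n <- c(sum(has_t & in_b), sum(has_t & !in_b),
             sum(!has_t & in_b), sum(!has_t & !in_b))
      rows[[length(rows) + 1L]] <- data.frame(
        target = tg, branch = b, n_tb = n[1], n_to = n[2], n_ob = n[3],
        n_oo = n[4], lor = log_odds_ratio(n[1], n[2], n[3], n[4]),
        stringsAsFactors = FALSE)
    }
  }
  target_table <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(target = character(), branch = character(), n_tb = integer(),
               n_to = integer(), n_ob = integer(), n_oo = integer(),
               lor = numeric())
  }
  max_lor <- if (nrow(target_table)) {
    tapply(target_table$lor, target_table$target, max)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  list(guide_table = guide_table, target_table = target_table,
       max_lor = max_lor, kept_guides = kept)
}
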