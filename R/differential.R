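#' Linear-model differential expression
#'
#' Per gene, OLS of log-normalized expression on covariates plus the
#' condition label; the condition coefficient is tested with the
#' single-coefficient F-test (ANOVA), BH-adjusted across genes. A constant
#' gene, or a condition aliased by the covariates, gets p = 1 / NA.
#'
#' @param Y genes x cells expression matrix.
#' @param condition Two-level condition label per cell.
#' @param covariates Optional data frame of per-cell covariates (default:
#'   none).
#' @return A data frame (feature, coefficient, pval, fdr, test).
#' @export
de_linear <- function(Y, condition, covariates = NULL) {
  condition <- factor(condition)
  if (nlevels(condition) != 2 || any(table(condition) == 0)) {
    stop("condition must have two nonempty levels")
  }
  cond_num <- as.numeric(condition == levels(condition)[2])
  design <- if (is.null(covariates)) {
    cbind(`(Intercept)` = 1, condition = cond_num)
  } else {
    cbind(stats::model.matrix(~ ., data = covariates),
          condition = cond_num)
  }
  qrd <- qr(design)
  aliased_cond <- qrd$rank < ncol(design) &&
    !(ncol(design) %in% qrd$pivot[seq_len(qrd$rank)])
  n <- nrow(design)
  if (aliased_cond) {
    tab <- data.frame(feature = rownames(Y), coefficient = NA_real_,
                      pval = NA_real_, fdr = NA_real_, test = "lm-anova",
                      stringsAsFactors = FALSE)
    return(tab)
  }
  df_res <- n - qrd$rank
  Yt <- t(Y)
  coefs <- qr.coef(qrd, Yt)
  resid <- qr.resid(qrd, Yt)
  sigma2 <- colSums(resid^2) / df_res
  xtx_inv <- chol2inv(qr.R(qrd))
  se <- sqrt(sigma2 * xtx_inv[ncol(design), ncol(design)])
  beta <- coefs["condition", ]
  tstat <- beta / se
  pv <- 2 * stats::pt(abs(tstat), df_res, lower.tail = FALSE)
  pv[!is.finite(tstat)] <- 1
  data.frame(feature = rownames(Y), coefficient = beta, pval = pv,
             fdr = stats::p.adjust(pv, method = "BH"), test = "lm-anova",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum differential expression
#'
#' Two-sided rank-sum test per gene between the two condition groups, with
#' the difference of group means (of log-normalized expression, i.e. a log
#' fold change) as the effect; BH-adjusted.
#'
#' @param Y genes x cells expression matrix.
#' @param condition Two-level condition label per cell.
#' @return A data frame (feature, effect, pval, fdr, test).
#' @export
de_wilcoxon <- function(Y, condition) {
  condition <- factor(condition)
  if (nlevels(condition) != 2) stop("condition must have two levels")
  if (is.null(rownames(Y))) {
    rownames(Y) <- paste0("feature", seq_len(nrow(Y)))
  }
  g1 <- condition == levels(condition)[1]
  res <- vapply(seq_len(nrow(Y)), function(i) {
    y <- as.numeric(Y[i, ])
    p <- suppressWarnings(stats::wilcox.test(y[g1], y[!g1])$p.value)
    c(mean(y[!g1]) - mean(y[g1]), p)
  }, numeric(2))
  data.frame(feature = rownames(Y), effect = res[1, ],
             pval = res[2, ],
             fdr = stats::p.adjust(res[2, ], method = "BH"),
             test = "wilcoxon", row.names = NULL, stringsAsFactors = FALSE)
}

#' Binomial-GLM differential accessibility with likelihood-ratio test
#'
#' Per peak, a binomial GLM (logit link) of binarized detection on
#' the per-cell fragment count plus the condition label is compared with
#' the null model omitting the condition via a 1-df likelihood ratio test;
#' BH-adjusted. On perfect separation, both models are refit with four
#' half-weight pseudo-observations balancing condition x outcome (a weakly
#' informative fallback) and the row is flagged.
#'
#' @param detections peaks x cells binary (0/1) matrix.
#' @param n_fragments Fragment count per cell.
#' @param condition Two-level condition label per cell.
#' @return A data frame (feature, coefficient, pval, fdr, test, fallback).
#' @export
da_binomial_lrt <- function(detections, n_fragments, condition) {
  condition <- factor(condition)
  if (nlevels(condition) != 2) stop("condition must have two levels")
  cond_num <- as.numeric(condition == levels(condition)[2])
  nf <- as.numeric(n_fragments)
  out <- lapply(seq_len(nrow(detections)), function(i) {
    y <- as.numeric(detections[i, ])
    if (length(unique(y)) == 1) {
      return(data.frame(coefficient = 0, pval = 1, fallback = FALSE))
    }
    sep <- FALSE
    fit1 <- withCallingHandlers(
      stats::glm(y ~ nf + cond_num, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          sep <<- TRUE
        }
        invokeRestart("muffleWarning")
      })
    fit0 <- suppressWarnings(stats::glm(y ~ nf, family = stats::binomial()))
    sep <- sep || !fit1$converged ||
      any(fit1$fitted.values > 1 - 1e-6) || any(fit1$fitted.values < 1e-6)
    if (sep) {
      aug_y <- c(y, 0, 1, 0, 1)
      aug_nf <- c(nf, rep(mean(nf), 4))
      aug_c <- c(cond_num, 0, 0, 1, 1)
      w <- c(rep(1, length(y)), rep(0.5, 4))
      fit1 <- suppressWarnings(stats::glm(aug_y ~ aug_nf + aug_c, weights = w,
                                          family = stats::binomial()))
      fit0 <- suppressWarnings(stats::glm(aug_y ~ aug_nf, weights = w,
                                          family = stats::binomial()))
      lr <- fit0$deviance - fit1$deviance
      return(data.frame(coefficient = unname(stats::coef(fit1)["aug_c"]),
                        pval = stats::pchisq(lr, 1, lower.tail = FALSE),
                        fallback = TRUE))
    }
    lr <- fit0$deviance - fit1$deviance
    data.frame(coefficient = unname(stats::coef(fit1)["cond_num"]),
               pval = stats::pchisq(max(lr, 0), 1, lower.tail = FALSE),
               fallback = FALSE)
  })
  tab <- do.call(rbind, out)
  data.frame(feature = rownames(detections), coefficient = tab$coefficient,
             pval = tab$pval, fdr = stats::p.adjust(tab$pval, method = "BH"),
             test = "binom-lrt", fallback = tab$fallback,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Stage-specific peak selection
#'
#' Specificity of a peak for a stage is its in-stage detection percentage
#' divided by the detection percentage over all observations outside the
#' stage. Peaks with in-stage detection > `min_detect_pct` and specificity
#' > `min_specificity` are kept; the `top_n` by specificity are returned
#' per stage. Zero out-stage detection gives infinite specificity, ranked
#' first.
#'
#' @param detection_pct peaks x stages matrix of detection percentages
#'   (0-100).
#' @param stage_sizes Observation count per stage, used to aggregate the
#'   out-stage denominator (default: equal sizes).
#' @param min_detect_pct In-stage detection threshold (default 15).
#' @param min_specificity Specificity threshold (default 1.5).
#' @param top_n Peaks kept per stage (default 5000).
#' @return Named list per stage: data frame (peak, in_pct, out_pct,
#'   specificity), sorted by decreasing specificity.
#' @export
stage_specific_peaks <- function(detection_pct, stage_sizes = NULL,
                                 min_detect_pct = 15, min_specificity = 1.5,
                                 top_n = 5000) {
  m <- as.matrix(detection_pct)
  if (any(m < 0 | m > 100)) stop("detection percentages must be in [0, 100]")
  stages <- colnames(m)
  if (is.null(stages)) stages <- paste0("stage", seq_len(ncol(m)))
  if (is.null(stage_sizes)) stage_sizes <- rep(1, ncol(m))
  out <- lapply(seq_len(ncol(m)), function(s) {
    w <- stage_sizes[-s]
    out_pct <- as.numeric(m[, -s, drop = FALSE] %*% w / sum(w))
    spec <- ifelse(out_pct == 0, Inf, m[, s] / out_pct)
    keep <- m[, s] > min_detect_pct & spec > min_specificity
    df <- data.frame(peak = rownames(m)[keep], in_pct = m[keep, s],
                     out_pct = out_pct[keep], specificity = spec[keep],
                     row.names = NULL, stringsAsFactors = FALSE)
    df <- df[order(-df$specificity, df$peak), , drop = FALSE]
    utils::head(df, top_n)
  })
  stats::setNames(out, stages)
}

#' Read a bedGraph intensity track
#' @param path Path to a 4-column bedGraph file (chrom, start, end, value).
#' @return A data frame with 0-based half-open intervals and `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), value = numeric()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 4)) {
    stop("bedGraph parse error at line ", which(lengths(parts) < 4)[1])
  }
  data.frame(chrom = vapply(parts, `[[`, "", 1),
             start = as.numeric(vapply(parts, `[[`, "", 2)),
             end = as.numeric(vapply(parts, `[[`, "", 3)),
             value = as.numeric(vapply(parts, `[[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Per-gene binding score from an intensity track
#'
#' Sums per-base intensities (interval value times overlapping bases) over
#' the gene body plus a strand-aware upstream promoter extension.
#'
#' @param track bedGraph data frame from [read_bedgraph()].
#' @param genes A [gene_annotation()].
#' @param promoter_ext Upstream extension in bp (default 2000).
#' @param both_sides If `TRUE`, extend downstream as well.
#' @return Named numeric score per gene; genes on chromosomes absent from
#'   the track score 0 with a warning.
#' @export
gene_binding_score <- function(track, genes, promoter_ext = 2000,
                               both_sides = FALSE) {
  scores <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
  if (nrow(track) == 0) return(scores)
  missing_chrom <- setdiff(unique(genes$chrom), unique(track$chrom))
  if (length(missing_chrom)) {
    warning("gene chromosome(s) absent from track: ",
            paste(missing_chrom, collapse = ","), "; scores set to 0")
  }
  win_start <- ifelse(genes$strand == "+" | both_sides,
                      pmax(0, genes$start - promoter_ext), genes$start)
  win_end <- ifelse(genes$strand == "-" | both_sides,
                    genes$end + promoter_ext, genes$end)
  win <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(win_start + 1, win_end))
  tr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1, track$end))
  hits <- GenomicRanges::findOverlaps(win, tr)
  if (length(hits)) {
    ov <- IRanges::width(IRanges::pintersect(
      win[S4Vectors::queryHits(hits)], tr[S4Vectors::subjectHits(hits)]))
    contrib <- ov * track$value[S4Vectors::subjectHits(hits)]
    agg <- tapply(contrib, S4Vectors::queryHits(hits), sum)
    scores[as.integer(names(agg))] <- as.numeric(agg)
  }
  scores
}
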