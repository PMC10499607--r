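#' Construct a paired expression/accessibility matrix
#'
#' Holds the three ingredients of the interaction regression: target and TF
#' expression come from `expression` (log-normalized, `ln(1 + 1e4 * count /
#' total)`, hence nonnegative) and the `a` term from `accessibility`
#' (per-region detection probabilities in `[0, 1]`). Both matrices share the
#' same observation (column) ordering; observations are typically
#' pseudocells or metacells.
#'
#' @param expression genes x observations matrix (dense or `Matrix` sparse).
#' @param accessibility peaks x observations matrix of probabilities.
#' @param obs_meta Optional per-observation data frame (e.g. columns
#'   `branch`, `pseudotime`, `organoid`, `condition`); one row per
#'   observation.
#' @return A list with class `paired_matrix`.
#' @export
paired_matrix <- function(expression, accessibility, obs_meta = NULL) {
  if (ncol(expression) != ncol(accessibility)) {
    stop("expression and accessibility must have the same observation count (",
         ncol(expression), " vs ", ncol(accessibility), ")")
  }
  if (min(expression) < 0) stop("expression values must be >= 0")
  rng <- range(accessibility)
  if (rng[1] < 0 || rng[2] > 1) {
    stop("accessibility values must lie in [0, 1] (found ",
         signif(if (rng[1] < 0) rng[1] else rng[2], 4), ")")
  }
  if (!is.null(obs_meta)) {
    if (nrow(obs_meta) != ncol(expression)) {
      stop("obs_meta must have one row per observation")
    }
  } else {
    obs_meta <- data.frame(row.names = seq_len(ncol(expression)))
  }
  if (is.null(rownames(expression))) {
    rownames(expression) <- paste0("gene", seq_len(nrow(expression)))
  }
  if (is.null(rownames(accessibility))) {
    rownames(accessibility) <- paste0("region", seq_len(nrow(accessibility)))
  }
  if (is.null(colnames(expression))) {
    colnames(expression) <- paste0("obs", seq_len(ncol(expression)))
  }
  colnames(accessibility) <- colnames(expression)
  structure(list(expression = expression, accessibility = accessibility,
                 obs_meta = obs_meta),
            class = "paired_matrix")
}

#' @export
print.paired_matrix <- function(x, ...) {
  cat("paired_matrix:", nrow(x$expression), "genes x", ncol(x$expression),
      "observations;", nrow(x$accessibility), "regions\n")
  invisible(x)
}

#' Number of observations in a paired matrix
#' @param x A [paired_matrix()].
#' @return Integer observation count.
#' @export
n_obs <- function(x) ncol(x$expression)

#' Load a paired matrix from MatrixMarket files with TSV sidecars
#'
#' @param expr_mtx,access_mtx Paths to MatrixMarket matrices
#'   (genes x observations, peaks x observations).
#' @param genes,peaks Paths to one-id-per-line sidecars naming the rows.
#' @param obs Path to a TSV with a header; the first column names the
#'   observations, remaining columns become `obs_meta`.
#' @return A [paired_matrix()].
#' @export
load_paired_matrix <- function(expr_mtx, access_mtx, genes, peaks, obs) {
  expression <- as.matrix(Matrix::readMM(expr_mtx))
  accessibility <- as.matrix(Matrix::readMM(access_mtx))
  gene_ids <- readLines(genes)
  peak_ids <- readLines(peaks)
  obs_tab <- utils::read.table(obs, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(expression) != length(gene_ids)) {
    stop("expression has ", nrow(expression), " rows but ", length(gene_ids),
         " gene ids")
  }
  if (nrow(accessibility) != length(peak_ids)) {
    stop("accessibility has ", nrow(accessibility), " rows but ",
         length(peak_ids), " peak ids")
  }
  if (ncol(expression) != nrow(obs_tab)) {
    stop("expression has ", ncol(expression), " observations but obs table has ",
         nrow(obs_tab), " rows")
  }
  rownames(expression) <- gene_ids
  rownames(accessibility) <- peak_ids
  colnames(expression) <- colnames(accessibility) <- obs_tab[[1]]
  paired_matrix(expression, accessibility,
                obs_meta = obs_tab[, -1, drop = FALSE])
}

#' Write a paired matrix as MTX + TSV sidecars
#' @param pm A [paired_matrix()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_paired_matrix <- function(pm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(pm$expression, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "expression.mtx"))
  Matrix::writeMM(methods::as(Matrix::Matrix(pm$accessibility, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "accessibility.mtx"))
  writeLines(rownames(pm$expression), file.path(dir, "genes.tsv"))
  writeLines(rownames(pm$accessibility), file.path(dir, "peaks.tsv"))
  obs <- cbind(data.frame(obs_id = colnames(pm$expression)), pm$obs_meta)
  utils::write.table(obs, file.path(dir, "obs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
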