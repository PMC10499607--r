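#' Simulate a pooled CRISPR screen with known ground truth
#'
#' Each cell carries one true guide; its UMI count is drawn from the
#' high component of a two-component log-normal mixture, while sporadic
#' ambient counts for other guides come from the low component, so
#' ln-counts are bimodal. Branch labels are drawn from baseline
#' probabilities shifted on the log-odds scale for cells whose target has
#' a compositional effect; a configurable fraction of guide-carrying cells
#' are escapers, phenotypically unperturbed (no expression shift and no
#' compositional shift). Expression is Gaussian around a positive baseline,
#' floored at 0, with the target's effect genes shifted in perturbed cells.
#'
#' @param n_cells Number of cells (must be at least `10 * length(targets)`).
#' @param targets Character vector of target gene names.
#' @param guides_per_target Guides designed per target (default 3).
#' @param effect_sizes Named list keyed by target; each element a list with
#'   `branch` (enriched branch), `lor` (compositional log-odds shift) and
#'   `expr_effect` (expression shift in noise-sd units applied to that
#'   target's effect genes). Targets without an entry are nulls. Names must
#'   be a subset of `targets`.
#' @param escaper_frac Fraction of guide-carrying cells that are
#'   phenotypically unperturbed (default 0.2).
#' @param n_organoids Number of organoids cells are distributed over
#'   (default 4).
#' @param branches Branch labels (default three regional branches).
#' @param n_genes Genes in the expression matrix (default 100).
#' @param n_effect_genes Effect genes per target with an expression effect
#'   (default 20).
#' @param expr_sd Expression noise standard deviation (default 0.5).
#' @param mu_high,mu_low Means of ln UMI counts for the real and ambient
#'   mixture components (default 4 and 0.5).
#' @param ambient_rate Probability of an ambient count per non-carried
#'   guide (default 0.05).
#' @param seed Integer seed.
#'
#' @return A list with `counts` (cells x guides UMI matrix), `guide_map`
#'   (guide, target), `obs_meta` (cell, organoid, branch, cell_type,
#'   n_features), `expression` (genes x cells, log-normalized scale) and
#'   `truth` (true guide, perturbed flag, effect genes, effect sizes).
#' @export
simulate_screen <- function(n_cells, targets, guides_per_target = 3,
                            effect_sizes = list(), escaper_frac = 0.2,
                            n_organoids = 4,
                            branches = c("dorsal", "ventral", "nonneural"),
                            n_genes = 100, n_effect_genes = 20,
                            expr_sd = 0.5, mu_high = 4, mu_low = 0.5,
                            ambient_rate = 0.05, seed = 1) {
  if (n_cells < 10 * length(targets)) {
    stop("n_cells must be at least 10 * number of targets")
  }
  unknown <- setdiff(names(effect_sizes), targets)
  if (length(unknown)) {
    stop("effect size given for unknown target(s): ",
         paste(unknown, collapse = ","))
  }
  set.seed(seed)
  guides <- as.vector(t(outer(targets, seq_len(guides_per_target),
                              function(t, i) sprintf("%s_g%d", t, i))))
  guide_map <- data.frame(guide = guides,
                          target = rep(targets, each = guides_per_target),
                          stringsAsFactors = FALSE)
  n_guides <- length(guides)
  cells <- sprintf("cell%05d", seq_len(n_cells))

  true_guide <- sample(guides, n_cells, replace = TRUE)
  true_target <- guide_map$target[match(true_guide, guide_map$guide)]
  has_effect <- true_target %in% names(effect_sizes)
  escaper <- stats::runif(n_cells) < escaper_frac
  perturbed <- has_effect & !escaper

  organoid <- paste0("org", sample(seq_len(n_organoids), n_cells, TRUE))

  # branch assignment: baseline log-odds + per-organoid wobble + target shift
  org_shift <- matrix(stats::rnorm(n_organoids * length(branches), 0, 0.3),
                      n_organoids, length(branches),
                      dimnames = list(paste0("org", seq_len(n_organoids)),
                                      branches))
  lo <- org_shift[organoid, , drop = FALSE]
  for (tg in names(effect_sizes)) {
    es <- effect_sizes[[tg]]
    idx <- perturbed & true_target == tg
    lo[idx, es$branch] <- lo[idx, es$branch] + es$lor
  }
  pr <- exp(lo)
  pr <- pr / rowSums(pr)
  branch <- branches[apply(pr, 1, function(p) sample.int(length(p), 1, prob = p))]

  # UMI counts: real guide high component, ambient low component
  counts <- matrix(0L, n_cells, n_guides, dimnames = list(cells, guides))
  counts[cbind(seq_len(n_cells), match(true_guide, guides))] <-
    pmax(1L, as.integer(round(exp(stats::rnorm(n_cells, mu_high, 0.5)))))
  amb <- which(matrix(stats::runif(n_cells * n_guides) < ambient_rate,
                      n_cells, n_guides) & counts == 0L)
  counts[amb] <- pmax(1L, as.integer(round(exp(stats::rnorm(length(amb),
                                                            mu_low, 0.5)))))

  # expression: positive baseline + per-target effect genes in perturbed cells
  gene_ids <- sprintf("gene%03d", seq_len(n_genes))
  effect_genes <- lapply(stats::setNames(nm = names(effect_sizes)), function(tg) {
    sample(gene_ids, min(n_effect_genes, n_genes))
  })
  base_mean <- stats::runif(n_genes, 1, 2)
  expression <- matrix(stats::rnorm(n_genes * n_cells, base_mean, expr_sd),
                       n_genes, n_cells, dimnames = list(gene_ids, cells))
  for (tg in names(effect_sizes)) {
    es <- effect_sizes[[tg]]
    idx <- which(perturbed & true_target == tg)
    if (length(idx)) {
      shift <- es$expr_effect * expr_sd
      expression[effect_genes[[tg]], idx] <-
        expression[effect_genes[[tg]], idx] + shift
    }
  }
  expression <- pmax(expression, 0)

  obs_meta <- data.frame(
    cell = cells, organoid = organoid, branch = branch,
    cell_type = sample(c("NPC", "neuron"), n_cells, TRUE),
    n_features = round(stats::rnorm(n_cells, 2000, 200)),
    stringsAsFactors = FALSE)

  list(counts = counts, guide_map = guide_map, obs_meta = obs_meta,
       expression = expression,
       truth = list(true_guide = true_guide, true_target = true_target,
                    perturbed = perturbed, escaper = escaper,
                    effect_genes = effect_genes,
                    effect_sizes = effect_sizes))
}
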