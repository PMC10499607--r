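#' Simulate a regulome with known ground truth
#'
#' Generates a complete, internally consistent input set for the GRN
#' inference pipeline: TF expression follows smooth latent trajectories
#' over pseudotime with branch-specific modulation after a branch point;
#' region accessibilities are smooth probabilities in `[0, 1]` with
#' branch-specific closed regions (accessibility exactly 0 in the closed
#' branch); target expression is computed exactly as
#' `Y = sum_j beta_j * e_j * a_j + eps`, `eps ~ N(0, noise_sd)`, floored at
#' 0 (log-normalized expression is nonnegative); each wired (TF, region)
#' pair has the TF's motif consensus written into the genome sequence at a
#' recorded offset inside that region, so a motif scan recovers the wiring
#' without threshold tuning. One decoy region with an unwired TF's motif
#' is placed in each target's regulatory window, giving downstream tests
#' true null terms.
#'
#' @param n_tfs,n_targets,n_obs Problem sizes (all >= 1).
#' @param n_regions Total number of regions; defaults to the wired-region
#'   count plus one decoy per target. Must be at least `n_targets` when
#'   given.
#' @param noise_sd Gaussian noise standard deviation on target expression.
#' @param seed Integer seed (R's default Mersenne-Twister stream).
#' @param n_branches Number of terminal branches (default 3).
#' @param branch_point Pseudotime at which branches diverge (default 0.3).
#' @param closed_fraction Fraction of wired regions closed in one random
#'   branch (default 0.1).
#' @param null_wiring If `TRUE`, all true coefficients are set to 0 (the
#'   wiring skeleton is kept), producing a null regulome for FDR-control
#'   simulations.
#' @param with_genome If `FALSE`, skip materializing the genome sequence
#'   (motif placements and all matrices are still generated).
#' @param region_len,motif_len,window_bp Geometry of regions, motifs and
#'   the regulatory window used to lay out the genome.
#'
#' @return A list with elements `truth` (wiring, placements, closed
#'   regions, absorption probabilities, ...), `paired`
#'   ([paired_matrix()]), `regions` ([region_set()]), `genes`
#'   ([gene_annotation()]), `motifs` (list of [motif_pfm()]), `genome`
#'   (named character vector or `NULL`), `sites` (truth-derived binding
#'   site table) and `gene_pairs` (truth-derived gene-region pairs).
#' @export
simulate_regulome <- function(n_tfs = 10, n_targets = 200, n_regions = NULL,
                              n_obs = 500, noise_sd = 0.1, seed = 1,
                              n_branches = 3, branch_point = 0.3,
                              closed_fraction = 0.1, null_wiring = FALSE,
                              with_genome = TRUE, region_len = 200,
                              motif_len = 10, window_bp = 1e5) {
  stopifnot(n_tfs >= 1, n_targets >= 1, n_obs >= 1, noise_sd >= 0)
  if (region_len < motif_len) {
    stop("infeasible placement: region_len shorter than motif_len")
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  tf_ids <- paste0("TF", seq_len(n_tfs))
  target_ids <- paste0("G", seq_len(n_targets))
  branches <- paste0("branch", LETTERS[seq_len(n_branches)])

  # distinct motif consensi, one per TF
  consensi <- character(0)
  while (length(consensi) < n_tfs) {
    cand <- paste(sample(bases, motif_len, replace = TRUE), collapse = "")
    if (!cand %in% consensi) consensi <- c(consensi, cand)
  }
  motifs <- lapply(seq_len(n_tfs), function(j) {
    cons <- strsplit(consensi[j], "")[[1]]
    m <- matrix(1, 4, motif_len, dimnames = list(bases, NULL))
    m[cbind(match(cons, bases), seq_len(motif_len))] <- 12
    motif_pfm(sprintf("M%03d", j), tf_ids[j], m)
  })

  # wiring: 1-3 edges per target, first always positive
  wiring <- do.call(rbind, lapply(seq_len(n_targets), function(i) {
    k <- sample(1:min(3, n_tfs), 1)
    tfs <- sample(tf_ids, k)
    beta <- c(stats::runif(1, 1, 3),
              if (k > 1) sample(c(-1, 1), k - 1, replace = TRUE) *
                stats::runif(k - 1, 0.5, 1.5))
    data.frame(tf = tfs, target = target_ids[i], beta = beta,
               stringsAsFactors = FALSE)
  }))
  if (null_wiring) wiring$beta <- 0

  n_wired <- nrow(wiring)
  n_decoy <- if (is.null(n_regions)) n_targets else n_regions - n_wired
  if (n_decoy < 0) {
    stop("n_regions must be at least the wired-region count (", n_wired, ")")
  }
  decoy_targets <- if (n_decoy > 0) {
    target_ids[1 + (seq_len(n_decoy) - 1) %% n_targets]
  } else character(0)

  # genome layout: one block per target on chr1, TF genes on chr2
  gene_len <- 2000
  block <- window_bp + gene_len + 10000
  tgt_strand <- rep(c("+", "-"), length.out = n_targets)
  tgt_strand <- sample(tgt_strand)
  block_start <- (seq_len(n_targets) - 1) * block
  gene_start <- ifelse(tgt_strand == "+", block_start + window_bp + 5000,
                       block_start + 5000)
  gene_end <- gene_start + gene_len
  genes <- gene_annotation(
    gene_id = c(target_ids, tf_ids),
    chrom = c(rep("chr1", n_targets), rep("chr2", n_tfs)),
    start = c(gene_start, (seq_len(n_tfs) - 1) * 5000 + 1000),
    end = c(gene_end, (seq_len(n_tfs) - 1) * 5000 + 1000 + 1500),
    strand = c(tgt_strand, rep("+", n_tfs)))

  # regions: wired regions upstream of their target, decoys likewise
  place_region <- function(target, slot) {
    i <- match(target, target_ids)
    if (tgt_strand[i] == "+") {
      s <- gene_start[i] - 2000 * slot - 1500
    } else {
      s <- gene_end[i] + 2000 * slot + 1300
    }
    c(s, s + region_len)
  }
  wired_slot <- stats::ave(seq_len(n_wired), wiring$target, FUN = seq_along)
  wired_pos <- t(mapply(place_region, wiring$target, wired_slot))
  decoy_pos <- if (n_decoy > 0) {
    t(mapply(place_region, decoy_targets, rep(40, n_decoy)))
  } else matrix(numeric(0), 0, 2)
  all_pos <- rbind(wired_pos, decoy_pos)
  region_ids <- sprintf("R%04d", seq_len(nrow(all_pos)))
  regions <- region_set("chr1", all_pos[, 1], all_pos[, 2], region_ids)
  wiring$region_id <- region_ids[seq_len(n_wired)]
  decoy_ids <- region_ids[seq_len(n_decoy) + n_wired]

  # motif placements: wired TF in its region; a random unwired TF per decoy
  decoy_tf <- if (n_decoy > 0) {
    vapply(decoy_targets, function(tg) {
      pool <- setdiff(tf_ids, wiring$tf[wiring$target == tg])
      if (!length(pool)) sample(tf_ids, 1) else sample(pool, 1)
    }, "")
  } else character(0)
  plc_tf <- c(wiring$tf, decoy_tf)
  plc_region <- c(wiring$region_id, decoy_ids)
  placements <- data.frame(
    region_id = plc_region,
    motif_id = sprintf("M%03d", match(plc_tf, tf_ids)),
    tf = plc_tf,
    offset = sample(0:(region_len - motif_len), length(plc_tf), replace = TRUE),
    strand = sample(c("+", "-"), length(plc_tf), replace = TRUE, prob = c(0.8, 0.2)),
    stringsAsFactors = FALSE)

  # latent trajectory: pseudotime, fate branch, absorption probabilities
  pseudotime <- sort(stats::runif(n_obs))
  branch <- sample(branches, n_obs, replace = TRUE)
  prog <- pmax(0, (pseudotime - branch_point) / (1 - branch_point))
  absorption <- matrix(1 / n_branches, n_obs, n_branches,
                       dimnames = list(NULL, branches))
  for (b in seq_len(n_branches)) {
    own <- branch == branches[b]
    lg <- ifelse(own, 5 * prog, -2.5 * prog) +
      stats::rnorm(n_obs, 0, 0.15)
    absorption[, b] <- exp(lg)
  }
  absorption <- absorption / rowSums(absorption)

  # TF expression: smooth bump over pseudotime, branch-modulated after fork
  e <- matrix(0, n_tfs, n_obs, dimnames = list(tf_ids, NULL))
  for (j in seq_len(n_tfs)) {
    b0 <- stats::runif(1, 0.1, 0.5)
    amp <- stats::runif(1, 1, 2)
    mu <- stats::runif(1, 0, 1)
    sj <- stats::runif(1, 0.25, 0.45)
    bmod <- stats::runif(n_branches, -0.5, 1)
    w <- 1 + bmod[match(branch, branches)] * prog
    e[j, ] <- pmax(0, b0 + amp * exp(-(pseudotime - mu)^2 / (2 * sj^2)) * w +
                     stats::rnorm(n_obs, 0, 0.05))
  }

  # accessibility probabilities, with branch-specific closures
  n_reg <- nrow(regions)
  a <- matrix(0, n_reg, n_obs, dimnames = list(region_ids, NULL))
  c0 <- stats::rnorm(n_reg, 0, 1)
  c1 <- stats::rnorm(n_reg, 0, 2)
  for (r in seq_len(n_reg)) {
    a[r, ] <- 0.3 + 0.6 * stats::plogis(c0[r] + c1[r] * pseudotime)
  }
  branch_closed <- stats::setNames(
    replicate(n_branches, character(0), simplify = FALSE), branches)
  n_closed <- floor(closed_fraction * n_wired)
  if (n_closed > 0) {
    closed <- sample(unique(wiring$region_id), min(n_closed, n_wired))
    for (rid in closed) {
      b <- sample(branches, 1)
      branch_closed[[b]] <- c(branch_closed[[b]], rid)
      a[rid, branch == b] <- 0
    }
  }

  # target expression from the generating model
  y <- matrix(0, n_targets, n_obs, dimnames = list(target_ids, NULL))
  for (i in seq_len(n_targets)) {
    w <- wiring[wiring$target == target_ids[i], , drop = FALSE]
    mu <- rep(0, n_obs)
    for (k in seq_len(nrow(w))) {
      mu <- mu + w$beta[k] * e[w$tf[k], ] * a[w$region_id[k], ]
    }
    eps <- if (noise_sd > 0) stats::rnorm(n_obs, 0, noise_sd) else 0
    y[i, ] <- pmax(0, mu + eps)
  }

  expression <- rbind(e, y)
  obs_meta <- data.frame(branch = branch, pseudotime = pseudotime,
                         organoid = paste0("org", sample(1:4, n_obs, TRUE)),
                         condition = "ctrl", stringsAsFactors = FALSE)
  paired <- paired_matrix(expression, a, obs_meta)

  genome <- NULL
  if (with_genome) {
    genome <- c(chr1 = random_sequence(n_targets * block),
                chr2 = random_sequence(n_tfs * 5000 + 5000))
    genome <- plant_motifs(genome, regions, placements, consensi, tf_ids)
  }

  sites <- data.frame(region_id = placements$region_id,
                      motif_id = placements$motif_id,
                      tf = placements$tf, strand = placements$strand,
                      offset = placements$offset,
                      logodds_score = NA_real_, stringsAsFactors = FALSE)
  gene_pairs <- rbind(
    data.frame(gene_id = wiring$target, region_id = wiring$region_id,
               stringsAsFactors = FALSE),
    data.frame(gene_id = decoy_targets, region_id = decoy_ids,
               stringsAsFactors = FALSE))
  gene_pairs <- unique(gene_pairs)

  list(truth = list(tf_ids = tf_ids, target_ids = target_ids,
                    region_ids = region_ids, wiring = wiring,
                    noise_sd = noise_sd, placements = placements,
                    branch_closed_regions = branch_closed,
                    absorption = absorption, branch_point = branch_point,
                    consensi = stats::setNames(consensi, tf_ids)),
       paired = paired, regions = regions, genes = genes, motifs = motifs,
       genome = genome, sites = sites, gene_pairs = gene_pairs)
}

random_sequence <- function(n) {
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

plant_motifs <- function(genome, regions, placements, consensi, tf_ids) {
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  ridx <- match(placements$region_id, regions$region_id)
  for (chrom in unique(regions$chrom[ridx])) {
    raw_seq <- charToRaw(genome[[chrom]])
    rows <- which(regions$chrom[ridx] == chrom)
    for (i in rows) {
      cons <- consensi[match(placements$tf[i], tf_ids)]
      if (placements$strand[i] == "-") cons <- rc(cons)
      pos <- regions$start[ridx[i]] + placements$offset[i]  # 0-based
      raw_seq[(pos + 1):(pos + nchar(cons))] <- charToRaw(cons)
    }
    genome[[chrom]] <- rawToChar(raw_seq)
  }
  genome
}

#' Build cluster-level fate-graph inputs from a simulated regulome
#'
#' Groups observations into trajectory nodes — shared "early" pseudotime
#' bins before the branch point, branch-specific bins after it — and
#' returns everything [build_fate_graph()] and [assign_branches()] consume:
#' per-node mean transition scores, pseudotime, a chain-structured
#' connectivity matrix, and the true node labels (branch name, or the
#' merged label for pre-branch nodes).
#'
#' @param sim Output of [simulate_regulome()].
#' @param n_bins Pseudotime bins per branch segment (default 5).
#' @param early_label Label for pre-branch nodes (default `"early"`).
#' @return A list with `scores` (nodes x terminal states), `pseudotime`,
#'   `connectivities`, `true_labels`, and `obs_node` (node id per
#'   observation).
#' @export
fate_graph_inputs <- function(sim, n_bins = 5, early_label = "early") {
  truth <- sim$truth
  pt <- sim$paired$obs_meta$pseudotime
  br <- sim$paired$obs_meta$branch
  bp <- truth$branch_point
  branches <- colnames(truth$absorption)
  early <- pt <= bp
  bin_early <- ceiling(pmax(pt[early], 1e-9) / bp * n_bins)
  node <- character(length(pt))
  node[early] <- sprintf("early_%02d", bin_early)
  bin_late <- ceiling(pmax(pt[!early] - bp, 1e-9) / (1 - bp) * n_bins)
  node[!early] <- sprintf("%s_%02d", br[!early], bin_late)
  scores_obs <- transition_scores(truth$absorption)
  nodes <- sort(unique(node))
  agg <- function(v) tapply(v, node, mean)[nodes]
  scores <- apply(scores_obs, 2, agg)
  node_pt <- as.numeric(agg(pt))
  # chain connectivity: early chain, fork to each branch chain
  n <- length(nodes)
  conn <- matrix(0, n, n, dimnames = list(nodes, nodes))
  chain <- function(ids) {
    ids <- ids[order(node_pt[match(ids, nodes)])]
    for (i in seq_len(length(ids) - 1)) {
      conn[ids[i], ids[i + 1]] <<- 1
      conn[ids[i + 1], ids[i]] <<- 1
    }
    ids
  }
  early_ids <- chain(grep("^early_", nodes, value = TRUE))
  last_early <- early_ids[length(early_ids)]
  for (b in branches) {
    ids <- chain(grep(paste0("^", b, "_"), nodes, value = TRUE))
    if (length(ids)) {
      conn[last_early, ids[1]] <- 1
      conn[ids[1], last_early] <- 1
    }
  }
  true_labels <- ifelse(grepl("^early_", nodes), early_label,
                        sub("_[0-9]+$", "", nodes))
  list(scores = scores, pseudotime = stats::setNames(node_pt, nodes),
       connectivities = conn,
       true_labels = stats::setNames(true_labels, nodes),
       obs_node = node)
}
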