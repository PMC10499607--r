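#' Convert a PFM to a log-odds (PWM) matrix
#'
#' Columns are normalized to probabilities after adding
#' `pseudocount * background` to each count, then converted to
#' `log2(p / background)` ("bits").
#'
#' @param pfm A [motif_pfm()].
#' @param background Length-4 base probabilities (A,C,G,T); must sum to 1
#'   with all entries > 0.
#' @param pseudocount Pseudocount scale (default 0.8).
#' @return A 4 x L numeric matrix of log-odds scores.
#' @export
pfm_to_logodds <- function(pfm, background = rep(0.25, 4), pseudocount = 0.8) {
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-8) {
    stop("background must be 4 positive probabilities summing to 1")
  }
  m <- pfm$matrix
  counts <- sweep(m, 1, pseudocount * background, `+`)
  if (any(colSums(counts) == 0)) {
    stop("zero PFM column with zero pseudocount cannot be normalized")
  }
  p <- sweep(counts, 2, colSums(counts), `/`)
  lo <- log2(sweep(p, 1, background, `/`))
  rownames(lo) <- c("A", "C", "G", "T")
  lo
}

# Discretize a log-odds matrix to integer bins (default 0.01 bits).
discretize_pwm <- function(logodds, bin = 0.01) {
  round(logodds / bin)
}

# Exact distribution of the integer-binned PWM score under the background
# model, by dynamic programming (column-wise convolution). Returns the
# smallest integer score t with P(S >= t) <= p_threshold.
pwm_score_threshold <- function(q, background, p_threshold) {
  lo <- sum(apply(q, 2, min))
  hi <- sum(apply(q, 2, max))
  if (p_threshold >= 1) return(lo)
  n_bins <- hi - lo + 1L
  dist <- numeric(n_bins)
  # state: distribution of partial score - running minimum, 0-based offset
  dist[1] <- 1
  run_lo <- 0L
  for (k in seq_len(ncol(q))) {
    col <- q[, k]
    cmin <- min(col)
    width <- max(col) - cmin
    new <- numeric(n_bins)
    for (b in 1:4) {
      shift <- col[b] - cmin
      idx <- which(dist > 0)
      new[idx + shift] <- new[idx + shift] + dist[idx] * background[b]
    }
    dist <- new
    run_lo <- run_lo + cmin
  }
  # dist[i] = P(S == run_lo + i - 1); run_lo == lo
  tail_p <- rev(cumsum(rev(dist)))
  ok <- which(tail_p <= p_threshold + 1e-12)
  if (!length(ok)) return(hi + 1L)  # nothing passes
  lo + ok[1] - 1L
}

# Score every window of an integer-coded sequence with an integer-binned
# PWM; windows containing codes outside 1..4 score NA.
score_windows <- function(codes, q) {
  L <- ncol(q)
  n <- length(codes)
  if (n < L) return(numeric(0))
  n_win <- n - L + 1L
  s <- numeric(n_win)
  for (k in seq_len(L)) {
    s <- s + q[, k][codes[k:(n_win + k - 1L)]]
  }
  s
}

reverse_complement_pwm <- function(q) {
  q[4:1, ncol(q):1, drop = FALSE]
}

#' Scan candidate regions for TF-binding motifs
#'
#' Scores every offset of every region on both strands with the motif's
#' log-odds matrix (discretized to 0.01-bit bins) and reports hits whose
#' score reaches the threshold corresponding to `p_threshold` under the
#' background model. The threshold is computed from the exact score
#' distribution by dynamic programming, so the scan is deterministic and
#' agrees with an exhaustive per-window scorer. Windows containing
#' non-ACGT bases are skipped. Region coordinates extending beyond the
#' chromosome are clamped to the available sequence.
#'
#' @param candidates A [region_set()] of regions to scan.
#' @param genome A named `Biostrings::DNAStringSet`, a named character
#'   vector of chromosome sequences, or a path to a FASTA file.
#' @param motifs A list of [motif_pfm()] objects.
#' @param p_threshold Per-window p-value threshold (default 5e-5).
#' @param background Background base probabilities (A,C,G,T).
#' @param pseudocount Pseudocount for [pfm_to_logodds()].
#' @return A binding-site table: data frame with columns `region_id`,
#'   `motif_id`, `tf`, `strand`, `offset` (0-based within the region, the
#'   leftmost base of the match on the forward strand) and
#'   `logodds_score` (bits). One row per (hit, TF name).
#' @export
scan_regions <- function(candidates, genome, motifs, p_threshold = 5e-5,
                         background = rep(0.25, 4), pseudocount = 0.8) {
  genome <- as_genome(genome)
  chrom_len <- Biostrings::width(genome)
  names(chrom_len) <- names(genome)
  unknown <- setdiff(unique(candidates$chrom), names(genome))
  if (length(unknown)) {
    stop("chromosome(s) absent from genome: ", paste(unknown, collapse = ","))
  }
  bin <- 0.01
  prepared <- lapply(motifs, function(m) {
    q <- discretize_pwm(pfm_to_logodds(m, background, pseudocount), bin)
    list(motif = m, q = q, q_rc = reverse_complement_pwm(q),
         thr = pwm_score_threshold(q, background, p_threshold))
  })
  base_codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  res <- list()
  for (ri in seq_len(nrow(candidates))) {
    chrom <- candidates$chrom[ri]
    from <- max(0, candidates$start[ri])
    to <- min(candidates$end[ri], chrom_len[[chrom]])
    if (to - from < 1) next
    seq_chr <- as.character(Biostrings::subseq(genome[[chrom]], from + 1, to))
    codes <- unname(base_codes[strsplit(toupper(seq_chr), "")[[1]]])
    for (pm in prepared) {
      L <- ncol(pm$q)
      if (length(codes) < L) next
      for (strand in c("+", "-")) {
        q <- if (strand == "+") pm$q else pm$q_rc
        s <- score_windows(codes, q)
        hit <- which(!is.na(s) & s >= pm$thr)
        if (!length(hit)) next
        res[[length(res) + 1L]] <- data.frame(
          region_id = candidates$region_id[ri],
          motif_id = pm$motif$motif_id,
          tf = rep(pm$motif$tf_names, each = length(hit)),
          strand = strand,
          offset = rep(hit - 1L, times = length(pm$motif$tf_names)),
          logodds_score = rep(s[hit] * bin, times = length(pm$motif$tf_names)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) {
    return(data.frame(region_id = character(), motif_id = character(),
                      tf = character(), strand = character(),
                      offset = integer(), logodds_score = numeric()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(genome))
  }
  stop("genome must be a DNAStringSet, a named character vector, or a FASTA path")
}

#' Write a genome as FASTA
#' @param genome Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path)
  invisible(path)
}
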