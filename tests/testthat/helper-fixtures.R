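# Shared fixture builders; everything is generated in code at test time.

write_lines_tmp <- function(lines) {
  path <- tempfile()
  writeLines(lines, path)
  path
}

# A one-hot PFM for a given consensus (count `hit` on the consensus base).
consensus_pfm <- function(consensus, motif_id = "M1", tf = "TFX", hit = 12) {
  bases <- c("A", "C", "G", "T")
  cons <- strsplit(consensus, "")[[1]]
  m <- matrix(1, 4, length(cons), dimnames = list(bases, NULL))
  m[cbind(match(cons, bases), seq_along(cons))] <- hit
  motif_pfm(motif_id, tf, m)
}

# Brute-force per-window PWM scorer over both strands: the independent
# oracle for scan_regions (same 0.01-bit discretization).
oracle_scan <- function(seq_chr, pfm, p_threshold,
                        background = rep(0.25, 4), pseudocount = 0.8) {
  lo <- pfm_to_logodds(pfm, background, pseudocount)
  q <- round(lo / 0.01)
  thr <- regulokit:::pwm_score_threshold(q, background, p_threshold)
  codes <- match(strsplit(seq_chr, "")[[1]], c("A", "C", "G", "T"))
  L <- ncol(q)
  n <- length(codes)
  hits <- NULL
  if (n >= L) {
    q_rc <- q[4:1, L:1, drop = FALSE]
    for (o in seq_len(n - L + 1)) {
      win <- codes[o:(o + L - 1)]
      if (anyNA(win)) next
      for (strand in c("+", "-")) {
        qq <- if (strand == "+") q else q_rc
        s <- sum(qq[cbind(win, seq_len(L))])
        if (s >= thr) {
          hits <- rbind(hits, data.frame(offset = o - 1L, strand = strand,
                                         score = s * 0.01))
        }
      }
    }
  }
  if (is.null(hits)) {
    hits <- data.frame(offset = integer(), strand = character(),
                       score = numeric())
  }
  hits
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random interval set on a toy genome of length `len`.
random_region_set <- function(n, len, max_width = 400, prefix = "r") {
  start <- sort(sample.int(len - max_width, n))
  width <- sample.int(max_width, n)
  region_set("toy", start, pmin(start + width, len),
             paste0(prefix, seq_len(n)))
}

# Per-base boolean-mask oracle for candidate-region selection.
mask_candidates <- function(peaks, conserved, exons, ccres, len) {
  mask_of <- function(rs) {
    m <- logical(len)
    for (i in seq_len(nrow(rs))) {
      m[(rs$start[i] + 1):rs$end[i]] <- TRUE
    }
    m
  }
  m <- (mask_of(peaks) & mask_of(conserved) & !mask_of(exons)) |
    (mask_of(peaks) & mask_of(ccres))
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}
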