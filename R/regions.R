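#' Filter ATAC peaks by width
#'
#' Retains peaks whose width (`end - start`) lies within the closed
#' interval `[min_bp, max_bp]`. The defaults implement the strict
#' "> 20 bp and < 10,000 bp" quality filter.
#'
#' @param peaks A [region_set()].
#' @param min_bp,max_bp Width bounds in bp (inclusive).
#' @return The filtered region set, input order preserved.
#' @export
filter_peaks_by_width <- function(peaks, min_bp = 21, max_bp = 9999) {
  w <- peaks$end - peaks$start
  peaks[w >= min_bp & w <= max_bp, , drop = FALSE]
}

#' Select candidate cis-regulatory regions
#'
#' Narrows ATAC peaks to sequence with regulatory evidence: peaks are
#' intersected (clipped to the overlap) with conserved elements, any base
#' overlapping an exon is subtracted from that conserved branch, peaks are
#' separately intersected with cCREs, and the union of the two branches is
#' carried forward. Overlapping or adjacent result intervals are merged;
#' each merged row carries a provenance flag: `conserved`, `cCRE`, or
#' `both` when it contains bases from both branches.
#'
#' @param peaks,conserved,exons,ccres [region_set()] objects. `exons` and
#'   `ccres` may be empty.
#' @return A region set with an extra `provenance` column; region ids are
#'   regenerated as `"chrom:start-end"`.
#' @export
select_candidate_regions <- function(peaks, conserved, exons, ccres) {
  check_chrom_compatibility(peaks, conserved, "peaks and conserved elements")
  empty <- function() {
    out <- region_set()
    out$provenance <- character(0)
    out
  }
  to_gr <- function(rs) {
    if (nrow(rs) == 0) GenomicRanges::GRanges() else
      GenomicRanges::reduce(regions_to_granges(rs))
  }
  gr_peaks <- to_gr(peaks)
  a <- GenomicRanges::intersect(gr_peaks, to_gr(conserved))
  if (nrow(exons) > 0) a <- GenomicRanges::setdiff(a, to_gr(exons))
  b <- GenomicRanges::intersect(gr_peaks, to_gr(ccres))
  merged <- GenomicRanges::reduce(c(a, b))
  if (length(merged) == 0) return(empty())
  from_a <- IRanges::overlapsAny(merged, a)
  from_b <- IRanges::overlapsAny(merged, b)
  prov <- ifelse(from_a & from_b, "both", ifelse(from_a, "conserved", "cCRE"))
  out <- granges_to_regions(merged, id = NULL)
  out$provenance <- prov
  sort_regions(out)
}

#' Regulatory window of a gene
#'
#' The window spans the gene body plus `upstream_bp` upstream of the TSS,
#' strand-aware: on `+` the window starts at `max(0, start - upstream_bp)`;
#' on `-` it ends at `end + upstream_bp`. Windows are not clipped at
#' chromosome ends (sequence lookups clamp later).
#'
#' @param gene One row of a [gene_annotation()] (or a list with the same
#'   fields).
#' @param upstream_bp Upstream extension in bp (default 100 kb).
#' @return A one-row [region_set()].
#' @export
regulatory_window <- function(gene, upstream_bp = 1e5) {
  if (gene$strand == "+") {
    region_set(gene$chrom, max(0, gene$start - upstream_bp), gene$end,
               paste0(gene$gene_id, "_window"))
  } else {
    region_set(gene$chrom, gene$start, gene$end + upstream_bp,
               paste0(gene$gene_id, "_window"))
  }
}

#' Assign candidate regions to genes in their vicinity
#'
#' A (gene, region) pair is emitted iff the region overlaps the gene's
#' regulatory window by at least 1 bp; a region may map to several genes.
#'
#' @param candidates A [region_set()] of candidate regions.
#' @param genes A [gene_annotation()].
#' @param upstream_bp Window extension passed to [regulatory_window()].
#' @return A data frame with columns `gene_id`, `region_id`.
#' @export
assign_regions_to_genes <- function(candidates, genes, upstream_bp = 1e5) {
  if (nrow(candidates) == 0 || nrow(genes) == 0) {
    return(data.frame(gene_id = character(), region_id = character()))
  }
  check_chrom_compatibility(candidates, genes, "candidate regions and genes")
  win_start <- ifelse(genes$strand == "+",
                      pmax(0, genes$start - upstream_bp), genes$start)
  win_end <- ifelse(genes$strand == "+",
                    genes$end, genes$end + upstream_bp)
  windows <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(win_start + 1, win_end))
  hits <- GenomicRanges::findOverlaps(regions_to_granges(candidates), windows)
  out <- data.frame(
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    region_id = candidates$region_id[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$region_id), , drop = FALSE]
}

#' Map candidate regions to their enclosing accessibility peaks
#'
#' Candidate regions are sub-intervals of ATAC peaks; their accessibility
#' is read from the overlapping peak. Each candidate is mapped to the peak
#' with the largest overlap.
#'
#' @param candidates A [region_set()] of candidate regions.
#' @param peaks The [region_set()] whose ids name the accessibility rows.
#' @return Named character vector: candidate region_id -> peak region_id
#'   (unmapped candidates are dropped).
#' @export
map_regions_to_peaks <- function(candidates, peaks) {
  hits <- GenomicRanges::findOverlaps(regions_to_granges(candidates),
                                      regions_to_granges(peaks))
  if (!length(hits)) return(stats::setNames(character(0), character(0)))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    regions_to_granges(candidates)[q], regions_to_granges(peaks)[s]))
  ord <- order(q, -ov)
  first <- !duplicated(q[ord])
  stats::setNames(peaks$region_id[s[ord][first]],
                  candidates$region_id[q[ord][first]])
}
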