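#' Construct a region set
#'
#' A region set is the currency of all genomic interval algebra in regulokit:
#' a data frame of intervals in 0-based, half-open (BED) coordinates with a
#' unique identifier per row.
#'
#' @param chrom Character vector of chromosome names (taken verbatim; no
#'   "chr" normalization is applied).
#' @param start,end Integer vectors; `start` is 0-based inclusive, `end`
#'   exclusive, so the width is `end - start`.
#' @param region_id Optional character vector of unique identifiers;
#'   defaults to `"chrom:start-end"`.
#'
#' @return A data frame with class `region_set` and columns `chrom`,
#'   `start`, `end`, `region_id`.
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), region_id = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.null(region_id)) {
    region_id <- sprintf("%s:%d-%d", chrom, start, end)
  }
  rs <- data.frame(chrom = chrom, start = start, end = end,
                   region_id = as.character(region_id),
                   stringsAsFactors = FALSE)
  validate_region_set(rs)
  class(rs) <- c("region_set", "data.frame")
  rs
}

validate_region_set <- function(rs) {
  stopifnot(all(c("chrom", "start", "end", "region_id") %in% names(rs)))
  if (any(rs$start >= rs$end)) {
    bad <- which(rs$start >= rs$end)[1]
    stop("invalid region: start >= end at row ", bad)
  }
  if (anyDuplicated(rs$region_id)) {
    stop("region_id values must be unique within a region set")
  }
  invisible(rs)
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set with", nrow(x), "regions on",
      length(unique(x$chrom)), "chromosome(s)\n")
  NextMethod()
}

#' Read a BED file into a region set
#'
#' BED coordinates are already 0-based half-open and are taken verbatim.
#' When a fourth column is absent, identifiers `"chrom:start-end"` are
#' generated.
#'
#' @param path Path to a BED3/BED4 (or wider) tab-separated file.
#' @return A [region_set()].
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(region_set())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(parts)
  if (any(n_col < 3)) {
    stop("BED parse error at line ", which(n_col < 3)[1],
         ": fewer than 3 tab-separated columns")
  }
  chrom <- vapply(parts, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start %% 1 != 0 | end %% 1 != 0)
  if (length(bad)) {
    stop("BED parse error at line ", bad[1], ": non-integer coordinates")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop("BED parse error at line ", bad[1], ": start >= end")
  }
  id <- ifelse(n_col >= 4, vapply(parts, function(p) p[4], ""),
               sprintf("%s:%d-%d", chrom, start, end))
  region_set(chrom, start, end, id)
}

#' Write a region set as BED
#'
#' Rows are emitted in canonical (chrom, start, end) order, which makes
#' `read_bed(write_bed(x))` an identity on canonically sorted sets.
#'
#' @param rs A [region_set()].
#' @param path Output path.
#' @export
write_bed <- function(rs, path) {
  validate_region_set(rs)
  ord <- order(rs$chrom, rs$start, rs$end)
  rs <- rs[ord, , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\t%s", rs$chrom, rs$start, rs$end,
                     rs$region_id), path)
  invisible(path)
}

#' Sort a region set canonically by (chrom, start, end)
#' @param rs A [region_set()].
#' @return The sorted region set.
#' @export
sort_regions <- function(rs) {
  rs[order(rs$chrom, rs$start, rs$end), , drop = FALSE]
}

# region_set (0-based half-open) <-> GRanges (1-based closed)
regions_to_granges <- function(rs) {
  GenomicRanges::GRanges(rs$chrom,
                         IRanges::IRanges(start = rs$start + 1, end = rs$end),
                         region_id = rs$region_id)
}

granges_to_regions <- function(gr, id = NULL) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr) - 1
  end <- GenomicRanges::end(gr)
  if (is.null(id) && !is.null(gr$region_id)) id <- gr$region_id
  region_set(chrom, start, end, id)
}

#' Construct a gene annotation table
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chrom Chromosome names.
#' @param start,end Gene-body coordinates, 0-based half-open.
#' @param strand Character vector in `{"+", "-"}`.
#' @return A data frame with class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand) {
  ga <- data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  if (any(ga$start >= ga$end)) stop("gene annotation: start >= end")
  if (!all(ga$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(ga$gene_id)) stop("gene_id values must be unique")
  class(ga) <- c("gene_annotation", "data.frame")
  ga
}

#' Read gene annotations from BED6 or a GTF subset
#'
#' BED coordinates are taken verbatim (0-based half-open); GTF `gene` rows
#' are converted from 1-based inclusive to 0-based half-open at the
#' boundary.
#'
#' @param path Input path.
#' @param format `"bed"` (name column = gene id) or `"gtf"` (gene_id parsed
#'   from the attributes column; only rows with feature type `gene` are
#'   used).
#' @return A [gene_annotation()].
#' @export
read_gene_annotation <- function(path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  if (format == "bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 6)) {
      stop("gene BED requires 6 columns (chrom,start,end,name,score,strand)")
    }
    return(gene_annotation(
      gene_id = vapply(parts, `[[`, "", 4),
      chrom = vapply(parts, `[[`, "", 1),
      start = as.numeric(vapply(parts, `[[`, "", 2)),
      end = as.numeric(vapply(parts, `[[`, "", 3)),
      strand = vapply(parts, `[[`, "", 6)))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(parts, function(p) length(p) >= 9 && p[3] == "gene", FALSE)
  parts <- parts[keep]
  if (!length(parts)) stop("no 'gene' rows found in GTF")
  gid <- vapply(parts, function(p) {
    m <- regmatches(p[9], regexpr('gene_id "[^"]+"', p[9]))
    if (!length(m)) stop("GTF gene row without gene_id attribute")
    sub('gene_id "([^"]+)"', "\\1", m)
  }, "")
  gene_annotation(
    gene_id = gid,
    chrom = vapply(parts, `[[`, "", 1),
    start = as.numeric(vapply(parts, `[[`, "", 4)) - 1,
    end = as.numeric(vapply(parts, `[[`, "", 5)),
    strand = vapply(parts, `[[`, "", 7))
}

genes_to_granges <- function(ga) {
  GenomicRanges::GRanges(ga$chrom,
                         IRanges::IRanges(start = ga$start + 1, end = ga$end),
                         strand = ga$strand, gene_id = ga$gene_id)
}

#' Warn when two inputs share no chromosome names
#'
#' Chromosome naming is taken verbatim everywhere; this surfaces naming
#' mismatches (e.g. "chr1" vs "1") instead of silently returning empty
#' overlaps.
#'
#' @param a,b Character vectors of chromosome names (or region sets).
#' @param what Label used in the warning.
#' @return Invisibly, the common chromosome names.
#' @export
check_chrom_compatibility <- function(a, b, what = "inputs") {
  if (is.data.frame(a)) a <- a$chrom
  if (is.data.frame(b)) b <- b$chrom
  common <- intersect(unique(a), unique(b))
  if (length(common) == 0 && length(a) && length(b)) {
    warning(what, " share no chromosome names: {",
            paste(utils::head(unique(a), 3), collapse = ","), "} vs {",
            paste(utils::head(unique(b), 3), collapse = ","), "}")
  }
  invisible(common)
}

#' Write gene annotations as BED6
#' @param ga A [gene_annotation()].
#' @param path Output path.
#' @export
write_gene_bed <- function(ga, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", ga$chrom, ga$start, ga$end,
                     ga$gene_id, ga$strand), path)
  invisible(path)
}
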