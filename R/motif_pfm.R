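#' Construct a motif position frequency matrix
#'
#' @param motif_id Motif identifier.
#' @param tf_names Character vector of TF names the motif is assigned to
#'   (at least one).
#' @param matrix 4 x L nonnegative matrix of counts or frequencies with
#'   rows A, C, G, T.
#' @return A list with class `motif_pfm`.
#' @export
motif_pfm <- function(motif_id, tf_names, matrix) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) stop("PFM must have 4 rows (A,C,G,T)")
  if (ncol(matrix) < 4) stop("PFM must have length >= 4")
  if (any(matrix < 0)) stop("PFM entries must be nonnegative")
  if (length(tf_names) < 1) stop("motif needs at least one TF name")
  rownames(matrix) <- c("A", "C", "G", "T")
  structure(list(motif_id = as.character(motif_id),
                 tf_names = as.character(tf_names),
                 matrix = matrix),
            class = "motif_pfm")
}

#' @export
print.motif_pfm <- function(x, ...) {
  cat("motif_pfm", x$motif_id, "(", paste(x$tf_names, collapse = ","),
      ") length", ncol(x$matrix), "\n")
  invisible(x)
}

#' Consensus sequence of a PFM (argmax base per column)
#' @param pfm A [motif_pfm()].
#' @return A character scalar over A/C/G/T.
#' @export
pfm_consensus <- function(pfm) {
  paste(rownames(pfm$matrix)[apply(pfm$matrix, 2, which.max)], collapse = "")
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR text format: a `>ID NAME` header followed by four
#' base rows like `A [ 4 19 0 0 ]`. Base rows may appear in any order;
#' they are normalized to A, C, G, T. Multiple TF names in the header may
#' be separated by `::`.
#'
#' @param path Path to a JASPAR PFM text file (one or more records).
#' @return A list of [motif_pfm()] objects.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  headers <- which(startsWith(lines, ">"))
  if (!length(headers)) stop("no JASPAR records ('>' headers) found")
  bounds <- c(headers, length(lines) + 1L)
  out <- vector("list", length(headers))
  for (i in seq_along(headers)) {
    head_line <- sub("^>", "", lines[headers[i]])
    fields <- strsplit(head_line, "[ \t]+")[[1]]
    motif_id <- fields[1]
    name <- if (length(fields) >= 2) paste(fields[-1], collapse = " ") else fields[1]
    tf_names <- strsplit(name, "::", fixed = TRUE)[[1]]
    body <- lines[seq(headers[i] + 1L, bounds[i + 1L] - 1L)]
    rows <- list()
    for (bl in body) {
      base <- toupper(substr(bl, 1, 1))
      if (!base %in% c("A", "C", "G", "T")) {
        stop("JASPAR parse error in record ", motif_id,
             ": unexpected row '", bl, "'")
      }
      rest <- substring(bl, 2)
      nums <- regmatches(
        rest, gregexpr("[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?", rest))[[1]]
      rows[[base]] <- as.numeric(nums)
    }
    missing <- setdiff(c("A", "C", "G", "T"), names(rows))
    if (length(missing)) {
      stop("JASPAR record ", motif_id, " is missing base row(s): ",
           paste(missing, collapse = ","))
    }
    lens <- vapply(rows, length, 0L)
    if (length(unique(lens)) != 1) {
      stop("JASPAR record ", motif_id, " has base rows of unequal length")
    }
    out[[i]] <- motif_pfm(motif_id, tf_names,
                          rbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T))
  }
  out
}

#' Write motifs in JASPAR text format
#' @param pfms A list of [motif_pfm()] objects.
#' @param path Output path.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  lines <- unlist(lapply(pfms, function(p) {
    c(sprintf(">%s %s", p$motif_id, paste(p$tf_names, collapse = "::")),
      vapply(c("A", "C", "G", "T"), function(b) {
        sprintf("%s  [ %s ]", b, paste(p$matrix[b, ], collapse = " "))
      }, ""))
  }))
  writeLines(lines, path)
  invisible(path)
}
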