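#' Global protein sequence similarity between two TFs
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, gap
#' extension 0.5); similarity is the fraction of alignment columns with
#' identical residues.
#'
#' @param tf_query_seq,tf_other_seq Protein sequences (20-letter alphabet,
#'   `X` allowed), nonempty.
#' @return Similarity in `[0, 1]`.
#' @export
family_similarity <- function(tf_query_seq, tf_other_seq) {
  if (!nzchar(tf_query_seq) || !nzchar(tf_other_seq)) {
    stop("protein sequences must be nonempty")
  }
  blosum62 <- get_blosum62()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(tf_query_seq), Biostrings::AAString(tf_other_seq),
    type = "global", substitutionMatrix = blosum62,
    gapOpening = 10, gapExtension = 0.5)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Assign motifs to a motif-less TF by family similarity
#'
#' Among TFs of the same family with global sequence similarity of at
#' least `min_similarity`, the motifs of the `top_k` most similar members
#' are emitted as family-inferred assignments (ties broken alphabetically
#' by member name). Fewer than `top_k` qualifying members is allowed.
#'
#' @param tf Name of the query TF.
#' @param tf_seq Protein sequence of the query TF.
#' @param family_members Named list; each element is a list with fields
#'   `seq` (protein sequence) and `motifs` (character vector of motif ids).
#' @param min_similarity Minimum similarity (default 0.20).
#' @param top_k Number of most-similar members whose motifs are taken
#'   (default 3).
#' @return A motif-assignment data frame with columns `tf`, `motif_id`,
#'   `source` (`"family-inferred"`), `similarity`.
#' @export
assign_motifs_by_similarity <- function(tf, tf_seq, family_members,
                                        min_similarity = 0.20, top_k = 3) {
  empty <- data.frame(tf = character(), motif_id = character(),
                      source = character(), similarity = numeric())
  members <- setdiff(names(family_members), tf)
  if (!length(members)) return(empty)
  sims <- vapply(members, function(m) {
    family_similarity(tf_seq, family_members[[m]]$seq)
  }, 0)
  keep <- members[sims >= min_similarity]
  if (!length(keep)) return(empty)
  keep <- keep[order(-sims[keep], keep)]
  keep <- utils::head(keep, top_k)
  rows <- lapply(keep, function(m) {
    motifs <- family_members[[m]]$motifs
    if (!length(motifs)) return(NULL)
    data.frame(tf = tf, motif_id = motifs, source = "family-inferred",
               similarity = unname(sims[m]), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, FALSE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Direct motif-assignment rows for motifs with known TFs
#' @param pfms A list of [motif_pfm()] objects.
#' @return A motif-assignment data frame (`source = "direct"`).
#' @export
direct_motif_assignment <- function(pfms) {
  rows <- lapply(pfms, function(p) {
    data.frame(tf = p$tf_names, motif_id = p$motif_id, source = "direct",
               similarity = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge motif assignments, prioritizing direct evidence
#'
#' Deduplicates (tf, motif_id) pairs keeping the best-ranked source
#' (direct evidence over family-inferred).
#'
#' @param ... Motif-assignment data frames.
#' @return The merged assignment table.
#' @export
merge_motif_assignments <- function(...) {
  all <- do.call(rbind, list(...))
  rank <- match(all$source, c("direct", "family-inferred"))
  ord <- order(all$tf, all$motif_id, rank)
  all <- all[ord, , drop = FALSE]
  all <- all[!duplicated(all[, c("tf", "motif_id")]), , drop = FALSE]
  rownames(all) <- NULL
  all
}

#' Extend motif TF lists with assignment rows
#'
#' Adds each assigned TF to the `tf_names` of the corresponding motif, so
#' family-inferred TFs participate in motif scans.
#'
#' @param pfms A list of [motif_pfm()] objects.
#' @param assignment A motif-assignment data frame.
#' @return The updated list of motifs.
#' @export
apply_motif_assignment <- function(pfms, assignment) {
  ids <- vapply(pfms, function(p) p$motif_id, "")
  for (i in seq_len(nrow(assignment))) {
    j <- match(assignment$motif_id[i], ids)
    if (is.na(j)) next
    pfms[[j]]$tf_names <- union(pfms[[j]]$tf_names, assignment$tf[i])
  }
  pfms
}
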