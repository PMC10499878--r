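#' Proteomics detection and specificity filter
#'
#' Retains a protein iff (rule 1) it is detected in both technical
#' replicates of at least one biological replicate of its own co-culture,
#' AND (rule 2) at least 80% of its counts (inclusive) fall in the correct
#' samples. A protein with zero total counts fails (it is simply
#' undetected, not an error). Both rules are monotone: adding a detection
#' can only keep or admit a protein.
#'
#' @param counts Numeric matrix, rows = proteins, columns = runs, values =
#'   detection counts (`>= 0`).
#' @param run_info Data frame, one row per run (matching columns of
#'   `counts`), with `bio_rep` (replicate id), `tech_rep` (e.g. "A"/"B"),
#'   `correct_sample` (logical: run belongs to the protein's own
#'   co-culture).
#' @param specificity Inclusive correct-sample count share (default 0.8).
#' @return Character vector of retained protein rownames (indices if
#'   unnamed).
#' @export
proteomics_detection_filter <- function(counts, run_info,
                                        specificity = 0.8) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == nrow(run_info),
            all(c("bio_rep", "tech_rep", "correct_sample") %in%
                  names(run_info)))
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (is.null(rownames(counts))) {
    rownames(counts) <- as.character(seq_len(nrow(counts)))
  }
  correct <- as.logical(run_info$correct_sample)
  keep <- vapply(seq_len(nrow(counts)), function(i) {
    x <- counts[i, ]
    tot <- sum(x)
    if (tot == 0) return(FALSE)
    # rule 1: some biological replicate of the correct culture has
    # detections in every one of its technical replicates
    rule1 <- FALSE
    for (b in unique(run_info$bio_rep[correct])) {
      sel <- correct & run_info$bio_rep == b
      if (all(tapply(x[sel], run_info$tech_rep[sel], sum) > 0)) {
        rule1 <- TRUE
        break
      }
    }
    rule1 && (sum(x[correct]) / tot >= specificity)
  }, logical(1))
  rownames(counts)[keep]
}

#' Pathway completeness against a gene requirement set
#'
#' Completeness is the fraction of required reaction steps observed in a
#' genome; a pathway is functionally complete when completeness reaches
#' the threshold (default 0.75, inclusive — draft genomes make perfect
#' recovery unrealistic). Steps with alternate reactions are encoded as
#' OR-groups: a step counts as present when any of its variants is.
#'
#' @param genes_present Character vector of genes observed in the genome.
#' @param required Required gene set: a character vector (each gene one
#'   step) and/or a list whose elements are character vectors of
#'   alternates (OR-groups). Must be non-empty.
#' @param threshold Inclusive completeness threshold in `[0, 1]`.
#' @return List with `completeness` (fraction) and `complete` (logical).
#' @examples
#' pathway_completeness(c("g1", "g2", "g3"), c("g1", "g2", "g3", "g4"))
#' # 3/4 = 0.75 -> complete at the default threshold
#' @export
pathway_completeness <- function(genes_present, required, threshold = 0.75) {
  if (length(required) == 0) stop("required gene set is empty", call. = FALSE)
  if (!is.list(required)) required <- as.list(required)
  hit <- vapply(required, function(step) any(step %in% genes_present),
                logical(1))
  comp <- mean(hit)
  list(completeness = comp, complete = comp >= threshold)
}
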