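#' Construct a multi-species alignment object
#'
#' @param mat Character matrix (rows = species, columns = aligned sites)
#'   over `A`, `C`, `G`, `T`, `-`.
#' @param labels Species labels, one per row.
#' @param reference Label of the reference (human) row.
#' @return An object of class `multi_alignment`.
#' @export
multi_alignment <- function(mat, labels, reference = labels[1]) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L)
    alignment_error("alignment needs at least 2 sequences")
  if (length(labels) != nrow(mat))
    alignment_error("one label per row required")
  if (anyDuplicated(labels))
    alignment_error(paste("duplicate species label:",
                          labels[duplicated(labels)][1]))
  if (!reference %in% labels)
    alignment_error(paste0("reference label '", reference,
                           "' not among the sequences"))
  bad <- !mat %in% c("A", "C", "G", "T", "-")
  if (any(bad))
    alignment_error(paste0("non-IUPAC character '", mat[bad][1],
                           "' in alignment"))
  ref_row <- mat[match(reference, labels), ]
  if (!any(ref_row != "-"))
    alignment_error("reference row is all gaps")
  rownames(mat) <- labels
  structure(list(labels = labels, matrix = mat, reference = reference),
            class = "multi_alignment")
}

alignment_error <- function(msg)
  stop(errorCondition(msg, class = c("alignment_format_error", "error")))

#' Read an aligned FASTA file
#'
#' Parses a per-gene multi-species alignment in aligned FASTA (gaps as
#' `-`). All rows must be the same length; a format error is raised
#' otherwise.
#'
#' @param path FASTA file path.
#' @param reference Label of the reference (human) row; defaults to the
#'   first sequence in the file.
#' @return A [multi_alignment].
#' @export
read_alignment <- function(path, reference = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) < 2L)
    alignment_error("alignment needs at least 2 sequences")
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) != 1L)
    alignment_error(sprintf(
      "rows of unequal length (%d vs %d): not an alignment",
      min(widths), max(widths)))
  labels <- sub("\\s.*$", "", names(seqs))
  mat <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  if (is.null(reference)) reference <- labels[1]
  multi_alignment(mat, labels, reference)
}

#' Write an alignment as aligned FASTA
#'
#' @param alignment A [multi_alignment].
#' @param path Output file path.
#' @export
write_alignment <- function(alignment, path) {
  seqs <- Biostrings::BStringSet(apply(alignment$matrix, 1, paste0,
                                       collapse = ""))
  names(seqs) <- alignment$labels
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @export
print.multi_alignment <- function(x, ...) {
  cat(sprintf("multi-species alignment: %d sequences x %d columns (reference: %s)\n",
              nrow(x$matrix), ncol(x$matrix), x$reference))
  invisible(x)
}

ref_column_index <- function(alignment, position) {
  ref <- alignment$matrix[match(alignment$reference, alignment$labels), ]
  ungapped <- which(ref != "-")
  if (position < 1L || position > length(ungapped))
    stop(errorCondition(
      sprintf("position %d outside the reference's ungapped length (%d)",
              position, length(ungapped)),
      class = c("position_out_of_range_error", "error")))
  ungapped[position]
}

#' Conservation index of a reference position
#'
#' The conservation index (CI) of a position is the percentage of
#' non-reference species whose base in the aligned column equals the
#' reference (human) base. The column is found by mapping the 1-based
#' ungapped reference position through the reference row's gaps.
#'
#' @param alignment A [multi_alignment].
#' @param position 1-based ungapped position within the reference sequence.
#' @param denominator `"nongap"` (default) counts only non-reference
#'   species with a non-gap base in the column; `"all"` uses every
#'   non-reference species.
#' @param threshold Functional-potential cutoff in percent (default 75);
#'   the flag is strict (`CI > threshold`).
#' @return An object of class `conservation_result`: `position`, `column`,
#'   `ref_base`, `ci_percent`, `n_compared`, `conserved`.
#' @examples
#' m <- rbind(rep("A", 4), rep("A", 4), c("A", "C", "A", "C"))
#' aln <- multi_alignment(m, c("human", "sp1", "sp2"), "human")
#' compute_ci(aln, 2)$ci_percent
#' @export
compute_ci <- function(alignment, position,
                       denominator = c("nongap", "all"), threshold = 75) {
  denominator <- match.arg(denominator)
  col <- ref_column_index(alignment, position)
  ref_i <- match(alignment$reference, alignment$labels)
  ref_base <- alignment$matrix[ref_i, col]
  others <- alignment$matrix[-ref_i, col]
  nongap <- others != "-"
  n_compared <- if (denominator == "nongap") sum(nongap) else length(others)
  if (n_compared == 0L)
    stop(errorCondition(
      sprintf("CI undefined at position %d: no comparable species", position),
      class = c("undefined_ci_error", "error")))
  matches <- sum(others[nongap] == ref_base)
  ci <- 100 * matches / n_compared
  structure(list(position = position, column = col, ref_base = ref_base,
                 ci_percent = ci, n_compared = n_compared,
                 conserved = is_functionally_relevant(ci, threshold)),
            class = "conservation_result")
}

#' @export
print.conservation_result <- function(x, ...) {
  cat(sprintf("position %d: CI = %.1f%% (%d species compared)%s\n",
              x$position, x$ci_percent, x$n_compared,
              if (x$conserved) ", functional potential" else ""))
  invisible(x)
}

#' CI profile over every reference position
#'
#' @inheritParams compute_ci
#' @return Data frame with one row per ungapped reference position.
#' @export
ci_profile <- function(alignment, denominator = c("nongap", "all"),
                       threshold = 75) {
  denominator <- match.arg(denominator)
  ref <- alignment$matrix[match(alignment$reference, alignment$labels), ]
  n <- sum(ref != "-")
  rows <- lapply(seq_len(n), function(i) {
    r <- compute_ci(alignment, i, denominator, threshold)
    data.frame(position = i, ref_base = r$ref_base,
               ci_percent = r$ci_percent, n_compared = r$n_compared,
               conserved = r$conserved, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Functional-potential call from a conservation index
#'
#' A position is flagged as having functional potential when its CI
#' strictly exceeds the threshold; CI exactly at the threshold does not
#' qualify.
#'
#' @param ci_percent CI in percent (0-100).
#' @param threshold Cutoff in percent, default 75.
#' @return Logical.
#' @examples
#' is_functionally_relevant(100)   # TRUE
#' is_functionally_relevant(75)    # FALSE: strict inequality
#' @export
is_functionally_relevant <- function(ci_percent, threshold = 75) {
  stopifnot(all(ci_percent >= 0), all(ci_percent <= 100))
  ci_percent > threshold
}
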