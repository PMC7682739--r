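# Independent oracles and fixture builders shared across the suite.

# brute-force CI: explicit per-row loop, no reuse of package internals
oracle_ci <- function(mat, ref_label, labels, position,
                      denominator = "nongap") {
  ref_row <- mat[which(labels == ref_label), ]
  col <- 0L; seen <- 0L
  for (j in seq_len(ncol(mat))) {
    if (ref_row[j] != "-") seen <- seen + 1L
    if (seen == position) { col <- j; break }
  }
  stopifnot(col > 0L)
  matches <- 0L; compared <- 0L
  for (i in seq_len(nrow(mat))) {
    if (labels[i] == ref_label) next
    b <- mat[i, col]
    if (denominator == "all") compared <- compared + 1L
    else if (b != "-") compared <- compared + 1L
    if (b != "-" && b == ref_row[col]) matches <- matches + 1L
  }
  if (compared == 0L) return(NA_real_)
  100 * matches / compared
}

# independent criterion sum for an evidence row (plain arithmetic,
# weights restated from the published scoring table)
oracle_total <- function(reports, cons, het, seg, hist, bio, sf, fun) {
  2 * reports + cons + 2 * het + 2 * seg + 2 * hist + 2 * bio +
    5 * sf + c(none = 0, weak = 2, strong = 5)[[fun]]
}

# every evidence record without functional evidence: 2^5 booleans x 3
# conservation levels (single_fiber FALSE, functional "none") = 96 rows;
# with the functional axes appended the full space is 2^6 x 3 x 3 = 576.
enumerate_no_functional <- function() {
  grid <- expand.grid(reports = c(FALSE, TRUE), cons = 0:2,
                      het = c(FALSE, TRUE), seg = c(FALSE, TRUE),
                      hist = c(FALSE, TRUE), bio = c(FALSE, TRUE))
  grid$total <- with(grid, 2 * reports + cons + 2 * het + 2 * seg +
                       2 * hist + 2 * bio)
  grid
}

fixture_evidence_record <- function(variant) {
  row <- ndm_fixture()$evidence
  row <- row[row$variant == variant, ]
  stopifnot(nrow(row) == 1L)
  evidence_record(row$independent_reports, row$conservation_points,
                  row$heteroplasmy, row$segregation_with_disease,
                  row$histochemical_evidence, row$biochemical_defect,
                  row$single_fiber_evidence, row$functional_study_strength)
}

# minimal hand-built gene with one WC pair, one wobble pair and a
# potential pair, for pair-effect edge cases
toy_gene <- function() {
  pm <- data.frame(genomic_pos = 101:110, canonical_pos = 1:10,
                   element = c(rep("acceptor-stem", 2), rep("D-stem", 2),
                               rep("anticodon-loop", 2), rep("T-stem", 2),
                               rep("T-loop", 2)),
                   ref_base = c("A", "G", "C", "N", "A", "N", "T", "C",
                                "N", "N"),
                   stringsAsFactors = FALSE)
  pairs <- data.frame(pos5 = c(1, 2, 4), pos3 = c(7, 8, 9),
                      ref5 = c("A", "G", "G"), ref3 = c("T", "C", "T"),
                      pair_class = c("WC", "WC", "wobble"),
                      element = c("acceptor-stem", "acceptor-stem",
                                  "D-stem"),
                      stringsAsFactors = FALSE)
  pm$ref_base[pm$canonical_pos == 4] <- "G"
  pm$ref_base[pm$canonical_pos == 9] <- "T"
  pot <- data.frame(canonical_pos = 5, partner_pos = 10,
                    partner_base = "C", label = "5A-10G",
                    stringsAsFactors = FALSE)
  trna_gene_model("tRNA-toy", 101, 110, "heavy", pm, pairs, pot)
}

write_temp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
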