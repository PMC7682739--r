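#' Specification for a synthetic multi-species alignment
#'
#' Defines the generative model used for testing the conservation module:
#' a reference row drawn uniformly over A/C/G/T, each non-reference base
#' equal to the reference with its column's conservation probability and
#' otherwise uniform over the three other bases, and gaps inserted
#' independently in non-reference rows. Under this model the expected CI
#' of a column equals 100 times its conservation probability, so the
#' estimator can be checked by parameter recovery.
#'
#' @param n_species Number of rows including the reference; default 15,
#'   the panel size conventional for mt-tRNA conservation analyses
#'   (human compared against 14 other species).
#' @param length Number of alignment columns.
#' @param per_column_conservation Probability in `[0, 1]`; scalar
#'   (recycled) or one value per column.
#' @param gap_rate Per-cell gap probability in non-reference rows.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `alignment_spec`.
#' @export
alignment_spec <- function(n_species = 15, length,
                           per_column_conservation, gap_rate = 0,
                           seed = 1L) {
  if (n_species < 2)
    spec_error("n_species must be at least 2")
  if (length < 1)
    spec_error("length must be at least 1")
  p <- per_column_conservation
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    spec_error("per_column_conservation must lie in [0, 1]")
  if (!length(p) %in% c(1L, length))
    spec_error("per_column_conservation must be scalar or one value per column")
  if (gap_rate < 0 || gap_rate > 1)
    spec_error("gap_rate must lie in [0, 1]")
  structure(list(n_species = as.integer(n_species),
                 length = as.integer(length),
                 per_column_conservation = rep_len(p, length),
                 gap_rate = gap_rate, seed = as.integer(seed)),
            class = "alignment_spec")
}

spec_error <- function(msg)
  stop(errorCondition(msg, class = c("alignment_spec_error", "error")))

BASES <- c("A", "C", "G", "T")

#' Generate a synthetic alignment with controlled conservation
#'
#' @param spec An [alignment_spec].
#' @return A [multi_alignment] with the reference labelled
#'   `"Homo_sapiens"` and the remaining rows `"species_02"`, ...
#' @examples
#' aln <- generate_alignment(alignment_spec(5, 20, 1, seed = 7))
#' compute_ci(aln, 1)$ci_percent    # degenerate spec: always 100
#' @export
generate_alignment <- function(spec) {
  stopifnot(inherits(spec, "alignment_spec"))
  withr::with_seed(spec$seed, {
    L <- spec$length
    n <- spec$n_species
    ref <- sample(BASES, L, replace = TRUE)
    mat <- matrix("", nrow = n, ncol = L)
    mat[1, ] <- ref
    for (i in seq_len(n - 1) + 1L) {
      keep <- stats::runif(L) < spec$per_column_conservation
      row <- ref
      n_mut <- sum(!keep)
      if (n_mut)                    # uniform over the three other bases
        row[!keep] <- vapply(ref[!keep], function(b)
          sample(setdiff(BASES, b), 1L), character(1))
      if (spec$gap_rate > 0) {
        gaps <- stats::runif(L) < spec$gap_rate
        row[gaps] <- "-"
      }
      mat[i, ] <- row
    }
    labels <- c("Homo_sapiens", sprintf("species_%02d", seq_len(n - 1) + 1L))
    multi_alignment(mat, labels, "Homo_sapiens")
  })
}

sample_evidence_fields <- function() {
  list(independent_reports = stats::runif(1) < 0.5,
       conservation_points = sample(0:2, 1L),
       heteroplasmy = stats::runif(1) < 0.5,
       segregation_with_disease = stats::runif(1) < 0.5,
       histochemical_evidence = stats::runif(1) < 0.5,
       biochemical_defect = stats::runif(1) < 0.5,
       single_fiber_evidence = stats::runif(1) < 0.3,
       functional_study_strength = sample(c("none", "weak", "strong"), 1L,
                                          prob = c(0.5, 0.25, 0.25)))
}

#' Generate evidence records with a requested class mix
#'
#' Samples random evidence records and keeps them by rejection against
#' the classifier until the realized class tally matches the request
#' exactly; reproducible from the seed.
#'
#' @param n Number of records.
#' @param class_mix Named vector over the four classes: either integer
#'   counts summing to `n` or proportions summing to 1 (converted to
#'   counts by largest remainder). Omitted classes count 0.
#' @param seed Integer seed.
#' @param rubric A rubric, default [default_rubric].
#' @param path Optional TSV output path.
#' @param max_attempts Attempt budget before giving up on an unreachable
#'   request; default `10000 * n`.
#' @return Data frame of evidence rows with `variant` ids
#'   `synthetic_001`, ..., plus columns `total` and `classification`;
#'   written to `path` (without the two outcome columns) when given.
#' @export
generate_evidence <- function(n, class_mix, seed = 1L,
                              rubric = default_rubric(), path = NULL,
                              max_attempts = 10000 * max(n, 1L)) {
  classes <- c("neutral polymorphism", "possibly pathogenic",
               "probably pathogenic", "definitely pathogenic")
  unknown <- setdiff(names(class_mix), classes)
  if (length(unknown))
    spec_error(paste("unknown classification in class_mix:", unknown[1]))
  counts <- stats::setNames(rep(0L, 4L), classes)
  if (all(class_mix %% 1 == 0) && sum(class_mix) == n) {
    counts[names(class_mix)] <- as.integer(class_mix)
  } else if (isTRUE(all.equal(sum(class_mix), 1))) {
    raw <- class_mix * n                 # largest-remainder apportionment
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    counts[names(class_mix)] <- as.integer(base)
  } else {
    spec_error("class_mix must be counts summing to n or proportions summing to 1")
  }
  header <- c("variant", "independent_reports", "conservation_points",
              "heteroplasmy", "segregation_with_disease",
              "histochemical_evidence", "biochemical_defect",
              "single_fiber_evidence", "functional_study_strength")
  rows <- vector("list", n)
  withr::with_seed(seed, {
    filled <- 0L
    attempts <- 0L
    while (filled < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(errorCondition(
          sprintf("could not realize the requested class mix within %d attempts (still missing: %s)",
                  max_attempts,
                  paste(names(counts)[counts > 0], collapse = ", ")),
          class = c("evidence_generation_error", "error")))
      f <- sample_evidence_fields()
      ev <- do.call(evidence_record, f)
      cls <- score_evidence(ev, rubric)$classification
      if (counts[[cls]] > 0L) {
        counts[[cls]] <- counts[[cls]] - 1L
        filled <- filled + 1L
        rows[[filled]] <- data.frame(
          variant = sprintf("synthetic_%03d", filled),
          independent_reports = f$independent_reports,
          conservation_points = f$conservation_points,
          heteroplasmy = f$heteroplasmy,
          segregation_with_disease = f$segregation_with_disease,
          histochemical_evidence = f$histochemical_evidence,
          biochemical_defect = f$biochemical_defect,
          single_fiber_evidence = f$single_fiber_evidence,
          functional_study_strength = f$functional_study_strength,
          total = score_evidence(ev, rubric)$total,
          classification = cls, stringsAsFactors = FALSE)
      }
    }
  })
  out <- if (n)
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else {
    empty <- data.frame(matrix(ncol = length(header) + 2L, nrow = 0L))
    names(empty) <- c(header, "total", "classification")
    empty
  }
  if (!is.null(path))
    utils::write.table(out[, header, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  out
}

#' The packaged nine-variant study fixture
#'
#' The nine mt-tRNA substitutions reported in a non-dystrophic myotonia
#' screening cohort, with their published structural characterization
#' (canonical position, cloverleaf element, plasmy, conservation index,
#' Watson-Crick pair effect, disease associations), the three fully
#' published evidence columns (A12308G, A15924G, G15928A), and one
#' consistent synthetic evidence decomposition for each of the six
#' variants whose published record gives only the total (4, 4, 2, 4, 4
#' and 2 points). The CI percentages are supplied metadata: the
#' multi-species alignment behind them is not publicly deposited and the
#' package does not recompute them.
#'
#' @return List with elements `variants` (data frame: `variant`,
#'   `plasmy`), `table1` (published structural metadata), `evidence`
#'   (9-row evidence table; column `provenance` distinguishes
#'   `"published"` from `"synthetic"` rows), `expected_totals` and
#'   `expected_classes` (named per variant).
#' @examples
#' fx <- ndm_fixture()
#' nrow(fx$variants)
#' @export
ndm_fixture <- function() {
  table1 <- data.frame(
    variant = c("T4454C", "A5568G", "T5794C", "A10438T", "T10462C",
                "A12308G", "A15907G", "A15924G", "G15928A"),
    gene = c("tRNA-Met", "tRNA-Trp", "tRNA-Cys", "tRNA-Arg", "tRNA-Arg",
             "tRNA-Leu(CUN)", "tRNA-Thr", "tRNA-Thr", "tRNA-Thr"),
    canonical_position = c(58L, 62L, 33L, 37L, 66L, 44L, 22L, 39L, 43L),
    element = c("T-loop", "T-stem", "anticodon-stem", "anticodon-stem",
                "acceptor-stem", "variable-region", "D-stem",
                "anticodon-stem", "anticodon-stem"),
    plasmy = c("homoplasmy", "homoplasmy", "homoplasmy", "heteroplasmy",
               "homoplasmy", "heteroplasmy", "homoplasmy", "heteroplasmy",
               "heteroplasmy"),
    ci_percent = c(59.6, 82.6, 75.0, 100, 21.1, 100, 65.4, 100, 100),
    pair_arrow = c(NA, NA, NA, NA, "A-T\u2193", "A-T\u2191", NA,
                   "T-A\u2193", "C-G\u2193"),
    disease_association = c(
      "hypertension", "hearing loss", "none", "progressive encephalopathy",
      "none",
      "chronic progressive external ophthalmoplegia; stroke; cardiomyopathy; breast cancer risk",
      "none",
      "lethal infantile mitochondrial myopathy; fatal infantile respiratory enzyme deficiency",
      "multiple sclerosis; Parkinson's disease"),
    stringsAsFactors = FALSE)

  ev <- function(variant, rep, cons, het, seg, hist, bio, sf, fun, prov)
    data.frame(variant = variant, independent_reports = rep,
               conservation_points = cons, heteroplasmy = het,
               segregation_with_disease = seg,
               histochemical_evidence = hist, biochemical_defect = bio,
               single_fiber_evidence = sf, functional_study_strength = fun,
               provenance = prov, stringsAsFactors = FALSE)
  evidence <- rbind(
    # published scoring columns
    ev("A12308G", TRUE, 2L, TRUE, TRUE, FALSE, FALSE, TRUE,  "weak",
       "published"),
    ev("A15924G", TRUE, 2L, TRUE, TRUE, FALSE, FALSE, FALSE, "strong",
       "published"),
    ev("G15928A", TRUE, 2L, TRUE, TRUE, FALSE, FALSE, FALSE, "weak",
       "published"),
    # synthetic decompositions matching only the published totals
    ev("T4454C",  TRUE,  0L, FALSE, TRUE,  FALSE, FALSE, FALSE, "none",
       "synthetic"),
    ev("A5568G",  TRUE,  0L, FALSE, TRUE,  FALSE, FALSE, FALSE, "none",
       "synthetic"),
    ev("T5794C",  FALSE, 0L, FALSE, TRUE,  FALSE, FALSE, FALSE, "none",
       "synthetic"),
    ev("A10438T", FALSE, 2L, TRUE,  FALSE, FALSE, FALSE, FALSE, "none",
       "synthetic"),
    ev("T10462C", FALSE, 0L, FALSE, TRUE,  TRUE,  FALSE, FALSE, "none",
       "synthetic"),
    ev("A15907G", FALSE, 0L, FALSE, TRUE,  FALSE, FALSE, FALSE, "none",
       "synthetic"))
  expected_totals <- c(T4454C = 4L, A5568G = 4L, T5794C = 2L, A10438T = 4L,
                       T10462C = 4L, A12308G = 15L, A15907G = 2L,
                       A15924G = 13L, G15928A = 10L)
  expected_classes <- c(
    T4454C = "neutral polymorphism", A5568G = "neutral polymorphism",
    T5794C = "neutral polymorphism", A10438T = "neutral polymorphism",
    T10462C = "neutral polymorphism", A12308G = "definitely pathogenic",
    A15907G = "neutral polymorphism", A15924G = "definitely pathogenic",
    G15928A = "possibly pathogenic")
  list(variants = table1[, c("variant", "plasmy")],
       table1 = table1,
       evidence = evidence,
       expected_totals = expected_totals,
       expected_classes = expected_classes)
}

#' Write the packaged fixture as pipeline input files
#'
#' Emits `variants.tsv`, `evidence.tsv`, `ci.tsv` (supplied CI metadata)
#' and `table1.tsv` (full published structural metadata) into a
#' directory, in the dialects [run_pipeline] consumes.
#'
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- ndm_fixture()
  paths <- c(variants = file.path(dir, "variants.tsv"),
             evidence = file.path(dir, "evidence.tsv"),
             ci = file.path(dir, "ci.tsv"),
             table1 = file.path(dir, "table1.tsv"))
  wt <- function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                          row.names = FALSE,
                                          fileEncoding = "UTF-8")
  wt(fx$variants, paths["variants"])
  wt(fx$evidence[, setdiff(names(fx$evidence), "provenance")],
     paths["evidence"])
  wt(fx$table1[, c("variant", "ci_percent")], paths["ci"])
  wt(fx$table1, paths["table1"])
  invisible(paths)
}
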