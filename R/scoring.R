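#' The default pathogenicity scoring rubric
#'
#' Point weights and class thresholds of the evidence-based scoring system
#' for mt-tRNA variants: six 2-point criteria (more than one independent
#' report, evolutionary conservation of the base pair, variant
#' heteroplasmy, segregation with disease, histochemical evidence,
#' biochemical defect in complex I/III/IV), 5 points for single-fiber
#' segregation evidence, and 2 (weak) or 5 (strong) points for mutant
#' steady-state level / trans-mitochondrial cybrid evidence. Classes:
#' total <= 6 neutral polymorphism; 7-10 possibly pathogenic; >= 11
#' probably pathogenic without functional evidence (reachable only up to
#' the no-functional maximum) or definitely pathogenic with it.
#'
#' `nominal_scale` records the "/20" the rubric is conventionally printed
#' against; note the criterion maxima sum to [rubric_maximum], which is
#' larger (see the methods vignette).
#'
#' @return An object of class `scoring_rubric`.
#' @export
default_rubric <- function() {
  structure(list(
    points = c(independent_reports = 2, conservation_max = 2,
               heteroplasmy = 2, segregation_with_disease = 2,
               histochemical_evidence = 2, biochemical_defect = 2,
               single_fiber_evidence = 5, functional_weak = 2,
               functional_strong = 5),
    neutral_max = 6, possibly_max = 10, probably_max = 13,
    nominal_scale = 20), class = "scoring_rubric")
}

#' Maximum attainable total under a rubric
#'
#' @param rubric A rubric from [default_rubric] (or a modified copy).
#' @param functional Include the functional-evidence criteria (default
#'   `TRUE`); with `FALSE`, the maximum attainable without single-fiber or
#'   steady-state/cybrid evidence.
#' @return Integer total.
#' @export
rubric_maximum <- function(rubric = default_rubric(), functional = TRUE) {
  p <- rubric$points
  base <- sum(p[c("independent_reports", "conservation_max", "heteroplasmy",
                  "segregation_with_disease", "histochemical_evidence",
                  "biochemical_defect")])
  if (!functional) return(unname(base))
  unname(base + p["single_fiber_evidence"] +
           max(p["functional_weak"], p["functional_strong"]))
}

#' Build a validated evidence record for one variant
#'
#' @param independent_reports More than one independent report of the
#'   variant in disease (logical).
#' @param conservation_points Evolutionary conservation of the base/pair,
#'   0, 1 or 2 points (2 = no changes across species).
#' @param heteroplasmy Variant observed heteroplasmic (logical).
#' @param segregation_with_disease Mutation segregates with disease
#'   (logical).
#' @param histochemical_evidence Histochemical evidence of mitochondrial
#'   disease, e.g. ragged-red or COX-negative fibers (logical).
#' @param biochemical_defect Defect in respiratory complex I, III or IV
#'   (logical).
#' @param single_fiber_evidence Mutation load segregates with the
#'   biochemical defect in single muscle fibers (logical).
#' @param functional_study_strength `"none"`, `"weak"` or `"strong"`
#'   steady-state-level / trans-mitochondrial cybrid evidence.
#' @return An object of class `evidence_record`.
#' @export
evidence_record <- function(independent_reports, conservation_points,
                            heteroplasmy, segregation_with_disease,
                            histochemical_evidence, biochemical_defect,
                            single_fiber_evidence,
                            functional_study_strength) {
  flags <- list(independent_reports = independent_reports,
                heteroplasmy = heteroplasmy,
                segregation_with_disease = segregation_with_disease,
                histochemical_evidence = histochemical_evidence,
                biochemical_defect = biochemical_defect,
                single_fiber_evidence = single_fiber_evidence)
  for (nm in names(flags))
    if (!is.logical(flags[[nm]]) || length(flags[[nm]]) != 1L ||
        is.na(flags[[nm]]))
      stop(errorCondition(paste0("field '", nm, "' must be TRUE or FALSE"),
                          class = c("evidence_validation_error", "error")))
  if (!conservation_points %in% c(0, 1, 2))
    stop(errorCondition("conservation_points must be 0, 1 or 2",
                        class = c("evidence_validation_error", "error")))
  functional_study_strength <- match.arg(functional_study_strength,
                                         c("none", "weak", "strong"))
  structure(c(flags,
              list(conservation_points = as.integer(conservation_points),
                   functional_study_strength = functional_study_strength)),
            class = "evidence_record")
}

#' Score an evidence record under the pathogenicity rubric
#'
#' Boolean criteria earn their full weight or 0; conservation contributes
#' its 0/1/2 points directly; functional-study strength maps to 0/weak/
#' strong weights. The total is the plain sum and the class follows
#' [classify_score], with functional evidence defined as single-fiber
#' evidence or a non-`"none"` functional study.
#'
#' @param evidence An [evidence_record].
#' @param rubric A rubric, default [default_rubric].
#' @return An object of class `score_result`: `per_criterion_points`
#'   (named numeric), `total`, `has_functional_evidence`,
#'   `classification`.
#' @examples
#' ev <- evidence_record(TRUE, 2, TRUE, TRUE, FALSE, FALSE, TRUE, "weak")
#' score_evidence(ev)$total
#' @export
score_evidence <- function(evidence, rubric = default_rubric()) {
  stopifnot(inherits(evidence, "evidence_record"))
  p <- rubric$points
  pts <- c(
    independent_reports = if (evidence$independent_reports)
      p[["independent_reports"]] else 0,
    conservation = evidence$conservation_points,
    heteroplasmy = if (evidence$heteroplasmy) p[["heteroplasmy"]] else 0,
    segregation_with_disease = if (evidence$segregation_with_disease)
      p[["segregation_with_disease"]] else 0,
    histochemical_evidence = if (evidence$histochemical_evidence)
      p[["histochemical_evidence"]] else 0,
    biochemical_defect = if (evidence$biochemical_defect)
      p[["biochemical_defect"]] else 0,
    single_fiber_evidence = if (evidence$single_fiber_evidence)
      p[["single_fiber_evidence"]] else 0,
    functional_study = switch(evidence$functional_study_strength,
                              none = 0, weak = p[["functional_weak"]],
                              strong = p[["functional_strong"]]))
  if (evidence$conservation_points > p[["conservation_max"]])
    stop(errorCondition("conservation_points exceed the rubric maximum",
                        class = c("evidence_validation_error", "error")))
  total <- sum(pts)
  has_functional <- evidence$single_fiber_evidence ||
    evidence$functional_study_strength != "none"
  structure(list(per_criterion_points = pts, total = total,
                 has_functional_evidence = has_functional,
                 classification = classify_score(total, has_functional,
                                                 rubric)),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("total %d/%d -> %s (functional evidence: %s)\n",
              x$total, default_rubric()$nominal_scale, x$classification,
              if (x$has_functional_evidence) "yes" else "no"))
  invisible(x)
}

#' Four-class pathogenicity call from a total score
#'
#' Totals at or below 6 are neutral polymorphisms; 7-10 possibly
#' pathogenic; 11 or more are definitely pathogenic when backed by
#' functional evidence (single-fiber, steady-state or cybrid studies) and
#' probably pathogenic otherwise. A total of 14 or more without
#' functional evidence is unreachable under the default rubric and raises
#' an infeasible-evidence error (the guard matters for custom rubrics).
#'
#' @param total Total score.
#' @param has_functional_evidence Logical.
#' @param rubric A rubric, default [default_rubric].
#' @return One of `"neutral polymorphism"`, `"possibly pathogenic"`,
#'   `"probably pathogenic"`, `"definitely pathogenic"`.
#' @export
classify_score <- function(total, has_functional_evidence,
                           rubric = default_rubric()) {
  stopifnot(length(total) == 1L, total >= 0,
            total <= rubric_maximum(rubric))
  if (total <= rubric$neutral_max) return("neutral polymorphism")
  if (total <= rubric$possibly_max) return("possibly pathogenic")
  if (has_functional_evidence) return("definitely pathogenic")
  if (total <= rubric$probably_max) return("probably pathogenic")
  stop(errorCondition(
    sprintf("total %d without functional evidence exceeds the probably-pathogenic band (max %d)",
            total, rubric$probably_max),
    class = c("infeasible_evidence_error", "error")))
}

YESNO <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("yes", "true", "1", "y")
}

#' Read an evidence TSV
#'
#' One row per variant; columns `variant`, `independent_reports`,
#' `conservation_points`, `heteroplasmy`, `segregation_with_disease`,
#' `histochemical_evidence`, `biochemical_defect`,
#' `single_fiber_evidence`, `functional_study_strength`. Boolean columns
#' accept yes/no or TRUE/FALSE.
#'
#' @param path File path.
#' @return Named list of [evidence_record] objects, keyed by variant.
#' @export
read_evidence <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant", "independent_reports", "conservation_points",
            "heteroplasmy", "segregation_with_disease",
            "histochemical_evidence", "biochemical_defect",
            "single_fiber_evidence", "functional_study_strength")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(errorCondition(paste("evidence table lacks columns:",
                              paste(miss, collapse = ", ")),
                        class = c("evidence_validation_error", "error")))
  recs <- lapply(seq_len(nrow(tab)), function(i)
    evidence_record(YESNO(tab$independent_reports[i]),
                    tab$conservation_points[i],
                    YESNO(tab$heteroplasmy[i]),
                    YESNO(tab$segregation_with_disease[i]),
                    YESNO(tab$histochemical_evidence[i]),
                    YESNO(tab$biochemical_defect[i]),
                    YESNO(tab$single_fiber_evidence[i]),
                    tab$functional_study_strength[i]))
  names(recs) <- tab$variant
  recs
}

#' Conservation points implied by a CI value
#'
#' Used when `auto_conservation` is on: full 2 points for complete
#' conservation (CI = 100), 1 point above the functional-potential
#' threshold, 0 otherwise.
#'
#' @param ci_percent CI in percent.
#' @param threshold Functional-potential threshold, default 75.
#' @return 0, 1 or 2.
#' @export
conservation_points_from_ci <- function(ci_percent, threshold = 75) {
  stopifnot(ci_percent >= 0, ci_percent <= 100)
  if (ci_percent == 100) 2L
  else if (ci_percent > threshold) 1L
  else 0L
}
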