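#' Pipeline configuration
#'
#' Bundles and validates the inputs of an end-to-end run: the variant
#' table, the per-variant evidence table, the structure catalogue, and
#' either a directory of per-gene alignments (to compute CI and
#' auto-derive conservation points) or a table of supplied CI values.
#'
#' @param variants Path to the variant TSV (columns `variant`, `plasmy`,
#'   or one variant per line).
#' @param evidence Path to the evidence TSV (see [read_evidence]).
#' @param out_dir Output directory for the report TSVs.
#' @param catalogue A [trna_catalogue]; defaults to the packaged one.
#' @param alignments_dir Optional directory with per-gene aligned FASTA
#'   files named `<gene>.fasta` (e.g. `tRNA-Thr.fasta`).
#' @param ci_path Optional TSV with columns `variant`, `ci_percent`
#'   carrying externally supplied CI values.
#' @param auto_conservation When `TRUE`, conservation points are derived
#'   from the computed CI instead of the evidence file; requires
#'   `alignments_dir`.
#' @param ci_denominator `"nongap"` or `"all"` (see [compute_ci]).
#' @param conservation_threshold Functional-potential threshold in
#'   percent, strictly inside (0, 100); default 75.
#' @param check_ref Passed to [annotate_variant].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(variants, evidence, out_dir,
                            catalogue = NULL, alignments_dir = NULL,
                            ci_path = NULL, auto_conservation = FALSE,
                            ci_denominator = c("nongap", "all"),
                            conservation_threshold = 75,
                            check_ref = TRUE) {
  ci_denominator <- match.arg(ci_denominator)
  for (p in c(variants, evidence, alignments_dir, ci_path))
    if (!file.exists(p))
      stop(errorCondition(paste("input path does not exist:", p),
                          class = c("pipeline_config_error", "error")))
  if (conservation_threshold <= 0 || conservation_threshold >= 100)
    stop(errorCondition("conservation_threshold must lie in (0, 100)",
                        class = c("pipeline_config_error", "error")))
  if (auto_conservation && is.null(alignments_dir))
    stop(errorCondition(
      "auto_conservation requires an alignments directory",
      class = c("pipeline_config_error", "error")))
  if (is.null(catalogue)) catalogue <- mt_trna_catalogue()
  structure(list(variants = variants, evidence = evidence,
                 out_dir = out_dir, catalogue = catalogue,
                 alignments_dir = alignments_dir, ci_path = ci_path,
                 auto_conservation = auto_conservation,
                 ci_denominator = ci_denominator,
                 conservation_threshold = conservation_threshold,
                 check_ref = check_ref),
            class = "pipeline_config")
}

fail_row <- function(variant, stage, message)
  data.frame(variant = variant, stage = stage, message = message,
             stringsAsFactors = FALSE)

#' Run the full variant-interpretation pipeline
#'
#' For each input variant: structural annotation (gene, canonical
#' position, element, Watson-Crick pair effect), conservation index
#' (computed from an alignment or carried over from supplied values),
#' evidence scoring and four-class pathogenicity call. A failure in any
#' stage is recorded against the variant and the run continues; the
#' report and per-criterion breakdown TSVs are written to the configured
#' output directory.
#'
#' @param config A [pipeline_config].
#' @param quiet Suppress the run log (default `FALSE`).
#' @return List with `report` (one row per successfully processed
#'   variant), `breakdown` (per-criterion points), `failures` (variant,
#'   stage, message), `class_tally`, and the written `paths`. Rerunning
#'   on unchanged inputs reproduces the output files byte for byte.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  variants <- read_variants(config$variants)
  evidence <- read_evidence(config$evidence)
  supplied_ci <- NULL
  if (!is.null(config$ci_path)) {
    tab <- utils::read.delim(config$ci_path, stringsAsFactors = FALSE)
    supplied_ci <- stats::setNames(tab$ci_percent, tab$variant)
  }
  say("read %d variants, %d evidence rows", length(variants),
      length(evidence))
  if (!length(variants))
    warning("variant file contains no variants; writing empty report")

  alignments <- list()   # per-gene cache
  report <- list(); breakdown <- list(); failures <- list()
  for (v in variants) {
    id <- format(v)
    ann <- tryCatch(annotate_variant(v, config$catalogue,
                                     check_ref = config$check_ref),
                    error = function(e) e)
    if (inherits(ann, "error")) {
      failures[[length(failures) + 1L]] <-
        fail_row(id, "annotate", conditionMessage(ann))
      next
    }
    ci <- NA_real_; ci_source <- "none"
    if (config$auto_conservation) {
      res <- tryCatch({
        gene <- config$catalogue[[ann$gene_name]]
        if (is.null(alignments[[ann$gene_name]])) {
          path <- file.path(config$alignments_dir,
                            paste0(ann$gene_name, ".fasta"))
          alignments[[ann$gene_name]] <- read_alignment(path)
        }
        idx <- match(v$genomic_position, gene$position_map$genomic_pos)
        compute_ci(alignments[[ann$gene_name]], idx,
                   config$ci_denominator, config$conservation_threshold)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          fail_row(id, "conservation", conditionMessage(res))
        next
      }
      ci <- res$ci_percent; ci_source <- "computed"
    } else if (!is.null(supplied_ci) && id %in% names(supplied_ci)) {
      ci <- unname(supplied_ci[id]); ci_source <- "supplied"
    }
    ev <- evidence[[id]]
    if (is.null(ev)) {
      failures[[length(failures) + 1L]] <-
        fail_row(id, "score", "no evidence row for variant")
      next
    }
    if (config$auto_conservation && !is.na(ci))
      ev$conservation_points <-
        conservation_points_from_ci(ci, config$conservation_threshold)
    sc <- tryCatch(score_evidence(ev), error = function(e) e)
    if (inherits(sc, "error")) {
      failures[[length(failures) + 1L]] <-
        fail_row(id, "score", conditionMessage(sc))
      next
    }
    report[[length(report) + 1L]] <- data.frame(
      gene = ann$gene_name, mutation = id,
      canonical_position = ann$canonical_position, element = ann$element,
      plasmy = v$plasmy, ci_percent = ci, ci_source = ci_source,
      pair_effect = ann$pair_effect,
      pair_descriptor = ann$pair_descriptor, pair_arrow = ann$pair_arrow,
      score_total = sc$total, classification = sc$classification,
      stringsAsFactors = FALSE)
    breakdown[[length(breakdown) + 1L]] <- data.frame(
      mutation = id, criterion = names(sc$per_criterion_points),
      points = unname(sc$per_criterion_points), stringsAsFactors = FALSE)
  }
  empty_report <- data.frame(
    gene = character(), mutation = character(),
    canonical_position = integer(), element = character(),
    plasmy = character(), ci_percent = numeric(), ci_source = character(),
    pair_effect = character(), pair_descriptor = character(),
    pair_arrow = character(), score_total = integer(),
    classification = character(), stringsAsFactors = FALSE)
  report <- if (length(report))
    do.call(rbind, c(report, list(make.row.names = FALSE))) else empty_report
  breakdown <- if (length(breakdown))
    do.call(rbind, c(breakdown, list(make.row.names = FALSE)))
  else data.frame(mutation = character(), criterion = character(),
                  points = numeric(), stringsAsFactors = FALSE)
  failures <- if (length(failures))
    do.call(rbind, c(failures, list(make.row.names = FALSE)))
  else fail_row(character(), character(), character())

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(report = file.path(config$out_dir, "variant_report.tsv"),
             breakdown = file.path(config$out_dir, "score_breakdown.tsv"))
  utils::write.table(report, paths["report"], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(breakdown, paths["breakdown"], sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  tally <- classification_tally(report)
  say("annotated and scored %d/%d variants (%d failed)", nrow(report),
      length(variants), nrow(failures))
  if (nrow(report))
    say("class tally: %s",
        paste(names(tally), tally, sep = " = ", collapse = ", "))
  for (i in seq_len(nrow(failures)))
    say("FAILED %s at stage %s: %s", failures$variant[i],
        failures$stage[i], failures$message[i])
  list(report = report, breakdown = breakdown, failures = failures,
       class_tally = tally, paths = paths)
}

#' Tally pathogenicity classes in a report
#'
#' @param report The `report` data frame from [run_pipeline].
#' @return Named integer vector over the classes present.
#' @export
classification_tally <- function(report) {
  tab <- table(report$classification)
  stats::setNames(as.integer(tab), names(tab))
}
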