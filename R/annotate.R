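#' Parse an mtDNA substitution written in compact or HGVS-like notation
#'
#' Accepts the compact form used in the mitochondrial literature
#' (`"T4454C"`) and the HGVS-like spelling (`"m.4454T>C"`). Only single
#' nucleotide substitutions are supported.
#'
#' @param text Variant string.
#' @param plasmy `"homoplasmy"`, `"heteroplasmy"` or `"unknown"` (default).
#' @return An object of class `mt_variant` with fields `genomic_position`,
#'   `ref_base`, `alt_base`, `plasmy` (bases on the rCRS heavy strand).
#' @examples
#' parse_mt_variant("T4454C")
#' parse_mt_variant("m.12308A>G", plasmy = "heteroplasmy")
#' @export
parse_mt_variant <- function(text, plasmy = "unknown") {
  stopifnot(length(text) == 1L, is.character(text))
  plasmy <- match.arg(plasmy, c("unknown", "homoplasmy", "heteroplasmy"))
  text <- trimws(text)
  m <- regmatches(text, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", text))[[1]]
  if (!length(m))
    m <- regmatches(text,
                    regexec("^m\\.([0-9]+)([A-Za-z])>([A-Za-z])$", text))[[1]]
  else
    m <- m[c(1, 3, 2, 4)]               # reorder to (all, pos, ref, alt)
  if (!length(m))
    stop(errorCondition(
      sprintf("cannot parse variant '%s' (expected e.g. T4454C or m.4454T>C)",
              text),
      class = c("variant_parse_error", "error")))
  pos <- as.integer(m[2])
  ref <- toupper(m[3]); alt <- toupper(m[4])
  if (!ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T"))
    stop(errorCondition(
      sprintf("variant '%s' contains a non-nucleotide base", text),
      class = c("variant_parse_error", "error")))
  if (ref == alt)
    stop(errorCondition(
      sprintf("variant '%s' has identical reference and alternate base", text),
      class = c("variant_parse_error", "error")))
  structure(list(genomic_position = pos, ref_base = ref, alt_base = alt,
                 plasmy = plasmy),
            class = "mt_variant")
}

#' @export
print.mt_variant <- function(x, ...) {
  cat(sprintf("m.%d%s>%s (%s)\n", x$genomic_position, x$ref_base,
              x$alt_base, x$plasmy))
  invisible(x)
}

#' @export
format.mt_variant <- function(x, ...)
  paste0(x$ref_base, x$genomic_position, x$alt_base)

#' Read a variant table
#'
#' Accepts either a TSV with columns `variant` and `plasmy`, or a bare
#' one-variant-per-line file.
#'
#' @param path File path.
#' @return List of `mt_variant` objects.
#' @export
read_variants <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) && grepl("^variant($|\t)", first)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!nrow(tab)) return(list())
    plasmy <- if ("plasmy" %in% names(tab)) tab$plasmy else "unknown"
    Map(parse_mt_variant, tab$variant, plasmy, USE.NAMES = FALSE)
  } else {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines)]
    lapply(lines, parse_mt_variant)
  }
}

#' Call the Watson-Crick pair effect of a substitution
#'
#' A substitution at a paired position whose reference pair is classic
#' Watson-Crick is `"disrupted"` when the alternate base no longer
#' WC-pairs the partner (turning a WC pair into a G-T wobble also counts
#' as disrupted). A position with a declared potential partner is
#' `"created"` when the alternate base WC-pairs the declared completing
#' base while the reference base does not. Everything else is `"none"`.
#'
#' @param gene A [trna_gene_model].
#' @param canonical_position Canonical position of the substitution.
#' @param ref_trna_base,alt_trna_base Bases in tRNA orientation
#'   (strand-corrected).
#' @return List with `pair_effect` (`"none"`, `"disrupted"`, `"created"`)
#'   and `pair_descriptor` (e.g. `"7A-66T"`, `NA` when effect is none).
#' @export
classify_pair_effect <- function(gene, canonical_position,
                                 ref_trna_base, alt_trna_base) {
  pair <- trna_pair_partner(gene, canonical_position)
  if (!is.null(pair)) {
    at5 <- pair$pos5 == canonical_position
    partner_base <- if (at5) pair$ref3 else pair$ref5
    self_base <- if (at5) pair$ref5 else pair$ref3
    descriptor <- paste0(pair$pos5, pair$ref5, "-", pair$pos3, pair$ref3)
    if (!is.na(self_base) && self_base != "N" && self_base != ref_trna_base)
      warning(sprintf("reference base %s at %s position %s differs from catalogue %s",
                      ref_trna_base, gene$gene_name, canonical_position,
                      self_base))
    if (pair$pair_class == "WC" &&
        is_wc(ref_trna_base, partner_base) &&
        !is_wc(alt_trna_base, partner_base))
      return(list(pair_effect = "disrupted", pair_descriptor = descriptor))
  }
  pp <- gene$potential_pairs
  hit <- pp[pp$canonical_pos == canonical_position, , drop = FALSE]
  if (nrow(hit)) {
    hit <- hit[1, ]
    if (!is_wc(ref_trna_base, hit$partner_base) &&
        is_wc(alt_trna_base, hit$partner_base))
      return(list(pair_effect = "created", pair_descriptor = hit$label))
  }
  list(pair_effect = "none", pair_descriptor = NA_character_)
}

pair_arrow <- function(pair_effect, pair_descriptor) {
  if (pair_effect == "none" || is.na(pair_descriptor)) return(NA_character_)
  bases <- regmatches(pair_descriptor,
                      gregexpr("[ACGT](?=-|$)", pair_descriptor,
                               perl = TRUE))[[1]]
  arrow <- if (pair_effect == "created") "\u2191" else "\u2193"
  paste0(bases[1], "-", bases[2], arrow)
}

#' Structurally annotate an mt-tRNA variant
#'
#' Locates the containing gene, maps the coordinate to its canonical
#' cloverleaf position and element, checks the reference base against the
#' catalogue (strand-corrected; skipped where the catalogue base is
#' uncurated), and calls the Watson-Crick pair effect.
#'
#' @param variant An `mt_variant` (see [parse_mt_variant]) or a variant
#'   string, parsed on the fly.
#' @param catalogue A [trna_catalogue].
#' @param check_ref Verify the variant's reference base against the
#'   catalogue (default `TRUE`); disable only to chase suspected
#'   coordinate errors.
#' @return An object of class `variant_annotation`: fields `variant`,
#'   `gene_name`, `canonical_position`, `element`, `pair_effect`,
#'   `pair_descriptor`, `pair_arrow`.
#' @examples
#' cat22 <- mt_trna_catalogue()
#' annotate_variant("T10462C", cat22)
#' @export
annotate_variant <- function(variant, catalogue, check_ref = TRUE) {
  if (is.character(variant)) variant <- parse_mt_variant(variant)
  stopifnot(inherits(variant, "mt_variant"))
  gene <- locate_trna_gene(catalogue, variant$genomic_position)
  if (is.null(gene))
    stop(errorCondition(
      sprintf("position %d falls in no mt-tRNA gene: not a tRNA variant",
              variant$genomic_position),
      class = c("not_trna_variant_error", "error")))
  mp <- map_trna_position(gene, variant$genomic_position)
  ref_trna <- variant$ref_base
  alt_trna <- variant$alt_base
  if (gene$strand == "light") {
    ref_trna <- unname(COMPLEMENT[ref_trna])
    alt_trna <- unname(COMPLEMENT[alt_trna])
  }
  cat_base <- gene$position_map$ref_base[
    match(variant$genomic_position, gene$position_map$genomic_pos)]
  if (check_ref && !is.na(cat_base) && cat_base != "N" && cat_base != ref_trna)
    stop(errorCondition(
      sprintf("reference mismatch at m.%d in %s: expected %s (tRNA orientation), got %s",
              variant$genomic_position, gene$gene_name, cat_base, ref_trna),
      class = c("reference_mismatch_error", "error")))
  pe <- classify_pair_effect(gene, mp$canonical_position, ref_trna, alt_trna)
  structure(list(variant = variant,
                 gene_name = gene$gene_name,
                 canonical_position = mp$canonical_position,
                 element = mp$element,
                 pair_effect = pe$pair_effect,
                 pair_descriptor = pe$pair_descriptor,
                 pair_arrow = pair_arrow(pe$pair_effect, pe$pair_descriptor)),
            class = "variant_annotation")
}

#' @export
print.variant_annotation <- function(x, ...) {
  cat(sprintf("%s  %s position %s (%s)  pair effect: %s%s\n",
              format(x$variant), x$gene_name, x$canonical_position,
              x$element, x$pair_effect,
              if (!is.na(x$pair_descriptor))
                paste0(" [", x$pair_descriptor, "]") else ""))
  invisible(x)
}

#' Annotate several variants into a data frame
#'
#' @param variants List of `mt_variant` objects or character vector of
#'   variant strings.
#' @inheritParams annotate_variant
#' @return Data frame with one row per variant: `variant`, `gene`,
#'   `canonical_position`, `element`, `plasmy`, `pair_effect`,
#'   `pair_descriptor`, `pair_arrow`.
#' @export
annotate_variants <- function(variants, catalogue, check_ref = TRUE) {
  if (is.character(variants)) variants <- lapply(variants, parse_mt_variant)
  rows <- lapply(variants, function(v) {
    a <- annotate_variant(v, catalogue, check_ref = check_ref)
    data.frame(variant = format(a$variant), gene = a$gene_name,
               canonical_position = a$canonical_position,
               element = a$element, plasmy = a$variant$plasmy,
               pair_effect = a$pair_effect,
               pair_descriptor = a$pair_descriptor,
               pair_arrow = a$pair_arrow, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(variant = character(), gene = character(),
                      canonical_position = integer(), element = character(),
                      plasmy = character(), pair_effect = character(),
                      pair_descriptor = character(),
                      pair_arrow = character(), stringsAsFactors = FALSE)
  out
}
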