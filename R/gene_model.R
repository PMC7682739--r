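#' @keywords internal
"_PACKAGE"

#' Structural-element vocabulary of the tRNA cloverleaf
#'
#' The closed set of element labels used throughout the package: the four
#' stems, the three loops, the variable region and the discriminator base.
#'
#' @format Character vector of length 9.
#' @export
TRNA_ELEMENTS <- c("acceptor-stem", "D-stem", "D-loop",
                   "anticodon-stem", "anticodon-loop", "variable-region",
                   "T-stem", "T-loop", "discriminator")

catalogue_error <- function(msg, gene = NULL, coordinate = NULL) {
  detail <- c(if (!is.null(gene)) paste0("gene ", gene),
              if (!is.null(coordinate)) paste0("coordinate ", coordinate))
  if (length(detail)) msg <- paste0(msg, " [", paste(detail, collapse = ", "), "]")
  stop(errorCondition(msg, class = c("catalogue_validation_error", "error")))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

is_wc <- function(a, b) {
  !is.na(a) & !is.na(b) & a %in% c("A", "C", "G", "T") &
    b == unname(COMPLEMENT[a])
}

is_wobble <- function(a, b) (a == "G" & b == "T") | (a == "T" & b == "G")

#' Construct a single mt-tRNA gene model
#'
#' Validates and assembles one gene's structural model: its rCRS span and
#' strand, the map from genomic coordinate to canonical (Sprinzl-style)
#' tRNA position and cloverleaf element, the Watson-Crick/wobble base-pair
#' inventory, and any declared potential pairs (pairs a substitution can
#' newly create).
#'
#' @param gene_name Gene label, e.g. `"tRNA-Met"` or `"tRNA-Leu(CUN)"`.
#' @param genomic_start,genomic_end 1-based inclusive rCRS coordinates.
#' @param strand `"heavy"` or `"light"`. For light-strand genes the tRNA
#'   runs 3'->5' along the rCRS and reference bases are stored in tRNA
#'   orientation (reverse complement of the rCRS base).
#' @param position_map Data frame with columns `genomic_pos`,
#'   `canonical_pos`, `element`, `ref_base` (tRNA orientation; `"N"` where
#'   uncurated). Rows must be in tRNA 5'->3' order.
#' @param pairs Data frame with columns `pos5`, `pos3`, `ref5`, `ref3`,
#'   `pair_class` (`"WC"` or `"wobble"`), `element`; may have zero rows.
#' @param potential_pairs Data frame with columns `canonical_pos`,
#'   `partner_pos`, `partner_base`, `label`; may have zero rows. The
#'   `partner_base` is the base a mutant must Watson-Crick pair with for a
#'   `"created"` call; `label` is reported verbatim.
#' @param numbering `"curated"` for genes with true canonical numbering,
#'   `"offset"` where canonical positions are plain 5' offsets.
#'
#' @return An object of class `trna_gene_model`.
#' @export
trna_gene_model <- function(gene_name, genomic_start, genomic_end, strand,
                            position_map,
                            pairs = empty_pairs(),
                            potential_pairs = empty_potential_pairs(),
                            numbering = "curated") {
  if (genomic_start > genomic_end)
    catalogue_error("genomic_start exceeds genomic_end", gene_name)
  if (!strand %in% c("heavy", "light"))
    catalogue_error(paste0("unknown strand '", strand, "'"), gene_name)
  pm <- as.data.frame(position_map)
  if (anyDuplicated(pm$genomic_pos))
    catalogue_error("duplicate genomic coordinate in position map", gene_name,
                    pm$genomic_pos[duplicated(pm$genomic_pos)][1])
  if (anyDuplicated(pm$canonical_pos))
    catalogue_error("duplicate canonical position", gene_name,
                    pm$canonical_pos[duplicated(pm$canonical_pos)][1])
  outside <- pm$genomic_pos < genomic_start | pm$genomic_pos > genomic_end
  if (any(outside))
    catalogue_error("position map coordinate outside gene span", gene_name,
                    pm$genomic_pos[outside][1])
  bad_el <- !pm$element %in% TRNA_ELEMENTS
  if (any(bad_el))
    catalogue_error(paste0("unknown structural element '",
                           pm$element[bad_el][1], "'"),
                    gene_name, pm$genomic_pos[bad_el][1])
  pr <- as.data.frame(pairs)
  for (k in seq_len(nrow(pr))) {
    if (pr$pos5[k] >= pr$pos3[k])
      catalogue_error("pair pos5 not below pos3", gene_name, pr$pos5[k])
    for (p in c(pr$pos5[k], pr$pos3[k]))
      if (!p %in% pm$canonical_pos)
        catalogue_error("pair endpoint not in position map", gene_name, p)
    ok <- switch(pr$pair_class[k],
                 WC = is_wc(pr$ref5[k], pr$ref3[k]),
                 wobble = is_wobble(pr$ref5[k], pr$ref3[k]),
                 catalogue_error(paste0("unknown pair class '",
                                        pr$pair_class[k], "'"), gene_name))
    if (!ok)
      catalogue_error(sprintf("bases %s-%s violate declared %s pair class",
                              pr$ref5[k], pr$ref3[k], pr$pair_class[k]),
                      gene_name, pr$pos5[k])
  }
  pp <- as.data.frame(potential_pairs)
  for (k in seq_len(nrow(pp)))
    if (!pp$canonical_pos[k] %in% pm$canonical_pos)
      catalogue_error("potential-pair position not in position map",
                      gene_name, pp$canonical_pos[k])
  structure(list(gene_name = gene_name,
                 genomic_start = as.integer(genomic_start),
                 genomic_end = as.integer(genomic_end),
                 strand = strand, numbering = numbering,
                 position_map = pm, pairs = pr, potential_pairs = pp),
            class = "trna_gene_model")
}

empty_pairs <- function() {
  data.frame(pos5 = integer(), pos3 = integer(), ref5 = character(),
             ref3 = character(), pair_class = character(),
             element = character(), stringsAsFactors = FALSE)
}

empty_potential_pairs <- function() {
  data.frame(canonical_pos = integer(), partner_pos = integer(),
             partner_base = character(), label = character(),
             stringsAsFactors = FALSE)
}

# generic element template for genes carrying 5'-offset numbering: the
# fixed cloverleaf core (59 nt) plus length-dependent D-loop / variable
# region expansion. Elements for these genes are approximate by design.
offset_position_map <- function(start, end, strand) {
  len <- end - start + 1L
  extra <- max(0L, len - 59L)
  d_extra <- min(extra, 8L)
  v_extra <- extra - d_extra
  elements <- c(rep("acceptor-stem", 7), rep("D-loop", 2), rep("D-stem", 4),
                rep("D-loop", 4 + d_extra), rep("D-stem", 4),
                rep("anticodon-stem", 5), rep("anticodon-loop", 7),
                rep("anticodon-stem", 5), rep("variable-region", 5 + v_extra),
                rep("T-stem", 5), rep("T-loop", 7), rep("T-stem", 5),
                rep("acceptor-stem", 7), "discriminator")
  elements <- elements[seq_len(len)]   # guards genes shorter than the core
  genomic <- if (strand == "heavy") start + seq_len(len) - 1L
             else end - seq_len(len) + 1L
  data.frame(genomic_pos = genomic, canonical_pos = seq_len(len),
             element = elements, ref_base = "N", stringsAsFactors = FALSE)
}

#' Load the packaged mt-tRNA structure catalogue
#'
#' Reads and validates the catalogue of the 22 human mt-tRNA genes: rCRS
#' spans and strands for all genes, and full curated canonical-position /
#' element / base-pair detail for the genes whose structural calls the
#' packaged fixture exercises (flagged `numbering = "curated"` in the genes
#' table). Genes flagged `"offset"` receive a 5'-offset position map with a
#' generic element template.
#'
#' @param genes_path,positions_path Paths to the two catalogue TSVs;
#'   default to the files shipped under `extdata/`.
#' @return An object of class `trna_catalogue`: a named list of
#'   [trna_gene_model] objects.
#' @examples
#' cat22 <- mt_trna_catalogue()
#' length(cat22)
#' @export
mt_trna_catalogue <- function(genes_path = NULL, positions_path = NULL) {
  if (is.null(genes_path))
    genes_path <- system.file("extdata", "trna_genes.tsv",
                              package = "mttrnascore", mustWork = TRUE)
  if (is.null(positions_path))
    positions_path <- system.file("extdata", "trna_positions.tsv",
                                  package = "mttrnascore", mustWork = TRUE)
  genes <- utils::read.delim(genes_path, stringsAsFactors = FALSE)
  need <- c("gene", "start", "end", "strand", "numbering")
  if (!all(need %in% names(genes)))
    catalogue_error(paste("genes table lacks columns:",
                          paste(setdiff(need, names(genes)), collapse = ", ")))
  if (nrow(genes) != 22L)
    catalogue_error(sprintf("expected 22 mt-tRNA genes, found %d", nrow(genes)))
  pos <- utils::read.delim(positions_path, stringsAsFactors = FALSE,
                           colClasses = c(potential_partner_base = "character",
                                          potential_pair_label = "character",
                                          ref_base = "character"))
  missing_gene <- setdiff(unique(pos$gene), genes$gene)
  if (length(missing_gene))
    catalogue_error("position rows reference unknown gene", missing_gene[1])
  models <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (g$numbering == "offset") {
      pm <- offset_position_map(g$start, g$end, g$strand)
      return(trna_gene_model(g$gene, g$start, g$end, g$strand, pm,
                             numbering = "offset"))
    }
    rows <- pos[pos$gene == g$gene, , drop = FALSE]
    if (!nrow(rows))
      catalogue_error("curated gene has no position rows", g$gene)
    pm <- rows[, c("genomic_pos", "canonical_pos", "element", "ref_base")]
    rownames(pm) <- NULL
    pr <- empty_pairs()
    declared <- rows[!is.na(rows$pair_partner), , drop = FALSE]
    for (k in seq_len(nrow(declared))) {
      r <- declared[k, ]
      mate <- rows[rows$canonical_pos == r$pair_partner, , drop = FALSE]
      if (nrow(mate) != 1L)
        catalogue_error("pair partner not in position map", g$gene,
                        r$pair_partner)
      if (is.na(mate$pair_partner) || mate$pair_partner != r$canonical_pos)
        catalogue_error("pair declaration not symmetric", g$gene,
                        r$canonical_pos)
      if (r$canonical_pos < r$pair_partner)
        pr <- rbind(pr, data.frame(
          pos5 = r$canonical_pos, pos3 = r$pair_partner,
          ref5 = r$ref_base, ref3 = mate$ref_base,
          pair_class = r$pair_class, element = r$element,
          stringsAsFactors = FALSE))
    }
    pp <- rows[!is.na(rows$potential_partner),
               c("canonical_pos", "potential_partner",
                 "potential_partner_base", "potential_pair_label")]
    names(pp) <- c("canonical_pos", "partner_pos", "partner_base", "label")
    rownames(pp) <- NULL
    trna_gene_model(g$gene, g$start, g$end, g$strand, pm, pr, pp,
                    numbering = "curated")
  })
  names(models) <- genes$gene
  structure(models, class = "trna_catalogue")
}

#' @export
print.trna_catalogue <- function(x, ...) {
  cat("mt-tRNA structure catalogue:", length(x), "genes,",
      sum(vapply(x, function(g) g$numbering == "curated", logical(1))),
      "with curated canonical numbering\n")
  invisible(x)
}

#' @export
print.trna_gene_model <- function(x, ...) {
  cat(sprintf("%s  rCRS %d-%d (%s strand), %d positions, %d base pairs\n",
              x$gene_name, x$genomic_start, x$genomic_end, x$strand,
              nrow(x$position_map), nrow(x$pairs)))
  invisible(x)
}

#' Find the mt-tRNA gene containing an rCRS coordinate
#'
#' @param catalogue A [trna_catalogue].
#' @param genomic_position 1-based rCRS coordinate.
#' @return The containing [trna_gene_model], or `NULL` when the coordinate
#'   falls in no mt-tRNA gene (not an error: most of the genome does).
#' @examples
#' cat22 <- mt_trna_catalogue()
#' locate_trna_gene(cat22, 4454)$gene_name
#' @export
locate_trna_gene <- function(catalogue, genomic_position) {
  stopifnot(length(genomic_position) == 1L, genomic_position >= 1)
  for (g in catalogue)
    if (genomic_position >= g$genomic_start && genomic_position <= g$genomic_end)
      return(g)
  NULL
}

#' Map an rCRS coordinate to canonical tRNA position and element
#'
#' @param gene A [trna_gene_model].
#' @param genomic_position rCRS coordinate inside the gene's span.
#' @return List with `canonical_position` and `element`.
#' @export
map_trna_position <- function(gene, genomic_position) {
  i <- match(genomic_position, gene$position_map$genomic_pos)
  if (is.na(i))
    stop(errorCondition(
      sprintf("coordinate %d is not mapped in %s (span %d-%d)",
              genomic_position, gene$gene_name,
              gene$genomic_start, gene$genomic_end),
      class = c("position_out_of_range_error", "error")))
  list(canonical_position = gene$position_map$canonical_pos[i],
       element = gene$position_map$element[i])
}

#' Invert the canonical-position map
#'
#' @param gene A [trna_gene_model].
#' @param canonical_position Canonical tRNA position present in the gene.
#' @return The rCRS coordinate carrying that canonical position.
#' @export
canonical_to_genomic <- function(gene, canonical_position) {
  i <- match(canonical_position, gene$position_map$canonical_pos)
  if (is.na(i))
    stop(errorCondition(
      sprintf("canonical position %s does not exist in %s",
              canonical_position, gene$gene_name),
      class = c("position_out_of_range_error", "error")))
  gene$position_map$genomic_pos[i]
}

#' Base-pair partner of a canonical position
#'
#' @param gene A [trna_gene_model].
#' @param canonical_position Canonical position present in the gene.
#' @return One row of the pair inventory (columns `pos5`, `pos3`, `ref5`,
#'   `ref3`, `pair_class`, `element`) containing the position, or `NULL`
#'   for unpaired (loop) positions.
#' @export
trna_pair_partner <- function(gene, canonical_position) {
  if (!canonical_position %in% gene$position_map$canonical_pos)
    stop(errorCondition(
      sprintf("canonical position %s does not exist in %s",
              canonical_position, gene$gene_name),
      class = c("position_out_of_range_error", "error")))
  hit <- gene$pairs[gene$pairs$pos5 == canonical_position |
                    gene$pairs$pos3 == canonical_position, , drop = FALSE]
  if (!nrow(hit)) return(NULL)
  rownames(hit) <- NULL
  hit[1, ]
}
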