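cat22 <- mt_trna_catalogue()
fx <- ndm_fixture()

test_that("both accepted variant spellings parse to the same substitution", {
  v1 <- parse_mt_variant("T4454C")
  expect_equal(v1$genomic_position, 4454)
  expect_equal(c(v1$ref_base, v1$alt_base), c("T", "C"))
  expect_equal(v1$plasmy, "unknown")
  v2 <- parse_mt_variant("m.12308A>G", plasmy = "heteroplasmy")
  expect_equal(v2$genomic_position, 12308)
  expect_equal(c(v2$ref_base, v2$alt_base), c("A", "G"))
  expect_equal(parse_mt_variant("m.4454T>C")[c("genomic_position",
                                               "ref_base", "alt_base")],
               v1[c("genomic_position", "ref_base", "alt_base")])
})

test_that("malformed variant strings are rejected with parse errors", {
  expect_error(parse_mt_variant("T4454T"), class = "variant_parse_error")
  expect_error(parse_mt_variant("X4454C"), class = "variant_parse_error")
  expect_error(parse_mt_variant("4454TC"), class = "variant_parse_error")
  expect_error(parse_mt_variant("m.4454T-C"), class = "variant_parse_error")
})

test_that("the nine study variants annotate exactly as published", {
  ann <- annotate_variants(
    Map(parse_mt_variant, fx$variants$variant, fx$variants$plasmy),
    cat22)
  expect_equal(nrow(ann), 9L)
  expect_equal(ann$gene, fx$table1$gene)
  expect_equal(ann$canonical_position, fx$table1$canonical_position)
  expect_equal(ann$element, fx$table1$element)
  expect_equal(ann$plasmy, fx$table1$plasmy)
  expect_equal(ann$pair_arrow, fx$table1$pair_arrow)
  # four of nine touch a Watson-Crick pairing: one created, three disrupted
  expect_equal(sum(ann$pair_effect != "none"), 4L)
  expect_equal(sum(ann$pair_effect == "created"), 1L)
  expect_equal(sum(ann$pair_effect == "disrupted"), 3L)
  expect_equal(ann$pair_descriptor[ann$variant == "T10462C"], "7A-66T")
  expect_equal(ann$pair_descriptor[ann$variant == "A12308G"], "25A-37T")
  expect_equal(ann$pair_descriptor[ann$variant == "A15924G"], "31T-39A")
  expect_equal(ann$pair_descriptor[ann$variant == "G15928A"], "27C-43G")
})

test_that("annotation is invariant under the two input spellings", {
  a <- annotate_variant("G15928A", cat22)
  b <- annotate_variant("m.15928G>A", cat22)
  expect_equal(a$pair_effect, b$pair_effect)
  expect_equal(a$canonical_position, b$canonical_position)
  expect_equal(a$pair_descriptor, b$pair_descriptor)
})

test_that("light-strand variants are complemented into tRNA orientation", {
  a <- annotate_variant("T5794C", cat22)   # tRNA-Cys runs on the light strand
  expect_equal(a$gene_name, "tRNA-Cys")
  expect_equal(a$canonical_position, 33)
  # rCRS heavy-strand T reads as A in the tRNA; a mismatching heavy-strand
  # ref must be caught after complementing
  expect_error(annotate_variant("A5794C", cat22),
               class = "reference_mismatch_error")
})

test_that("non-tRNA positions and reference mismatches are hard errors", {
  expect_error(annotate_variant("A1555G", cat22),
               class = "not_trna_variant_error")  # 12S rRNA
  expect_error(annotate_variant("G7000A", cat22),
               class = "not_trna_variant_error")  # protein-coding COX1
  err <- tryCatch(annotate_variant("C10462T", cat22), error = identity)
  expect_s3_class(err, "reference_mismatch_error")
  expect_match(conditionMessage(err), "expected T")
  # the override downgrades the mismatch to a warning at pair evaluation
  expect_warning(
    a <- annotate_variant("C10462T", cat22, check_ref = FALSE),
    "differs from catalogue")
  expect_s3_class(a, "variant_annotation")
})

test_that("every complement-breaking substitution at a WC-paired site disrupts", {
  for (g in cat22) {
    for (k in seq_len(nrow(g$pairs))) {
      p <- g$pairs[k, ]
      if (p$pair_class != "WC") next
      for (side in c("pos5", "pos3")) {
        pos <- p[[side]]
        ref <- if (side == "pos5") p$ref5 else p$ref3
        for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
          eff <- classify_pair_effect(g, pos, ref, alt)
          expect_equal(eff$pair_effect, "disrupted",
                       info = sprintf("%s %s %s>%s", g$gene_name, pos,
                                      ref, alt))
        }
      }
    }
  }
})

test_that("pair-effect edge cases behave on a hand-built gene", {
  g <- toy_gene()
  # WC -> wobble counts as disrupted
  eff <- classify_pair_effect(g, 7, "T", "G")   # A-T becomes A-G? no: T->G
  expect_equal(eff$pair_effect, "disrupted")
  expect_equal(eff$pair_descriptor, "1A-7T")
  # mutating a wobble pair never yields a disruption call
  expect_equal(classify_pair_effect(g, 4, "G", "A")$pair_effect, "none")
  expect_equal(classify_pair_effect(g, 9, "T", "C")$pair_effect, "none")
  # potential pair: only the completing alternate base creates
  expect_equal(classify_pair_effect(g, 5, "A", "G")$pair_effect, "created")
  expect_equal(classify_pair_effect(g, 5, "A", "G")$pair_descriptor,
               "5A-10G")
  expect_equal(classify_pair_effect(g, 5, "A", "T")$pair_effect, "none")
  # unpaired loop position
  expect_equal(classify_pair_effect(g, 6, "A", "C")$pair_effect, "none")
  expect_error(classify_pair_effect(g, 42, "A", "C"),
               class = "position_out_of_range_error")
})

test_that("variant tables read in both dialects", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant\tplasmy", "T4454C\thomoplasmy",
               "A12308G\theteroplasmy"), tsv)
  vs <- read_variants(tsv)
  expect_length(vs, 2L)
  expect_equal(vs[[2]]$plasmy, "heteroplasmy")
  bare <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("T4454C", "G15928A"), bare)
  vs2 <- read_variants(bare)
  expect_length(vs2, 2L)
  expect_equal(vs2[[1]]$plasmy, "unknown")
})
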