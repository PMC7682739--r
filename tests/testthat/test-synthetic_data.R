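test_that("alignment specs validate their probabilities and sizes", {
  expect_error(alignment_spec(1, 10, 0.5), class = "alignment_spec_error")
  expect_error(alignment_spec(5, 0, 0.5), class = "alignment_spec_error")
  expect_error(alignment_spec(5, 10, 1.2), class = "alignment_spec_error")
  expect_error(alignment_spec(5, 10, c(0.5, 0.5)),
               class = "alignment_spec_error")
  expect_error(alignment_spec(5, 10, 0.5, gap_rate = -0.1),
               class = "alignment_spec_error")
  expect_s3_class(alignment_spec(5, 10, rep(0.5, 10)), "alignment_spec")
})

test_that("degenerate conservation specs yield the limiting alignments", {
  aln <- generate_alignment(alignment_spec(6, 25, 1, seed = 3))
  expect_true(all(apply(aln$matrix, 2, function(col)
    length(unique(col)) == 1L)))
  prof <- ci_profile(aln)
  expect_true(all(prof$ci_percent == 100))
  # p = 0: non-reference bases never match the reference
  zero <- generate_alignment(alignment_spec(40, 50, 0, seed = 3))
  prof0 <- ci_profile(zero)
  expect_true(all(prof0$ci_percent == 0))
})

test_that("generation is bit-reproducible from the seed and leaves the RNG alone", {
  spec <- alignment_spec(10, 40, 0.7, gap_rate = 0.1, seed = 99L)
  a <- generate_alignment(spec)
  b <- generate_alignment(spec)
  expect_identical(a$matrix, b$matrix)
  c2 <- generate_alignment(alignment_spec(10, 40, 0.7, gap_rate = 0.1,
                                          seed = 100L))
  expect_false(identical(a$matrix, c2$matrix))
  set.seed(1); before <- runif(1)
  generate_alignment(spec)
  set.seed(1); expect_identical(runif(1), before)
})

test_that("generated alignments round-trip through aligned FASTA", {
  spec <- alignment_spec(8, 30, 0.8, gap_rate = 0.15, seed = 17L)
  aln <- generate_alignment(spec)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(aln, path)
  back <- read_alignment(path, "Homo_sapiens")
  expect_identical(back$matrix, aln$matrix)
  expect_identical(back$labels, aln$labels)
})

test_that("mean CI recovers the conservation probability of the generator", {
  # 200 comparison species, 500 columns at p = 0.8: the mean CI estimator
  # is unbiased with standard error 100 * sqrt(p(1-p)/200/500)
  spec <- alignment_spec(201, 500, 0.8, seed = 42L)
  prof <- ci_profile(generate_alignment(spec))
  se <- 100 * sqrt(0.8 * 0.2 / 200 / 500)
  expect_lt(abs(mean(prof$ci_percent) - 80), 3 * se)
})

test_that("evidence generation realizes the requested class mix exactly", {
  mix <- c("definitely pathogenic" = 2, "possibly pathogenic" = 1,
           "neutral polymorphism" = 6)
  ev <- generate_evidence(9, mix, seed = 5L)
  expect_equal(nrow(ev), 9L)
  tally <- table(ev$classification)
  expect_equal(as.integer(tally[names(mix)]), unname(mix),
               ignore_attr = TRUE)
  # re-scoring the emitted records reproduces the recorded outcome
  for (i in seq_len(nrow(ev))) {
    s <- score_evidence(evidence_record(
      ev$independent_reports[i], ev$conservation_points[i],
      ev$heteroplasmy[i], ev$segregation_with_disease[i],
      ev$histochemical_evidence[i], ev$biochemical_defect[i],
      ev$single_fiber_evidence[i], ev$functional_study_strength[i]))
    expect_equal(s$total, ev$total[i])
    expect_equal(s$classification, ev$classification[i])
  }
  expect_identical(generate_evidence(9, mix, seed = 5L), ev)
})

test_that("proportions, empty requests and TSV output are handled", {
  ev <- generate_evidence(9, c("neutral polymorphism" = 6 / 9,
                               "possibly pathogenic" = 1 / 9,
                               "definitely pathogenic" = 2 / 9),
                          seed = 8L)
  expect_equal(sum(ev$classification == "neutral polymorphism"), 6L)
  empty <- withr::local_tempfile(fileext = ".tsv")
  e0 <- generate_evidence(0, c("neutral polymorphism" = 0), path = empty)
  expect_equal(nrow(e0), 0L)
  expect_equal(nrow(read.delim(empty)), 0L)
  path <- withr::local_tempfile(fileext = ".tsv")
  generate_evidence(4, c("neutral polymorphism" = 4), seed = 2L,
                    path = path)
  expect_length(read_evidence(path), 4L)
})

test_that("a 100% probably-pathogenic request lands only on totals 11-12", {
  ev <- generate_evidence(5, c("probably pathogenic" = 5), seed = 13L)
  expect_true(all(ev$total %in% c(11, 12)))
  expect_false(any(ev$single_fiber_evidence))
  expect_true(all(ev$functional_study_strength == "none"))
})

test_that("unreachable class requests fail after a bounded attempt budget", {
  flat <- default_rubric()
  flat$points[setdiff(names(flat$points), "conservation_max")] <- 0
  # only conservation can score: totals top out at 2, all neutral
  expect_error(generate_evidence(2, c("definitely pathogenic" = 2),
                                 seed = 1L, rubric = flat,
                                 max_attempts = 500),
               class = "evidence_generation_error")
  expect_error(generate_evidence(3, c("neutral polymorphism" = 2),
                                 seed = 1L),
               class = "alignment_spec_error")   # counts must sum to n
})

test_that("the packaged study fixture matches its published metadata", {
  fx <- ndm_fixture()
  expect_equal(nrow(fx$variants), 9L)
  expect_equal(sum(fx$evidence$provenance == "published"), 3L)
  expect_equal(fx$evidence$functional_study_strength[
    fx$evidence$variant == "A15924G"], "strong")
  expect_equal(fx$table1$ci_percent[fx$table1$variant == "A5568G"], 82.6)
  expect_equal(unname(fx$expected_totals[c("T4454C", "A5568G", "T5794C",
                                           "A10438T", "T10462C",
                                           "A15907G")]),
               c(4L, 4L, 2L, 4L, 4L, 2L))
  # the supplied CI flags agree with the strict threshold
  expect_equal(is_functionally_relevant(fx$table1$ci_percent),
               fx$table1$ci_percent > 75)
})
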