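test_that("the three published evidence columns reproduce totals 15, 13 and 10", {
  expected <- list(A12308G = c(15L, "definitely pathogenic"),
                   A15924G = c(13L, "definitely pathogenic"),
                   G15928A = c(10L, "possibly pathogenic"))
  for (v in names(expected)) {
    s <- score_evidence(fixture_evidence_record(v))
    expect_equal(s$total, as.integer(expected[[v]][1]), info = v)
    expect_equal(s$classification, expected[[v]][2], info = v)
    expect_equal(s$total, sum(s$per_criterion_points), info = v)
  }
  # the single-fiber criterion carries the 5 points separating A12308G
  s <- score_evidence(fixture_evidence_record("A12308G"))
  expect_equal(unname(s$per_criterion_points["single_fiber_evidence"]), 5)
  expect_equal(unname(s$per_criterion_points["functional_study"]), 2)
})

test_that("degenerate and maximal evidence records score as derived", {
  zero <- evidence_record(FALSE, 0, FALSE, FALSE, FALSE, FALSE, FALSE,
                          "none")
  s0 <- score_evidence(zero)
  expect_equal(s0$total, 0)
  expect_equal(s0$classification, "neutral polymorphism")
  expect_false(s0$has_functional_evidence)
  # independent sum of the rubric maxima: 6 x 2 + 5 + 5
  all_max <- evidence_record(TRUE, 2, TRUE, TRUE, TRUE, TRUE, TRUE,
                             "strong")
  expect_equal(score_evidence(all_max)$total,
               oracle_total(TRUE, 2, TRUE, TRUE, TRUE, TRUE, TRUE,
                            "strong"))
  expect_equal(score_evidence(all_max)$total, 22)
  expect_equal(rubric_maximum(), 22)
})

test_that("totals agree with the independent criterion sum across the evidence space", {
  grid <- expand.grid(reports = c(FALSE, TRUE), cons = 0:2,
                      het = c(FALSE, TRUE), seg = c(FALSE, TRUE),
                      hist = c(FALSE, TRUE), bio = c(FALSE, TRUE),
                      sf = c(FALSE, TRUE),
                      fun = c("none", "weak", "strong"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    s <- score_evidence(evidence_record(g$reports, g$cons, g$het, g$seg,
                                        g$hist, g$bio, g$sf, g$fun))
    expect_equal(s$total, oracle_total(g$reports, g$cons, g$het, g$seg,
                                       g$hist, g$bio, g$sf, g$fun))
    expect_equal(s$has_functional_evidence, g$sf || g$fun != "none")
  }
})

test_that("without functional evidence the maximum total is 12, by enumeration", {
  space <- enumerate_no_functional()
  expect_equal(nrow(space), 96L)
  totals <- vapply(seq_len(nrow(space)), function(i) {
    g <- space[i, ]
    score_evidence(evidence_record(g$reports, g$cons, g$het, g$seg,
                                   g$hist, g$bio, FALSE, "none"))$total
  }, numeric(1))
  expect_equal(max(totals), 12)
  classes <- vapply(seq_along(totals), function(i)
    classify_score(totals[i], FALSE), character(1))
  # probably pathogenic only reachable at 11-12; the guard never fires
  expect_setequal(unique(totals[classes == "probably pathogenic"]),
                  c(11, 12))
  expect_false(any(totals >= 14))
})

test_that("classification maps every feasible total to its band", {
  for (t in 0:22) {
    if (t <= 6) {
      expect_equal(classify_score(t, FALSE), "neutral polymorphism")
      expect_equal(classify_score(t, TRUE), "neutral polymorphism")
    } else if (t <= 10) {
      expect_equal(classify_score(t, FALSE), "possibly pathogenic")
      expect_equal(classify_score(t, TRUE), "possibly pathogenic")
    } else {
      expect_equal(classify_score(t, TRUE), "definitely pathogenic")
      if (t <= 13)
        expect_equal(classify_score(t, FALSE), "probably pathogenic")
      else
        expect_error(classify_score(t, FALSE),
                     class = "infeasible_evidence_error")
    }
  }
  # published boundary examples
  expect_equal(classify_score(10, TRUE), "possibly pathogenic")
  expect_equal(classify_score(13, TRUE), "definitely pathogenic")
  expect_equal(classify_score(6, FALSE), "neutral polymorphism")
})

test_that("classification is monotone in the total at fixed functional status", {
  rank <- c("neutral polymorphism" = 1, "possibly pathogenic" = 2,
            "probably pathogenic" = 3, "definitely pathogenic" = 3)
  for (fun in c(FALSE, TRUE)) {
    upper <- if (fun) 22 else 13
    r <- vapply(0:upper, function(t) rank[[classify_score(t, fun)]],
                numeric(1))
    expect_true(all(diff(r) >= 0))
  }
})

test_that("evidence records validate their fields", {
  expect_error(evidence_record("yes", 2, TRUE, TRUE, FALSE, FALSE, FALSE,
                               "none"),
               class = "evidence_validation_error")
  expect_error(evidence_record(TRUE, 3, TRUE, TRUE, FALSE, FALSE, FALSE,
                               "none"),
               class = "evidence_validation_error")
  expect_error(evidence_record(TRUE, 2, TRUE, TRUE, FALSE, FALSE, FALSE,
                               "overwhelming"))
})

test_that("evidence TSVs round-trip through the reader", {
  fx <- ndm_fixture()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(fx$evidence[, setdiff(names(fx$evidence), "provenance")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  recs <- read_evidence(tsv)
  expect_length(recs, 9L)
  totals <- vapply(recs, function(r) score_evidence(r)$total, numeric(1))
  expect_equal(totals[names(fx$expected_totals)],
               as.numeric(fx$expected_totals), ignore_attr = TRUE)
  truncated <- withr::local_tempfile(fileext = ".tsv")
  write.table(fx$evidence[, 1:4], truncated, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_evidence(truncated),
               class = "evidence_validation_error")
})

test_that("CI values map onto conservation points as configured", {
  expect_equal(conservation_points_from_ci(100), 2L)
  expect_equal(conservation_points_from_ci(82.6), 1L)
  expect_equal(conservation_points_from_ci(75), 0L)
  expect_equal(conservation_points_from_ci(21.1), 0L)
})
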