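rules <- load_rule_pack()

test_that("temporal constraints need a quantity+unit plus an anchor", {
  expect_true(detect_temporal("at least 2 weeks since therapy with drug", rules)$flag)
  expect_true(detect_temporal(
    "Patients must be taking MTX for at least 3 months before randomization",
    rules)$flag)
  expect_true(detect_temporal("diagnosis of disease ≤3 years", rules)$flag)
  # quantity+unit without an anchor, and vice versa, do not fire
  expect_false(detect_temporal("treated for 2 weeks during the study", rules)$flag)
  expect_false(detect_temporal("no prior malignancy", rules)$flag)
})

test_that("age bounds are structured fields, excluded from detection", {
  expect_false(detect_temporal("Age 18 years or older", rules)$flag)
  expect_false(detect_temporal("Ages 2 to 21", rules)$flag)
  expect_false(detect_lab_or_score("aged 18 years or older", rules)$flag)
})

test_that("lab values and scores need a lexicon term in numeric context", {
  expect_true(detect_lab_or_score("ANC ≥ 1,500/µL", rules)$flag)
  expect_true(detect_lab_or_score("ECOG performance status 0-2", rules)$flag)
  expect_true(detect_lab_or_score("Serum creatinine <= 1.5 mg/dL", rules)$flag)
  expect_false(detect_lab_or_score("Histologically confirmed diagnosis", rules)$flag)
  # analyte mentioned without any numeric context does not fire
  expect_false(detect_lab_or_score("documented normal bilirubin", rules)$flag)
})

test_that("patient-dependency fires on volition and ability phrases", {
  expect_true(detect_patient_dependency(
    "patient must be willing to comply with radiation safety procedures", rules)$flag)
  expect_true(detect_patient_dependency(
    "able to walk on treadmill or cycle on a stationary bike", rules)$flag)
  expect_false(detect_patient_dependency("Serum creatinine <= 1.5 mg/dL", rules)$flag)
})

test_that("sub-populations fire lexically and structurally", {
  lex <- data.frame(
    text = "If patients are receiving oral corticosteroids, then dose must be stable",
    indent_depth = 0L)
  expect_true(detect_subpopulation(lex, rules)$flag)

  flat <- data.frame(text = c("criterion one", "criterion two"),
                     indent_depth = c(0L, 0L))
  expect_false(detect_subpopulation(flat, rules)$flag)

  nested <- data.frame(
    text = c("Patients with hepatic involvement:", "bilirubin <= 1.5 x ULN"),
    indent_depth = c(0L, 1L))
  res <- detect_subpopulation(nested, rules)
  expect_true(res$flag)
  expect_true(res$criterion_flags[1])  # evidence attributed to the parent
})

test_that("every true flag carries an evidence span that slices back", {
  texts <- c("at least 2 weeks since therapy with imatinib",
             "ANC ≥ 1,500/µL",
             "willing to comply with study procedures")
  dets <- list(detect_temporal, detect_lab_or_score, detect_patient_dependency)
  for (i in seq_along(texts)) {
    res <- dets[[i]](texts[i], rules)
    expect_true(res$flag)
    expect_gte(nrow(res$evidence), 1)
    for (j in seq_len(nrow(res$evidence))) {
      ev <- res$evidence[j, ]
      expect_identical(substr(texts[i], ev$start, ev$end), ev$text)
      expect_gte(ev$start, 1)
      expect_lte(ev$end, nchar(texts[i]))
    }
  }
})

test_that("trial aggregation ORs criterion flags and counts them", {
  crit <- data.frame(
    ordinal = 1:4, role = "inclusion", indent_depth = 0L, negated = FALSE,
    text = c("at least 2 weeks since therapy with imatinib",
             "Hemoglobin >= 9 g/dL",
             "histologically confirmed diagnosis",
             "adequate documentation available"),
    stringsAsFactors = FALSE)
  row <- annotate_trial(crit, rules, nct_id = "NCT00000001")
  expect_true(row$temporal); expect_true(row$lab_or_score)
  expect_false(row$subpopulation); expect_false(row$patient_dependent)
  expect_true(row$any)
  expect_equal(row$n_temporal, 1L)
  expect_equal(row$n_lab_or_score, 1L)
  expect_equal(row$rules_version, rules$version)

  none <- annotate_trial(crit[3:4, ], rules, nct_id = "NCT00000002")
  expect_false(none$any)
})

test_that("one planted template per category flags all four, counts all 1", {
  bank <- load_template_bank()
  set.seed(3)
  rend <- render_criteria(c("temporal", "lab", "subpopulation", "patient"),
                          "suggested", bank)
  crit <- segment_criteria(rend$text)
  row <- annotate_trial(crit, rules, nct_id = "NCT00000003")
  expect_true(all(c(row$subpopulation, row$lab_or_score, row$temporal,
                    row$patient_dependent, row$any)))
  expect_equal(c(row$n_subpopulation, row$n_lab_or_score, row$n_temporal,
                 row$n_patient_dependent), rep(1L, 4))
})

test_that("unsegmentable trials are annotated from raw lines, flagged degraded", {
  txt <- paste("Patients are selected by the investigator.",
               "At least 2 weeks since therapy with imatinib", sep = "\n")
  row <- annotate_trial(NULL, rules, nct_id = "NCT00000004",
                        eligibility_text = txt)
  expect_true(row$degraded)
  expect_true(row$temporal)
})

test_that("annotation is deterministic and invariant to trial order", {
  g <- generate_corpus(small_spec(seed = 19L))
  a1 <- annotate_corpus(g$corpus)$trials
  rev_corpus <- ctg_corpus(rev(g$corpus$records), g$corpus$reference_dates)
  a2 <- annotate_corpus(rev_corpus)$trials
  a2 <- a2[match(a1$nct_id, a2$nct_id), ]
  rownames(a2) <- NULL
  expect_identical(a1, a2)
  a3 <- annotate_corpus(g$corpus)$trials
  expect_identical(a1, a3)
})

test_that("the barrier table's 'any' column dominates each category", {
  tab <- barrier_table(default_annotation()$trials)
  for (cc in c("percent_subpopulation", "percent_lab_or_score",
               "percent_temporal", "percent_patient_dependent"))
    expect_true(all(tab$percent_any >= tab[[cc]]))
})
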