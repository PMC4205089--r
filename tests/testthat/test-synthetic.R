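test_that("the default spec yields the declared per-domain counts", {
  g <- default_fixture()
  expect_length(g$corpus$records, 437)
  doms <- table(vapply(g$corpus$records, function(r) r$domain_tag, ""))
  expect_equal(as.integer(doms[c("gleevec", "cataract", "neuroblastoma",
                                 "rheumatoid_arthritis")]),
               c(98L, 113L, 124L, 102L))
  expect_equal(nrow(g$truth$trials), 437)
})

test_that("generation is a pure function of the spec seed", {
  s <- small_spec(seed = 77L)
  g1 <- generate_corpus(s)
  g2 <- generate_corpus(s)
  expect_identical(g1$corpus, g2$corpus)
  expect_identical(g1$truth, g2$truth)
  # and serialized records are byte-identical
  expect_identical(write_trial_xml(g1$corpus$records[[5]]),
                   write_trial_xml(g2$corpus$records[[5]]))
  g3 <- generate_corpus(small_spec(seed = 78L))
  expect_false(identical(g1$corpus, g3$corpus))
})

test_that("zero conflict prevalence yields an all-zero conflict table", {
  s <- small_spec(seed = 7L)
  s$domains$conflict_prevalence <- 0
  g <- generate_corpus(s)
  tab <- conflict_table(g$corpus)
  expect_true(all(tab$n_conflicting == 0))
  expect_true(all(tab$percent_conflicting == 0))
})

test_that("planted conflicts are realized structurally, not just labeled", {
  g <- default_fixture()
  aud <- audit_corpus_status(g$corpus)
  m <- merge(aud, g$truth$trials[, c("nct_id", "conflict")], by = "nct_id")
  expect_equal(m$conflicting, m$conflict)
})

test_that("criterion totals are planted exactly and conserved by segmentation", {
  g <- default_fixture()
  seg <- default_segmentation()
  expect_equal(nrow(seg$criteria), 5950L)
  expect_equal(sum(g$truth$trials$n_criteria), 5950L)
  # per-trial conservation
  per_trial <- table(seg$criteria$nct_id)
  truth <- g$truth$trials[g$truth$trials$format != "neither", ]
  expect_equal(as.integer(per_trial[truth$nct_id]), truth$n_criteria)
  # unsegmentable trials reported separately, not silently counted
  expect_setequal(seg$unsegmentable,
                  g$truth$trials$nct_id[g$truth$trials$format == "neither"])
})

test_that("invalid specs are rejected with the offending fields named", {
  s <- small_spec()
  s$domains$conflict_prevalence[1] <- 1.4
  expect_error(generate_corpus(s), class = "ctg_spec_error")
  s2 <- small_spec()
  s2$domains$p_suggested[1] <- 0.9
  s2$domains$p_extended[1] <- 0.3
  expect_error(generate_corpus(s2), regexp = "format mix")
})

test_that("every category template trips its own detector and no other", {
  bank <- load_template_bank()
  rules <- load_rule_pack()
  set.seed(15)
  for (rep in 1:5) {  # several slot fills per template
    for (cat in c("temporal", "lab", "subpopulation", "patient")) {
      for (tpl in bank[[cat]]) {
        txt <- ctgaudit:::fill_template(tpl, bank$lexicons)
        crit <- data.frame(ordinal = 1L, role = "inclusion", indent_depth = 0L,
                           negated = FALSE, text = txt, stringsAsFactors = FALSE)
        ann <- annotate_criteria(crit, rules)$criteria
        got <- c(subpopulation = ann$subpopulation, lab = ann$lab_or_score,
                 temporal = ann$temporal, patient = ann$patient_dependent)
        want <- setNames(names(got) == cat, names(got))
        expect_equal(got, want, info = txt)
      }
    }
    for (tpl in c(bank$distractor, bank$distractor_negated, bank$prose)) {
      txt <- ctgaudit:::fill_template(tpl, bank$lexicons)
      crit <- data.frame(ordinal = 1L, role = "inclusion", indent_depth = 0L,
                         negated = FALSE, text = txt, stringsAsFactors = FALSE)
      ann <- annotate_criteria(crit, rules)$criteria
      expect_false(any(ann$subpopulation, ann$lab_or_score, ann$temporal,
                       ann$patient_dependent), info = txt)
    }
  }
})

test_that("prose renderings match neither format", {
  set.seed(4)
  rend <- render_criteria(c("prose", "prose"), "neither")
  cls <- classify_format(rend$text)
  expect_false(cls$either)
})

test_that("rendered formats classify as their planted label across the corpus", {
  g <- default_fixture()
  seg <- default_segmentation()
  m <- merge(seg$classifications, g$truth$trials[, c("nct_id", "format")],
             by = "nct_id")
  expect_equal(m$suggested, m$format == "suggested")
  expect_equal(m$extended & !m$suggested, m$format == "extended")
  expect_equal(m$either, m$format != "neither")
})
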