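suggested_text <- paste(
  "Inclusion Criteria:", "",
  "  -  age > 18",
  "  -  histologically confirmed disease",
  "  -  adequate organ function", "",
  "Exclusion Criteria:", "",
  "  -  pregnancy",
  "  -  prior enrollment", sep = "\n")

extended_text <- paste(
  "DISEASE CHARACTERISTICS:", "",
  "  -  Histologically confirmed neuroblastoma", "",
  "PATIENT CHARACTERISTICS:", "",
  "  -  No prior chemotherapy", sep = "\n")

test_that("the suggested macro-format is recognized, order enforced", {
  cls <- classify_format(suggested_text)
  expect_true(cls$suggested)
  expect_true(cls$either)

  rev <- classify_format(paste("Exclusion Criteria:", "  -  x",
                               "Inclusion Criteria:", "  -  y", sep = "\n"))
  expect_false(rev$suggested)

  # inclusion-only trials with a bulleted list still qualify
  only <- classify_format(paste("Inclusion Criteria:", "", "  -  something",
                                sep = "\n"))
  expect_true(only$suggested)

  # a heading without any bulleted item does not
  bare <- classify_format("Inclusion Criteria:\njust prose, no list")
  expect_false(bare$suggested)
})

test_that("the extended (cancer) format needs two topic headings with lists", {
  cls <- classify_format(extended_text)
  expect_false(cls$suggested)
  expect_true(cls$extended)

  one_topic <- classify_format(paste("DISEASE CHARACTERISTICS:",
                                     "  -  confirmed disease", sep = "\n"))
  expect_false(one_topic$extended)

  prose <- classify_format("Patients are selected at the discretion of the investigator.")
  expect_false(prose$either)
})

test_that("segmentation yields one criterion per bullet with correct roles", {
  crit <- segment_criteria(suggested_text)
  expect_equal(nrow(crit), 5)
  expect_equal(sum(crit$role == "inclusion"), 3)
  expect_equal(sum(crit$role == "exclusion"), 2)
  expect_equal(crit$ordinal[crit$role == "exclusion"], 1:2)
  expect_true(all(crit$indent_depth == 0))
  expect_false(any(crit$negated))
})

test_that("extended-format items are inclusion criteria, 'No ...' negated", {
  crit <- segment_criteria(extended_text)
  expect_equal(nrow(crit), 2)
  expect_true(all(crit$role == "inclusion"))
  expect_equal(crit$negated, c(FALSE, TRUE))
})

test_that("nested bullets get deeper indent depth than their parent", {
  txt <- paste("Inclusion Criteria:", "",
               "  -  Patients with hepatic involvement:",
               "      -  documented stable disease",
               "  -  back at top level", sep = "\n")
  crit <- segment_criteria(txt)
  expect_equal(crit$indent_depth, c(0L, 1L, 0L))
  expect_gt(crit$indent_depth[2], crit$indent_depth[1])
})

test_that("continuation lines join their bullet with a single space", {
  txt <- paste("Inclusion Criteria:", "",
               "  -  a criterion that wraps",
               "     onto the next line",
               "  -  a second criterion", sep = "\n")
  crit <- segment_criteria(txt)
  expect_equal(nrow(crit), 2)
  expect_equal(crit$text[1], "a criterion that wraps onto the next line")
})

test_that("segmentation refuses text matching neither format", {
  expect_error(segment_criteria("free prose with no structure"),
               class = "ctg_format_error")
})

test_that("numbered and starred bullets are recognized too", {
  txt <- paste("Inclusion Criteria:", "",
               "  1. first criterion",
               "  2. second criterion",
               "  *  third criterion", sep = "\n")
  crit <- segment_criteria(txt)
  expect_equal(nrow(crit), 3)
})

test_that("format table: either never falls below suggested; overall is weighted", {
  tab <- format_table(default_segmentation()$classifications)
  expect_true(all(tab$percent_either >= tab$percent_suggested))
  per <- tab[tab$domain_tag != "overall", ]
  ovr <- tab[tab$domain_tag == "overall", ]
  expect_equal(ovr$n_trials, sum(per$n_trials))
  expect_equal(ovr$percent_suggested,
               percent_of(sum(per$n_suggested), sum(per$n_trials)))

  single <- format_table(data.frame(nct_id = "NCT00000001", domain_tag = "solo",
                                    suggested = TRUE, extended = FALSE,
                                    either = TRUE))
  expect_equal(single$percent_suggested, c(100, 100))
})

test_that("rendered corpora re-segment to the generator's texts and order", {
  g <- default_fixture()
  seg <- default_segmentation()
  truth <- g$truth
  ids <- truth$trials$nct_id[truth$trials$format != "neither"]
  for (id in ids[seq(1, length(ids), by = 17)]) {
    got <- seg$criteria[seg$criteria$nct_id == id, ]
    want <- truth$criteria[truth$criteria$nct_id == id, ]
    expect_equal(got$text, want$text)
    # child bullets sit deeper than their subgroup parent
    if (any(want$category == "subpopulation_child")) {
      pc <- which(want$category == "subpopulation_parent")
      expect_true(all(got$indent_depth[pc + 1L] > got$indent_depth[pc]))
    }
  }
})
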