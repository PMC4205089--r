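test_that("haversine distance behaves like a metric on the sphere", {
  bos <- c(42.3601, -71.0589)
  nyc <- c(40.7128, -74.0060)
  expect_equal(haversine_km(bos, bos), 0)
  d <- haversine_km(bos, nyc)
  expect_equal(d, 306, tolerance = 2 / 306)
  # independent spherical-law-of-cosines oracle
  expect_equal(d, slc_km(bos, nyc), tolerance = 1e-6)
  set.seed(9)
  for (i in 1:10) {
    a <- c(runif(1, -90, 90), runif(1, -180, 180))
    b <- c(runif(1, -90, 90), runif(1, -180, 180))
    expect_equal(haversine_km(a, b), haversine_km(b, a))
    expect_equal(haversine_km(a, b), slc_km(a, b), tolerance = 1e-4)
  }
  expect_error(haversine_km(c(91, 0), bos), class = "ctg_coord_error")
})

us_loc <- function(contact = TRUE, lat = 40, lon = -100) {
  trial_location("Center", "Town", "United States", lat, lon,
                 contact = if (contact) contact_info("Dr. A", phone = "555") else NULL)
}

sample_frame <- function(n, seed = 13) {
  with_seed <- function(s, code) { set.seed(s); code }
  with_seed(seed, lapply(seq_len(n), function(i)
    make_record(sprintf("NCT%08d", i),
                last_update = fuzzy_date(2013, sample(1:5, 1), sample(1:28, 1)),
                locations = list(us_loc()))))
}

test_that("stratified sampling takes whole small segments, samples large ones", {
  tr40 <- sample_frame(40)
  p40 <- stratified_sample(tr40, seed = 3)
  expect_equal(p40$segment_sizes, rep(10L, 4))
  expect_setequal(p40$sampled_ids, vapply(tr40, function(r) r$nct_id, ""))

  tr33 <- sample_frame(33)
  p33 <- stratified_sample(tr33, seed = 3)
  expect_equal(p33$segment_sizes, c(9L, 8L, 8L, 8L))
  expect_equal(length(p33$sampled_ids), 33L)

  tr90 <- sample_frame(90)
  p90 <- stratified_sample(tr90, seed = 3)
  expect_equal(p90$segment_sizes, c(23L, 23L, 22L, 22L))
  expect_equal(length(p90$sampled_ids), 40L)
  # per-segment draws come from their segment and are disjoint
  bounds <- cumsum(p90$segment_sizes)
  starts <- c(1, head(bounds, -1) + 1)
  seg_of <- function(id) which(vapply(seq_len(4), function(k)
    id %in% p90$eligible_ids[starts[k]:bounds[k]], logical(1)))
  segs <- vapply(p90$sampled_ids, seg_of, integer(1))
  expect_equal(as.integer(table(segs)), rep(10L, 4))
  expect_false(anyDuplicated(p90$sampled_ids) > 0)
})

test_that("sampling is deterministic under a fixed seed and ordered by update", {
  tr <- sample_frame(60)
  p1 <- stratified_sample(tr, seed = 99)
  p2 <- stratified_sample(tr, seed = 99)
  expect_identical(p1$sampled_ids, p2$sampled_ids)
  upd <- setNames(
    vapply(tr, function(r) as.character(latest_day(r$last_update)), ""),
    vapply(tr, function(r) r$nct_id, ""))
  expect_true(all(diff(as.Date(upd[p1$eligible_ids])) >= 0))
  expect_length(stratified_sample(list(), seed = 1)$sampled_ids, 0)
})

test_that("contact plans use the three nearest contactable locations", {
  near <- us_loc(lat = 42.4, lon = -71.1)      # ~Boston
  mid <- us_loc(lat = 40.7, lon = -74.0)       # ~NYC
  far <- us_loc(lat = 34.0, lon = -118.2)      # ~LA
  farther <- us_loc(lat = 47.6, lon = -122.3)  # ~Seattle
  no_contact <- us_loc(contact = FALSE, lat = 42.36, lon = -71.06)
  rec <- make_record(locations = list(far, no_contact, mid, farther, near),
                     overall = contact_info("O", email = "o@x.org"),
                     backup = contact_info("B", phone = "1"))
  plan <- build_contact_plan(rec)
  expect_equal(nrow(plan), 5)  # 3 locations + overall + backup
  expect_equal(plan$source, c("location", "location", "location", "overall", "backup"))
  expect_true(all(diff(plan$distance_km[1:3]) >= 0))
  # contact-less location (essentially at the reference point) is skipped
  expect_gt(min(plan$distance_km[1:3]), 1)
  expect_true(all(plan$max_calls == 3) && all(plan$max_emails == 1))

  # permuting location order never changes the nearest-3 set
  rec2 <- make_record(locations = list(near, farther, far, no_contact, mid))
  plan2 <- build_contact_plan(rec2)
  expect_equal(sort(plan2$distance_km[1:3]), sort(plan$distance_km[1:3]))
})

test_that("records without locations or contacts degrade gracefully", {
  only_overall <- make_record(overall = contact_info("O", phone = "1"))
  plan <- build_contact_plan(only_overall)
  expect_equal(plan$source, "overall")

  nothing <- make_record()
  expect_equal(nrow(build_contact_plan(nothing)), 0)
})

test_that("the first informative response decides the outcome", {
  expect_equal(classify_outcome(c("unreachable", "confirmed_open"))$category, "open")
  expect_equal(classify_outcome(c("refused", "unreachable"))$category, "dont_know")
  expect_equal(classify_outcome(character(0))$category, "no_answer")
  expect_equal(classify_outcome(rep("unreachable", 4))$category, "no_answer")
  out <- classify_outcome(c("refused", "confirmed_closed"),
                          list(NULL, fuzzy_date(2012, 5)))
  expect_equal(out$category, "closed")
  expect_equal(out$attempts_used, 2L)
  expect_equal(out$close_date$month, 5L)
})

test_that("a noiseless simulation recovers every trial's true status", {
  g <- generate_corpus(small_spec(seed = 23L))
  # guarantee nonempty plans by adding an overall contact everywhere
  recs <- lapply(g$corpus$records, function(r) {
    r$overall_contact <- contact_info("O", phone = "1"); r })
  corp <- ctg_corpus(recs, g$corpus$reference_dates)
  ids <- vapply(recs, function(r) r$nct_id, "")
  resp <- simulate_followup(corp, g$truth, ids,
                            followup_params(1, 0, 1), seed = 2)
  out <- followup_outcomes(resp, ids, corp)
  truth_open <- setNames(g$truth$trials$true_open, g$truth$trials$nct_id)
  expect_true(all(out$category %in% c("open", "closed")))
  expect_equal(out$category == "open", unname(truth_open[out$nct_id]))

  # unreachable world: everything is no_answer
  resp0 <- simulate_followup(corp, g$truth, ids, followup_params(0, 0, 1), seed = 2)
  out0 <- followup_outcomes(resp0, ids, corp)
  expect_true(all(out0$category == "no_answer"))
})

test_that("follow-up tables conserve n and honor the dropped flag", {
  out <- data.frame(
    nct_id = sprintf("NCT%08d", 1:10),
    domain_tag = rep(c("a", "b"), each = 5),
    category = c("open", "open", "closed", "no_answer", "dont_know",
                 "open", "closed", "no_answer", "no_answer", "open"),
    dropped = c(FALSE, FALSE, FALSE, FALSE, FALSE,
                TRUE, FALSE, FALSE, FALSE, FALSE))
  tab <- followup_table(out)
  ovr <- tab[tab$domain_tag == "overall", ]
  expect_equal(ovr$n, 9)
  expect_equal(ovr$n_dropped, 1)
  expect_equal(ovr$n_open + ovr$n_closed + ovr$n_dont_know + ovr$n_no_answer,
               ovr$n)
  expect_equal(ovr$percent_no_answer, percent_of(3, 9))
})
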