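# shared fixtures, generated once per test run

.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_cache$g)) .fixture_cache$g <- generate_corpus()
  .fixture_cache$g
}

default_annotation <- function() {
  if (is.null(.fixture_cache$ann))
    .fixture_cache$ann <- annotate_corpus(default_fixture()$corpus)
  .fixture_cache$ann
}

default_segmentation <- function() {
  if (is.null(.fixture_cache$seg))
    .fixture_cache$seg <- segment_corpus(default_fixture()$corpus)
  .fixture_cache$seg
}

# a compact two-domain spec for cheap property runs
small_spec <- function(seed = 11L) {
  spec <- default_corpus_spec(seed)
  spec$domains <- spec$domains[1:2, ]
  spec$domains$n_trials <- c(25L, 25L)
  spec$domains$criteria_total <- c(250L, 250L)
  spec
}

make_record <- function(nct_id = "NCT00000001", status = "recruiting",
                        last_update = fuzzy_date(2013, 5, 1),
                        completion = NULL, eligibility = "", domain = "test",
                        locations = list(), overall = NULL, backup = NULL) {
  trial_record(nct_id = nct_id, domain_tag = domain, overall_status = status,
               first_received = fuzzy_date(2010, 1, 1),
               last_update = last_update, completion_date = completion,
               eligibility_text = eligibility, locations = locations,
               overall_contact = overall, backup_contact = backup)
}

# independent rank-sum oracle: full enumeration of the rank splits
enum_ranksum_p <- function(x, y, alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n <- n1 + length(y)
  stopifnot(!any(duplicated(c(x, y))))
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(n, n1), 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
  if (alternative == "less") mean(us <= u_obs) else mean(us >= u_obs)
}

# independent distance oracle: spherical law of cosines, R = 6371 km
slc_km <- function(a, b) {
  to <- pi / 180
  ang <- sin(a[1] * to) * sin(b[1] * to) +
    cos(a[1] * to) * cos(b[1] * to) * cos((b[2] - a[2]) * to)
  acos(pmin(1, pmax(-1, ang))) * 6371
}
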