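# ctgaudit

Data-quality audits for clinical-trial registry records.

Trial registries such as ClinicalTrials.gov could power semi-automated
eligibility screening at the point of care — *if* their records are current
and their eligibility criteria are interpretable by software. `ctgaudit`
implements that audit as a tested, reusable pipeline for records in the
classic `clinical_study` XML dialect. It is aimed at clinical research
informaticians who want to quantify, on a registry corpus, how far the data
are from machine readability.

The pipeline has five stages:

* **Status audit.** A record is *conflicting* when it declares an open
  recruitment status ("Recruiting" / "Not yet recruiting") while stating a
  study completion date entirely in the past. Fuzzy registry dates (year /
  month / day precision) are compared under the conservative latest-day
  rule, so "June 2013" only counts as past once June 30 has elapsed.
* **Eligibility formats.** Textblocks are classified as the suggested
  macro-format (bulleted "Inclusion Criteria" then "Exclusion Criteria"),
  the extended cancer-trial format (inclusion-only, possibly negated, under
  "disease characteristics" / "patient characteristics" / "prior concurrent
  therapy"), or neither — then segmented into individual criteria with
  roles, indent depths, and negation flags.
* **Barrier annotation.** Rule-based detectors (a versioned, swappable rule
  pack) flag four properties that block automated interpretation:
  sub-population scoping, laboratory values and medical scores, temporal
  constraints, and patient behavior/abilities, each with evidence spans.
* **Follow-up machinery.** Last-update-stratified sampling (4 segments × 10
  trials) of open US trials, contact plans ordered by great-circle distance
  to Boston, MA, and four-category outcome classification
  (open / closed / don't know / no answer) over simulated responses.
* **Recency statistics.** One-sided Mann–Whitney rank-sum tests
  (U from midranks; exact null distribution for small tie-free samples,
  tie-corrected continuity-corrected normal approximation otherwise)
  compare staleness between conflicting/clean and closed/open groups.

Because registry snapshots are ephemeral, the package also ships a
synthetic-corpus generator (`generate_corpus()`) with *planted ground
truth*: configured conflict prevalences, format mixes, barrier prevalences,
and exact criterion totals are realized exactly, and barrier criteria are
rendered from a template bank kept independent of the detector rule pack.
Every pipeline stage is validated against what the generator planted.

## Worked example

```r
library(ctgaudit)

gen <- generate_corpus()          # default 4-domain, 437-trial corpus (seed 42)
conflict_table(gen$corpus)
#>             domain_tag n_trials n_conflicting percent_conflicting
#> 1             cataract      113            52                  46
#> 2              gleevec       98            14                  14
#> 3        neuroblastoma      124            19                  15
#> 4 rheumatoid_arthritis      102            19                  19
#> 5              overall      437           104                  24
```

Nearly half of the cataract-domain records conflict (open status, past
completion date); overall, 104 of 437 records (24%) are out of date.

```r
format_table(gen$corpus)
#>             domain_tag n_trials n_suggested n_either percent_suggested percent_either
#> 1             cataract      113         111      112                98             99
#> 2              gleevec       98          86       95                88             97
#> 3        neuroblastoma      124          98      120                79             97
#> 4 rheumatoid_arthritis      102         100      100                98             98
#> 5              overall      437         395      427                90             98
```

90% of trials follow the suggested macro-format; accounting for the
extended cancer-trial format raises machine-recognizable coverage to 98%.
Segmenting the corpus yields its 5,950 individual criteria
(`segment_corpus()`), which `annotate_corpus()` then scores against the
barrier rule pack.

The rank-sum statistic behind the recency figures:

```r
rank_sum_test(c(1, 2, 3), c(4, 5, 6), "less")
#> Mann-Whitney rank-sum test (exact, one-sided 'less')
#>   U = 0 (n1 = 3, n2 = 3), p = 0.05
```

A command-line front end over the same functions lives in
`inst/scripts/audit.R` (`synth`, `status`, `format`, `barriers`, `sample`
subcommands).

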