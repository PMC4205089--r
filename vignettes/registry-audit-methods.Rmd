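---
title: "Auditing registry records for machine-readable eligibility screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing registry records for machine-readable eligibility screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ctgaudit)
```

## The problem

Semi-automated trial matching at the point of care needs two things from a
registry: records that are *current* (a trial advertised as recruiting should
actually be recruiting) and eligibility criteria that are *machine readable*
(a program should be able to decide, from coded patient data, whether a
criterion can even be evaluated automatically). ctgaudit operationalizes an
audit of both properties for records in the classic ClinicalTrials.gov
(CTG) XML dialect, in five stages:

1. **Status audit** — flag records that declare an open recruitment status
   ("Recruiting" / "Not yet recruiting") while stating a study completion
   date entirely in the past, and measure record staleness (days since the
   last update).
2. **Format classification and segmentation** — decide whether an
   eligibility textblock follows one of the two machine-recognizable
   macro-formats, and split it into individual criteria.
3. **Barrier annotation** — rule-based detection of four properties that
   impede automated interpretation: sub-population scoping, laboratory
   values and medical scores, temporal constraints, and patient
   behavior/abilities.
4. **Follow-up sampling** — a last-update-stratified sample of open,
   US-located trials with distance-ordered contact plans and four-category
   outcome classification (open / closed / don't know / no answer).
5. **Recency comparison** — one-sided Mann-Whitney rank-sum tests of
   staleness between groups (conflicting vs. clean records; verified-closed
   vs. verified-open trials).

Because no public snapshot accompanies the audit design, the package ships a
synthetic corpus generator with planted ground truth; every stage is
validated against what the generator planted rather than against
hand-labeled data.

## Fuzzy dates and the latest-day rule

Registry dates come at year, month, or day precision (`fuzzy_date`). The
audit needs an order on them, and the choice is consequential: a trial whose
completion date is "June 2013" audited on 2013-06-12 is *not* counted as
past. We adopt the **latest-day interpretation** throughout: a fuzzy date
maps to the last calendar day consistent with it (month → last day of the
month, year → December 31). This is the conservative reading — a record is
flagged as conflicting only when the *entire* stated completion period has
elapsed, so imprecise dates can never produce false conflict flags. The
registry itself does not document a comparison convention; this is a
reconstruction and is marked as such here.

The same rule drives staleness: `days_since_update` counts days from the
latest-day reading of the last update to the domain's reference date. If the
fuzzy update period merely straddles the reference date the staleness clamps
to zero; an update whose *earliest* possible day lies after the reference
date cannot arise from a consistent snapshot and raises an error instead.

The reference date ("today" for the audit) is never the wall clock: it is
the per-domain retrieval date carried on the corpus manifest, so audits are
reproducible byte for byte.

## Format classification and segmentation

Two layouts are treated as machine-recognizable:

* **Suggested format** — a bulleted list under an "Inclusion Criteria"
  heading, optionally followed by "Exclusion Criteria", in that order. The
  order is enforced only when both headings appear; inclusion-only texts
  with a list still qualify, because an exclusion section may be
  legitimately absent.
* **Extended format** — the layout common in cancer trials: inclusion-only
  items, possibly negated ("No prior chemotherapy"), under the topics
  "disease characteristics", "patient characteristics", and "prior
  concurrent therapy". Detection requires at least **two of the three**
  topic headings, each followed by a bulleted list: requiring all three
  under-detects on real records, a single one is too weak a signal.

Everything else is "neither"; such trials are excluded from criterion counts
and reported separately, and barrier annotation falls back to a degraded
line-by-line mode (flagged `degraded` in the output).

Segmentation recognizes `-`, `*`, `•`, and `N.` bullets; continuation lines
(no marker, at least the bullet's indent) join their bullet with a single
space. Indent depth is measured relative to the section's first bullet with
a stack of indent levels; a new level requires at least 2 more spaces, and
tabs expand to 4 spaces before measurement. The 2-space unit is arbitrary
but fixed and matches the registry's own rendering style. Relative
indentation is semantic — it is one of the two signals for sub-population
scoping — which is why the XML reader strips only the *common* leading
indent of a textblock and preserves the rest.

## The barrier rule pack

The four detectors are an explicit rule-based reconstruction of what was
originally a manual annotation exercise. Their knowledge lives in a
versioned data file (`inst/extdata/barrier_rules.json`), not in code:
time-unit and anchor patterns, analyte and score lexicons, conditional
markers, volition phrases. The version tag is recorded in every output row.

Detection logic, per criterion:

* **temporal** — a quantity-plus-time-unit pattern ("2 weeks", "three
  months") co-occurring with a temporal anchor (since, within, prior,
  before, at least, no more than, comparators…).
* **lab_or_score** — an analyte or named-score term co-occurring with a
  numeric context (comparator + number, number + unit token such as mg/dL
  or /µL, or a bare numeric level for scores). A score name without any
  numeric context does not fire; the audit counts quantitative
  requirements, not mere mentions.
* **subpopulation** — lexically (if, unless, only applies, for patients
  with, …) or structurally: a criterion indented beneath a parent that
  names a condition subgroup ("Patients with hepatic involvement:"). The
  structural rule attributes the flag to the parent.
* **patient_dependent** — volition/ability phrases (willing to, able to,
  must agree, capable of, consent to, …).

Age and gender criteria are excluded from temporal and lab detection: the
registry carries them as structured fields that need no text
interpretation. Unicode comparators (≤ ≥ × µ) are normalized to ASCII
character-for-character before matching, so evidence offsets computed on the
normalized text slice correctly out of the original. Every positive flag
carries at least one such evidence span. A criterion may carry several
category flags at once; there is no mutual exclusion.

Trial-level flags are ORs over the trial's criteria; `any` is the OR of the
four categories.

## Rank-sum testing

`rank_sum_test` computes the Mann-Whitney U of the first sample from
midranks (`U = R1 − n1(n1+1)/2`). With no ties and `min(n1, n2) ≤ 8` the
p-value comes from the exact null distribution of U; otherwise from the
normal approximation with tie-corrected variance and a continuity
correction of 0.5 — the standard construction. Two numerical notes:

* The exact route and a brute-force enumeration of all rank splits agree to
  machine precision (the test suite enumerates every split up to
  `n1 + n2 = 10`).
* The approximation tracks the exact tail to better than 0.05 absolute
  whenever both samples have at least two observations. For singleton
  samples the null distribution of U is uniform and no normal curve tracks
  it that closely (worst case ≈ 0.065); the package sidesteps the issue in
  practice because the exact route always applies at such sizes.

## The synthetic generator

`generate_corpus()` emulates a four-domain registry snapshot. The default
spec (`default_corpus_spec()`) fixes, per domain: trial count (98 / 113 /
124 / 102), retrieval date (June–July 2013), conflict prevalence (14 / 46 /
15 / 19%), format mix, per-category barrier prevalences, and an exact
criterion total (1641 / 1163 / 1979 / 1167, mean ≈ 13.6 criteria per trial,
negative-binomial dispersion 6, minimum 1).

**Variance-controlled planting.** Prevalences are realized as exact counts
— `round(n·p)` (largest-remainder apportionment for the three-way format
mix) assigned to uniformly random trials — rather than independent
Bernoulli draws. The planted design therefore reproduces its configured
percentages exactly at the configured n, while remaining inside any exact
binomial interval a recovery check might use. Randomness decides *which*
trials carry each label, never *how many*.

**Structural realization.** A planted conflict is realized as an open
status plus a completion date strictly in the past under the latest-day
rule; clean trials get future or absent completion dates. Planted barrier
categories are realized by rendering one category-unambiguous template into
the trial's criteria; all remaining criteria come from distractor templates
built to trip no detector. Template bank and rule pack are separate data
files maintained against the category *definitions*, so the test that
detectors recover planted labels exactly is a drift check between two
independently written artifacts, not a tautology.

**Date coupling.** Each trial is assigned to a fresh or stale update regime
(gamma-distributed lags, means ≈ 60 vs ≈ 700 days). Conflicting trials are
stale with probability 0.9 (clean: 0.2); stale trials are truly closed with
probability 0.75 (fresh: 0.12). These couplings produce the directional
recency effects the rank-sum stage is designed to detect, at effect sizes a
few hundred trials resolve comfortably.

**Follow-up simulation.** `simulate_followup()` models outreach with a
per-trial reachability draw (default unreachability 0.31 — when a trial is
unreachable, every attempt in its contact plan goes unanswered), a refusal
probability among the reached (default 0.03; "reached but does not know"
is folded into refusal, as both yield *don't know*), and truthful answers
otherwise. The per-location budget of 3 calls + 1 email is modeled as
attempt metadata, not wall-clock scheduling, and the two-week reply window
becomes part of the simulation rather than real time.

**What the generator does not emulate.** Realistic medical language (slot
grammar is deliberately narrow so detector recovery is exact); correlation
*between* barrier categories (they are planted independently, so the
emergent `any` prevalence runs higher than in real corpora, where
categories co-occur); free-text noise such as typos, mixed formats within
one textblock, or criteria whose interpretation needs logical inference.
Passing recovery tests therefore demonstrates that the pipeline is correct
*mechanics*, not that the rule pack would match human annotation on real
registry text.

## Sampling and contact plans

Follow-up eligibility mirrors the audit's frame: open status and at least
one United States location. The eligible list is ordered by last update
(latest-day reading, `nct_id` tiebreak) and split into 4 contiguous
segments of as-equal-as-possible size — the remainder goes to the earliest
segments, a deterministic and order-stable convention chosen because the
original segmenting rule is not recoverable. Ten trials are drawn per
segment without replacement (seeded); smaller segments are taken whole, so
33 eligible trials yield segments of 9/8/8/8 and a complete sample.

Contact plans take the three geographically closest locations that carry
any contact information — great-circle distance to Boston, MA (42.3601,
−71.0589), locations without coordinates sorting last, stably — then the
overall and backup contacts. Outcome classification is first-informative-
wins: confirmed open/closed decide immediately; a refusal with no later
informative answer is *don't know*; nothing informative at all — including
trials with no contact information anywhere — is *no answer*. Trials that
completed or withdrew between corpus creation and contact download are
handled as a pre-classification `dropped` flag, excluded from the
denominator and reported separately.

One bookkeeping note: with 146 kept trials, a confirmed-open count of 74
corresponds to 51% under this package's rounding; published figures
sometimes quote 53% for the same count, which does not survive
recomputation. The package reports the count path.

## Problem sizes and determinism

The default corpus (437 trials, 5,950 criteria) generates in a few seconds
and annotates in well under a minute; the test suite and the acceptance
script both run on that scale. Everything downstream of a seed is a pure
function of it: two runs from the same spec produce byte-identical corpora,
sampling plans, and simulated responses. The package default seed is 42;
`scripts/acceptance.R` threads its `--seed` argument through every stage.

## Known limitations

* The detectors are regular-expression systems; on real registry text they
  would need lexicon growth and would still miss paraphrases and criteria
  requiring inference ("limited disease that would not normally be
  treated"). Those are reported as unflagged, by design.
* Temporal expressions are detected, not normalized to a timeline.
* The status vocabulary collapses everything outside the two open statuses
  into not-open; suspended/terminated semantics are not modeled.
* Geocoding is out of scope: coordinates must arrive on the record (the
  generator supplies them; the reader accepts their absence and sorts such
  locations last in contact plans).
* The XML dialect is the classic `clinical_study` export; the post-2024
  JSON API is a non-goal.
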