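---
title: "Profile construction and evaluation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile construction and evaluation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keeper)
```

# The procedure

`keeper` evaluates phenotype algorithms by replacing the chart with a
compact, standardized view of the patient's structured data. Three
principles drive the design: the profile follows the order of diagnostic
reasoning, extraction and representation are identical for every condition,
and only information relevant to the phenotype is shown.

A profile is assembled per cohort entry `(person_id, index_date)`. Each
*data element* of the phenotype configuration binds one conceptual element
(presentation, prior history, comorbidities/risk factors, competing
diagnoses, diagnostic procedures, laboratory tests, treatment procedures,
medications, follow-up, complications) to

- a set of clinical **domains** it may draw from,
- a **concept set** — seed concepts, each optionally expanded to all of its
  descendants in the `concept_ancestor` hierarchy, optionally excluded —
  resolved once against the loaded vocabulary, and
- an inclusive **temporal window** `[lo, hi]` of day offsets from the
  index date.

Events are selected when their domain, concept and start-date offset all
match; membership uses the start date only, while end dates feed duration
computation. Selected events are then summarized:

- **measurements** group by (concept, qualifier), where the qualifier
  compares the value with the recorded reference range — `abnormal_high`
  strictly above the upper bound, `abnormal_low` strictly below the lower
  bound, `normal` inside the inclusive range, `unknown` when the value or
  the whole range is missing; one-sided ranges classify against the
  available bound;
- **drugs** roll up to their unique `Ingredient`-class ancestor; each
  exposure contributes a day interval starting at its start offset and
  spanning `days_supply` days (its recorded start-to-end span when days
  supply is absent, a single day when both are absent); intervals are
  unioned and the union's size is the displayed duration;
- other domains group by concept, with same-day duplicate codes collapsed.

Sections appear in a fixed order, and the whole batch is blinded: a seeded
random permutation assigns opaque study identifiers, and reviewer-facing
renderings (markdown, html, csv) never contain the person identifier.

# Assumptions

The store holds one standard concept per event; mapping from source codes
is assumed done upstream, as it is in any curated CDM instance. Dates are
calendar dates with exact integer day arithmetic; no time-of-day component
exists. The `concept_ancestor` input may be a precomputed transitive
closure (the CDM convention) or plain parent-child edges — the loader
normalizes both to a reflexive-transitive closure, so "descendants of X"
always includes X itself. That matches how grouping terms are used in
practice: the grouper code itself may be recorded on a patient.

# Window encodings

The published element windows anchor everything on day 0:

| element | default window |
|---|---|
| presentation, demographics | `[0, 0]` |
| prior history, comorbidities/risk factors | `(-inf, -1]` |
| competing diagnoses, complications, follow-up | `[+1, +inf)` |
| treatment procedures, medications | `[0, +inf)` |
| diagnostic procedures, laboratory tests, visit context | unbounded |

Two boundary decisions deserve a note. "Before day 0" is encoded with an
upper bound of −1, so a day-0 code belongs to presentation, not to history.
"After the index date" starts at +1 for competing diagnoses and
complications but at 0 for treatment, because treatment legitimately begins
on the index encounter itself. Whether the diagnostics/labs window should
be bounded by the visit is genuinely open; the default here is unbounded,
with a per-element override (`window: {lo, hi}`, `"-inf"`/`"+inf"`
literals) because real deployments will want ±N-day windows.

A day-0 code whose concept belongs to both the presentation set and the
competing-diagnosis set appears in both sections: windows overlap by
design, and suppressing either occurrence would hide evidence from the
reviewer.

# Rendering choices

Day sets print with a run-length rule: maximal consecutive runs of at least
four days are dashed (`day 1-5`), everything else is slash-separated
(`day 0/1/2/5`). The threshold of four is the smallest that reproduces both
observed formats — a run of three days stays slashed while a run of five is
dashed. `parse_days()` inverts the format exactly, which the tests exercise
as a round-trip property.

Drug intervals merge only when touching or overlapping (gap 0). No
persistence-window rule is assumed; when refills leave a gap, the duration
is the number of covered days, not the calendar span. Where both a days
supply and an exposure span are recorded, days supply wins, since it is the
coded dispensing duration.

The index-visit summary selects visits whose span contains day 0 or that
start on day 0, orders them by start date with emergency-room visits before
inpatient stays on same-day ties, and annotates inpatient stays with length
of stay = end − start days (`hospitalization (3 days)`). Concept names are
lower-cased in profile text.

# Evaluation statistics

Percentages are `100·k/n` rounded to one decimal, ties away from zero. The
convention matters only for exact-tie cells (e.g. `61/80 = 76.25 → 76.3`)
and is stated here because published tables are not always internally
consistent on such ties.

Cohen's kappa uses `κ = (p_o − p_e)/(1 − p_e)` with the marginal-product
chance agreement; perfect agreement on a degenerate margin (`p_o = p_e =
1`) is defined as κ = 1, while `p_e = 1` with imperfect agreement is an
error. The default 95% CI uses the simple asymptotic standard error
`sqrt(p_o(1 − p_o)/(n(1 − p_e)²))`, truncated to `[-1, 1]`; the
Fleiss–Cohen–Everitt large-sample variance is available via
`variance = "fleiss"` for comparison, since no single CI convention
dominates in the applied literature.

Fleiss's kappa takes per-subject category counts with a fixed number of
raters `m`; with `m = 2` it equals Scott's π, which the tests use as an
independent oracle. Its CI uses the Fleiss–Nee–Landis large-sample
variance. When one overall interrater figure is needed across several
reviewer pairs who saw disjoint patient sets, the default pools all
subjects into one Fleiss computation (`fleiss_pooling = "pooled"`);
averaging the per-condition Cohen kappas is available as an alternative
because the pooling convention is ambiguous in practice.

The Cochran–Mantel–Haenszel statistic is the standard 2×2×K form
`(|Σ(a_k − E a_k)| − c)²/ΣVar(a_k)` with hypergeometric expectations and
variances per stratum. Strata with a zero margin carry zero variance and
are skipped; the continuity correction (0.5, clamped at the absolute
deviation) is on by default, matching common statistical software, and can
be disabled because no universal convention exists. The two-sided Fisher
exact p-value follows the probability-ordering rule — the sum of
probabilities of all tables with the observed margins whose probability
does not exceed the observed table's (within relative tolerance 1e-7) —
rather than the doubled one-tail. Review times use Student's pooled-variance
t-test (paired on request), with identical arms short-circuited to `t = 0,
p = 1` rather than failing on zero variance.

Crossover assignment shuffles the study ids with a seeded uniform
permutation and halves them; round 1 assigns group A to profile review and
group B to chart review, round 2 swaps. The washout duration is carried as
metadata only — scheduling is outside the package's scope.

# The synthetic generator

`generate_cdm()` exists so that every pipeline stage is testable without
any real data. It emulates the *shape* of a curated EHR-derived CDM
instance, not clinical reality:

- each patient is a case with probability `case_prevalence` (default 0.5,
  mirroring an enriched validation sample rather than population
  prevalence);
- cases carry a planted acute-surgical signature: index-day symptom and
  diagnosis codes, a day-0 diagnostic procedure, leukocyte values that are
  high on days 0–1 and normalize by day 3 against the canonical 4–11
  reference range, a 3-day antibiotic course, an appendectomy on day 2,
  and with probability 1/2 a day-25 complication;
- controls carry a competing-diagnosis signature (hematemesis plus a
  rule-out diagnosis code, endoscopy, a normal lab, acid-suppressing drugs
  with long days supply, a later esophagitis code), so that a naive
  "has the diagnosis code" rule fails while the profile's organized
  evidence separates the groups;
- every planted fact survives with probability `capture_probability`
  (default 1), emulating incomplete capture;
- `Poisson(noise_rate)` background events per patient (default 5) are
  drawn only from concepts outside every configured concept set, which
  makes the dimensionality-reduction property sharply testable: no noise
  concept may ever appear in a profile.

What the generator does **not** emulate: realistic care pathways and visit
billing structure, source-to-standard coding noise, measurement-unit
heterogeneity, inter-patient correlation, or free-text content. Passing
tests on synthetic data therefore demonstrate the mechanical correctness of
extraction, windowing, summarization and statistics — not that profile
review reaches any particular agreement with chart review on real records;
that is an empirical property of a data source.

Simulated reviewers label each patient independently with fixed
sensitivity/specificity against ground truth. At sensitivity =
specificity = 0.9 on balanced truth, expected accuracy is 90% and expected
raw two-reviewer agreement is `p² + (1 − p)² = 0.82`; the test suite checks
both inside central 95% binomial bands at n = 1000.

# Problem sizes and determinism

The test suite runs the fidelity checks on two handcrafted worked-profile
patients, the property suites on fixtures of up to 100 concepts, the
exhaustive Fisher cross-check on every 2×2 table with total count ≤ 30, the
window re-verification on a generated batch of 1000 patients, and the
reviewer calibration at n = 1000 — sizes chosen so the whole suite
completes in minutes on a single core while still exercising the asymptotic
statistics at realistic n. All randomness flows through explicit integer
seeds; the same seed reproduces generated CSVs byte for byte, and batch
construction is deterministic given (inputs, seed).

# Known limitations

Combination drug products (multiple `Ingredient` ancestors) are rejected
rather than decomposed. Problem-list conditions and billing diagnoses are
not distinguished — the store keeps a single condition stream. Source-code
mapping, live database connectivity, visit-detail/note tables and automated
concept-set discovery are out of scope. The evaluation report currently
expects exactly two reviewers per condition, the fully crossed design it
was built for.
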