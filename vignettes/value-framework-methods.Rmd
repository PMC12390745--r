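---
title: "Methods: the value framework, its defaults, and the reference portfolio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the value framework, its defaults, and the reference portfolio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htavalue)
```

`htavalue` operationalises a value framework used to issue coverage
recommendations in rapid health technology assessments (rHTA): streamlined
appraisals produced in 4–8 weeks from existing evidence, typically for
payers in settings without established cost-effectiveness thresholds. This
vignette explains the model the package implements, the defaults it ships,
what the synthetic data emulate, and the numerical and design choices that
were genuinely open.

## The grading model

Both clinical domains use a single global judgement rather than
outcome-by-outcome grading. The grade of the most critical outcome in the
PICO question is the *anchor*; everything else the deliberation considered
is recorded as signed one-level *adjustment steps*, each with a mandatory
rationale. The package formalises this as

> result = clamp(anchor + sum of deltas, scale bounds),

which is the minimal auditable formalisation of an anchored deliberation:
it is order-insensitive (only the sum matters), reduces to the anchor when
no adjustment is made, and cannot leave the scale. Three consequences are
deliberate:

* **Exactly one anchor.** Worksheets must designate a single
  criticality-rank-1 outcome; tied ranks are rejected rather than broken
  silently. Co-primary outcomes are expressed as adjustment steps against
  the designated anchor, which keeps the trace explicit.
* **Harms never raise net benefit.** An adjustment step that cites a harm
  outcome (via its optional `outcome` reference) must have delta ≤ 0.
  Without an outcome reference the rule cannot fire; the linkage is the
  worksheet author's responsibility.
* **Unbounded total movement for domain grades.** Nothing documents a
  deliberation moving a domain grade more than one level in total, but
  nothing forbids it either; the clamp permits multi-step movement for the
  two domain grades. The *recommendation* shift, by contrast, is
  explicitly capped at one net level, so `recommend()` validates
  `|sum(deltas)| ≤ 1` while the graders do not.

## The economic classifier

The framework's economic criteria are threshold rules against country
parameters (all monetary values in the same currency per year):

| Rule | Threshold | Boundary |
|---|---|---|
| Cost-effective | ICER ≤ 1 × GDP per capita per QALY/LY (2 × for rare disease) | inclusive ("equal to or less than") |
| High budget impact | > 15 annual per-capita health expenditures per 100,000 covered people = 0.015 % of total health spending | strict ("greater than") |
| High incremental cost | > annual per-capita health expenditure **or** > 25 % of the annual catastrophic household amount | strict, disjunction |
| Small population | ≤ 15 cases per 100,000 | inclusive ("up to") |

Cost-effectiveness is tri-state: only a good-quality study carried out for
the country (`icer_study_quality = "good_local"`) can yield *yes* or *no*;
anything else is *unknown* rather than a guess. The catastrophic household
amount is supplied directly as a country parameter (the WHO definition —
40 % of non-basic household expenses — describes how a country derives it,
not a computation this package performs on microdata).

The criteria are combined by an ordered first-match rule list (favorable
iff cost-effective, or cost-saving with at least minor benefit;
unfavorable iff demonstrably not cost-effective, or high budget impact
**and** high incremental cost **and** benefit ≤ minor **and** no prior
coverage elsewhere; uncertain otherwise, annotating the small-population
criterion when it holds). The combination logic is a package default, not
part of the framework's published criteria: the framework lists the
factors considered but not their boolean structure. The default was chosen
so that *favorable* requires affirmative evidence and *uncertain* is the
residual class, matching the observed dominance of uncertain economics in
practice; the rationale trace labels the policy
(`default_ordered_rules_v1`) so a differing agency policy is
distinguishable in every output. Two resolutions were genuinely open and
are resolved conservatively: prior coverage elsewhere alone never makes
economics favorable (it only blocks the compound unfavorable rule), and a
cost-effective technology with very high budget impact classifies
favorable — cost-effectiveness wins, visibly in the trace.

Every classification satisfies two properties the tests enforce: currency
invariance (multiplying all monetary inputs and parameters by a common
positive factor changes nothing) and monotonicity (lowering ICER, budget
impact or incremental cost never moves the class toward unfavorable).

## The recommendation matrix

The full 48-cell matrix behind the framework's recommendations is not
published; only ten combination→recommendation mappings are documented
from its implementation record. The package default completes the grid
with the smallest monotone integer scheme found consistent with all ten:

> score = rank(evidence) + 2 · rank(benefit) + econ_points,
> econ_points = 0 / 1 / 4 (unfavorable / uncertain / favorable)

banded ≤ 4 → strongly against, 5–6 → moderately against, 7–8 → uncertain,
9 → moderately in favor, ≥ 10 → fully in favor, then two gates: fully in
favor requires favorable economics **and** at least moderate evidence
(failing cells demote one band). The benefit weight of 2 is what separates
(HIGH, MINOR, UNCERTAIN) — documented *moderately against* — from cells an
evidence-heavy weighting would overrate; the economics jump from 1 to 4
points encodes that favorable economics is categorical, not incremental
(the only documented fully-in-favor pattern has favorable economics, and
only a handful of assessments ever met both high-quality evidence and
favorable economics). Cells matching a documented mapping carry provenance
`paper_anchored`; the other 38 carry `default_rule` and are an explicit
stand-in, not a claim about the unpublished matrix — agencies supply their
own via `load_matrix()`, which fills gaps from the default (with a
warning) and reports monotonicity violations rather than dropping them.

One documented observation is deliberately *not* a matrix cell: 17
records combining very-low/null evidence with minor benefit ended
moderately in favor. Honouring that as a raw cell would force an inversion
against (LOW, MINOR, UNCERTAIN) → strongly against, so the package treats
it as a post-deliberation outcome; the reference portfolio flags those
records `adjusted = TRUE`.

The economics-skip rule (economics not evaluated because evidence is
very low/null) substitutes `UNCERTAIN` rather than removing the dimension,
keeping the matrix total; the substitution is flagged in the audit trace
and the skip is rejected for any higher evidence level.

## The reference portfolio

`paper_fixture()` rebuilds, in code, a portfolio realising every published
count of the framework's first five years simultaneously: 264 reports, of
which 166 issued one recommendation and 87 issued two; per-level record
totals 166 / 83 / 77 / 49 / 3; the ten documented combination patterns at
their exact counts; and the stated recommendation total of 375 as the
percentage denominator. Points where the source record is internally
inconsistent are preserved, not reconciled (the `fixture_notes` attribute
carries them verbatim):

* The per-level counts sum to 378, not 375. The fixture holds 378 records
  and pins `denominator_override = 375`, which reproduces the published
  percentages (44.3 / 22.1 / 20.5 / 0.8) exactly.
* The remaining 38 records belong to the 11 multi-recommendation reports.
  Described as "more than three" recommendations each, that is
  arithmetically impossible (11 × 4 = 44 > 38), so the fixture assigns
  six reports three recommendations and five reports four — the
  deterministic allocation closest to the description that preserves all
  totals.
* Records beyond the ten documented patterns carry missing domain values
  (an *unspecified combination* sentinel): they count toward level totals
  but are excluded from combination tabulations, so no analysis can
  mistake filler for documented data.
* Technology types and clinical areas are synthetic fill assigned by
  largest-remainder allocation to match the published marginals only
  (drugs 40.3 %, therapeutic procedures 35.7 %, cancer 16.6 %, neurology
  15.8 %); the per-cell breakdown and the underlying dates are not
  published, so fixture dates are absent and area/type cross-tabs on the
  fixture are illustrative, not evidential.

## The synthetic generator

`generate_portfolio()` samples portfolios for property testing and
simulation. Defaults are fixed once to emulate the implementation record:
recommendation counts per report follow the observed 166 / 87 / 11 split
(three-plus reports drawing 3 or 4 equally); domain category probabilities
echo the observed marginals with uncertain economics dominant (0.87);
technology/area probabilities match the fixture's; and the two production
intervals are log-normal with parameters solved from the published medians
and IQRs — request→assignment meanlog log 4, sdlog 1.19 (median 4 days,
IQR 2–10); assignment→publication meanlog log 42, sdlog 0.342 (median 42,
IQR 33.25–52.75), using sdlog = (log q3 − log q1) / (2 · 0.674).

Each record's recommendation is derived by applying the default matrix to
its sampled triple, so generated portfolios are internally consistent.
What the generator does **not** emulate: correlation between domains
(real evidence quality and benefit are correlated; samples are
independent), deliberative adjustments, skipped economics, missing data,
or any real assessment content — so tests passing on synthetic portfolios
demonstrate the analytics and plotting machinery, not distributional
claims about real assessment portfolios. The generator requires a seed,
restores the global RNG state, and is byte-reproducible.

## Numerical choices

* **Rounding** of reported percentages is half away from zero
  (`round_half_up()`), the convention that reproduces the published
  one-decimal figures from their counts and denominator; base `round()`
  rounds half to even. An epsilon guard (√machine-epsilon) keeps decimal
  halves such as 22.15, stored minutely below the half, from rounding
  down.
* **Quartiles** use linear interpolation between order statistics
  (`stats::quantile()` type 7), the convention that admits fractional
  bounds such as 33.25 and matches the hand-checked case
  [1, 2, 3, 4, 5] → (2, 4).
* **Threshold boundaries** follow the wording: strict for "greater than"
  (budget impact, incremental cost), inclusive for "equal to or less
  than" (cost-effectiveness) and "up to" (small population). The
  budget-impact rule's two algebraic formulations (absolute currency vs
  fraction of total spend) are the same expression rearranged; in floating
  point they are verified to agree bit-for-bit on exactly representable
  parameter sets (integer expenditure, population in multiples of
  100,000), and can differ by at most one unit in the last place
  elsewhere.
* **Degenerate inputs** fail loudly: empty outcome lists, tied criticality
  ranks, undocumented non-zero adjustments, negative monetary values,
  duplicate matrix cells and non-total matrices are all validation errors,
  never silent defaults.

## Problem sizes

The test suite and acceptance script run at desk scale, matching the
descriptive nature of the quantities they check: the 48-cell matrix is
validated exhaustively; the reference portfolio is its full 378 records;
property suites use 25–200 seeded replicates; generator frequency
conformance uses 10,000 reports (≈ 14,000 records), where a 3-standard-
error binomial band is ± 1.3 percentage points; acceptance timing medians
use 2,000 synthetic reports.

## Limitations

The package evaluates supplied figures; it does not build
cost-effectiveness or budget-impact models, synthesise evidence, or grade
risk of bias. The default matrix's 38 undocumented cells and the economic
combination logic are package conventions, clearly labelled in provenance
and policy fields, to be replaced by an agency's own matrix and policy
where these exist. Deliberative judgement — the heart of the framework in
practice — is captured only as documented deltas; the package makes
deliberation auditable, not reproducible. Diagnostics-specific appraisal
(accuracy plus clinical consequences) and multi-indication pricing
questions such as me-too drugs are outside the scope of the three-domain
matrix.
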