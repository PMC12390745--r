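# htavalue

A value-framework engine for rapid health technology assessment (HTA)
coverage recommendations.

HTA agencies in resource-constrained settings must turn heterogeneous,
often incomplete evidence about drugs, procedures, devices and programs
into transparent coverage advice within weeks. `htavalue` implements a
multi-criteria value framework built for that setting: each technology is
scored on three ordinal domains, the triple is mapped through an explicit
recommendation matrix, and any contextual deliberation is captured as an
audited one-level shift — so every recommendation can be replayed from its
trace.

## The framework

**Domains.** Three ordinal scales:

* *Quality of evidence* (GRADE-adapted, one global judgement anchored on
  the most critical PICO outcome): `VERY_LOW_NULL < LOW < MODERATE < HIGH`.
* *Net benefit* (adapted from the IQWiG added-benefit categories, same
  anchor-and-deliberate procedure, with the rule that harms can never
  raise the level): `MARGINAL_NULL_UNCERTAIN_NEGATIVE < MINOR <
  CONSIDERABLE < MAJOR`.
* *Economic impact*: `UNFAVORABLE < UNCERTAIN < FAVORABLE`, classified by
  ordered threshold rules against country parameters:
  - cost-effective iff a good-quality local study estimates
    ICER ≤ 1 × GDP per capita per QALY/life-year gained (2 × GDP for rare
    diseases);
  - high budget impact iff annual impact > 15 annual per-capita health
    expenditures per 100,000 covered people (&equiv; 0.015 % of total
    health spending);
  - high incremental cost iff > annual per-capita health expenditure, or
    > 25 % of the annual catastrophic household amount (WHO definition);
  - small population iff ≤ 15 cases per 100,000 inhabitants.

**Matrix.** A total map from the 4 × 4 × 3 domain grid to a five-level,
colour-coded recommendation — strongly against (red), moderately against
(yellow-red), uncertain (yellow), moderately in favor (yellow-green),
fully in favor (green). The package default scores each cell
`rank(evidence) + 2·rank(benefit) + {0,1,4}[economics]`, bands the score,
and gates full approval on favorable economics with at least moderate
evidence; it is monotone in every domain and reproduces all documented
combination→recommendation mappings. Agencies with their own matrix load
it from CSV (`load_matrix()`), with monotonicity checking.

**Deliberative adjustment.** The matrix output may be shifted up or down
by at most one level, each step requiring a written rationale; the audit
trace records the cell, its provenance and every step. When evidence is
very low/null the economic domain may be skipped (`UNCERTAIN` is
substituted and flagged).

## Worked example

```r
library(htavalue)

r <- recommend("MODERATE", "MINOR", "UNCERTAIN",
  adjustments = tibble::tibble(delta = 1, rationale = "equity: pediatric orphan indication"))
print(r)
#> <vf_recommendation> UNCERTAIN (yellow)
#>   cell (MODERATE, MINOR, UNCERTAIN) -> MODERATELY_AGAINST [paper_anchored, policy additive_score_v1]
#>   net deliberative adjustment +1 over 1 step(s)
```

The matrix sends moderate evidence with minor benefit and uncertain
economics to *moderately against*; the documented equity deliberation
lifts it one level to *uncertain*. `tidy(r)` returns the step-by-step
trace.

Portfolio analytics on the packaged reference portfolio (the framework's
first five years: 264 reports, 378 recommendation records, percentages on
the stated denominator of 375):

```r
summarize_recommendations(paper_fixture())
#> # A tibble: 5 x 6
#>   recommendation      color            n   pct pct_integer pct_1dp
#> 1 STRONGLY_AGAINST    red            166  44.3          44    44.3
#> 2 MODERATELY_AGAINST  yellow-red      83  22.1          22    22.1
#> 3 UNCERTAIN           yellow          77  20.5          21    20.5
#> 4 MODERATELY_IN_FAVOR yellow-green    49  13.1          13    13.1
#> 5 FULLY_IN_FAVOR      green            3   0.8           1     0.8
```

Two-thirds of recommendations were moderately or strongly against
coverage and only 0.8 % fully in favor — the typical picture when rapid
assessments meet sparse local evidence.

Other entry points: `appraise()` (full worksheet → recommendation),
`classify_economic_impact()` (with a rationale trace), `paper_fixture()` /
`generate_portfolio()` (reference and synthetic portfolios),
`tabulate_combinations()`, `crosstab_portfolio()`, `timing_stats()`,
`plot_parallel_coordinates()` and `plot_area_grid()`.

A command-line interface wraps the same functions
(`inst/cli/htavalue`): `recommend`, `classify-economics`,
`matrix validate`, `summarize`, `timing`, `plot fig2`, `plot fig3`,
`fixture export`, `simulate`. Machine outputs are JSON and embed the tool
version, the policy in effect and input digests.

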