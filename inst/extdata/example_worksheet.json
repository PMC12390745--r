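{
  "technology": "example intrathecal drug",
  "outcomes": [
    {
      "name": "overall survival",
      "criticality_rank": 1,
      "grade": "MODERATE",
      "benefit_magnitude": "CONSIDERABLE",
      "direction": "benefit"
    },
    {
      "name": "serious adverse events",
      "criticality_rank": 2,
      "grade": "LOW",
      "benefit_magnitude": null,
      "direction": "harm"
    }
  ],
  "benefit_adjustments": [
    {
      "delta": 0,
      "rationale": "harms reviewed, no change",
      "author": "panel",
      "outcome": "serious adverse events"
    }
  ],
  "economic_inputs": {
    "annual_budget_impact": 120000,
    "incremental_cost_per_patient": 900,
    "cases_per_100k": 12,
    "prior_coverage": "mixed"
  },
  "skip_economics": false
}
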