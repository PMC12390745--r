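gdp_per_capita: 13000.0
health_expenditure_per_capita: 1300.0
catastrophic_household_amount: 6000.0
covered_population: 1000000.0
rare_disease_multiplier: 2.0
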