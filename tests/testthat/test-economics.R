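test_that("cost-effectiveness is tri-state against the GDP threshold", {
  p <- test_params(gdp = 10000)
  expect_identical(is_cost_effective(9000, "good_local", p), "yes")
  expect_identical(is_cost_effective(10000, "good_local", p), "yes") # inclusive
  expect_identical(is_cost_effective(10001, "good_local", p), "no")
  # rare disease doubles the threshold
  expect_identical(is_cost_effective(15000, "good_local", p, rare = TRUE), "yes")
  expect_identical(is_cost_effective(20001, "good_local", p, rare = TRUE), "no")
  # anything but a good local study is unknown
  expect_identical(is_cost_effective(15000, "none", p), "unknown")
  expect_identical(is_cost_effective(15000, "other", p), "unknown")
  expect_identical(is_cost_effective(NA, "good_local", p), "unknown")
  expect_error(is_cost_effective(-5, "good_local", p), "negative")
})

test_that("high budget impact is strict and both threshold formulations agree", {
  p <- test_params(hec = 1000, pop = 1e6)
  # threshold = 15 * 1000 * 10 = 150,000
  expect_true(is_high_budget_impact(200000, p))
  expect_false(is_high_budget_impact(150000, p)) # boundary: strictly greater
  expect_false(is_high_budget_impact(0, p))

  set.seed(7)
  for (i in 1:100) {
    # integer expenditure and a population in whole multiples of 100,000
    # keep every quantity exactly representable, so the absolute-currency
    # and fraction-of-total-spend formulations must agree bit for bit
    q <- test_params(
      hec = sample.int(10000, 1), pop = sample.int(1000, 1) * 1e5,
      gdp = sample.int(100000, 1), cat = sample.int(100000, 1)
    )
    threshold <- 15 * q$health_expenditure_per_capita * q$covered_population / 1e5
    total_spend <- q$health_expenditure_per_capita * q$covered_population
    expect_equal(threshold, 0.00015 * total_spend)
    for (impact in c(0, floor(threshold / 2), threshold, threshold + 1, 2 * threshold)) {
      expect_identical(
        is_high_budget_impact(impact, q),
        impact / total_spend > 0.00015
      )
    }
    expect_false(is_high_budget_impact(threshold, q))
    expect_true(is_high_budget_impact(threshold + 1, q))
  }
})

test_that("high incremental cost is a disjunction of its two triggers", {
  p <- test_params(hec = 1000, cat = 6000) # 25% of catastrophic = 1500
  expect_true(is_high_incremental_cost(1100, p)) # over per-capita only
  q <- test_params(hec = 10000, cat = 6000)
  expect_true(is_high_incremental_cost(1800, q)) # over 25% catastrophic only
  expect_false(is_high_incremental_cost(0, p))
  expect_false(is_high_incremental_cost(1000, p)) # strict on both triggers
})

test_that("small population is inclusive at 15 cases per 100,000", {
  expect_true(is_small_population(15))
  expect_false(is_small_population(15.1))
  expect_true(is_small_population(0))
  expect_error(is_small_population(-1), "non-negative")
})

test_that("classification walks the ordered rule list, first match wins", {
  p <- test_params(gdp = 10000)
  # rule 1: affirmative cost-effectiveness
  r <- classify_economic_impact(
    economic_inputs(icer = 8000, icer_study_quality = "good_local"),
    p, "CONSIDERABLE"
  )
  expect_identical(as.character(r$impact), "FAVORABLE")
  expect_identical(tail(tidy(r)$rule, 1), "rule_1_cost_effective")

  # rule 2: cost saving with at least minor benefit
  r <- classify_economic_impact(
    economic_inputs(is_cost_saving = TRUE), p, "MINOR"
  )
  expect_identical(as.character(r$impact), "FAVORABLE")
  # but not with marginal/null benefit
  r <- classify_economic_impact(
    economic_inputs(is_cost_saving = TRUE), p, "MARGINAL_NULL_UNCERTAIN_NEGATIVE"
  )
  expect_identical(as.character(r$impact), "UNCERTAIN")

  # rule 3: demonstrably not cost-effective
  r <- classify_economic_impact(
    economic_inputs(icer = 50000, icer_study_quality = "good_local"),
    p, "MAJOR"
  )
  expect_identical(as.character(r$impact), "UNFAVORABLE")

  # rule 4: the compound unfavorable pattern
  r <- classify_economic_impact(
    economic_inputs(
      annual_budget_impact = 1e9, incremental_cost_per_patient = 1e6,
      prior_coverage = "none"
    ),
    p, "MINOR"
  )
  expect_identical(as.character(r$impact), "UNFAVORABLE")
  # prior coverage elsewhere blocks rule 4
  r <- classify_economic_impact(
    economic_inputs(
      annual_budget_impact = 1e9, incremental_cost_per_patient = 1e6,
      prior_coverage = "broad"
    ),
    p, "MINOR"
  )
  expect_identical(as.character(r$impact), "UNCERTAIN")

  # rule 5 residual: no qualifying study, moderate figures
  r <- classify_economic_impact(
    economic_inputs(annual_budget_impact = 1000, cases_per_100k = 3),
    p, "CONSIDERABLE"
  )
  expect_identical(as.character(r$impact), "UNCERTAIN")
  expect_true("small_population_mitigation" %in% tidy(r)$rule)
  # every numeric comparison in the trace records its operands
  expect_true(all(nzchar(tidy(r)$detail)))
})

test_that("classification is invariant to a common currency rescaling", {
  set.seed(23)
  for (i in 1:40) {
    k <- runif(1, 0.01, 250)
    gdp <- runif(1, 1e3, 5e4)
    hec <- runif(1, 50, 5e3)
    cat_amt <- runif(1, 500, 5e4)
    inputs <- list(
      icer = sample(c(NA, runif(1, 100, 1e5)), 1),
      icer_study_quality = sample(c("good_local", "other", "none"), 1),
      annual_budget_impact = runif(1, 0, 1e8),
      incremental_cost_per_patient = runif(1, 0, 1e5),
      cases_per_100k = runif(1, 0, 100),
      is_rare_disease = sample(c(TRUE, FALSE), 1),
      prior_coverage = sample(c("broad", "mixed", "none", "unknown"), 1)
    )
    nb <- sample(c("MARGINAL_NULL_UNCERTAIN_NEGATIVE", "MINOR", "CONSIDERABLE", "MAJOR"), 1)
    scale_money <- function(x, f) {
      x[c("icer", "annual_budget_impact", "incremental_cost_per_patient")] <-
        lapply(x[c("icer", "annual_budget_impact", "incremental_cost_per_patient")], `*`, f)
      x
    }
    base <- classify_economic_impact(
      do.call(economic_inputs, inputs),
      test_params(gdp = gdp, hec = hec, cat = cat_amt), nb
    )
    scaled <- classify_economic_impact(
      do.call(economic_inputs, scale_money(inputs, k)),
      test_params(gdp = k * gdp, hec = k * hec, cat = k * cat_amt), nb
    )
    expect_identical(as.character(base$impact), as.character(scaled$impact))
  }
})

test_that("lowering any monetary input never moves the class toward unfavorable", {
  p <- test_params(gdp = 10000)
  rank_of <- function(inputs, nb = "MINOR") {
    level_rank(classify_economic_impact(do.call(economic_inputs, inputs), p, nb)$impact)
  }
  set.seed(31)
  for (i in 1:40) {
    inputs <- list(
      icer = runif(1, 1000, 40000),
      icer_study_quality = sample(c("good_local", "none"), 1),
      annual_budget_impact = runif(1, 0, 1e9),
      incremental_cost_per_patient = runif(1, 0, 1e5),
      prior_coverage = "none"
    )
    better <- inputs
    field <- sample(c("icer", "annual_budget_impact", "incremental_cost_per_patient"), 1)
    better[[field]] <- inputs[[field]] * runif(1, 0, 1)
    expect_gte(rank_of(better), rank_of(inputs))
  }
})

test_that("input validation catches contradictory economic figures", {
  expect_error(economic_inputs(icer = 1000, is_cost_saving = TRUE), "mutually exclusive")
  expect_error(economic_inputs(icer = -100), "is_cost_saving")
  expect_error(economic_inputs(annual_budget_impact = -1), "non-negative")
  expect_error(country_parameters(-1, 1, 1, 1), "positive")
  expect_error(country_parameters(1, 1, 1, 1, rare_disease_multiplier = 0.5), ">= 1")
})
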