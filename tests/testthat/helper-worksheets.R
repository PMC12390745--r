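# shared builders for grading and appraisal tests

`%||%` <- function(x, y) if (is.null(x)) y else x

make_outcomes <- function(grades = "MODERATE",
                          benefits = "CONSIDERABLE",
                          directions = "benefit",
                          ranks = seq_along(grades)) {
  n <- max(length(grades), length(benefits), length(directions))
  tibble::tibble(
    name = paste("outcome", seq_len(n)),
    criticality_rank = ranks,
    grade = rep_len(grades, n),
    benefit_magnitude = rep_len(benefits, n),
    direction = rep_len(directions, n)
  )
}

make_adjustments <- function(deltas, rationales = NULL, outcomes = NULL) {
  tibble::tibble(
    delta = deltas,
    rationale = rationales %||% ifelse(deltas != 0, "documented deliberation", NA),
    author = "panel",
    outcome = outcomes %||% NA_character_
  )
}

test_params <- function(gdp = 13000, hec = 1300, cat = 6000, pop = 1e6, mult = 2) {
  country_parameters(
    gdp_per_capita = gdp, health_expenditure_per_capita = hec,
    catastrophic_household_amount = cat, covered_population = pop,
    rare_disease_multiplier = mult
  )
}

# minimal three-level portfolio used by analytics/plot tests
tiny_portfolio <- function() {
  as_portfolio(tibble::tibble(
    report_id = c("A", "A", "B", "C"),
    recommendation_index = c(1, 2, 1, 1),
    technology_type = c("drug", "drug", "device", "drug"),
    clinical_area = c("cancer", "cancer", "neurology", "cancer"),
    evidence = c("HIGH", "LOW", "MODERATE", NA),
    benefit = c("MAJOR", "MINOR", "CONSIDERABLE", NA),
    economics = c("FAVORABLE", "UNCERTAIN", "UNCERTAIN", NA),
    recommendation = c(
      "FULLY_IN_FAVOR", "STRONGLY_AGAINST", "UNCERTAIN", "MODERATELY_AGAINST"
    ),
    request_date = as.Date("2020-01-01") + c(0, 0, 10, NA),
    assignment_date = as.Date("2020-01-01") + c(4, 4, 12, NA),
    publication_date = as.Date("2020-01-01") + c(50, 50, 40, NA)
  ))
}
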