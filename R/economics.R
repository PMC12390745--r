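#' Country-level parameters for the economic criteria
#'
#' All economic threshold rules are expressed relative to the assessing
#' country's economy: the cost-effectiveness threshold is 1 GDP per capita
#' per QALY or life-year gained (2 GDP for rare diseases), the budget-impact
#' threshold is 15 annual per-capita health expenditures per 100,000 covered
#' people (0.015% of total health spending), and the incremental-cost rule
#' compares against the annual per-capita health expenditure and against 25%
#' of the annual amount considered catastrophic for a household (WHO
#' definition: health spending above 40% of non-basic household expenses).
#'
#' @param gdp_per_capita GDP per capita, currency units per year; > 0.
#' @param health_expenditure_per_capita annual health expenditure per
#'   capita, same currency; > 0.
#' @param catastrophic_household_amount annual amount considered
#'   catastrophic for a household, same currency; > 0.
#' @param covered_population number of people covered by the payer; > 0.
#' @param rare_disease_multiplier multiplier applied to the
#'   cost-effectiveness threshold for rare diseases; >= 1, default 2.
#' @return A `vf_country_parameters` list.
#' @examples
#' country_parameters(
#'   gdp_per_capita = 13000, health_expenditure_per_capita = 1300,
#'   catastrophic_household_amount = 6000, covered_population = 1e6
#' )
#' @export
country_parameters <- function(gdp_per_capita,
                               health_expenditure_per_capita,
                               catastrophic_household_amount,
                               covered_population,
                               rare_disease_multiplier = 2) {
  vals <- c(
    gdp_per_capita = gdp_per_capita,
    health_expenditure_per_capita = health_expenditure_per_capita,
    catastrophic_household_amount = catastrophic_household_amount,
    covered_population = covered_population
  )
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all country parameters must be finite and strictly positive",
      call. = FALSE
    )
  }
  if (!is.finite(rare_disease_multiplier) || rare_disease_multiplier < 1) {
    stop("rare_disease_multiplier must be >= 1", call. = FALSE)
  }
  structure(
    list(
      gdp_per_capita = gdp_per_capita,
      health_expenditure_per_capita = health_expenditure_per_capita,
      catastrophic_household_amount = catastrophic_household_amount,
      covered_population = covered_population,
      rare_disease_multiplier = rare_disease_multiplier
    ),
    class = "vf_country_parameters"
  )
}

#' Read country parameters from a YAML or JSON file
#'
#' @param path file with the fields of [country_parameters()].
#' @return A `vf_country_parameters` list.
#' @export
read_country_parameters <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(country_parameters, raw[intersect(
    names(raw),
    c(
      "gdp_per_capita", "health_expenditure_per_capita",
      "catastrophic_household_amount", "covered_population",
      "rare_disease_multiplier"
    )
  )])
}

#' Economic inputs of an appraisal
#'
#' Bundles the supplied economic figures for one technology. The package
#' evaluates these against the framework's thresholds; it does not build
#' cost-effectiveness or budget-impact models.
#'
#' @param icer incremental cost-effectiveness ratio (currency per QALY or
#'   life-year gained) or `NA` when no estimate exists.
#' @param icer_study_quality `"good_local"` (a good-quality study carried
#'   out for the country), `"other"`, or `"none"`.
#' @param annual_budget_impact expected annual net budget impact, or `NA`.
#' @param incremental_cost_per_patient annual incremental cost versus the
#'   comparator per patient, or `NA`.
#' @param cases_per_100k affected cases per 100,000 inhabitants, or `NA`.
#' @param is_rare_disease logical rare-disease flag.
#' @param is_cost_saving logical; mutually exclusive with a positive `icer`.
#' @param prior_coverage coverage status in other health systems:
#'   `"broad"`, `"mixed"`, `"none"` or `"unknown"`.
#' @return A `vf_economic_inputs` list.
#' @export
economic_inputs <- function(icer = NA_real_,
                            icer_study_quality = c("none", "good_local", "other"),
                            annual_budget_impact = NA_real_,
                            incremental_cost_per_patient = NA_real_,
                            cases_per_100k = NA_real_,
                            is_rare_disease = FALSE,
                            is_cost_saving = FALSE,
                            prior_coverage = c("unknown", "broad", "mixed", "none")) {
  icer_study_quality <- match.arg(icer_study_quality)
  prior_coverage <- match.arg(prior_coverage)
  for (nm in c("annual_budget_impact", "incremental_cost_per_patient", "cases_per_100k")) {
    v <- get(nm)
    if (!is.na(v) && v < 0) stop(nm, " must be non-negative", call. = FALSE)
  }
  if (!is.na(icer) && icer < 0 && !is_cost_saving) {
    stop("negative icer requires is_cost_saving = TRUE (dominant technology)",
      call. = FALSE
    )
  }
  if (is_cost_saving && !is.na(icer) && icer > 0) {
    stop("is_cost_saving and a positive icer are mutually exclusive", call. = FALSE)
  }
  structure(
    list(
      icer = icer, icer_study_quality = icer_study_quality,
      annual_budget_impact = annual_budget_impact,
      incremental_cost_per_patient = incremental_cost_per_patient,
      cases_per_100k = cases_per_100k,
      is_rare_disease = isTRUE(is_rare_disease),
      is_cost_saving = isTRUE(is_cost_saving),
      prior_coverage = prior_coverage
    ),
    class = "vf_economic_inputs"
  )
}

#' Threshold rules of the economic domain
#'
#' The four per-criterion rules behind the economic-impact classification.
#'
#' * `is_cost_effective()`: tri-state. `"yes"` iff a good-quality local
#'   study estimates an ICER at or below 1 GDP per capita per QALY/life-year
#'   gained (2 GDP for rare diseases, via `rare_disease_multiplier`);
#'   `"no"` iff such a study estimates more; `"unknown"` otherwise.
#' * `is_high_budget_impact()`: `TRUE` iff the expected annual budget impact
#'   exceeds 15 annual per-capita health expenditures per 100,000 covered
#'   people, i.e. more than 0.015% of total health expenditure (strict).
#' * `is_high_incremental_cost()`: `TRUE` iff the annual incremental cost
#'   per patient exceeds the annual per-capita health expenditure *or* 25%
#'   of the annual catastrophic household amount (either trigger suffices).
#' * `is_small_population()`: `TRUE` iff at most 15 cases per 100,000
#'   inhabitants (inclusive).
#'
#' @param icer incremental cost-effectiveness ratio, currency per QALY or
#'   life-year gained; `NA` when no estimate exists.
#' @param quality `"good_local"`, `"other"` or `"none"`.
#' @param params a [country_parameters()] object.
#' @param rare logical rare-disease flag.
#' @param annual_budget_impact expected annual budget impact (>= 0).
#' @param incremental_cost_per_patient annual incremental cost versus
#'   comparator per patient (>= 0).
#' @param cases_per_100k affected cases per 100,000 inhabitants (>= 0).
#' @return `is_cost_effective()` returns `"yes"`, `"no"` or `"unknown"`;
#'   the others return a logical.
#' @examples
#' ar <- country_parameters(13000, 1300, 6000, 1e6)
#' is_cost_effective(0.9 * 13000, "good_local", ar)
#' is_high_budget_impact(2e5, country_parameters(13000, 1000, 6000, 1e6))
#' is_small_population(15)
#' @name economic_rules
NULL

#' @rdname economic_rules
#' @export
is_cost_effective <- function(icer, quality, params, rare = FALSE) {
  stopifnot(inherits(params, "vf_country_parameters"))
  if (!is.na(icer) && icer < 0) {
    stop("negative icer: model a dominant technology with is_cost_saving",
      call. = FALSE
    )
  }
  if (is.na(icer) || !identical(quality, "good_local")) {
    return("unknown")
  }
  threshold <- params$gdp_per_capita *
    (if (isTRUE(rare)) params$rare_disease_multiplier else 1)
  if (icer <= threshold) "yes" else "no"
}

#' @rdname economic_rules
#' @export
is_high_budget_impact <- function(annual_budget_impact, params) {
  stopifnot(inherits(params, "vf_country_parameters"))
  if (is.na(annual_budget_impact) || annual_budget_impact < 0) {
    stop("annual_budget_impact must be a non-negative number", call. = FALSE)
  }
  threshold <- 15 * params$health_expenditure_per_capita *
    (params$covered_population / 1e5)
  annual_budget_impact > threshold
}

#' @rdname economic_rules
#' @export
is_high_incremental_cost <- function(incremental_cost_per_patient, params) {
  stopifnot(inherits(params, "vf_country_parameters"))
  if (is.na(incremental_cost_per_patient) || incremental_cost_per_patient < 0) {
    stop("incremental_cost_per_patient must be a non-negative number", call. = FALSE)
  }
  incremental_cost_per_patient > params$health_expenditure_per_capita ||
    incremental_cost_per_patient > 0.25 * params$catastrophic_household_amount
}

#' @rdname economic_rules
#' @export
is_small_population <- function(cases_per_100k) {
  if (is.na(cases_per_100k) || cases_per_100k < 0) {
    stop("cases_per_100k must be a non-negative number", call. = FALSE)
  }
  cases_per_100k <= 15
}

econ_rule_row <- function(rule, result, detail) {
  tibble::tibble(rule = rule, result = as.character(result), detail = detail)
}

#' Classify the economic impact of a technology
#'
#' Combines the threshold rules, the net-benefit grade and prior coverage
#' into the three-level economic-impact classification, recording every
#' evaluation in an ordered rationale trace. The package-default policy is
#' an ordered first-match rule list:
#'
#' 1. `FAVORABLE` if cost-effective (`is_cost_effective() == "yes"`).
#' 2. `FAVORABLE` if cost-saving with at least `MINOR` net benefit.
#' 3. `UNFAVORABLE` if demonstrably not cost-effective.
#' 4. `UNFAVORABLE` if high budget impact *and* high incremental cost *and*
#'    net benefit at most `MINOR` *and* no prior coverage elsewhere.
#' 5. `UNCERTAIN` otherwise, with the small-population criterion recorded
#'    as a mitigating annotation when it holds.
#'
#' `FAVORABLE` thus requires affirmative evidence and `UNCERTAIN` is the
#' residual class — in practice the dominant one, since good-quality local
#' cost-effectiveness studies are rare in this setting.
#'
#' @param inputs an [economic_inputs()] object.
#' @param params a [country_parameters()] object.
#' @param net_benefit the technology's net-benefit grade (level name,
#'   ordered factor, or `vf_grade`).
#' @return A `vf_econ_class` object: the `EconomicImpact` level plus the
#'   rationale trace (`tidy()` returns it as a tibble).
#' @examples
#' ar <- country_parameters(13000, 1300, 6000, 1e6)
#' classify_economic_impact(
#'   economic_inputs(icer = 10000, icer_study_quality = "good_local"),
#'   ar,
#'   net_benefit = "CONSIDERABLE"
#' )
#' @export
classify_economic_impact <- function(inputs, params, net_benefit) {
  stopifnot(inherits(inputs, "vf_economic_inputs"))
  stopifnot(inherits(params, "vf_country_parameters"))
  if (inherits(net_benefit, "vf_grade")) net_benefit <- net_benefit$result
  nb <- as_vf_level(net_benefit, "benefit", arg = "net_benefit")
  nb_rank <- level_rank(nb, "benefit")

  trace <- list()
  ce <- is_cost_effective(
    inputs$icer, inputs$icer_study_quality, params,
    rare = inputs$is_rare_disease
  )
  ce_threshold <- params$gdp_per_capita *
    (if (inputs$is_rare_disease) params$rare_disease_multiplier else 1)
  trace[[1]] <- econ_rule_row(
    "cost_effective", ce,
    sprintf(
      "icer %s vs threshold %s (quality %s, rare %s)",
      format(inputs$icer), format(ce_threshold),
      inputs$icer_study_quality, inputs$is_rare_disease
    )
  )

  decided <- NULL
  decide <- function(level, rule) {
    trace[[length(trace) + 1]] <<- econ_rule_row(rule, level, "first matching rule")
    decided <<- level
  }

  if (ce == "yes") decide("FAVORABLE", "rule_1_cost_effective")

  if (is.null(decided)) {
    cs_ok <- inputs$is_cost_saving && nb_rank >= 1
    trace[[length(trace) + 1]] <- econ_rule_row(
      "cost_saving_with_benefit", cs_ok,
      sprintf(
        "is_cost_saving %s, net benefit %s (>= MINOR: %s)",
        inputs$is_cost_saving, as.character(nb), nb_rank >= 1
      )
    )
    if (cs_ok) decide("FAVORABLE", "rule_2_cost_saving")
  }

  if (is.null(decided) && ce == "no") decide("UNFAVORABLE", "rule_3_not_cost_effective")

  if (is.null(decided)) {
    hbi <- if (!is.na(inputs$annual_budget_impact)) {
      is_high_budget_impact(inputs$annual_budget_impact, params)
    } else {
      NA
    }
    bi_threshold <- 15 * params$health_expenditure_per_capita *
      (params$covered_population / 1e5)
    trace[[length(trace) + 1]] <- econ_rule_row(
      "high_budget_impact", hbi,
      sprintf(
        "annual impact %s vs threshold %s (0.015%% of total spend)",
        format(inputs$annual_budget_impact), format(bi_threshold)
      )
    )
    hic <- if (!is.na(inputs$incremental_cost_per_patient)) {
      is_high_incremental_cost(inputs$incremental_cost_per_patient, params)
    } else {
      NA
    }
    trace[[length(trace) + 1]] <- econ_rule_row(
      "high_incremental_cost", hic,
      sprintf(
        "cost/patient %s vs per-capita expenditure %s or 25%% of catastrophic %s",
        format(inputs$incremental_cost_per_patient),
        format(params$health_expenditure_per_capita),
        format(0.25 * params$catastrophic_household_amount)
      )
    )
    unfavorable <- isTRUE(hbi) && isTRUE(hic) && nb_rank <= 1 &&
      inputs$prior_coverage %in% c("none", "unknown")
    trace[[length(trace) + 1]] <- econ_rule_row(
      "rule_4_unfavorable_pattern", unfavorable,
      sprintf(
        "high budget impact %s & high incremental cost %s & benefit <= MINOR %s & prior coverage '%s'",
        format(hbi), format(hic), nb_rank <= 1, inputs$prior_coverage
      )
    )
    if (unfavorable) decide("UNFAVORABLE", "rule_4_unfavorable_pattern")
  }

  if (is.null(decided)) {
    small <- if (!is.na(inputs$cases_per_100k)) {
      is_small_population(inputs$cases_per_100k)
    } else {
      NA
    }
    trace[[length(trace) + 1]] <- econ_rule_row(
      "small_population_mitigation", small,
      sprintf("cases per 100k %s vs 15 (inclusive)", format(inputs$cases_per_100k))
    )
    decide("UNCERTAIN", "rule_5_residual_uncertain")
  }

  rationale <- dplyr::bind_rows(trace)
  rationale$step <- seq_len(nrow(rationale))
  structure(
    list(
      impact = as_vf_level(decided, "economics"),
      rationale = rationale[c("step", "rule", "result", "detail")],
      policy = "default_ordered_rules_v1"
    ),
    class = "vf_econ_class"
  )
}

#' @export
print.vf_econ_class <- function(x, ...) {
  cat(sprintf(
    "<vf_econ_class> %s (policy %s)\n", as.character(x$impact), x$policy
  ))
  print(x$rationale)
  invisible(x)
}

#' @rdname classify_economic_impact
#' @param x a `vf_econ_class` object.
#' @param ... unused.
#' @export
tidy.vf_econ_class <- function(x, ...) x$rationale

#' @rdname classify_economic_impact
#' @export
glance.vf_econ_class <- function(x, ...) {
  tibble::tibble(
    impact = as.character(x$impact),
    decisive_rule = x$rationale$rule[match(as.character(x$impact), x$rationale$result)],
    n_rules_evaluated = nrow(x$rationale),
    policy = x$policy
  )
}
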