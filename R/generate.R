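#' Configuration for the synthetic portfolio generator
#'
#' Defines the sampling distributions for a random portfolio of rapid-HTA
#' assessments. The defaults emulate the conditions of the framework's
#' implementation record: the recommendation-count distribution over
#' reports follows the observed 166 / 87 / 11 split, category
#' probabilities echo the observed marginals (uncertain economics
#' dominant, drugs and therapeutic procedures the most common technology
#' types), and the production-timing intervals are log-normal with
#' parameters solved from the observed medians and interquartile ranges
#' (request to assignment: median 4 days, IQR 2-10; assignment to
#' publication: median 42 days, IQR 33.25-52.75).
#'
#' @param n_reports number of reports to generate.
#' @param seed integer seed; mandatory, the generator is reproducible.
#' @param rec_count_probs probabilities over 1 / 2 / 3-plus recommendations
#'   per report (3-plus reports get 3 or 4 with equal probability).
#' @param evidence_probs,benefit_probs,economics_probs named probability
#'   vectors over the respective scale levels.
#' @param technology_probs,area_probs named probability vectors over
#'   technology types and clinical areas.
#' @param timing list with `request_to_assignment` and
#'   `assignment_to_publication`, each `c(meanlog, sdlog)` for a log-normal
#'   day count.
#' @return A `vf_generator_config` list.
#' @export
generator_config <- function(n_reports,
                             seed,
                             rec_count_probs = c(`1` = 166, `2` = 87, `3+` = 11) / 264,
                             evidence_probs = c(
                               VERY_LOW_NULL = 0.25, LOW = 0.32,
                               MODERATE = 0.33, HIGH = 0.10
                             ),
                             benefit_probs = c(
                               MARGINAL_NULL_UNCERTAIN_NEGATIVE = 0.33,
                               MINOR = 0.32, CONSIDERABLE = 0.25, MAJOR = 0.10
                             ),
                             economics_probs = c(
                               UNFAVORABLE = 0.05, UNCERTAIN = 0.87,
                               FAVORABLE = 0.08
                             ),
                             technology_probs = fixture_type_probs,
                             area_probs = fixture_area_probs,
                             timing = list(
                               request_to_assignment = c(
                                 meanlog = log(4), sdlog = 1.19
                               ),
                               assignment_to_publication = c(
                                 meanlog = log(42), sdlog = 0.342
                               )
                             )) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("a seed is mandatory: the generator must be reproducible", call. = FALSE)
  }
  if (is.na(n_reports) || n_reports < 0 || n_reports != floor(n_reports)) {
    stop("n_reports must be a non-negative integer", call. = FALSE)
  }
  check_probs <- function(p, what, levels = NULL) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(what, " must be non-negative and sum to 1 (tolerance 1e-9)",
        call. = FALSE
      )
    }
    if (!is.null(levels) && !identical(names(p), levels)) {
      stop(what, " must be named over: ", paste(levels, collapse = ", "),
        call. = FALSE
      )
    }
    p
  }
  structure(
    list(
      n_reports = as.integer(n_reports),
      seed = as.integer(seed),
      rec_count_probs = check_probs(rec_count_probs, "rec_count_probs"),
      evidence_probs = check_probs(evidence_probs, "evidence_probs", vf_levels$evidence),
      benefit_probs = check_probs(benefit_probs, "benefit_probs", vf_levels$benefit),
      economics_probs = check_probs(economics_probs, "economics_probs", vf_levels$economics),
      technology_probs = check_probs(technology_probs, "technology_probs"),
      area_probs = check_probs(area_probs, "area_probs"),
      timing = timing
    ),
    class = "vf_generator_config"
  )
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file whose fields are the arguments of
#'   [generator_config()] (probability vectors as named maps).
#' @return A `vf_generator_config`.
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  for (nm in grep("_probs$", names(raw), value = TRUE)) {
    raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$timing)) raw$timing <- lapply(raw$timing, unlist)
  do.call(generator_config, raw)
}

#' Generate a seeded synthetic portfolio
#'
#' Samples a reproducible random portfolio under a
#' [generator_config()]: per report a recommendation count, technology
#' type, clinical area and production dates; per record the three domain
#' levels, independently from the configured category probabilities. Each
#' record's recommendation is obtained by applying the default
#' recommendation matrix to its sampled triple, so synthetic portfolios
#' are internally consistent with the framework. The same configuration
#' (including seed) always yields an identical portfolio; the global RNG
#' state is left untouched.
#'
#' @param config a `vf_generator_config`.
#' @param matrix the `vf_matrix` used to derive recommendations; defaults
#'   to [default_matrix()].
#' @return A `vf_portfolio`.
#' @examples
#' p <- generate_portfolio(generator_config(n_reports = 20, seed = 42))
#' summarize_recommendations(p)
#' @export
generate_portfolio <- function(config, matrix = default_matrix()) {
  stopifnot(inherits(config, "vf_generator_config"))
  empty <- as_portfolio(tibble::tibble(
    report_id = character(), recommendation_index = integer(),
    recommendation = character()
  )[0, ])
  if (config$n_reports == 0) {
    return(empty)
  }
  withr::with_seed(config$seed, {
    n <- config$n_reports
    bucket <- sample(names(config$rec_count_probs), n,
      replace = TRUE, prob = config$rec_count_probs
    )
    sizes <- integer(n)
    sizes[bucket == "1"] <- 1L
    sizes[bucket == "2"] <- 2L
    sizes[bucket == "3+"] <- sample(3:4, sum(bucket == "3+"), replace = TRUE)
    total <- sum(sizes)

    request <- as.Date("2017-05-01") + sample.int(1827L, n, replace = TRUE) - 1L
    to_assign <- round(stats::rlnorm(
      n, config$timing$request_to_assignment[["meanlog"]],
      config$timing$request_to_assignment[["sdlog"]]
    ))
    to_publish <- round(stats::rlnorm(
      n, config$timing$assignment_to_publication[["meanlog"]],
      config$timing$assignment_to_publication[["sdlog"]]
    ))

    reports <- tibble::tibble(
      report_id = sprintf("S%05d", seq_len(n)),
      size = sizes,
      technology_type = sample(names(config$technology_probs), n,
        replace = TRUE, prob = config$technology_probs
      ),
      clinical_area = sample(names(config$area_probs), n,
        replace = TRUE, prob = config$area_probs
      ),
      request_date = request,
      assignment_date = request + to_assign,
      publication_date = request + to_assign + to_publish
    )

    records <- reports[rep(seq_len(n), times = sizes), ] |>
      dplyr::mutate(
        recommendation_index = unlist(lapply(sizes, seq_len)),
        evidence = sample(vf_levels$evidence, total,
          replace = TRUE, prob = config$evidence_probs
        ),
        benefit = sample(vf_levels$benefit, total,
          replace = TRUE, prob = config$benefit_probs
        ),
        economics = sample(vf_levels$economics, total,
          replace = TRUE, prob = config$economics_probs
        ),
        economics_skip_reason = NA_character_
      )
    cells <- matrix$cells
    idx <- match(
      paste(records$evidence, records$benefit, records$economics),
      paste(cells$evidence, cells$benefit, cells$economics)
    )
    records$recommendation <- as.character(cells$recommendation[idx])
    as_portfolio(dplyr::select(
      records,
      "report_id", "recommendation_index", "technology_type", "clinical_area",
      "evidence", "benefit", "economics", "economics_skip_reason",
      "recommendation", "request_date", "assignment_date", "publication_date"
    ))
  })
}
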