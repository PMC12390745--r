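#' Printed portfolio counts of the framework's first five years
#'
#' The constants behind the packaged reference portfolio: the per-level
#' recommendation totals, the documented (evidence, benefit, economics)
#' combination patterns with their counts and assigned levels, the report
#' structure (how many reports issued one, two, or three-plus
#' recommendations) and the stated recommendation total of 375 that the
#' published percentages divide by — even though the per-level counts sum
#' to 378. Both facts are preserved; no reconciliation is invented.
#'
#' @return A list with elements `level_totals`, `named_patterns` (tibble),
#'   `report_structure`, `denominator` and `notes` (verbatim discrepancies
#'   carried as metadata).
#' @export
fixture_spec <- function() {
  list(
    level_totals = c(
      STRONGLY_AGAINST = 166L, MODERATELY_AGAINST = 83L, UNCERTAIN = 77L,
      MODERATELY_IN_FAVOR = 49L, FULLY_IN_FAVOR = 3L
    ),
    named_patterns = tibble::tribble(
      ~evidence, ~benefit, ~economics, ~recommendation, ~n, ~adjusted,
      "VERY_LOW_NULL", "MARGINAL_NULL_UNCERTAIN_NEGATIVE", "UNCERTAIN", "STRONGLY_AGAINST", 55L, FALSE,
      "LOW", "MARGINAL_NULL_UNCERTAIN_NEGATIVE", "UNCERTAIN", "STRONGLY_AGAINST", 23L, FALSE,
      "MODERATE", "MARGINAL_NULL_UNCERTAIN_NEGATIVE", "UNCERTAIN", "STRONGLY_AGAINST", 17L, FALSE,
      "LOW", "MINOR", "UNCERTAIN", "STRONGLY_AGAINST", 29L, FALSE,
      "MODERATE", "MINOR", "UNCERTAIN", "MODERATELY_AGAINST", 30L, FALSE,
      "LOW", "CONSIDERABLE", "UNCERTAIN", "MODERATELY_AGAINST", 20L, FALSE,
      "HIGH", "MINOR", "UNCERTAIN", "MODERATELY_AGAINST", 13L, FALSE,
      "VERY_LOW_NULL", "MINOR", "UNCERTAIN", "MODERATELY_IN_FAVOR", 17L, TRUE,
      "MODERATE", "MAJOR", "UNCERTAIN", "MODERATELY_IN_FAVOR", 18L, FALSE,
      "MODERATE", "CONSIDERABLE", "FAVORABLE", "FULLY_IN_FAVOR", 3L, FALSE
    ),
    report_structure = c(one_rec = 166L, two_rec = 87L, three_plus_rec = 11L),
    denominator = 375L,
    notes = c(
      "per-level recommendation counts sum to 378 while the stated total is 375; percentages use 375",
      "moderately-against share printed as both 22.1 and 22.2 percent",
      "uncertain share printed as 19.7 (abstract) and 20.5 (body) percent",
      "drug share printed as 40.5 (abstract) and 40.3 (body) percent",
      "technology types and clinical areas per report are synthetic fill matching the printed marginals only",
      "the 17 very-low-evidence/minor-benefit records at moderately-in-favor are flagged adjusted: inconsistent with any monotone matrix, read as a post-deliberation outcome"
    )
  )
}

# deterministic allocation of counts to categories by largest remainder,
# used to fill technology types and clinical areas for fixture reports
allocate_counts <- function(n, probs) {
  raw <- n * probs / sum(probs)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(probs))
}

fixture_type_probs <- c(
  drug = 0.403, therapeutic_procedure = 0.357, diagnostic = 0.110,
  device = 0.070, program = 0.035, other = 0.025
)

fixture_area_probs <- c(
  cancer = 0.166, neurology = 0.158, musculoskeletal = 0.120,
  endocrinology = 0.100, infectious_diseases = 0.100, cardiology = 0.090,
  other = 0.266
)

#' The packaged reference portfolio
#'
#' Builds, deterministically and entirely in code, the portfolio that
#' realises every printed count of the framework's 2017-2022
#' implementation record: 264 reports (166 with one recommendation, 87
#' with two, 11 with three or more) carrying 378 recommendation records
#' whose per-level totals are 166 / 83 / 77 / 49 / 3; each documented
#' combination pattern appears with its printed count and level; records
#' beyond the documented patterns carry missing domains (an unspecified
#' combination — they count toward level totals but are excluded from
#' combination tabulations). The percentage denominator is pinned to the
#' stated total of 375.
#'
#' Technology types and clinical areas are synthetic fill: assigned
#' deterministically so the portfolio marginals match the printed shares
#' (drugs 40.3%, therapeutic procedures 35.7%, cancer 16.6%, neurology
#' 15.8%), because the per-cell breakdown is not published. Dates are
#' absent for the same reason.
#'
#' @return A `vf_portfolio` with `denominator_override = 375` and a
#'   `fixture_notes` attribute carrying the verbatim source discrepancies.
#' @examples
#' p <- paper_fixture()
#' summarize_recommendations(p)
#' @export
paper_fixture <- function() {
  spec <- fixture_spec()
  patterns <- spec$named_patterns
  level_order <- names(spec$level_totals)

  records <- purrr::pmap(patterns, function(evidence, benefit, economics,
                                            recommendation, n, adjusted) {
    tibble::tibble(
      evidence = evidence, benefit = benefit, economics = economics,
      recommendation = recommendation, adjusted = adjusted
    )[rep(1, n), ]
  }) |>
    dplyr::bind_rows()

  filler <- purrr::imap(spec$level_totals, function(total, level) {
    named <- sum(patterns$n[patterns$recommendation == level])
    stopifnot(named <= total)
    k <- total - named
    if (k == 0) {
      return(NULL)
    }
    tibble::tibble(
      evidence = NA_character_, benefit = NA_character_,
      economics = NA_character_, recommendation = level, adjusted = FALSE
    )[rep(1, k), ]
  }) |>
    dplyr::bind_rows()

  records <- dplyr::bind_rows(records, filler)
  records$recommendation <- factor(records$recommendation, levels = level_order)
  records <- records[order(records$recommendation), ]
  stopifnot(nrow(records) == sum(spec$level_totals))

  # report sizes: 166 x 1, 87 x 2, then 11 multi-recommendation reports
  # absorbing the remaining records (38 left => six reports of 3, five of 4)
  n_multi <- spec$report_structure[["three_plus_rec"]]
  remaining <- nrow(records) - spec$report_structure[["one_rec"]] -
    2L * spec$report_structure[["two_rec"]]
  base <- remaining %/% n_multi
  n_big <- remaining - base * n_multi
  sizes <- c(
    rep(1L, spec$report_structure[["one_rec"]]),
    rep(2L, spec$report_structure[["two_rec"]]),
    rep(base + 1L, n_big), rep(base, n_multi - n_big)
  )
  stopifnot(sum(sizes) == nrow(records), length(sizes) == 264L)

  # deal records out in a deterministic stride so the level blocks
  # interleave across reports, then assign consecutively to report slots
  records <- records[order(rep_len(seq_len(max(sizes)), nrow(records))), ]
  records$report_id <- sprintf("R%03d", rep(seq_along(sizes), times = sizes))
  records$recommendation_index <- unlist(lapply(sizes, seq_len))

  report_meta <- tibble::tibble(
    report_id = sprintf("R%03d", seq_along(sizes)),
    technology_type = rep(names(fixture_type_probs),
      times = allocate_counts(length(sizes), fixture_type_probs)
    ),
    clinical_area = rep_len(
      rep(names(fixture_area_probs),
        times = allocate_counts(length(sizes), fixture_area_probs)
      ),
      length(sizes)
    )
  )
  # decouple type and area assignment so cells mix deterministically
  report_meta$clinical_area <- report_meta$clinical_area[
    order(rep_len(seq_len(7L), nrow(report_meta)))
  ]

  out <- records |>
    dplyr::left_join(report_meta, by = "report_id") |>
    dplyr::mutate(
      economics_skip_reason = ifelse(
        is.na(.data$evidence), "unspecified_combination", NA_character_
      ),
      request_date = as.Date(NA), assignment_date = as.Date(NA),
      publication_date = as.Date(NA)
    ) |>
    dplyr::select(
      "report_id", "recommendation_index", "technology_type", "clinical_area",
      "evidence", "benefit", "economics", "economics_skip_reason",
      "recommendation", "request_date", "assignment_date", "publication_date",
      "adjusted"
    )
  out <- as_portfolio(out, denominator_override = spec$denominator)
  attr(out, "fixture_notes") <- spec$notes
  out
}

#' Path of the packaged fixture CSV
#'
#' The reference portfolio also ships as a plain CSV in the portfolio
#' interchange schema (plus the fixture's `adjusted` flag column);
#' [paper_fixture()] is the authoritative in-code constructor and the CSV
#' is its exact serialisation.
#'
#' @return File path of the installed CSV.
#' @export
fixture_csv_path <- function() {
  system.file("extdata", "reference_portfolio.csv",
    package = "htavalue", mustWork = TRUE
  )
}
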