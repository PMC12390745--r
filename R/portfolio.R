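#' Portfolios of assessment records
#'
#' A portfolio is a tibble with one row per coverage recommendation issued
#' (a report with a broad PICO question can issue several, one per
#' subpopulation or comparator). Columns:
#'
#' * `report_id`, `recommendation_index` — jointly unique; index 1 is the
#'   main recommendation of a report.
#' * `technology_type` — `drug`, `therapeutic_procedure`, `diagnostic`,
#'   `device`, `program` or `other`.
#' * `clinical_area` — free label (cancer, neurology, ...).
#' * `evidence`, `benefit`, `economics` — domain levels, possibly missing
#'   (`economics_skip_reason` documents a skipped economic domain).
#' * `recommendation` — the five-level coverage recommendation.
#' * `request_date`, `assignment_date`, `publication_date` — optional
#'   ISO-8601 dates, ordered request <= assignment <= publication.
#'
#' `as_portfolio()` validates a data frame into a `vf_portfolio`;
#' `denominator_override` replaces the record count as the percentage
#' denominator in [summarize_recommendations()] (used when an externally
#' stated total differs from the row count) and is documented in the
#' summary output.
#'
#' @param x data frame with the columns above (domain/recommendation
#'   columns as uppercase names or factors).
#' @param denominator_override optional positive integer.
#' @return A `vf_portfolio` tibble.
#' @export
as_portfolio <- function(x, denominator_override = NULL) {
  x <- tibble::as_tibble(x)
  required <- c("report_id", "recommendation_index", "recommendation")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("portfolio is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  defaults <- list(
    technology_type = NA_character_, clinical_area = NA_character_,
    evidence = NA_character_, benefit = NA_character_,
    economics = NA_character_, economics_skip_reason = NA_character_,
    request_date = as.Date(NA), assignment_date = as.Date(NA),
    publication_date = as.Date(NA)
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(x)) x[[nm]] <- defaults[[nm]]
  }
  if (anyDuplicated(x[c("report_id", "recommendation_index")])) {
    stop("(report_id, recommendation_index) must be unique", call. = FALSE)
  }
  x$evidence <- evidence_quality(x$evidence)
  x$benefit <- net_benefit(x$benefit)
  x$economics <- economic_impact(x$economics)
  x$recommendation <- recommendation_level(x$recommendation)
  if (any(is.na(x$recommendation))) {
    stop("every record needs a recommendation level", call. = FALSE)
  }
  x$recommendation_index <- as.integer(x$recommendation_index)
  for (nm in c("request_date", "assignment_date", "publication_date")) {
    x[[nm]] <- as.Date(x[[nm]])
  }
  bad_order <- (!is.na(x$request_date) & !is.na(x$assignment_date) &
    x$request_date > x$assignment_date) |
    (!is.na(x$assignment_date) & !is.na(x$publication_date) &
      x$assignment_date > x$publication_date)
  if (any(bad_order)) {
    stop(
      "dates must be ordered request <= assignment <= publication; bad row(s): ",
      paste(which(bad_order), collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(denominator_override)) {
    if (length(denominator_override) != 1 || is.na(denominator_override) ||
      denominator_override < 1 || denominator_override != floor(denominator_override)) {
      stop("denominator_override must be a positive integer", call. = FALSE)
    }
    attr(x, "denominator_override") <- as.integer(denominator_override)
  }
  class(x) <- c("vf_portfolio", class(x))
  x
}

portfolio_denominator <- function(portfolio) {
  attr(portfolio, "denominator_override") %||% nrow(portfolio)
}

#' Read / write a portfolio CSV
#'
#' The interchange format is one CSV row per recommendation with the
#' columns documented in [as_portfolio()] and ISO-8601 dates. Unknown extra
#' columns are preserved with a warning.
#'
#' @param path CSV file path.
#' @param denominator_override optional, see [as_portfolio()].
#' @return `read_portfolio()`: a `vf_portfolio`; `write_portfolio()`:
#'   `path`, invisibly.
#' @export
read_portfolio <- function(path, denominator_override = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  known <- c(
    "report_id", "recommendation_index", "technology_type", "clinical_area",
    "evidence", "benefit", "economics", "economics_skip_reason",
    "recommendation", "request_date", "assignment_date", "publication_date"
  )
  raw <- readr::read_csv(path, col_types = readr::cols(
    recommendation_index = readr::col_integer(),
    request_date = readr::col_date(),
    assignment_date = readr::col_date(),
    publication_date = readr::col_date(),
    .default = readr::col_character()
  ))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop("malformed portfolio row(s): ", paste(unique(prob$row), collapse = ", "),
      call. = FALSE
    )
  }
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    warning("preserving unknown portfolio column(s): ",
      paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  as_portfolio(raw, denominator_override = denominator_override)
}

#' @rdname read_portfolio
#' @param portfolio a `vf_portfolio` (or coercible data frame).
#' @export
write_portfolio <- function(portfolio, path) {
  out <- dplyr::mutate(
    tibble::as_tibble(portfolio),
    dplyr::across(dplyr::where(is.factor), as.character)
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Recommendation distribution of a portfolio
#'
#' Counts records per recommendation level and reports percentages at both
#' integer and one-decimal precision under half-up rounding. The
#' denominator is the record count unless the portfolio carries a
#' `denominator_override`.
#'
#' @param portfolio a `vf_portfolio`.
#' @return A `vf_summary` tibble: `recommendation`, `color`, `n`,
#'   `pct` (exact), `pct_integer`, `pct_1dp`, with attributes `denominator`
#'   and `denominator_overridden`.
#' @export
summarize_recommendations <- function(portfolio) {
  stopifnot(inherits(portfolio, "vf_portfolio"))
  if (nrow(portfolio) == 0) stop("empty portfolio", call. = FALSE)
  denom <- portfolio_denominator(portfolio)
  out <- tibble::as_tibble(tibble::new_tibble(portfolio)) |>
    dplyr::count(.data$recommendation, .drop = FALSE, name = "n") |>
    dplyr::mutate(
      color = unname(vf_rec_colors[as.character(.data$recommendation)]),
      pct = .data$n / denom * 100,
      pct_integer = round_half_up(.data$pct, 0),
      pct_1dp = round_half_up(.data$pct, 1),
      .after = "recommendation"
    ) |>
    dplyr::relocate("n", .after = "color")
  attr(out, "denominator") <- denom
  attr(out, "denominator_overridden") <- !is.null(attr(portfolio, "denominator_override"))
  class(out) <- c("vf_summary", class(out))
  out
}

#' Tabulate domain-combination patterns
#'
#' Exact counts per (evidence, benefit, economics, recommendation)
#' quadruple over the fully classified records, ordered by descending count
#' then lexical key. Records missing any domain are counted separately
#' under the `unclassifiable` attribute (with skip reasons where recorded),
#' never silently dropped.
#'
#' @param portfolio a `vf_portfolio`.
#' @return A tibble of combination counts; attribute `unclassifiable`
#'   holds the excluded-record count.
#' @export
tabulate_combinations <- function(portfolio) {
  stopifnot(inherits(portfolio, "vf_portfolio"))
  classifiable <- !is.na(portfolio$evidence) & !is.na(portfolio$benefit) &
    !is.na(portfolio$economics)
  out <- tibble::as_tibble(tibble::new_tibble(portfolio[classifiable, ])) |>
    dplyr::count(
      .data$evidence, .data$benefit, .data$economics, .data$recommendation,
      name = "n"
    ) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.factor), as.character)) |>
    dplyr::arrange(
      dplyr::desc(.data$n), .data$evidence, .data$benefit, .data$economics,
      .data$recommendation
    )
  attr(out, "unclassifiable") <- sum(!classifiable)
  out
}

#' Cross-tabulate a portfolio
#'
#' Counts by technology type x clinical area x recommendation, with the
#' (type, area) marginals attached. With `primary_only` each report
#' contributes only its main recommendation (`recommendation_index == 1`).
#'
#' @param portfolio a `vf_portfolio`.
#' @param primary_only logical.
#' @return A tibble of cell counts with attribute `marginals` (a tibble of
#'   per-(type, area) totals).
#' @export
crosstab_portfolio <- function(portfolio, primary_only = FALSE) {
  stopifnot(inherits(portfolio, "vf_portfolio"))
  records <- tibble::as_tibble(tibble::new_tibble(portfolio))
  if (isTRUE(primary_only)) {
    records <- dplyr::filter(records, .data$recommendation_index == 1L)
  }
  cells <- records |>
    dplyr::count(
      .data$technology_type, .data$clinical_area, .data$recommendation,
      name = "n"
    ) |>
    dplyr::mutate(recommendation = as.character(.data$recommendation)) |>
    dplyr::arrange(.data$technology_type, .data$clinical_area, .data$recommendation)
  marginals <- cells |>
    dplyr::summarise(
      n = sum(.data$n),
      .by = c("technology_type", "clinical_area")
    )
  attr(cells, "marginals") <- marginals
  cells
}

#' Production-timing statistics
#'
#' Medians and interquartile ranges, in days, of the request-to-assignment
#' and assignment-to-publication intervals. Quartiles use linear
#' interpolation between order statistics (`stats::quantile()` type 7),
#' which can yield fractional bounds. Records lacking the relevant date
#' pair are excluded and counted.
#'
#' @param portfolio a `vf_portfolio`.
#' @return A tibble with one row per interval: `interval`, `n`,
#'   `n_missing`, `median`, `q1`, `q3`.
#' @export
timing_stats <- function(portfolio) {
  stopifnot(inherits(portfolio, "vf_portfolio"))
  intervals <- list(
    request_to_assignment = as.numeric(portfolio$assignment_date - portfolio$request_date),
    assignment_to_publication = as.numeric(portfolio$publication_date - portfolio$assignment_date)
  )
  if (all(vapply(intervals, function(v) all(is.na(v)), logical(1)))) {
    stop("no records carry the dates needed for timing statistics", call. = FALSE)
  }
  purrr::imap(intervals, function(v, nm) {
    ok <- v[!is.na(v)]
    q <- if (length(ok) > 0) {
      stats::quantile(ok, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    } else {
      rep(NA_real_, 3)
    }
    tibble::tibble(
      interval = nm, n = length(ok), n_missing = sum(is.na(v)),
      median = q[2], q1 = q[1], q3 = q[3]
    )
  }) |>
    dplyr::bind_rows()
}
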