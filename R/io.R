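#' Read / write an appraisal worksheet (JSON)
#'
#' A worksheet is the JSON record of one appraisal: the outcome list with
#' evidence grades and benefit magnitudes, the deliberative adjustment
#' steps per domain, the economic inputs, and the economics-skip flag.
#' Scale members serialise as their uppercase names; adjustment traces as
#' ordered lists of `{delta, rationale, author}` objects.
#'
#' @param path JSON file path.
#' @return `read_worksheet()`: a list with `technology`, `outcomes`
#'   (tibble), the three adjustment tibbles, `economic_inputs` (list) and
#'   `skip_economics`; `write_worksheet()`: `path`, invisibly.
#' @export
read_worksheet <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ws <- list(
    technology = raw$technology %||% NA_character_,
    outcomes = tibble::as_tibble(raw$outcomes),
    evidence_adjustments = if (!is.null(raw$evidence_adjustments)) {
      tibble::as_tibble(raw$evidence_adjustments)
    },
    benefit_adjustments = if (!is.null(raw$benefit_adjustments)) {
      tibble::as_tibble(raw$benefit_adjustments)
    },
    recommendation_adjustments = if (!is.null(raw$recommendation_adjustments)) {
      tibble::as_tibble(raw$recommendation_adjustments)
    },
    economic_inputs = raw$economic_inputs,
    skip_economics = isTRUE(raw$skip_economics)
  )
  validate_outcomes(ws$outcomes)
  ws
}

#' @rdname read_worksheet
#' @param worksheet a worksheet list (see `read_worksheet()`).
#' @export
write_worksheet <- function(worksheet, path) {
  jsonlite::write_json(
    purrr::compact(worksheet[c(
      "technology", "outcomes", "evidence_adjustments", "benefit_adjustments",
      "recommendation_adjustments", "economic_inputs", "skip_economics"
    )]),
    path,
    auto_unbox = TRUE, pretty = TRUE, na = "null", null = "null"
  )
  invisible(path)
}

# metadata block embedded in every machine-readable CLI output: tool
# version, policy in effect, md5 digests of the inputs it was computed from
output_meta <- function(policy = NULL, inputs = character()) {
  inputs <- inputs[!is.na(inputs) & file.exists(inputs)]
  digests <- if (length(inputs) > 0) {
    as.list(stats::setNames(unname(tools::md5sum(inputs)), basename(inputs)))
  } else {
    NULL
  }
  purrr::compact(list(
    tool = "htavalue",
    version = as.character(utils::packageVersion("htavalue")),
    policy = policy,
    input_digests = digests
  ))
}

write_output_json <- function(x, path = NULL) {
  json <- jsonlite::toJSON(x,
    auto_unbox = TRUE, pretty = TRUE, na = "null", null = "null",
    dataframe = "rows", digits = NA
  )
  if (is.null(path)) cat(json, "\n") else writeLines(json, path)
  invisible(path)
}
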