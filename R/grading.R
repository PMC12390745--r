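#' Anchor-outcome grading of evidence quality and net benefit
#'
#' Both domains are graded by a global judgement: the grade of the single
#' most critical outcome (criticality rank 1 in the PICO question) is the
#' anchor, and structured deliberation about the remaining outcomes is
#' recorded as signed one-level adjustment steps, each with a mandatory
#' rationale. The result is the anchor shifted by the *sum* of the deltas,
#' clamped to the scale bounds, together with a full audit trace.
#'
#' `grade_net_benefit()` additionally enforces that an adjustment step
#' justified by a harm outcome (its `outcome` column names an outcome whose
#' `direction` is `"harm"`) can never raise the level.
#'
#' @param outcomes data frame of outcome assessments with columns `name`,
#'   `criticality_rank` (positive integers, unique, exactly one rank 1),
#'   `grade` (evidence-quality level), `benefit_magnitude` (net-benefit
#'   level) and `direction` (`"benefit"`, `"harm"` or `"neutral"`). Only the
#'   column the domain anchors on is required to be non-missing for the
#'   rank-1 outcome.
#' @param adjustments optional data frame of deliberative steps with columns
#'   `delta` (integer in -1/0/+1), `rationale` (non-empty text whenever
#'   `delta != 0`) and optionally `author` and `outcome` (name of the outcome
#'   motivating the step).
#' @return An object of class `vf_grade`: the graded level plus an audit
#'   trace. `tidy()` returns the trace as a tibble, `glance()` a one-row
#'   summary.
#' @examples
#' outs <- tibble::tibble(
#'   name = c("overall survival", "serious adverse events"),
#'   criticality_rank = c(1, 2),
#'   grade = c("HIGH", "MODERATE"),
#'   benefit_magnitude = c("MAJOR", NA),
#'   direction = c("benefit", "harm")
#' )
#' grade_evidence(outs, tibble::tibble(
#'   delta = -1, rationale = "inconsistency across secondary outcomes"
#' ))
#' @name grading
NULL

validate_outcomes <- function(outcomes) {
  if (is.null(outcomes) || !is.data.frame(outcomes) || nrow(outcomes) == 0) {
    stop("no anchor outcome: the outcome list is empty", call. = FALSE)
  }
  outcomes <- tibble::as_tibble(outcomes)
  required <- c("name", "criticality_rank")
  missing <- setdiff(required, names(outcomes))
  if (length(missing) > 0) {
    stop("outcomes are missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  rk <- outcomes$criticality_rank
  if (any(is.na(rk)) || any(rk < 1) || any(rk != floor(rk))) {
    stop("criticality_rank must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(rk)) {
    stop("criticality_rank values must be unique within a worksheet; ",
      "designate exactly one rank-1 anchor outcome",
      call. = FALSE
    )
  }
  if (sum(rk == 1) != 1) {
    stop("no anchor outcome: exactly one outcome must have criticality_rank 1",
      call. = FALSE
    )
  }
  outcomes
}

validate_adjustments <- function(adjustments, outcomes = NULL, harm_rule = FALSE) {
  if (is.null(adjustments) || (is.data.frame(adjustments) && nrow(adjustments) == 0)) {
    return(tibble::tibble(
      delta = integer(), rationale = character(),
      author = character(), outcome = character()
    ))
  }
  adjustments <- tibble::as_tibble(adjustments)
  if (!"delta" %in% names(adjustments)) {
    stop("adjustments need a `delta` column", call. = FALSE)
  }
  if (!"rationale" %in% names(adjustments)) adjustments$rationale <- NA_character_
  if (!"author" %in% names(adjustments)) adjustments$author <- NA_character_
  if (!"outcome" %in% names(adjustments)) adjustments$outcome <- NA_character_
  d <- adjustments$delta
  if (any(is.na(d)) || !all(d %in% c(-1L, 0L, 1L))) {
    stop("each adjustment step must have delta -1, 0 or +1", call. = FALSE)
  }
  adjustments$delta <- as.integer(d)
  no_reason <- adjustments$delta != 0 &
    (is.na(adjustments$rationale) | !nzchar(trimws(adjustments$rationale)))
  if (any(no_reason)) {
    stop("a rationale is mandatory for every adjustment with a non-zero delta",
      call. = FALSE
    )
  }
  if (harm_rule && !is.null(outcomes)) {
    harm_names <- outcomes$name[!is.na(outcomes$direction) & outcomes$direction == "harm"]
    bad <- adjustments$delta > 0 & !is.na(adjustments$outcome) &
      adjustments$outcome %in% harm_names
    if (any(bad)) {
      stop("an adjustment justified by a harm outcome cannot raise the level ",
        "(delta must be <= 0): ", paste(adjustments$outcome[bad], collapse = ", "),
        call. = FALSE
      )
    }
  }
  adjustments[c("delta", "rationale", "author", "outcome")]
}

anchor_grade <- function(outcomes, column, scale) {
  anchor <- outcomes[outcomes$criticality_rank == 1, ]
  if (!column %in% names(outcomes) || is.na(anchor[[column]][1])) {
    stop(sprintf("the rank-1 anchor outcome has no `%s`", column), call. = FALSE)
  }
  list(
    name = anchor$name[1],
    level = as_vf_level(anchor[[column]][1], scale)
  )
}

new_vf_grade <- function(domain, scale, anchor, adjustments) {
  anchor_rank <- level_rank(anchor$level, scale)
  max_rank <- length(vf_levels[[scale]]) - 1L
  net <- sum(adjustments$delta)
  result_rank <- max(0L, min(max_rank, anchor_rank + net))
  structure(
    list(
      domain = domain,
      result = as_vf_level(result_rank, scale),
      anchor_outcome = anchor$name,
      anchor_level = anchor$level,
      net_delta = as.integer(net),
      adjustments = adjustments
    ),
    class = "vf_grade"
  )
}

#' @rdname grading
#' @export
grade_evidence <- function(outcomes, adjustments = NULL) {
  outcomes <- validate_outcomes(outcomes)
  adjustments <- validate_adjustments(adjustments)
  anchor <- anchor_grade(outcomes, "grade", "evidence")
  new_vf_grade("evidence", "evidence", anchor, adjustments)
}

#' @rdname grading
#' @export
grade_net_benefit <- function(outcomes, adjustments = NULL) {
  outcomes <- validate_outcomes(outcomes)
  adjustments <- validate_adjustments(adjustments, outcomes, harm_rule = TRUE)
  anchor <- anchor_grade(outcomes, "benefit_magnitude", "benefit")
  new_vf_grade("benefit", "benefit", anchor, adjustments)
}

#' @export
print.vf_grade <- function(x, ...) {
  cat(sprintf(
    "<vf_grade> %s: %s\n  anchor: %s (%s), net adjustment %+d over %d step(s)\n",
    x$domain, as.character(x$result), x$anchor_outcome,
    as.character(x$anchor_level), x$net_delta, nrow(x$adjustments)
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname grading
#' @param x a `vf_grade` object.
#' @param ... unused.
#' @export
tidy.vf_grade <- function(x, ...) {
  steps <- x$adjustments
  tibble::tibble(
    step = seq_len(nrow(steps) + 1L) - 1L,
    action = c("anchor", rep("adjustment", nrow(steps))),
    delta = c(NA_integer_, steps$delta),
    rationale = c(
      sprintf("anchor outcome '%s'", x$anchor_outcome),
      steps$rationale
    ),
    author = c(NA_character_, steps$author),
    level_after = as_vf_level(
      pmin(
        length(vf_levels[[x$domain]]) - 1L,
        pmax(0L, level_rank(x$anchor_level) + cumsum(c(0L, steps$delta)))
      ),
      x$domain
    )
  )
}

#' @rdname grading
#' @export
glance.vf_grade <- function(x, ...) {
  tibble::tibble(
    domain = x$domain,
    result = as.character(x$result),
    anchor_outcome = x$anchor_outcome,
    anchor_level = as.character(x$anchor_level),
    net_delta = x$net_delta,
    n_steps = nrow(x$adjustments)
  )
}
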