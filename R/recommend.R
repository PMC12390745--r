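#' Coverage recommendation for one domain-score triple
#'
#' Looks up the matrix cell for the triple and applies the deliberative
#' adjustment: contextual factors outside the three formal domains (equity,
#' rare-disease status, ...) may shift the matrix output up or down by one
#' level, each step documented with a rationale. Multiple steps may be
#' logged but their net effect must be -1, 0 or +1.
#'
#' When the evidence is very low / null the economic domain may be skipped
#' (`skip_economics = TRUE`, the late-policy rule under which economics is
#' not evaluated because the evidence cannot support it); the lookup then
#' substitutes `UNCERTAIN` economics so the matrix stays total, and the
#' substitution is flagged in the trace. Skipping with any higher evidence
#' level is a validation error.
#'
#' @param evidence evidence-quality level (name, factor or `vf_grade`).
#' @param benefit net-benefit level (name, factor or `vf_grade`).
#' @param economics economic-impact level (name, factor or `vf_econ_class`);
#'   may be `NULL` when `skip_economics` is set.
#' @param matrix a `vf_matrix`; defaults to [default_matrix()].
#' @param adjustments optional data frame of deliberative steps (`delta`,
#'   `rationale`, optional `author`); net delta in -1/0/+1.
#' @param skip_economics logical; permitted only with `VERY_LOW_NULL`
#'   evidence.
#' @return A `vf_recommendation`: the recommendation level plus an audit
#'   trace (matrix cell, provenance, substitution, each adjustment step).
#'   `tidy()` returns the step trace, `glance()` a one-row summary.
#' @examples
#' recommend("MODERATE", "CONSIDERABLE", "FAVORABLE")
#' recommend("MODERATE", "MINOR", "UNCERTAIN",
#'   adjustments = tibble::tibble(delta = 1, rationale = "equity consideration")
#' )
#' @export
recommend <- function(evidence, benefit, economics = NULL,
                      matrix = default_matrix(), adjustments = NULL,
                      skip_economics = FALSE) {
  stopifnot(inherits(matrix, "vf_matrix"))
  if (inherits(evidence, "vf_grade")) evidence <- evidence$result
  if (inherits(benefit, "vf_grade")) benefit <- benefit$result
  if (inherits(economics, "vf_econ_class")) economics <- economics$impact
  e <- as_vf_level(evidence, "evidence")
  b <- as_vf_level(benefit, "benefit")

  substituted <- FALSE
  if (isTRUE(skip_economics)) {
    if (level_rank(e, "evidence") > 0L) {
      stop("the economic domain can only be skipped when evidence is ",
        "VERY_LOW_NULL; got ", as.character(e),
        call. = FALSE
      )
    }
    economics <- "UNCERTAIN"
    substituted <- TRUE
  }
  if (is.null(economics)) {
    stop("economics is required unless skip_economics = TRUE", call. = FALSE)
  }
  ec <- as_vf_level(economics, "economics")

  adjustments <- validate_adjustments(adjustments)
  net <- sum(adjustments$delta)
  if (abs(net) > 1) {
    stop("the deliberative process may shift the recommendation by at most ",
      "one level: net adjustment ", sprintf("%+d", net), " is not allowed",
      call. = FALSE
    )
  }

  cell <- matrix_cell(matrix, e, b, ec)
  cell_rank <- level_rank(cell$recommendation, "recommendation")
  final_rank <- max(0L, min(4L, cell_rank + net))
  structure(
    list(
      recommendation = as_vf_level(final_rank, "recommendation"),
      color = unname(vf_rec_colors[final_rank + 1L]),
      evidence = e, benefit = b, economics = ec,
      economics_skipped = substituted,
      matrix_recommendation = cell$recommendation,
      cell_provenance = cell$provenance,
      policy_name = matrix$policy_name,
      net_delta = as.integer(net),
      adjustments = adjustments
    ),
    class = "vf_recommendation"
  )
}

#' @export
print.vf_recommendation <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<vf_recommendation> %s (%s)\n",
      "  cell (%s, %s, %s%s) -> %s [%s, policy %s]\n",
      "  net deliberative adjustment %+d over %d step(s)\n"
    ),
    as.character(x$recommendation), x$color,
    as.character(x$evidence), as.character(x$benefit), as.character(x$economics),
    if (x$economics_skipped) ", substituted: economics skipped" else "",
    as.character(x$matrix_recommendation), x$cell_provenance, x$policy_name,
    x$net_delta, nrow(x$adjustments)
  ))
  invisible(x)
}

#' @rdname recommend
#' @param x a `vf_recommendation` object.
#' @param ... unused.
#' @export
tidy.vf_recommendation <- function(x, ...) {
  steps <- x$adjustments
  tibble::tibble(
    step = seq_len(nrow(steps) + 1L) - 1L,
    action = c("matrix_lookup", rep("adjustment", nrow(steps))),
    delta = c(NA_integer_, steps$delta),
    rationale = c(
      sprintf(
        "cell (%s, %s, %s)%s [%s]",
        as.character(x$evidence), as.character(x$benefit),
        as.character(x$economics),
        if (x$economics_skipped) " economics substituted UNCERTAIN (skip rule)" else "",
        x$cell_provenance
      ),
      steps$rationale
    ),
    author = c(NA_character_, steps$author),
    level_after = as_vf_level(
      pmin(4L, pmax(0L, level_rank(x$matrix_recommendation) + cumsum(c(0L, steps$delta)))),
      "recommendation"
    )
  )
}

#' @rdname recommend
#' @export
glance.vf_recommendation <- function(x, ...) {
  tibble::tibble(
    recommendation = as.character(x$recommendation),
    color = x$color,
    evidence = as.character(x$evidence),
    benefit = as.character(x$benefit),
    economics = as.character(x$economics),
    economics_skipped = x$economics_skipped,
    matrix_recommendation = as.character(x$matrix_recommendation),
    cell_provenance = x$cell_provenance,
    policy_name = x$policy_name,
    net_delta = x$net_delta
  )
}

#' Appraise a full worksheet
#'
#' Runs the whole pipeline on one appraisal worksheet: grade evidence
#' quality and net benefit from the outcome list, classify the economic
#' impact from the supplied economic figures (or apply the skip rule), and
#' look up the coverage recommendation with any deliberative adjustment.
#'
#' @param worksheet a worksheet list as returned by [read_worksheet()]:
#'   fields `outcomes` (data frame), optional `evidence_adjustments`,
#'   `benefit_adjustments`, `recommendation_adjustments` (data frames),
#'   `economic_inputs` (list of [economic_inputs()] arguments) and
#'   `skip_economics` (flag).
#' @param params a [country_parameters()] object.
#' @param matrix a `vf_matrix`; defaults to [default_matrix()].
#' @return A `vf_appraisal` list: the three `vf_grade` / `vf_econ_class`
#'   domain results and the final `vf_recommendation`.
#' @export
appraise <- function(worksheet, params, matrix = default_matrix()) {
  stopifnot(is.list(worksheet))
  ev <- grade_evidence(worksheet$outcomes, worksheet$evidence_adjustments)
  nb <- grade_net_benefit(worksheet$outcomes, worksheet$benefit_adjustments)
  skip <- isTRUE(worksheet$skip_economics)
  econ <- NULL
  if (!skip) {
    inputs <- do.call(economic_inputs, worksheet$economic_inputs %||% list())
    econ <- classify_economic_impact(inputs, params, nb)
  }
  rec <- recommend(
    evidence = ev, benefit = nb,
    economics = econ,
    matrix = matrix,
    adjustments = worksheet$recommendation_adjustments,
    skip_economics = skip
  )
  structure(
    list(
      evidence = ev, benefit = nb, economics = econ, recommendation = rec,
      technology = worksheet$technology %||% NA_character_
    ),
    class = "vf_appraisal"
  )
}

#' @export
print.vf_appraisal <- function(x, ...) {
  cat(sprintf(
    "<vf_appraisal>%s\n  evidence %s | benefit %s | economics %s\n  recommendation: %s (%s)\n",
    if (is.na(x$technology)) "" else paste0(" ", x$technology),
    as.character(x$evidence$result), as.character(x$benefit$result),
    if (is.null(x$economics)) "skipped (very low/null evidence)" else as.character(x$economics$impact),
    as.character(x$recommendation$recommendation), x$recommendation$color
  ))
  invisible(x)
}
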