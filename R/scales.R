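#' Ordinal scales of the value framework
#'
#' The framework scores a technology on three ordinal domains and maps the
#' triple to a five-level coverage recommendation:
#'
#' * **Evidence quality** (GRADE-adapted, global judgement anchored on the
#'   most critical outcome): `VERY_LOW_NULL < LOW < MODERATE < HIGH`.
#' * **Net benefit** (adapted from the IQWiG added-benefit categories):
#'   `MARGINAL_NULL_UNCERTAIN_NEGATIVE < MINOR < CONSIDERABLE < MAJOR`.
#' * **Economic impact**: `UNFAVORABLE < UNCERTAIN < FAVORABLE`.
#' * **Recommendation**: `STRONGLY_AGAINST < MODERATELY_AGAINST < UNCERTAIN <
#'   MODERATELY_IN_FAVOR < FULLY_IN_FAVOR`, colour-coded red, yellow-red,
#'   yellow, yellow-green, green.
#'
#' Levels are represented as ordered factors; ranks are 0-based integers
#' (`VERY_LOW_NULL` = 0, ..., `HIGH` = 3).
#'
#' @param x character vector of level names (case-insensitive), an ordered
#'   factor on the same levels, or an integer rank vector (0-based).
#' @return An ordered factor on the scale's levels. `NA` input stays `NA`.
#' @examples
#' evidence_quality("moderate")
#' net_benefit(c("MAJOR", "MINOR"))
#' recommendation_colors()
#' @name vf_scales
NULL

vf_levels <- list(
  evidence = c("VERY_LOW_NULL", "LOW", "MODERATE", "HIGH"),
  benefit = c("MARGINAL_NULL_UNCERTAIN_NEGATIVE", "MINOR", "CONSIDERABLE", "MAJOR"),
  economics = c("UNFAVORABLE", "UNCERTAIN", "FAVORABLE"),
  recommendation = c(
    "STRONGLY_AGAINST", "MODERATELY_AGAINST", "UNCERTAIN",
    "MODERATELY_IN_FAVOR", "FULLY_IN_FAVOR"
  )
)

vf_rec_colors <- c(
  STRONGLY_AGAINST = "red",
  MODERATELY_AGAINST = "yellow-red",
  UNCERTAIN = "yellow",
  MODERATELY_IN_FAVOR = "yellow-green",
  FULLY_IN_FAVOR = "green"
)

# hex used by the figure renderers, one per recommendation level
vf_rec_hex <- c(
  STRONGLY_AGAINST = "#D7191C",
  MODERATELY_AGAINST = "#F47D20",
  UNCERTAIN = "#FFD92F",
  MODERATELY_IN_FAVOR = "#A6D96A",
  FULLY_IN_FAVOR = "#1A9641"
)

as_vf_level <- function(x, scale, arg = scale) {
  levels <- vf_levels[[scale]]
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    bad <- !is.na(x) & (x < 0 | x > length(levels) - 1 | x != floor(x))
    if (any(bad)) {
      stop(sprintf(
        "invalid %s rank(s): %s (expected integers in 0..%d)",
        arg, paste(x[bad], collapse = ", "), length(levels) - 1
      ), call. = FALSE)
    }
    return(factor(levels[as.integer(x) + 1L], levels = levels, ordered = TRUE))
  }
  x <- toupper(trimws(as.character(x)))
  x[!nzchar(x)] <- NA_character_
  bad <- !is.na(x) & !x %in% levels
  if (any(bad)) {
    stop(sprintf(
      "unknown %s level(s): %s (expected one of %s)",
      arg, paste(unique(x[bad]), collapse = ", "), paste(levels, collapse = ", ")
    ), call. = FALSE)
  }
  factor(x, levels = levels, ordered = TRUE)
}

#' @rdname vf_scales
#' @export
evidence_quality <- function(x) as_vf_level(x, "evidence")

#' @rdname vf_scales
#' @export
net_benefit <- function(x) as_vf_level(x, "benefit")

#' @rdname vf_scales
#' @export
economic_impact <- function(x) as_vf_level(x, "economics")

#' @rdname vf_scales
#' @export
recommendation_level <- function(x) as_vf_level(x, "recommendation")

#' @rdname vf_scales
#' @export
recommendation_colors <- function() vf_rec_colors

#' 0-based rank of a scale level
#'
#' @param x an ordered factor produced by one of the scale constructors
#'   (or a character vector convertible by `scale`).
#' @param scale one of `"evidence"`, `"benefit"`, `"economics"`,
#'   `"recommendation"`; inferred from the factor levels when omitted.
#' @return integer vector of ranks, lowest level = 0.
#' @export
level_rank <- function(x, scale = NULL) {
  if (is.null(scale)) {
    if (!is.factor(x)) stop("supply `scale` for non-factor input", call. = FALSE)
    match_scale <- purrr::detect_index(vf_levels, ~ identical(.x, levels(x)))
    if (match_scale == 0) stop("factor levels match no framework scale", call. = FALSE)
    scale <- names(vf_levels)[match_scale]
  }
  as.integer(as_vf_level(x, scale)) - 1L
}
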