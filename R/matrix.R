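#' Additive score underlying the default recommendation matrix
#'
#' The default completion of the recommendation matrix is an additive
#' integer score over the three domains: one point per evidence level, two
#' per net-benefit level, and 0 / 1 / 4 points for unfavorable / uncertain /
#' favorable economics. Score bands then set the recommendation (see
#' [default_matrix()]). The weights are the smallest monotone integer
#' scheme consistent with every combination-to-recommendation mapping the
#' framework's implementation record documents.
#'
#' @param evidence,benefit,economics scale levels (names, ordered factors
#'   or 0-based ranks); vectorised.
#' @return Integer score(s) in 0..13.
#' @examples
#' score_cell("MODERATE", "CONSIDERABLE", "FAVORABLE") # 10
#' @export
score_cell <- function(evidence, benefit, economics) {
  e <- level_rank(as_vf_level(evidence, "evidence"), "evidence")
  b <- level_rank(as_vf_level(benefit, "benefit"), "benefit")
  ec <- level_rank(as_vf_level(economics, "economics"), "economics")
  econ_points <- c(0L, 1L, 4L)[ec + 1L]
  e + 2L * b + econ_points
}

# the combination -> recommendation mappings documented for the framework's
# implementation period; these cells carry provenance "paper_anchored"
anchored_cells <- function() {
  tibble::tribble(
    ~evidence, ~benefit, ~economics, ~recommendation,
    "VERY_LOW_NULL", "MARGINAL_NULL_UNCERTAIN_NEGATIVE", "UNCERTAIN", "STRONGLY_AGAINST",
    "LOW", "MARGINAL_NULL_UNCERTAIN_NEGATIVE", "UNCERTAIN", "STRONGLY_AGAINST",
    "MODERATE", "MARGINAL_NULL_UNCERTAIN_NEGATIVE", "UNCERTAIN", "STRONGLY_AGAINST",
    "LOW", "MINOR", "UNCERTAIN", "STRONGLY_AGAINST",
    "MODERATE", "MINOR", "UNCERTAIN", "MODERATELY_AGAINST",
    "LOW", "CONSIDERABLE", "UNCERTAIN", "MODERATELY_AGAINST",
    "HIGH", "MINOR", "UNCERTAIN", "MODERATELY_AGAINST",
    "MODERATE", "CONSIDERABLE", "UNCERTAIN", "UNCERTAIN",
    "MODERATE", "MAJOR", "UNCERTAIN", "MODERATELY_IN_FAVOR",
    "MODERATE", "CONSIDERABLE", "FAVORABLE", "FULLY_IN_FAVOR"
  )
}

new_vf_matrix <- function(cells, policy_name) {
  cells <- dplyr::arrange(cells, .data$evidence, .data$benefit, .data$economics)
  m <- structure(
    list(
      cells = cells,
      policy_name = policy_name,
      monotonicity_report = NULL
    ),
    class = "vf_matrix"
  )
  m$monotonicity_report <- validate_matrix(m)
  m
}

#' The package-default recommendation matrix
#'
#' Builds the total 4x4x3 matrix mapping every (evidence quality, net
#' benefit, economic impact) triple to a coverage recommendation. Each cell
#' is scored with [score_cell()] and banded: score <= 4 strongly against,
#' 5-6 moderately against, 7-8 uncertain, 9 moderately in favor, >= 10
#' fully in favor. Two gates then apply: a fully-in-favor recommendation
#' requires favorable economics *and* at least moderate evidence; cells
#' failing a gate are demoted to moderately in favor. Cells matching a
#' documented mapping carry provenance `paper_anchored`; the rest
#' `default_rule`. The default matrix is monotone in each domain (empty
#' [validate_matrix()] report).
#'
#' @return A `vf_matrix`: a list with `cells` (48-row tibble with columns
#'   `evidence`, `benefit`, `economics`, `recommendation`, `provenance`),
#'   `policy_name`, and `monotonicity_report`.
#' @examples
#' m <- default_matrix()
#' dplyr::filter(
#'   tidy(m),
#'   evidence == "HIGH", benefit == "MAJOR", economics == "FAVORABLE"
#' )
#' @export
default_matrix <- function() {
  grid <- tidyr::expand_grid(
    evidence = evidence_quality(vf_levels$evidence),
    benefit = net_benefit(vf_levels$benefit),
    economics = economic_impact(vf_levels$economics)
  )
  score <- score_cell(grid$evidence, grid$benefit, grid$economics)
  band <- cut(score,
    breaks = c(-Inf, 4, 6, 8, 9, Inf), labels = vf_levels$recommendation,
    right = TRUE
  )
  rec_rank <- as.integer(band) - 1L
  gate_fail <- rec_rank == 4L &
    (grid$economics != "FAVORABLE" | grid$evidence < "MODERATE")
  rec_rank[gate_fail] <- 3L
  cells <- grid
  cells$recommendation <- as_vf_level(rec_rank, "recommendation")
  anchored <- anchored_cells()
  key <- paste(cells$evidence, cells$benefit, cells$economics)
  cells$provenance <- ifelse(
    key %in% paste(anchored$evidence, anchored$benefit, anchored$economics),
    "paper_anchored", "default_rule"
  )
  new_vf_matrix(cells, policy_name = "additive_score_v1")
}

#' Load a recommendation matrix from CSV
#'
#' Reads a matrix file with header `evidence,benefit,economics,
#' recommendation` and uppercase scale-member names (the interchange format
#' for a full externally supplied matrix). Loaded cells carry provenance
#' `configured`; combinations absent from the file are filled from
#' [default_matrix()] with provenance `default_rule` and a warning.
#' Duplicate combinations or unknown scale names are errors.
#'
#' @param path CSV file path.
#' @return A `vf_matrix` (always total: 48 cells).
#' @export
load_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  needed <- c("evidence", "benefit", "economics", "recommendation")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop("matrix file is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  extra <- setdiff(names(raw), needed)
  if (length(extra) > 0) {
    warning("ignoring unknown matrix column(s): ", paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  cells <- tibble::tibble(
    evidence = evidence_quality(raw$evidence),
    benefit = net_benefit(raw$benefit),
    economics = economic_impact(raw$economics),
    recommendation = recommendation_level(raw$recommendation),
    provenance = "configured"
  )
  if (any(is.na(cells$evidence) | is.na(cells$benefit) | is.na(cells$economics) |
    is.na(cells$recommendation))) {
    stop("matrix file contains empty scale values", call. = FALSE)
  }
  key <- paste(cells$evidence, cells$benefit, cells$economics)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate matrix combination(s): ", paste(dup, collapse = "; "),
      call. = FALSE
    )
  }
  defaults <- default_matrix()$cells
  fill <- defaults[!paste(defaults$evidence, defaults$benefit, defaults$economics) %in% key, ]
  if (nrow(fill) > 0) {
    fill$provenance <- "default_rule"
    warning(sprintf(
      "matrix file covers %d of 48 combinations; %d filled from the default matrix",
      nrow(cells), nrow(fill)
    ), call. = FALSE)
    cells <- dplyr::bind_rows(cells, fill)
  }
  new_vf_matrix(cells, policy_name = paste0("configured:", basename(path)))
}

#' Write a recommendation matrix to CSV
#'
#' @param matrix a `vf_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "vf_matrix"))
  out <- dplyr::mutate(
    matrix$cells[c("evidence", "benefit", "economics", "recommendation")],
    dplyr::across(dplyr::everything(), as.character)
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Check a matrix for monotonicity violations
#'
#' A recommendation matrix is monotone when improving any single domain
#' (holding the others fixed) never lowers the recommendation. The report
#' lists every pair of cells ordered component-wise on (evidence, benefit,
#' economics) whose recommendations are strictly inverted.
#'
#' @param matrix a `vf_matrix`.
#' @return A tibble of violating cell pairs (zero rows when monotone).
#' @export
validate_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "vf_matrix"))
  cells <- matrix$cells
  if (nrow(cells) != 48) {
    stop("matrix is not total: expected 48 cells, found ", nrow(cells),
      call. = FALSE
    )
  }
  e <- level_rank(cells$evidence, "evidence")
  b <- level_rank(cells$benefit, "benefit")
  ec <- level_rank(cells$economics, "economics")
  r <- level_rank(cells$recommendation, "recommendation")
  n <- nrow(cells)
  lo <- rep(seq_len(n), each = n)
  hi <- rep(seq_len(n), times = n)
  dominated <- e[lo] <= e[hi] & b[lo] <= b[hi] & ec[lo] <= ec[hi] &
    (e[lo] < e[hi] | b[lo] < b[hi] | ec[lo] < ec[hi])
  inverted <- dominated & r[lo] > r[hi]
  idx_lo <- lo[inverted]
  idx_hi <- hi[inverted]
  tibble::tibble(
    lower_evidence = as.character(cells$evidence[idx_lo]),
    lower_benefit = as.character(cells$benefit[idx_lo]),
    lower_economics = as.character(cells$economics[idx_lo]),
    lower_recommendation = as.character(cells$recommendation[idx_lo]),
    higher_evidence = as.character(cells$evidence[idx_hi]),
    higher_benefit = as.character(cells$benefit[idx_hi]),
    higher_economics = as.character(cells$economics[idx_hi]),
    higher_recommendation = as.character(cells$recommendation[idx_hi])
  )
}

#' Look up one matrix cell
#'
#' @param matrix a `vf_matrix`.
#' @param evidence,benefit,economics scale levels.
#' @return One-row tibble: the cell with its provenance.
#' @export
matrix_cell <- function(matrix, evidence, benefit, economics) {
  stopifnot(inherits(matrix, "vf_matrix"))
  e <- as_vf_level(evidence, "evidence")
  b <- as_vf_level(benefit, "benefit")
  ec <- as_vf_level(economics, "economics")
  hit <- matrix$cells[
    matrix$cells$evidence == e & matrix$cells$benefit == b &
      matrix$cells$economics == ec,
  ]
  if (nrow(hit) != 1) {
    stop("matrix has no unique cell for the requested combination", call. = FALSE)
  }
  hit
}

#' @export
print.vf_matrix <- function(x, ...) {
  cat(sprintf(
    "<vf_matrix> policy '%s', %d cells, %d monotonicity violation(s)\n",
    x$policy_name, nrow(x$cells), nrow(x$monotonicity_report)
  ))
  print(dplyr::count(x$cells, .data$recommendation))
  invisible(x)
}

#' @rdname default_matrix
#' @param x a `vf_matrix` object.
#' @param ... unused.
#' @export
tidy.vf_matrix <- function(x, ...) x$cells

#' @rdname default_matrix
#' @export
glance.vf_matrix <- function(x, ...) {
  tibble::tibble(
    policy_name = x$policy_name,
    n_cells = nrow(x$cells),
    n_paper_anchored = sum(x$cells$provenance == "paper_anchored"),
    n_configured = sum(x$cells$provenance == "configured"),
    n_monotonicity_violations = nrow(x$monotonicity_report)
  )
}
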