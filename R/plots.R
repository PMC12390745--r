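#' Parallel-coordinates view of a portfolio
#'
#' One polyline per fully classified record across three categorical axes
#' (evidence quality, net benefit, economic impact), coloured by the
#' record's coverage recommendation using the framework's five colours.
#' Within each axis the levels are spread on a common 0-1 span so the
#' three scales (of 4, 4 and 3 levels) share the panel. Records missing
#' any domain are not drawn.
#'
#' @param portfolio a `vf_portfolio`.
#' @return A ggplot object; the polyline count per colour equals the
#'   portfolio's per-level record counts over classifiable records.
#' @export
plot_parallel_coordinates <- function(portfolio) {
  stopifnot(inherits(portfolio, "vf_portfolio"))
  df <- tibble::as_tibble(tibble::new_tibble(portfolio)) |>
    dplyr::filter(
      !is.na(.data$evidence), !is.na(.data$benefit), !is.na(.data$economics)
    )
  if (nrow(df) == 0) stop("no records with all three domains", call. = FALSE)
  long <- df |>
    dplyr::mutate(
      record = paste(.data$report_id, .data$recommendation_index),
      evidence_y = level_rank(.data$evidence, "evidence") / 3,
      benefit_y = level_rank(.data$benefit, "benefit") / 3,
      economics_y = level_rank(.data$economics, "economics") / 2
    ) |>
    dplyr::select("record", "recommendation", dplyr::ends_with("_y")) |>
    tidyr::pivot_longer(dplyr::ends_with("_y"),
      names_to = "axis", values_to = "y",
      names_pattern = "(.*)_y"
    ) |>
    dplyr::mutate(axis = factor(.data$axis,
      levels = c("evidence", "benefit", "economics"),
      labels = c("Evidence quality", "Net benefit", "Economic impact")
    ))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$axis, y = .data$y,
    group = .data$record, colour = .data$recommendation
  )) +
    ggplot2::geom_line(alpha = 0.35, linewidth = 0.5) +
    ggplot2::geom_point(size = 0.8, alpha = 0.5) +
    ggplot2::scale_colour_manual(
      values = vf_rec_hex, drop = FALSE, name = "Recommendation",
      labels = function(l) sprintf("%s (%s)", l, vf_rec_colors[l])
    ) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(
      x = NULL, y = "domain level (low to high)",
      title = "Domain classifications and coverage recommendations"
    ) +
    ggplot2::theme_minimal()
}

#' Area-by-technology recommendation grid
#'
#' Stacked counts of main recommendations (`recommendation_index == 1`)
#' per clinical area and technology type, coloured with the framework's
#' five recommendation colours. Empty area/type cells are simply blank.
#'
#' @param portfolio a `vf_portfolio`.
#' @return A ggplot object whose stacked totals agree with
#'   [crosstab_portfolio()] under `primary_only = TRUE`.
#' @export
plot_area_grid <- function(portfolio) {
  stopifnot(inherits(portfolio, "vf_portfolio"))
  df <- tibble::as_tibble(tibble::new_tibble(portfolio)) |>
    dplyr::filter(.data$recommendation_index == 1L)
  if (nrow(df) == 0) stop("no main recommendations to plot", call. = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$technology_type, fill = .data$recommendation
  )) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::facet_wrap(ggplot2::vars(.data$clinical_area)) +
    ggplot2::scale_fill_manual(
      values = vf_rec_hex, drop = FALSE, name = "Recommendation",
      labels = function(l) sprintf("%s (%s)", l, vf_rec_colors[l])
    ) +
    ggplot2::labs(
      x = "technology type", y = "reports (main recommendation)",
      title = "Recommendations by clinical area and technology type"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

render_figure <- function(plot, path, width = 9, height = 6) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("svg", "png")) {
    stop("figure path must end in .svg or .png", call. = FALSE)
  }
  if (!dir.exists(dirname(path))) {
    stop("cannot write figure: no such directory ", dirname(path), call. = FALSE)
  }
  if (ext == "svg") {
    ggplot2::ggsave(path, plot,
      device = grDevices::svg, width = width, height = height
    )
  } else {
    ggplot2::ggsave(path, plot, width = width, height = height, dpi = 150)
  }
  invisible(path)
}

#' Render portfolio figures to SVG or PNG
#'
#' Thin wrappers writing [plot_parallel_coordinates()] /
#' [plot_area_grid()] to disk; the format follows the file extension.
#'
#' @param portfolio a `vf_portfolio`.
#' @param path output file ending in `.svg` or `.png`.
#' @return `path`, invisibly.
#' @export
render_parallel_coordinates <- function(portfolio, path) {
  render_figure(plot_parallel_coordinates(portfolio), path)
}

#' @rdname render_parallel_coordinates
#' @export
render_area_grid <- function(portfolio, path) {
  render_figure(plot_area_grid(portfolio), path)
}
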