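#' Plot a mass-difference histogram
#'
#' Line plot of pair counts against the mass difference, on a square-root
#' count scale so minor recurring differences stay visible next to the
#' dominant isotope and adduct peaks.
#'
#' @param object a `delta_histogram` from [compute_delta_histogram()].
#' @param max_delta optional upper limit (Da) for the x axis.
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot delta_histogram
#' @export
autoplot.delta_histogram <- function(object, max_delta = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(max_delta)) df <- df[df$bin_center <= max_delta, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center, y = .data$count)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$bin_center, yend = 0),
                          linewidth = 0.3) +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = "m/z difference (Da)", y = "coeluting pairs",
                  title = "Mass differences among coeluting features") +
    ggplot2::theme_minimal()
}

#' Plot khipu composition
#'
#' Bar chart of feature roles assigned by the conservative pre-annotation.
#'
#' @param object a `khipu_annotation` from [preannotate()].
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot khipu_annotation
#' @export
autoplot.khipu_annotation <- function(object, ...) {
  df <- dplyr::count(object$roles, .data$role, name = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$role, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "features",
                  title = "Feature roles after khipu pre-annotation") +
    ggplot2::theme_minimal()
}

#' Plot the pipeline's abundance picture
#'
#' Dispatches to [plot_quantile_coverage()] on the pipeline's coverage curve.
#'
#' @param object a `preannotation_pipeline` from [run_pipeline()].
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot preannotation_pipeline
#' @export
autoplot.preannotation_pipeline <- function(object, ...) {
  plot_quantile_coverage(object$curve)
}

#' Coverage across abundance quantiles
#'
#' Step/point plot of the fraction of features pre-annotated within each
#' one-percent abundance slice, from least (1) to most (99) abundant.
#'
#' @param curve tibble from [quantile_coverage_curve()].
#' @return a ggplot object.
#' @export
plot_quantile_coverage <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$quantile, y = .data$coverage)) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::geom_line(linewidth = 0.3, na.rm = TRUE) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "intensity quantile (1 = lowest)",
                  y = "fraction pre-annotated",
                  title = "Annotation coverage by abundance") +
    ggplot2::theme_minimal()
}

#' Role composition per intensity quartile
#'
#' Stacked bar chart of the per-quartile role fractions.
#'
#' @param strata tibble from [stratified_annotation_summary()].
#' @return a ggplot object.
#' @export
plot_strata <- function(strata) {
  ggplot2::ggplot(strata,
                  ggplot2::aes(x = factor(.data$quartile), y = .data$fraction,
                               fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "intensity quartile (4 = highest)", y = "fraction",
                  fill = NULL,
                  title = "Annotation composition by intensity quartile") +
    ggplot2::theme_minimal()
}

#' Intensity distribution by final role
#'
#' Overlaid log10-intensity densities for each final feature role.
#'
#' @param table a [feature_table()].
#' @param annotation a `khipu_annotation`.
#' @param links optional ISF link tibble.
#' @return a ggplot object.
#' @export
plot_intensity_by_role <- function(table, annotation, links = NULL) {
  roles <- final_roles(annotation,
                       links %||% tibble::tibble(child = character(),
                                                 child_kind = character()))
  df <- tibble::tibble(
    log10_intensity = log10(table$intensity),
    role = roles$role[match(table$id, roles$feature_id)]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_intensity,
                                   colour = .data$role)) +
    ggplot2::geom_density(linewidth = 0.5) +
    ggplot2::labs(x = "log10 intensity", y = "density", colour = NULL,
                  title = "Intensity distribution by feature role") +
    ggplot2::theme_minimal()
}

#' RT-shift profile of in-source fragment links
#'
#' Bar chart of child-minus-parent retention time shifts; the modal bin is
#' highlighted.
#'
#' @param profile tibble from [rt_shift_profile()].
#' @return a ggplot object.
#' @export
plot_rt_shift_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$bin_center, y = .data$count,
                               fill = .data$is_mode)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#D55E00",
                                          `FALSE` = "grey40")) +
    ggplot2::labs(x = "RT shift, child - parent (s)", y = "links",
                  title = "Retention time shifts of in-source fragment links") +
    ggplot2::theme_minimal()
}
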