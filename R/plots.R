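# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_col
#'   geom_segment facet_wrap labs theme_minimal position_dodge
NULL

#' @export
ggplot2::autoplot

#' Bland-Altman plot
#'
#' Differences against pair means with the bias line and the 95% limits of
#' agreement.
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  s <- object$summary
  ggplot(object$data, aes(x = .data$mean, y = .data$diff)) +
    geom_point(alpha = 0.7) +
    geom_hline(yintercept = s$bias, linetype = 1, color = "steelblue") +
    geom_hline(yintercept = c(s$loa_low, s$loa_high), linetype = 2, color = "firebrick") +
    labs(x = "Mean of methods", y = "Difference (a - b)",
         title = sprintf("Bland-Altman: bias %.3g, LoA [%.3g, %.3g]",
                         s$bias, s$loa_low, s$loa_high)) +
    theme_minimal()
}

#' Plot a 2D film force map
#'
#' Film points positioned on the film plane, sized by force and colored by
#' contact area.
#'
#' @param object A [force_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.force_map <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$u_mm, y = .data$v_mm,
                                size = .data$force_N, color = .data$area_mm2)) +
    geom_point(alpha = 0.8) +
    ggplot2::coord_equal() +
    labs(x = "u (mm)", y = "v (mm)", size = "Force (N)", color = "Area (mm²)",
         title = "Pressure-film force record") +
    theme_minimal()
}

#' Per-tooth force profile
#'
#' Resultant and x/y/z component sums per tooth, the per-tooth view of a
#' whole-arch force analysis.
#'
#' @param per_tooth Tibble from [aggregate_by_tooth()].
#' @return A ggplot.
#' @export
plot_tooth_forces <- function(per_tooth) {
  long <- per_tooth |>
    dplyr::select("tooth", "resultant_N", "Fx", "Fy", "Fz") |>
    tidyr::pivot_longer(-"tooth", names_to = "component", values_to = "force_N") |>
    dplyr::mutate(component = factor(.data$component,
                                     levels = c("resultant_N", "Fx", "Fy", "Fz"),
                                     labels = c("Resultant", "Fx", "Fy", "Fz")))
  ggplot(long, aes(x = factor(.data$tooth), y = .data$force_N)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~component, scales = "free_y") +
    labs(x = "Tooth (FDI)", y = "Force (N)",
         title = "Per-tooth occlusal forces") +
    theme_minimal()
}

#' Regional force profile
#'
#' @param object A [regional_comparison()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.regional_report <- function(object, ...) {
  long <- object$regions |>
    dplyr::filter(.data$region != "unassigned") |>
    dplyr::select("region", "resultant_N", "abs_Fx", "abs_Fy", "abs_Fz") |>
    tidyr::pivot_longer(-"region", names_to = "measure", values_to = "force_N") |>
    dplyr::mutate(region = factor(.data$region, levels = c("anterior", "premolar", "molar")))
  ggplot(long, aes(x = .data$region, y = .data$force_N, fill = .data$measure)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "Force (N)", fill = NULL,
         title = "Regional occlusal loading") +
    theme_minimal()
}

#' Occlusal-plane overlay of contacts, film points and force glyphs
#'
#' Projected patch centroids, registered film points, and the matched
#' force vectors' horizontal components, in occlusal-plane coordinates.
#'
#' @param run An [run_pipeline()] result.
#' @return A ggplot.
#' @export
plot_overlay <- function(run) {
  proj <- project_to_plane(to_frame(
    cbind(run$patches$centroid_x, run$patches$centroid_y, run$patches$centroid_z),
    run$frame))
  pc <- tibble(x = proj[, 1], y = proj[, 2], what = "SA contact patch")
  pts <- as_tibble(run$forces)
  ggplot(pc, aes(x = .data$x, y = .data$y)) +
    geom_point(aes(shape = .data$what), size = 2) +
    geom_segment(data = pts,
                 aes(x = .data$base_x, y = .data$base_y,
                     xend = .data$base_x + .data$Fx, yend = .data$base_y + .data$Fy),
                 arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                 color = "firebrick") +
    ggplot2::coord_equal() +
    labs(x = "x anterior (mm)", y = "y patient-left (mm)", shape = NULL,
         title = "Occlusal-plane overlay with horizontal force components") +
    theme_minimal()
}
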