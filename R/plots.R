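#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted growth curve over its observations
#'
#' @param object A `growth_fit`.
#' @param n_grid Curve evaluation points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.growth_fit <- function(object, n_grid = 200, ...) {
  grid <- tibble::tibble(
    age = seq(min(object$data$age), max(object$data$age), length.out = n_grid)
  )
  grid$value <- growth_value(object$model, object$params, grid$age)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "Age (years)", y = "Trait value",
                  title = sprintf("%s fit (SSE %.3g)", object$model, object$sse)) +
    ggplot2::theme_minimal()
}

#' Plot genotype-class trajectories from a trajectory LR test
#'
#' Observed class means and the fitted per-class curves, with the pooled
#' fit dashed.
#'
#' @param object An `lr_test`.
#' @param n_grid Curve evaluation points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lr_test <- function(object, n_grid = 200, ...) {
  span <- range(object$pooled_fit$data$age)
  grid_t <- seq(span[1], span[2], length.out = n_grid)
  curves <- purrr::imap_dfr(object$class_fits, function(f, lab) {
    tibble::tibble(class = lab, age = grid_t,
                   value = growth_value(f$model, f$params, grid_t))
  })
  pts <- purrr::imap_dfr(object$class_fits, function(f, lab) {
    dplyr::mutate(
      dplyr::summarise(f$data, value = mean(.data$value), .by = "age"),
      class = lab
    )
  })
  pooled <- tibble::tibble(
    age = grid_t,
    value = growth_value(object$model, object$pooled_fit$params, grid_t)
  )
  ggplot2::ggplot(curves, ggplot2::aes(.data$age, .data$value, colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = pts) +
    ggplot2::geom_line(data = pooled, ggplot2::aes(.data$age, .data$value),
                       inherit.aes = FALSE, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = "Age (years)", y = "Trait value", colour = "Genotype",
      title = sprintf("SNP %s, %s: LR = %.2f, df = %d, p = %.3g",
                      object$snp, object$trait, object$lr, object$df, object$p)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an ontogenetic phase report
#'
#' Fitted class curves with the maximum-curvature phase boundary (solid
#' vertical) and the inflection age (dotted vertical) marked per class.
#'
#' @param class_fits Named list of `growth_fit` objects (as in
#'   [phase_report()]).
#' @param report Optional precomputed [phase_report()]; recomputed when
#'   `NULL`.
#' @param t_max Right edge of the plotted age axis; defaults to 1.5x the
#'   largest phase boundary (extrapolated regions shaded by line type).
#' @return A ggplot.
#' @export
plot_phases <- function(class_fits, report = NULL, t_max = NULL) {
  if (inherits(class_fits, "growth_fit")) class_fits <- list(all = class_fits)
  if (is.null(report)) report <- suppressWarnings(phase_report(class_fits))
  if (is.null(t_max)) t_max <- 1.5 * max(report$t_mc)
  grid_t <- seq(0, t_max, length.out = 300)
  curves <- purrr::imap_dfr(class_fits, function(f, lab) {
    tibble::tibble(class = lab, age = grid_t,
                   value = growth_value(f$model, f$params, grid_t),
                   extrapolated = grid_t > max(f$data$age))
  })
  ggplot2::ggplot(curves, ggplot2::aes(.data$age, .data$value, colour = .data$class)) +
    ggplot2::geom_line(ggplot2::aes(linetype = .data$extrapolated)) +
    ggplot2::geom_vline(data = report,
                        ggplot2::aes(xintercept = .data$t_mc, colour = .data$class)) +
    ggplot2::geom_vline(data = report[!is.na(report$t_max_growth), ],
                        ggplot2::aes(xintercept = .data$t_max_growth,
                                     colour = .data$class),
                        linetype = "dotted") +
    ggplot2::scale_linetype_manual(values = c(`FALSE` = "solid", `TRUE` = "longdash"),
                                   guide = "none") +
    ggplot2::labs(x = "Age (years)", y = "Trait value", colour = "Class",
                  title = "Rapid vs reduced growth phases (boundary = max curvature)") +
    ggplot2::theme_minimal()
}
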