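#' Plot a selection or fixation landscape
#'
#' Raster plot of the grid values over the two axis parameters.
#'
#' @param object A `landscape_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.landscape_grid <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data[[object$x_name]], y = .data[[object$y_name]],
    fill = .data[[object$quantity]]
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = object$x_name, y = object$y_name, fill = object$quantity,
      title = if (object$quantity == "s") {
        "Selection coefficient of expression-changing mutations"
      } else {
        "Fixation probability of expression-changing mutations"
      }
    )
}

#' Plot a stability distribution
#'
#' @param object A [stability_distribution()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_distribution <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$dg_kcal, y = .data$mass)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(Delta * G ~ "(kcal/mol)"),
                  y = "probability mass")
}

#' Plot the phases of a stability trajectory
#'
#' Early phases in light blue shading to dark; useful to see the drift from
#' the initial point mass towards the equilibrium distribution.
#'
#' @param object A `stability_trajectory`.
#' @param every Plot every `every`-th phase (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stability_trajectory <- function(object, every = 1, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$phase %% every == 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dg_kcal, y = .data$mass,
                                   group = .data$phase,
                                   colour = .data$phase)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = expression(Delta * G ~ "(kcal/mol)"),
                  y = "probability mass", colour = "phase")
}

#' Plot equilibrium distributions from a sweep
#'
#' @param sweep A tibble returned by [stability_sweep()].
#' @return A ggplot object with one curve per scenario value.
#' @export
plot_sweep <- function(sweep) {
  df <- sweep |>
    dplyr::mutate(curve = purrr::map(.data$distribution, tidy)) |>
    dplyr::select("scenario", "value", "curve") |>
    tidyr::unnest("curve")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dg_kcal, y = .data$mass,
                                   colour = factor(.data$value))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(Delta * G ~ "(kcal/mol)"),
                  y = "probability mass",
                  colour = unique(df$scenario))
}
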