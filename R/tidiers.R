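#' Tidy a landscape grid into a long tibble
#'
#' @param x A `landscape_grid`.
#' @param ... Unused.
#' @return A tibble with the two axis columns (named after the axes) and the
#'   grid quantity (`s` or `p_fix`).
#' @export
tidy.landscape_grid <- function(x, ...) {
  out <- tidyr::expand_grid(
    .y = x$y_values, .x = x$x_values
  )[, c(".x", ".y")]
  out[[x$quantity]] <- as.vector(x$values)
  names(out)[1:2] <- c(x$x_name, x$y_name)
  out
}

#' Tidy a stability distribution
#'
#' @param x A [stability_distribution()].
#' @param ... Unused.
#' @return A tibble with columns `dg_kcal` and `mass`.
#' @export
tidy.stability_distribution <- function(x, ...) {
  tibble::tibble(dg_kcal = x$grid, mass = x$pmf)
}

#' Tidy a stability trajectory
#'
#' @param x A `stability_trajectory`.
#' @param ... Unused.
#' @return A long tibble with columns `phase`, `dg_kcal`, `mass`.
#' @export
tidy.stability_trajectory <- function(x, ...) {
  tidyr::expand_grid(phase = 0:x$iterations, dg_kcal = x$grid) |>
    dplyr::mutate(mass = as.vector(t(x$phases)))
}

#' Tidy / summarise a stability equilibrium
#'
#' `tidy()` returns the equilibrium distribution as a tibble; `glance()`
#' returns a one-row summary (mode, mean, phases to convergence, the
#' KS-based convergence diagnostic, and the convergence flag).
#'
#' @param x A `stability_equilibrium`.
#' @param ... Unused.
#' @export
tidy.stability_equilibrium <- function(x, ...) {
  tidy.stability_distribution(x$distribution)
}

#' @rdname tidy.stability_equilibrium
#' @export
glance.stability_equilibrium <- function(x, ...) {
  tibble::tibble(
    mode_kcal = x$mode,
    mean_kcal = x$mean,
    iterations = x$iterations,
    ks_phase = ks_convergence_phase(x$trajectory, alpha = x$config$ks_alpha),
    converged = x$converged
  )
}

#' Tidy a Monte-Carlo trajectory
#'
#' @param x An `mc_trajectory`.
#' @param ... Unused.
#' @return A long tibble with columns `replicate`, `phase`, `dg_kcal`.
#' @export
tidy.mc_trajectory <- function(x, ...) {
  tidyr::expand_grid(replicate = seq_len(nrow(x$samples)),
                     phase = 0:(ncol(x$samples) - 1)) |>
    dplyr::mutate(dg_kcal = as.vector(t(x$samples)))
}
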