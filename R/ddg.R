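#' Bi-Gaussian distribution of mutational stability effects
#'
#' Mutational effects on folding free energy (ddG, kcal/mol, positive =
#' destabilising) are modelled as a two-component Gaussian mixture, the
#' components corresponding roughly to surface and core residues. The
#' component means and standard deviations default to the experimentally
#' derived values mu1 = 0.56, mu2 = 1.96, sigma1 = 0.90, sigma2 = 1.93
#' kcal/mol. The mixture weight `p1` on the milder (surface) component is
#' not experimentally pinned down; the default 0.7 puts the mixture mean
#' near 1 kcal/mol (~5 kJ/mol), the typical destabilisation of an arising
#' mutation.
#'
#' @param p1 Weight of the first component, in [0, 1].
#' @param mu1,mu2 Component means, kcal/mol.
#' @param sigma1,sigma2 Component standard deviations, kcal/mol (> 0).
#' @return An object of class `ddg_model`.
#' @examples
#' m <- ddg_model()
#' ddg_mean(m)
#' @export
ddg_model <- function(p1 = 0.7, mu1 = 0.56, mu2 = 1.96,
                      sigma1 = 0.90, sigma2 = 1.93) {
  if (p1 < 0 || p1 > 1) abort("`p1` must lie in [0, 1].")
  if (sigma1 <= 0 || sigma2 <= 0) abort("Component sigmas must be > 0.")
  structure(list(p1 = p1, mu1 = mu1, mu2 = mu2,
                 sigma1 = sigma1, sigma2 = sigma2),
            class = "ddg_model")
}

#' @export
print.ddg_model <- function(x, ...) {
  cat(sprintf(
    "<ddg_model> %.2f N(%.2f, %.2f^2) + %.2f N(%.2f, %.2f^2) kcal/mol (mean %.3f)\n",
    x$p1, x$mu1, x$sigma1, 1 - x$p1, x$mu2, x$sigma2, ddg_mean(x)))
  invisible(x)
}

#' Density, mean and sampling of the ddG mixture
#'
#' @param x ddG values, kcal/mol.
#' @param model A [ddg_model()].
#' @return `ddg_density()` the mixture density at `x`; `ddg_mean()` the
#'   analytic mixture mean `p1 mu1 + (1 - p1) mu2`.
#' @export
ddg_density <- function(x, model) {
  stopifnot(inherits(model, "ddg_model"))
  model$p1 * dnorm(x, model$mu1, model$sigma1) +
    (1 - model$p1) * dnorm(x, model$mu2, model$sigma2)
}

#' @rdname ddg_density
#' @export
ddg_mean <- function(model) {
  stopifnot(inherits(model, "ddg_model"))
  model$p1 * model$mu1 + (1 - model$p1) * model$mu2
}

#' @rdname ddg_density
#' @param n Number of draws.
#' @param seed Mandatory integer seed.
#' @export
ddg_sample <- function(model, n, seed) {
  stopifnot(inherits(model, "ddg_model"))
  if (missing(seed)) abort("`seed` is mandatory for reproducible sampling.")
  if (n < 1) abort("`n` must be >= 1.")
  withr::with_seed(seed, .ddg_draw(model, n))
}

# raw mixture draw using the current RNG state
.ddg_draw <- function(model, n) {
  first <- runif(n) < model$p1
  ifelse(first,
         rnorm(n, model$mu1, model$sigma1),
         rnorm(n, model$mu2, model$sigma2))
}
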