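#' Multi-compartment isotropic signal model
#'
#' A mixture of non-exchanging Gaussian compartments, each described by a
#' signal fraction `f` and an isotropic apparent diffusivity `D` (um^2/ms).
#' Under spherical tensor encoding the per-compartment signal is isotropic, so
#' the total signal is `S0 * sum_i f_i * exp(-b * D_i)`.
#'
#' @param f numeric vector of signal fractions; all >= 0, summing to 1
#'   (within 1e-9).
#' @param D numeric vector of diffusivities (um^2/ms), same length as `f`,
#'   all >= 0.
#' @param S0 non-diffusion-weighted signal (arbitrary units), > 0.
#' @return A `compartment_mixture` object.
#' @examples
#' gm <- compartment_mixture(c(0.2, 0.72, 0.08), c(3, 1, 0.1))
#' forward_signal(gm, c(0, 1500, 15000))
#' @export
compartment_mixture <- function(f, D, S0 = 1) {
  if (length(f) != length(D)) stop("`f` and `D` must have the same length")
  if (any(!is.finite(f)) || any(f < 0)) stop("all signal fractions must be finite and >= 0")
  if (abs(sum(f) - 1) > 1e-9) stop("signal fractions must sum to 1 (got ", sum(f), ")")
  if (any(!is.finite(D)) || any(D < 0)) stop("all diffusivities must be finite and >= 0")
  if (!is.finite(S0) || S0 <= 0) stop("`S0` must be finite and > 0")
  structure(list(f = as.numeric(f), D = as.numeric(D), S0 = as.numeric(S0)),
            class = "compartment_mixture")
}

#' Forward STE signal of a compartment mixture
#'
#' Evaluates `S0 * sum_i f_i * exp(-b * D_i)`. b-values are given in s/mm^2
#' and converted to ms/um^2 at this boundary (1000 s/mm^2 = 1 ms/um^2), so
#' diffusivities in um^2/ms plug in directly.
#'
#' @param model a [compartment_mixture()].
#' @param b numeric vector of b-values (s/mm^2), all >= 0.
#' @return numeric vector of signal values, one per element of `b`.
#' @export
forward_signal <- function(model, b) {
  if (!inherits(model, "compartment_mixture")) stop("`model` must be a compartment_mixture")
  if (any(!is.finite(b)) || any(b < 0)) stop("b-values must be finite and >= 0")
  bms <- b / 1000
  model$S0 * as.vector(exp(-outer(bms, model$D)) %*% model$f)
}

#' Sphere signal fraction
#'
#' The free-water-eliminated tissue signal fraction of the sphere compartment,
#' `fs = S0s / (ft * S0)`. Voxels where `ft * S0 <= 0` are undefined and return
#' `NA` rather than raising an error, so maps can be computed wholesale.
#'
#' @param S0s sphere-compartment signal at b = 0 (high-b fit intercept), >= 0.
#' @param ft tissue signal fraction from the free-water-elimination fit.
#' @param S0 b = 0 signal from the free-water-elimination fit.
#' @return `S0s / (ft * S0)`, vectorised; `NA` where `ft * S0 <= 0` or any
#'   input is not finite.
#' @export
compute_fs <- function(S0s, ft, S0) {
  n <- max(length(S0s), length(ft), length(S0))
  S0s <- rep_len(S0s, n); ft <- rep_len(ft, n); S0 <- rep_len(S0, n)
  if (any(S0s < 0, na.rm = TRUE)) stop("`S0s` must be >= 0")
  denom <- ft * S0
  ok <- is.finite(S0s) & is.finite(denom) & denom > 0
  out <- rep(NA_real_, n)
  out[ok] <- S0s[ok] / denom[ok]
  out
}
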