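#' Estimate the per-voxel Rician noise level
#'
#' Uses the repeated measurements of the highest-b shell, where the true
#' signal is smallest, and takes the sample standard deviation across repeats.
#' Where the repeat mean is below twice the raw SD the voxel is treated as
#' noise-floor dominated (Rayleigh regime) and the SD is rescaled by
#' `1/sqrt(2 - pi/2)`, the factor relating the magnitude SD of pure noise to
#' the underlying Gaussian sigma.
#'
#' @param dataset a [dwi_dataset()] whose highest-b shell has >= 3 repeats.
#' @return 3D array of per-voxel sigma estimates (signal units).
#' @export
estimate_sigma <- function(dataset) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  scheme <- dataset$scheme
  bmax <- max(scheme$b)
  idx <- which(scheme$b == bmax)
  if (length(idx) < 3) {
    stop("highest-b shell (b = ", bmax, ") has only ", length(idx),
         " repeats; >= 3 are needed to estimate sigma - supply a sigma_map instead")
  }
  shape <- dim(dataset$signal)[1:3]
  x <- matrix(dataset$signal, prod(shape), dim(dataset$signal)[4])[, idx, drop = FALSE]
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (length(idx) - 1))
  rayleigh <- s > 0 & m < 2 * s
  s[rayleigh] <- s[rayleigh] / sqrt(2 - pi / 2)
  array(s, dim = shape)
}

#' Rician noise-floor correction
#'
#' Method-of-moments magnitude correction: since `E[M^2] = A^2 + 2 sigma^2`
#' for a Rician magnitude M with underlying amplitude A, each measurement is
#' replaced by `sqrt(max(M^2 - 2 sigma^2, 0))`. This removes the artificial
#' signal plateau at high b; with sigma = 0 it is the identity.
#'
#' @param dataset a [dwi_dataset()].
#' @param sigma_map per-voxel noise level; defaults to the dataset's
#'   `sigma_map`, or [estimate_sigma()] when absent.
#' @return the corrected [dwi_dataset()] (sigma_map attached).
#' @export
rician_correct <- function(dataset, sigma_map = NULL) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  if (is.null(sigma_map)) sigma_map <- dataset$sigma_map
  if (is.null(sigma_map)) sigma_map <- estimate_sigma(dataset)
  if (any(!is.finite(sigma_map)) || any(sigma_map < 0)) {
    stop("`sigma_map` must be finite and >= 0")
  }
  shape <- dim(dataset$signal)[1:3]
  if (!all(dim(sigma_map) == shape)) stop("`sigma_map` must match the signal grid")
  nvol <- dim(dataset$signal)[4]
  m <- matrix(dataset$signal, prod(shape), nvol)
  corrected <- sqrt(pmax(m^2 - 2 * as.vector(sigma_map)^2, 0))
  out <- dwi_dataset(array(corrected, dim = c(shape, nvol)), dataset$scheme,
                     sigma_map = sigma_map, beff_map = dataset$beff_map,
                     voxel_size = dataset$voxel_size)
  out$rician_corrected <- TRUE
  out
}

#' Temporal signal drift correction
#'
#' Fits a polynomial (default quadratic) in acquisition index to the spatial
#' mean of the interleaved b0 volumes and divides every volume by the fitted
#' gain, normalised to 1 at the first b0. After correction the b0 means are
#' flat up to noise.
#'
#' @param dataset a [dwi_dataset()] with >= 3 b0 volumes.
#' @param order polynomial order, 1-3 (default 2).
#' @param allow_skip with fewer than 3 b0s, return the data uncorrected
#'   instead of erroring (explicit opt-in).
#' @return the corrected [dwi_dataset()]; the fitted per-volume gain is
#'   attached as attribute `"drift_gain"`.
#' @export
drift_correct <- function(dataset, order = 2, allow_skip = FALSE) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  if (!order %in% 1:3) stop("`order` must be 1, 2 or 3")
  scheme <- dataset$scheme
  b0 <- which(scheme$is_b0)
  if (length(b0) < 3) {
    if (allow_skip) return(dataset)
    stop("drift correction needs >= 3 interleaved b0 volumes (got ", length(b0),
         "); pass allow_skip = TRUE to leave the data uncorrected")
  }
  shape <- dim(dataset$signal)[1:3]
  nvol <- dim(dataset$signal)[4]
  m <- matrix(dataset$signal, prod(shape), nvol)
  b0_mean <- colMeans(m[, b0, drop = FALSE])
  t_all <- scheme$acq_index
  fit <- stats::lm(y ~ stats::poly(t, degree = order, raw = TRUE),
                   data = data.frame(y = b0_mean, t = t_all[b0]))
  gain <- stats::predict(fit, newdata = data.frame(t = t_all))
  gain <- gain / gain[b0[1]]
  if (any(gain <= 0)) stop("fitted drift gain is non-positive; data look degenerate")
  corrected <- sweep(m, 2, gain, "/")
  out <- dwi_dataset(array(corrected, dim = c(shape, nvol)), scheme,
                     sigma_map = dataset$sigma_map, beff_map = dataset$beff_map,
                     voxel_size = dataset$voxel_size)
  out$rician_corrected <- isTRUE(dataset$rician_corrected)
  attr(out, "drift_gain") <- gain
  out
}

#' Modified Z-score outlier report
#'
#' Robust outlier statistic `0.6745 * (x - median) / MAD` with
#' `MAD = median(|x - median|)`. When the MAD degenerates to zero the
#' mean-absolute-deviation fallback `0.7979 * (x - median) / meanAD` is used;
#' if that is also zero all scores are zero. Values whose absolute score
#' exceeds the threshold are flagged excluded.
#'
#' @param values numeric vector; fewer than 3 values yields an empty report
#'   (nothing scored, nothing excluded).
#' @param threshold exclusion threshold on |score| (default 3.5).
#' @return an `outlier_report`: list with `scores`, `excluded` and
#'   `threshold`.
#' @export
modified_zscore <- function(values, threshold = 3.5) {
  if (length(values) < 3) {
    return(structure(list(scores = numeric(0), excluded = logical(0),
                          threshold = threshold, n = length(values)),
                     class = "outlier_report"))
  }
  med <- stats::median(values)
  mad_ <- stats::median(abs(values - med))
  if (mad_ > 0) {
    scores <- 0.6745 * (values - med) / mad_
  } else {
    mean_ad <- mean(abs(values - med))
    scores <- if (mean_ad > 0) 0.7979 * (values - med) / mean_ad else rep(0, length(values))
  }
  structure(list(scores = scores, excluded = abs(scores) > threshold,
                 threshold = threshold, n = length(values)),
            class = "outlier_report")
}
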