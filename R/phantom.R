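#' Tissue-class mixtures for phantoms
#'
#' `default_tissue_classes()` returns realistic grey matter (a tri-exponential
#' with free-water, tissue and sphere compartments), white matter and CSF
#' mixtures. `exact_tissue_classes()` returns two-compartment mixtures
#' (free water at `d_fw` plus a single low-diffusivity compartment) that lie
#' exactly inside the generative family of both regime fits, so noiseless
#' phantoms built from them are recovered to machine precision; in this family
#' the tissue compartment is itself the sphere, hence truth fs = 1.
#'
#' @param d_fw free-water diffusivity (um^2/ms).
#' @return named list of [compartment_mixture()] objects (GM, WM, CSF).
#' @export
default_tissue_classes <- function(d_fw = 3) {
  list(
    GM = compartment_mixture(c(0.2, 0.72, 0.08), c(d_fw, 1, 0.1)),
    WM = compartment_mixture(c(0.1, 0.87, 0.03), c(d_fw, 0.8, 0.1)),
    CSF = compartment_mixture(1, d_fw)
  )
}

#' @rdname default_tissue_classes
#' @export
exact_tissue_classes <- function(d_fw = 3) {
  list(
    GM = compartment_mixture(c(0.2, 0.8), c(d_fw, 0.1)),
    WM = compartment_mixture(c(0.1, 0.9), c(d_fw, 0.07)),
    CSF = compartment_mixture(c(0.95, 0.05), c(d_fw, 0.4))
  )
}

# ground-truth parameters implied by a mixture: free water = compartments at
# D == d_fw; sphere = lowest-D tissue compartment
truth_of_mixture <- function(mix, d_fw = 3, S0 = 1) {
  fw <- abs(mix$D - d_fw) < 1e-9
  ft <- sum(mix$f[!fw])
  if (ft <= 0) {
    return(list(MD = NA_real_, ft = 0, fs = NA_real_, Ds = NA_real_,
                S0 = S0 * mix$S0, S0s = NA_real_))
  }
  ti <- which(!fw)
  sphere <- ti[which.min(mix$D[ti])]
  list(
    MD = sum(mix$f[ti] * mix$D[ti]) / ft,
    ft = ft,
    fs = mix$f[sphere] / ft,
    Ds = mix$D[sphere],
    S0 = S0 * mix$S0,
    S0s = S0 * mix$S0 * mix$f[sphere]
  )
}

#' Concentric lobule-labelled phantom geometry
#'
#' A spherical phantom: white-matter core, grey-matter shell carved into ten
#' lobule labels (nine angular sectors plus a deliberately small polar cap for
#' lobule X, so the flocculonodular small-ROI rule is exercisable), and a CSF
#' rim. Anything outside the rim is background (class 0, label 0).
#'
#' @param shape integer vector of 3 grid dimensions.
#' @return list with integer arrays `class_id` (1 = GM, 2 = WM, 3 = CSF,
#'   0 = background) and `labels` (lobules 1-10 on GM voxels, 0 elsewhere).
#' @export
default_phantom_geometry <- function(shape = c(24, 24, 24)) {
  stopifnot(length(shape) == 3, all(shape >= 8))
  cx <- (shape + 1) / 2
  rmax <- min(shape) / 2 - 0.5
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]), z = seq_len(shape[3]))
  dx <- (g$x - cx[1]) / rmax; dy <- (g$y - cx[2]) / rmax; dz <- (g$z - cx[3]) / rmax
  r <- sqrt(dx^2 + dy^2 + dz^2)
  class_id <- integer(nrow(g))
  class_id[r <= 1] <- 3L                  # CSF rim
  class_id[r <= 0.88] <- 1L               # GM shell
  class_id[r <= 0.52] <- 2L               # WM core
  labels <- integer(nrow(g))
  gm <- class_id == 1L
  cz <- ifelse(r > 0, dz / r, 0)
  cap <- gm & cz < -0.99                  # small lobule X cap
  theta <- atan2(dy, dx)                  # (-pi, pi]
  sector <- pmin(9L, 1L + as.integer(floor((theta + pi) / (2 * pi) * 9)))
  labels[gm] <- sector[gm]
  labels[cap] <- 10L
  list(class_id = array(class_id, dim = shape),
       labels = array(labels, dim = shape))
}

#' Phantom specification
#'
#' Describes the synthetic object the generator builds: geometry, per-class
#' compartment mixtures, Rician noise level, and a slow multiplicative signal
#' drift over the acquisition.
#'
#' @param shape grid dimensions (voxels).
#' @param classes named list of [compartment_mixture()] per tissue class, in
#'   class-id order (1, 2, 3, ...); see [default_tissue_classes()].
#' @param geometry optional list with `class_id` and `labels` arrays on
#'   `shape`; defaults to [default_phantom_geometry()].
#' @param S0 non-diffusion-weighted signal level (arbitrary units).
#' @param sigma Rician noise level as a fraction of `S0` (default 1/50, i.e.
#'   SNR 50 at b = 0).
#' @param drift polynomial coefficients `c(a0, a1, a2, ...)` of the gain over
#'   normalised acquisition position t in [0, 1]; the default
#'   `c(1, 0, -0.05)` decays quadratically from 1 to 0.95 across the scan.
#'   The gain must stay > 0.
#' @param d_fw free-water diffusivity used to identify the free-water
#'   compartment in the ground truth (um^2/ms).
#' @param seed integer seed for the noise draw.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c(24, 24, 24),
                         classes = default_tissue_classes(),
                         geometry = NULL,
                         S0 = 100, sigma = 1 / 50,
                         drift = c(1, 0, -0.05),
                         d_fw = 3, seed = 1L) {
  if (is.null(geometry)) geometry <- default_phantom_geometry(shape)
  stopifnot(all(dim(geometry$class_id) == shape), all(dim(geometry$labels) == shape))
  ids <- sort(unique(as.integer(geometry$class_id[geometry$class_id > 0])))
  if (length(ids) == 0) stop("phantom geometry labels no voxels")
  if (max(ids) > length(classes)) {
    stop("geometry uses class id ", max(ids), " but only ", length(classes),
         " tissue classes are defined")
  }
  if (!is.finite(sigma) || sigma < 0) stop("`sigma` must be >= 0")
  tt <- seq(0, 1, length.out = 101)
  if (any(polyval(drift, tt) <= 0)) stop("drift gain must stay > 0 over the scan")
  structure(list(shape = shape, classes = classes, geometry = geometry,
                 S0 = S0, sigma = sigma, drift = drift, d_fw = d_fw,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

polyval <- function(coefs, t) {
  out <- 0
  for (i in seq_along(coefs)) out <- out + coefs[i] * t^(i - 1)
  out
}

drift_gain <- function(drift, acq_index) {
  n <- max(acq_index)
  t <- if (n > 1) (acq_index - 1) / (n - 1) else rep(0, length(acq_index))
  polyval(drift, t)
}

#' Generate a phantom dataset with ground truth
#'
#' Each voxel's noiseless signal is the forward model of its tissue-class
#' mixture, multiplied by the drift gain at its acquisition position, then
#' Rician-corrupted: `M = |S + e1 + i e2|` with `e ~ N(0, sigma^2)`. The
#' returned truth maps hold the generating parameters: MD (fraction-weighted
#' tissue diffusivity), ft (1 - free-water fraction), fs (sphere fraction /
#' ft), Ds (sphere diffusivity), S0 and S0s.
#'
#' @param spec a [phantom_spec()].
#' @param scheme an `acq_scheme`.
#' @return list with `dataset` (a [dwi_dataset()] carrying the true
#'   `sigma_map`), `truth` (list of 3D parameter arrays), `labels` and
#'   `class_id` arrays.
#' @export
generate_phantom <- function(spec, scheme) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_scheme(scheme)
  shape <- spec$shape
  nvol <- nrow(scheme)
  nvox <- prod(shape)
  cid <- as.integer(spec$geometry$class_id)
  gain <- drift_gain(spec$drift, scheme$acq_index)

  sig <- matrix(0, nvox, nvol)
  truth_names <- c("MD", "ft", "fs", "Ds", "S0", "S0s")
  truth <- lapply(truth_names, function(nm) array(NA_real_, dim = shape))
  names(truth) <- truth_names
  for (id in sort(unique(cid[cid > 0]))) {
    mix <- spec$classes[[id]]
    base <- spec$S0 * forward_signal(mix, scheme$b) * gain
    vox <- which(cid == id)
    sig[vox, ] <- matrix(base, length(vox), nvol, byrow = TRUE)
    tr <- truth_of_mixture(mix, d_fw = spec$d_fw, S0 = spec$S0)
    for (nm in truth_names) truth[[nm]][vox] <- tr[[nm]]
  }
  if (spec$sigma > 0) {
    s <- spec$sigma * spec$S0
    sig <- with_seed(spec$seed, {
      e1 <- matrix(stats::rnorm(nvox * nvol, 0, s), nvox, nvol)
      e2 <- matrix(stats::rnorm(nvox * nvol, 0, s), nvox, nvol)
      sqrt((sig + e1)^2 + e2^2)
    })
  }
  dataset <- dwi_dataset(array(sig, dim = c(shape, nvol)), scheme,
                         sigma_map = array(spec$sigma * spec$S0, dim = shape))
  list(dataset = dataset, truth = truth,
       labels = spec$geometry$labels, class_id = spec$geometry$class_id)
}
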