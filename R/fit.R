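#' Fit configuration
#'
#' Tunable parameters of the two-regime decay fit.
#'
#' @param lowb_max low-b regime cutoff (s/mm^2); shells with b <= this (plus
#'   b0) feed the free-water-elimination fit. Default 1500.
#' @param highb_min high-b regime cutoff (s/mm^2); shells with b >= this feed
#'   the sphere fit. Default 10000.
#' @param d_fw fixed free-water diffusivity (um^2/ms). Default 3.
#' @param ds_bounds bounds on the sphere diffusivity Ds (um^2/ms).
#' @param md_bounds bounds on the tissue MD (um^2/ms).
#' @param zmax modified Z-score exclusion threshold. Default 3.5.
#' @param maxit maximum Levenberg-Marquardt iterations.
#' @param ftol,ptol convergence tolerances on the cost and the parameters.
#' @return a `fit_config` list.
#' @export
fit_config <- function(lowb_max = 1500, highb_min = 10000, d_fw = 3,
                       ds_bounds = c(0, 1), md_bounds = c(0, 3),
                       zmax = 3.5, maxit = 200, ftol = 1e-13, ptol = 1e-13) {
  if (lowb_max >= highb_min) stop("`lowb_max` must be < `highb_min`")
  if (d_fw <= 0) stop("`d_fw` must be > 0")
  structure(list(lowb_max = lowb_max, highb_min = highb_min, d_fw = d_fw,
                 ds_bounds = ds_bounds, md_bounds = md_bounds, zmax = zmax,
                 maxit = maxit, ftol = ftol, ptol = ptol),
            class = "fit_config")
}

lm_control <- function(config) {
  minpack.lm::nls.lm.control(maxiter = config$maxit, ftol = config$ftol,
                             ptol = config$ptol)
}

not_converged <- function(names) {
  out <- as.list(rep(NA_real_, length(names)))
  names(out) <- names
  c(out, list(converged = FALSE))
}

#' High-b mono-exponential sphere fit
#'
#' Nonlinear least squares of `S0s * exp(-b * Ds)` on the high-b shells,
#' where only the sphere ("dot") compartment retains signal. Initialised from
#' a log-linear regression on the positive signals; bounded `S0s >= 0`,
#' `Ds` within `config$ds_bounds` (default \[0, 1\] um^2/ms).
#'
#' @param signals numeric vector of signal values.
#' @param b matching b-values (s/mm^2), already restricted to the high-b
#'   regime.
#' @param config a [fit_config()].
#' @return list with `S0s`, `Ds` and a `converged` flag (degenerate input,
#'   e.g. all-zero signal or a single shell, yields `converged = FALSE`
#'   rather than an error).
#' @export
fit_highb_monoexp <- function(signals, b, config = fit_config()) {
  ok <- is.finite(signals) & is.finite(b)
  signals <- signals[ok]; b <- b[ok]
  if (length(signals) < 2 || length(unique(b)) < 2 || all(signals <= 0)) {
    return(not_converged(c("S0s", "Ds")))
  }
  bms <- b / 1000
  lo <- c(0, config$ds_bounds[1])
  hi <- c(Inf, config$ds_bounds[2])
  pos <- signals > 0
  if (sum(pos) >= 2 && length(unique(bms[pos])) >= 2) {
    cf <- stats::coef(stats::lm.fit(cbind(1, bms[pos]), log(signals[pos])))
    init <- c(exp(cf[1]), min(max(-cf[2], lo[2]), hi[2]))
  } else {
    init <- c(min(signals[pos]), 0.1)
  }
  res <- minpack.lm::nls.lm(
    par = init, lower = lo, upper = hi,
    fn = function(p) p[1] * exp(-bms * p[2]) - signals,
    control = lm_control(config))
  list(S0s = unname(res$par[1]), Ds = unname(res$par[2]),
       converged = res$info %in% 1:4)
}

#' Low-b bi-exponential free-water-elimination fit
#'
#' Nonlinear least squares of
#' `S0 * (ft * exp(-b * MD) + (1 - ft) * exp(-b * D_fw))` on the low-b shells
#' (b0 included), with the free-water diffusivity fixed at `config$d_fw`
#' (default 3 um^2/ms). Bounds: `ft` in \[0, 1\], `MD` within
#' `config$md_bounds` (default \[0, 3\] um^2/ms), `S0 > 0`. Initialisation:
#' `ft = 0.9`, MD from the log-linear slope, S0 from the b0 mean.
#'
#' @inheritParams fit_highb_monoexp
#' @return list with `S0`, `ft`, `MD` and a `converged` flag.
#' @export
fit_lowb_freewater <- function(signals, b, config = fit_config()) {
  ok <- is.finite(signals) & is.finite(b)
  signals <- signals[ok]; b <- b[ok]
  if (length(unique(b)) < 3 || all(signals <= 0)) {
    return(not_converged(c("S0", "ft", "MD")))
  }
  bms <- b / 1000
  s0_init <- if (any(b == 0)) mean(signals[b == 0]) else max(signals)
  if (s0_init <= 0) return(not_converged(c("S0", "ft", "MD")))
  pos <- signals > 0
  md_init <- 1
  if (sum(pos) >= 2 && length(unique(bms[pos])) >= 2) {
    cf <- stats::coef(stats::lm.fit(cbind(1, bms[pos]), log(signals[pos])))
    md_init <- min(max(-cf[2], config$md_bounds[1]), config$md_bounds[2])
  }
  res <- minpack.lm::nls.lm(
    par = c(s0_init, 0.9, md_init),
    lower = c(1e-12, 0, config$md_bounds[1]),
    upper = c(Inf, 1, config$md_bounds[2]),
    fn = function(p) p[1] * (p[2] * exp(-bms * p[3]) +
                             (1 - p[2]) * exp(-bms * config$d_fw)) - signals,
    control = lm_control(config))
  list(S0 = unname(res$par[1]), ft = unname(res$par[2]),
       MD = unname(res$par[3]), converged = res$info %in% 1:4)
}

#' Voxelwise two-regime parameter mapping
#'
#' Runs the full per-voxel estimation: per-shell modified Z-score outlier
#' exclusion (shells with >= 3 repeats), averaging of the surviving b0
#' volumes into a single b = 0 datum, the low-b free-water-elimination fit,
#' the high-b sphere fit, and `fs = S0s / (ft * S0)`. When the dataset
#' carries a `beff_map`, each voxel's nominal b-values are scaled by its
#' effective-b factor before fitting. Deterministic given its inputs.
#'
#' Noise-floor handling: when the dataset carries a `sigma_map` (and has not
#' already been through [rician_correct()]), the low-b/b0 values receive the
#' elementwise magnitude correction while each high-b shell is collapsed to
#' its noise-floor-corrected quadratic mean `sqrt(max(mean(M^2) - 2 sigma^2,
#' 0))` over the surviving repeats. The second moment `E[M^2] = A^2 +
#' 2 sigma^2` is exact at every SNR, so the shell representatives stay
#' unbiased even where the top shells approach the noise floor and the
#' elementwise correction would be biased low. Without noise information the
#' high-b shells are collapsed to their plain means.
#'
#' @param dataset a drift-corrected [dwi_dataset()]; pass the uncorrected
#'   magnitudes plus a `sigma_map` and let the internal noise-floor handling
#'   run, or data already through [rician_correct()] (then flagged and not
#'   re-corrected).
#' @param config a [fit_config()].
#' @param mask optional logical 3D array; voxels outside it are left `NA`.
#' @return a `param_maps` list of 3D arrays: `MD`, `ft`, `S0`, `S0s`, `Ds`,
#'   `fs`, outlier counts `n_excluded_lowb` / `n_excluded_highb`, and flags
#'   `converged_low` / `converged_high`. Voxels failing either fit carry
#'   non-finite parameters; `fs` is set only where both fits converged and
#'   `ft * S0 > 0`.
#' @export
fit_voxelwise <- function(dataset, config = fit_config(), mask = NULL) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  check_scheme_fittable(dataset$scheme, config)
  scheme <- dataset$scheme
  shape <- dim(dataset$signal)[1:3]
  nvol <- nrow(scheme)
  if (is.null(mask)) {
    vox <- seq_len(prod(shape))
  } else {
    stopifnot(all(dim(mask) == shape))
    vox <- which(mask)
  }
  sig <- matrix(dataset$signal, prod(shape), nvol)
  beff <- if (is.null(dataset$beff_map)) rep(1, prod(shape)) else as.vector(dataset$beff_map)
  correct <- !isTRUE(dataset$rician_corrected) && !is.null(dataset$sigma_map)
  sigma <- if (correct) as.vector(dataset$sigma_map) else rep(0, prod(shape))

  b0_idx <- which(scheme$is_b0)
  shell_idx <- split(seq_len(nvol), scheme$b)
  low_dwi <- which(!scheme$is_b0 & scheme$b <= config$lowb_max)
  high_b <- sort(unique(scheme$b[scheme$b >= config$highb_min]))
  high_shells <- lapply(high_b, function(bb) which(scheme$b == bb))
  high_all <- unlist(high_shells)

  maps <- c("MD", "ft", "S0", "S0s", "Ds", "fs",
            "n_excluded_lowb", "n_excluded_highb")
  out <- lapply(maps, function(nm) array(NA_real_, dim = shape))
  names(out) <- maps
  out$converged_low <- array(FALSE, dim = shape)
  out$converged_high <- array(FALSE, dim = shape)

  for (v in vox) {
    y <- sig[v, ]
    excl <- logical(nvol)
    for (sh in shell_idx) {
      if (length(sh) >= 3) {
        rep_ <- modified_zscore(y[sh], config$zmax)
        excl[sh[rep_$excluded]] <- TRUE
      }
    }
    b_v <- scheme$b * beff[v]
    s2 <- 2 * sigma[v]^2

    b0_keep <- b0_idx[!excl[b0_idx]]
    if (length(b0_keep) == 0) b0_keep <- b0_idx
    b0_val <- mean(sqrt(pmax(y[b0_keep]^2 - s2, 0)))

    low_keep <- low_dwi[!excl[low_dwi]]
    low_val <- sqrt(pmax(y[low_keep]^2 - s2, 0))
    fl <- fit_lowb_freewater(c(b0_val, low_val), c(0, b_v[low_keep]), config)

    high_y <- high_bv <- numeric(0)
    for (k in seq_along(high_shells)) {
      keep <- high_shells[[k]][!excl[high_shells[[k]]]]
      if (length(keep) == 0) next
      high_y <- c(high_y, sqrt(max(mean(y[keep]^2) - s2, 0)))
      high_bv <- c(high_bv, high_b[k] * beff[v])
    }
    fh <- fit_highb_monoexp(high_y, high_bv, config)

    out$n_excluded_lowb[v] <- sum(excl[c(b0_idx, low_dwi)])
    out$n_excluded_highb[v] <- sum(excl[high_all])
    out$converged_low[v] <- fl$converged
    out$converged_high[v] <- fh$converged
    if (fl$converged) {
      out$MD[v] <- fl$MD; out$ft[v] <- fl$ft; out$S0[v] <- fl$S0
    }
    if (fh$converged) {
      out$S0s[v] <- fh$S0s; out$Ds[v] <- fh$Ds
    }
    if (fl$converged && fh$converged) {
      out$fs[v] <- compute_fs(fh$S0s, fl$ft, fl$S0)
    }
  }
  structure(out, class = "param_maps", config = config)
}

#' Write parameter maps as NIfTI volumes
#'
#' One 3D NIfTI per parameter (`MD.nii.gz`, `ft.nii.gz`, `S0.nii.gz`,
#' `S0s.nii.gz`, `Ds.nii.gz`, `fs.nii.gz`) plus `flags.nii.gz` coding
#' convergence (0 none, 1 low only, 2 high only, 3 both).
#'
#' @param maps a `param_maps` object.
#' @param dir output directory (created if needed).
#' @param voxel_size voxel size in mm written to the headers.
#' @return the directory, invisibly.
#' @export
write_param_maps <- function(maps, dir, voxel_size = 4) {
  stopifnot(inherits(maps, "param_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vs <- rep(voxel_size, 3)
  for (nm in c("MD", "ft", "S0", "S0s", "Ds", "fs")) {
    RNifti::writeNifti(RNifti::asNifti(maps[[nm]], pixdim = vs),
                       file.path(dir, paste0(nm, ".nii.gz")), datatype = "float")
  }
  flags <- maps$converged_low + 2 * maps$converged_high
  RNifti::writeNifti(RNifti::asNifti(flags + 0, pixdim = vs),
                     file.path(dir, "flags.nii.gz"), datatype = "float")
  invisible(dir)
}
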