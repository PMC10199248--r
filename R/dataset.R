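#' Diffusion-weighted dataset
#'
#' Bundles a 4D signal array (x, y, z, volume) with its acquisition scheme and
#' optional per-voxel maps: `sigma_map`, the Rician noise level in signal
#' units, and `beff_map`, a dimensionless multiplicative scaling of the nominal
#' b-value that accounts for gradient nonlinearities. The pipeline operates in
#' voxel space: all maps must share the spatial grid of the signal.
#'
#' @param signal 4D numeric array, non-negative and finite.
#' @param scheme an `acq_scheme` whose length equals `dim(signal)[4]`.
#' @param sigma_map optional 3D array of per-voxel noise levels (>= 0).
#' @param beff_map optional 3D array of per-voxel b-scaling factors (> 0).
#' @param voxel_size isotropic voxel size in mm (default 4, the acquisition's
#'   resolution).
#' @return A `dwi_dataset` object.
#' @export
dwi_dataset <- function(signal, scheme, sigma_map = NULL, beff_map = NULL,
                        voxel_size = 4) {
  if (!is.array(signal) || length(dim(signal)) != 4) stop("`signal` must be a 4D array")
  validate_scheme(scheme)
  if (dim(signal)[4] != nrow(scheme)) {
    stop("volume count mismatch: signal has ", dim(signal)[4],
         " volumes but scheme has ", nrow(scheme), " rows")
  }
  if (any(!is.finite(signal))) stop("all signals must be finite")
  if (any(signal < 0)) stop("all signals must be >= 0")
  grid <- dim(signal)[1:3]
  check_map <- function(map, name, positive = FALSE) {
    if (is.null(map)) return(NULL)
    if (!is.array(map) || length(dim(map)) != 3 || !all(dim(map) == grid)) {
      stop("`", name, "` must be a 3D array on the signal grid (",
           paste(grid, collapse = "x"), ")")
    }
    if (any(!is.finite(map))) stop("`", name, "` must be finite everywhere")
    if (positive && any(map <= 0)) stop("`", name, "` must be > 0 everywhere")
    if (!positive && any(map < 0)) stop("`", name, "` must be >= 0 everywhere")
    map
  }
  structure(list(
    signal = signal,
    scheme = scheme,
    sigma_map = check_map(sigma_map, "sigma_map"),
    beff_map = check_map(beff_map, "beff_map", positive = TRUE),
    voxel_size = voxel_size
  ), class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$signal)
  cat("dwi_dataset:", paste(d[1:3], collapse = "x"), "grid,", d[4], "volumes (",
      sum(x$scheme$is_b0), "b0 ),", length(unique(x$scheme$b[!x$scheme$is_b0])),
      "shells, voxel", x$voxel_size, "mm\n")
  invisible(x)
}

#' Read / write a diffusion dataset
#'
#' NIfTI-1 images for the 4D signal and the optional 3D maps, plus the
#' plain-text scheme sidecar. A write/read round trip preserves signals to
#' 32-bit float precision and the scheme order exactly.
#'
#' @param image_path path to the 4D NIfTI (.nii or .nii.gz).
#' @param scheme_path path to the scheme sidecar (see [write_scheme()]).
#' @param sigma_path,beff_path optional paths for the noise-level and
#'   effective-b maps.
#' @param voxel_size voxel size in mm recorded on the dataset.
#' @return `read_dwi` returns a [dwi_dataset()].
#' @export
read_dwi <- function(image_path, scheme_path, sigma_path = NULL,
                     beff_path = NULL, voxel_size = 4) {
  for (p in c(image_path, scheme_path, sigma_path, beff_path)) {
    if (!file.exists(p)) stop("cannot read file: ", p)
  }
  signal <- read_nifti_array(image_path, ndim = 4)
  scheme <- read_scheme(scheme_path)
  if (dim(signal)[4] != nrow(scheme)) {
    stop("volume count mismatch between ", image_path, " (", dim(signal)[4],
         ") and ", scheme_path, " (", nrow(scheme), ")")
  }
  sigma_map <- if (!is.null(sigma_path)) read_nifti_array(sigma_path, ndim = 3)
  beff_map <- if (!is.null(beff_path)) read_nifti_array(beff_path, ndim = 3)
  dwi_dataset(signal, scheme, sigma_map = sigma_map, beff_map = beff_map,
              voxel_size = voxel_size)
}

#' @rdname read_dwi
#' @param dataset a [dwi_dataset()].
#' @export
write_dwi <- function(dataset, image_path, scheme_path, sigma_path = NULL,
                      beff_path = NULL) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  vs <- rep(dataset$voxel_size, 3)
  RNifti::writeNifti(RNifti::asNifti(dataset$signal, pixdim = vs), image_path,
                     datatype = "float")
  write_scheme(dataset$scheme, scheme_path)
  if (!is.null(sigma_path) && !is.null(dataset$sigma_map)) {
    RNifti::writeNifti(RNifti::asNifti(dataset$sigma_map, pixdim = vs),
                       sigma_path, datatype = "float")
  }
  if (!is.null(beff_path) && !is.null(dataset$beff_map)) {
    RNifti::writeNifti(RNifti::asNifti(dataset$beff_map, pixdim = vs),
                       beff_path, datatype = "float")
  }
  invisible(image_path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @param ndim required dimensionality (3 or 4); errors otherwise.
#' @return a numeric array stripped of NIfTI metadata.
#' @export
read_nifti_array <- function(path, ndim = 3) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != ndim) {
    stop(path, " is ", length(dim(arr)), "-dimensional; expected ", ndim, "D")
  }
  arr
}
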