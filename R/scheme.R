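#' Default STE b-shells (s/mm^2)
#'
#' The eleven diffusion-weighted shells of the default spherical-tensor-encoded
#' (STE) acquisition, spanning b = 250 to 15000 s/mm^2.
#' @export
default_b_values <- function() {
  c(250, 1500, 3000, 4500, 6000, 7500, 9000, 10500, 12000, 13500, 15000)
}

#' Default per-shell repetition counts
#'
#' Repetitions increase monotonically with b to compensate the decaying signal;
#' totals 204 diffusion-weighted volumes over the default shells.
#' @export
default_repeats <- function() {
  c(1, 2, 6, 10, 12, 13, 17, 20, 31, 45, 47)
}

#' Build an STE acquisition scheme
#'
#' Expands per-shell repetition counts into an ordered list of volumes, shuffles
#' the diffusion-weighted volumes into a seed-reproducible random order (shell
#' order is randomised at acquisition to decouple b from scanner drift), and
#' interleaves b = 0 reference volumes every `b0_interval`-th image, starting
#' with a leading b0.
#'
#' @param b_values numeric vector of shell b-values (s/mm^2), all > 0.
#' @param repeats integer vector, same length as `b_values`; number of
#'   repetitions per shell (>= 1).
#' @param b0_interval integer >= 2; a b0 occupies every `b0_interval`-th
#'   position (positions 1, 1 + b0_interval, ...).
#' @param seed integer; seeds the shuffle so the scheme is reproducible.
#' @return An `acq_scheme`: a data frame with one row per volume and columns
#'   `b` (s/mm^2), `encoding` ("STE"), `acq_index` (1-based acquisition
#'   position) and `is_b0`.
#' @export
build_scheme <- function(b_values = default_b_values(),
                         repeats = default_repeats(),
                         b0_interval = 15,
                         seed = 1L) {
  if (length(b_values) != length(repeats)) {
    stop("`b_values` and `repeats` must have the same length (got ",
         length(b_values), " vs ", length(repeats), ")")
  }
  if (any(!is.finite(b_values)) || any(b_values <= 0)) {
    stop("all `b_values` must be finite and > 0 (b0 volumes are interleaved automatically)")
  }
  if (any(repeats < 1) || any(repeats != round(repeats))) {
    stop("`repeats` must be integers >= 1")
  }
  if (b0_interval < 2) stop("`b0_interval` must be >= 2")

  dwi_b <- rep(b_values, times = repeats)
  perm <- with_seed(seed, sample.int(length(dwi_b)))
  dwi_b <- dwi_b[perm]

  n_dwi <- length(dwi_b)
  b <- numeric(0); flag <- logical(0)
  i_dwi <- 0L
  p <- 0L
  while (i_dwi < n_dwi) {
    p <- p + 1L
    if ((p - 1L) %% b0_interval == 0L) {
      b <- c(b, 0); flag <- c(flag, TRUE)
    } else {
      i_dwi <- i_dwi + 1L
      b <- c(b, dwi_b[i_dwi]); flag <- c(flag, FALSE)
    }
  }
  scheme <- data.frame(
    b = b,
    encoding = "STE",
    acq_index = seq_along(b),
    is_b0 = flag,
    stringsAsFactors = FALSE
  )
  class(scheme) <- c("acq_scheme", "data.frame")
  validate_scheme(scheme)
  scheme
}

#' Validate an acquisition scheme
#'
#' Checks the structural invariants: non-negative b, b0 flags consistent with
#' b = 0, and unique, ordered acquisition indices.
#' @param scheme an `acq_scheme` data frame.
#' @return the scheme, invisibly.
#' @export
validate_scheme <- function(scheme) {
  req <- c("b", "encoding", "acq_index", "is_b0")
  if (!is.data.frame(scheme) || !all(req %in% names(scheme))) {
    stop("scheme must be a data frame with columns ", paste(req, collapse = ", "))
  }
  if (any(!is.finite(scheme$b)) || any(scheme$b < 0)) stop("scheme b-values must be finite and >= 0")
  if (any(scheme$is_b0 & scheme$b != 0)) stop("every is_b0 volume must have b = 0")
  if (any(!scheme$is_b0 & scheme$b == 0)) stop("every b = 0 volume must be flagged is_b0")
  if (anyDuplicated(scheme$acq_index)) stop("acq_index values must be unique")
  invisible(scheme)
}

#' Check a scheme supports both fitting regimes
#'
#' Fitting requires at least two distinct non-zero shells at or below the low-b
#' cutoff (plus b0) and at least two distinct shells at or above the high-b
#' cutoff.
#' @param scheme an `acq_scheme`.
#' @param config a [fit_config()].
#' @return the scheme, invisibly; errors naming the missing regime otherwise.
#' @export
check_scheme_fittable <- function(scheme, config = fit_config()) {
  validate_scheme(scheme)
  low <- unique(scheme$b[!scheme$is_b0 & scheme$b <= config$lowb_max])
  high <- unique(scheme$b[scheme$b >= config$highb_min])
  if (length(low) < 2) {
    stop("scheme lacks the low-b regime: need >= 2 distinct non-zero shells with b <= ",
         config$lowb_max, " s/mm^2")
  }
  if (!any(scheme$is_b0)) stop("scheme lacks b0 volumes required by the low-b regime")
  if (length(high) < 2) {
    stop("scheme lacks the high-b regime: need >= 2 distinct shells with b >= ",
         config$highb_min, " s/mm^2")
  }
  invisible(scheme)
}

#' Write / read a scheme sidecar file
#'
#' Plain-text sidecar, one row per volume: `b  encoding  acq_index  is_b0`,
#' whitespace-delimited, with a `#`-prefixed header line.
#' @param scheme an `acq_scheme`.
#' @param path file path.
#' @return `read_scheme` returns an `acq_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  validate_scheme(scheme)
  lines <- c("# b_s_per_mm2 encoding acq_index is_b0",
             sprintf("%g %s %d %d", scheme$b, scheme$encoding,
                     scheme$acq_index, as.integer(scheme$is_b0)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  tab <- utils::read.table(path, comment.char = "#", stringsAsFactors = FALSE,
                           col.names = c("b", "encoding", "acq_index", "is_b0"))
  scheme <- data.frame(b = as.numeric(tab$b), encoding = as.character(tab$encoding),
                       acq_index = as.integer(tab$acq_index),
                       is_b0 = as.logical(as.integer(tab$is_b0)),
                       stringsAsFactors = FALSE)
  class(scheme) <- c("acq_scheme", "data.frame")
  validate_scheme(scheme)
  scheme
}

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
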