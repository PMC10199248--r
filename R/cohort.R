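#' Cohort group definition
#'
#' Target overall-cerebellum medians and between-subject spreads (MAD scale)
#' for one group of a synthetic cohort, plus the total-cerebellar-volume
#' covariate distribution.
#'
#' @param name group label.
#' @param n_subjects number of subjects (>= 1).
#' @param md,fs,ds target group medians: tissue MD (um^2/ms) in (0, 3),
#'   sphere fraction fs in (0, 1), sphere diffusivity Ds (um^2/ms) > 0.
#' @param md_mad,fs_mad,ds_mad between-subject spreads on the MAD scale.
#' @param volume,volume_mad total cerebellar volume median and MAD (cm^3).
#' @return a `cohort_group` list.
#' @export
cohort_group <- function(name, n_subjects = 5,
                         md = 0.60, fs = 0.11, ds = 0.12,
                         md_mad = 0.03, fs_mad = 0.01, ds_mad = 0.02,
                         volume = 115.94, volume_mad = 21.02) {
  if (n_subjects < 1) stop("`n_subjects` must be >= 1")
  if (!(md > 0 && md < 3)) stop("target MD must lie in (0, 3) um^2/ms")
  if (!(fs > 0 && fs < 1)) stop("target fs must lie in (0, 1)")
  if (ds <= 0) stop("target Ds must be > 0")
  structure(list(name = name, n_subjects = as.integer(n_subjects),
                 md = md, fs = fs, ds = ds,
                 md_mad = md_mad, fs_mad = fs_mad, ds_mad = ds_mad,
                 volume = volume, volume_mad = volume_mad),
            class = "cohort_group")
}

#' Default two-group cohort: healthy controls vs an SCA6-like group
#'
#' Targets and spreads follow the reported cerebellar grey-matter values for
#' age-matched controls (MD 0.60 (0.03) um^2/ms, fs 0.11 (0.01), Ds 0.12
#' (0.02), volume 115.94 (21.02) cm^3) and the SCA6 group (MD 0.54 (0.07),
#' fs 0.14 (0.03), Ds 0.13 (0.02), volume 89.60 (12.90) cm^3).
#' @param n_subjects subjects per group.
#' @export
default_cohort_groups <- function(n_subjects = 5) {
  list(
    cohort_group("control", n_subjects,
                 md = 0.60, fs = 0.11, ds = 0.12,
                 md_mad = 0.03, fs_mad = 0.01, ds_mad = 0.02,
                 volume = 115.94, volume_mad = 21.02),
    cohort_group("SCA6", n_subjects,
                 md = 0.54, fs = 0.14, ds = 0.13,
                 md_mad = 0.07, fs_mad = 0.03, ds_mad = 0.02,
                 volume = 89.60, volume_mad = 12.90)
  )
}

#' Per-lobe multiplicative profiles
#'
#' Fixed anatomical offsets applied to each subject's metric targets, so that
#' anterior, superior-posterior and inferior-posterior lobes differ the way
#' the control cohort's lobe medians do (anterior MD highest, inferior
#' posterior fs highest). Rows A, SP, IP, F; columns MD, fs, Ds.
#' @export
default_lobe_profile <- function() {
  m <- rbind(
    A  = c(MD = 0.62 / 0.60, fs = 0.10 / 0.11, Ds = 0.13 / 0.12),
    SP = c(MD = 1.00,        fs = 0.10 / 0.11, Ds = 1.00),
    IP = c(MD = 0.59 / 0.60, fs = 1.00,        Ds = 0.13 / 0.12),
    F  = c(MD = 1.00,        fs = 1.00,        Ds = 1.00)
  )
  m
}

#' Cohort specification
#'
#' @param groups list of [cohort_group()]s; defaults to
#'   [default_cohort_groups()].
#' @param template a [phantom_spec()] shared by all subjects (geometry, noise
#'   level, drift); per-subject grey-matter mixtures are derived from the
#'   group targets, white matter and CSF come from the template classes.
#' @param lobule_jitter log-scale SD of the within-subject lobule-to-lobule
#'   variation (default 0.03).
#' @param lobe_profile per-lobe multiplicative offsets
#'   ([default_lobe_profile()]).
#' @param ft grey-matter tissue fraction used to build mixtures from targets.
#' @param seed integer.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(groups = default_cohort_groups(),
                        template = phantom_spec(shape = c(16, 16, 16)),
                        lobule_jitter = 0.03,
                        lobe_profile = default_lobe_profile(),
                        ft = 0.8, seed = 1L) {
  stopifnot(length(groups) >= 1, inherits(template, "phantom_spec"))
  for (g in groups) stopifnot(inherits(g, "cohort_group"))
  if (anyDuplicated(vapply(groups, `[[`, "", "name"))) stop("group names must be unique")
  structure(list(groups = groups, template = template,
                 lobule_jitter = lobule_jitter, lobe_profile = lobe_profile,
                 ft = ft, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Build a compartment mixture hitting (MD, fs, Ds) targets
#'
#' Solves for a three-compartment mixture (free water at `d_fw`, an
#' intermediate tissue compartment, and a sphere compartment) with tissue
#' fraction `ft` whose fraction-weighted tissue diffusivity equals `md`,
#' sphere fraction equals `fs`, and sphere diffusivity equals `ds`.
#'
#' @param md,fs,ds target tissue MD, sphere fraction, sphere diffusivity.
#' @param ft tissue fraction.
#' @param d_fw free-water diffusivity.
#' @return a [compartment_mixture()]; errors when the targets are unreachable
#'   (no valid intermediate compartment exists).
#' @export
mixture_from_targets <- function(md, fs, ds, ft = 0.8, d_fw = 3) {
  if (!(ft > 0 && ft <= 1)) stop("`ft` must lie in (0, 1]")
  if (!(fs > 0 && fs < 1)) stop("unreachable targets: fs must lie in (0, 1)")
  f_s <- fs * ft
  f_mid <- ft - f_s
  if (f_mid <= 0) stop("unreachable targets: sphere fraction exhausts the tissue")
  d_mid <- (md * ft - f_s * ds) / f_mid
  if (!is.finite(d_mid) || d_mid <= ds || d_mid >= d_fw) {
    stop("unreachable targets: implied tissue diffusivity ", signif(d_mid, 3),
         " must lie in (Ds, D_fw) = (", ds, ", ", d_fw, ")")
  }
  compartment_mixture(c(1 - ft, f_mid, f_s), c(d_fw, d_mid, ds))
}

#' Generate a synthetic cohort
#'
#' Per subject, the group's (MD, fs, Ds) targets are perturbed by a log-normal
#' subject factor with the group's MAD-scale spread, modulated per lobule by
#' the lobe profile and a log-normal lobule jitter, and turned into a
#' grey-matter mixture per lobule via [mixture_from_targets()]. With
#' `voxels = TRUE`, voxel-grid truth maps (and, with `dwi = TRUE`, noisy
#' drifting DWI volumes) are materialised on the template geometry; with
#' `voxels = FALSE` only the per-lobule truth table is returned, which is
#' exact because every voxel of a lobule shares its mixture.
#'
#' @param spec a [cohort_spec()].
#' @param scheme an `acq_scheme`; required when `dwi = TRUE`.
#' @param voxels build voxel-grid truth maps and labels per subject.
#' @param dwi additionally synthesise the 4D diffusion-weighted signal.
#' @param lobe_map lobule-to-lobe table ([default_lobe_map()]).
#' @param seed overrides the spec's seed (convenient for replicate draws from
#'   one spec).
#' @return list with `subjects` (per subject: `id`, `group`,
#'   `lobule_truth` data frame, and when requested `truth`, `labels`,
#'   `dataset`), `covariates` (subject, group, cerebellar_volume) and
#'   `lobule_table`, a long data frame of per-lobule truth values.
#' @export
generate_cohort <- function(spec, scheme = NULL, voxels = FALSE, dwi = FALSE,
                            lobe_map = default_lobe_map(), seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(seed)) seed <- spec$seed
  if (dwi && is.null(scheme)) stop("`scheme` is required when dwi = TRUE")
  if (dwi) voxels <- TRUE
  tpl <- spec$template
  labels <- tpl$geometry$labels
  lobules <- sort(unique(as.integer(labels[labels > 0])))
  lobe_of <- stats::setNames(lobe_map$lobe, lobe_map$label)

  mad_to_sd <- function(mad, target) mad / (0.6745 * target)

  subjects <- list()
  cov_rows <- list()
  lob_rows <- list()
  with_seed(seed, {
    for (g in spec$groups) {
      s_md <- mad_to_sd(g$md_mad, g$md)
      s_fs <- mad_to_sd(g$fs_mad, g$fs)
      s_ds <- mad_to_sd(g$ds_mad, g$ds)
      s_vol <- mad_to_sd(g$volume_mad, g$volume)
      for (i in seq_len(g$n_subjects)) {
        id <- sprintf("%s_%02d", g$name, i)
        md_i <- g$md * exp(stats::rnorm(1, 0, s_md))
        fs_i <- g$fs * exp(stats::rnorm(1, 0, s_fs))
        ds_i <- g$ds * exp(stats::rnorm(1, 0, s_ds))
        vol_i <- g$volume * exp(stats::rnorm(1, 0, s_vol))
        lt <- data.frame(label = lobules,
                         lobe = unname(lobe_of[as.character(lobules)]),
                         stringsAsFactors = FALSE)
        jit <- function() exp(stats::rnorm(nrow(lt), 0, spec$lobule_jitter))
        prof <- spec$lobe_profile[lt$lobe, , drop = FALSE]
        lt$MD <- pmin(2.99, md_i * prof[, "MD"] * jit())
        lt$fs <- pmin(0.99, fs_i * prof[, "fs"] * jit())
        lt$Ds <- ds_i * prof[, "Ds"] * jit()
        subj <- list(id = id, group = g$name, lobule_truth = lt)
        if (voxels) {
          mixes <- lapply(seq_len(nrow(lt)), function(k) {
            mixture_from_targets(lt$MD[k], lt$fs[k], lt$Ds[k],
                                 ft = spec$ft, d_fw = tpl$d_fw)
          })
          subj <- c(subj, build_subject_volumes(tpl, lt, mixes, scheme, dwi))
        }
        subjects[[id]] <- subj
        cov_rows[[id]] <- data.frame(subject = id, group = g$name,
                                     cerebellar_volume = vol_i,
                                     stringsAsFactors = FALSE)
        lob_rows[[id]] <- cbind(subject = id, group = g$name, lt,
                                stringsAsFactors = FALSE)
      }
    }
  })
  list(subjects = subjects,
       covariates = do.call(rbind, c(cov_rows, make.row.names = FALSE)),
       lobule_table = do.call(rbind, c(lob_rows, make.row.names = FALSE)))
}

# materialise one subject's truth maps (and optionally DWI) on the template
# geometry, with per-lobule GM mixtures and template WM/CSF classes
build_subject_volumes <- function(tpl, lt, mixes, scheme, dwi) {
  shape <- tpl$shape
  labels <- tpl$geometry$labels
  cid <- as.integer(tpl$geometry$class_id)
  truth_names <- c("MD", "ft", "fs", "Ds", "S0", "S0s")
  truth <- lapply(truth_names, function(nm) array(NA_real_, dim = shape))
  names(truth) <- truth_names
  nvox <- prod(shape)
  sig <- if (dwi) matrix(0, nvox, nrow(scheme)) else NULL
  gain <- if (dwi) drift_gain(tpl$drift, scheme$acq_index) else NULL

  assign_class <- function(vox, mix) {
    tr <- truth_of_mixture(mix, d_fw = tpl$d_fw, S0 = tpl$S0)
    for (nm in truth_names) truth[[nm]][vox] <<- tr[[nm]]
    if (dwi) {
      base <- tpl$S0 * forward_signal(mix, scheme$b) * gain
      sig[vox, ] <<- matrix(base, length(vox), ncol(sig), byrow = TRUE)
    }
  }
  for (k in seq_len(nrow(lt))) {
    vox <- which(as.integer(labels) == lt$label[k])
    if (length(vox)) assign_class(vox, mixes[[k]])
  }
  for (id in setdiff(sort(unique(cid[cid > 0])), 1L)) {
    assign_class(which(cid == id & as.integer(labels) == 0L), tpl$classes[[id]])
  }
  out <- list(truth = truth, labels = labels)
  if (dwi) {
    if (tpl$sigma > 0) {
      s <- tpl$sigma * tpl$S0
      e1 <- matrix(stats::rnorm(length(sig), 0, s), nrow(sig), ncol(sig))
      e2 <- matrix(stats::rnorm(length(sig), 0, s), nrow(sig), ncol(sig))
      sig <- sqrt((sig + e1)^2 + e2^2)
    }
    out$dataset <- dwi_dataset(array(sig, dim = c(shape, nrow(scheme))), scheme,
                               sigma_map = array(tpl$sigma * tpl$S0, dim = shape))
  }
  out
}
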