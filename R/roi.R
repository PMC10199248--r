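#' Default lobule-to-lobe mapping
#'
#' Lobules I-V form the anterior lobe (A), VI-VII (including the crura) the
#' superior posterior lobe (SP), VIII-IX the inferior posterior lobe (IP) and
#' X the flocculonodular lobe (F), following standard cerebellar atlases.
#' @return data frame with columns `label` (integer) and `lobe`.
#' @export
default_lobe_map <- function() {
  data.frame(label = 1:10,
             lobe = c(rep("A", 5), "SP", "SP", "IP", "IP", "F"),
             stringsAsFactors = FALSE)
}

validate_lobe_map <- function(lobe_map, labels) {
  stopifnot(is.data.frame(lobe_map), all(c("label", "lobe") %in% names(lobe_map)))
  if (!all(lobe_map$lobe %in% c("A", "SP", "IP", "F"))) {
    stop("lobes must be drawn from {A, SP, IP, F}")
  }
  present <- sort(unique(as.integer(labels[labels > 0])))
  missing <- setdiff(present, lobe_map$label)
  if (length(missing)) {
    stop("labels without a lobe assignment: ", paste(missing, collapse = ", "))
  }
  invisible(lobe_map)
}

#' Grey-matter voxel inclusion filter
#'
#' Implements the voxel filters applied before ROI statistics: labelled GM
#' voxels with finite parameters and `ft > ft_min` are retained, then voxels
#' above the per-subject `pct`-th percentile of fs or of Ds (computed over the
#' ft-filtered labelled voxels) are trimmed. `ft_min = 0, pct = 100` disables
#' both filters.
#'
#' @param maps a `param_maps` object (or list of arrays `MD`, `ft`, `fs`,
#'   `Ds`).
#' @param labels integer 3D label array on the same grid.
#' @param ft_min tissue-fraction threshold (default 0.3).
#' @param pct upper percentile retained for fs and Ds (default 99).
#' @return logical 3D inclusion mask, with the fs/Ds thresholds attached as
#'   attribute `"thresholds"`.
#' @export
filter_voxels <- function(maps, labels, ft_min = 0.3, pct = 99) {
  shape <- dim(maps$ft)
  stopifnot(all(dim(labels) == shape))
  labelled <- labels > 0
  if (!any(labelled)) stop("label volume contains no labelled voxels")
  finite_ok <- is.finite(maps$MD) & is.finite(maps$ft) &
    is.finite(maps$fs) & is.finite(maps$Ds)
  base <- labelled & finite_ok & maps$ft > ft_min
  if (!any(base)) {
    mask <- array(FALSE, dim = shape)
    attr(mask, "thresholds") <- c(fs = NA_real_, Ds = NA_real_)
    return(mask)
  }
  fs_thr <- stats::quantile(maps$fs[base], pct / 100, names = FALSE)
  ds_thr <- stats::quantile(maps$Ds[base], pct / 100, names = FALSE)
  mask <- base & maps$fs <= fs_thr & maps$Ds <= ds_thr
  attr(mask, "thresholds") <- c(fs = fs_thr, Ds = ds_thr)
  mask
}

#' Per-lobule and per-lobe median summaries
#'
#' Medians of each metric over the masked voxels of every lobule, and of every
#' lobe with its lobules' voxels pooled (never a median of lobule medians).
#' Regions with fewer than `min_voxels` masked voxels are flagged excluded and
#' carry no value — the rule that removes the flocculonodular lobe when it
#' holds fewer than 5 voxels.
#'
#' @param maps a `param_maps` object.
#' @param labels integer 3D label array.
#' @param mask logical inclusion mask from [filter_voxels()].
#' @param lobe_map lobule-to-lobe table ([default_lobe_map()]).
#' @param min_voxels minimum voxel count per region (default 5).
#' @param metrics map names to summarise.
#' @return an `roi_summary` data frame: `region`, `region_type`
#'   ("lobule"/"lobe"), `metric`, `median`, `n_voxels`, `excluded`.
#' @export
summarize_rois <- function(maps, labels, mask, lobe_map = default_lobe_map(),
                           min_voxels = 5, metrics = c("MD", "fs", "Ds")) {
  stopifnot(all(dim(labels) == dim(mask)))
  validate_lobe_map(lobe_map, labels)
  lab_vec <- as.integer(labels)
  mask_vec <- as.logical(mask)
  regions <- list()
  for (l in sort(unique(lobe_map$label))) {
    regions[[paste0("lobule_", l)]] <- list(type = "lobule", vox = which(mask_vec & lab_vec == l))
  }
  for (lb in unique(lobe_map$lobe)) {
    members <- lobe_map$label[lobe_map$lobe == lb]
    regions[[lb]] <- list(type = "lobe", vox = which(mask_vec & lab_vec %in% members))
  }
  rows <- lapply(names(regions), function(rn) {
    r <- regions[[rn]]
    n <- length(r$vox)
    excluded <- n < min_voxels
    data.frame(region = rn, region_type = r$type, metric = metrics,
               median = if (excluded) NA_real_ else
                 vapply(metrics, function(m) stats::median(maps[[m]][r$vox]), 0),
               n_voxels = n, excluded = excluded,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("roi_summary", "data.frame")
  out
}

#' Cohort-level summary table
#'
#' Stacks per-subject ROI summaries into a long table joined with the
#' covariates, and computes the group-level median and median absolute
#' deviation per (group, region, metric) over the non-excluded subject
#' medians.
#'
#' @param summaries named list of `roi_summary` data frames, one per subject
#'   (names are the subject ids).
#' @param covariates data frame with columns `subject`, `group` and any
#'   additional covariates (e.g. `cerebellar_volume`).
#' @return list with `subject_table` (one row per subject x region x metric)
#'   and `group_table` (group, region, metric, median, mad, n_subjects).
#' @export
summarize_cohort <- function(summaries, covariates) {
  stopifnot(is.list(summaries), length(summaries) >= 1)
  ids <- names(summaries)
  if (is.null(ids) || anyDuplicated(ids)) stop("summaries must be uniquely named by subject id")
  if (anyDuplicated(covariates$subject)) stop("duplicated subject ids in covariates")
  if (!all(ids %in% covariates$subject)) stop("covariates missing for some subjects")
  key <- function(s) paste(s$region, s$metric)
  ref <- sort(key(summaries[[1]]))
  for (id in ids) {
    if (!identical(sort(key(summaries[[id]])), ref)) {
      stop("region/metric sets differ across subjects (first mismatch: ", id, ")")
    }
  }
  subject_table <- do.call(rbind, lapply(ids, function(id) {
    cbind(subject = id, summaries[[id]], stringsAsFactors = FALSE)
  }))
  subject_table <- merge(subject_table, covariates, by = "subject", sort = FALSE)
  grp <- subject_table[!subject_table$excluded, ]
  group_table <- do.call(rbind, lapply(
    split(grp, list(grp$group, grp$region, grp$metric), drop = TRUE),
    function(d) data.frame(group = d$group[1], region = d$region[1],
                           region_type = d$region_type[1], metric = d$metric[1],
                           median = stats::median(d$median),
                           mad = stats::median(abs(d$median - stats::median(d$median))),
                           n_subjects = nrow(d), stringsAsFactors = FALSE)))
  row.names(group_table) <- NULL
  list(subject_table = subject_table, group_table = group_table)
}
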