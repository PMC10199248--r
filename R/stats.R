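#' Statistical test result container
#'
#' @param test test name.
#' @param statistic test statistic value.
#' @param p raw p-value.
#' @param alpha_adj adjusted significance threshold; a result is flagged
#'   significant iff `p < alpha_adj`.
#' @param groups character vector of group labels involved.
#' @param n integer vector of per-group sample sizes.
#' @param estimate optional effect estimate (e.g. regression coefficient).
#' @param se optional standard error of the estimate.
#' @return a one-row `stat_result` data frame.
#' @export
stat_result <- function(test, statistic, p, alpha_adj = 0.05,
                        groups = NA_character_, n = NA_integer_,
                        estimate = NA_real_, se = NA_real_) {
  if (!is.na(p) && (p < 0 || p > 1)) stop("p must lie in [0, 1]")
  out <- data.frame(test = test, statistic = statistic, p = p,
                    alpha_adj = alpha_adj, significant = p < alpha_adj,
                    groups = paste(groups, collapse = " vs "),
                    n = paste(n, collapse = ","),
                    estimate = estimate, se = se,
                    stringsAsFactors = FALSE)
  class(out) <- c("stat_result", "data.frame")
  out
}

#' Two-sided Mann-Whitney test
#'
#' Exact p-value (rank-sum enumeration) when the combined sample size is at
#' most 20 and there are no ties; normal approximation with tie correction and
#' continuity correction otherwise.
#'
#' @param x,y numeric samples, each of size >= 2.
#' @param alpha_adj significance threshold (e.g. a Bonferroni-adjusted alpha).
#' @return a [stat_result()] row (`statistic` is the Mann-Whitney U of `x`).
#' @export
mann_whitney <- function(x, y, alpha_adj = 0.05) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  stat_result("mann_whitney", unname(wt$statistic), wt$p.value,
              alpha_adj = alpha_adj, groups = c("x", "y"),
              n = c(length(x), length(y)))
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation, computed from the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` for `n` subjects and
#' `k` sessions. Absolute agreement penalises systematic session shifts.
#'
#' @param measurements numeric matrix, subjects in rows, sessions in columns;
#'   no missing cells.
#' @return the ICC value (numeric scalar).
#' @export
icc <- function(measurements) {
  m <- as.matrix(measurements)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 subjects and >= 2 sessions")
  if (any(!is.finite(m))) stop("missing or non-finite cells are not supported")
  n <- nrow(m); k <- ncol(m)
  rowm <- rowMeans(m); colm <- colMeans(m); grand <- mean(m)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  mse <- sum((m - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand)^2) /
    ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' One-way ANOVA with Tukey HSD post-hoc
#'
#' Omnibus F-test across the groups, followed by all pairwise comparisons with
#' Tukey's honestly-significant-difference adjustment (studentized-range
#' distribution).
#'
#' @param groups named list of numeric samples, >= 2 groups, each n >= 2.
#' @param alpha_adj significance threshold applied to every row.
#' @return `stat_result` rows: one `"anova"` omnibus row, then one
#'   `"tukey:<a>-<b>"` row per pair (statistic = mean difference, p = Tukey
#'   adjusted).
#' @export
anova_tukey <- function(groups, alpha_adj = 0.05) {
  if (length(groups) < 2) stop("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("every group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  d <- data.frame(y = unlist(groups, use.names = FALSE),
                  g = factor(rep(names(groups), sizes)))
  fit <- stats::aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  out <- stat_result("anova", an[["F value"]][1], an[["Pr(>F)"]][1],
                     alpha_adj = alpha_adj, groups = names(groups), n = sizes)
  tk <- stats::TukeyHSD(fit)$g
  for (i in seq_len(nrow(tk))) {
    pair <- strsplit(rownames(tk)[i], "-", fixed = TRUE)[[1]]
    out <- rbind(out, stat_result(paste0("tukey:", rownames(tk)[i]),
                                  tk[i, "diff"], tk[i, "p adj"],
                                  alpha_adj = alpha_adj, groups = pair,
                                  n = sizes[pair]))
  }
  out
}

#' Group comparison adjusted for total cerebellar volume
#'
#' Ordinary least squares of the outcome on group indicators plus a numeric
#' covariate (total cerebellar volume in the cerebellum-wide analyses). One
#' row per non-reference group, reporting the group-vs-reference coefficient,
#' its standard error and p-value.
#'
#' @param outcome numeric per-subject values.
#' @param group group labels (factor or character).
#' @param covariate numeric per-subject covariate; must not be constant.
#' @param reference reference group; default the first level alphabetically
#'   (the control group in the default cohort).
#' @param alpha_adj significance threshold.
#' @return `stat_result` rows, one per contrast.
#' @export
adjusted_group_regression <- function(outcome, group, covariate,
                                      reference = NULL, alpha_adj = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  if (length(unique(covariate)) < 2) stop("covariate is constant (collinear with the intercept)")
  if (is.null(reference)) reference <- sort(levels(group))[1]
  group <- stats::relevel(group, ref = reference)
  fit <- stats::lm(outcome ~ group + covariate)
  cf <- summary(fit)$coefficients
  rows <- grep("^group", rownames(cf), value = TRUE)
  out <- NULL
  for (r in rows) {
    lvl <- sub("^group", "", r)
    res <- stat_result(paste0("regression:", lvl, "-", reference),
                       cf[r, "t value"], cf[r, "Pr(>|t|)"],
                       alpha_adj = alpha_adj, groups = c(lvl, reference),
                       n = c(sum(group == lvl), sum(group == reference)),
                       estimate = cf[r, "Estimate"], se = cf[r, "Std. Error"])
    out <- if (is.null(out)) res else rbind(out, res)
  }
  out
}

#' Bonferroni-adjusted significance threshold
#'
#' `alpha / m` for `m` comparisons. With alpha = 0.05 and the 15 comparisons
#' of the cerebellar analyses (3 metrics across 5 region-level analyses) this
#' gives 0.0033, the operative "p < 0.003" threshold.
#'
#' @param alpha family-wise level (default 0.05).
#' @param m number of comparisons, >= 1.
#' @return the adjusted threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (!is.finite(m) || m < 1) stop("`m` must be >= 1")
  alpha / m
}
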