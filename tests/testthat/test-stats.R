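test_that("Mann-Whitney: identical samples, complete separation, tie handling", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  same <- mann_whitney(x, x)
  expect_equal(same$p, 1)
  expect_false(same$significant)

  sep <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  # exact two-sided p: 2 / choose(6, 3) rank assignments
  expect_equal(sep$p, 0.1)

  # ties: normal approximation cross-checked against a permutation oracle
  xt <- c(1, 2, 2, 3, 5, 5, 6, 8)
  yt <- c(2, 4, 5, 5, 7, 9, 9, 11)
  got <- mann_whitney(xt, yt)$p
  perm_p <- withr::with_seed(1, {
    pooled <- c(xt, yt); nx <- length(xt)
    u_of <- function(lab) {
      r <- rank(pooled)
      sum(r[lab]) - nx * (nx + 1) / 2
    }
    u0 <- u_of(seq_len(nx))
    mu <- nx * length(yt) / 2
    stat <- replicate(2e4, {
      lab <- sample(length(pooled), nx)
      abs(u_of(lab) - mu)
    })
    mean(stat >= abs(u0 - mu))
  })
  expect_equal(got, perm_p, tolerance = 0.25)
  expect_error(mann_whitney(1, c(1, 2)), "n >= 2")
})

test_that("Mann-Whitney is invariant under strictly monotone transforms", {
  withr::with_seed(5, {
    for (i in 1:5) {
      x <- stats::rnorm(8); y <- stats::rnorm(8, 0.5)
      p0 <- mann_whitney(x, y)$p
      expect_equal(mann_whitney(exp(x), exp(y))$p, p0)
      expect_equal(mann_whitney(atan(3 * x + 1), atan(3 * y + 1))$p, p0)
    }
  })
})

test_that("ICC(2,1): perfect duplication, independent sessions, hand oracle", {
  m <- cbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(icc(m), 1)

  big <- withr::with_seed(2, cbind(stats::rnorm(200), stats::rnorm(200)))
  expect_lt(abs(icc(big)), 0.1)

  worked <- cbind(c(9, 6, 8, 7, 10), c(10, 5, 9, 8, 10))
  # oracle: mean squares from the two-way ANOVA decomposition via aov()
  d <- data.frame(y = as.vector(worked),
                  subject = factor(rep(1:5, 2)),
                  session = factor(rep(1:2, each = 5)))
  ms <- summary(stats::aov(y ~ subject + session, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 5; k <- 2
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc(worked), oracle, tolerance = 1e-12)

  # absolute agreement penalises a constant session shift
  shifted <- cbind(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5) + 2)
  expect_lt(icc(shifted), 1)

  worked_na <- worked; worked_na[2, 1] <- NA
  expect_error(icc(worked_na), "missing")
  expect_error(icc(worked[1, , drop = FALSE]), ">= 2")
})

test_that("ANOVA + Tukey: null, strong separation, and the two-group identity", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- anova_tukey(g)
  omnibus <- res[res$test == "anova", ]
  expect_equal(omnibus$statistic, 0)
  expect_equal(omnibus$p, 1)

  withr::with_seed(3, {
    g2 <- list(a = stats::rnorm(8, 0, 0.01), b = stats::rnorm(8, 0, 0.01),
               c = stats::rnorm(8, 5, 0.01))
    r2 <- anova_tukey(g2, alpha_adj = 0.003)
    expect_lt(r2[r2$test == "anova", "p"], 1e-10)
    expect_lt(r2[grepl("c-a", r2$test), "p"], 0.003)
    expect_lt(r2[grepl("c-b", r2$test), "p"], 0.003)
    expect_gt(r2[grepl("b-a", r2$test), "p"], 0.05)
  })

  withr::with_seed(4, {
    x <- stats::rnorm(10); y <- stats::rnorm(12, 0.8)
    r <- anova_tukey(list(x = x, y = y))
    tt <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(r[r$test == "anova", "statistic"],
                 unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(r[r$test == "anova", "p"], tt$p.value, tolerance = 1e-10)
  })
  expect_error(anova_tukey(list(a = 1, b = c(1, 2))), "n >= 2")
})

test_that("Tukey-adjusted p-values are never below the unadjusted t-test p", {
  withr::with_seed(6, {
    for (i in 1:10) {
      g <- list(a = stats::rnorm(6), b = stats::rnorm(6, 0.5), c = stats::rnorm(6, 1))
      res <- anova_tukey(g)
      d <- data.frame(y = unlist(g), grp = rep(names(g), each = 6))
      mse <- summary(stats::aov(y ~ grp, data = d))[[1]]["Residuals", "Mean Sq"]
      for (pair in list(c("b", "a"), c("c", "a"), c("c", "b"))) {
        t_stat <- (mean(g[[pair[1]]]) - mean(g[[pair[2]]])) / sqrt(mse * (2 / 6))
        p_t <- 2 * stats::pt(-abs(t_stat), df = 15)
        p_tukey <- res[res$test == paste0("tukey:", pair[1], "-", pair[2]), "p"]
        expect_gte(p_tukey + 1e-12, p_t)
      }
    }
  })
})

test_that("volume-adjusted regression matches hand-solved normal equations", {
  # exactly determined 3-point system: intercept, one group contrast, covariate
  outcome <- c(1, 3, 6)
  group <- c("ctrl", "ctrl", "pat")
  covariate <- c(0, 2, 1)
  res <- adjusted_group_regression(outcome, group, covariate)
  X <- cbind(1, c(0, 0, 1), covariate)
  beta <- solve(t(X) %*% X, t(X) %*% outcome)
  expect_equal(res$estimate, beta[2], tolerance = 1e-10)

  # outcome fully explained by the covariate: group coefficient ~ 0
  withr::with_seed(7, {
    cov2 <- stats::runif(40, 80, 140)
    grp2 <- rep(c("ctrl", "pat"), 20)
    r2 <- suppressWarnings(adjusted_group_regression(cov2, grp2, cov2))
    expect_lt(abs(r2$estimate), 1e-10)

    # independent covariate: coefficient approaches the raw mean difference
    grp3 <- rep(c("ctrl", "pat"), each = 300)
    y3 <- ifelse(grp3 == "pat", 0.54, 0.60) + stats::rnorm(600, 0, 0.03)
    cov3 <- stats::rnorm(600, 100, 10)
    r3 <- adjusted_group_regression(y3, grp3, cov3)
    expect_equal(r3$estimate, -0.06, tolerance = 0.12)
    expect_true(r3$significant)
  })
  expect_error(adjusted_group_regression(c(1, 2, 3), c("a", "b", "a"), rep(5, 3)),
               "constant")
})

test_that("Bonferroni threshold is alpha / m and consistent with p < 0.003", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  thr <- bonferroni_threshold(0.05, 15)
  expect_equal(thr, 0.05 / 15)
  expect_equal(round(thr, 4), 0.0033)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
  # stat_result wires the significance flag to the adjusted threshold
  r <- stat_result("demo", 1, 0.004, alpha_adj = thr)
  expect_false(r$significant)
  expect_true(stat_result("demo", 1, 0.002, alpha_adj = thr)$significant)
})

test_that("type-I error of the subject-level group comparison is near nominal", {
  # identical group targets: rejection of the Mann-Whitney at alpha = 0.05
  # on per-subject overall medians should occur at about the nominal rate
  spec <- cohort_spec(groups = list(
    cohort_group("g1", 10, md = 0.60, fs = 0.11, ds = 0.12),
    cohort_group("g2", 10, md = 0.60, fs = 0.11, ds = 0.12)))
  hits <- vapply(1:1000, function(r) {
    lt <- generate_cohort(spec, seed = 20000 + r)$lobule_table
    md <- tapply(lt$MD, lt$subject, stats::median)
    grp <- tapply(lt$group, lt$subject, `[`, 1)
    mann_whitney(md[grp == "g1"], md[grp == "g2"])$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.03)
  expect_lte(mean(hits), 0.07)
})
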