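test_that("high-b fit is exact on mono-exponential data and bounded on Fig-style mixtures", {
  b <- c(10500, 12000, 13500, 15000)
  y <- 0.08 * exp(-b / 1000 * 0.1)
  f <- fit_highb_monoexp(y, b)
  expect_true(f$converged)
  expect_equal(f$S0s, 0.08, tolerance = 1e-9)
  expect_equal(f$Ds, 0.1, tolerance = 1e-9)

  # tri-exponential grey matter: contamination from the D = 1 compartment
  # keeps both parameters within 2% of the sphere ground truth, and the NLS
  # solution agrees with the brute-force grid oracle
  y3 <- forward_signal(gm_mixture(), b)
  f3 <- fit_highb_monoexp(y3, b)
  expect_equal(f3$Ds, 0.1, tolerance = 0.02)
  expect_equal(f3$S0s, 0.08, tolerance = 0.02)
  orc <- oracle_monoexp(y3, b)
  expect_equal(f3$Ds, orc$Ds, tolerance = 1e-3)
  expect_equal(f3$S0s, orc$S0s, tolerance = 1e-3)
})

test_that("degenerate high-b inputs are flagged, not thrown", {
  b <- c(10500, 12000, 13500, 15000)
  f <- fit_highb_monoexp(rep(0, 4), b)
  expect_false(f$converged)
  expect_true(is.na(f$Ds))
  expect_false(fit_highb_monoexp(c(1, 2), c(12000, 12000))$converged)
})

test_that("low-b free-water fit recovers exactly identifiable parameters", {
  b <- c(0, 250, 1500)
  y <- 100 * (0.8 * exp(-b / 1000 * 0.6) + 0.2 * exp(-b / 1000 * 3))
  f <- fit_lowb_freewater(y, b)
  expect_true(f$converged)
  expect_equal(f$S0, 100, tolerance = 1e-9)
  expect_equal(f$ft, 0.8, tolerance = 1e-9)
  expect_equal(f$MD, 0.6, tolerance = 1e-9)

  # pure tissue: ft pinned at its upper bound, MD equal to the generating value
  y1 <- 50 * exp(-b / 1000 * 0.9)
  f1 <- fit_lowb_freewater(y1, b)
  expect_equal(f1$ft, 1, tolerance = 1e-7)
  expect_equal(f1$MD, 0.9, tolerance = 1e-7)

  expect_false(fit_lowb_freewater(c(1, 0.5), c(0, 1500))$converged)
})

test_that("low-b fit of the tri-exponential matches the grid-search oracle", {
  b <- c(0, 250, 1500)
  y <- forward_signal(gm_mixture(), b)
  f <- fit_lowb_freewater(y, b)
  orc <- oracle_lowb(y, b)
  expect_equal(f$ft, orc$ft, tolerance = 1e-3)
  expect_equal(f$MD, orc$MD, tolerance = 1e-3)
  # the generating tissue fraction 0.8 is NOT the least-squares solution here:
  # the tissue itself is bi-exponential, so the fit settles below it
  expect_lt(f$ft, 0.8)
})

test_that("voxelwise fit round-trips a noiseless phantom at machine precision", {
  sc <- small_scheme(seed = 2)
  spec <- phantom_spec(shape = c(8, 8, 8), classes = exact_tissue_classes(),
                       sigma = 0, drift = c(1, 0, 0), seed = 1)
  ph <- generate_phantom(spec, sc)
  mask <- ph$class_id > 0 & ph$class_id < 3 # GM + WM (CSF is ~pure free water)
  maps <- fit_voxelwise(ph$dataset, mask = mask)
  for (nm in c("MD", "ft", "S0", "S0s", "Ds", "fs")) {
    rel <- abs(maps[[nm]][mask] - ph$truth[[nm]][mask]) /
      pmax(abs(ph$truth[[nm]][mask]), 1e-12)
    expect_lt(max(rel), 1e-6)
  }
  expect_true(all(maps$converged_low[mask]))
  expect_true(all(maps$converged_high[mask]))
  expect_true(all(is.na(maps$MD[!mask])))
})

test_that("effective-b maps rescale the fitted diffusivities as expected", {
  sc <- small_scheme(seed = 3)
  mono <- compartment_mixture(1, 0.5)
  spec <- uniform_phantom_spec(mono, n = 2)
  ph <- generate_phantom(spec, sc)
  base <- fit_voxelwise(ph$dataset)
  # beff = 1 everywhere is a no-op
  ds1 <- ph$dataset; ds1$beff_map <- array(1, dim = rep(2, 3))
  same <- fit_voxelwise(ds1)
  expect_equal(same$Ds, base$Ds, tolerance = 1e-12)
  expect_equal(same$MD, base$MD, tolerance = 1e-12)
  # beff = 1.1 in one voxel: that voxel's Ds scales by 1/1.1
  beff <- array(1, dim = rep(2, 3)); beff[1] <- 1.1
  ds2 <- ph$dataset; ds2$beff_map <- beff
  scaled <- fit_voxelwise(ds2)
  expect_equal(scaled$Ds[1], base$Ds[1] / 1.1, tolerance = 1e-8)
  expect_equal(scaled$Ds[2], base$Ds[2], tolerance = 1e-12)
})

test_that("fs is invariant to global signal scaling", {
  sc <- small_scheme(seed = 5)
  spec <- uniform_phantom_spec(gm_mixture(), n = 2)
  ph <- generate_phantom(spec, sc)
  a <- fit_voxelwise(ph$dataset)
  scaled <- dwi_dataset(ph$dataset$signal * 37.5, sc)
  b <- fit_voxelwise(scaled)
  expect_equal(b$fs, a$fs, tolerance = 1e-9)
  expect_equal(b$S0s[1] / a$S0s[1], 37.5, tolerance = 1e-9)
})

test_that("fit results do not depend on volume ordering within shells", {
  sc <- small_scheme(seed = 7)
  spec <- uniform_phantom_spec(gm_mixture(), n = 2, sigma = 0.02, seed = 11)
  ph <- generate_phantom(spec, sc)
  a <- fit_voxelwise(ph$dataset)
  perm <- with_seed_local(13, sample.int(nrow(sc)))
  sc2 <- ph$dataset$scheme[perm, ]
  sc2$acq_index <- seq_len(nrow(sc2)) # reindex after reshuffle
  class(sc2) <- c("acq_scheme", "data.frame")
  ds2 <- dwi_dataset(ph$dataset$signal[, , , perm, drop = FALSE], sc2,
                     sigma_map = ph$dataset$sigma_map)
  b <- fit_voxelwise(ds2)
  expect_equal(b$Ds, a$Ds, tolerance = 1e-10)
  expect_equal(b$fs, a$fs, tolerance = 1e-10)
})

test_that("outliers injected into a shell are excluded before fitting", {
  sc <- build_scheme(b_values = c(250, 1500, 10500, 15000),
                     repeats = c(5, 5, 8, 8), seed = 2)
  spec <- uniform_phantom_spec(gm_mixture(), n = 2)
  ph <- generate_phantom(spec, sc)
  clean <- fit_voxelwise(ph$dataset)
  sig <- ph$dataset$signal
  spike <- which(sc$b == 15000)[1]
  sig[1, 1, 1, spike] <- sig[1, 1, 1, spike] * 40
  dirty <- fit_voxelwise(dwi_dataset(sig, sc))
  expect_equal(dirty$n_excluded_highb[1], 1)
  expect_equal(dirty$Ds[1], clean$Ds[1], tolerance = 1e-9)
  expect_equal(dirty$S0s[1], clean$S0s[1], tolerance = 1e-9)
})

test_that("unfittable schemes are rejected up front", {
  lowonly <- build_scheme(b_values = c(250, 1500), repeats = c(3, 3))
  ph <- generate_phantom(uniform_phantom_spec(gm_mixture(), n = 2), lowonly)
  expect_error(fit_voxelwise(ph$dataset), "high-b regime")
})
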