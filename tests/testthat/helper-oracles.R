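# Independent brute-force oracles, kept free of the package's fitting code.

# grid-search least squares for the low-b bi-exponential with fixed d_fw:
# S0 is profiled out linearly for each (ft, MD) grid point, the grid is
# refined twice around the incumbent optimum
oracle_lowb <- function(signals, b, d_fw = 3, md_max = 3, n_grid = 400) {
  bms <- b / 1000
  sse_best <- Inf
  best <- c(ft = NA, MD = NA, S0 = NA)
  ft_rng <- c(0, 1); md_rng <- c(0, md_max)
  for (round in 1:3) {
    ft_g <- seq(ft_rng[1], ft_rng[2], length.out = n_grid)
    md_g <- seq(md_rng[1], md_rng[2], length.out = n_grid)
    for (ft in ft_g) {
      # g is a matrix: rows = data points, cols = MD grid
      g <- ft * exp(-outer(bms, md_g)) + (1 - ft) * exp(-bms * d_fw)
      s0 <- colSums(g * signals) / colSums(g^2)
      sse <- sum(signals^2) - 2 * s0 * colSums(g * signals) + s0^2 * colSums(g^2)
      k <- which.min(sse)
      if (sse[k] < sse_best) {
        sse_best <- sse[k]
        best <- c(ft = ft, MD = md_g[k], S0 = s0[k])
      }
    }
    dft <- diff(ft_rng) / n_grid * 4
    dmd <- diff(md_rng) / n_grid * 4
    ft_rng <- c(max(0, best["ft"] - dft), min(1, best["ft"] + dft))
    md_rng <- c(max(0, best["MD"] - dmd), min(md_max, best["MD"] + dmd))
  }
  as.list(best)
}

# 1D grid search for the mono-exponential, S0s profiled out linearly
oracle_monoexp <- function(signals, b, ds_max = 1, n_grid = 4000) {
  bms <- b / 1000
  ds_rng <- c(0, ds_max)
  best <- c(Ds = NA, S0s = NA)
  for (round in 1:3) {
    ds_g <- seq(ds_rng[1], ds_rng[2], length.out = n_grid)
    g <- exp(-outer(bms, ds_g))
    s0 <- colSums(g * signals) / colSums(g^2)
    sse <- sum(signals^2) - 2 * s0 * colSums(g * signals) + s0^2 * colSums(g^2)
    k <- which.min(sse)
    best <- c(Ds = ds_g[k], S0s = s0[k])
    d <- diff(ds_rng) / n_grid * 4
    ds_rng <- c(max(0, best["Ds"] - d), min(ds_max, best["Ds"] + d))
  }
  as.list(best)
}

# tri-exponential grey-matter mixture used throughout the tests
gm_mixture <- function() compartment_mixture(c(0.2, 0.72, 0.08), c(3, 1, 0.1))

# small single-class phantom on an n^3 grid, every voxel labelled as lobule 1
uniform_phantom_spec <- function(mix, n = 4, sigma = 0, drift = c(1, 0, 0),
                                 S0 = 100, seed = 1) {
  shape <- rep(n, 3)
  phantom_spec(shape = shape, classes = list(GM = mix),
               geometry = list(class_id = array(1L, shape),
                               labels = array(1L, shape)),
               S0 = S0, sigma = sigma, drift = drift, seed = seed)
}

# compact scheme: one repeat of every default shell, b0 interleaved
small_scheme <- function(seed = 1, repeats = rep(2, 11)) {
  build_scheme(repeats = repeats, seed = seed)
}

# evaluate expr under a temporary seed without disturbing the session RNG
with_seed_local <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
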