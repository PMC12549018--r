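test_that("rate binarization uses a strict threshold", {
  r <- matrix(c(0, 0.7, 0.71, 1.2, 0.5, 0.3, 0.69, 2), 2, 4)
  b <- binarize_rates(r)
  expect_equal(sum(b$bits), 3)
  expect_equal(b$p, 3 / 8)
  expect_equal(b$L, 8)
  z <- binarize_rates(matrix(0, 3, 5))
  expect_equal(z$p, 0)
  expect_error(binarize_rates(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("z-score binarization flags only extreme positive excursions", {
  # crafted 10-sample vector with one extreme spike
  x <- c(1, 1, 1, 1, 1, 1, 1, 1, 1, 40)
  zb <- zscore_binarize(matrix(x, 1), z_threshold = 2)
  z <- (x - mean(x)) / stats::sd(x)
  expect_equal(which(zb$bits[1, ] == 1), which(z > 2))
  expect_equal(sum(zb$bits), 1)
  # constant channel: all-zero with a warning
  expect_warning(zc <- zscore_binarize(rbind(x, rep(2, 10))), "zero-variance")
  expect_equal(sum(zc$bits[2, ]), 0)
})

test_that("z > 3 exceedance rate matches the Gaussian tail", {
  set.seed(11)
  x <- matrix(stats::rnorm(4 * 2e5), 4)
  b <- zscore_binarize(x, 3)
  expect_lt(abs(b$p - stats::pnorm(3, lower.tail = FALSE)) /
              stats::pnorm(3, lower.tail = FALSE), 0.15)
})

test_that("lz76 equals the brute-force parser on all short strings", {
  for (len in 0:9) {
    for (bits in all_bitstrings(len)) {
      expect_identical(lz76(bits), as.numeric(lz76_oracle(bits)),
                       label = paste0("lz76({", paste(bits, collapse = ""),
                                      "})"))
    }
  }
})

test_that("lz76 handles edge cases and approaches the random-string rate", {
  expect_equal(lz76(integer(0)), 0)
  expect_equal(lz76(0L), 1)
  expect_equal(lz76(rep(0L, 100)), 2)
  set.seed(5)
  L <- 1e4
  ratio <- vapply(1:10, function(i) {
    lz76(as.integer(stats::runif(L) < 0.5)) / (L / log2(L))
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("lz76 is non-decreasing under sequence extension", {
  set.seed(7)
  for (rep in 1:5) {
    bits <- as.integer(stats::runif(400) < 0.5)
    counts <- vapply(seq(50, 400, by = 50),
                     function(k) lz76(bits[1:k]), numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("the random-raster normalizer C_L matches the closed form", {
  # L = 1024, p = 0.5: H = 1, log2 L = 10, so C_L = 102.4
  set.seed(3)
  bits <- matrix(as.integer(stats::runif(1024) < 0.5), 4)
  raster <- binary_raster(bits)
  # reconstruct C_L from the definition via a p = 0.5 raster
  p <- raster$p
  H <- -p * log2(p) - (1 - p) * log2(1 - p)
  CL_emp <- raster$L * H / log2(raster$L)
  CL_half <- 1024 * 1 / 10
  expect_equal(1024 * 1 / log2(1024), CL_half)
  expect_lt(abs(CL_emp - CL_half) / CL_half, 0.01)
})

test_that("pci is missing for saturated rasters and near 1 for random ones", {
  expect_true(is.na(pci_normalized(binary_raster(matrix(1, 3, 10)))))
  expect_true(is.na(pci_normalized(binary_raster(matrix(0, 3, 10)))))
  set.seed(21)
  b <- binary_raster(matrix(as.integer(stats::runif(10 * 1000) < 0.5), 10))
  expect_lt(abs(pci_normalized(b) - 1), 0.05)
})

test_that("pci is invariant under a global 0-1 bit swap", {
  set.seed(9)
  for (p in c(0.1, 0.4)) {
    bits <- matrix(as.integer(stats::runif(6 * 300) < p), 6)
    expect_equal(pci_normalized(binary_raster(bits)),
                 pci_normalized(binary_raster(1L - bits)))
  }
})

test_that("flatten order changes the parse but not saturation handling", {
  set.seed(2)
  bits <- matrix(as.integer(stats::runif(5 * 50) < 0.3), 5)
  cm <- pci_normalized(binary_raster(bits), "channel-major")
  tm <- pci_normalized(binary_raster(bits), "time-major")
  expect_true(is.finite(cm) && is.finite(tm))
})

test_that("cascade AUC matches the folded-normal floor for iid channels", {
  set.seed(31)
  N <- 20; T <- 20000
  cp <- cascade_profile(matrix(stats::rnorm(N * T), N), dt_s = 0.01)
  expect_lt(abs(cp$auc / ((T - 1) * 0.01) - sqrt(2 / (pi * N))), 0.01)
})

test_that("cascade profile respects symmetry and synchrony", {
  set.seed(13)
  base <- stats::rnorm(500)
  x <- rbind(base, base, base)
  cp <- cascade_profile(x, dt_s = 0.01)
  z <- (base - mean(base)) / stats::sd(base)
  expect_equal(cp$profile, abs(z), tolerance = 1e-10)
  # channel permutations leave the profile invariant
  y <- matrix(stats::rnorm(5 * 400), 5)
  expect_equal(cascade_profile(y, dt_s = 0.01)$profile,
               cascade_profile(y[c(3, 1, 5, 2, 4), ], dt_s = 0.01)$profile)
  expect_error(cascade_profile(matrix(1, 3, 10), dt_s = 0.01),
               "zero variance")
})

test_that("zero-amplitude stimulation gives a ratio of exactly 1", {
  cn <- tiny_connectome()
  for (seed in c(1, 2, 3)) {
    cfg <- sim_config(g = 0.5, sigma_noise = 0.04, dt = 0.05,
                      duration = 3000, record_dt = 10, seed = seed,
                      init = "random")
    res <- spci_trial(cn, nmm_params(), cfg,
                      stimulus_spec(1, onset = 500, amplitude = 0),
                      window_s = 2)
    expect_identical(res$spci_stim, res$spci_baseline)
    if (!is.na(res$ratio)) expect_identical(res$ratio, 1)
  }
})

test_that("spci_max aggregates trial ratios and handles zero amplitude", {
  cn <- tiny_connectome()
  cfg <- sim_config(g = 0.5, sigma_noise = 0.04, dt = 0.05, duration = 6000,
                    record_dt = 10, seed = 8, init = "random")
  res <- spci_max(cn, nmm_params(), cfg, nodes = c(1, 2), n_trials = 2,
                  window_s = 2, amplitude = 0)
  expect_equal(res$spci_max, 1)
  expect_equal(res$spci_min, 1)
  res2 <- spci_max(cn, nmm_params(), cfg, nodes = c(1, 2), n_trials = 2,
                   window_s = 2, amplitude = 5)
  expect_equal(res2$spci_max,
               max(vapply(res2$trials, function(t) t$ratio, numeric(1)),
                   na.rm = TRUE))
  expect_lte(res2$spci_min, res2$spci_max)
})
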