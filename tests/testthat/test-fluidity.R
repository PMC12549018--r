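test_that("pearson windowed FC handles identical and degenerate channels", {
  set.seed(1)
  base <- stats::rnorm(1000)
  x <- rbind(base, base, stats::rnorm(1000))
  st <- windowed_fc(x, fs = 100, fc_window_spec(2, 1, "pearson"))
  expect_true(all(abs(st$matrices[1, 2, ] - 1) < 1e-12))
  expect_true(all(diag(st$matrices[, , 1]) == 1))
  # zero-variance channel within windows
  y <- rbind(base, rep(1, 1000))
  expect_warning(sty <- windowed_fc(y, 100, fc_window_spec(2, 1, "pearson")),
                 "zero-variance")
  expect_true(all(is.na(sty$matrices[1, 2, ])))
})

test_that("circular FC is 1 for identical phases and -1 for mirrored ones", {
  set.seed(2)
  ph <- matrix(stats::runif(600, -pi, pi), 1)
  x <- rbind(ph, ph, -ph)
  st <- windowed_fc(x, fs = 100, fc_window_spec(2, 2, "circular"))
  expect_true(all(abs(st$matrices[1, 2, ] - 1) < 1e-10))
  expect_true(all(abs(st$matrices[1, 3, ] + 1) < 1e-10))
})

test_that("independent uniform phases decorrelate over long windows", {
  set.seed(3)
  x <- matrix(stats::runif(4 * 20000, -pi, pi), 4)
  st <- windowed_fc(x, fs = 1000, fc_window_spec(20, 20, "circular"))
  off <- st$matrices[upper.tri(st$matrices[, , 1])]
  expect_lt(max(abs(off)), 0.05)
})

test_that("instantaneous phase tracks a sinusoid and its transforms", {
  fs <- 200; f <- 7
  t <- seq(0, 5, by = 1 / fs)[-1]
  x <- rbind(sin(2 * pi * f * t), -sin(2 * pi * f * t),
             3.7 * sin(2 * pi * f * t))
  ph <- instantaneous_phase(x)
  core <- 200:800  # away from edges
  slope <- diff(ph[1, core])
  slope <- slope[abs(slope) < pi]  # drop wraps
  expect_lt(abs(mean(slope) * fs - 2 * pi * f) / (2 * pi * f), 0.01)
  # sign flip shifts the phase by pi
  d <- abs(ph[1, core] - ph[2, core])
  expect_true(all(abs(pmin(d, 2 * pi - d) - pi) < 0.05))
  # amplitude scaling leaves the phase unchanged (modulo the pi wrap point)
  dphi <- abs(ph[1, ] - ph[3, ])
  expect_lt(max(pmin(dphi, 2 * pi - dphi)), 1e-8)
  expect_error(instantaneous_phase(matrix(1, 2, 100)), "constant")
})

test_that("dfc matrix has the exact block structure of a two-state stream", {
  n <- 4
  A <- diag(n); B <- diag(n)
  A[upper.tri(A)] <- c(1, -1, 1, -1, 1, -1)
  B[upper.tri(B)] <- c(1, 1, -1, -1, 1, -1)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  B[lower.tri(B)] <- t(B)[lower.tri(B)]
  stream <- structure(list(matrices = array(c(A, A, B, B), c(n, n, 4)),
                           window_centers = 1:4, wlen = 10, hop = 10,
                           n_overlap = 0,
                           spec = fc_window_spec(1, 1, "pearson")),
                      class = "fc_stream")
  d <- dfc_matrix(stream)
  expect_equal(d$offset, 1L)
  expect_equal(d$dfc, t(d$dfc))
  expect_true(all(diag(d$dfc) == 1))
  c_ab <- stats::cor(A[upper.tri(A)], B[upper.tri(B)])
  expect_equal(d$dfc[1, 2], 1)
  expect_equal(d$dfc[3, 4], 1)
  expect_equal(d$dfc[1, 3], c_ab)
  # hand-computed fluidity of the retained entries {1, 1, c, c, c, c}
  expect_equal(fluidity(d), stats::var(c(1, 1, rep(c_ab, 4))))
})

test_that("a stream of identical FC matrices has zero fluidity", {
  set.seed(4)
  A <- stats::cor(matrix(stats::rnorm(200 * 5), 200, 5))
  stream <- structure(list(matrices = array(rep(A, 6), c(5, 5, 6)),
                           window_centers = 1:6, wlen = 10, hop = 10,
                           n_overlap = 0,
                           spec = fc_window_spec(1, 1, "pearson")),
                      class = "fc_stream")
  expect_equal(fluidity(dfc_matrix(stream)), 0)
})

test_that("the overlap-exclusion offset follows the window geometry", {
  set.seed(5)
  x <- matrix(stats::rnorm(6 * 3000), 6)
  # step = window: no overlap, offset 1
  d1 <- dfc_matrix(windowed_fc(x, 100, fc_window_spec(2, 2, "pearson")))
  expect_equal(d1$offset, 1L)
  # 3 s window, 1 s step: offset ceiling(200/100)+1 = 3
  d3 <- dfc_matrix(windowed_fc(x, 100, fc_window_spec(3, 1, "pearson")))
  expect_equal(d3$offset, 3L)
  expect_gte(fluidity(d3), 0)
})

test_that("stationary independent channels sit at the finite-pair noise floor", {
  # dFC entries for stationary input are correlations of P-dimensional
  # noise vectors (P = pairs), so fluidity ~ 1/P; with 16 channels the
  # floor is about 1/120
  set.seed(6)
  vals <- vapply(1:3, function(i) {
    x <- matrix(stats::rnorm(16 * 6000), 16)
    fluidity_of(x, 100, fc_window_spec(5, 5, "pearson"))
  }, numeric(1))
  expect_lt(mean(vals), 2 / 120)
})

test_that("printed-variant circular correlation is available and differs", {
  set.seed(7)
  x <- matrix(stats::runif(3 * 500, -pi, pi), 3)
  std <- windowed_fc(x, 100, fc_window_spec(2, 2, "circular"),
                     printed_variant = FALSE)
  alt <- windowed_fc(x, 100, fc_window_spec(2, 2, "circular"),
                     printed_variant = TRUE)
  expect_false(isTRUE(all.equal(std$matrices, alt$matrices)))
  expect_true(all(abs(std$matrices) <= 1 + 1e-12))
})
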