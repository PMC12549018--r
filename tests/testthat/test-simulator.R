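test_that("isolated-mass equilibria match the bifurcation structure", {
  eq <- stationary_states(nmm_params())
  expect_equal(nrow(eq), 3)
  expect_equal(eq$type, c("stable-node", "saddle", "stable-focus"))
  expect_equal(sum(eq$stable), 2)
  # fixed-point residuals vanish
  for (i in seq_len(nrow(eq))) {
    expect_equal(1 / pi + 2 * eq$r[i] * eq$v[i], 0, tolerance = 1e-10)
    expect_equal(eq$v[i]^2 - 5 + 15 * eq$r[i] - (pi * eq$r[i])^2, 0,
                 tolerance = 1e-9)
  }
  # uncoupled mass (J = 0) is monostable; strong input washes out bistability
  expect_equal(sum(stationary_states(nmm_params(j_syn = 0))$stable), 1)
  hi <- stationary_states(nmm_params(), input_current = 50)
  expect_equal(sum(hi$stable), 1)
  expect_gt(hi$r[hi$stable], 1)
})

test_that("noise-free dynamics stays at attractors and leaves saddles", {
  eq <- stationary_states(nmm_params())
  cn <- single_mass()
  for (i in which(eq$stable)) {
    cfg <- sim_config(g = 0, sigma_noise = 0, dt = 0.01, duration = 100,
                      record_dt = 1,
                      init = list(r = eq$r[i], v = eq$v[i]))
    s <- simulate_network(cn, config = cfg)
    expect_lt(max(abs(s$r - eq$r[i])), 1e-6)
    expect_lt(max(abs(s$v - eq$v[i])), 1e-6)
  }
})

test_that("identical seeds give bit-identical trajectories", {
  cn <- tiny_connectome()
  cfg <- sim_config(g = 0.5, sigma_noise = 0.04, dt = 0.02, duration = 500,
                    record_dt = 1, seed = 9, init = "random")
  a <- simulate_network(cn, config = cfg)
  b <- simulate_network(cn, config = cfg)
  expect_identical(a$r, b$r)
  expect_identical(a$v, b$v)
  cfg2 <- cfg; cfg2$seed <- 10L
  expect_false(identical(a$r, simulate_network(cn, config = cfg2)$r))
})

test_that("firing rates stay non-negative under strong noise", {
  cn <- tiny_connectome()
  cfg <- sim_config(g = 0.4, sigma_noise = 0.06, dt = 0.05, duration = 2000,
                    record_dt = 1, seed = 2, init = "down")
  s <- simulate_network(cn, config = cfg)
  expect_gte(min(s$r), 0)
})

test_that("halving dt changes a noise-free endpoint only slightly", {
  cn <- toy3()
  init <- list(r = c(0.1, 0.9, 0.5), v = c(-1.5, -0.2, -0.4))
  ends <- lapply(c(0.02, 0.01), function(dt) {
    cfg <- sim_config(g = 0.3, sigma_noise = 0, dt = dt, duration = 50,
                      record_dt = 50, init = init, conduction_speed = Inf)
    s <- simulate_network(cn, config = cfg)
    c(s$r[, ncol(s$r)], s$v[, ncol(s$v)])
  })
  expect_lt(max(abs(ends[[1]] - ends[[2]])), 1e-3)
})

test_that("infinite conduction speed equals an explicit zero-delay graph", {
  cn <- tiny_connectome()
  cn0 <- cn; cn0$lengths[] <- 0
  cfg <- sim_config(g = 0.5, sigma_noise = 0.03, dt = 0.02, duration = 300,
                    record_dt = 1, seed = 4, init = "random",
                    conduction_speed = Inf)
  a <- simulate_network(cn, config = cfg)
  cfg$conduction_speed <- 1
  b <- simulate_network(cn0, config = cfg)
  expect_identical(a$r, b$r)
})

test_that("the C++ integrator matches an R reference Heun step (no noise)", {
  cn <- toy3()
  p <- nmm_params()
  dt <- 0.02; n_steps <- 250
  r <- c(0.2, 1.0, 0.6); v <- c(-1.2, -0.2, -0.5)
  W <- cn$weights
  for (s in seq_len(n_steps)) {
    I <- 0.3 * as.vector(W %*% r)
    f <- function(r, v) {
      fr <- p$delta / pi + 2 * r * v
      fv <- v^2 + p$eta_bar + p$j_syn * r + I - (pi * r)^2
      # same increment taming as the integrator: per-stage drift capped at
      # 2 state-units
      m <- pmax(abs(fr), abs(fv))
      s <- ifelse(dt * m > 2, 2 / (dt * m), 1)
      list(r = fr * s, v = fv * s)
    }
    k1 <- f(r, v)
    rp <- pmax(r + dt * k1$r, 0); vp <- v + dt * k1$v
    k2 <- f(rp, vp)
    r <- pmax(r + dt / 2 * (k1$r + k2$r), 0)
    v <- v + dt / 2 * (k1$v + k2$v)
  }
  cfg <- sim_config(g = 0.3, sigma_noise = 0, dt = dt,
                    duration = n_steps * dt, record_dt = dt,
                    init = list(r = c(0.2, 1.0, 0.6),
                                v = c(-1.2, -0.2, -0.5)),
                    conduction_speed = Inf)
  s <- simulate_network(cn, config = cfg)
  expect_equal(s$r[, ncol(s$r)], r, tolerance = 1e-12)
  expect_equal(s$v[, ncol(s$v)], v, tolerance = 1e-12)
})

test_that("stimulus drives a downstate mass past the saddle", {
  cn <- single_mass()
  eq <- stationary_states(nmm_params())
  cfg <- sim_config(g = 0, sigma_noise = 0, dt = 0.01, duration = 100,
                    record_dt = 1, init = "down")
  stim <- stimulus_spec(1, onset = 20, duration_ms = 10, amplitude = 5)
  s <- simulate_network(cn, config = cfg, stimulus = stim)
  up <- eq$r[eq$type == "stable-focus"]
  expect_lt(abs(s$r[1, ncol(s$r)] - up) / up, 0.05)
  expect_error(simulate_network(cn, config = cfg,
                                stimulus = stimulus_spec(5, 20)),
               "out of range")
  expect_error(simulate_network(cn, config = cfg,
                                stimulus = stimulus_spec(1, 95, 10)),
               "past simulation end")
})

test_that("config validation rejects bad settings", {
  expect_error(sim_config(dt = 0.2), "dt")
  expect_error(sim_config(g = -1), "non-negative")
  expect_error(sim_config(duration = 0.001, dt = 0.01), "duration")
})
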