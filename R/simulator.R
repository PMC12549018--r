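#' Neural mass parameters
#'
#' Parameters of the exact mean-field reduction of an all-to-all network of
#' quadratic integrate-and-fire neurons (the Montbrio-Pazo-Roxin model). With
#' the defaults (`eta_bar = -5`, `delta = 1`, `j_syn = 15`) an isolated mass
#' is bistable: a low-firing stable node (downstate) coexists with a
#' high-firing stable focus (upstate).
#'
#' @param eta_bar Mode of the Lorentzian excitability distribution.
#' @param delta Half-width of the excitability distribution (> 0).
#' @param j_syn Synaptic weight J.
#' @return An object of class `nmm_params`.
#' @export
nmm_params <- function(eta_bar = -5, delta = 1, j_syn = 15) {
  if (delta <= 0) stop("delta must be positive")
  structure(list(eta_bar = eta_bar, delta = delta, j_syn = j_syn),
            class = "nmm_params")
}

#' Simulation configuration
#'
#' Time is measured in model milliseconds throughout; analysis windows quoted
#' in seconds elsewhere in the package mean thousands of model time units.
#'
#' @param g Global coupling G (>= 0), scaling the connectome weights.
#' @param sigma_noise Additive noise standard deviation; per-step increments
#'   are `sigma_noise * sqrt(dt)`.
#' @param dt Integration step (ms), must be <= 0.1.
#' @param duration Simulated duration (ms).
#' @param conduction_speed Conduction speed (mm/ms); `Inf` disables delays.
#' @param noise_targets `"r-and-v"` applies independent noise to both state
#'   variables (the default: the model's stochastic term acts on the whole
#'   node state); `"v-only"` restricts it to the membrane potential.
#' @param seed Integer seed for the simulator's counter-based noise stream.
#' @param init Initial state: `"down"` / `"up"` place every node at the
#'   corresponding isolated-mass attractor, `"random"` assigns each node to
#'   one of the two attractors with equal probability (seeded), or a list
#'   with numeric vectors `r` and `v`.
#' @param record_dt Recording resolution (ms); trajectories are stored every
#'   `record_dt / dt` steps.
#' @param v_bound Divergence guard: the run aborts if any |v| exceeds this.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(g = 0.56, sigma_noise = 0.036, dt = 0.01,
                       duration = 1000, conduction_speed = 1,
                       noise_targets = c("r-and-v", "v-only"),
                       seed = 1, init = "down", record_dt = 1,
                       v_bound = 1e3) {
  noise_targets <- match.arg(noise_targets)
  if (dt <= 0 || dt > 0.1) stop("dt must be in (0, 0.1]")
  if (duration < dt) stop("duration must be >= dt")
  if (g < 0) stop("g must be non-negative")
  if (sigma_noise < 0) stop("sigma_noise must be non-negative")
  if (conduction_speed <= 0) stop("conduction_speed must be positive")
  if (record_dt < dt) stop("record_dt must be >= dt")
  structure(list(g = g, sigma_noise = sigma_noise, dt = dt,
                 duration = duration, conduction_speed = conduction_speed,
                 noise_targets = noise_targets, seed = as.integer(seed),
                 init = init, record_dt = record_dt, v_bound = v_bound),
            class = "sim_config")
}

#' Single-pulse stimulus specification
#'
#' A transient external current added to the membrane-potential equation of
#' one region, mimicking a single-pulse cortical stimulation. The default
#' amplitude (5, current units of the v-equation) comfortably exceeds the
#' saddle-node current of the isolated mass (about 1.86 at the default
#' parameters), so a downstate node is driven past the saddle within the
#' default 10 ms pulse.
#'
#' @param node Stimulated region index (1-based).
#' @param onset Pulse onset (ms from simulation start).
#' @param duration_ms Pulse duration (ms).
#' @param amplitude Additive current on the v-equation.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(node, onset, duration_ms = 10, amplitude = 5) {
  if (duration_ms <= 0) stop("duration_ms must be positive")
  structure(list(node = as.integer(node), onset = onset,
                 duration_ms = duration_ms, amplitude = amplitude),
            class = "stimulus_spec")
}

delay_steps <- function(connectome, conduction_speed, dt) {
  if (is.infinite(conduction_speed)) {
    matrix(0L, connectome$n_regions, connectome$n_regions)
  } else {
    matrix(as.integer(ceiling(connectome$lengths / conduction_speed / dt)),
           connectome$n_regions, connectome$n_regions)
  }
}

resolve_init <- function(init, p, n, seed) {
  if (is.list(init)) {
    if (length(init$r) != n || length(init$v) != n)
      stop("explicit initial state must supply r and v of length n")
    return(list(r = as.numeric(init$r), v = as.numeric(init$v)))
  }
  eq <- stationary_states(p, input_current = 0)
  att <- eq[eq$stable, , drop = FALSE]
  dn <- att[which.min(att$r), ]
  up <- att[which.max(att$r), ]
  switch(init,
    down = list(r = rep(dn$r, n), v = rep(dn$v, n)),
    up = list(r = rep(up$r, n), v = rep(up$v, n)),
    random = {
      # deterministic per-node assignment derived from the seed
      u <- vapply(seq_len(n), function(i) {
        x <- (as.numeric(seed) * 2654435761 + i * 40503) %% 65536
        x / 65536
      }, numeric(1))
      upmask <- u < 0.5
      list(r = ifelse(upmask, up$r, dn$r), v = ifelse(upmask, up$v, dn$v))
    },
    stop("unknown init: ", init))
}

#' Simulate the whole-brain network
#'
#' Integrates the network of Montbrio-Pazo-Roxin neural masses coupled by the
#' connectome: each region's membrane-potential equation receives the
#' delayed, weight- and G-scaled firing rates of its neighbours, additive
#' Gaussian white noise (per [sim_config()] `noise_targets`), and optionally
#' a single-pulse stimulus current. Integration uses a stochastic Heun
#' scheme with the coupling term frozen over each step; firing rates are
#' clamped at zero after every stage. Runs are bit-reproducible given the
#' seed, and noise is a pure function of (seed, step), so two runs differing
#' only in the stimulus share an identical noise stream.
#'
#' @param connectome A [connectome()].
#' @param params [nmm_params()].
#' @param config [sim_config()].
#' @param stimulus Optional [stimulus_spec()].
#' @return An object of class `sim_result`: firing-rate matrix `r`
#'   (regions x time), membrane potentials `v`, the recording time base `t`
#'   (ms), `dt_record`, and `config_echo` (params, config, stimulus)
#'   sufficient to re-run the simulation bit-identically.
#' @export
simulate_network <- function(connectome, params = nmm_params(),
                             config = sim_config(), stimulus = NULL) {
  validate_connectome(connectome)
  n <- connectome$n_regions
  if (!is.null(stimulus)) {
    if (stimulus$node < 1 || stimulus$node > n)
      stop("stimulus node out of range")
    if (stimulus$onset + stimulus$duration_ms > config$duration)
      stop("stimulus extends past simulation end")
  }
  out <- run_core(connectome, params, config, stimulus,
                  init_state = resolve_init(config$init, params, n,
                                            config$seed))
  if (out$diverged)
    stop("simulation diverged (|v| exceeded ", config$v_bound,
         " at step ", out$steps_done, "); reduce dt or coupling")
  sim_result(out, connectome, params, config, stimulus)
}

# shared C++ call; init_state is {r, v} or a checkpoint (with r_hist/pos)
run_core <- function(connectome, params, config, stimulus, init_state,
                     step_offset = 0, n_steps = NULL, checkpoints = integer(0)) {
  dt <- config$dt
  if (is.null(n_steps)) n_steps <- round(config$duration / dt)
  dmat <- delay_steps(connectome, config$conduction_speed, dt)
  stim_node <- -1L; stim_on <- 0L; stim_off <- 0L; stim_amp <- 0
  if (!is.null(stimulus)) {
    stim_node <- stimulus$node - 1L
    stim_on <- as.integer(round(stimulus$onset / dt))
    stim_off <- as.integer(round((stimulus$onset + stimulus$duration_ms) / dt))
    stim_amp <- stimulus$amplitude
  }
  rec_every <- max(1L, as.integer(round(config$record_dt / dt)))
  hist0 <- NULL; pos0 <- 0L
  if (!is.null(init_state$r_hist)) {
    hist0 <- init_state$r_hist
    pos0 <- init_state$pos
  }
  .sim_montbrio_cpp(connectome$weights, dmat,
                    params$eta_bar, params$delta, params$j_syn,
                    config$g, config$sigma_noise, dt, as.integer(n_steps),
                    rec_every, config$noise_targets == "r-and-v",
                    as.double(config$seed), as.double(step_offset),
                    init_state$r, init_state$v, hist0, pos0,
                    stim_node, stim_on, stim_off, stim_amp,
                    as.integer(checkpoints), config$v_bound)
}

sim_result <- function(out, connectome, params, config, stimulus,
                       t0 = 0) {
  rec_every <- max(1L, as.integer(round(config$record_dt / config$dt)))
  dt_rec <- rec_every * config$dt
  T <- ncol(out$r)
  structure(list(r = out$r, v = out$v,
                 t = t0 + dt_rec * seq_len(T),
                 dt_record = dt_rec, t0 = t0,
                 config_echo = list(params = params, config = config,
                                    stimulus = stimulus,
                                    labels = connectome$labels)),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d regions x %d samples (%.1f ms at %.2f ms resolution)\n",
              nrow(x$r), ncol(x$r), max(x$t), x$dt_record))
  cat(sprintf("  G = %.3g, sigma = %.3g, seed = %d%s\n",
              x$config_echo$config$g, x$config_echo$config$sigma_noise,
              x$config_echo$config$seed,
              if (is.null(x$config_echo$stimulus)) "" else
                sprintf(", stimulus on node %d", x$config_echo$stimulus$node)))
  invisible(x)
}

#' Equilibria of an isolated neural mass
#'
#' Solves the fixed-point equations of a single mass under a constant input
#' current I: `delta/pi + 2 r v = 0` and
#' `v^2 + eta_bar + J r + I - (pi r)^2 = 0`. Substituting
#' `v = -delta / (2 pi r)` turns the system into a quartic in r, whose real
#' positive roots are classified by the Jacobian eigenvalues into stable
#' nodes, stable foci, saddles, and unstable points. At the default
#' parameters and I = 0 the mass has a low-rate stable node (downstate), a
#' saddle, and a high-rate stable focus (upstate).
#'
#' @param params [nmm_params()].
#' @param input_current Constant input current I.
#' @return A data frame with columns `r`, `v`, `type` (one of
#'   `"stable-node"`, `"stable-focus"`, `"saddle"`, `"unstable"`), and
#'   `stable` (logical), sorted by `r`.
#' @export
stationary_states <- function(params, input_current = 0) {
  eta <- params$eta_bar; delta <- params$delta; J <- params$j_syn
  I <- input_current
  # -pi^2 r^4 + J r^3 + (eta + I) r^2 + delta^2/(4 pi^2) = 0
  coefs <- c(delta^2 / (4 * pi^2), 0, eta + I, J, -pi^2)
  roots <- polyroot(coefs)
  scale <- max(1, Mod(roots))
  re <- Re(roots)[abs(Im(roots)) < 1e-8 * scale & Re(roots) > 0]
  if (length(re) == 0) stop("no positive equilibria found")
  re <- sort(unique(round(re, 12)))
  res <- lapply(re, function(r) {
    v <- -delta / (2 * pi * r)
    jac <- matrix(c(2 * v, J - 2 * pi^2 * r, 2 * r, 2 * v), 2, 2)
    ev <- eigen(jac, only.values = TRUE)$values
    type <-
      if (all(Re(ev) < 0)) {
        if (max(abs(Im(ev))) > 1e-10) "stable-focus" else "stable-node"
      } else if (is.complex(ev) && max(abs(Im(ev))) > 1e-10) {
        "unstable"
      } else if (prod(Re(ev)) < 0) "saddle" else "unstable"
    data.frame(r = r, v = v, type = type,
               stable = all(Re(ev) < 0), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Saddle-node input current of the isolated mass: the I at which the
# downstate and the saddle collide. Used to calibrate synthetic-connectome
# strength and to reason about stimulus amplitudes.
saddle_node_current <- function(params = nmm_params()) {
  lo <- 0; hi <- 50
  n_att <- function(I) sum(stationary_states(params, I)$stable)
  if (n_att(lo) < 2) stop("mass not bistable at I = 0")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (n_att(mid) >= 2) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
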