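#' Binary raster constructor
#'
#' A channels-by-time binary matrix together with the bookkeeping needed for
#' normalized Lempel-Ziv complexity: the flattened length `L` and the
#' fraction of ones `p`.
#'
#' @param bits Logical or 0/1 integer matrix (channels x time).
#' @param provenance Character note recording the thresholding rule applied.
#' @return An object of class `binary_raster` with fields `bits`, `L`, `p`,
#'   `provenance`.
#' @export
binary_raster <- function(bits, provenance = "unspecified") {
  bits <- matrix(as.integer(bits), nrow = nrow(bits))
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) stop("bits must be binary")
  structure(list(bits = bits, L = length(bits), p = mean(bits),
                 provenance = provenance),
            class = "binary_raster")
}

#' @export
print.binary_raster <- function(x, ...) {
  cat(sprintf("binary_raster: %d channels x %d samples (L=%d, p=%.4f; %s)\n",
              nrow(x$bits), ncol(x$bits), x$L, x$p, x$provenance))
  invisible(x)
}

#' Threshold firing rates into a binary raster
#'
#' A sample is active when the firing rate strictly exceeds the threshold.
#' The default threshold 0.7 sits between the downstate (r about 0.08) and
#' upstate (r about 1.0) rates of the neural mass, so the raster encodes the
#' up/down state of every region over time.
#'
#' @param r Firing-rate matrix (regions x time) or a `sim_result`.
#' @param threshold Activation threshold on the rate.
#' @return A [binary_raster()].
#' @export
binarize_rates <- function(r, threshold = 0.7) {
  if (inherits(r, "sim_result")) r <- r$r
  if (anyNA(r) || any(!is.finite(r))) stop("rates must be finite")
  binary_raster(r > threshold,
                provenance = sprintf("rate > %g", threshold))
}

#' Binarize signals by z-score threshold
#'
#' Each channel is z-scored along time and a sample is active when its
#' z-score strictly exceeds `z_threshold` (one-sided: only positive
#' excursions count). This is the binarization used for avalanche extraction
#' from EEG. Channels with zero variance are emitted all-zero with a
#' warning.
#'
#' @param x Signal matrix (channels x time).
#' @param z_threshold Threshold in standard deviations (default 3).
#' @return A [binary_raster()].
#' @export
zscore_binarize <- function(x, z_threshold = 3) {
  x <- as.matrix(x)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    warning(sum(sds == 0), " zero-variance channel(s) emitted all-zero")
  z <- (x - rowMeans(x)) / ifelse(sds == 0, 1, sds)
  z[sds == 0, ] <- 0
  binary_raster(z > z_threshold,
                provenance = sprintf("z > %g s.d.", z_threshold))
}

#' Lempel-Ziv (1976) complexity of a binary sequence
#'
#' Counts the number of phrases in the exhaustive-history factorization of
#' the sequence: scanning left to right, each new phrase is the shortest
#' prefix of the remainder that cannot be copied (with self-overlap allowed)
#' from an earlier starting position. For a fair-coin random string of
#' length L the count approaches `L / log2(L)`.
#'
#' @param bits 0/1 vector (or logical).
#' @return Integer phrase count; 0 for the empty sequence.
#' @export
lz76 <- function(bits) {
  bits <- as.integer(bits)
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) stop("bits must be binary")
  .lz76_cpp(bits)
}

#' Normalized perturbational complexity of a binary raster
#'
#' Computes `LZ_L / C_L` where `LZ_L` is the Lempel-Ziv complexity of the
#' flattened raster and `C_L = L * H(p) / log2(L)` is the asymptotic
#' complexity of a random sequence of the same length and activity, with
#' `H(p)` the binary entropy. Returns `NA` when the raster is saturated
#' (p equal to 0 or 1), where the measure is undefined.
#'
#' @param raster A [binary_raster()].
#' @param flatten_order `"channel-major"` (default) concatenates each
#'   channel's full time series in channel order; `"time-major"` interleaves
#'   channels sample by sample.
#' @return Numeric scalar, or `NA` for saturated rasters.
#' @export
pci_normalized <- function(raster,
                           flatten_order = c("channel-major", "time-major")) {
  flatten_order <- match.arg(flatten_order)
  p <- raster$p
  if (p <= 0 || p >= 1) return(NA_real_)
  flat <- if (flatten_order == "channel-major") as.vector(t(raster$bits))
          else as.vector(raster$bits)
  L <- length(flat)
  H <- -p * log2(p) - (1 - p) * log2(1 - p)
  .lz76_cpp(flat) / (L * H / log2(L))
}

#' Coactivation cascade profile and area under the curve
#'
#' The cascade profile is the absolute value of the mean z-scored activity
#' across channels at each time point: coherent network-wide excursions
#' produce large values, while independent fluctuations average out to the
#' folded-normal floor `sqrt(2 / (pi * N))`. The AUC is the trapezoidal
#' integral of the profile over time in seconds, quantifying how much
#' coactivation cascading the segment contains.
#'
#' @param r Activity matrix (channels x time) or `sim_result` (firing rates
#'   used).
#' @param dt_s Sampling interval in seconds (taken from a `sim_result`
#'   automatically, with 1 model ms = 1/1000 s).
#' @return List with `profile` (numeric vector) and `auc` (scalar,
#'   z-units x seconds).
#' @export
cascade_profile <- function(r, dt_s = NULL) {
  if (inherits(r, "sim_result")) {
    if (is.null(dt_s)) dt_s <- r$dt_record / 1000
    r <- r$r
  }
  if (is.null(dt_s)) stop("dt_s required for plain matrices")
  sds <- apply(r, 1, stats::sd)
  if (all(sds == 0)) stop("all channels have zero variance")
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance channel(s) dropped")
    r <- r[sds > 0, , drop = FALSE]
  }
  z <- (r - rowMeans(r)) / apply(r, 1, stats::sd)
  profile <- abs(colMeans(z))
  T <- length(profile)
  auc <- sum((profile[-1] + profile[-T]) / 2) * dt_s
  list(profile = profile, auc = auc)
}

#' Single stimulation trial of the simulated perturbational-complexity protocol
#'
#' Runs the stimulated simulation and the seed-matched baseline (the exact
#' same simulation, same noise stream, without the stimulus), binarizes the
#' firing rates of both over a window starting at stimulus onset, and
#' returns the normalized complexity of each together with their ratio. A
#' ratio above one means the pulse created complexity (triggered a cascade);
#' below one, that it destroyed ongoing structure. The ratio is `NA` when
#' either window is saturated (all-quiet or all-active), which carries no
#' complexity signal.
#'
#' @param connectome,params,config As for [simulate_network()]; the
#'   simulation must extend at least `window_s` past the stimulus onset.
#' @param stimulus A [stimulus_spec()].
#' @param window_s Analysis window length in seconds of model time.
#' @param threshold Rate binarization threshold.
#' @return An object of class `spci_result`: `spci_stim`, `spci_baseline`,
#'   `ratio`, and the protocol coordinates.
#' @export
spci_trial <- function(connectome, params = nmm_params(), config = sim_config(),
                       stimulus, window_s = 10, threshold = 0.7) {
  need <- stimulus$onset + window_s * 1000
  if (config$duration < need) {
    config$duration <- need
  }
  s_stim <- simulate_network(connectome, params, config, stimulus)
  s_base <- simulate_network(connectome, params, config, NULL)
  i0 <- floor(stimulus$onset / s_stim$dt_record) + 1
  i1 <- min(ncol(s_stim$r), i0 + round(window_s * 1000 / s_stim$dt_record) - 1)
  win <- i0:i1
  spci_from_windows(s_stim$r[, win, drop = FALSE],
                    s_base$r[, win, drop = FALSE],
                    threshold, stimulus$node, stimulus$onset,
                    config$g, config$sigma_noise)
}

spci_from_windows <- function(r_stim, r_base, threshold, node, onset, g, sigma) {
  ps <- pci_normalized(binarize_rates(r_stim, threshold))
  pb <- pci_normalized(binarize_rates(r_base, threshold))
  ratio <- if (is.na(ps) || is.na(pb)) NA_real_ else ps / pb
  structure(list(spci_stim = ps, spci_baseline = pb, ratio = ratio,
                 node = node, trial_time = onset, g = g, sigma = sigma),
            class = "spci_result")
}

#' @export
print.spci_result <- function(x, ...) {
  cat(sprintf("spci_result: node %d at t=%.0f ms, stim %.3f / baseline %.3f = ratio %s\n",
              x$node, x$trial_time, x$spci_stim, x$spci_baseline,
              ifelse(is.na(x$ratio), "NA", sprintf("%.3f", x$ratio))))
  invisible(x)
}

# Background-plus-branches protocol engine shared by spci_max / spci_min and
# the sweep. Runs one spontaneous background simulation with checkpoints at
# the trial onsets; each trial re-integrates only the post-onset window from
# the checkpoint with the stimulus applied. Because noise is a pure function
# of (seed, step), the baseline window is exactly the background segment.
spci_protocol <- function(connectome, params, config, nodes, n_trials,
                          window_s = 10, threshold = 0.7, amplitude = 5,
                          stim_duration_ms = 10, burn_in_s = 2) {
  dt <- config$dt
  win_steps <- round(window_s * 1000 / dt)
  rec_every <- max(1L, as.integer(round(config$record_dt / dt)))
  win_rec <- win_steps %/% rec_every
  burn_steps <- round(burn_in_s * 1000 / dt)
  total_steps <- round(config$duration / dt)
  if (n_trials > 1) {
    spacing <- (total_steps - burn_steps - win_steps) / (n_trials - 1)
    if (spacing <= 0) stop("duration too short for the trial plan")
  } else spacing <- 0
  onsets <- round(burn_steps + (seq_len(n_trials) - 1) * spacing)
  onsets <- (onsets %/% rec_every) * rec_every  # align to recording grid
  init <- resolve_init(config$init, params, connectome$n_regions, config$seed)
  bg <- run_core(connectome, params, config, NULL, init,
                 checkpoints = as.integer(onsets))
  if (bg$diverged) stop("background simulation diverged")
  # baseline windows are shared across nodes: evaluate their complexity once
  base_pci <- vapply(seq_len(n_trials), function(ti) {
    base_cols <- (onsets[ti] %/% rec_every) + seq_len(win_rec)
    pci_normalized(binarize_rates(bg$r[, base_cols, drop = FALSE], threshold))
  }, numeric(1))
  trials <- list()
  for (ni in seq_along(nodes)) {
    node <- nodes[ni]
    for (ti in seq_len(n_trials)) {
      ck <- bg$checkpoints[[ti]]
      onset <- onsets[ti]
      stim <- list(node = node, onset = 0, duration_ms = stim_duration_ms,
                   amplitude = amplitude)
      branch <- run_core(connectome, params, config,
                         structure(stim, class = "stimulus_spec"),
                         init_state = list(r = ck$r, v = ck$v,
                                           r_hist = ck$r_hist, pos = ck$pos),
                         step_offset = onset, n_steps = win_steps)
      if (branch$diverged) { trials <- c(trials, list(NULL)); next }
      ps <- pci_normalized(binarize_rates(branch$r[, seq_len(win_rec),
                                                   drop = FALSE], threshold))
      pb <- base_pci[ti]
      res <- structure(list(spci_stim = ps, spci_baseline = pb,
                            ratio = if (is.na(ps) || is.na(pb)) NA_real_
                                    else ps / pb,
                            node = node, trial_time = onset * dt,
                            g = config$g, sigma = config$sigma_noise),
                       class = "spci_result")
      trials <- c(trials, list(res))
    }
  }
  list(trials = Filter(Negate(is.null), trials), background = bg,
       onsets_ms = onsets * dt, nodes = nodes)
}

#' Maximum (and minimum) sPCI over a stimulation protocol
#'
#' Implements the protocol used to characterize a (G, sigma) regime: trial
#' onsets are spaced through one ongoing background simulation; each trial
#' stimulates one node and compares the post-stimulus window against the
#' seed-matched unstimulated background. The regime's sPCI is the maximum
#' ratio over nodes and trial onsets (the minimum is also reported);
#' saturated windows yield missing ratios and are excluded.
#'
#' @param connectome A [connectome()].
#' @param params [nmm_params()].
#' @param config [sim_config()]; `duration` must cover the trial plan.
#' @param nodes Integer vector of stimulation targets (drawn from the
#'   cortical mask).
#' @param n_trials Trials per node (onsets shared across nodes).
#' @param window_s Post-stimulus window (seconds of model time).
#' @param threshold Rate binarization threshold.
#' @param amplitude,stim_duration_ms Stimulus current and pulse length.
#' @return List with `spci_max`, `spci_min`, `ratios` (all defined trial
#'   ratios), and `trials` (the individual `spci_result`s).
#' @export
spci_max <- function(connectome, params = nmm_params(), config = sim_config(),
                     nodes, n_trials, window_s = 10, threshold = 0.7,
                     amplitude = 5, stim_duration_ms = 10) {
  if (any(nodes < 1 | nodes > connectome$n_regions))
    stop("stimulation node out of range")
  prot <- spci_protocol(connectome, params, config, nodes, n_trials,
                        window_s, threshold, amplitude, stim_duration_ms)
  ratios <- vapply(prot$trials, function(t) t$ratio, numeric(1))
  ratios <- ratios[!is.na(ratios)]
  rec_every <- max(1L, as.integer(round(config$record_dt / config$dt)))
  list(spci_max = if (length(ratios)) max(ratios) else NA_real_,
       spci_min = if (length(ratios)) min(ratios) else NA_real_,
       ratios = ratios, trials = prot$trials,
       background = list(r = prot$background$r, v = prot$background$v,
                         dt_record = rec_every * config$dt))
}
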