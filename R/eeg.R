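#' EEG recording container
#'
#' @param signals Channels x time numeric matrix (microvolts).
#' @param fs Sampling rate (Hz).
#' @param channel_names Optional channel labels.
#' @param subject_id Subject identifier.
#' @param condition `"wakefulness"` or `"anesthesia"`.
#' @param drug One of `"ketamine"`, `"propofol"`, `"xenon"`, `"none"`.
#' @return An object of class `eeg_recording` (also carries `duration_min`).
#' @export
eeg_recording <- function(signals, fs, channel_names = NULL,
                          subject_id = "s01",
                          condition = c("wakefulness", "anesthesia"),
                          drug = c("none", "ketamine", "propofol", "xenon")) {
  condition <- match.arg(condition)
  drug <- match.arg(drug)
  signals <- as.matrix(signals)
  if (fs <= 0) stop("fs must be positive")
  if (is.null(channel_names))
    channel_names <- sprintf("ch%02d", seq_len(nrow(signals)))
  structure(list(signals = signals, fs = fs, channel_names = channel_names,
                 subject_id = subject_id, condition = condition, drug = drug,
                 duration_min = ncol(signals) / fs / 60,
                 provenance = character(0)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("eeg_recording: %s (%s, %s), %d channels x %.1f min at %g Hz\n",
              x$subject_id, x$condition, x$drug, nrow(x$signals),
              x$duration_min, x$fs))
  if (length(x$provenance)) cat("  ", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

#' Read a multichannel recording from delimited text
#'
#' One channel per row, whitespace- or comma-delimited, with an optional
#' sidecar file of channel names (one per line).
#'
#' @param path Signal file path.
#' @param fs Sampling rate (Hz).
#' @param channels_path Optional channel-name sidecar.
#' @param ... Passed to [eeg_recording()].
#' @return An [eeg_recording()].
#' @export
read_eeg_delim <- function(path, fs, channels_path = NULL, ...) {
  m <- unname(as.matrix(utils::read.table(path, header = FALSE)))
  nm <- if (!is.null(channels_path)) readLines(channels_path) else NULL
  eeg_recording(m, fs, channel_names = nm, ...)
}

#' Broadband zero-phase band-pass filtering
#'
#' Band-passes every channel with 4th-order Butterworth high-pass and
#' low-pass sections applied forward-backward (zero phase). The default
#' band 0.5-60 Hz is the broadband range used for the resting-state
#' metrics.
#'
#' @param rec An [eeg_recording()].
#' @param hp High-pass corner (Hz).
#' @param lp Low-pass corner (Hz); must be below `fs / 2`.
#' @return The filtered recording with provenance updated.
#' @export
preprocess_eeg <- function(rec, hp = 0.5, lp = 60) {
  fs <- rec$fs
  if (lp >= fs / 2) stop("low-pass corner must be below fs/2")
  if (hp <= 0 || hp >= lp) stop("need 0 < hp < lp")
  bh <- signal::butter(4, hp / (fs / 2), type = "high")
  bl <- signal::butter(4, lp / (fs / 2), type = "low")
  out <- t(apply(rec$signals, 1, function(ch) {
    signal::filtfilt(bl, signal::filtfilt(bh, ch))
  }))
  rec$signals <- out
  rec$provenance <- c(rec$provenance,
                      sprintf("band-pass %.2g-%.2g Hz (butter 4, zero-phase)",
                              hp, lp))
  rec
}

#' Bootstrap fixed-length segments from a recording
#'
#' Samples `n` segments of `seg_len_s` seconds with uniformly random start
#' times, with replacement (segments may overlap), reproducibly from the
#' seed.
#'
#' @param rec An [eeg_recording()].
#' @param n Number of segments (default 50).
#' @param seg_len_s Segment length in seconds (default 60).
#' @param seed Integer seed.
#' @return List of `eeg_recording` segments (subject/condition inherited,
#'   segment index recorded in `provenance`).
#' @export
bootstrap_segments <- function(rec, n = 50, seg_len_s = 60, seed = 1) {
  L <- round(seg_len_s * rec$fs)
  T <- ncol(rec$signals)
  if (T < L) stop("recording shorter than the segment length")
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  starts <- floor(stats::runif(n, 0, T - L + 1)) + 1
  lapply(seq_len(n), function(k) {
    seg <- rec
    seg$signals <- rec$signals[, starts[k]:(starts[k] + L - 1), drop = FALSE]
    seg$duration_min <- L / rec$fs / 60
    seg$provenance <- c(rec$provenance,
                        sprintf("bootstrap segment %d (start %.1f s)",
                                k, (starts[k] - 1) / rec$fs))
    seg
  })
}

#' Per-recording and per-segment resting-state metric table
#'
#' For each recording: fluidity is computed once on the full recording
#' (circular correlation of instantaneous phases, sliding window per
#' `fc_spec`); Lempel-Ziv complexity (on the z > 3 s.d. binarized raster,
#' flattened), the avalanche-based functional repertoire, and GAP are
#' computed on each bootstrap segment; and a `"full"` row reports the
#' full-recording complexity and repertoire normalized per minute (the
#' quantities used for classification) together with GAP and fluidity.
#' Metric failures (e.g. saturated rasters in silent segments) are recorded
#' as `NA` cells.
#'
#' @param recordings List of preprocessed [eeg_recording()]s.
#' @param fc_spec [fc_window_spec()] for the fluidity dFC windowing;
#'   default the 0.55 s window with 50 ms step. The 1 s window / 100 ms
#'   step preset is `fc_window_spec(1, 0.1, "circular")`.
#' @param n_boot,seg_len_s,seed Bootstrap plan (see [bootstrap_segments()]).
#' @param z_threshold Binarization threshold in s.d.
#' @param bin_size Avalanche bin size in samples.
#' @return Data frame with one row per segment plus one `"full"` row per
#'   recording; columns `subject_id`, `condition`, `drug`, `segment_id`,
#'   `fluidity`, `lz_complexity`, `repertoire`, `gap`, `normalized`.
#' @export
metric_table <- function(recordings,
                         fc_spec = fc_window_spec(0.55, 0.05, "circular"),
                         n_boot = 50, seg_len_s = 60, seed = 1,
                         z_threshold = 3, bin_size = 1) {
  maybe <- function(expr) tryCatch(suppressWarnings(expr),
                                   error = function(e) NA_real_)
  rows <- list()
  for (ri in seq_along(recordings)) {
    rec <- recordings[[ri]]
    fl <- maybe(fluidity_of(instantaneous_phase(rec$signals), rec$fs,
                            fc_spec))
    raster_full <- suppressWarnings(zscore_binarize(rec$signals, z_threshold))
    lz_full <- if (raster_full$p > 0 && raster_full$p < 1)
      .lz76_cpp(as.vector(t(raster_full$bits))) else NA_real_
    rep_full <- functional_repertoire_eeg(extract_avalanches(raster_full,
                                                             bin_size))
    segs <- bootstrap_segments(rec, n_boot, seg_len_s, seed)
    for (si in seq_along(segs)) {
      seg <- segs[[si]]
      raster <- suppressWarnings(zscore_binarize(seg$signals, z_threshold))
      lz <- if (raster$p > 0 && raster$p < 1)
        .lz76_cpp(as.vector(t(raster$bits))) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = rec$subject_id, condition = rec$condition,
        drug = rec$drug, segment_id = as.character(si),
        fluidity = fl, lz_complexity = lz,
        repertoire = functional_repertoire_eeg(
          extract_avalanches(raster, bin_size)),
        gap = maybe(gap(seg$signals, seg$fs)),
        normalized = FALSE, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- data.frame(
      subject_id = rec$subject_id, condition = rec$condition,
      drug = rec$drug, segment_id = "full",
      fluidity = fl,
      lz_complexity = if (is.na(lz_full)) NA_real_ else
        lz_full / rec$duration_min,
      repertoire = rep_full / rec$duration_min,
      gap = maybe(gap(rec$signals, rec$fs)),
      normalized = TRUE, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

pink_noise <- function(n_channels, T, fs, alpha = 1) {
  f <- seq(0, fs / 2, length.out = floor(T / 2) + 1)
  amp <- c(0, 1 / (pmax(f[-1], 0.5)^(alpha / 2)))
  t(sapply(seq_len(n_channels), function(i) {
    white <- stats::rnorm(T)
    X <- stats::fft(white)
    idx <- seq_along(amp)
    scale <- numeric(T)
    scale[idx] <- amp
    if (T %% 2 == 0) scale[T:(T / 2 + 2)] <- amp[2:(T / 2)]
    else scale[T:((T + 3) / 2)] <- amp[2:((T + 1) / 2)]
    Re(stats::fft(X * scale, inverse = TRUE) / T)
  }))
}

#' Generate a synthetic multichannel EEG recording
#'
#' Produces surrogate EEG with the statistical structure the resting-state
#' metrics are sensitive to, so the full pipeline is testable without any
#' data download. All states share a pink-noise background mixed through
#' spatial patterns; they differ in their dynamics:
#' \describe{
#'   \item{wake-like}{Markov switching among `n_patterns` spatial coupling
#'     patterns at `switch_rate` (drives fluidity) plus frequent brief
#'     high-amplitude bursts over random channel subsets (drives the
#'     repertoire, complexity and GAP).}
#'   \item{anesthesia-like}{a single static coupling pattern and slow
#'     stereotyped global waves (one repeated activation pattern).}
#'   \item{burst-suppression}{the same slow global waves over a strongly
#'     suppressed background.}
#' }
#' Output is bit-reproducible given the seed.
#'
#' @param n_channels Number of channels (default 60, the study montage).
#' @param fs Sampling rate (Hz).
#' @param duration_s Duration in seconds.
#' @param state `"wake-like"`, `"anesthesia-like"`, or `"burst-suppression"`.
#' @param switch_rate Pattern-switching rate (Hz) for the wake-like state;
#'   0 freezes the pattern (degenerating to anesthesia-like statistics).
#' @param burst_amp Burst amplitude gain; default 8 for the wake-like
#'   transients and 12 for the slow waves (strongly suprathreshold, so
#'   every wave recruits all channels and repeats the same pattern).
#' @param burst_rate Burst rate (Hz); default depends on state (0.4 wake,
#'   0.04 anesthesia, 0.12 burst-suppression).
#' @param n_patterns Number of spatial coupling patterns (wake-like).
#' @param seed Integer seed.
#' @param ... Passed to [eeg_recording()] (subject_id, condition, drug).
#' @return An [eeg_recording()].
#' @export
generate_synthetic_eeg <- function(n_channels = 60, fs = 256, duration_s = 60,
                                   state = c("wake-like", "anesthesia-like",
                                             "burst-suppression"),
                                   switch_rate = 0.2, burst_amp = NULL,
                                   burst_rate = NULL, n_patterns = 4,
                                   seed = 1, ...) {
  state <- match.arg(state)
  if (is.null(burst_rate))
    burst_rate <- switch(state, "wake-like" = 1.2, "anesthesia-like" = 0.05,
                         "burst-suppression" = 0.2)
  if (is.null(burst_amp))
    burst_amp <- if (state == "wake-like") 10 else 20
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  T <- round(duration_s * fs)
  n_groups <- 6
  # wake sources are mildly colored (alpha = 0.5) so they decorrelate within
  # an FC window; the anesthesia states ride on slow (alpha = 1.5) sources,
  # the slow-wave character of anesthetized EEG
  src <- pink_noise(n_groups, T, fs,
                    alpha = if (state == "wake-like") 0.5 else 1.5)
  noise <- pink_noise(n_channels, T, fs)
  # each spatial pattern is a partition of channels into coherent clusters:
  # channels within a cluster share a source (strong phase locking), so a
  # pattern switch reshapes the whole FC block structure
  K <- if (state == "wake-like") n_patterns else 1
  A <- lapply(seq_len(K), function(k) sample(n_groups, n_channels,
                                             replace = TRUE))
  # pattern sequence: Markov switching for wake, static otherwise
  pat <- integer(T)
  if (K > 1 && switch_rate > 0) {
    pswitch <- switch_rate / fs
    cur <- 1L
    switches <- which(stats::runif(T) < pswitch)
    pat[] <- 1L
    bounds <- c(1L, switches, T + 1L)
    for (b in seq_len(length(bounds) - 1)) {
      pat[bounds[b]:(bounds[b + 1] - 1L)] <- cur
      cur <- 1L + (cur %% K)  # cycle; which pattern is irrelevant, change is
    }
  } else pat[] <- 1L
  x <- matrix(0, n_channels, T)
  runs <- rle(pat)
  pos <- 1L
  for (ri in seq_along(runs$lengths)) {
    idx <- pos:(pos + runs$lengths[ri] - 1L)
    x[, idx] <- src[A[[runs$values[ri]]], idx, drop = FALSE]
    pos <- pos + runs$lengths[ri]
  }
  x <- 0.9 * x / stats::sd(x) + 0.15 * noise / stats::sd(noise)
  if (state != "wake-like") {
    # monotonous background: soft-saturate at 2.2 s.d. so ordinary samples
    # can never cross the z = 3 threshold; only the slow waves do
    s0 <- 2.2 * stats::sd(x)
    x <- s0 * tanh(x / s0)
  }
  if (state == "burst-suppression") x <- 0.25 * x
  # bursts: multiplicative amplitude gain on the recruited channels. The
  # Hilbert phase is amplitude-invariant, so bursts drive the z-threshold
  # metrics (repertoire, complexity, GAP) without corrupting phase-based
  # functional connectivity
  n_burst <- round(burst_rate * duration_s)  # fixed count, random timing
  # wake: brief sharp transients over varying channel subsets (rich
  # repertoire, fast RSS changes); anesthesia / burst-suppression: slow
  # stereotyped global waves (one repeated pattern, slow RSS changes) whose
  # amplitude also dominates the per-channel s.d., so ordinary background
  # samples stay below the z threshold
  blen <- if (state == "wake-like") round(0.15 * fs) else round(2.0 * fs)
  env <- sin(seq(0, pi, length.out = blen))^2
  if (n_burst > 0) {
    onsets <- sort(floor(stats::runif(n_burst, 1, T - blen)))
    for (bi in seq_len(n_burst)) {
      chans <- if (state == "wake-like") {
        sz <- sample(seq(round(n_channels / 6), round(2 * n_channels / 3)), 1)
        sample(n_channels, sz)
      } else seq_len(n_channels)
      idx <- onsets[bi]:(onsets[bi] + blen - 1)
      gain <- 1 + (burst_amp - 1) * env
      x[chans, idx] <- x[chans, idx, drop = FALSE] *
        matrix(gain, length(chans), blen, byrow = TRUE)
    }
  }
  x <- x * 10  # microvolt-ish scale
  eeg_recording(x, fs, ...)
}
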