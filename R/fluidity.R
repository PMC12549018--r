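#' Sliding-window specification for functional connectivity
#'
#' @param tau_win Window length in seconds.
#' @param step Hop between consecutive windows in seconds (0 < step <=
#'   tau_win).
#' @param method `"pearson"` (zero-lag correlation, used on simulated firing
#'   rates) or `"circular"` (circular correlation of instantaneous phases,
#'   used on EEG).
#' @return An object of class `fc_window_spec`.
#' @export
fc_window_spec <- function(tau_win = 3, step = 1,
                           method = c("pearson", "circular")) {
  method <- match.arg(method)
  if (step <= 0 || step > tau_win) stop("need 0 < step <= tau_win")
  structure(list(tau_win = tau_win, step = step, method = method),
            class = "fc_window_spec")
}

#' Instantaneous phase via the analytic signal
#'
#' Computes the Hilbert-transform analytic signal of each channel (after
#' removing the channel mean) and returns its phase in radians in
#' (-pi, pi]. Inputs should be band-limited; constant channels are an
#' error.
#'
#' @param x Signal matrix (channels x time).
#' @return Phase matrix of the same shape.
#' @export
instantaneous_phase <- function(x) {
  x <- as.matrix(x)
  if (any(apply(x, 1, stats::sd) == 0)) stop("constant channel has no phase")
  T <- ncol(x)
  h <- numeric(T)
  if (T %% 2 == 0) {
    h[c(1, T / 2 + 1)] <- 1
    h[2:(T / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((T + 1) / 2)] <- 2
  }
  ph <- t(apply(x, 1, function(ch) {
    a <- stats::fft(stats::fft(ch - mean(ch)) * h, inverse = TRUE) / T
    Arg(a)
  }))
  ph
}

circular_fc <- function(ph, printed_variant = FALSE) {
  # per-channel circular mean inside the window
  phbar <- atan2(rowMeans(sin(ph)), rowMeans(cos(ph)))
  S <- sin(ph - phbar)
  num <- tcrossprod(S)
  if (printed_variant) {
    S2 <- S^2
    den <- sqrt(tcrossprod(S2))
    fc <- num / den
  } else {
    ss <- rowSums(S^2)
    fc <- num / sqrt(outer(ss, ss))
  }
  fc
}

#' Sliding-window functional connectivity stream
#'
#' Computes one N x N functional connectivity matrix per window position:
#' zero-lag Pearson correlation for `method = "pearson"`, or the circular
#' correlation coefficient of instantaneous phases for
#' `method = "circular"` (inputs must then be phases, see
#' [instantaneous_phase()]). Pairs involving a zero-variance channel within
#' a window are set to `NA` with a warning and excluded downstream.
#'
#' @param x Signal (or phase) matrix, channels x time, at sampling rate `fs`.
#' @param fs Sampling rate (Hz).
#' @param spec An [fc_window_spec()].
#' @param printed_variant Logical; for circular correlation, use the
#'   non-normalized denominator variant (both squared sines under one sum)
#'   instead of the standard separate-sum form. Default `FALSE`.
#' @return An object of class `fc_stream`: 3-d array `matrices`
#'   (N x N x M), `window_centers` (s), window/hop sizes in samples, and the
#'   spec.
#' @export
windowed_fc <- function(x, fs, spec = fc_window_spec(),
                        printed_variant = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x); T <- ncol(x)
  if (n < 2) stop("need at least 2 channels")
  wlen <- round(spec$tau_win * fs)
  hop <- max(1L, round(spec$step * fs))
  if (T < wlen) stop("signal shorter than the window")
  starts <- seq(1, T - wlen + 1, by = hop)
  M <- length(starts)
  mats <- array(NA_real_, dim = c(n, n, M))
  warned <- FALSE
  for (k in seq_len(M)) {
    idx <- starts[k]:(starts[k] + wlen - 1)
    if (spec$method == "pearson") {
      seg <- x[, idx, drop = FALSE]
      sds <- apply(seg, 1, stats::sd)
      fc <- suppressWarnings(stats::cor(t(seg)))
      if (any(sds == 0)) {
        warned <- TRUE
        fc[sds == 0, ] <- NA
        fc[, sds == 0] <- NA
      }
    } else {
      fc <- circular_fc(x[, idx, drop = FALSE], printed_variant)
      bad <- !is.finite(diag(fc))
      if (any(bad)) { warned <- TRUE; fc[bad, ] <- NA; fc[, bad] <- NA }
    }
    diag(fc) <- 1
    mats[, , k] <- fc
  }
  if (warned) warning("zero-variance channel(s) within windows; pairs set NA")
  structure(list(matrices = mats,
                 window_centers = (starts - 1 + (wlen - 1) / 2) / fs,
                 wlen = wlen, hop = hop, n_overlap = wlen - hop,
                 spec = spec),
            class = "fc_stream")
}

#' Dynamic functional connectivity matrix
#'
#' Correlates the upper-triangular parts of every pair of windowed FC
#' matrices, yielding the M x M recurrence matrix of functional patterns.
#' Carries the diagonal-exclusion offset
#' `offset = ceiling(n_overlap / (wlen - n_overlap)) + 1`, the first window
#' separation at which two windows share no samples.
#'
#' @param stream An [fc_stream()].
#' @return An object of class `dfc_matrix`: `dfc` (M x M, unit diagonal) and
#'   `offset`.
#' @export
dfc_matrix <- function(stream) {
  mats <- stream$matrices
  n <- dim(mats)[1]; M <- dim(mats)[3]
  if (M < 2) stop("need at least 2 windows")
  ut <- upper.tri(matrix(0, n, n))
  V <- apply(mats, 3, function(m) m[ut])
  d <- suppressWarnings(stats::cor(V, use = "pairwise.complete.obs"))
  # degenerate (constant or all-NA) FC vectors leave NA rows; keep them NA
  diag(d) <- 1
  hop <- stream$hop
  offset <- as.integer(ceiling(stream$n_overlap / hop) + 1)
  structure(list(dfc = d, offset = offset, window_centers =
                   stream$window_centers),
            class = "dfc_matrix")
}

#' Fluidity of a dynamic functional connectivity matrix
#'
#' The variance of the upper-triangular dFC entries after excluding pairs of
#' overlapping windows (entries with `|row - col| < offset`), with missing
#' entries dropped. High fluidity means the system keeps switching between
#' correlated and uncorrelated functional patterns; a stationary system has
#' fluidity near zero.
#'
#' @param d A [dfc_matrix()].
#' @return Non-negative scalar.
#' @export
fluidity <- function(d) {
  m <- d$dfc
  keep <- upper.tri(m) & (col(m) - row(m) >= d$offset)
  vals <- m[keep]
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2)
    stop("no retained window pairs; recording too short for this windowing")
  stats::var(vals)
}

#' Fluidity of a signal matrix in one call
#'
#' Convenience wrapper: windowed FC, dFC, fluidity. For simulated firing
#' rates use `method = "pearson"` with 3 s windows and 1 s steps; for EEG,
#' compute phases first and use `method = "circular"`.
#'
#' @inheritParams windowed_fc
#' @return Scalar fluidity.
#' @export
fluidity_of <- function(x, fs, spec = fc_window_spec()) {
  fluidity(dfc_matrix(windowed_fc(x, fs, spec)))
}
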