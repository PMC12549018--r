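#' Extract neuronal avalanches from a binary raster
#'
#' Time is binned at `bin_size` samples (a channel is active in a bin if any
#' of its samples in the bin is 1). An avalanche is a maximal run of bins in
#' which at least one channel is active, bounded by all-quiet bins. Each
#' avalanche carries its recruited-channel pattern (the set of channels
#' active at any point during the avalanche) and, when it spans at least two
#' bins, a branching ratio: the geometric mean of consecutive
#' event-count ratios,
#' `sigma_i = prod_j (n_events(j+1) / n_events(j))^(1/(N_bin - 1))`.
#' Avalanches touching the recording edges are kept and flagged rather than
#' dropped, so short bootstrap segments are not biased.
#'
#' @param raster A [binary_raster()] (or binary matrix).
#' @param bin_size Bin width in samples (default 1).
#' @return An object of class `avalanche_set`: `avalanches` (list with
#'   `start_bin`, `end_bin`, `events_per_bin`, `pattern`, `sigma_i`,
#'   `edge`), `bin_size`, `sigma` (geometric mean of defined `sigma_i`, NA
#'   if none), and `repertoire` (set of distinct patterns).
#' @export
extract_avalanches <- function(raster, bin_size = 1) {
  bits <- if (inherits(raster, "binary_raster")) raster$bits else
    matrix(as.integer(raster), nrow = nrow(raster))
  n <- nrow(bits); T <- ncol(bits)
  nb <- ceiling(T / bin_size)
  # bin activity: any sample within the bin
  act <- matrix(0L, n, nb)
  for (b in seq_len(nb)) {
    idx <- ((b - 1) * bin_size + 1):min(b * bin_size, T)
    act[, b] <- as.integer(rowSums(bits[, idx, drop = FALSE]) > 0)
  }
  nev <- colSums(act)
  on <- nev > 0
  if (!any(on)) {
    return(structure(list(avalanches = list(), bin_size = bin_size,
                          sigma = NA_real_, repertoire = list()),
                     class = "avalanche_set"))
  }
  runs <- rle(on)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  av <- list()
  for (k in which(runs$values)) {
    b0 <- starts[k]; b1 <- ends[k]
    epb <- nev[b0:b1]
    nbins <- length(epb)
    sigma_i <- if (nbins >= 2)
      prod((epb[-1] / epb[-nbins])^(1 / (nbins - 1))) else NA_real_
    pattern <- which(rowSums(act[, b0:b1, drop = FALSE]) > 0)
    av[[length(av) + 1]] <- list(start_bin = b0, end_bin = b1,
                                 events_per_bin = epb, pattern = pattern,
                                 sigma_i = sigma_i,
                                 edge = (b0 == 1 || b1 == nb))
  }
  sig <- vapply(av, function(a) a$sigma_i, numeric(1))
  sig <- sig[!is.na(sig)]
  patterns <- unique(lapply(av, function(a) a$pattern))
  structure(list(avalanches = av, bin_size = bin_size,
                 sigma = if (length(sig)) prod(sig)^(1 / length(sig)) else NA_real_,
                 repertoire = patterns),
            class = "avalanche_set")
}

#' @export
print.avalanche_set <- function(x, ...) {
  cat(sprintf("avalanche_set: %d avalanches (bin %d), sigma = %s, repertoire %d\n",
              length(x$avalanches), x$bin_size,
              ifelse(is.na(x$sigma), "NA", sprintf("%.3f", x$sigma)),
              length(x$repertoire)))
  invisible(x)
}

#' Functional repertoire size from avalanches
#'
#' The number of distinct recruited-channel sets across all avalanches in a
#' recording (repetitions discarded). This is the repertoire definition used
#' for EEG.
#'
#' @param aset An [extract_avalanches()] result.
#' @return Integer count.
#' @export
functional_repertoire_eeg <- function(aset) {
  length(aset$repertoire)
}

#' Functional repertoire size from binarized activity
#'
#' For simulations, avalanche extraction is not always possible (in the
#' high-coupling regime activity never returns to quiet), so the repertoire
#' is simplified to the number of unique network states: distinct binary
#' column vectors across all time points.
#'
#' @param raster A [binary_raster()] (or binary matrix).
#' @return Integer count, at most `min(T, 2^channels)`.
#' @export
functional_repertoire_sim <- function(raster) {
  bits <- if (inherits(raster, "binary_raster")) raster$bits else
    matrix(as.integer(raster), nrow = nrow(raster))
  length(unique(apply(bits, 2, paste0, collapse = "")))
}

#' Global activation potential
#'
#' Each channel is z-scored along time (zero-variance channels contribute
#' zero), the root-sum-square across channels `RSS(t) = sqrt(sum_i z_i(t)^2)`
#' is formed, and GAP is the maximum absolute discrete derivative
#' `max_t |dRSS/dt|`, with the first difference scaled by the sampling rate.
#' It captures the sharpest global activation (or collapse) event in the
#' recording, in z-units per second.
#'
#' @param x Signal matrix (channels x time).
#' @param fs Sampling rate (Hz).
#' @return Non-negative scalar (z / s).
#' @export
gap <- function(x, fs) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 time samples")
  sds <- apply(x, 1, stats::sd)
  z <- (x - rowMeans(x)) / ifelse(sds == 0, 1, sds)
  z[sds == 0, ] <- 0
  rss <- sqrt(colSums(z^2))
  max(abs(diff(rss))) * fs
}

#' Branching-ratio diagnostic across bin sizes
#'
#' Recomputes the avalanche branching ratio for a list of candidate bin
#' sizes, supporting the bin-size selection step (pick the bin size at which
#' sigma is closest to 1, the critical value).
#'
#' @param raster A [binary_raster()] (or binary matrix).
#' @param bin_sizes Integer vector of bin widths in samples.
#' @return Data frame with `bin_size`, `sigma`, `n_avalanches`.
#' @export
branching_diagnostic <- function(raster, bin_sizes = 1:5) {
  rows <- lapply(bin_sizes, function(bs) {
    aset <- extract_avalanches(raster, bs)
    if (length(aset$avalanches) == 0) stop("no avalanches in raster")
    data.frame(bin_size = bs, sigma = aset$sigma,
               n_avalanches = length(aset$avalanches))
  })
  do.call(rbind, rows)
}
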