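#' Construct and validate a structural connectome
#'
#' A connectome is the region-by-region structural graph that parameterizes
#' the network simulator: a symmetric, non-negative matrix of tract weights
#' (fiber bundle "width", arbitrary units), a matching matrix of tract
#' lengths (mm) that generates conduction delays, region labels, and a
#' logical mask marking cortical regions (stimulation targets are drawn from
#' cortical regions only).
#'
#' @param weights n x n non-negative symmetric numeric matrix, zero diagonal.
#' @param lengths n x n non-negative symmetric numeric matrix (mm), zero
#'   diagonal; entries may be positive only where `weights` is positive.
#' @param labels character vector of region names (defaults to
#'   `"region_001"` ...).
#' @param cortical_mask logical vector flagging cortical regions. Defaults to
#'   the first 80\% of regions (mirroring the 68-of-84 cortical fraction of
#'   the Desikan-Killiany parcellation).
#' @return An object of class `connectome` with fields `n_regions`,
#'   `weights`, `lengths`, `labels`, `cortical_mask`.
#' @export
connectome <- function(weights, lengths, labels = NULL, cortical_mask = NULL) {
  weights <- as.matrix(weights)
  lengths <- as.matrix(lengths)
  n <- nrow(weights)
  if (is.null(labels)) labels <- sprintf("region_%03d", seq_len(n))
  if (is.null(cortical_mask)) {
    cortical_mask <- seq_len(n) <= ceiling(0.8 * n)
  }
  obj <- structure(list(n_regions = n, weights = unname(weights),
                        lengths = unname(lengths), labels = labels,
                        cortical_mask = cortical_mask),
                   class = "connectome")
  validate_connectome(obj)
  obj
}

#' Validate connectome invariants
#'
#' Checks symmetry, non-negativity, zero diagonals, shape agreement, and that
#' positive tract lengths only occur on existing edges. Called by every
#' constructor; exported so tests and pipelines can assert the invariants on
#' any connectome they produce.
#'
#' @param c A `connectome` object.
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_connectome <- function(c) {
  w <- c$weights; l <- c$lengths; n <- c$n_regions
  if (!is.matrix(w) || !is.matrix(l)) stop("weights and lengths must be matrices")
  if (nrow(w) != n || ncol(w) != n) stop("weights must be ", n, "x", n)
  if (nrow(l) != n || ncol(l) != n) stop("lengths must be ", n, "x", n)
  if (anyNA(w) || anyNA(l)) stop("connectome matrices contain missing values")
  if (any(w < 0)) stop("negative tract weights")
  if (any(l < 0)) stop("negative tract lengths")
  if (max(abs(w - t(w))) > 1e-12 * max(1, max(abs(w)))) stop("weights not symmetric")
  if (max(abs(l - t(l))) > 1e-12 * max(1, max(abs(l)))) stop("lengths not symmetric")
  if (any(diag(w) != 0)) stop("weights diagonal must be zero")
  if (any(diag(l) != 0)) stop("lengths diagonal must be zero")
  if (any(l > 0 & w == 0)) stop("positive length on a zero-weight edge")
  if (length(c$labels) != n) stop("labels length mismatch")
  if (length(c$cortical_mask) != n) stop("cortical_mask length mismatch")
  invisible(TRUE)
}

#' @export
print.connectome <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("connectome: %d regions (%d cortical), %d edges, density %.2f\n",
              x$n_regions, sum(x$cortical_mask), nz,
              nz / choose(x$n_regions, 2)))
  cat(sprintf("  weights: max %.3g, mean node strength %.3g\n",
              max(x$weights), mean(rowSums(x$weights))))
  invisible(x)
}

read_square_matrix <- function(source) {
  m <- as.matrix(utils::read.table(source, header = FALSE))
  if (!is.numeric(m)) stop("non-numeric cells in ", source)
  if (nrow(m) != ncol(m)) stop("matrix in ", source, " is not square")
  unname(m)
}

#' Load a connectome from delimited text files
#'
#' Reads whitespace- or comma-delimited square matrices of tract weights and
#' lengths (one row per line), with an optional one-label-per-line text file.
#' A zip bundle in the TVB-style layout (`weights.txt`, `tract_lengths.txt`,
#' `centres.txt`) is also accepted as `weights_source`, in which case
#' `lengths_source` is ignored. Asymmetric inputs are symmetrized by
#' averaging with a warning; negative entries are an error.
#'
#' @param weights_source Path to the weights matrix file or a zip bundle.
#' @param lengths_source Path to the lengths matrix file.
#' @param labels_source Optional path to a text file with one label per line.
#' @return A validated [connectome()].
#' @export
load_connectome <- function(weights_source, lengths_source = NULL,
                            labels_source = NULL) {
  labels <- NULL
  if (grepl("\\.zip$", weights_source, ignore.case = TRUE)) {
    exdir <- tempfile("conn")
    files <- utils::unzip(weights_source, exdir = exdir)
    pick <- function(pat) {
      hit <- grep(pat, basename(files), value = FALSE)
      if (length(hit) == 0) stop("zip bundle lacks a file matching ", pat)
      files[hit[1]]
    }
    w <- read_square_matrix(pick("^weights"))
    l <- read_square_matrix(pick("^tract_lengths"))
    centres <- grep("^centres", basename(files))
    if (length(centres) > 0) {
      cen <- utils::read.table(files[centres[1]], header = FALSE,
                               stringsAsFactors = FALSE)
      labels <- as.character(cen[[1]])
    }
  } else {
    w <- read_square_matrix(weights_source)
    if (is.null(lengths_source)) stop("lengths_source required")
    l <- read_square_matrix(lengths_source)
  }
  if (!identical(dim(w), dim(l))) stop("weights and lengths shapes differ")
  if (any(w < 0)) stop("negative tract weights in input")
  if (any(l < 0)) stop("negative tract lengths in input")
  sym <- function(m, what) {
    if (max(abs(m - t(m))) > 1e-12 * max(1, max(abs(m)))) {
      warning(what, " matrix asymmetric; symmetrized by averaging")
      m <- (m + t(m)) / 2
    }
    m
  }
  w <- sym(w, "weights"); l <- sym(l, "lengths")
  diag(w) <- 0; diag(l) <- 0
  l[w == 0] <- 0
  if (!is.null(labels_source)) {
    labels <- readLines(labels_source)
    labels <- labels[nzchar(labels)]
  }
  connectome(w, l, labels = labels)
}

#' Write a connectome to delimited text files
#'
#' @param c A `connectome`.
#' @param weights_path,lengths_path,labels_path Output file paths
#'   (`labels_path` optional).
#' @return Invisibly `c`.
#' @export
write_connectome <- function(c, weights_path, lengths_path, labels_path = NULL) {
  utils::write.table(c$weights, weights_path, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(c$lengths, lengths_path, row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(labels_path)) writeLines(c$labels, labels_path)
  invisible(c)
}

#' Generate a synthetic modular connectome
#'
#' Emulates the features of a diffusion-imaging connectome that the network
#' dynamics depend on: a symmetric, zero-diagonal graph with heavy-tailed
#' (log-normal) edge weights, strictly positive tract lengths with an
#' exponential tail, and a modular community structure. Regions are split
#' into `n_modules` equal blocks; within-module edge weights are drawn with
#' a wider log-s.d. (`intra_sd_factor * log_weight_sd`, producing the strong
#' intra-community fibers along which activity is recruited) and each
#' module's mean within-module node strength is normalized to a descending
#' ladder `module_strength * module_ladder^(m-1)`, while between-module
#' weights are normalized to a mean node strength of `inter_strength`.
#'
#' The leading module's strength (`module_strength = 1.62` at the reference
#' noise) is calibrated so that its stochastic ignition threshold lies at
#' the working coupling G of about 0.55: below it the network is sparse and
#' quiet, around it the leading modules collectively ignite and collapse
#' (coactivation cascades, maximal fluidity), above it the active pattern
#' locks in. The ladder staggers the remaining modules so the transition
#' unfolds gradually above the working point. See the methods vignette for
#' the calibration rationale.
#'
#' @param n_regions Number of regions (>= 2); default 84.
#' @param log_weight_mean,log_weight_sd Location and scale of log edge
#'   weights before the strength normalization (natural log). The
#'   between-module log-weight s.d. equals `log_weight_sd` exactly (the
#'   normalization shifts only the mean).
#' @param density Fraction of node pairs connected, in (0, 1].
#' @param length_scale Tract length scale (mm); lengths are drawn as
#'   `length_scale * (0.5 + Exponential(1))` so they are strictly positive.
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   seed.
#' @param n_modules Number of modules (blocks of contiguous regions).
#' @param module_strength Mean within-module node strength of the leading
#'   module (the working-point calibration constant).
#' @param module_ladder Geometric ratio between successive module strengths.
#' @param inter_strength Mean between-module node strength.
#' @param intra_sd_factor Multiplier on `log_weight_sd` for within-module
#'   edges.
#' @return A validated [connectome()] with a `modules` field (module index
#'   per region).
#' @export
generate_synthetic_connectome <- function(n_regions = 84,
                                          log_weight_mean = 0,
                                          log_weight_sd = 1.0,
                                          density = 0.65,
                                          length_scale = 40,
                                          seed = 1,
                                          n_modules = 6,
                                          module_strength = 1.62,
                                          module_ladder = 0.86,
                                          inter_strength = 0.85,
                                          intra_sd_factor = 1.5) {
  if (n_regions < 2) stop("n_regions must be >= 2")
  if (!(density > 0 && density <= 1)) stop("density must be in (0, 1]")
  n_modules <- max(1L, min(as.integer(n_modules), n_regions %/% 4))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  n <- n_regions
  mod <- rep(seq_len(n_modules), length.out = n)
  mod <- sort(mod)
  w <- matrix(0, n, n); l <- matrix(0, n, n)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  same <- mod[ut[, 1]] == mod[ut[, 2]]
  keep <- if (density >= 1) rep(TRUE, nrow(ut)) else
    stats::runif(nrow(ut)) < density
  sdlog <- ifelse(same, intra_sd_factor * log_weight_sd, log_weight_sd)
  wv <- ifelse(keep, stats::rlnorm(nrow(ut), log_weight_mean, sdlog), 0)
  lv <- ifelse(keep, length_scale * (0.5 + stats::rexp(nrow(ut))), 0)
  w[upper.tri(w)] <- wv; l[upper.tri(l)] <- lv
  w <- w + t(w); l <- l + t(l)
  if (all(w == 0)) stop("generated connectome has no edges; increase density")
  # per-module strength normalization: descending ladder of within-module
  # strengths; single scale for all between-module edges
  targets <- module_strength * module_ladder^(seq_len(n_modules) - 1)
  for (a in seq_len(n_modules)) {
    ia <- which(mod == a)
    wi <- w[ia, ia]
    s <- mean(rowSums(wi))
    if (s > 0) w[ia, ia] <- wi * targets[a] / s
  }
  inter <- outer(mod, mod, "!=")
  s_inter <- mean(rowSums(w * inter))
  if (s_inter > 0) w[inter] <- w[inter] * inter_strength / s_inter
  out <- connectome(w, l)
  out$modules <- mod
  out
}

# save/restore .Random.seed so generators don't disturb the caller's RNG
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Rescale connectome weights
#'
#' `max-one` divides all weights by the maximum weight (idempotent);
#' `row-sum-one` scales each row to unit sum and then re-symmetrizes by
#' averaging; `none` returns the input unchanged.
#'
#' @param c A `connectome`.
#' @param mode One of `"max-one"`, `"row-sum-one"`, `"none"`.
#' @return A validated `connectome` with rescaled weights.
#' @export
normalize_weights <- function(c, mode = c("max-one", "row-sum-one", "none")) {
  mode <- match.arg(mode)
  validate_connectome(c)
  w <- c$weights
  if (mode != "none" && all(w == 0)) stop("all-zero weight matrix")
  w <- switch(mode,
    "max-one" = w / max(w),
    "row-sum-one" = {
      s <- rowSums(w)
      s[s == 0] <- 1
      ws <- w / s
      (ws + t(ws)) / 2
    },
    "none" = w)
  c$weights <- w
  validate_connectome(c)
  c
}
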