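#' Metrics of one (G, sigma) cell
#'
#' Runs the spontaneous and stimulation protocol for a single point of the
#' coupling/noise plane and returns every requested metric. This is the
#' unit of work of [run_sweep()]; it is exported so any sweep cell can be
#' replayed in isolation from the manifest (same arguments, same seeds,
#' bit-identical result).
#'
#' @param connectome A [connectome()].
#' @param params [nmm_params()].
#' @param g,sigma Cell coordinates.
#' @param cell_seed Integer seed for this cell (spontaneous run s uses
#'   `cell_seed + s - 1`; the protocol background uses `cell_seed`).
#' @param metrics Character subset of `c("fluidity", "cascade_auc",
#'   "lz_complexity", "repertoire", "gap", "spci")`.
#' @param spont_duration_s Spontaneous run length (seconds of model time).
#' @param n_spont Number of spontaneous runs (metrics averaged).
#' @param stim_nodes Nodes to stimulate for the sPCI protocol.
#' @param n_trials Trials per node.
#' @param dt,record_dt Integration and recording steps (ms).
#' @param burn_in_s Seconds discarded before computing spontaneous metrics.
#' @param fc_spec [fc_window_spec()] for fluidity (3 s window, 1 s step by
#'   default, Pearson on firing rates).
#' @param window_s sPCI analysis window (s).
#' @param threshold Rate binarization threshold.
#' @param amplitude,stim_duration_ms Stimulus parameters.
#' @param init Initial state for all runs.
#' @return Named list of metric values (means over spontaneous runs), plus
#'   `spci_max` / `spci_min` when `"spci"` is requested, and `dt_used`.
#' @export
sweep_cell <- function(connectome, params, g, sigma, cell_seed,
                       metrics = c("fluidity", "cascade_auc", "lz_complexity",
                                   "repertoire", "gap", "spci"),
                       spont_duration_s = 60, n_spont = 1,
                       stim_nodes = integer(0), n_trials = 6,
                       dt = 0.05, record_dt = 10, burn_in_s = 2,
                       fc_spec = fc_window_spec(3, 1, "pearson"),
                       window_s = 10, threshold = 0.7,
                       amplitude = 5, stim_duration_ms = 10,
                       init = "random") {
  out <- list(g = g, sigma = sigma, cell_seed = cell_seed)
  spont_names <- intersect(metrics, c("fluidity", "cascade_auc",
                                      "lz_complexity", "repertoire", "gap"))
  acc <- list()
  # a cell retries at half the step if the integration diverges
  run_robust <- function(cfg, stim = NULL) {
    for (attempt in 1:3) {
      res <- tryCatch(simulate_network(connectome, params, cfg, stim),
                      error = function(e) e)
      if (!inherits(res, "error")) return(list(sim = res, dt = cfg$dt))
      if (!grepl("diverged", conditionMessage(res))) stop(res)
      cfg$dt <- cfg$dt / 2
    }
    stop("integration diverged repeatedly at g=", cfg$g)
  }
  dt_used <- dt
  spont_metrics <- function(r, v, dt_rec) {
    burn <- round(burn_in_s * 1000 / dt_rec)
    r <- r[, -seq_len(burn), drop = FALSE]
    v <- v[, -seq_len(burn), drop = FALSE]
    fs <- 1000 / dt_rec
    vals <- c()
    if ("fluidity" %in% spont_names)
      vals["fluidity"] <- tryCatch(fluidity_of(r, fs, fc_spec),
                                   error = function(e) NA_real_)
    if ("cascade_auc" %in% spont_names)
      vals["cascade_auc"] <- tryCatch(
        cascade_profile(r, dt_s = dt_rec / 1000)$auc,
        error = function(e) NA_real_)
    raster <- binarize_rates(r, threshold)
    if ("lz_complexity" %in% spont_names)
      vals["lz_complexity"] <- .lz76_cpp(as.vector(t(raster$bits)))
    if ("repertoire" %in% spont_names)
      vals["repertoire"] <- functional_repertoire_sim(raster)
    if ("gap" %in% spont_names)
      vals["gap"] <- tryCatch(gap(v, fs), error = function(e) NA_real_)
    vals
  }
  sp <- NULL
  if ("spci" %in% metrics && length(stim_nodes) > 0) {
    dt_try <- dt
    for (attempt in 1:3) {
      cfg <- sim_config(g = g, sigma_noise = sigma, dt = dt_try,
                        duration = spont_duration_s * 1000,
                        record_dt = record_dt, seed = cell_seed, init = init)
      sp <- tryCatch(
        spci_max(connectome, params, cfg, stim_nodes, n_trials, window_s,
                 threshold, amplitude, stim_duration_ms),
        error = function(e) e)
      if (!inherits(sp, "error")) { dt_used <- dt_try; break }
      if (!grepl("diverged", conditionMessage(sp))) stop(sp)
      dt_try <- dt_try / 2
      sp <- NULL
    }
    if (is.null(sp)) sp <- list(spci_max = NA_real_, spci_min = NA_real_,
                                ratios = numeric(0), background = NULL)
    out$spci_max <- sp$spci_max
    out$spci_min <- sp$spci_min
    out$n_trials_done <- length(sp$ratios)
  }
  if (length(spont_names) > 0) {
    for (s in seq_len(n_spont)) {
      # the protocol's background run is the first spontaneous run (same
      # seed, same configuration); reuse its recording
      if (s == 1 && !is.null(sp) && !is.null(sp$background)) {
        bg <- sp$background
        acc[[s]] <- spont_metrics(bg$r, bg$v, bg$dt_record)
        next
      }
      cfg <- sim_config(g = g, sigma_noise = sigma, dt = dt,
                        duration = spont_duration_s * 1000,
                        record_dt = record_dt, seed = cell_seed + s - 1,
                        init = init)
      rr <- run_robust(cfg)
      dt_used <- rr$dt
      acc[[s]] <- spont_metrics(rr$sim$r, rr$sim$v, rr$sim$dt_record)
    }
    means <- colMeans(do.call(rbind, acc), na.rm = TRUE)
    out[names(means)] <- as.list(means)
  }
  out$dt_used <- dt_used
  out
}

#' Sweep the (G, sigma) parameter plane
#'
#' Produces the metric maps characterizing the model's dynamical regimes:
#' for every grid cell, spontaneous runs yield fluidity, cascade AUC,
#' Lempel-Ziv complexity, functional repertoire and GAP, and the
#' stimulation protocol yields maximum and minimum sPCI. Trials are denser
#' inside the near-working-point box than elsewhere. Each cell's seeds and
#' settings are recorded in a manifest from which any cell can be replayed
#' bit-identically with [sweep_cell()]; cell failures are recorded as
#' missing values without aborting the sweep.
#'
#' @param connectome A [connectome()].
#' @param params [nmm_params()].
#' @param g_grid,sigma_grid Numeric grids.
#' @param metrics Metrics to compute (see [sweep_cell()]).
#' @param n_stim_nodes Number of stimulation targets, drawn without
#'   replacement from the highest-strength cortical regions.
#' @param trials_near,trials_far Trials per node inside/outside `near_box`.
#' @param near_box List with `g` and `sigma` ranges of the near-working-
#'   point box.
#' @param seed Master seed; cell seeds are derived deterministically.
#' @param ... Further arguments passed to [sweep_cell()].
#' @return An object of class `sweep_result`: `g_grid`, `sigma_grid`,
#'   `maps` (named list of length(g) x length(sigma) matrices), and
#'   `manifest` (data frame, one row per cell).
#' @export
run_sweep <- function(connectome, params = nmm_params(),
                      g_grid, sigma_grid = 0.036,
                      metrics = c("fluidity", "cascade_auc", "lz_complexity",
                                  "repertoire", "gap", "spci"),
                      n_stim_nodes = 3, trials_near = 6, trials_far = 6,
                      near_box = list(g = c(0.52, 0.57),
                                      sigma = c(0.022, 0.039)),
                      seed = 1, ...) {
  g_grid <- sort(g_grid); sigma_grid <- sort(sigma_grid)
  strengths <- rowSums(connectome$weights)
  cortical <- which(connectome$cortical_mask)
  stim_nodes <- cortical[order(strengths[cortical],
                               decreasing = TRUE)][seq_len(n_stim_nodes)]
  map_names <- setdiff(metrics, "spci")
  if ("spci" %in% metrics) map_names <- c(map_names, "spci_max", "spci_min")
  maps <- stats::setNames(lapply(map_names, function(nm)
    matrix(NA_real_, length(g_grid), length(sigma_grid),
           dimnames = list(g = g_grid, sigma = sigma_grid))), map_names)
  manifest <- list()
  idx <- 0L
  for (si in seq_along(sigma_grid)) for (gi in seq_along(g_grid)) {
    idx <- idx + 1L
    g <- g_grid[gi]; sg <- sigma_grid[si]
    cell_seed <- (as.integer(seed) * 1009L + idx * 9973L) %% 2147483647L
    near <- g >= near_box$g[1] && g <= near_box$g[2] &&
      sg >= near_box$sigma[1] && sg <= near_box$sigma[2]
    n_trials <- if (near) trials_near else trials_far
    cell <- tryCatch(
      sweep_cell(connectome, params, g, sg, cell_seed, metrics = metrics,
                 stim_nodes = stim_nodes, n_trials = n_trials, ...),
      error = function(e) { message("cell (", g, ", ", sg, ") failed: ",
                                    conditionMessage(e)); NULL })
    for (nm in map_names)
      if (!is.null(cell) && !is.null(cell[[nm]]))
        maps[[nm]][gi, si] <- cell[[nm]]
    manifest[[idx]] <- data.frame(
      g = g, sigma = sg, cell_seed = cell_seed, near = near,
      n_trials = n_trials,
      stim_nodes = paste(stim_nodes, collapse = ","),
      dt_used = if (is.null(cell)) NA_real_ else cell$dt_used,
      failed = is.null(cell))
  }
  manifest <- do.call(rbind, manifest)
  if (all(vapply(maps, function(m) all(is.na(m)), logical(1))))
    stop("all sweep cells are missing")
  structure(list(g_grid = g_grid, sigma_grid = sigma_grid, maps = maps,
                 manifest = manifest,
                 missing_fraction = mean(manifest$failed)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %d x %d grid (G in [%g, %g], sigma in [%g, %g])\n",
              length(x$g_grid), length(x$sigma_grid), min(x$g_grid),
              max(x$g_grid), min(x$sigma_grid), max(x$sigma_grid)))
  cat("  maps:", paste(names(x$maps), collapse = ", "), "\n")
  for (nm in names(x$maps)) {
    m <- x$maps[[nm]]
    if (all(is.na(m))) next
    am <- arrayInd(which.max(m), dim(m))
    cat(sprintf("  %s: argmax at G=%g, sigma=%g (%.4g)\n", nm,
                x$g_grid[am[1]], x$sigma_grid[am[2]], max(m, na.rm = TRUE)))
  }
  invisible(x)
}

#' Grid coordinate of a map's maximum
#'
#' @param sweep A [run_sweep()] result.
#' @param map Map name (e.g. `"fluidity"`, `"spci_max"`).
#' @return List with `g`, `sigma`, `value`.
#' @export
sweep_argmax <- function(sweep, map) {
  m <- sweep$maps[[map]]
  if (is.null(m)) stop("no map named ", map)
  if (all(is.na(m))) stop("map ", map, " is all-missing")
  am <- arrayInd(which.max(m), dim(m))
  list(g = sweep$g_grid[am[1]], sigma = sweep$sigma_grid[am[2]],
       value = m[am])
}
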