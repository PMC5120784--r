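#' Regional time series
#'
#' Container for a multi-region signal matrix (time points in rows, regions in
#' columns) together with its acquisition structure: the sampling period (TR)
#' of each run, the run lengths in volumes, and one task label per run. Runs
#' are stored concatenated along the time axis, as produced by concatenating
#' consecutive scanner runs.
#'
#' @param values numeric matrix, time points x regions; all entries finite.
#' @param sampling_period sampling period in seconds; a scalar (recycled) or
#'   one value per run.
#' @param run_lengths integer vector of volumes per run; must sum to
#'   `nrow(values)`.
#' @param task_labels character vector, one task label per run.
#'
#' @return An object of class `regional_ts` with fields `values`,
#'   `sampling_period`, `run_lengths`, `task_labels`.
#' @export
regional_ts <- function(values, sampling_period, run_lengths = nrow(values),
                        task_labels = "task") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    stop("regional_ts: 'values' contains non-finite entries")
  }
  run_lengths <- as.integer(run_lengths)
  if (any(run_lengths < 1)) stop("regional_ts: run lengths must be >= 1")
  if (sum(run_lengths) != nrow(values)) {
    stop(sprintf("regional_ts: run lengths sum to %d but matrix has %d rows",
                 sum(run_lengths), nrow(values)))
  }
  n_runs <- length(run_lengths)
  sampling_period <- as.numeric(sampling_period)
  if (length(sampling_period) == 1L) {
    sampling_period <- rep(sampling_period, n_runs)
  }
  if (length(sampling_period) != n_runs) {
    stop("regional_ts: need one sampling period per run (or a scalar)")
  }
  if (any(sampling_period <= 0)) stop("regional_ts: sampling period must be > 0")
  task_labels <- as.character(task_labels)
  if (length(task_labels) != n_runs) {
    stop("regional_ts: need one task label per run")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("r", seq_len(ncol(values)))
  }
  structure(
    list(values = values, sampling_period = sampling_period,
         run_lengths = run_lengths, task_labels = task_labels),
    class = "regional_ts"
  )
}

#' @export
print.regional_ts <- function(x, ...) {
  cat(sprintf("<regional_ts> %d time points x %d regions, %d run(s)\n",
              nrow(x$values), ncol(x$values), length(x$run_lengths)))
  cat(sprintf("  runs: %s\n",
              paste(sprintf("%s (%d vol @ TR %gs)", x$task_labels,
                            x$run_lengths, x$sampling_period),
                    collapse = ", ")))
  invisible(x)
}

# first/last row index of each run
run_ranges <- function(x) {
  ends <- cumsum(x$run_lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  cbind(start = starts, end = ends)
}

#' Band-pass filter regional time series
#'
#' Restricts every regional signal to a frequency band (default 0.06-0.125 Hz,
#' the range carrying task-related BOLD fluctuations) with a zero-phase
#' Butterworth band-pass run forward and backward, so no phase distortion is
#' introduced across window boundaries. By default runs are concatenated and
#' filtered as one series; `per_run = TRUE` filters each run independently
#' before concatenation (a variant that suppresses run-boundary edge effects).
#' Runs acquired at different sampling periods are always filtered per run,
#' since a single digital filter cannot span two sampling rates.
#'
#' @param series a [regional_ts()] object.
#' @param low,high band edges in Hz; `high` must lie below the Nyquist
#'   frequency 1 / (2 TR) of every run.
#' @param order Butterworth filter order of the band-pass (even; default 4).
#' @param per_run logical; filter each run separately.
#'
#' @return A [regional_ts()] with identical structure and filtered values.
#' @export
bandpass_filter <- function(series, low = 0.06, high = 0.125, order = 4,
                            per_run = FALSE) {
  stopifnot(inherits(series, "regional_ts"))
  if (low <= 0 || high <= low) stop("bandpass_filter: need 0 < low < high")
  if (order %% 2 != 0 || order < 2) stop("bandpass_filter: order must be even")
  nyq <- 1 / (2 * series$sampling_period)
  if (any(high >= nyq)) {
    stop(sprintf(
      "bandpass_filter: high edge %g Hz is not below the Nyquist frequency %g Hz",
      high, min(nyq)))
  }
  mixed_tr <- length(unique(series$sampling_period)) > 1L
  out <- series$values
  if (per_run || mixed_tr) {
    rr <- run_ranges(series)
    for (r in seq_len(nrow(rr))) {
      idx <- rr[r, "start"]:rr[r, "end"]
      out[idx, ] <- butter_bandpass(series$values[idx, , drop = FALSE],
                                    series$sampling_period[r], low, high, order)
    }
  } else {
    out <- butter_bandpass(series$values, series$sampling_period[1],
                           low, high, order)
  }
  series$values <- out
  series
}

# zero-phase Butterworth band-pass of each column; fs = 1/tr.
# Columns are demeaned first so the DC step does not excite edge transients.
butter_bandpass <- function(mat, tr, low, high, order) {
  w <- c(low, high) * 2 * tr              # edges as a fraction of Nyquist
  bf <- signal::butter(order / 2, w, type = "pass")
  apply(mat, 2, function(col) signal::filtfilt(bf, col - mean(col)))
}

#' Segment runs into non-overlapping analysis windows
#'
#' Cuts each run into consecutive non-overlapping windows of (approximately)
#' `window_seconds`, aligned to the run start; each window spans
#' `floor(window_seconds / TR)` volumes and the trailing remainder of each run
#' is discarded. Optionally the first and last `drop_boundary_windows` windows
#' of every run are removed to guard against filtering edge effects at run
#' boundaries.
#'
#' @param series a [regional_ts()] object.
#' @param window_seconds window length in seconds (default 60).
#' @param drop_boundary_windows number of windows removed from each end of
#'   every run (default 0).
#'
#' @return A data frame with one row per retained window: `start`, `end`
#'   (row indices into the series), `run`, `task`.
#' @export
segment_windows <- function(series, window_seconds = 60,
                            drop_boundary_windows = 0) {
  stopifnot(inherits(series, "regional_ts"))
  d <- as.integer(drop_boundary_windows)
  if (d < 0) stop("segment_windows: drop_boundary_windows must be >= 0")
  rr <- run_ranges(series)
  out <- vector("list", nrow(rr))
  for (r in seq_len(nrow(rr))) {
    spw <- floor(window_seconds / series$sampling_period[r])
    if (spw < 3) {
      stop(sprintf("segment_windows: run %d ('%s'): window of %g s holds only %d samples (< 3)",
                   r, series$task_labels[r], window_seconds, spw))
    }
    n_win <- series$run_lengths[r] %/% spw
    if (n_win < 1 + 2 * d) {
      stop(sprintf(
        "segment_windows: run %d ('%s') has %d volumes: %d full window(s) of %d samples, need %d",
        r, series$task_labels[r], series$run_lengths[r], n_win, spw, 1 + 2 * d))
    }
    keep <- seq_len(n_win)
    if (d > 0) keep <- keep[(d + 1):(n_win - d)]
    starts <- rr[r, "start"] + (keep - 1L) * spw
    out[[r]] <- data.frame(start = starts, end = starts + spw - 1L,
                           run = r, task = series$task_labels[r],
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Windowed Pearson correlation matrix
#'
#' Correlation of every region pair over one window of samples. Regions that
#' are constant within the window have undefined correlations; these entries
#' are set to 0 with a warning so a degenerate window does not abort a cohort
#' run. The diagonal is always 1.
#'
#' @param window_values numeric matrix, samples x regions, >= 3 rows.
#' @return A symmetric regions x regions correlation matrix with unit diagonal.
#' @export
window_adjacency <- function(window_values) {
  window_values <- as.matrix(window_values)
  if (nrow(window_values) < 3) {
    stop("window_adjacency: need at least 3 samples per window")
  }
  m <- suppressWarnings(stats::cor(window_values))
  if (anyNA(m)) {
    warning("window_adjacency: constant region(s) in window; correlations set to 0")
    m[is.na(m)] <- 0
  }
  diag(m) <- 1
  m
}

#' Windowed connectivity sequence
#'
#' Applies [window_adjacency()] to every window of a segmented series,
#' producing the dynamic functional connectivity graph: one symmetric N x N
#' adjacency matrix per window, each carrying its run's task label.
#'
#' @param series a [regional_ts()] object (normally already band-passed).
#' @param windows window table from [segment_windows()]; computed with
#'   defaults when omitted.
#' @return An object of class `windowed_connectivity`: list with `matrices`
#'   (list of N x N matrices), `window_task` (labels) and `window_seconds`.
#' @export
windowed_connectivity <- function(series, windows = NULL) {
  stopifnot(inherits(series, "regional_ts"))
  if (is.null(windows)) windows <- segment_windows(series)
  mats <- lapply(seq_len(nrow(windows)), function(w) {
    window_adjacency(series$values[windows$start[w]:windows$end[w], ,
                                   drop = FALSE])
  })
  structure(list(matrices = mats,
                 window_task = windows$task,
                 window_seconds = attr(windows, "window_seconds")),
            class = "windowed_connectivity")
}

#' Canonical edge index map
#'
#' Bijection between edge ids and unordered node pairs. Edges are ranked in
#' lexicographic upper-triangle order: (1,2), (1,3), ..., (1,N), (2,3), ...
#' so that `E = N(N-1)/2`.
#'
#' @param n_nodes number of nodes N (>= 2).
#' @return An object of class `edge_index_map`: list with `n_nodes`, `n_edges`
#'   and `pairs`, an E x 2 integer matrix with `pairs[e, 1] < pairs[e, 2]`.
#' @export
edge_index_map <- function(n_nodes) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 2) stop("edge_index_map: need at least 2 nodes to form an edge")
  i <- rep(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- unlist(lapply(seq_len(n_nodes - 1L), function(a) (a + 1L):n_nodes))
  structure(list(n_nodes = n_nodes,
                 n_edges = (n_nodes * (n_nodes - 1L)) %/% 2L,
                 pairs = cbind(i = i, j = j)),
            class = "edge_index_map")
}

#' Edge id of a node pair
#'
#' Inverse of the pair lookup in [edge_index_map()]: the canonical rank of the
#' unordered pair (i, j).
#'
#' @param index an [edge_index_map()].
#' @param i,j node indices (order irrelevant, i != j).
#' @return Integer edge id(s).
#' @export
edge_id <- function(index, i, j) {
  stopifnot(inherits(index, "edge_index_map"))
  a <- pmin(i, j); b <- pmax(i, j)
  if (any(a < 1 | b > index$n_nodes | a == b)) {
    stop("edge_id: node pair out of range")
  }
  n <- index$n_nodes
  as.integer((a - 1) * n - a * (a - 1) / 2 + (b - a))
}

#' Edge weight time series
#'
#' Rearranges a windowed connectivity sequence into an E x W matrix: one row
#' per edge (canonical order from [edge_index_map()]), one column per window.
#' This is the object on which the edge-edge (hypergraph) analysis operates.
#'
#' @param conn a [windowed_connectivity()] object.
#' @param tol symmetry tolerance for the input matrices.
#' @return An object of class `edge_ts`: list with `weights` (E x W),
#'   `index` (the [edge_index_map()]) and `window_task`.
#' @export
build_edge_timeseries <- function(conn, tol = 1e-8) {
  stopifnot(inherits(conn, "windowed_connectivity"))
  w_count <- length(conn$matrices)
  if (w_count < 1) stop("build_edge_timeseries: need at least one window")
  n <- nrow(conn$matrices[[1]])
  idx <- edge_index_map(n)
  sel <- idx$pairs
  weights <- matrix(NA_real_, nrow = idx$n_edges, ncol = w_count)
  for (w in seq_len(w_count)) {
    m <- conn$matrices[[w]]
    if (nrow(m) != n || ncol(m) != n) {
      stop("build_edge_timeseries: window matrices differ in size")
    }
    if (max(abs(m - t(m))) > tol) {
      stop(sprintf("build_edge_timeseries: window %d matrix is not symmetric", w))
    }
    weights[, w] <- m[sel]
  }
  structure(list(weights = weights, index = idx,
                 window_task = conn$window_task),
            class = "edge_ts")
}

#' @export
print.edge_ts <- function(x, ...) {
  cat(sprintf("<edge_ts> %d edges (N = %d nodes) x %d windows\n",
              x$index$n_edges, x$index$n_nodes, ncol(x$weights)))
  invisible(x)
}
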