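#' Specification of one synthetic subject
#'
#' Describes a synthetic multi-region recording with planted hyperedge
#' structure. Each planted module is a set of at least three regions that
#' share a band-limited common component that is present, with log-normal
#' amplitude jitter, in a sparse random subset of analysis windows and absent
#' elsewhere. Within a module the windowed correlations of all node pairs
#' therefore rise and fall together, so the downstream analysis should
#' recover exactly one non-singleton hyperedge per module. Background regions
#' are pure noise.
#'
#' @param n_regions number of regions (nodes).
#' @param runs data frame with columns `task`, `n_volumes`, `sampling_period`
#'   (seconds); one row per run.
#' @param modules list of disjoint integer vectors of region indices, each of
#'   length >= 3; use [planted_modules()] for a canonical layout. May be empty.
#' @param modulation_strength log-scale standard deviation (sdlog) of the
#'   log-normal amplitude jitter of the module component in its active
#'   windows (dimensionless, >= 0). Default 0.5.
#' @param active_fraction fraction of windows in which a module's component is
#'   present (rounded to a whole window count and assigned by seeded
#'   permutation, independently per module); in the remaining windows the
#'   module regions are pure noise. Default 0.10. Sparse activity is what
#'   separates planted hyperedges: it keeps a member pair's average shared
#'   signal fraction low, so edges from two members to a common third region
#'   do not become significantly correlated themselves.
#' @param noise_sd standard deviation of the independent white noise added to
#'   every region, relative to the unit-median active component (default
#'   0.25).
#' @param window_seconds window length the gain sequence is aligned to
#'   (default 60, matching the analysis).
#' @param age optional covariate in years, carried along as metadata.
#' @param seed integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_regions, runs, modules = list(),
                           modulation_strength = 0.5, active_fraction = 0.10,
                           noise_sd = 0.25, window_seconds = 60,
                           age = NA_real_, seed = 1L) {
  n_regions <- as.integer(n_regions)
  if (n_regions < 2) stop("synthetic_spec: need at least 2 regions")
  stopifnot(is.data.frame(runs),
            all(c("task", "n_volumes", "sampling_period") %in% names(runs)))
  if (any(runs$n_volumes < 1) || any(runs$sampling_period <= 0)) {
    stop("synthetic_spec: invalid run table")
  }
  spw <- floor(window_seconds / runs$sampling_period)
  if (any(runs$n_volumes < spw)) {
    stop("synthetic_spec: every run must hold at least one full window")
  }
  modules <- lapply(modules, function(m) sort(as.integer(m)))
  if (length(modules) > 0) {
    all_nodes <- unlist(modules)
    if (any(lengths(modules) < 3)) {
      stop("synthetic_spec: each module needs >= 3 regions (>= 3 edges)")
    }
    if (anyDuplicated(all_nodes)) {
      stop("synthetic_spec: module node sets must be pairwise disjoint")
    }
    if (any(all_nodes < 1 | all_nodes > n_regions)) {
      stop("synthetic_spec: module node index out of range")
    }
  }
  if (noise_sd <= 0) stop("synthetic_spec: noise_sd must be > 0")
  if (modulation_strength < 0) stop("synthetic_spec: modulation_strength must be >= 0")
  if (active_fraction <= 0 || active_fraction > 1) {
    stop("synthetic_spec: active_fraction must be in (0, 1]")
  }
  structure(list(n_regions = n_regions, runs = runs, modules = modules,
                 modulation_strength = modulation_strength,
                 active_fraction = active_fraction,
                 noise_sd = noise_sd, window_seconds = window_seconds,
                 age = age, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Canonical planted module layout
#'
#' Assigns the first `k * size` regions to `k` disjoint modules of `size`
#' regions each. Three regions per module is the smallest hyperedge-generating
#' unit (three co-fluctuating edges) and is the default.
#'
#' @param k number of modules.
#' @param n_regions total regions available.
#' @param size regions per module (>= 3, default 3).
#' @return List of `k` disjoint integer vectors.
#' @export
planted_modules <- function(k, n_regions, size = 3) {
  k <- as.integer(k); size <- as.integer(size)
  if (k == 0) return(list())
  if (size < 3) stop("planted_modules: size must be >= 3")
  if (k * size > n_regions) {
    stop(sprintf("planted_modules: %d modules of %d regions exceed %d regions",
                 k, size, n_regions))
  }
  lapply(seq_len(k), function(m) ((m - 1L) * size + 1L):(m * size))
}

#' Default synthetic run layout
#'
#' A run table of concatenated task runs whose total window count is
#' `n_windows`: windows are split as evenly as possible across tasks and each
#' run's volume count is an exact multiple of the samples per window, so no
#' volumes are discarded.
#'
#' @param n_windows total analysis windows across all runs (default 58).
#' @param sampling_period TR in seconds (default 2).
#' @param tasks task labels, one per run.
#' @param window_seconds window length the layout is sized for (default 60).
#' @return Data frame with columns `task`, `n_volumes`, `sampling_period`.
#' @export
default_runs <- function(n_windows = 58, sampling_period = 2,
                         tasks = c("rest", "taskA", "taskB"),
                         window_seconds = 60) {
  spw <- floor(window_seconds / sampling_period)
  per_run <- diff(round(seq(0, n_windows, length.out = length(tasks) + 1)))
  data.frame(task = tasks, n_volumes = as.integer(per_run * spw),
             sampling_period = sampling_period, stringsAsFactors = FALSE)
}

#' Generate one synthetic subject
#'
#' Realizes the model described in [synthetic_spec()]: every module owns a
#' band-limited (0.06-0.125 Hz) common component of unit variance; within each
#' `active_fraction` of the analysis windows (chosen by seeded permutation,
#' independently per module) the component enters with a log-normal gain;
#' in the remaining windows it is absent. Member regions receive the gained
#' component plus independent white noise, background regions receive white
#' noise only. Samples in the trailing remainder of a run (discarded by the
#' windowing) reuse the last window's gain.
#'
#' @param spec a [synthetic_spec()].
#' @return A [regional_ts()] with an `age` attribute.
#' @export
generate_subject <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  runs <- spec$runs
  n_total <- sum(runs$n_volumes)
  n <- spec$n_regions
  values <- matrix(stats::rnorm(n_total * n, sd = spec$noise_sd),
                   nrow = n_total, ncol = n)
  ts_skeleton <- regional_ts(matrix(0, n_total, 1),
                             sampling_period = runs$sampling_period,
                             run_lengths = runs$n_volumes,
                             task_labels = runs$task)
  windows <- segment_windows(ts_skeleton, spec$window_seconds)
  # per-sample window id; remainder samples inherit the run's last window
  win_of <- integer(n_total)
  for (w in seq_len(nrow(windows))) {
    win_of[windows$start[w]:windows$end[w]] <- w
  }
  rr <- run_ranges(ts_skeleton)
  for (r in seq_len(nrow(rr))) {
    idx <- rr[r, "start"]:rr[r, "end"]
    tail0 <- idx[win_of[idx] == 0L]
    if (length(tail0) > 0) win_of[tail0] <- max(win_of[idx])
  }
  n_win <- nrow(windows)
  for (k in seq_along(spec$modules)) {
    comp <- bandlimited_noise(n_total, runs)
    n_on <- max(1L, round(spec$active_fraction * n_win))
    gains <- numeric(n_win)
    gains[sample.int(n_win, n_on)] <-
      stats::rlnorm(n_on, meanlog = 0, sdlog = spec$modulation_strength)
    scaled <- gains[win_of] * comp
    for (region in spec$modules[[k]]) {
      values[, region] <- values[, region] + scaled
    }
  }
  out <- regional_ts(values, sampling_period = runs$sampling_period,
                     run_lengths = runs$n_volumes, task_labels = runs$task)
  attr(out, "age") <- spec$age
  attr(out, "n_modules") <- length(spec$modules)
  out
}

# unit-variance white noise band-limited to the analysis band, per run
bandlimited_noise <- function(n_total, runs, low = 0.06, high = 0.125) {
  x <- stats::rnorm(n_total)
  ends <- cumsum(runs$n_volumes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  for (r in seq_len(nrow(runs))) {
    idx <- starts[r]:ends[r]
    seg <- butter_bandpass(matrix(x[idx], ncol = 1),
                           runs$sampling_period[r], low, high, 4)
    s <- stats::sd(seg)
    x[idx] <- if (s > 0) seg / s else seg
  }
  x
}

#' Generate a structureless null subject
#'
#' Independent stationary white noise in every region, with no planted
#' cross-edge temporal structure: the downstream hypergraph should contain
#' only singletons (up to the FDR level).
#'
#' @param n_regions number of regions (>= 2).
#' @param runs run table as in [synthetic_spec()].
#' @param seed integer seed.
#' @return A [regional_ts()].
#' @export
generate_null_subject <- function(n_regions, runs, seed = 1L) {
  spec <- synthetic_spec(n_regions, runs, modules = list(), seed = seed)
  generate_subject(spec)
}

#' Default individual-difference measure categories
#'
#' Measure counts per category for the 42-measure table: 6 performance, 4
#' demographics (age, education, sex, handedness), 10 state-of-mind, 10
#' cognitive-factor and 12 personality measures.
#'
#' @return Named integer vector summing to 42.
#' @export
default_measure_categories <- function() {
  c(performance = 6L, demographics = 4L, state_of_mind = 10L,
    cognitive = 10L, personality = 12L)
}

#' Specification of a synthetic cohort
#'
#' Describes a cohort in which age modulates the number of planted modules
#' (the hyperedge-generating groups): a subject of age `a` carries
#' `base_modules + round(cardinality_slope * (a - min age))` modules, planting
#' a positive age-to-cardinality relationship for the individual-differences
#' stage to recover. Alongside the recordings the cohort carries a
#' category-structured individual-difference table.
#'
#' @param n_subjects cohort size.
#' @param age_range two-element numeric, years (default c(18, 75)).
#' @param base_modules module count at the youngest age (default 2).
#' @param cardinality_slope planted modules per year of age (default 1/15).
#' @param measure_categories named integer vector of measures per category
#'   (default [default_measure_categories()]).
#' @param n_regions regions per subject (default 50).
#' @param runs run table (default: three concatenated runs of one memory task
#'   at TR 2 s totalling 100 windows of `window_seconds`).
#' @param module_size regions per planted module (default 3).
#' @param window_seconds analysis window length the gains align to (default
#'   120; the analysis of a cohort should use the same window length).
#' @param modulation_strength,active_fraction,noise_sd passed to
#'   [synthetic_spec()].
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, age_range = c(18, 75), base_modules = 2,
                        cardinality_slope = 1 / 15,
                        measure_categories = default_measure_categories(),
                        n_regions = 50, runs = NULL, module_size = 3,
                        window_seconds = 120, modulation_strength = 0.5,
                        active_fraction = 0.10, noise_sd = 0.25, seed = 1L) {
  if (is.null(runs)) {
    runs <- default_runs(n_windows = 100, sampling_period = 2,
                         tasks = rep("memory", 3),
                         window_seconds = window_seconds)
  }
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2) stop("cohort_spec: need at least 2 subjects")
  stopifnot(length(age_range) == 2, age_range[1] <= age_range[2])
  k_max <- base_modules + round(cardinality_slope * diff(age_range))
  if (k_max * module_size > n_regions) {
    stop(sprintf(
      "cohort_spec: up to %d modules of %d regions infeasible with %d regions",
      k_max, module_size, n_regions))
  }
  if (is.null(names(measure_categories)) || any(measure_categories < 1)) {
    stop("cohort_spec: measure_categories must be a named count vector")
  }
  structure(list(n_subjects = n_subjects, age_range = age_range,
                 base_modules = base_modules,
                 cardinality_slope = cardinality_slope,
                 measure_categories = measure_categories,
                 n_regions = as.integer(n_regions), runs = runs,
                 module_size = as.integer(module_size),
                 window_seconds = window_seconds,
                 modulation_strength = modulation_strength,
                 active_fraction = active_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws subject ages uniformly over the age range, generates each subject's
#' recording with the age-determined module count, and builds the
#' individual-difference table: every category has a two-factor low-rank
#' structure plus standard-normal residual noise; the first demographics
#' factor is (standardized) age itself, so the demographics category carries
#' the planted covariate. A head-motion proxy mildly correlated with age is
#' included as an extra covariate.
#'
#' @param spec a [cohort_spec()].
#' @return List with `subjects` (list of [regional_ts()]), `ages`, `n_modules`
#'   (planted K per subject) and `measures` (a [measure_table()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  ages <- round(stats::runif(n, spec$age_range[1], spec$age_range[2]))
  k <- spec$base_modules + round(spec$cardinality_slope *
                                   (ages - spec$age_range[1]))
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  subjects <- vector("list", n)
  for (s in seq_len(n)) {
    sspec <- synthetic_spec(
      n_regions = spec$n_regions, runs = spec$runs,
      modules = planted_modules(k[s], spec$n_regions, spec$module_size),
      modulation_strength = spec$modulation_strength,
      active_fraction = spec$active_fraction, noise_sd = spec$noise_sd,
      window_seconds = spec$window_seconds,
      age = ages[s], seed = subject_seeds[s])
    subjects[[s]] <- generate_subject(sspec)
  }
  measures <- synth_measure_table(ages, spec$measure_categories)
  list(subjects = subjects, ages = ages, n_modules = k, measures = measures)
}

# category-structured measure table: 2 latent factors per category, the first
# demographics factor is standardized age; residual noise sd 0.3
synth_measure_table <- function(ages, categories, noise_sd = 0.3) {
  n <- length(ages)
  cols <- list()
  category_of <- character(0)
  z_age <- as.vector(scale(ages))
  for (cat in names(categories)) {
    m <- categories[[cat]]
    f1 <- if (cat == "demographics") z_age else stats::rnorm(n)
    f2 <- stats::rnorm(n)
    load1 <- stats::runif(m, 0.7, 1.3) * sample(c(-1, 1), m, replace = TRUE)
    load2 <- stats::runif(m, 0.2, 0.6) * sample(c(-1, 1), m, replace = TRUE)
    x <- outer(f1, load1) + outer(f2, load2) +
      matrix(stats::rnorm(n * m, sd = noise_sd), n, m)
    colnames(x) <- paste0(cat, "_", seq_len(m))
    cols[[cat]] <- x
    category_of <- c(category_of, stats::setNames(rep(cat, m), colnames(x)))
  }
  data <- do.call(cbind, cols)
  head_motion <- 0.3 * z_age + stats::rnorm(n, sd = 0.5)
  measure_table(as.data.frame(data), category_of,
                covariates = data.frame(age = ages, head_motion = head_motion))
}

#' Well-separated validation regime
#'
#' The reference parameter regime for planted-structure recovery experiments:
#' 50 regions, 100 windows of 120 s (TR 2 s) across three concatenated runs,
#' and the sparse crisp module activity of the generator defaults. In this
#' regime every planted module is recovered as exactly one non-singleton
#' hyperedge by the analysis settings of [recovery_config()] in the large
#' majority of seeds, so hypergraph cardinality equals the planted module
#' count. Use together with [recovery_config()].
#'
#' @param k planted module count.
#' @param seed integer seed.
#' @param n_regions regions (default 50).
#' @param n_windows total analysis windows (default 100).
#' @return A [synthetic_spec()].
#' @export
well_separated_spec <- function(k, seed, n_regions = 50, n_windows = 100) {
  synthetic_spec(
    n_regions,
    default_runs(n_windows = n_windows, window_seconds = 120),
    modules = planted_modules(k, n_regions),
    window_seconds = 120, seed = seed)
}
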