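#' Individual-difference measure table
#'
#' Subjects x measures table in which every measure belongs to exactly one of
#' a small set of categories (demographics, performance, personality, ...),
#' plus separately flagged covariates such as age and a head-motion proxy that
#' are used directly as predictors rather than entering the factor reduction.
#'
#' @param data data frame or matrix, subjects x measures, numeric, no missing
#'   values.
#' @param category_of named character vector mapping every measure (column
#'   name) to its category.
#' @param covariates optional data frame of per-subject covariates (e.g.
#'   `age`, `head_motion`).
#' @return An object of class `measure_table`.
#' @export
measure_table <- function(data, category_of, covariates = NULL) {
  data <- as.data.frame(data)
  if (!all(vapply(data, is.numeric, TRUE))) {
    stop("measure_table: all measures must be numeric")
  }
  if (anyNA(data)) stop("measure_table: missing values in measures")
  missing_map <- setdiff(names(data), names(category_of))
  if (length(missing_map) > 0) {
    stop(sprintf("measure_table: measures without category: %s",
                 paste(missing_map, collapse = ", ")))
  }
  category_of <- category_of[names(data)]
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(data)) {
      stop("measure_table: covariates must have one row per subject")
    }
    if (anyNA(covariates)) stop("measure_table: missing values in covariates")
  }
  structure(list(data = data, category_of = category_of,
                 covariates = covariates),
            class = "measure_table")
}

#' @export
print.measure_table <- function(x, ...) {
  tab <- table(x$category_of)
  cat(sprintf("<measure_table> %d subjects x %d measures in %d categories\n",
              nrow(x$data), ncol(x$data), length(tab)))
  cat(sprintf("  %s\n", paste(names(tab), tab, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Category-wise SVD factor reduction
#'
#' Demeans every measure and performs a singular value decomposition
#' separately within each category, keeping the minimum number of factors
#' whose cumulative squared-singular-value fraction reaches the variance
#' threshold (default 75%). Factor scores are the projections of the (this
#' table's) demeaned data onto the retained right singular directions;
#' loadings are the unit-norm direction vectors, sign-flipped so each factor's
#' largest-magnitude loading is positive. With `joint_tables`, the directions
#' and the variance count are fitted on the row-stacked data of all tables,
#' emulating a factor basis shared between studies.
#'
#' @param table a [measure_table()].
#' @param threshold minimum fraction of variance retained per category
#'   (default 0.75).
#' @param joint_tables optional list of additional [measure_table()]s with the
#'   same measures, stacked for fitting the directions.
#' @param standardize also scale measures to unit variance before the SVD
#'   (default FALSE: measures are demeaned only).
#' @return An object of class `factor_set`: per category a list with
#'   `scores`, `loadings`, `k` and `variance_retained`, plus a combined
#'   `scores` matrix with columns `<category>.f<j>`.
#' @export
choose_factors <- function(table, threshold = 0.75, joint_tables = NULL,
                           standardize = FALSE) {
  stopifnot(inherits(table, "measure_table"))
  cats <- unique(table$category_of)
  per_cat <- list()
  all_scores <- NULL
  for (cat in cats) {
    meas <- names(table$category_of)[table$category_of == cat]
    x <- as.matrix(table$data[meas])
    fit_x <- x
    if (!is.null(joint_tables)) {
      extra <- lapply(joint_tables, function(jt) {
        stopifnot(inherits(jt, "measure_table"))
        as.matrix(jt$data[meas])
      })
      fit_x <- do.call(rbind, c(list(x), extra))
    }
    keep <- apply(fit_x, 2, stats::sd) > 0
    if (!all(keep)) {
      warning(sprintf("choose_factors: dropping constant measure(s) in '%s': %s",
                      cat, paste(meas[!keep], collapse = ", ")))
      fit_x <- fit_x[, keep, drop = FALSE]
      x <- x[, keep, drop = FALSE]
    }
    if (ncol(fit_x) == 0) stop(sprintf("choose_factors: category '%s' is empty", cat))
    fit_c <- scale(fit_x, center = TRUE, scale = standardize)
    sv <- svd(fit_c)
    ev <- sv$d^2
    cumfrac <- cumsum(ev) / sum(ev)
    k <- which(cumfrac >= threshold)[1]
    v <- sv$v[, seq_len(k), drop = FALSE]
    flip <- apply(v, 2, function(col) sign(col[which.max(abs(col))]))
    v <- sweep(v, 2, flip, `*`)
    xc <- scale(x, center = TRUE, scale = standardize)
    scores <- xc %*% v
    colnames(scores) <- paste0(cat, ".f", seq_len(k))
    rownames(v) <- colnames(fit_x)
    per_cat[[cat]] <- list(scores = scores, loadings = v, k = k,
                           variance_retained = cumfrac[k])
    all_scores <- cbind(all_scores, scores)
  }
  structure(list(categories = per_cat, scores = all_scores,
                 threshold = threshold),
            class = "factor_set")
}

#' @export
print.factor_set <- function(x, ...) {
  for (cat in names(x$categories)) {
    fc <- x$categories[[cat]]
    cat(sprintf("  %s: %d factor(s), %.1f%% variance retained\n",
                cat, fc$k, 100 * fc$variance_retained))
  }
  invisible(x)
}

#' Hierarchical regression with per-category R-squared change
#'
#' Ordinary least squares of a per-subject metric (e.g. hypergraph
#' cardinality) on all category factors plus optional extra predictors (head
#' motion, rest cardinality, ...). The contribution of a category is the drop
#' in model R-squared when all of that category's factors are removed while
#' every other predictor, including the extras, is retained - equivalent to a
#' hierarchical regression entering the category last. Extra predictors stay
#' in both the full and every reduced model. Per-coefficient two-sided t-test
#' p-values are reported for use with [bonferroni_flags()].
#'
#' @param dependent numeric vector, one value per subject.
#' @param factors a [choose_factors()] object.
#' @param extra_predictors optional data frame of always-retained predictors.
#' @return An object of class `regression_result`: `coefficients`,
#'   `p_values`, `r_squared`, `r2_change` (per category, >= 0),
#'   `r2_change_normalized` (sums to 1 when any change > 0), `n`, and the
#'   fitted `model`.
#' @export
r2_change_regression <- function(dependent, factors, extra_predictors = NULL) {
  stopifnot(inherits(factors, "factor_set"))
  y <- as.numeric(dependent)
  x <- as.data.frame(factors$scores)
  if (!is.null(extra_predictors)) {
    extra_predictors <- as.data.frame(extra_predictors)
    stopifnot(nrow(extra_predictors) == length(y))
    x <- cbind(x, extra_predictors)
  }
  if (length(y) != nrow(x)) {
    stop("r2_change_regression: dependent length does not match subjects")
  }
  if (length(y) <= ncol(x) + 1) {
    stop("r2_change_regression: need more subjects than predictors + 1")
  }
  if (stats::sd(y) == 0) {
    stop("r2_change_regression: dependent variable is constant; R^2 undefined")
  }
  dat <- cbind(data.frame(.y = y), x)
  full <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(full)))) {
    bad <- names(which(is.na(stats::coef(full))))
    stop(sprintf("r2_change_regression: rank-deficient design; collinear: %s",
                 paste(bad, collapse = ", ")))
  }
  r2_full <- summary(full)$r.squared
  cats <- names(factors$categories)
  change <- stats::setNames(numeric(length(cats)), cats)
  for (cat in cats) {
    drop_cols <- colnames(factors$categories[[cat]]$scores)
    red <- stats::lm(.y ~ ., data = dat[, !(names(dat) %in% drop_cols),
                                        drop = FALSE])
    change[cat] <- r2_full - summary(red)$r.squared
  }
  stopifnot(all(change >= -1e-10))            # nested models
  change <- pmax(change, 0)
  total <- sum(change)
  norm <- if (total > 0) change / total else change
  sm <- summary(full)$coefficients
  structure(list(coefficients = sm[, "Estimate"],
                 p_values = sm[, "Pr(>|t|)"],
                 r_squared = r2_full,
                 r2_change = change,
                 r2_change_normalized = norm,
                 n = length(y), model = full),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> n = %d, R^2 = %.4f\n", x$n, x$r_squared))
  cat("  normalized R^2 change by category:\n")
  for (cat in names(x$r2_change)) {
    cat(sprintf("    %-14s %.3f (raw %.4f)\n", cat,
                x$r2_change_normalized[cat], x$r2_change[cat]))
  }
  invisible(x)
}

#' Bonferroni significance flags
#'
#' Flags p-values significant at `alpha / m`, where `m` is the size of the
#' whole family of tests performed in the session (all coefficient t-tests
#' across all regressions), the most stringent correction.
#'
#' @param p_values numeric vector of p-values.
#' @param m family size (>= length of `p_values`).
#' @param alpha uncorrected level (default 0.05).
#' @return Logical vector.
#' @export
bonferroni_flags <- function(p_values, m, alpha = 0.05) {
  if (m <= 0) stop("bonferroni_flags: family size m must be positive")
  if (m < length(p_values)) {
    stop("bonferroni_flags: family size smaller than the number of tests")
  }
  p_values < alpha / m
}

#' Spearman correlation between age and hypergraph cardinality
#'
#' Rank correlation with average-rank tie handling; the two-sided p-value uses
#' the t approximation on the rank correlation.
#'
#' @param cardinalities,ages numeric vectors, length n >= 5.
#' @return List with `rho` and `p`.
#' @export
spearman_age <- function(cardinalities, ages) {
  n <- length(ages)
  stopifnot(length(cardinalities) == n)
  if (n < 5) stop("spearman_age: need at least 5 pairs")
  if (stats::sd(cardinalities) == 0 || stats::sd(ages) == 0) {
    stop("spearman_age: correlation undefined for a constant vector")
  }
  rho <- stats::cor(rank(cardinalities), rank(ages))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  if (abs(rho) >= 1) p <- 0
  list(rho = rho, p = p)
}

#' Age-group comparison of hyperedge node degree
#'
#' Splits subjects into discrete age bins, reports the mean hyperedge node
#' degree per region within each bin, and compares the youngest against the
#' oldest bin. The default test is a per-region Welch two-sample t-test (the
#' groups contain different subjects); `method = "paired"` instead runs a
#' single paired t-test across regions on the two groups' per-region mean
#' profiles.
#'
#' @param profiles matrix of node degrees, subjects x regions.
#' @param ages numeric vector of subject ages.
#' @param bins list of two-element numeric ranges (inclusive); default the
#'   three groups 18, 25-33 and 60-75 years.
#' @param method `"welch"` (default) or `"paired"`.
#' @return List with `group_means` (regions x bins), `n_per_bin`, and for
#'   `"welch"` per-region `statistic` and `p_values` (youngest vs oldest), or
#'   for `"paired"` a single `statistic` and `p_value`.
#' @export
age_group_degree_comparison <- function(profiles, ages,
                                        bins = list(c(18, 18), c(25, 33),
                                                    c(60, 75)),
                                        method = c("welch", "paired")) {
  method <- match.arg(method)
  profiles <- as.matrix(profiles)
  stopifnot(nrow(profiles) == length(ages))
  groups <- lapply(bins, function(b) which(ages >= b[1] & ages <= b[2]))
  n_per_bin <- lengths(groups)
  if (n_per_bin[1] == 0 || n_per_bin[length(bins)] == 0) {
    stop("age_group_degree_comparison: empty youngest or oldest bin")
  }
  group_means <- vapply(groups, function(g) {
    if (length(g) == 0) rep(NA_real_, ncol(profiles))
    else colMeans(profiles[g, , drop = FALSE])
  }, numeric(ncol(profiles)))
  colnames(group_means) <- vapply(bins, function(b)
    paste0(b[1], "-", b[2]), "")
  young <- profiles[groups[[1]], , drop = FALSE]
  old <- profiles[groups[[length(groups)]], , drop = FALSE]
  if (method == "welch") {
    if (nrow(young) < 2 || nrow(old) < 2) {
      stop("age_group_degree_comparison: Welch test needs >= 2 subjects per compared bin")
    }
    tests <- lapply(seq_len(ncol(profiles)), function(r) {
      if (stats::sd(young[, r]) == 0 && stats::sd(old[, r]) == 0) {
        list(statistic = 0, p.value = 1)
      } else {
        stats::t.test(old[, r], young[, r])
      }
    })
    list(group_means = group_means, n_per_bin = n_per_bin,
         statistic = vapply(tests, function(t) unname(t$statistic), 1),
         p_values = vapply(tests, function(t) t$p.value, 1))
  } else {
    tt <- stats::t.test(colMeans(old), colMeans(young), paired = TRUE)
    list(group_means = group_means, n_per_bin = n_per_bin,
         statistic = unname(tt$statistic), p_value = tt$p.value)
  }
}
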