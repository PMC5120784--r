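make_table <- function(n = 40, seed = 1) {
  set.seed(seed)
  f <- matrix(rnorm(n * 4), n, 4)
  data <- cbind(
    a1 = f[, 1] + rnorm(n, sd = 0.1), a2 = -f[, 1] + rnorm(n, sd = 0.1),
    a3 = f[, 2] + rnorm(n, sd = 0.1),
    b1 = f[, 3] + rnorm(n, sd = 0.1), b2 = f[, 3] + rnorm(n, sd = 0.1),
    b3 = f[, 4] + rnorm(n, sd = 0.1), b4 = 2 * f[, 4] + rnorm(n, sd = 0.1))
  measure_table(as.data.frame(data),
                c(a1 = "A", a2 = "A", a3 = "A",
                  b1 = "B", b2 = "B", b3 = "B", b4 = "B"))
}

test_that("measure tables validate categories and missing values", {
  d <- data.frame(x = 1:3, y = 4:6)
  expect_error(measure_table(d, c(x = "A")), "without category")
  d2 <- d; d2$x[2] <- NA
  expect_error(measure_table(d2, c(x = "A", y = "A")), "missing values")
  expect_error(measure_table(d, c(x = "A", y = "A"),
                             covariates = data.frame(age = 1:2)),
               "one row per subject")
})

test_that("factor choice keeps the minimal count reaching the threshold", {
  # rank-1 category: one factor retains everything
  set.seed(6)
  u <- rnorm(30)
  d <- data.frame(m1 = u, m2 = 2 * u, m3 = -u)
  mt <- measure_table(d, c(m1 = "C", m2 = "C", m3 = "C"))
  fs <- choose_factors(mt)
  expect_equal(fs$categories$C$k, 1)
  expect_equal(fs$categories$C$variance_retained, 1.0)

  # constructed singular values (2, 1, 1): 4/6 < 0.75 <= 5/6 -> k = 2
  set.seed(8)
  q <- qr.Q(qr(matrix(rnorm(36 * 3), 36, 3)))
  v <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  x <- q %*% diag(c(2, 1, 1)) %*% t(v)
  x <- scale(x, center = TRUE, scale = FALSE)
  # re-impose exact singular values after centering
  sv <- svd(x)
  x <- sv$u %*% diag(c(2, 1, 1)) %*% t(sv$v)
  mt2 <- measure_table(as.data.frame(`colnames<-`(x, c("p", "q", "r"))),
                       c(p = "D", q = "D", r = "D"))
  fs2 <- choose_factors(mt2)
  expect_equal(fs2$categories$D$k, 2)
  expect_equal(fs2$categories$D$variance_retained, 5 / 6, tolerance = 1e-8)
})

test_that("variance retained is nondecreasing and k minimal across random tables", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(20:40, 1); m <- sample(3:6, 1)
    x <- matrix(rnorm(n * m), n, m) %*% diag(exp(rnorm(m)))
    colnames(x) <- paste0("v", 1:m)
    mt <- measure_table(as.data.frame(x),
                        setNames(rep("Z", m), colnames(x)))
    thr <- runif(1, 0.5, 0.95)
    fs <- choose_factors(mt, threshold = thr)
    ev <- svd(scale(x, scale = FALSE))$d^2
    cumfrac <- cumsum(ev) / sum(ev)
    expect_equal(fs$categories$Z$k, which(cumfrac >= thr)[1])
    expect_true(all(diff(cumfrac) >= -1e-12))
  }
})

test_that("factor scores and loadings follow the documented conventions", {
  mt <- make_table()
  fs <- choose_factors(mt)
  for (cat in names(fs$categories)) {
    fc <- fs$categories[[cat]]
    # unit-norm loadings, largest-magnitude entry positive
    expect_equal(unname(apply(fc$loadings, 2, function(c) sqrt(sum(c^2)))),
                 rep(1, fc$k))
    for (j in seq_len(fc$k)) {
      l <- fc$loadings[, j]
      expect_gt(l[which.max(abs(l))], 0)
    }
    # scores orthogonal within category
    if (fc$k > 1) {
      g <- crossprod(fc$scores)
      expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)
    }
  }
})

test_that("joint-table fitting uses the stacked data for directions", {
  mt1 <- make_table(seed = 2)
  mt2 <- make_table(seed = 3)
  fs_joint <- choose_factors(mt1, joint_tables = list(mt2))
  expect_equal(nrow(fs_joint$scores), 40)   # scores for the first table only
  fs_solo <- choose_factors(mt1)
  expect_false(identical(fs_solo$categories$A$loadings,
                         fs_joint$categories$A$loadings))
})

test_that("R-squared changes match the normal-equations oracle", {
  set.seed(30)
  n <- 60
  mt <- make_table(n = n, seed = 30)
  fs <- choose_factors(mt)
  extra <- data.frame(motion = rnorm(n))
  y <- rnorm(n)
  res <- r2_change_regression(y, fs, extra_predictors = extra)
  x_full <- cbind(as.data.frame(fs$scores), extra)
  expect_equal(res$r_squared, r2_normal_equations(y, x_full), tolerance = 1e-9)
  for (cat in names(fs$categories)) {
    drop_cols <- colnames(fs$categories[[cat]]$scores)
    x_red <- x_full[, setdiff(names(x_full), drop_cols), drop = FALSE]
    expect_equal(res$r2_change[[cat]],
                 res$r_squared - r2_normal_equations(y, x_red),
                 tolerance = 1e-9)
  }
  expect_true(all(res$r2_change >= 0))
  expect_equal(sum(res$r2_change_normalized), 1)
})

test_that("a dependent equal to one category's factor attributes all change there", {
  set.seed(40)
  n <- 50
  # orthogonal design: categories built from disjoint orthonormal columns
  q <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  d <- data.frame(a1 = q[, 1], a2 = q[, 2], b1 = q[, 3], b2 = q[, 4])
  mt <- measure_table(d, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  fs <- choose_factors(mt, threshold = 0.99)
  y <- fs$categories$A$scores[, 1]
  res <- suppressWarnings(r2_change_regression(y, fs))  # perfect fit intended
  expect_equal(unname(res$r2_change["A"]), 1, tolerance = 1e-8)
  expect_equal(unname(res$r2_change["B"]), 0, tolerance = 1e-8)
  # dependent orthogonal to every predictor
  y2 <- residuals(lm(rnorm(n) ~ fs$scores))
  res2 <- r2_change_regression(y2, fs)
  expect_lt(res2$r_squared, 1e-8)
})

test_that("rank-deficient designs error with the collinear columns named", {
  set.seed(50)
  n <- 30
  u <- rnorm(n)
  d <- data.frame(a1 = u, a2 = u)      # same direction twice
  mt <- measure_table(d, c(a1 = "A", a2 = "A"))
  fs <- choose_factors(mt, threshold = 0.99)
  dup <- as.data.frame(fs$scores)      # duplicate the factor as an extra
  names(dup) <- "dup"
  expect_error(r2_change_regression(rnorm(n), fs, extra_predictors = dup),
               "collinear")
})

test_that("Bonferroni flags use the family-wide threshold", {
  expect_true(bonferroni_flags(0.01, m = 1))
  expect_false(bonferroni_flags(0.01, m = 10))
  set.seed(60)
  p <- runif(25)
  expect_equal(bonferroni_flags(p, m = 25), p < 0.05 / 25)
  expect_error(bonferroni_flags(p, m = 0), "positive")
  expect_error(bonferroni_flags(p, m = 10), "smaller")
})

test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  expect_equal(spearman_age(1:10, 1:10)$rho, 1)
  expect_equal(spearman_age(10:1, 1:10)$rho, -1)
  set.seed(70)
  card <- sample(0:5, 12, TRUE)        # ties guaranteed
  ages <- sample(20:60, 12)
  s <- spearman_age(card, ages)
  expect_equal(s$rho, cor_sum_formula(rank(card), rank(ages)),
               tolerance = 1e-12)
  expect_equal(s$p, cor.test(card, ages, method = "spearman",
                             exact = FALSE)$p.value, tolerance = 1e-10)
  expect_error(spearman_age(rep(2, 6), 1:6), "constant")
  expect_error(spearman_age(1:4, 1:4), "at least 5")
})

test_that("age-group degree comparison flags a planted old-age increase", {
  set.seed(80)
  n_reg <- 12
  ages <- c(rep(18, 10), sample(25:33, 10, TRUE), sample(60:75, 10, TRUE))
  base <- matrix(rpois(30 * n_reg, 4), 30, n_reg)
  planted <- base
  planted[ages >= 60, ] <- planted[ages >= 60, ] * 5
  res <- age_group_degree_comparison(planted, ages)
  expect_true(all(res$p_values < 0.05))
  expect_true(all(res$statistic > 0))
  expect_equal(dim(res$group_means), c(n_reg, 3))
  # identical distributions: few flags beyond the alpha expectation
  res0 <- age_group_degree_comparison(base, ages)
  expect_lt(mean(res0$p_values < 0.05), 0.25)
  # paired variant returns a single test across regions
  resp <- age_group_degree_comparison(planted, ages, method = "paired")
  expect_length(resp$p_value, 1)
  expect_lt(resp$p_value, 0.01)
  expect_error(
    age_group_degree_comparison(planted[c(1, 30), ], ages[c(1, 30)]),
    ">= 2 subjects")
})
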