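test_that("edge-edge correlations handle self, negated and constant rows", {
  set.seed(3)
  w <- matrix(rnorm(60), 6, 10)
  w[2, ] <- -w[1, ]
  w[5, ] <- 2                      # constant edge
  ee <- edge_edge_correlation(make_ets(w))
  expect_equal(diag(ee$correlations), rep(1, 6))
  expect_equal(ee$correlations[1, 2], -1)
  expect_equal(ee$p_values[1, 2], 0)   # both signs are link-eligible
  expect_equal(ee$correlations[5, 3], 0)
  expect_equal(ee$p_values[5, 3], 1)
  expect_true(isSymmetric(ee$p_values))
  expect_error(edge_edge_correlation(make_ets(matrix(rnorm(18), 6, 3))),
               "at least 4 windows")
})

test_that("analytic p-values agree with a permutation oracle", {
  set.seed(21)
  w <- matrix(rnorm(100), 5, 20)
  ee <- edge_edge_correlation(make_ets(w))
  n_perm <- 4000
  for (pair in list(c(1, 2), c(2, 5), c(3, 4))) {
    i <- pair[1]; j <- pair[2]
    obs <- abs(ee$correlations[i, j])
    null_r <- replicate(n_perm, abs(cor(w[i, ], w[j, sample.int(20)])))
    p_perm <- mean(null_r >= obs)
    se <- sqrt(p_perm * (1 - p_perm) / n_perm)
    expect_lt(abs(ee$p_values[i, j] - p_perm), 3 * se + 0.01)
  }
})

test_that("BH binarization matches the step-up enumeration oracle", {
  p_ut <- c(0.001, 0.004, 0.012, 0.03, 0.2, 0.5, 0.7, 0.8, 0.9, 1.0)
  # place the ten p-values in the upper triangle of a 5x5 matrix
  pm <- matrix(0, 5, 5)
  pm[upper.tri(pm)] <- p_ut
  pm <- pm + t(pm)
  rm <- matrix(0.5, 5, 5); diag(rm) <- 1
  g <- fdr_binarize(rm, pm, alpha = 0.05)
  kept <- as.matrix(g$xi_binary)[upper.tri(pm)]
  expect_equal(as.vector(kept), bh_reject_oracle(p_ut, 0.05))

  set.seed(9)
  for (rep in 1:100) {
    p <- runif(15)^sample(1:3, 1)          # varied signal strength
    pm <- matrix(0, 6, 6); pm[upper.tri(pm)] <- p; pm <- pm + t(pm)
    g <- fdr_binarize(rm <- diag(6) * 0 + 0.3, pm, alpha = 0.05)
    expect_equal(as.vector(as.matrix(g$xi_binary)[upper.tri(pm)]),
                 bh_reject_oracle(p, 0.05))
  }
})

test_that("degenerate alpha levels behave as expected", {
  set.seed(4)
  w <- matrix(rnorm(48), 4, 12)
  ee <- edge_edge_correlation(make_ets(w))
  all_sig <- fdr_binarize(ee$correlations, matrix(0, 4, 4), alpha = 0.05)
  hg <- extract_hypergraph(all_sig)
  expect_equal(hg$cardinality, 1)
  expect_equal(hg$sizes, 4L)
  none <- fdr_binarize(ee$correlations, matrix(1, 4, 4), alpha = 0.05)
  expect_equal(extract_hypergraph(none)$cardinality, 0)
  zero_alpha <- fdr_binarize(ee$correlations, matrix(0, 4, 4), alpha = 0)
  expect_equal(extract_hypergraph(zero_alpha)$cardinality, 0)
})

test_that("link sets are nested as alpha decreases (BH monotonicity)", {
  set.seed(13)
  for (rep in 1:20) {
    p <- runif(45)^2
    pm <- matrix(0, 10, 10); pm[upper.tri(pm)] <- p; pm <- pm + t(pm)
    rm <- matrix(0.4, 10, 10); diag(rm) <- 1
    alphas <- sort(runif(3, 0.01, 0.3))
    links <- lapply(alphas, function(a) {
      which(as.matrix(fdr_binarize(rm, pm, alpha = a)$xi_binary))
    })
    expect_true(all(links[[1]] %in% links[[2]]))
    expect_true(all(links[[2]] %in% links[[3]]))
  }
})

test_that("hyperedges equal breadth-first-search components on random graphs", {
  set.seed(31)
  for (rep in 1:100) {
    e <- sample(20:200, 1)
    n_links <- sample(0:(2 * e), 1)
    links <- cbind(sample.int(e, n_links, TRUE), sample.int(e, n_links, TRUE))
    links <- links[links[, 1] != links[, 2], , drop = FALSE]
    links <- cbind(pmin(links[, 1], links[, 2]), pmax(links[, 1], links[, 2]))
    links <- unique(links)
    pm <- matrix(1, e, e)
    if (nrow(links) > 0) {
      pm[links] <- 0
      pm[links[, 2:1, drop = FALSE]] <- 0
    }
    rm <- matrix(0.9, e, e); diag(rm) <- 1
    hg <- extract_hypergraph(fdr_binarize(rm, pm, alpha = 0.05))
    oracle <- bfs_components(e, links)
    oracle_sets <- unname(split(seq_len(e), oracle))
    oracle_hyper <- oracle_sets[lengths(oracle_sets) >= 2]
    oracle_singletons <- sort(unlist(oracle_sets[lengths(oracle_sets) == 1]))
    expect_equal(hg$cardinality, length(oracle_hyper))
    expect_setequal(lapply(hg$hyperedges, sort), lapply(oracle_hyper, sort))
    expect_equal(hg$singletons, as.integer(oracle_singletons))
    # partition invariant
    expect_equal(length(hg$singletons) + sum(hg$sizes), e)
  }
})

test_that("chain links form one hyperedge and empty graphs only singletons", {
  pm <- matrix(1, 10, 10)
  pm[1, 2] <- pm[2, 1] <- pm[2, 3] <- pm[3, 2] <- 0
  rm <- matrix(0.8, 10, 10); diag(rm) <- 1
  hg <- extract_hypergraph(fdr_binarize(rm, pm))
  expect_equal(hg$cardinality, 1)
  expect_equal(sort(hg$hyperedges[[1]]), 1:3)
  expect_equal(hg$sizes, 3L)
  empty <- extract_hypergraph(fdr_binarize(rm, matrix(1, 10, 10)))
  expect_equal(empty$cardinality, 0)
  expect_length(empty$singletons, 10)
})

test_that("node degree counts each hyperedge once per node", {
  idx <- edge_index_map(4)
  hg <- structure(list(
    hyperedges = list(c(edge_id(idx, 1, 2), edge_id(idx, 2, 3))),
    sizes = 2L, singletons = setdiff(1:6, c(edge_id(idx, 1, 2),
                                            edge_id(idx, 2, 3))),
    cardinality = 1L, n_edges = 6L, index = idx), class = "hypergraph")
  deg <- node_degree(hg)
  expect_equal(unname(deg), c(1L, 1L, 1L, 0L))

  # random hypergraphs vs direct enumeration
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(5:12, 1)
    idx <- edge_index_map(n)
    n_h <- sample(1:4, 1)
    pool <- sample.int(idx$n_edges)
    sizes <- pmin(sample(2:5, n_h, TRUE), length(pool) %/% n_h)
    hyper <- list(); used <- 0
    for (h in seq_len(n_h)) {
      hyper[[h]] <- pool[(used + 1):(used + sizes[h])]
      used <- used + sizes[h]
    }
    hg <- structure(list(hyperedges = hyper, sizes = lengths(hyper),
                         singletons = setdiff(seq_len(idx$n_edges), unlist(hyper)),
                         cardinality = n_h, n_edges = idx$n_edges, index = idx),
                    class = "hypergraph")
    deg <- node_degree(hg)
    for (v in seq_len(n)) {
      expect_equal(unname(deg[v]), sum(vapply(hyper, function(ids) {
        any(idx$pairs[ids, , drop = FALSE] == v)
      }, TRUE)))
    }
  }
})

test_that("temporal shuffle preserves each row's values and is seeded", {
  set.seed(2)
  w <- matrix(rnorm(80), 8, 10)
  ets <- make_ets(w)
  sh1 <- shuffle_null(ets, seed = 5)
  sh2 <- shuffle_null(ets, seed = 5)
  sh3 <- shuffle_null(ets, seed = 6)
  expect_identical(sh1$weights, sh2$weights)
  expect_false(identical(sh1$weights, sh3$weights))
  for (e in 1:8) {
    expect_equal(sort(sh1$weights[e, ]), sort(w[e, ]))
    expect_equal(mean(sh1$weights[e, ]), mean(w[e, ]))
    expect_equal(var(sh1$weights[e, ]), var(w[e, ]))
  }
})

test_that("cumulative size distribution counts and largest-removal behave", {
  mk_hg <- function(sizes, n_edges = 100) {
    used <- 0; hyper <- list()
    for (s in sizes) { hyper <- c(hyper, list(used + seq_len(s))); used <- used + s }
    structure(list(hyperedges = hyper, sizes = as.integer(sizes),
                   singletons = seq.int(used + 1, n_edges),
                   cardinality = length(sizes), n_edges = n_edges,
                   index = NULL), class = "hypergraph")
  }
  d <- size_distribution(mk_hg(c(2, 2, 4)))
  expect_equal(d$size, c(2L, 4L))
  expect_equal(d$count_ge, c(3L, 1L))
  # one subject, one hyperedge, flag on -> empty
  d2 <- size_distribution(mk_hg(5), drop_largest_per_subject = TRUE)
  expect_equal(nrow(d2), 0)
  # pooling two subjects {2,3} and {3}
  d3 <- size_distribution(list(mk_hg(c(2, 3)), mk_hg(3)))
  expect_equal(d3$size, c(2L, 3L))
  expect_equal(d3$count_ge, c(3L, 2L))
  d4 <- size_distribution(list(mk_hg(c(2, 3)), mk_hg(3)),
                          drop_largest_per_subject = TRUE)
  expect_equal(d4$size, 2L)
  expect_equal(d4$count_ge, 1L)
})

test_that("power-law fit recovers an exact generating line", {
  s <- 2^(1:6)
  d <- data.frame(size = s, count_ge = 1e4 * s^(-2.2))
  fit <- powerlaw_fit(d)
  expect_equal(fit$power, -2.2, tolerance = 1e-9)
  expect_equal(fit$intercept, 1e4, tolerance = 1e-6)
  flat <- powerlaw_fit(data.frame(size = s, count_ge = rep(7, 6)))
  expect_equal(flat$power, 0, tolerance = 1e-12)
  expect_error(powerlaw_fit(data.frame(size = c(2, 4), count_ge = c(5, 1))),
               "3 distinct sizes")
})

test_that("power-law fit matches an independent regression on sampled data", {
  set.seed(77)
  sizes <- floor((2 - 0.999) * (1 - runif(5000))^(-1 / 1.2)) + 1
  sizes <- sizes[sizes >= 2 & sizes <= 500]
  ss <- sort(unique(sizes))
  d <- data.frame(size = ss,
                  count_ge = vapply(ss, function(s) sum(sizes >= s), 1L))
  fit <- powerlaw_fit(d)
  # oracle: closed-form least squares on the log-log pairs
  lx <- log10(d$size); ly <- log10(d$count_ge)
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  expect_equal(fit$power, slope, tolerance = 1e-12)
  expect_lt(abs(fit$power - slope), 0.15)
})
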