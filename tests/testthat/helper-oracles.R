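# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths they verify.

# connected components by breadth-first search over an explicit link list
bfs_components <- function(n_vertices, links) {
  adj <- vector("list", n_vertices)
  if (nrow(links) > 0) {
    for (r in seq_len(nrow(links))) {
      i <- links[r, 1]; j <- links[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  comp <- integer(n_vertices)
  cur <- 0L
  for (v in seq_len(n_vertices)) {
    if (comp[v] == 0L) {
      cur <- cur + 1L
      queue <- v
      comp[v] <- cur
      while (length(queue) > 0) {
        head <- queue[1]; queue <- queue[-1]
        for (nb in adj[[head]]) {
          if (comp[nb] == 0L) {
            comp[nb] <- cur
            queue <- c(queue, nb)
          }
        }
      }
    }
  }
  comp
}

# Benjamini-Hochberg step-up by exhaustive threshold enumeration
bh_reject_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  k_max <- 0L
  for (k in seq_len(m)) {
    if (p[ord[k]] <= k * alpha / m) k_max <- k
  }
  rejected <- rep(FALSE, m)
  if (k_max > 0) rejected[ord[seq_len(k_max)]] <- TRUE
  rejected
}

# Pearson correlation from the textbook sum formula
cor_sum_formula <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# OLS R^2 via the normal equations, nothing from lm()
r2_normal_equations <- function(y, x_mat) {
  x <- cbind(1, as.matrix(x_mat))
  beta <- solve(t(x) %*% x, t(x) %*% y)
  fitted <- x %*% beta
  1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
}

# small synthetic edge time-series object built directly (bypasses dfc);
# the index map covers at least nrow(weights) edges
make_ets <- function(weights, window_task = NULL) {
  e <- nrow(weights)
  n <- ceiling((1 + sqrt(1 + 8 * e)) / 2)
  if (is.null(window_task)) window_task <- rep("t", ncol(weights))
  structure(list(weights = weights, index = edge_index_map(n),
                 window_task = window_task),
            class = "edge_ts")
}

# regional series of independent noise, one run, handy for io/dfc tests
noise_ts <- function(n_time = 120, n_regions = 4, tr = 2, seed = 1) {
  set.seed(seed)
  regional_ts(matrix(rnorm(n_time * n_regions), n_time, n_regions),
              sampling_period = tr)
}
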