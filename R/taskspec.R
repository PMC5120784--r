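#' Hyperedge coherence on a window subset
#'
#' Summary of how cohesively the member edges of one hyperedge evolve over a
#' given set of windows: the mean absolute pairwise Pearson correlation over
#' all member-edge pairs, computed on those windows only. Pairs involving an
#' edge whose weights are constant on the window set contribute 0.
#'
#' @param ets an [build_edge_timeseries()] object.
#' @param edge_ids member edges of the hyperedge (>= 2).
#' @param windows integer window indices (>= 3).
#' @param statistic `"mean_abs"` (default, matching the absolute-valued
#'   hypergraph construction) or `"mean_signed"`.
#' @return The coherence statistic (scalar in [0, 1] for `"mean_abs"`).
#' @export
hyperedge_coherence <- function(ets, edge_ids, windows,
                                statistic = c("mean_abs", "mean_signed")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(ets, "edge_ts"))
  if (length(windows) < 3) stop("hyperedge_coherence: need >= 3 windows")
  if (length(edge_ids) < 2) stop("hyperedge_coherence: need >= 2 member edges")
  sub <- ets$weights[edge_ids, windows, drop = FALSE]
  r <- suppressWarnings(stats::cor(t(sub)))
  r[is.na(r)] <- 0
  vals <- r[upper.tri(r)]
  if (statistic == "mean_abs") mean(abs(vals)) else mean(vals)
}

#' Classify task-specific hyperedges
#'
#' Tests, for every non-singleton hyperedge and every task, whether the
#' hyperedge's coherence within that task's windows is significantly higher
#' than its coherence on window sets of the same size drawn at random (without
#' replacement) from all tasks pooled. The one-sided permutation p-value uses
#' the add-one estimator, so it is never exactly zero. Significance is
#' Bonferroni-corrected over the family of all tests performed for the
#' subject (cardinality x number of tasks); a hyperedge is labeled with a task
#' only if that task is the single one surviving correction, and is otherwise
#' unclassified.
#'
#' @param ets an [build_edge_timeseries()] object with >= 2 tasks, each
#'   holding >= 3 windows.
#' @param hypergraph an [extract_hypergraph()] object.
#' @param n_perm permutation draws per hyperedge-task pair (default 1000).
#' @param alpha family-wise level before correction (default 0.05).
#' @param seed integer seed for the permutation draws.
#' @param statistic passed to [hyperedge_coherence()].
#' @return Data frame with one row per non-singleton hyperedge: `hyperedge`
#'   (index into `hypergraph$hyperedges`), `label` (task or NA), and one
#'   `p_<task>` column per task. Zero rows when cardinality is 0.
#' @export
classify_task_specific <- function(ets, hypergraph, n_perm = 1000,
                                   alpha = 0.05, seed = 1L,
                                   statistic = c("mean_abs", "mean_signed")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(ets, "edge_ts"), inherits(hypergraph, "hypergraph"))
  tasks <- unique(ets$window_task)
  if (length(tasks) < 2) stop("classify_task_specific: need >= 2 tasks")
  w_all <- seq_along(ets$window_task)
  m_t <- vapply(tasks, function(t) sum(ets$window_task == t), 1L)
  if (any(m_t < 3)) {
    stop(sprintf("classify_task_specific: task '%s' has fewer than 3 windows",
                 tasks[which.min(m_t)]))
  }
  card <- hypergraph$cardinality
  res <- data.frame(hyperedge = seq_len(card), label = NA_character_,
                    stringsAsFactors = FALSE)
  for (t in tasks) res[[paste0("p_", t)]] <- NA_real_
  if (card == 0) return(res)
  set.seed(seed)
  thr <- alpha / (card * length(tasks))
  for (h in seq_len(card)) {
    ids <- hypergraph$hyperedges[[h]]
    surviving <- character(0)
    for (t in tasks) {
      obs <- hyperedge_coherence(ets, ids, w_all[ets$window_task == t],
                                 statistic = statistic)
      null <- vapply(seq_len(n_perm), function(b) {
        hyperedge_coherence(ets, ids, sample(w_all, m_t[[t]]),
                            statistic = statistic)
      }, numeric(1))
      p <- (1 + sum(null >= obs)) / (1 + n_perm)
      res[[paste0("p_", t)]][h] <- p
      if (p < thr) surviving <- c(surviving, t)
    }
    if (length(surviving) == 1) res$label[h] <- surviving
  }
  res
}
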