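#' Edge-edge correlation matrix with p-values
#'
#' Pearson correlation between every pair of edge weight time series, the raw
#' material of the hypergraph: entry (i, j) measures whether edges i and j
#' strengthen and weaken together across windows. Two-sided p-values come from
#' the usual t transform with W - 2 degrees of freedom. Edges whose weight
#' series is constant have undefined correlations; their entries are set to
#' r = 0, p = 1 so they can only become singletons.
#'
#' @param ets an [build_edge_timeseries()] object.
#' @return List with `correlations` (E x E symmetric, unit diagonal) and
#'   `p_values` (E x E symmetric; diagonal 0 but never used as a link).
#' @export
edge_edge_correlation <- function(ets) {
  stopifnot(inherits(ets, "edge_ts"))
  w <- ncol(ets$weights)
  if (w < 4) stop("edge_edge_correlation: need at least 4 windows (df = W - 2 >= 2)")
  r <- suppressWarnings(stats::cor(t(ets$weights)))
  const <- is.na(r[, 1]) | apply(ets$weights, 1, stats::sd) == 0
  r[is.na(r)] <- 0
  diag(r) <- 1
  p <- r_to_p(r, w)
  diag(p) <- 0
  if (any(const)) {
    p[const, ] <- 1
    p[, const] <- 1
    r[const, ] <- 0
    r[, const] <- 0
    diag(r) <- 1
  }
  list(correlations = r, p_values = p)
}

# two-sided p for Pearson r at n observations (t transform, df = n - 2)
r_to_p <- function(r, n) {
  rc <- pmin(pmax(r, -1), 1)
  tstat <- abs(rc) * sqrt((n - 2) / pmax(1 - rc^2, .Machine$double.eps))
  p <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  p[abs(rc) >= 1] <- 0
  p
}

#' FDR-threshold and binarize the edge-edge matrix
#'
#' Applies a false discovery rate correction (Benjamini-Hochberg by default,
#' Benjamini-Yekutieli by option) at level `alpha` to the E(E-1)/2
#' upper-triangle p-values of one subject. Pairs that survive keep their
#' correlation in the thresholded matrix; everything else is zero. The
#' binarized matrix marks exactly the surviving pairs; both significantly
#' positive and significantly negative correlations count as links. The
#' diagonal is never a link.
#'
#' @param correlations,p_values matrices from [edge_edge_correlation()].
#' @param alpha FDR level (default 0.05).
#' @param method `"BH"` (default) or `"BY"`.
#' @return An object of class `edge_edge_graph`: sparse symmetric `xi`
#'   (thresholded correlations), sparse binary `xi_binary`, `alpha`, `method`,
#'   `n_tests` and `n_edges`.
#' @export
fdr_binarize <- function(correlations, p_values, alpha = 0.05,
                         method = c("BH", "BY")) {
  method <- match.arg(method)
  e <- nrow(p_values)
  stopifnot(ncol(p_values) == e, nrow(correlations) == e)
  ut <- upper.tri(p_values)
  p <- p_values[ut]
  if (any(p < 0 | p > 1)) stop("fdr_binarize: p-values outside [0, 1]")
  keep <- if (alpha <= 0) rep(FALSE, length(p)) else
    stats::p.adjust(p, method = method) <= alpha
  sel <- which(ut, arr.ind = TRUE)[keep, , drop = FALSE]
  xi <- Matrix::sparseMatrix(i = sel[, 1], j = sel[, 2],
                             x = correlations[ut][keep],
                             dims = c(e, e), symmetric = TRUE)
  structure(list(xi = xi,
                 xi_binary = xi != 0,
                 alpha = alpha, method = method,
                 n_tests = length(p), n_edges = e),
            class = "edge_edge_graph")
}

#' Extract the hypergraph from an edge-edge graph
#'
#' Hyperedges are the connected components of the binarized edge-edge graph:
#' maximal sets of edges linked (directly or through intermediaries) by
#' significant correlations of their weight time series. Edge-vertices with no
#' links are singletons and are excluded from the non-singleton metrics. The
#' size of a hyperedge is its member-edge count; the hypergraph cardinality is
#' the number of non-singleton hyperedges.
#'
#' @param g an [fdr_binarize()] object.
#' @param index optional [edge_index_map()] carried along for node-level
#'   metrics.
#' @return An object of class `hypergraph`: list with `hyperedges` (list of
#'   integer edge-id vectors, each of size >= 2, ordered by decreasing size),
#'   `sizes`, `singletons`, `cardinality`, `n_edges`, and `index` (possibly
#'   NULL).
#' @export
extract_hypergraph <- function(g, index = NULL) {
  stopifnot(inherits(g, "edge_edge_graph"))
  e <- g$n_edges
  tm <- methods::as(g$xi, "TsparseMatrix")
  links <- cbind(tm@i + 1L, tm@j + 1L)
  links <- links[links[, 1] < links[, 2], , drop = FALSE]
  gr <- igraph::make_empty_graph(n = e, directed = FALSE)
  if (nrow(links) > 0) {
    gr <- igraph::add_edges(gr, t(links))
  }
  comp <- igraph::components(gr)
  members <- split(seq_len(e), comp$membership)
  sizes_all <- lengths(members)
  hyper <- members[sizes_all >= 2]
  singletons <- unlist(members[sizes_all == 1], use.names = FALSE)
  if (is.null(singletons)) singletons <- integer(0)
  ord <- order(-lengths(hyper), vapply(hyper, min, 1L))
  hyper <- unname(hyper[ord])
  hg <- structure(list(hyperedges = hyper, sizes = lengths(hyper),
                       singletons = sort(singletons),
                       cardinality = length(hyper),
                       n_edges = e, index = index),
                  class = "hypergraph")
  # partition invariant: every edge is in exactly one component
  stopifnot(length(hg$singletons) + sum(hg$sizes) == e)
  hg
}

#' @export
print.hypergraph <- function(x, ...) {
  cat(sprintf("<hypergraph> %d edges: cardinality %d, %d singleton(s)%s\n",
              x$n_edges, x$cardinality, length(x$singletons),
              if (x$cardinality > 0)
                sprintf(", max size %d", max(x$sizes)) else ""))
  invisible(x)
}

#' Link-sum size diagnostic
#'
#' The literal upper-triangle sum of the binarized edge-edge matrix within one
#' hyperedge, i.e. its link count. Reported as a secondary diagnostic; the
#' primary size measure is the member-edge count, which is what the size
#' distribution and the system-size ceiling E refer to.
#'
#' @param g an [fdr_binarize()] object.
#' @param edge_ids members of one hyperedge.
#' @return Number of links among the members.
#' @export
hyperedge_link_count <- function(g, edge_ids) {
  stopifnot(inherits(g, "edge_edge_graph"))
  sub <- g$xi[edge_ids, edge_ids, drop = FALSE]
  as.integer(sum(sub != 0) / 2)
}

#' Hyperedge node degree
#'
#' For every node, the number of hyperedges that contain at least one edge
#' incident to it; each hyperedge counts at most once per node. Singletons are
#' excluded.
#'
#' @param h a [extract_hypergraph()] object.
#' @param index an [edge_index_map()]; defaults to the one stored in `h`.
#' @return Integer vector of length N (named by node).
#' @export
node_degree <- function(h, index = h$index) {
  stopifnot(inherits(h, "hypergraph"))
  if (is.null(index)) stop("node_degree: no edge index map available")
  stopifnot(inherits(index, "edge_index_map"))
  deg <- integer(index$n_nodes)
  for (he in h$hyperedges) {
    if (any(he < 1 | he > index$n_edges)) {
      stop("node_degree: hyperedge contains edge id out of range")
    }
    nodes <- unique(as.vector(index$pairs[he, , drop = FALSE]))
    deg[nodes] <- deg[nodes] + 1L
  }
  names(deg) <- paste0("r", seq_len(index$n_nodes))
  deg
}

#' Temporal-shuffle null model
#'
#' Destroys temporal correspondence between edges while exactly preserving
#' each edge's weight distribution (hence mean and variance): every edge row's
#' window sequence is permuted independently and uniformly. Running the
#' hypergraph construction on shuffled data should yield only singletons.
#'
#' @param ets an [build_edge_timeseries()] object.
#' @param seed integer seed for the permutations.
#' @return An `edge_ts` with shuffled rows.
#' @export
shuffle_null <- function(ets, seed = NULL) {
  stopifnot(inherits(ets, "edge_ts"))
  w <- ncol(ets$weights)
  if (w < 2) stop("shuffle_null: need at least 2 windows")
  if (!is.null(seed)) set.seed(seed)
  shuffled <- t(apply(ets$weights, 1, function(row) row[sample.int(w)]))
  ets$weights <- shuffled
  ets
}

#' Pooled cumulative hyperedge size distribution
#'
#' For each observed size s, the number of non-singleton hyperedges of size
#' >= s, pooled over subjects. With `drop_largest_per_subject`, each subject's
#' single largest hyperedge is removed first (ties broken by the lowest
#' minimum member edge id), which strips the near-system-size hyperedge most
#' subjects carry and exposes the power-law regime of the small sizes.
#'
#' @param hypergraphs a list of [extract_hypergraph()] objects (one per
#'   subject) or a single hypergraph.
#' @param drop_largest_per_subject logical (default FALSE).
#' @return Data frame with columns `size` and `count_ge` (decreasing counts);
#'   zero rows if no hyperedges remain.
#' @export
size_distribution <- function(hypergraphs, drop_largest_per_subject = FALSE) {
  if (inherits(hypergraphs, "hypergraph")) hypergraphs <- list(hypergraphs)
  sizes <- unlist(lapply(hypergraphs, function(h) {
    stopifnot(inherits(h, "hypergraph"))
    s <- h$sizes
    if (drop_largest_per_subject && length(s) > 0) {
      big <- which(s == max(s))
      if (length(big) > 1) {
        mins <- vapply(h$hyperedges[big], min, 1L)
        big <- big[which.min(mins)]
      }
      s <- s[-big]
    }
    s
  }), use.names = FALSE)
  if (length(sizes) == 0) {
    return(data.frame(size = integer(0), count_ge = integer(0)))
  }
  ss <- sort(unique(sizes))
  data.frame(size = ss,
             count_ge = vapply(ss, function(s) sum(sizes >= s), 1L))
}

#' Power-law fit to a cumulative size distribution
#'
#' Least-squares line through log10(count >= s) against log10(s). The slope is
#' the reported "power" of the cumulative distribution; the intercept is
#' returned on the count scale (10^intercept).
#'
#' @param distribution data frame from [size_distribution()].
#' @return List with `power` (slope) and `intercept` (count at s = 1).
#' @export
powerlaw_fit <- function(distribution) {
  d <- distribution[distribution$count_ge > 0 & distribution$size > 0, ]
  if (length(unique(d$size)) < 3) {
    stop("powerlaw_fit: need at least 3 distinct sizes")
  }
  fit <- stats::lm(log10(count_ge) ~ log10(size), data = d)
  co <- stats::coef(fit)
  list(power = unname(co[2]), intercept = 10^unname(co[1]))
}
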