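#' Write a regional time series as TSV plus run manifest
#'
#' The matrix goes to a tab-separated file (rows = time points, columns =
#' regions, header row of region ids); the acquisition structure goes to a
#' YAML sidecar manifest listing, per run, the task label, volume count and
#' sampling period.
#'
#' @param series a [regional_ts()].
#' @param path output TSV path.
#' @param manifest_path sidecar path; default `<path>.manifest.yaml`.
#' @return Invisibly, the manifest path.
#' @export
write_timeseries <- function(series, path,
                             manifest_path = paste0(path, ".manifest.yaml")) {
  stopifnot(inherits(series, "regional_ts"))
  utils::write.table(series$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  manifest <- list(runs = lapply(seq_along(series$run_lengths), function(r) {
    list(task = series$task_labels[r],
         n_volumes = series$run_lengths[r],
         sampling_period = series$sampling_period[r])
  }))
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest_path)
}

#' Read a regional time series written by [write_timeseries()]
#'
#' Validates the file shape before constructing the object: ragged rows and
#' non-numeric cells are reported with their position, and the manifest's
#' total volume count must match the number of data rows.
#'
#' @param path TSV path.
#' @param manifest_path sidecar path; default `<path>.manifest.yaml`.
#' @return A [regional_ts()].
#' @export
read_timeseries <- function(path,
                            manifest_path = paste0(path, ".manifest.yaml")) {
  if (!file.exists(path)) stop(sprintf("read_timeseries: no such file '%s'", path))
  if (!file.exists(manifest_path)) {
    stop(sprintf("read_timeseries: missing manifest '%s'", manifest_path))
  }
  fields <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(fields)) > 1) {
    bad <- which(fields != fields[1])[1]
    stop(sprintf("read_timeseries: ragged file '%s': line %d has %d fields, expected %d",
                 path, bad, fields[bad], fields[1]))
  }
  raw <- utils::read.delim(path, header = TRUE, colClasses = "character",
                           check.names = FALSE)
  mat <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  if (anyNA(mat)) {
    pos <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("read_timeseries: non-numeric cell at data row %d, column '%s'",
                 pos[1], colnames(raw)[pos[2]]))
  }
  colnames(mat) <- colnames(raw)
  manifest <- yaml::read_yaml(manifest_path)
  runs <- manifest$runs
  if (is.null(runs) || length(runs) == 0) {
    stop("read_timeseries: manifest lists no runs")
  }
  n_vol <- vapply(runs, function(r) as.integer(r$n_volumes), 1L)
  if (sum(n_vol) != nrow(mat)) {
    stop(sprintf("read_timeseries: manifest totals %d volumes but file has %d rows",
                 sum(n_vol), nrow(mat)))
  }
  regional_ts(mat,
              sampling_period = vapply(runs, function(r)
                as.numeric(r$sampling_period), 1),
              run_lengths = n_vol,
              task_labels = vapply(runs, function(r) as.character(r$task), ""))
}

#' Write a measure table as CSV plus category map
#'
#' @param table a [measure_table()].
#' @param path output CSV path for the measures (covariate columns, when
#'   present, are appended with a `cov_` prefix).
#' @param category_path category-map CSV (`measure,category`); default
#'   `<path>.categories.csv`.
#' @return Invisibly, `path`.
#' @export
write_measure_table <- function(table, path,
                                category_path = paste0(path, ".categories.csv")) {
  stopifnot(inherits(table, "measure_table"))
  out <- table$data
  if (!is.null(table$covariates)) {
    cov <- table$covariates
    names(cov) <- paste0("cov_", names(cov))
    out <- cbind(out, cov)
  }
  utils::write.csv(out, path, row.names = FALSE)
  utils::write.csv(data.frame(measure = names(table$category_of),
                              category = unname(table$category_of)),
                   category_path, row.names = FALSE)
  invisible(path)
}

#' Read a measure table written by [write_measure_table()]
#'
#' @param path measures CSV path.
#' @param category_path category-map CSV path.
#' @return A [measure_table()].
#' @export
read_measure_table <- function(path,
                               category_path = paste0(path, ".categories.csv")) {
  raw <- utils::read.csv(path, check.names = FALSE)
  cmap <- utils::read.csv(category_path, stringsAsFactors = FALSE)
  category_of <- stats::setNames(cmap$category, cmap$measure)
  cov_cols <- grep("^cov_", names(raw), value = TRUE)
  covariates <- NULL
  if (length(cov_cols) > 0) {
    covariates <- raw[cov_cols]
    names(covariates) <- sub("^cov_", "", names(covariates))
  }
  measure_table(raw[setdiff(names(raw), cov_cols)], category_of, covariates)
}

#' Write hypergraph membership, metrics and node degrees as CSV
#'
#' Three tidy files per subject set: (a) hyperedge membership (`subject`,
#' `hyperedge`, `edge`, `node_i`, `node_j`), (b) per-subject metrics
#' (`subject`, `cardinality`, `max_size`, `n_singletons`, `n_edges`), (c)
#' node degrees (`subject`, `node`, `degree`). All ids are 1-based, as
#' documented in the headers.
#'
#' @param hypergraphs named list of [extract_hypergraph()] objects (names =
#'   subject ids); each must carry its edge index map.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of file paths.
#' @export
write_hypergraph_csv <- function(hypergraphs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(names(hypergraphs))) {
    names(hypergraphs) <- paste0("s", seq_along(hypergraphs))
  }
  membership <- list(); metrics <- list(); degrees <- list()
  for (s in names(hypergraphs)) {
    h <- hypergraphs[[s]]
    stopifnot(inherits(h, "hypergraph"), !is.null(h$index))
    if (h$cardinality > 0) {
      membership[[s]] <- do.call(rbind, lapply(seq_along(h$hyperedges),
        function(i) {
          ids <- h$hyperedges[[i]]
          data.frame(subject = s, hyperedge = i, edge = ids,
                     node_i = h$index$pairs[ids, 1],
                     node_j = h$index$pairs[ids, 2])
        }))
    }
    metrics[[s]] <- data.frame(
      subject = s, cardinality = h$cardinality,
      max_size = if (h$cardinality > 0) max(h$sizes) else 1L,
      n_singletons = length(h$singletons), n_edges = h$n_edges)
    deg <- node_degree(h)
    degrees[[s]] <- data.frame(subject = s, node = seq_along(deg),
                               degree = unname(deg))
  }
  paths <- file.path(dir, c("hyperedge_membership.csv",
                            "subject_metrics.csv", "node_degree.csv"))
  empty_membership <- data.frame(subject = character(0), hyperedge = integer(0),
                                 edge = integer(0), node_i = integer(0),
                                 node_j = integer(0))
  utils::write.csv(if (length(membership) > 0) do.call(rbind, membership)
                   else empty_membership,
                   paths[1], row.names = FALSE)
  utils::write.csv(do.call(rbind, metrics), paths[2], row.names = FALSE)
  utils::write.csv(do.call(rbind, degrees), paths[3], row.names = FALSE)
  invisible(paths)
}
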