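#' Read and write adjacency matrices
#'
#' Adjacencies travel as either a CSV 0/1 matrix (header row of 1-based
#' region indices) or a two-column edge-list TSV (`i<TAB>j`, 1-based; rows
#' are normalized to `i < j` on read, so an edge list in either orientation
#' round-trips).  Reading validates symmetry, binariness, and the zero
#' diagonal.
#'
#' @param path File path; format chosen by extension (`.csv` matrix,
#'   anything else edge list).
#' @param n_nodes For edge lists: total node count (isolated nodes carry no
#'   rows).  Ignored for CSV matrices.
#' @return `read_adjacency()`: a [group_adjacency()].
#' @export
read_adjacency <- function(path, n_nodes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    m <- as.matrix(utils::read.csv(path, header = TRUE, check.names = FALSE))
    storage.mode(m) <- "numeric"
    group_adjacency(m)
  } else {
    el <- utils::read.table(path, header = FALSE,
                            col.names = c("i", "j"))
    n <- if (is.null(n_nodes)) max(el$i, el$j, 0) else as.integer(n_nodes)
    a <- matrix(0, n, n)
    if (nrow(el) > 0) {
      ii <- pmin(el$i, el$j)
      jj <- pmax(el$i, el$j)
      if (any(ii == jj)) stop("edge list contains a self-loop")
      a[cbind(ii, jj)] <- 1
      a[cbind(jj, ii)] <- 1
    }
    group_adjacency(a)
  }
}

#' @rdname read_adjacency
#' @param g A `group_adjacency` or binary adjacency matrix.
#' @export
write_adjacency <- function(g, path) {
  a <- as.matrix(unclass(g))
  validate_adjacency(a)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    colnames(a) <- seq_len(ncol(a))
    utils::write.csv(a, path, row.names = FALSE)
  } else {
    ut <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
    utils::write.table(ut[order(ut[, 1], ut[, 2]), , drop = FALSE], path,
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write and read subject time series
#'
#' One TSV per subject (`T` rows x `N` columns, header = region indices)
#' plus a JSON manifest listing `subject_id`, `group`, and file name.
#'
#' @param ts_list List of `subject_ts` objects.
#' @param dir Output directory (created if needed).
#' @return `write_timeseries()`: the manifest path, invisibly;
#'   `read_timeseries()`: a list of `subject_ts`.
#' @export
write_timeseries <- function(ts_list, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(ts_list, function(ts) {
    fn <- paste0(ts$subject_id, ".tsv")
    utils::write.table(ts$data, file.path(dir, fn), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    list(subject_id = ts$subject_id, group = ts$group, file = fn)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_timeseries
#' @param manifest Path to a manifest JSON.
#' @export
read_timeseries <- function(manifest) {
  entries <- jsonlite::read_json(manifest)
  base <- dirname(manifest)
  lapply(entries, function(e) {
    m <- as.matrix(utils::read.table(file.path(base, e$file), header = TRUE,
                                     sep = "\t", check.names = FALSE))
    structure(list(subject_id = e$subject_id, group = e$group, data = m),
              class = "subject_ts")
  })
}
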