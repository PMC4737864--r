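#' Load a region table
#'
#' Reads the region metadata that fixes the node order of every graph in the
#' analysis: one row per parcellated region with its 1-based index, label,
#' hemisphere, and (optionally) target-network memberships.  With no
#' arguments it returns the built-in 90-region AAL parcellation, in which
#' odd indices are left-hemisphere and even indices right-hemisphere
#' homologues.
#'
#' @param source Path to a CSV/TSV file with columns `index`, `name`,
#'   `hemisphere` (values `"left"`/`"right"`) and optionally `networks`
#'   (semicolon-separated target-network names), or `NULL` for the built-in
#'   AAL-90 table.
#' @return A `region_table`: a data frame with columns `index`, `name`,
#'   `hemisphere` (and `networks` if supplied), validated so that indices
#'   are the contiguous range `1..N` with no duplicates.
#' @examples
#' regions <- load_regions()
#' nrow(regions)                      # 90
#' table(regions$hemisphere)          # 45 left, 45 right
#' @export
load_regions <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "aal90_regions.tsv", package = "netlesion",
                          mustWork = TRUE)
  }
  if (is.character(source)) {
    sep <- if (grepl("\\.csv$", source, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(source, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, strip.white = TRUE)
  } else if (is.data.frame(source)) {
    tab <- as.data.frame(source, stringsAsFactors = FALSE)
  } else {
    stop("'source' must be NULL, a file path, or a data frame")
  }
  as_region_table(tab)
}

#' @rdname load_regions
#' @param x A data frame with at least `index`, `name`, `hemisphere` columns.
#' @export
as_region_table <- function(x) {
  required <- c("index", "name", "hemisphere")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0)
    stop("region table is missing column(s): ", paste(missing_cols, collapse = ", "))
  x$index <- as.integer(x$index)
  dup <- unique(x$index[duplicated(x$index)])
  if (length(dup) > 0)
    stop("duplicate region index: ", paste(dup, collapse = ", "))
  n <- nrow(x)
  gap <- setdiff(seq_len(n), x$index)
  if (length(gap) > 0)
    stop("region indices must form the contiguous range 1..", n,
         "; missing: ", paste(gap, collapse = ", "))
  bad_hemi <- x$hemisphere[!x$hemisphere %in% c("left", "right")]
  if (length(bad_hemi) > 0)
    stop("unknown hemisphere label (expected 'left' or 'right'): ",
         paste(unique(bad_hemi), collapse = ", "),
         " at row ", which(!x$hemisphere %in% c("left", "right"))[1])
  x <- x[order(x$index), , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("region_table", "data.frame")
  x
}

#' Load target-network definitions
#'
#' Reads a YAML (or JSON) mapping of target-network name to a list of
#' 1-based region indices.  The built-in configuration carries the standard
#' lobe groupings, the default-mode network (both the in-text definition,
#' the default under name `"DMN"`, and the published table's variant
#' `"DMN_table1"`), limbic and central (striatal/thalamic) structures, and
#' the hippocampal and striatal building blocks used for edge lesioning.
#'
#' @param path Path to a YAML/JSON config, or `NULL` for the built-in sets.
#' @return A named list of integer vectors.
#' @export
load_target_networks <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "target_networks.yaml", package = "netlesion",
                        mustWork = TRUE)
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(cfg) || is.null(names(cfg)) || any(names(cfg) == ""))
    stop("target-network config must be a named mapping of name -> indices")
  lapply(cfg, function(v) as.integer(v))
}

#' Look up a target network as a node set
#'
#' @param name Name of a configured target network (e.g. `"DMN"`,
#'   `"frontal_lobe"`, `"limbic"`).
#' @param table A `region_table` (defaults to the built-in AAL-90 table).
#' @param config Named list of index vectors, as returned by
#'   [load_target_networks()].
#' @return A `node_set`: a list with elements `name` and `indices`.
#' @examples
#' target_network("limbic")$indices   # 37..42
#' @export
target_network <- function(name, table = load_regions(),
                           config = load_target_networks()) {
  if (!name %in% names(config))
    stop("unknown target network '", name, "'; available: ",
         paste(sort(names(config)), collapse = ", "))
  idx <- sort(unique(config[[name]]))
  if (name == "insula_cingulate_table1")
    warning("'insula_cingulate_table1' reproduces a published row that ",
            "prints the same indices as the DMN row; it is most likely a ",
            "typesetting error in the source table", call. = FALSE)
  node_set(name, idx, table)
}

#' Construct a node set over a region table
#'
#' @param name Label for the set.
#' @param indices Integer vector of 1-based region indices.
#' @param table A `region_table` the indices must belong to.
#' @return A `node_set` (list with `name`, `indices`).
#' @export
node_set <- function(name, indices, table = load_regions()) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) == 0)
    stop("node set '", name, "' is empty")
  bad <- setdiff(indices, table$index)
  if (length(bad) > 0)
    stop("node set '", name, "' has indices outside the region table: ",
         paste(bad, collapse = ", "))
  structure(list(name = name, indices = indices), class = "node_set")
}

#' @export
print.node_set <- function(x, ...) {
  cat("<node_set> ", x$name, ": ", length(x$indices), " regions {",
      paste(x$indices, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Hemisphere node sets
#'
#' Returns all regions of one hemisphere as a node set.  Under the built-in
#' AAL-90 ordering odd indices are left and even indices right; a custom
#' region table can override the mapping.
#'
#' @param side `"left"` or `"right"`.
#' @param table A `region_table`.
#' @return A `node_set` of the hemisphere's region indices.
#' @export
hemisphere_nodes <- function(side = c("left", "right"), table = load_regions()) {
  side <- match.arg(side)
  node_set(paste0(side, "_hemisphere"), table$index[table$hemisphere == side],
           table)
}
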