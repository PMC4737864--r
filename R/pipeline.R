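#' Run the full lesion-analysis pipeline
#'
#' End-to-end driver: for each group, build (or load) the binary group
#' graph, then compute the graph summary, the single-node lesion sweep with
#' its degree-vs-loss regression, the target-network lesion table, the
#' edge-set lesion table (within-DMN, left-right hippocampal,
#' hippocampus-DMN, frontal-striatum), and the hemispheric lesion report.
#' All tables are written as TSV, summaries as JSON, and a run manifest
#' records the configuration and seed so every number is reproducible from
#' the config alone.
#'
#' @param config A named list (or path to a YAML/JSON file) with elements:
#'   `input` — either `list(preset_groups = list(young = "young-like",
#'   old = "old-like"), n_subjects =, n_timepoints =)` for synthetic input,
#'   or `list(manifests = c(young = "path/manifest.json", ...))` for
#'   time-series on disk; `alpha` (default 0.05); `edge_sign` (`"both"` /
#'   `"positive"`); `mode` (`"isolate"` / `"remove"`); `seed`; `out_dir`;
#'   optional `regions` and `networks` paths overriding the built-in
#'   region table and target-network config.
#' @param quiet Suppress per-stage log lines.
#' @return Invisibly, a named list per group with elements `graph`,
#'   `summary`, `sweep`, `regression`, `targets`, `edge_lesions`,
#'   `hemisphere`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  alpha <- config$alpha %||% 0.05
  edge_sign <- config$edge_sign %||% "both"
  mode <- config$mode %||% "isolate"
  seed <- as.integer(config$seed %||% 1)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  regions <- load_regions(config$regions)
  networks <- load_target_networks(config$networks)
  log_stage <- function(...) if (!quiet) message("[netlesion] ", ...)

  groups <- pipeline_inputs(config, seed, log_stage)
  results <- list()
  for (gname in names(groups)) {
    ts_list <- groups[[gname]]
    log_stage(gname, ": ", length(ts_list), " subjects x ",
              nrow(ts_list[[1]]$data), " timepoints x ",
              ncol(ts_list[[1]]$data), " regions")
    g <- build_group_graph(ts_list, alpha = alpha, edge_sign = edge_sign,
                           group = gname)
    summ <- graph_summary(g)
    log_stage(gname, ": graph built, ", summ$n_edges, " edges (alpha = ",
              alpha, ", m = ", attr(g, "m"), ")")
    write_adjacency(g, file.path(out_dir, paste0(gname, "_adjacency.csv")))
    write_adjacency(g, file.path(out_dir, paste0(gname, "_edges.tsv")))

    res <- list(graph = g, summary = summ)
    res$global_efficiency <- global_efficiency(g)
    ok <- res$global_efficiency > 0
    if (!ok)
      log_stage(gname, ": baseline efficiency is zero; lesion stages skipped")
    if (ok) {
      res$sweep <- single_node_sweep(g, mode = mode, regions = regions)
      utils::write.table(res$sweep,
                         file.path(out_dir, paste0(gname, "_sweep.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      res$regression <- tryCatch(degree_loss_regression(res$sweep),
                                 error = function(e) NULL)
      tnames <- intersect(c("DMN", "frontal_lobe", "temporal_lobe",
                            "occipital_lobe", "parietal_lobe",
                            "central", "limbic"), names(networks))
      targets <- lapply(tnames, function(nm)
        node_set(nm, networks[[nm]], regions))
      res$targets <- lesion_target_networks(g, targets, mode = mode)
      utils::write.table(res$targets,
                         file.path(out_dir, paste0(gname, "_targets.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      res$edge_lesions <- edge_lesion_table(g, networks, regions)
      utils::write.table(res$edge_lesions,
                         file.path(out_dir,
                                   paste0(gname, "_edge_lesions.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      res$hemisphere <- lesion_hemisphere(g, regions, mode = mode)
      log_stage(gname, sprintf(
        ": Sigma = %.4f, mean single-node loss = %.2f%%, hemi loss L/R = %.2f%%/%.2f%%",
        res$global_efficiency, 100 * attr(res$sweep, "mean_loss"),
        100 * res$hemisphere$left$loss, 100 * res$hemisphere$right$loss))
    }
    jsonlite::write_json(
      list(group = gname, alpha = alpha, m = attr(g, "m"),
           n_edges = summ$n_edges, mean_degree = summ$mean_degree,
           global_efficiency = res$global_efficiency,
           mean_loss = if (ok) attr(res$sweep, "mean_loss") else NA,
           hemisphere = if (ok) list(left = res$hemisphere$left$loss,
                                     right = res$hemisphere$right$loss,
                                     asymmetry = res$hemisphere$asymmetry)
                        else NULL),
      file.path(out_dir, paste0(gname, "_summary.json")),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    results[[gname]] <- res
  }
  jsonlite::write_json(
    list(seed = seed, alpha = alpha, edge_sign = edge_sign, mode = mode,
         groups = names(groups),
         version = as.character(utils::packageVersion("netlesion")),
         config_hash = config_hash(config)),
    file.path(out_dir, "run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  # small deterministic digest; avoids a hashing dependency
  sum(utf8ToInt(as.character(s)) * (seq_along(utf8ToInt(as.character(s))) %% 97 + 1)) %% 1e9
}

pipeline_inputs <- function(config, seed, log_stage) {
  input <- config$input %||% stop("config$input is required")
  if (!is.null(input$manifests)) {
    manifests <- input$manifests
    missing <- manifests[!file.exists(unlist(manifests))]
    if (length(missing) > 0)
      stop("manifest not found: ", paste(unlist(missing), collapse = ", "))
    out <- lapply(manifests, read_timeseries)
    names(out) <- names(manifests)
    return(out)
  }
  presets <- input$preset_groups %||%
    stop("config$input needs either $manifests or $preset_groups")
  n_subjects <- input$n_subjects %||% 20
  n_timepoints <- input$n_timepoints %||% 150
  out <- list()
  for (i in seq_along(presets)) {
    gname <- names(presets)[i]
    log_stage("simulating '", gname, "' from preset ", presets[[i]])
    truth <- group_preset(presets[[i]])
    out[[gname]] <- simulate_group_timeseries(
      n_subjects, n_timepoints, truth, group = gname, seed = seed + i)
  }
  out
}

# The standard edge-set lesions: internal DMN edges, left vs right
# hippocampal/parahippocampal edges, hippocampus-DMN edges, and
# frontal-striatum edges.
edge_lesion_table <- function(g, networks = load_target_networks(),
                              regions = load_regions()) {
  ns <- function(nm) node_set(nm, networks[[nm]], regions)
  specs <- list(
    list(label = "DMN-DMN", a = ns("DMN"), b = ns("DMN")),
    list(label = "HC-HC", a = ns("HC_left"), b = ns("HC_right")),
    list(label = "HC-DMN", a = ns("HC"), b = ns("DMN")),
    list(label = "frontal-striatum", a = ns("frontal_lobe"),
         b = ns("striatum")))
  rows <- lapply(specs, function(sp) {
    r <- lesion_edges_between(g, sp$a, sp$b)
    data.frame(disconnection = sp$label, n_edges_removed = r$n_removed,
               loss = r$loss, loss_pct = round(100 * r$loss, 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
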