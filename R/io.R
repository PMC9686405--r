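# Input/output: CSV tables, JSON documents, GraphML/DOT graph exports.
# All JSON artifacts embed the seed and a hash of the configuration so a
# run can be matched to its outputs.

#' Read a person-by-item response table
#'
#' Expects a header row; reserved columns `sample`, `age`, `gender` are
#' carried along as covariates, every other column must be binary 0/1 and
#' is treated as an item whose scale is the part of its name before the
#' final underscore.
#'
#' @param path CSV file.
#' @param key optional named key vector (+1/-1) per item.
#' @return list with `items` (an [item_matrix()]) and `covariates` (data
#'   frame, possibly empty).
#' @export
read_items <- function(path, key = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df) || !ncol(df)) stop("empty table: ", path)
  if (anyDuplicated(names(df))) stop("duplicate column names in ", path)
  reserved <- intersect(names(df), c("sample", "age", "gender"))
  icols <- setdiff(names(df), reserved)
  for (cn in icols) {
    bad <- which(!(df[[cn]] %in% c(0, 1)))
    if (length(bad)) {
      stop(sprintf("non-binary entry %s in item column '%s', row %d",
                   format(df[[cn]][bad[1]]), cn, bad[1]))
    }
  }
  list(items = item_matrix(df[, icols, drop = FALSE], key = key),
       covariates = df[, reserved, drop = FALSE])
}

#' Read a person-by-variable scale score table
#'
#' @param path CSV file with a header row.
#' @return list with `data` (numeric data frame) and `roles` (from
#'   [infer_roles()]).
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df) || !ncol(df)) stop("empty table: ", path)
  if (anyDuplicated(names(df))) stop("duplicate column names in ", path)
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop("all columns must be numeric in ", path)
  }
  list(data = df, roles = infer_roles(names(df)))
}

#' Write a table as CSV (UTF-8, header row, no row names)
#' @param x data frame
#' @param path output file
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @keywords internal
fmt_num <- function(x) signif(x, 9)

#' Stable hash of a configuration (FNV-1a over its JSON serialization)
#' @keywords internal
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write a generating model as a JSON document
#' @param model a [pf_model()]
#' @param path output file
#' @export
write_model_json <- function(model, path) {
  obj <- unclass(model)
  obj$spectra_map <- unclass(obj$spectra_map)
  obj <- lapply(obj, function(x) if (is.numeric(x)) fmt_num(x) else x)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a proxy scale (selected items, keys, loadings) as JSON
#' @param proxy a `p_proxy`
#' @param path output file
#' @param seed seed to record
#' @export
write_proxy_json <- function(proxy, path, seed = NA_integer_) {
  obj <- list(selected_items = proxy$selected_items,
              item_keys = as.list(proxy$item_keys),
              loadings = as.list(fmt_num(proxy$loadings)),
              excluded_scale = proxy$excluded_scale,
              seed = seed)
  if (!is.null(proxy$solution)) {
    obj$fit <- list(chi_square = fmt_num(proxy$solution$chi_square),
                    df = proxy$solution$df,
                    converged = proxy$solution$converged,
                    iterations = proxy$solution$iterations)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a comparison report as JSON
#' @param report a `pf_comparison`
#' @param path output file
#' @param seed seed to record
#' @export
write_report_json <- function(report, path, seed = NA_integer_) {
  models <- lapply(report$models, function(m) {
    list(within = m$within, cross = m$cross,
         cross_pairs = if (nrow(m$cross_pairs))
           paste(m$cross_pairs$a, m$cross_pairs$b, sep = "-")
         else character(0),
         named_links = as.list(m$named_links),
         p_adjacency = m$p_adjacency,
         edges = nrow(graph_edges(m$fit$graph)))
  })
  obj <- list(models = models,
              cross_link_delta = report$cross_link_delta,
              verdict = report$verdict,
              agreement = lapply(report$agreement, fmt_num),
              seed = seed,
              config = unclass(report$config),
              config_hash = config_hash(report$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export a mixed graph as GraphML
#'
#' Endpoint marks are stored as edge attributes `mark_a` and `mark_b`
#' (relative to the `a` and `b` endpoints), the edge reliability as
#' `reliability`, node roles as a node attribute.
#'
#' @param graph a `mixed_graph` or `bccd` fit
#' @param path output file
#' @export
write_graphml <- function(graph, path) {
  if (inherits(graph, "bccd")) graph <- graph$graph
  e <- graph_edges(graph)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  w('  <key id="role" for="node" attr.name="role" attr.type="string"/>')
  w('  <key id="mark_a" for="edge" attr.name="mark_a" attr.type="string"/>')
  w('  <key id="mark_b" for="edge" attr.name="mark_b" attr.type="string"/>')
  w('  <key id="reliability" for="edge" attr.name="reliability" attr.type="double"/>')
  w('  <graph id="G" edgedefault="undirected">')
  for (i in seq_len(nrow(graph$nodes))) {
    w('    <node id="%s"><data key="role">%s</data></node>',
      graph$nodes$name[i], graph$nodes$role[i])
  }
  if (nrow(e)) {
    for (i in seq_len(nrow(e))) {
      w(paste0('    <edge source="%s" target="%s">',
               '<data key="mark_a">%s</data>',
               '<data key="mark_b">%s</data>',
               '<data key="reliability">%s</data></edge>'),
        e$a[i], e$b[i], e$mark_a[i], e$mark_b[i],
        format(fmt_num(e$reliability[i])))
    }
  }
  w('  </graph>')
  w('</graphml>')
  invisible(path)
}

#' Export a mixed graph in Graphviz DOT format
#'
#' Undirected layout; the reliability is the edge label and the marks are
#' written into the arrowtail/arrowhead attributes (circle marks become
#' `odot`, arrows `normal`, tails `none`).
#'
#' @param graph a `mixed_graph` or `bccd` fit
#' @param path output file
#' @export
write_dot <- function(graph, path) {
  if (inherits(graph, "bccd")) graph <- graph$graph
  e <- graph_edges(graph)
  arrow <- c(none = "none", circle = "odot", arrow = "normal", tail = "none")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("graph pfnet {", con)
  for (i in seq_len(nrow(graph$nodes))) {
    writeLines(sprintf('  "%s" [role="%s"];', graph$nodes$name[i],
                       graph$nodes$role[i]), con)
  }
  if (nrow(e)) {
    for (i in seq_len(nrow(e))) {
      writeLines(sprintf(
        '  "%s" -- "%s" [label="%.3f", arrowtail=%s, arrowhead=%s];',
        e$a[i], e$b[i], e$reliability[i], arrow[e$mark_a[i]],
        arrow[e$mark_b[i]]), con)
    }
  }
  writeLines("}", con)
  invisible(path)
}
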