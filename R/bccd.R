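#' Bayesian constraint-based causal discovery
#'
#' Fits a mixed causal graph to a table of scale scores. Columns are
#' standardized; conditional-independence statements are scored with
#' Bayesian reliabilities (BGe model averaging over small subsets, with a
#' Bayes-factor fallback for larger conditioning sets); the skeleton is
#' built by processing independence constraints in order of reliability
#' ([learn_skeleton()]); endpoint marks are oriented with collider and
#' FCI-style propagation rules under exogeneity constraints for context
#' variables ([orient_edges()]). The result is a graph whose edges carry
#' the probability that the direct interaction exists, tolerating latent
#' confounders of the observed variables.
#'
#' @param data numeric data frame of scale scores (persons as rows).
#' @param roles named character vector with entries in `system`, `proxy`,
#'   `higher_order`, `context`; inferred from column names when `NULL`
#'   (see [infer_roles()]).
#' @param config a [bccd_config()].
#' @param reliability_fun optional oracle replacing the scored reliability
#'   (see [learn_skeleton()]).
#' @return an object of class `bccd`: list with `graph` (the oriented
#'   `mixed_graph`), `config`, `n`, `call`.
#' @examples
#' sim <- simulate(pf_model("bifactor"), nsim = 400, seed = 1)
#' fit <- bccd(sim$scales[, c("RC1", "RC2", "RC6", "RC8")],
#'             config = bccd_config(max_subset_size = 4))
#' fit
#' @export
bccd <- function(data, roles = NULL, config = bccd_config(),
                 reliability_fun = NULL) {
  data <- as.data.frame(data)
  if (!all(vapply(data, is.numeric, logical(1)))) {
    stop("all columns must be numeric")
  }
  sk <- learn_skeleton(data, config = config, roles = roles,
                       reliability_fun = reliability_fun)
  g <- orient_edges(sk, config = config)
  structure(list(graph = g, config = config, n = nrow(data),
                 call = match.call()), class = "bccd")
}

#' @export
print.bccd <- function(x, ...) {
  e <- graph_edges(x$graph)
  cat(sprintf("BCCD fit: %d nodes, %d edges (n = %s)\n",
              nrow(x$graph$nodes), nrow(e), format(x$n)))
  cat(sprintf("  statements scored: %d, edges deleted: %d, conflicts: %d\n",
              x$graph$log$n_statements, x$graph$log$n_deleted,
              length(x$graph$log$conflicts)))
  invisible(x)
}

#' @export
summary.bccd <- function(object, ...) {
  e <- graph_edges(object$graph)
  e <- e[order(-e$reliability), ]
  structure(list(edges = e, nodes = object$graph$nodes,
                 log = object$graph$log), class = "summary.bccd")
}

#' @export
print.summary.bccd <- function(x, ...) {
  cat("Nodes:\n")
  for (role in unique(x$nodes$role)) {
    cat(sprintf("  %-12s %s\n", role,
                paste(x$nodes$name[x$nodes$role == role], collapse = ", ")))
  }
  cat("Edges (by reliability):\n")
  if (nrow(x$edges)) {
    sym <- function(m) c(none = "", circle = "o", arrow = "<", tail = "-")[m]
    for (r in seq_len(nrow(x$edges))) {
      cat(sprintf("  %s %s-%s %s  %.3f\n", x$edges$a[r],
                  sym(x$edges$mark_a[r]),
                  chartr("<", ">", sym(x$edges$mark_b[r])), x$edges$b[r],
                  x$edges$reliability[r]))
    }
  } else cat("  (none)\n")
  invisible(x)
}

#' @export
plot.bccd <- function(x, vertex.size = 28, ...) {
  e <- graph_edges(x$graph)
  g <- igraph::graph_from_data_frame(
    e[, c("a", "b")], directed = FALSE,
    vertices = x$graph$nodes[, "name", drop = FALSE])
  role <- x$graph$nodes$role
  cols <- c(system = "lightsteelblue", proxy = "gold",
            higher_order = "darkseagreen", context = "grey80")
  igraph::plot.igraph(
    g, vertex.color = cols[role], vertex.size = vertex.size,
    edge.label = sprintf("%.2f", e$reliability),
    edge.width = 1 + 3 * e$reliability, ...)
  invisible(x)
}
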