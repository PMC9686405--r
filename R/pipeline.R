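# Study pipeline: the five model configurations, cross-spectrum link
# accounting, p-factor attachment and the bifactor-vs-hierarchical verdict.

#' Specification of one model configuration
#'
#' The five configurations compare how the network of scale scores changes
#' as p-factor proxies and higher-order scores enter the model:
#' M1 eight subfactor scales (no RCd, no proxy); M2 adds the p-factor proxy
#' built without demoralization items; M3 as M2 plus RCd; M4 the eight
#' scales with the full-pool proxy (with demoralization items); M5 nine
#' scales, the three higher-order scores and the p-factor proxy.
#'
#' @param id one of `"M1"`..`"M5"`.
#' @param include_context include the `sample` context indicator (default
#'   `TRUE`, mirroring joint causal inference over the pooled samples).
#' @param include_covariates include `age` and `gender` (default `FALSE`).
#' @return a `model_spec`: list with `id`, `variables`, `proxy_variant`.
#' @export
model_spec <- function(id = c("M1", "M2", "M3", "M4", "M5"),
                       include_context = TRUE, include_covariates = FALSE) {
  id <- match.arg(id)
  rc8 <- setdiff(rc_scales(), "RCd")
  base <- switch(id,
    M1 = list(vars = rc8, proxy = "none"),
    M2 = list(vars = c(rc8, "p_factor"), proxy = "p_factor"),
    M3 = list(vars = c(rc_scales(), "p_factor"), proxy = "p_factor"),
    M4 = list(vars = c(rc8, "p_factor_rcd"), proxy = "p_factor_rcd"),
    M5 = list(vars = c(rc_scales(), "EID", "THD", "BXD", "p_factor"),
              proxy = "p_factor"))
  vars <- base$vars
  if (include_context) vars <- c(vars, "sample")
  if (include_covariates) vars <- c(vars, "age", "gender")
  structure(list(id = id, variables = vars, proxy_variant = base$proxy),
            class = "model_spec")
}

#' Assemble the analysis table for the pipeline
#'
#' Takes a simulated sample (or an item matrix plus scale scores), extracts
#' both p-factor proxies from the item pool — `p_factor` from the pool
#' without RCd items, `p_factor_rcd` from the full pool — and returns the
#' scale scores augmented with the proxy columns.
#'
#' @param sim a `pf_sim` from [simulate.pf_model()], or a list with
#'   elements `items` (an [item_matrix()]) and `scales` (data frame).
#' @param k proxy length.
#' @param proxy_score `"sum"` for raw keyed sums over the selected items
#'   (default), `"regression"` for Thomson regression factor scores over
#'   the whole pool.
#' @return list with `data` (scale scores + proxies), `proxies` (the two
#'   `p_proxy` objects), `roles`.
#' @export
prepare_study_data <- function(sim, k = 21L,
                               proxy_score = c("sum", "regression")) {
  proxy_score <- match.arg(proxy_score)
  if (inherits(sim, "pf_sim")) {
    icols <- sim$truth$item_ids
    im <- item_matrix(sim$items[, icols], sim$truth$item_scale_map,
                      sim$truth$item_key)
    scl <- sim$scales
  } else {
    im <- sim$items
    scl <- sim$scales
  }
  px <- extract_p_proxy(im, k = k, excluded_scale = "RCd")
  px_rcd <- extract_p_proxy(im, k = k, excluded_scale = NULL)
  scl$p_factor <- if (proxy_score == "sum") px$scores else px$regression_scores
  scl$p_factor_rcd <- if (proxy_score == "sum") px_rcd$scores
                      else px_rcd$regression_scores
  list(data = scl, proxies = list(p_factor = px, p_factor_rcd = px_rcd),
       roles = infer_roles(names(scl)))
}

#' Run one model configuration
#'
#' Subsets the analysis table to the model's variables and runs [bccd()].
#'
#' @param data data frame holding at least the model's variables.
#' @param spec a [model_spec()] (or a model id string).
#' @param config a [bccd_config()].
#' @return a `bccd` fit; the model spec is attached as `$model_spec`.
#' @export
run_model <- function(data, spec, config = bccd_config()) {
  if (is.character(spec)) spec <- model_spec(spec)
  miss <- setdiff(spec$variables, names(data))
  if (length(miss)) stop("missing variable(s): ", paste(miss, collapse = ", "))
  fit <- bccd(data[, spec$variables, drop = FALSE], config = config)
  fit$model_spec <- spec
  fit
}

#' Count within- and cross-spectrum edges among system scales
#'
#' An edge between two system scales is a cross-link when the scales share
#' no spectrum, counting both primary and secondary assignments (RC3's
#' secondary thought-disorder membership makes RC3--RC8 a within-cluster
#' edge). Edges involving proxy, higher-order or context nodes are counted
#' in neither bin.
#'
#' @param graph a `mixed_graph` or `bccd` fit.
#' @param map a `spectra_map`.
#' @return list with `within`, `cross`, `cross_pairs` (data frame),
#'   `within_pairs`.
#' @export
cross_cluster_edges <- function(graph, map = default_spectra_map()) {
  if (inherits(graph, "bccd")) graph <- graph$graph
  e <- graph_edges(graph)
  roles <- stats::setNames(graph$nodes$role, graph$nodes$name)
  sys <- e[roles[e$a] == "system" & roles[e$b] == "system", , drop = FALSE]
  unmapped <- setdiff(unique(c(sys$a, sys$b)), names(map$primary))
  if (length(unmapped)) {
    stop("system scale(s) missing from the spectra map: ",
         paste(unmapped, collapse = ", "))
  }
  if (nrow(sys)) {
    is_within <- mapply(function(a, b) shares_spectrum(map, a, b),
                        sys$a, sys$b)
  } else is_within <- logical(0)
  list(within = sum(is_within), cross = sum(!is_within),
       cross_pairs = sys[!is_within, c("a", "b"), drop = FALSE],
       within_pairs = sys[is_within, c("a", "b"), drop = FALSE])
}

#' Nodes adjacent to the p-factor proxy
#'
#' @param graph a `mixed_graph` or `bccd` fit containing exactly one node
#'   with role `proxy`.
#' @return character vector of neighbor names.
#' @export
p_adjacency <- function(graph) {
  if (inherits(graph, "bccd")) graph <- graph$graph
  px <- graph$nodes$name[graph$nodes$role == "proxy"]
  if (length(px) != 1) {
    stop("graph must contain exactly one proxy node, found ", length(px))
  }
  vars <- graph$nodes$name
  vars[graph$marks[match(px, vars), ] != 0L]
}

#' Bifactor-vs-hierarchical verdict from the proxy's attachments
#'
#' In a bifactor world the general factor touches the subfactor scales
#' directly, so its proxy should attach at the scale level and not to the
#' higher-order scores; in a hierarchical world the proxy should attach
#' only at the higher-order level.
#'
#' @param graph a `mixed_graph` or `bccd` fit with one proxy node and at
#'   least one higher-order node.
#' @return `"bifactor"` (proxy adjacent to at least one system scale and to
#'   no higher-order node), `"hierarchical"` (adjacent only to higher-order
#'   nodes), or `"indeterminate"`.
#' @export
classify_bifactor <- function(graph) {
  if (inherits(graph, "bccd")) graph <- graph$graph
  roles <- stats::setNames(graph$nodes$role, graph$nodes$name)
  if (!any(roles == "higher_order")) {
    stop("graph contains no higher-order node")
  }
  adj <- p_adjacency(graph)
  n_sys <- sum(roles[adj] == "system")
  n_ho <- sum(roles[adj] == "higher_order")
  if (n_sys >= 1 && n_ho == 0) "bifactor"
  else if (n_sys == 0 && n_ho >= 1) "hierarchical"
  else "indeterminate"
}

#' Run the five model configurations and compare them
#'
#' Runs M1-M5 (or a subset) on the analysis table, counts within- and
#' cross-spectrum links per model, tracks the three focal cross-links
#' RC1--RC2, RC7--RC6 and RC7--RC2, records the proxy's adjacency set per
#' model, computes the cross-link change from M1 to M2, and the
#' bifactor-vs-hierarchical verdict from M5. Optionally the runs are
#' repeated on the clinical and normative halves and with age and gender
#' added, reporting pairwise skeleton agreement among system scales.
#'
#' @param data analysis table from [prepare_study_data()].
#' @param config a [bccd_config()].
#' @param models character vector of model ids to run.
#' @param map a `spectra_map`.
#' @param robustness also run per-subsample and with covariates, reporting
#'   skeleton agreement (slower; default `FALSE`).
#' @param include_context passed to [model_spec()].
#' @return a `pf_comparison` object.
#' @export
run_all_models <- function(data, config = bccd_config(),
                           models = paste0("M", 1:5),
                           map = default_spectra_map(),
                           robustness = FALSE, include_context = TRUE) {
  named_pairs <- list(c("RC1", "RC2"), c("RC7", "RC6"), c("RC7", "RC2"))
  res <- list()
  for (id in models) {
    spec <- model_spec(id, include_context = include_context)
    fit <- run_model(data, spec, config)
    cc <- cross_cluster_edges(fit, map)
    vars <- fit$graph$nodes$name
    named <- vapply(named_pairs, function(pr) {
      if (!all(pr %in% vars)) return(NA)
      fit$graph$marks[match(pr[1], vars), match(pr[2], vars)] != 0L
    }, logical(1))
    names(named) <- vapply(named_pairs, paste, character(1), collapse = "-")
    res[[id]] <- list(
      fit = fit, within = cc$within, cross = cc$cross,
      cross_pairs = cc$cross_pairs, named_links = named,
      p_adjacency = if (spec$proxy_variant != "none") p_adjacency(fit)
                    else character(0))
  }
  delta <- if (all(c("M1", "M2") %in% models))
    res$M1$cross - res$M2$cross else NA_integer_
  verdict <- if ("M5" %in% models) classify_bifactor(res$M5$fit)
             else NA_character_

  agreement <- NULL
  if (robustness) {
    sys_agree <- function(fit_a, fit_b) {
      common <- intersect(fit_a$graph$nodes$name[
                            fit_a$graph$nodes$role == "system"],
                          fit_b$graph$nodes$name[
                            fit_b$graph$nodes$role == "system"])
      prs <- utils::combn(common, 2)
      same <- vapply(seq_len(ncol(prs)), function(k) {
        a <- prs[1, k]; b <- prs[2, k]
        ea <- fit_a$graph$marks[match(a, fit_a$graph$nodes$name),
                                match(b, fit_a$graph$nodes$name)] != 0L
        eb <- fit_b$graph$marks[match(a, fit_b$graph$nodes$name),
                                match(b, fit_b$graph$nodes$name)] != 0L
        ea == eb
      }, logical(1))
      mean(same)
    }
    base_id <- if ("M2" %in% models) "M2" else models[1]
    spec_cov <- model_spec(base_id, include_context = include_context,
                           include_covariates = TRUE)
    fit_cov <- run_model(data, spec_cov, config)
    agreement <- list(covariates = sys_agree(res[[base_id]]$fit, fit_cov))
    if ("sample" %in% names(data)) {
      for (grp in c(clinical = 1, normative = 0)) {
        sub <- data[data$sample == grp,
                    setdiff(names(data), "sample"), drop = FALSE]
        spec_sub <- model_spec(base_id, include_context = FALSE)
        fit_sub <- run_model(sub, spec_sub, config)
        agreement[[names(which(c(clinical = 1, normative = 0) == grp))]] <-
          sys_agree(res[[base_id]]$fit, fit_sub)
      }
    }
  }

  structure(list(models = res, cross_link_delta = delta, verdict = verdict,
                 agreement = agreement, config = config),
            class = "pf_comparison")
}

#' @export
print.pf_comparison <- function(x, ...) {
  cat("Model comparison:\n")
  cat(sprintf("  %-3s %7s %6s  %s\n", "id", "within", "cross",
              "named links present"))
  for (id in names(x$models)) {
    m <- x$models[[id]]
    nl <- m$named_links[!is.na(m$named_links)]
    cat(sprintf("  %-3s %7d %6d  %s\n", id, m$within, m$cross,
                if (length(nl)) paste(names(nl)[nl], collapse = ", ")
                else "-"))
  }
  if (!is.na(x$cross_link_delta)) {
    cat(sprintf("Cross-link change M1 -> M2: %d fewer cross-spectrum edges\n",
                x$cross_link_delta))
  }
  if (!is.na(x$verdict)) cat("M5 verdict:", x$verdict, "\n")
  if (!is.null(x$agreement)) {
    cat("Skeleton agreement (system scales):",
        paste(sprintf("%s %.2f", names(x$agreement),
                      unlist(x$agreement)), collapse = ", "), "\n")
  }
  invisible(x)
}
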