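#' Learn the skeleton of the causal graph
#'
#' Starts from the complete graph over the data columns. For conditioning
#' set sizes 0 up to `max_cond_size`, every still-adjacent pair is tested
#' against every conditioning set drawn from its current neighborhoods, and
#' the reliability of each independence statement is computed (see
#' [independence_reliability()]). Edges whose pair reaches a reliability
#' above the threshold are removed between levels (stable variant: removals
#' apply after a level finishes). All independence statements above the
#' threshold are then sorted by reliability (descending, ties broken
#' lexicographically) and processed in order: the first statement that
#' removes a pair defines its separating set and absence reliability.
#' Surviving edges carry `1 - max` independence reliability found for the
#' pair; every endpoint mark is a circle.
#'
#' @param data numeric data frame or matrix.
#' @param config a [bccd_config()].
#' @param roles named character vector of variable roles (inferred from
#'   names when `NULL`).
#' @param reliability_fun optional replacement for the scored reliability:
#'   a `function(x, y, z)` returning a probability, e.g. a d-separation
#'   oracle. Used for oracle-based validation.
#' @return a `mixed_graph`: list with `nodes` (data frame of `name`,
#'   `role`), `marks` (matrix; entry `[i, j]` is the mark at j on edge i--j:
#'   0 none, 1 circle, 2 arrow, 3 tail), `edge_reliability`,
#'   `absence_reliability`, `sepsets` (named list `"a|b"`), `statements`
#'   (data frame), and `log`.
#' @export
learn_skeleton <- function(data, config = bccd_config(), roles = NULL,
                           reliability_fun = NULL) {
  X <- as.data.frame(data)
  vars <- names(X)
  p <- length(vars)
  stopifnot(p >= 2)
  if (is.null(roles)) roles <- infer_roles(vars)
  roles <- roles[vars]

  if (is.null(reliability_fun)) {
    eng <- make_reliability_engine(X, config)
    relfun <- function(i, j, zidx) eng$reliability(i, j, zidx)
    n_obs <- eng$n
  } else {
    relfun <- function(i, j, zidx) {
      list(rel = reliability_fun(vars[i], vars[j], vars[zidx]),
           source = "oracle")
    }
    n_obs <- NA_integer_
  }

  adj <- matrix(TRUE, p, p); diag(adj) <- FALSE
  sx <- character(0); sy <- character(0); szs <- character(0)
  srel <- numeric(0); ssrc <- character(0)
  seen <- new.env(parent = emptyenv())
  n_skipped <- 0L

  for (l in 0:config$max_cond_size) {
    pairs <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    if (!nrow(pairs)) break
    ord <- order(pairs[, 1], pairs[, 2])
    pairs <- pairs[ord, , drop = FALSE]
    to_remove <- matrix(integer(0), 0, 2)
    any_cand <- FALSE
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      nbi <- setdiff(which(adj[i, ]), j)
      nbj <- setdiff(which(adj[j, ]), i)
      cands <- c(subsets_of(nbi, l), if (l > 0) subsets_of(nbj, l))
      if (!length(cands)) next
      any_cand <- TRUE
      keys <- vapply(cands, function(z) paste(sort(z), collapse = ","),
                     character(1))
      cands <- cands[!duplicated(keys)]
      keys <- keys[!duplicated(keys)]
      for (ci in seq_along(cands)) {
        z <- sort(as.integer(cands[[ci]]))
        pkey <- paste(i, j, keys[ci], sep = "|")
        if (!is.null(seen[[pkey]])) next
        seen[[pkey]] <- TRUE
        res <- relfun(i, j, z)
        if (res$source == "skipped" || is.na(res$rel)) {
          n_skipped <- n_skipped + 1L
          next
        }
        sx <- c(sx, vars[i]); sy <- c(sy, vars[j])
        szs <- c(szs, paste(vars[z], collapse = ","))
        srel <- c(srel, res$rel); ssrc <- c(ssrc, res$source)
        if (res$rel > config$reliability_threshold) {
          to_remove <- rbind(to_remove, c(i, j))
        }
      }
    }
    if (nrow(to_remove)) {
      for (r in seq_len(nrow(to_remove))) {
        adj[to_remove[r, 1], to_remove[r, 2]] <- FALSE
        adj[to_remove[r, 2], to_remove[r, 1]] <- FALSE
      }
    }
    if (!any_cand) break
  }

  statements <- data.frame(x = sx, y = sy, z = szs, reliability = srel,
                           source = ssrc, stringsAsFactors = FALSE)

  # reliability-ordered constraint processing
  marks <- matrix(0L, p, p, dimnames = list(vars, vars))
  marks[upper.tri(marks) | lower.tri(marks)] <- 1L
  edge_rel <- matrix(1, p, p, dimnames = list(vars, vars))
  diag(edge_rel) <- 0
  absence <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  sepsets <- list()
  deletions <- 0L

  if (nrow(statements)) {
    indep <- statements[statements$reliability > config$reliability_threshold, ,
                        drop = FALSE]
    if (nrow(indep)) {
      o <- order(-indep$reliability, indep$x, indep$y, indep$z)
      indep <- indep[o, , drop = FALSE]
      for (r in seq_len(nrow(indep))) {
        i <- match(indep$x[r], vars); j <- match(indep$y[r], vars)
        if (marks[i, j] != 0L) {
          marks[i, j] <- marks[j, i] <- 0L
          key <- pair_key(indep$x[r], indep$y[r])
          sepsets[[key]] <- if (nzchar(indep$z[r]))
            strsplit(indep$z[r], ",", fixed = TRUE)[[1]] else character(0)
          absence[i, j] <- absence[j, i] <- indep$reliability[r]
          deletions <- deletions + 1L
        }
      }
    }
    for (r in seq_len(nrow(statements))) {
      i <- match(statements$x[r], vars); j <- match(statements$y[r], vars)
      edge_rel[i, j] <- edge_rel[j, i] <-
        min(edge_rel[i, j], 1 - statements$reliability[r])
    }
  }

  structure(list(
    nodes = data.frame(name = vars, role = unname(roles),
                       stringsAsFactors = FALSE),
    marks = marks,
    edge_reliability = edge_rel,
    absence_reliability = absence,
    sepsets = sepsets,
    statements = statements,
    log = list(n = n_obs, n_statements = nrow(statements),
               n_deleted = deletions, n_skipped = n_skipped,
               conflicts = character(0))
  ), class = "mixed_graph")
}

#' @keywords internal
pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

#' All size-l subsets of an index vector (safe for length-1 vectors)
#' @keywords internal
subsets_of <- function(v, l) {
  if (l == 0) return(list(integer(0)))
  if (length(v) < l) return(list())
  if (length(v) == l) return(list(as.integer(v)))
  asplit(utils::combn(as.integer(v), l), 2)
}

#' Edges of a mixed graph as a data frame
#'
#' @param graph a `mixed_graph` (or [bccd()] fit).
#' @return data frame with columns `a`, `b`, `mark_a`, `mark_b`,
#'   `reliability`.
#' @export
graph_edges <- function(graph) {
  if (inherits(graph, "bccd")) graph <- graph$graph
  M <- graph$marks
  vars <- graph$nodes$name
  idx <- which(upper.tri(M) & M != 0L, arr.ind = TRUE)
  mark_chr <- c("none", "circle", "arrow", "tail")
  data.frame(
    a = vars[idx[, 1]], b = vars[idx[, 2]],
    mark_a = mark_chr[M[cbind(idx[, 2], idx[, 1])] + 1L],
    mark_b = mark_chr[M[cbind(idx[, 1], idx[, 2])] + 1L],
    reliability = graph$edge_reliability[idx],
    stringsAsFactors = FALSE)
}

#' @export
print.mixed_graph <- function(x, ...) {
  e <- graph_edges(x)
  cat(sprintf("Mixed graph: %d nodes, %d edges\n", nrow(x$nodes), nrow(e)))
  invisible(x)
}
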