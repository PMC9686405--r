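# Endpoint-mark orientation: unshielded colliders by separating set, then
# FCI propagation rules R1-R4, under exogeneity constraints for context
# variables (no arrowhead may point into a context node; their endpoint
# marks are tails). Mark codes: 0 none, 1 circle, 2 arrow, 3 tail.

#' Orient the endpoint marks of a learned skeleton
#'
#' Unshielded triples x -- w -- y with x, y non-adjacent are oriented as
#' colliders (arrowheads at w) when w is not in the separating set of
#' (x, y); triples are processed in decreasing order of the reliability of
#' the separating statement, and an existing arrow or tail is never
#' overwritten (the lower-reliability orientation is skipped and the
#' conflict logged). The propagation rules R1-R4 are then applied to a
#' fixpoint. Throughout, endpoints at context nodes are forced to tails and
#' arrowheads into context nodes are refused.
#'
#' @param graph a `mixed_graph` from [learn_skeleton()].
#' @param sepsets separating sets (default: those stored in `graph`).
#' @param config a [bccd_config()].
#' @return the graph with oriented marks; `graph$colliders` holds the
#'   oriented unshielded colliders as a data frame `(x, w, y)`.
#' @export
orient_edges <- function(graph, sepsets = graph$sepsets,
                         config = bccd_config()) {
  M <- graph$marks
  vars <- graph$nodes$name
  roles <- stats::setNames(graph$nodes$role, vars)
  conflicts <- character(0)

  # set the mark at `at` on the edge other--at; returns updated matrix
  set_mark <- function(M, other, at, mark, why) {
    i <- match(other, vars); j <- match(at, vars)
    cur <- M[i, j]
    if (cur == 0L) return(M)  # edge vanished (defensive)
    if (mark == 2L && roles[[at]] == "context") {
      conflicts <<- c(conflicts,
                      sprintf("refused arrowhead into context node %s (%s)",
                              at, why))
      return(M)
    }
    if (cur %in% c(2L, 3L) && cur != mark) {
      conflicts <<- c(conflicts,
                      sprintf("conflict at %s on edge %s-%s: %s kept over %s (%s)",
                              at, other, at,
                              c("none", "circle", "arrow", "tail")[cur + 1L],
                              c("none", "circle", "arrow", "tail")[mark + 1L],
                              why))
      return(M)
    }
    M[i, j] <- mark
    M
  }

  adjacent <- function(a, b) M[match(a, vars), match(b, vars)] != 0L
  neighbors <- function(a) vars[M[match(a, vars), ] != 0L]

  # JCI exogeneity: tails at context endpoints
  for (cv in vars[roles == "context"]) {
    for (nb in neighbors(cv)) M <- set_mark(M, nb, cv, 3L, "context tail")
  }

  # unshielded colliders, most reliable separating statement first
  triples <- list()
  for (w in vars) {
    nb <- neighbors(w)
    if (length(nb) < 2) next
    for (cmb in asplit(utils::combn(nb, 2), 2)) {
      x <- cmb[1]; y <- cmb[2]
      if (adjacent(x, y)) next
      key <- pair_key(x, y)
      if (is.null(sepsets[[key]])) next
      if (w %in% sepsets[[key]]) next
      rel <- graph$absence_reliability[match(x, vars), match(y, vars)]
      triples[[length(triples) + 1L]] <-
        list(x = x, w = w, y = y, rel = if (is.na(rel)) 0 else rel)
    }
  }
  colliders <- data.frame(x = character(0), w = character(0),
                          y = character(0), stringsAsFactors = FALSE)
  if (length(triples)) {
    ord <- order(-vapply(triples, `[[`, numeric(1), "rel"),
                 vapply(triples, `[[`, character(1), "x"),
                 vapply(triples, `[[`, character(1), "w"),
                 vapply(triples, `[[`, character(1), "y"))
    for (t in triples[ord]) {
      if (roles[[t$w]] == "context") {
        conflicts <- c(conflicts,
                       sprintf("collider at context node %s skipped", t$w))
        next
      }
      M <- set_mark(M, t$x, t$w, 2L, "collider")
      M <- set_mark(M, t$y, t$w, 2L, "collider")
      colliders <- rbind(colliders,
                         data.frame(x = t$x, w = t$w, y = t$y,
                                    stringsAsFactors = FALSE))
    }
  }

  mark_at <- function(a, b) M[match(a, vars), match(b, vars)]  # mark at b

  # R1-R4 to fixpoint
  repeat {
    changed <- FALSE
    before <- M
    for (b in vars) {
      for (a in neighbors(b)) {
        # R1: a *-> b o-* c, a and c non-adjacent  =>  b -> c
        if (mark_at(a, b) == 2L) {
          for (cc in setdiff(neighbors(b), a)) {
            if (!adjacent(a, cc) && mark_at(cc, b) == 1L) {
              M <- set_mark(M, cc, b, 3L, "R1")
              M <- set_mark(M, b, cc, 2L, "R1")
            }
          }
        }
        # R2: a -> b *-> c or a *-> b -> c, with a *-o c  =>  a *-> c
        for (cc in setdiff(neighbors(b), a)) {
          if (!adjacent(a, cc)) next
          if (mark_at(a, cc) != 1L) next
          chain1 <- mark_at(a, b) == 2L && mark_at(b, a) == 3L &&
            mark_at(b, cc) == 2L
          chain2 <- mark_at(a, b) == 2L && mark_at(b, cc) == 2L &&
            mark_at(cc, b) == 3L
          if (chain1 || chain2) M <- set_mark(M, a, cc, 2L, "R2")
        }
      }
    }
    # R3: a *-> b <-* c, a o-* d *-o c (a, c non-adjacent), d *-o b  =>  d *-> b
    for (b in vars) {
      nb <- neighbors(b)
      into_b <- nb[vapply(nb, function(u) mark_at(u, b) == 2L, logical(1))]
      if (length(into_b) < 2) next
      for (cmb in asplit(utils::combn(into_b, 2), 2)) {
        a <- cmb[1]; cc <- cmb[2]
        if (adjacent(a, cc)) next
        for (d in setdiff(intersect(neighbors(a), neighbors(cc)), b)) {
          if (mark_at(a, d) == 1L && mark_at(cc, d) == 1L &&
              adjacent(d, b) && mark_at(d, b) == 1L) {
            M <- set_mark(M, d, b, 2L, "R3")
          }
        }
      }
    }
    # R4: discriminating paths
    M <- apply_r4(M, vars, roles, sepsets, set_mark, mark_at, neighbors,
                  adjacent)
    if (identical(M, before)) break else changed <- TRUE
  }

  graph$marks <- M
  graph$colliders <- colliders
  graph$log$conflicts <- c(graph$log$conflicts, conflicts)
  graph
}

# R4: for a discriminating path <d, q1, ..., qk, b, c> (every q a collider
# on the path and a parent of c, d not adjacent to c): if b is in
# sepset(d, c) orient b -> c, else orient the triple around b as a
# double-arrow collider.
#' @keywords internal
apply_r4 <- function(M, vars, roles, sepsets, set_mark, mark_at, neighbors,
                     adjacent) {
  parent_of <- function(u, v) mark_at(v, u) == 3L && mark_at(u, v) == 2L
  for (cc in vars) {
    for (b in neighbors(cc)) {
      if (mark_at(b, cc) != 1L && mark_at(cc, b) != 1L) {
        # b o-* c or b *-o c needed for the rule to add information
        if (mark_at(b, cc) != 1L) next
      }
      # grow collider paths towards b over parents of cc
      starts <- Filter(function(q) parent_of(q, cc) &&
                         adjacent(q, b) && mark_at(q, b) != 0L,
                       setdiff(neighbors(cc), b))
      for (q1 in starts) {
        # path so far: q1 (adjacent to b); extend backwards to find d
        stack <- list(list(path = c(q1)))
        while (length(stack)) {
          cur <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          tailnode <- cur$path[length(cur$path)]
          for (d in setdiff(neighbors(tailnode), c(cur$path, b, cc))) {
            if (mark_at(d, tailnode) != 2L) next  # needs arrow into collider
            if (!adjacent(d, cc)) {
              key <- pair_key(d, cc)
              if (!is.null(sepsets[[key]])) {
                if (b %in% sepsets[[key]]) {
                  M <- set_mark(M, cc, b, 3L, "R4")
                  M <- set_mark(M, b, cc, 2L, "R4")
                } else {
                  q_last <- cur$path[1]
                  M <- set_mark(M, q_last, b, 2L, "R4")
                  M <- set_mark(M, cc, b, 2L, "R4")
                  M <- set_mark(M, b, cc, 2L, "R4")
                }
              }
            } else if (parent_of(d, cc) && mark_at(cur$path[length(cur$path)], d) == 2L) {
              stack[[length(stack) + 1L]] <- list(path = c(cur$path, d))
            }
          }
        }
      }
    }
  }
  M
}
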