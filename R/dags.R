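# Enumeration of labeled DAGs on small node sets, with cached d-separation
# patterns. DAGs are stored compactly as an integer matrix of parent-set
# bitmasks: row = DAG, column j = bitmask of the parents of node j.

.pfnet_cache <- new.env(parent = emptyenv())

#' Enumerate all labeled DAGs on m nodes
#'
#' Every orientation assignment over the m(m-1)/2 node pairs (absent, ->,
#' <-) is generated and filtered for acyclicity. Counts follow the
#' classical sequence 1, 3, 25, 543, 29281 for m = 1..5.
#'
#' @param m number of nodes (1 to 5).
#' @return integer matrix with one row per DAG and one column per node,
#'   holding the parent set of that node as a bitmask (bit j-1 = node j).
#' @examples
#' nrow(enumerate_dags(3))  # 25
#' @export
enumerate_dags <- function(m) {
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m > 5 || m != round(m)) {
    stop("m must be an integer between 1 and 5")
  }
  m <- as.integer(m)
  key <- paste0("dags", m)
  if (!is.null(.pfnet_cache[[key]])) return(.pfnet_cache[[key]])
  if (m == 1L) {
    out <- matrix(0L, 1, 1)
  } else {
    prs <- utils::combn(m, 2)
    np <- ncol(prs)
    states <- as.matrix(expand.grid(rep(list(0:2), np)))
    nc <- nrow(states)
    pa <- matrix(0L, nc, m)
    for (k in seq_len(np)) {
      i <- prs[1, k]; j <- prs[2, k]
      s <- states[, k]
      pa[s == 1L, j] <- bitwOr(pa[s == 1L, j], bitwShiftL(1L, i - 1L))
      pa[s == 2L, i] <- bitwOr(pa[s == 2L, i], bitwShiftL(1L, j - 1L))
    }
    acyclic <- vapply(seq_len(nc), function(r) is_acyclic_masks(pa[r, ]),
                      logical(1))
    out <- pa[acyclic, , drop = FALSE]
  }
  .pfnet_cache[[key]] <- out
  out
}

#' @keywords internal
is_acyclic_masks <- function(pa) {
  m <- length(pa)
  alive <- bitwShiftL(1L, m) - 1L       # bitmask of remaining nodes
  repeat {
    removed <- FALSE
    for (j in seq_len(m)) {
      bj <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(alive, bj) == 0L) next
      if (bitwAnd(pa[j], alive) == 0L) {  # no remaining parents
        alive <- bitwAnd(alive, bitwNot(bj))
        removed <- TRUE
      }
    }
    if (alive == 0L) return(TRUE)
    if (!removed) return(FALSE)
  }
}

#' d-separation for a bitmask-encoded DAG
#' @keywords internal
dsep_masks <- function(pa, ix, iy, zmask) {
  m <- length(pa)
  bits <- bitwShiftL(1L, seq_len(m) - 1L)
  # ancestors of {x,y} union z
  anc <- bitwOr(bitwOr(bits[ix], bits[iy]), zmask)
  repeat {
    newanc <- anc
    for (j in seq_len(m)) {
      if (bitwAnd(anc, bits[j]) != 0L) newanc <- bitwOr(newanc, pa[j])
    }
    if (newanc == anc) break
    anc <- newanc
  }
  # moral graph over ancestors as adjacency bitmasks
  adj <- integer(m)
  for (j in seq_len(m)) {
    if (bitwAnd(anc, bits[j]) == 0L) next
    paj <- bitwAnd(pa[j], anc)
    adj[j] <- bitwOr(adj[j], paj)
    for (i in seq_len(m)) {
      if (bitwAnd(paj, bits[i]) != 0L) {
        adj[i] <- bitwOr(adj[i], bits[j])              # child link
        adj[i] <- bitwOr(adj[i], bitwAnd(paj, bitwNot(bits[i])))  # marry
      }
    }
  }
  # reachability from x avoiding z
  blocked <- zmask
  reach <- bits[ix]
  frontier <- bits[ix]
  while (frontier != 0L) {
    nxt <- 0L
    for (j in seq_len(m)) {
      if (bitwAnd(frontier, bits[j]) != 0L) nxt <- bitwOr(nxt, adj[j])
    }
    nxt <- bitwAnd(nxt, bitwNot(bitwOr(reach, blocked)))
    if (bitwAnd(nxt, bits[iy]) != 0L) return(FALSE)
    reach <- bitwOr(reach, nxt)
    frontier <- nxt
  }
  TRUE
}

#' Cached d-separation pattern over all enumerated DAGs on m nodes
#'
#' @return logical vector, one entry per DAG of [enumerate_dags()], TRUE
#'   where node `ix` is d-separated from `iy` given the nodes in `zmask`.
#' @keywords internal
dsep_pattern <- function(m, ix, iy, zmask) {
  key <- sprintf("pat%d_%d_%d_%d", m, min(ix, iy), max(ix, iy), zmask)
  pat <- .pfnet_cache[[key]]
  if (is.null(pat)) {
    dags <- enumerate_dags(m)
    pat <- vapply(seq_len(nrow(dags)), function(r)
      dsep_masks(dags[r, ], ix, iy, zmask), logical(1))
    .pfnet_cache[[key]] <- pat
  }
  pat
}
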