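#' d-separation on a DAG
#'
#' Tests whether `x` and `y` are d-separated given the set `z` in a directed
#' acyclic graph. The test uses the classical reduction: restrict to the
#' ancestors of `{x, y} union z`, moralize, delete `z`, and check whether
#' `x` and `y` are disconnected. For a [pf_model()] the DAG is the
#' generating graph over context variables, the general factor, the spectrum
#' factors and the scale composites, so the function is an exact oracle for
#' the conditional independences the generating model implies (the causal
#' Markov and faithfulness assumptions made by constraint-based discovery).
#'
#' @param model a [pf_model()] or a 0/1 adjacency matrix with dimnames
#'   (entry `[i, j] = 1` meaning i -> j).
#' @param x,y node names, distinct and not in `z`.
#' @param z character vector of conditioning node names (may be empty).
#' @return `TRUE` if every path between `x` and `y` is blocked given `z`.
#' @examples
#' m <- pf_model("bifactor")
#' d_separated(m, "RC1", "RC4", character(0))  # FALSE: G connects them
#' d_separated(m, "RC1", "RC4", "G")           # TRUE: sole shared parent
#' @export
d_separated <- function(model, x, y, z = character(0)) {
  A <- if (inherits(model, "pf_model")) model_dag(model) else as.matrix(model)
  nodes <- rownames(A)
  miss <- setdiff(c(x, y, z), nodes)
  if (length(miss)) stop("unknown node name: ", paste(miss, collapse = ", "))
  if (x == y) stop("x and y must be distinct")
  if (x %in% z || y %in% z) stop("x and y must not be part of z")
  dsep_amat(A, match(x, nodes), match(y, nodes), match(z, nodes))
}

#' Workhorse d-separation on an adjacency matrix by node index
#' @keywords internal
dsep_amat <- function(A, ix, iy, iz) {
  p <- nrow(A)
  # ancestors of {x, y} union z (including themselves)
  anc <- rep(FALSE, p)
  anc[c(ix, iy, iz)] <- TRUE
  repeat {
    newanc <- anc | (A %*% anc > 0)  # parents of current set
    if (all(newanc == anc)) break
    anc <- as.logical(newanc)
  }
  keep <- which(anc)
  Ak <- A[keep, keep, drop = FALSE]
  # moralize: undirected adjacency + marry parents of common children
  U <- (Ak + t(Ak)) > 0
  for (ch in seq_along(keep)) {
    pa <- which(Ak[, ch] > 0)
    if (length(pa) > 1) U[pa, pa] <- TRUE
  }
  diag(U) <- FALSE
  # delete z, test connectivity x -- y
  zk <- match(iz, keep)
  xk <- match(ix, keep)
  yk <- match(iy, keep)
  ok <- setdiff(seq_along(keep), zk)
  reach <- rep(FALSE, length(keep))
  reach[xk] <- TRUE
  frontier <- xk
  while (length(frontier)) {
    nb <- which(colSums(U[frontier, , drop = FALSE]) > 0)
    nb <- setdiff(intersect(nb, ok), which(reach))
    if (yk %in% nb) return(FALSE)
    reach[nb] <- TRUE
    frontier <- nb
  }
  !reach[yk]
}
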