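# Independent oracles used across the test files. These deliberately use
# different algorithms from the package internals (path enumeration instead
# of moralization, Wright path tracing instead of loading algebra) so that
# agreement is informative.

# all simple paths between x and y in a DAG given as adjacency matrix
enumerate_paths <- function(A, x, y) {
  U <- (A + t(A)) > 0
  n <- nrow(A)
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == y) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (nb in which(U[last, ])) {
      if (!(nb %in% path)) walk(c(path, nb))
    }
  }
  walk(x)
  paths
}

# descendant bitmap
descendants_of <- function(A, v) {
  out <- rep(FALSE, nrow(A))
  frontier <- v
  while (length(frontier)) {
    ch <- which(colSums(A[frontier, , drop = FALSE] > 0) > 0)
    ch <- setdiff(ch, which(out))
    out[ch] <- TRUE
    frontier <- ch
  }
  out
}

# brute-force d-separation: every path must be blocked given z
dsep_brute <- function(A, x, y, z) {
  for (path in enumerate_paths(A, x, y)) {
    blocked <- FALSE
    if (length(path) > 2) {
      for (k in 2:(length(path) - 1)) {
        a <- path[k - 1]; b <- path[k]; cc <- path[k + 1]
        collider <- A[a, b] > 0 && A[cc, b] > 0
        if (collider) {
          desc <- which(descendants_of(A, b)) # descendants of b
          if (!(b %in% z) && !any(desc %in% z)) { blocked <- TRUE; break }
        } else {
          if (b %in% z) { blocked <- TRUE; break }
        }
      }
    }
    if (!blocked) return(FALSE)
  }
  TRUE
}

# Wright path tracing for the generating SEM: full linear system over
# (G, spectrum factors, composites); returns the composite covariance
path_tracing_cov <- function(model) {
  stopifnot(model$context_effect == 0)
  sps <- pfnet::spectrum_names()
  scales <- model$scales
  nodes <- c("G", sps, scales)
  B <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))  # B[child, parent]
  resid <- stats::setNames(rep(1, length(nodes)), nodes)
  prim <- model$spectra_map$primary
  if (model$kind == "hierarchical") {
    for (sp in sps) {
      g <- model$hierarchy_loading[[sp]]
      B[sp, "G"] <- g
      resid[sp] <- 1 - g^2
    }
  }
  for (s in scales) {
    cl <- model$cross_loadings
    cx <- cl[cl$scale == s, , drop = FALSE]
    if (model$kind == "bifactor") {
      B[s, "G"] <- model$general_loading[[s]]
      B[s, prim[[s]]] <- B[s, prim[[s]]] + model$specific_loading[[s]]
      tot <- model$general_loading[[s]]^2 + model$specific_loading[[s]]^2
    } else {
      B[s, prim[[s]]] <- B[s, prim[[s]]] + model$scale_loading[[s]]
      tot <- model$scale_loading[[s]]^2
    }
    if (nrow(cx)) {
      for (i in seq_len(nrow(cx))) {
        B[s, cx$spectrum[i]] <- B[s, cx$spectrum[i]] + cx$loading[i]
      }
      tot <- tot + sum(cx$loading^2)
    }
    resid[s] <- 1 - tot
  }
  # residuals of scales with several correlated parents: recompute from the
  # factor-subsystem covariance so the composite variance is exactly one
  fac <- c("G", sps)
  IBf <- solve(diag(length(fac)) - B[fac, fac])
  Sf <- IBf %*% diag(resid[fac]) %*% t(IBf)
  for (s in scales) {
    resid[s] <- 1 - drop(B[s, fac] %*% Sf %*% B[s, fac])
  }
  IB <- solve(diag(length(nodes)) - B)
  S <- IB %*% diag(resid) %*% t(IB)
  dimnames(S) <- list(nodes, nodes)
  S[scales, scales]
}

# true skeleton of a fully observed DAG: adjacency iff no subset separates
true_skeleton <- function(A) {
  p <- nrow(A)
  S <- matrix(FALSE, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    rest <- setdiff(seq_len(p), c(i, j))
    sep <- FALSE
    for (l in 0:length(rest)) {
      zs <- if (l == 0) list(integer(0)) else
        if (length(rest) == l) list(rest) else
          asplit(utils::combn(rest, l), 2)
      for (z in zs) {
        if (dsep_brute(A, i, j, as.integer(z))) { sep <- TRUE; break }
      }
      if (sep) break
    }
    S[i, j] <- S[j, i] <- !sep
  }
  S
}

# v-structures (unshielded colliders) of a DAG
v_structures <- function(A) {
  p <- nrow(A)
  out <- matrix(integer(0), 0, 3)
  for (w in seq_len(p)) {
    pa <- which(A[, w] > 0)
    if (length(pa) < 2) next
    for (cmb in asplit(utils::combn(pa, 2), 2)) {
      x <- cmb[1]; y <- cmb[2]
      if (A[x, y] == 0 && A[y, x] == 0) {
        out <- rbind(out, c(min(x, y), w, max(x, y)))
      }
    }
  }
  out
}

# small standard fixtures
toy_items <- function() {
  # 3 persons x 6 items over scales A (4 items) and B (2 items), mixed keys
  V <- rbind(c(1, 0, 1, 1, 0, 1),
             c(0, 0, 0, 1, 1, 1),
             c(1, 1, 1, 1, 1, 0))
  colnames(V) <- c("A_1", "A_2", "A_3", "A_4", "B_1", "B_2")
  key <- c(A_1 = 1L, A_2 = -1L, A_3 = 1L, A_4 = 1L, B_1 = 1L, B_2 = -1L)
  item_matrix(V, key = key)
}

small_config <- function(...) bccd_config(max_subset_size = 4, ...)
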