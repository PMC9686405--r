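#' Configuration of the causal discovery engine
#'
#' @param max_subset_size largest variable subset scored by exhaustive BGe
#'   model averaging (statements on larger subsets fall back to a
#'   Bayes-factor test on the partial correlation). Between 3 and 5.
#' @param max_cond_size largest conditioning set searched during skeleton
#'   construction.
#' @param reliability_threshold posterior probability above which an
#'   independence statement removes an edge (0.5 = maximum-posterior
#'   decision; must be in [0.5, 1)).
#' @param alpha_mu prior precision scalar of the normal-Wishart prior. The
#'   Wishart degrees of freedom are fixed at subset size + 2 and the prior
#'   scale matrix at the identity.
#' @param seed integer recorded with the run.
#' @return list of class `bccd_config`.
#' @export
bccd_config <- function(max_subset_size = 5L, max_cond_size = 4L,
                        reliability_threshold = 0.5, alpha_mu = 1,
                        seed = 1L) {
  stopifnot(max_subset_size >= 3, max_subset_size <= 5,
            reliability_threshold >= 0.5, reliability_threshold < 1,
            max_cond_size >= 0)
  structure(list(max_subset_size = as.integer(max_subset_size),
                 max_cond_size = as.integer(max_cond_size),
                 reliability_threshold = reliability_threshold,
                 alpha_mu = alpha_mu, seed = as.integer(seed)),
            class = "bccd_config")
}

# internal evaluator shared by independence_reliability and learn_skeleton;
# st holds precomputed data statistics and caches
make_reliability_engine <- function(data, config) {
  X <- as.matrix(data)
  vars <- colnames(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ", paste(vars[sds == 0], collapse = ", "))
  }
  Xs <- scale(X)
  n <- nrow(Xs)
  Cor <- stats::cor(Xs)
  post_cache <- new.env(parent = emptyenv())

  subset_posterior <- function(idx) {   # idx sorted variable indices
    key <- paste(idx, collapse = ",")
    got <- post_cache[[key]]
    if (!is.null(got)) return(got)
    suff <- subset_suffstats(Xs, idx)
    out <- tryCatch(bge_dag_posterior(suff, config$alpha_mu),
                    error = function(e) NULL)
    post_cache[[key]] <- out
    out
  }

  reliability <- function(ix, iy, iz) {
    s <- length(iz) + 2L
    if (s <= config$max_subset_size) {
      idx <- sort(c(ix, iy, iz))
      post <- subset_posterior(idx)
      if (is.null(post)) {
        return(list(rel = 0, source = "singular"))
      }
      px <- match(ix, idx); py <- match(iy, idx)
      zmask <- sum(bitwShiftL(1L, match(iz, idx) - 1L))
      pat <- dsep_pattern(length(idx), px, py, as.integer(zmask))
      list(rel = sum(post$weights[pat]), source = "bge_averaged")
    } else if (length(iz) <= config$max_cond_size) {
      v <- c(ix, iy, iz)
      P <- tryCatch(solve(Cor[v, v, drop = FALSE]), error = function(e) NULL)
      if (is.null(P)) return(list(rel = 0, source = "singular"))
      r <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
      if (1 - r^2 <= 1e-12) return(list(rel = 0, source = "bic_bayes_factor"))
      Lam <- -n * log(1 - r^2)
      list(rel = stats::plogis((log(n) - Lam) / 2),
           source = "bic_bayes_factor")
    } else {
      list(rel = NA_real_, source = "skipped")
    }
  }

  list(vars = vars, n = n, cor = Cor, X = Xs, reliability = reliability)
}

#' Posterior reliability of a conditional independence statement
#'
#' Computes the probability that `x` is independent of `y` given `z`. When
#' the subset `{x, y} union z` has at most `max_subset_size` variables, all
#' DAGs on the subset are enumerated, scored with the BGe marginal
#' likelihood, and the reliability is the posterior mass (uniform prior
#' over DAGs) of the structures in which `x` is d-separated from `y` given
#' `z`. For larger subsets a Bayes-factor approximation based on the sample
#' partial correlation `r` is used: `Lambda = -n log(1 - r^2)`,
#' `BF(indep : dep) = exp((log n - Lambda)/2)`, reliability
#' `BF / (1 + BF)`. Conditioning sets larger than `max_cond_size` are
#' skipped (reliability `NA`, source `"skipped"`). The reliability of the
#' complementary dependence statement is one minus the returned value.
#'
#' @param x,y distinct variable names.
#' @param z character vector of conditioning variable names.
#' @param data numeric data frame or matrix (columns are standardized
#'   internally).
#' @param config a [bccd_config()].
#' @return a `causal_statement`: list with `x`, `y`, `z`, `reliability`,
#'   `source`.
#' @export
independence_reliability <- function(x, y, z = character(0), data,
                                     config = bccd_config()) {
  eng <- make_reliability_engine(data, config)
  miss <- setdiff(c(x, y, z), eng$vars)
  if (length(miss)) stop("unknown variable: ", paste(miss, collapse = ", "))
  if (x == y || x %in% z || y %in% z) {
    stop("x, y and z must be disjoint")
  }
  r <- eng$reliability(match(x, eng$vars), match(y, eng$vars),
                       match(z, eng$vars))
  structure(list(x = x, y = y, z = z, reliability = r$rel,
                 source = r$source), class = "causal_statement")
}

#' @export
print.causal_statement <- function(x, ...) {
  cat(sprintf("P( %s _||_ %s | {%s} ) = %.4f  [%s]\n", x$x, x$y,
              paste(x$z, collapse = ", "), x$reliability, x$source))
  invisible(x)
}
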