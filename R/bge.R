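# BGe scoring: Gaussian marginal likelihoods under a normal-Wishart prior.
#
# The score of a DAG decomposes into ratios of set marginals,
#   score(DAG) = sum_j  g(fam_j) - g(pa_j),
# where g(W) is the log marginal likelihood of the data restricted to the
# variable set W. Because equivalent DAGs differ by covered edge reversals
# and those leave the telescoped sum unchanged, the score is constant on
# Markov equivalence classes. Hyperparameters follow common practice: prior
# mean 0 (columns are standardized), prior precision scalar alpha_mu = 1,
# Wishart degrees of freedom alpha_w = k + 2 for a k-variable subset, and
# identity prior scale matrix; the degrees of freedom of an l-dimensional
# marginal are alpha_w - k + l so that marginals are consistent.

#' Sufficient statistics of a variable subset
#'
#' @param X standardized data matrix.
#' @param vars column indices or names.
#' @return list with `n`, `mean`, `scatter` (centered cross-product).
#' @keywords internal
subset_suffstats <- function(X, vars) {
  M <- X[, vars, drop = FALSE]
  n <- nrow(M)
  mu <- colMeans(M)
  S <- crossprod(sweep(M, 2, mu))
  list(n = n, mean = mu, scatter = S)
}

#' Log marginal likelihoods g(W) for every subset W of a variable set
#'
#' @param suff sufficient statistics of the full k-variable subset.
#' @param alpha_mu prior precision scalar.
#' @return numeric vector of length 2^k indexed by subset bitmask + 1.
#' @keywords internal
bge_set_marginals <- function(suff, alpha_mu = 1) {
  n <- suff$n
  k <- length(suff$mean)
  alpha_w <- k + 2
  shift <- (alpha_mu * n / (alpha_mu + n)) * tcrossprod(suff$mean)
  Rfull <- diag(k) + suff$scatter + shift
  g <- numeric(2^k)
  for (mask in seq_len(2^k - 1)) {
    W <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    l <- length(W)
    a <- alpha_w - k + l
    RW <- Rfull[W, W, drop = FALSE]
    ld <- determinant(RW, logarithm = TRUE)
    if (ld$sign <= 0) stop("singular scatter matrix in BGe scoring")
    j <- seq_len(l)
    g[mask + 1] <-
      -(n * l / 2) * log(pi) +
      (l / 2) * (log(alpha_mu) - log(alpha_mu + n)) +
      sum(lgamma((n + a + 1 - j) / 2) - lgamma((a + 1 - j) / 2)) -
      ((n + a) / 2) * ld$modulus[1]
    # logdet of the identity prior scale marginal is 0, so the (a/2)*logdet
    # prior term vanishes
  }
  g
}

#' BGe log marginal likelihood of one DAG
#'
#' @param dag integer vector of parent bitmasks (one per node), as one row
#'   of [enumerate_dags()].
#' @param suff sufficient statistics of the subset ([subset_suffstats()]).
#' @param alpha_mu prior precision scalar.
#' @return log marginal likelihood (sum of local scores).
#' @examples
#' X <- scale(matrix(rnorm(200), 100, 2))
#' s <- subset_suffstats(X, 1:2)
#' # X -> Y and Y -> X are Markov equivalent and score identically
#' bge_dag_score(c(0L, 1L), s) - bge_dag_score(c(2L, 0L), s)
#' @export
bge_dag_score <- function(dag, suff, alpha_mu = 1) {
  g <- bge_set_marginals(suff, alpha_mu)
  k <- length(dag)
  bits <- bitwShiftL(1L, seq_len(k) - 1L)
  sum(vapply(seq_len(k), function(j)
    g[bitwOr(dag[j], bits[j]) + 1] - g[dag[j] + 1], numeric(1)))
}

#' Posterior over all DAGs on a subset (uniform structure prior)
#'
#' @return list with `weights` (posterior probabilities, one per enumerated
#'   DAG) and `scores` (log marginal likelihoods).
#' @keywords internal
bge_dag_posterior <- function(suff, alpha_mu = 1) {
  k <- length(suff$mean)
  g <- bge_set_marginals(suff, alpha_mu)
  dags <- enumerate_dags(k)
  bits <- bitwShiftL(1L, seq_len(k) - 1L)
  scores <- numeric(nrow(dags))
  for (j in seq_len(k)) {
    scores <- scores + g[bitwOr(dags[, j], bits[j]) + 1] - g[dags[, j] + 1]
  }
  mx <- max(scores)
  w <- exp(scores - mx)
  list(weights = w / sum(w), scores = scores)
}
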