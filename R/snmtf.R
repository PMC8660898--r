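# Supervised non-negative matrix tri-factorization: hyperparameters,
# random-Acol initialization, and the training/test objective functions.

#' Hyperparameters for the tri-factorization solvers
#'
#' @param k_V variant-cluster rank (columns of V).
#' @param k_S score-cluster rank (columns of S).
#' @param k_D disease-cluster rank (three-source only).
#' @param gamma1,gamma2,gamma3 non-negative Laplacian regularization weights
#'   for the variant-variant, score-score and disease-disease networks.
#' @param max_iter maximum number of multiplicative update sweeps.
#' @param tol stopping threshold on the relative objective change.
#' @param seed integer seed driving initialization.
#' @param eps denominator guard for the multiplicative updates.
#' @param acol_p number of data columns averaged per factor column in the
#'   random-Acol initialization.
#' @param reuse_u if TRUE, the trained cluster-interaction core U is held
#'   fixed at test time instead of being re-estimated from a warm start.
#' @return A list of class `snmtf_hyperparams`.
#' @export
snmtf_hyperparams <- function(k_V = 10L, k_S = 3L, k_D = 5L,
                              gamma1 = 0.1, gamma2 = 0.1, gamma3 = 0.1,
                              max_iter = 500L, tol = 1e-5, seed = 1L,
                              eps = 1e-10, acol_p = 5L, reuse_u = FALSE) {
  hp <- list(k_V = as.integer(k_V), k_S = as.integer(k_S), k_D = as.integer(k_D),
             gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
             max_iter = as.integer(max_iter), tol = tol, seed = as.integer(seed),
             eps = eps, acol_p = as.integer(acol_p), reuse_u = isTRUE(reuse_u))
  if (hp$k_V < 1L || hp$k_S < 1L || hp$k_D < 1L)
    stop("validation error: ranks must be >= 1")
  if (hp$gamma1 < 0 || hp$gamma2 < 0 || hp$gamma3 < 0)
    stop("validation error: regularization weights must be >= 0")
  if (hp$max_iter < 0L) stop("validation error: max_iter must be >= 0")
  if (hp$tol <= 0) stop("validation error: tol must be > 0")
  structure(hp, class = "snmtf_hyperparams")
}

#' Random-Acol initialization of the factor matrices
#'
#' Each column of V0 is the average of `p` uniformly chosen columns of R;
#' each column of S0 is the average of `p` uniformly chosen rows of R. The
#' core U0 and label indicator G0 are drawn uniform on (0, 1]. A small
#' epsilon keeps all entries strictly positive so multiplicative updates can
#' move every coordinate.
#'
#' @param R non-negative m x n data matrix.
#' @param k_rows rank of the row (variant) clustering, <= m.
#' @param k_cols rank of the column (score) clustering, <= n.
#' @param seed optional seed; when NULL the current RNG stream is used.
#' @param p columns/rows averaged per factor column (capped at what is
#'   available).
#' @param eps positivity guard added to V0 and S0.
#' @return list(V, U, S, G) with dims m x k_rows, k_rows x k_cols,
#'   n x k_cols, 1 x k_cols.
#' @export
init_factors <- function(R, k_rows, k_cols, seed = NULL, p = 5L, eps = 1e-10) {
  R <- as.matrix(R)
  m <- nrow(R); n <- ncol(R)
  if (k_rows < 1L || k_rows > m || k_cols < 1L || k_cols > n)
    stop("validation error: rank exceeds matrix dimension")
  if (!is.null(seed)) set.seed(seed)
  pV <- min(p, n); pS <- min(p, m)
  V <- vapply(seq_len(k_rows),
              function(j) rowMeans(R[, sample.int(n, pV), drop = FALSE]),
              numeric(m)) + eps
  S <- vapply(seq_len(k_cols),
              function(j) colMeans(R[sample.int(m, pS), , drop = FALSE]),
              numeric(n)) + eps
  U <- matrix(stats::runif(k_rows * k_cols), k_rows, k_cols)
  G <- matrix(stats::runif(k_cols), 1L, k_cols)
  list(V = matrix(V, m, k_rows), U = U, S = matrix(S, n, k_cols), G = G)
}

# Random-Acol draw of a single row-factor matrix. Used at test time, where
# the trained rank may legitimately exceed the number of test variants.
.acol_V <- function(R, k, seed = NULL, p = 5L, eps = 1e-10) {
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(R)
  pV <- min(p, n)
  V <- vapply(seq_len(k),
              function(j) rowMeans(R[, sample.int(n, pV), drop = FALSE]),
              numeric(nrow(R))) + eps
  matrix(V, nrow(R), k)
}

# squared Frobenius norm and Laplacian quadratic form tr(X' L X)
.fro2 <- function(X) sum(X * X)
.trq <- function(X, L) sum(X * (L %*% X))

.as_laplacian <- function(L) {
  if (inherits(L, "weighted_graph")) laplacian(L) else as.matrix(L)
}

#' Two-source training objective
#'
#' J = ||R - V U S'||_F^2 + ||Y - V U G'||_F^2 + gamma1 tr(V' L_V V)
#'   + gamma2 tr(S' L_S S). The trace terms are taken in the canonical
#' orientation (Laplacian acting on the object dimension).
#'
#' @param R m x n relation matrix.
#' @param Y m x 1 label vector (0/1).
#' @param V,U,S,G factor matrices (m x k_V, k_V x k_S, n x k_S, 1 x k_S).
#' @param L_V,L_S Laplacians (or [weighted_graph()]s) of the variant and
#'   score networks.
#' @param gamma1,gamma2 regularization weights.
#' @return The scalar objective value.
#' @export
objective_two_source <- function(R, Y, V, U, S, G, L_V, L_S, gamma1, gamma2) {
  L_V <- .as_laplacian(L_V); L_S <- .as_laplacian(L_S)
  Y <- matrix(Y, ncol = 1L)
  if (nrow(R) != nrow(V) || ncol(R) != nrow(S) || nrow(Y) != nrow(R) ||
      any(dim(U) != c(ncol(V), ncol(S))) || ncol(G) != ncol(S))
    stop("validation error: factor shapes are inconsistent")
  VU <- V %*% U
  .fro2(R - VU %*% t(S)) + .fro2(Y - VU %*% t(G)) +
    gamma1 * .trq(V, L_V) + gamma2 * .trq(S, L_S)
}

#' Three-source training objective
#'
#' Adds the disease terms ||R_VD - V U2 D'||_F^2 and gamma3 tr(D' L_D D) to
#' the two-source objective (whose core becomes U1).
#'
#' @param R_VS,R_VD relation matrices (m x n and m x n_D).
#' @param Y m x 1 label vector.
#' @param V,U1,U2,S,D,G factors (m x k_V, k_V x k_S, k_V x k_D, n x k_S,
#'   n_D x k_D, 1 x k_S).
#' @param L_V,L_S,L_D Laplacians (or [weighted_graph()]s).
#' @param gamma1,gamma2,gamma3 regularization weights.
#' @return The scalar objective value.
#' @export
objective_three_source <- function(R_VS, R_VD, Y, V, U1, U2, S, D, G,
                                   L_V, L_S, L_D, gamma1, gamma2, gamma3) {
  L_D <- .as_laplacian(L_D)
  if (nrow(R_VD) != nrow(V) || ncol(R_VD) != nrow(D) ||
      any(dim(U2) != c(ncol(V), ncol(D))))
    stop("validation error: disease factor shapes are inconsistent")
  objective_two_source(R_VS, Y, V, U1, S, G, L_V, L_S, gamma1, gamma2) +
    .fro2(R_VD - V %*% U2 %*% t(D)) + gamma3 * .trq(D, L_D)
}

# One multiplicative step: X <- X * num / (den + eps), elementwise.
.mult_update <- function(X, num, den, eps) X * num / (den + eps)
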