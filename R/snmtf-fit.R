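# Training and test-time inference for the two-source and three-source
# algorithms, plus hyperparameter grid search.
#
# All solvers use multiplicative updates in which each factor is multiplied
# elementwise by (positive gradient part) / (negative gradient part); the
# Laplacians are split as L = Deg - W so both parts stay non-negative, which
# preserves factor non-negativity and makes the objective non-increasing.

.check_nonneg <- function(X, what) {
  if (anyNA(X) || min(X) < 0)
    stop(sprintf("validation error: %s must be non-negative and finite", what))
}

.check_objective <- function(J) {
  if (!is.finite(J))
    stop("numerical error: objective overflowed; try smaller regularization weights (gamma)")
  J
}

#' Fit the two-source supervised tri-factorization
#'
#' Minimizes ||R - V U S'||^2 + ||Y - V U G_Y'||^2 + gamma1 tr(V' L_V V) +
#' gamma2 tr(S' L_S S) over non-negative factors by multiplicative updates,
#' jointly factorizing the variant-score relation matrix and the label
#' vector so that variant clusters align with class structure.
#'
#' @param R m x n relation matrix with entries in \[0, 1\].
#' @param Y length-m 0/1 label vector (1 = deleterious).
#' @param L_V,L_S variant and score network Laplacians, or
#'   [weighted_graph()] objects.
#' @param hp a [snmtf_hyperparams()] object.
#' @return Object of class `two_source_model` with factors `V`, `U`, `S`,
#'   `G_Y`, the per-iteration `objective_trace`, and `hyperparams`.
#' @export
fit_two_source <- function(R, Y, L_V, L_S, hp = snmtf_hyperparams()) {
  R <- as.matrix(R); .check_nonneg(R, "R")
  Y <- matrix(as.numeric(Y), ncol = 1L)
  L_V <- .as_laplacian(L_V); L_S <- .as_laplacian(L_S)
  pv <- .split_laplacian(L_V); ps <- .split_laplacian(L_S)
  eps <- hp$eps
  f <- init_factors(R, hp$k_V, hp$k_S, seed = hp$seed, p = hp$acol_p, eps = eps)
  V <- f$V; U <- f$U; S <- f$S; G <- f$G
  J <- .check_objective(objective_two_source(R, Y, V, U, S, G, L_V, L_S,
                                             hp$gamma1, hp$gamma2))
  trace <- J
  for (it in seq_len(hp$max_iter)) {
    VtV <- crossprod(V)
    StS_GtG <- crossprod(S) + crossprod(G)
    U <- .mult_update(U, crossprod(V, R %*% S) + crossprod(V, Y %*% G),
                      VtV %*% U %*% StS_GtG, eps)
    UtVtVU <- crossprod(U, VtV) %*% U
    S <- .mult_update(S, crossprod(R, V %*% U) + hp$gamma2 * (ps$W %*% S),
                      S %*% UtVtVU + hp$gamma2 * ps$Deg * S, eps)
    G <- .mult_update(G, crossprod(Y, V %*% U), G %*% UtVtVU, eps)
    StS_GtG <- crossprod(S) + crossprod(G)
    core <- U %*% StS_GtG %*% t(U)
    V <- .mult_update(V, R %*% S %*% t(U) + Y %*% G %*% t(U) +
                        hp$gamma1 * (pv$W %*% V),
                      V %*% core + hp$gamma1 * pv$Deg * V, eps)
    Jnew <- .check_objective(objective_two_source(R, Y, V, U, S, G, L_V, L_S,
                                                  hp$gamma1, hp$gamma2))
    trace <- c(trace, Jnew)
    if (abs(Jnew - J) / max(J, eps) < hp$tol) break
    J <- Jnew
  }
  structure(list(V = V, U = U, S = S, G_Y = G,
                 objective_trace = trace, hyperparams = hp,
                 score_names = colnames(R), threshold = NULL),
            class = "two_source_model")
}

#' @export
print.two_source_model <- function(x, ...) {
  cat(sprintf("two_source_model: m=%d, n=%d, k_V=%d, k_S=%d; %d iterations, final J=%.4g\n",
              nrow(x$V), nrow(x$S), ncol(x$V), ncol(x$S),
              length(x$objective_trace) - 1L, utils::tail(x$objective_trace, 1L)))
  invisible(x)
}

#' Predict deleteriousness for new variants with a two-source model
#'
#' The score cluster indicator S and label indicator G_Y are held fixed; the
#' test objective ||R_ts - V U S'||^2 + gamma1 tr(V' L_V V) is minimized
#' over a fresh V (random-Acol initialized on R_ts) and a warm-started U
#' (copied from training; held fixed when `hp$reuse_u`). The continuous
#' deleteriousness score is y = V_ts U_ts G_Y'.
#'
#' @param model a fitted `two_source_model`.
#' @param R_ts test relation matrix; columns must match training score order.
#' @param L_V_ts Laplacian (or graph) of the test-side variant network.
#' @param hp hyperparameters; defaults to the model's.
#' @return Object of class `snmtf_prediction` with `y_score`, test factors,
#'   and the test objective trace.
#' @export
predict_two_source <- function(model, R_ts, L_V_ts, hp = model$hyperparams) {
  stopifnot(inherits(model, "two_source_model"))
  R_ts <- as.matrix(R_ts)
  if (!is.null(model$score_names) && !is.null(colnames(R_ts)) &&
      !identical(colnames(R_ts), model$score_names))
    stop("validation error: test score columns do not match training order")
  if (ncol(R_ts) != nrow(model$S))
    stop("validation error: test relation matrix has wrong number of scores")
  if (nrow(R_ts) == 0L)
    return(structure(list(y_score = numeric(0), V_ts = NULL, U_ts = model$U,
                          objective_trace = numeric(0),
                          threshold = model$threshold),
                     class = "snmtf_prediction"))
  .check_nonneg(R_ts, "R_ts")
  L_V <- .as_laplacian(L_V_ts)
  pv <- .split_laplacian(L_V)
  eps <- hp$eps
  S <- model$S; U <- model$U
  V <- .acol_V(R_ts, hp$k_V, seed = hp$seed, p = hp$acol_p, eps = eps)
  StS <- crossprod(S)
  obj <- function(V, U) .check_objective(
    .fro2(R_ts - V %*% U %*% t(S)) + hp$gamma1 * .trq(V, L_V))
  J <- obj(V, U)
  trace <- J
  for (it in seq_len(hp$max_iter)) {
    if (!hp$reuse_u)
      U <- .mult_update(U, crossprod(V, R_ts %*% S),
                        crossprod(V) %*% U %*% StS, eps)
    core <- U %*% StS %*% t(U)
    V <- .mult_update(V, R_ts %*% S %*% t(U) + hp$gamma1 * (pv$W %*% V),
                      V %*% core + hp$gamma1 * pv$Deg * V, eps)
    Jnew <- obj(V, U)
    trace <- c(trace, Jnew)
    if (abs(Jnew - J) / max(J, eps) < hp$tol) break
    J <- Jnew
  }
  structure(list(y_score = as.numeric(V %*% U %*% t(model$G_Y)),
                 V_ts = V, U_ts = U, objective_trace = trace,
                 threshold = model$threshold),
            class = "snmtf_prediction")
}

#' Fit the three-source supervised tri-factorization
#'
#' Extends [fit_two_source()] with gene-disease information: R_VS and the
#' binary variant-disease relation R_VD are factorized jointly (R_VS ~
#' V U1 S', R_VD ~ V U2 D', Y ~ V U1 G_Y') with an additional Jaccard
#' disease network penalty gamma3 tr(D' L_D D).
#'
#' @param R_VS m x n relation matrix in \[0, 1\].
#' @param R_VD m x n_D binary variant-disease relation matrix.
#' @param Y length-m 0/1 label vector.
#' @param L_V,L_S,L_D network Laplacians or [weighted_graph()]s.
#' @param hp a [snmtf_hyperparams()]; `k_D` is the disease-cluster rank.
#' @return Object of class `three_source_model` with factors `V`, `U1`,
#'   `U2`, `S`, `D`, `G_Y`, `objective_trace`, `hyperparams`.
#' @export
fit_three_source <- function(R_VS, R_VD, Y, L_V, L_S, L_D,
                             hp = snmtf_hyperparams()) {
  R_VS <- as.matrix(R_VS); .check_nonneg(R_VS, "R_VS")
  R_VD <- as.matrix(R_VD); .check_nonneg(R_VD, "R_VD")
  if (hp$k_D > ncol(R_VD))
    stop("validation error: k_D exceeds the number of diseases")
  Y <- matrix(as.numeric(Y), ncol = 1L)
  L_V <- .as_laplacian(L_V); L_S <- .as_laplacian(L_S); L_D <- .as_laplacian(L_D)
  pv <- .split_laplacian(L_V); ps <- .split_laplacian(L_S)
  pd <- .split_laplacian(L_D)
  eps <- hp$eps
  n_D <- ncol(R_VD)
  # shared seed stream: the two-source factors are drawn first so that, with
  # an uninformative R_VD, results are comparable with fit_two_source
  f <- init_factors(R_VS, hp$k_V, hp$k_S, seed = hp$seed, p = hp$acol_p, eps = eps)
  V <- f$V; U1 <- f$U; S <- f$S; G <- f$G
  U2 <- matrix(stats::runif(hp$k_V * hp$k_D), hp$k_V, hp$k_D)
  pD <- min(hp$acol_p, nrow(R_VD))
  D <- vapply(seq_len(hp$k_D),
              function(j) colMeans(R_VD[sample.int(nrow(R_VD), pD), , drop = FALSE]),
              numeric(n_D)) + eps
  D <- matrix(D, n_D, hp$k_D)
  obj <- function() .check_objective(objective_three_source(
    R_VS, R_VD, Y, V, U1, U2, S, D, G, L_V, L_S, L_D,
    hp$gamma1, hp$gamma2, hp$gamma3))
  J <- obj()
  trace <- J
  for (it in seq_len(hp$max_iter)) {
    VtV <- crossprod(V)
    U1 <- .mult_update(U1, crossprod(V, R_VS %*% S) + crossprod(V, Y %*% G),
                       VtV %*% U1 %*% (crossprod(S) + crossprod(G)), eps)
    U2 <- .mult_update(U2, crossprod(V, R_VD %*% D),
                       VtV %*% U2 %*% crossprod(D), eps)
    U1tVtVU1 <- crossprod(U1, VtV) %*% U1
    S <- .mult_update(S, crossprod(R_VS, V %*% U1) + hp$gamma2 * (ps$W %*% S),
                      S %*% U1tVtVU1 + hp$gamma2 * ps$Deg * S, eps)
    D <- .mult_update(D, crossprod(R_VD, V %*% U2) +
                        hp$gamma3 * (pd$W %*% D),
                      D %*% crossprod(U2, VtV) %*% U2 + hp$gamma3 * pd$Deg * D,
                      eps)
    G <- .mult_update(G, crossprod(Y, V %*% U1), G %*% U1tVtVU1, eps)
    core <- U1 %*% (crossprod(S) + crossprod(G)) %*% t(U1) +
      U2 %*% crossprod(D) %*% t(U2)
    V <- .mult_update(V, R_VS %*% S %*% t(U1) + R_VD %*% D %*% t(U2) +
                        Y %*% G %*% t(U1) + hp$gamma1 * (pv$W %*% V),
                      V %*% core + hp$gamma1 * pv$Deg * V, eps)
    Jnew <- obj()
    trace <- c(trace, Jnew)
    if (abs(Jnew - J) / max(J, eps) < hp$tol) break
    J <- Jnew
  }
  structure(list(V = V, U1 = U1, U2 = U2, S = S, D = D, G_Y = G,
                 objective_trace = trace, hyperparams = hp,
                 score_names = colnames(R_VS), disease_names = colnames(R_VD),
                 threshold = NULL),
            class = "three_source_model")
}

#' @export
print.three_source_model <- function(x, ...) {
  cat(sprintf("three_source_model: m=%d, n=%d, n_D=%d, k_V=%d, k_S=%d, k_D=%d; %d iterations, final J=%.4g\n",
              nrow(x$V), nrow(x$S), nrow(x$D), ncol(x$V), ncol(x$S), ncol(x$D),
              length(x$objective_trace) - 1L, utils::tail(x$objective_trace, 1L)))
  invisible(x)
}

#' Predict deleteriousness with a three-source model
#'
#' S, D and G_Y are fixed from training; the test objective
#' ||R_VS_ts - V U1 S'||^2 + ||R_VD_ts - V U2 D'||^2 + gamma1 tr(V' L_V V)
#' is minimized over V (random-Acol on R_VS_ts) and warm-started U1, U2.
#' The prediction is y = V_ts U1_ts G_Y'.
#'
#' @param model a fitted `three_source_model`.
#' @param R_VS_ts,R_VD_ts test relation matrices; column orders must match
#'   training.
#' @param L_V_ts test-side variant network Laplacian or graph.
#' @param hp hyperparameters; defaults to the model's.
#' @return Object of class `snmtf_prediction`.
#' @export
predict_three_source <- function(model, R_VS_ts, R_VD_ts, L_V_ts,
                                 hp = model$hyperparams) {
  stopifnot(inherits(model, "three_source_model"))
  R_VS_ts <- as.matrix(R_VS_ts); R_VD_ts <- as.matrix(R_VD_ts)
  if (!is.null(model$score_names) && !is.null(colnames(R_VS_ts)) &&
      !identical(colnames(R_VS_ts), model$score_names))
    stop("validation error: test score columns do not match training order")
  if (!is.null(model$disease_names) && !is.null(colnames(R_VD_ts)) &&
      !identical(colnames(R_VD_ts), model$disease_names))
    stop("validation error: test disease columns do not match training order")
  if (ncol(R_VD_ts) != nrow(model$D))
    stop("validation error: test disease relation matrix has wrong width")
  if (nrow(R_VS_ts) == 0L)
    return(structure(list(y_score = numeric(0), V_ts = NULL, U1_ts = model$U1,
                          U2_ts = model$U2, objective_trace = numeric(0),
                          threshold = model$threshold),
                     class = "snmtf_prediction"))
  .check_nonneg(R_VS_ts, "R_VS_ts"); .check_nonneg(R_VD_ts, "R_VD_ts")
  L_V <- .as_laplacian(L_V_ts)
  pv <- .split_laplacian(L_V)
  eps <- hp$eps
  S <- model$S; D <- model$D; U1 <- model$U1; U2 <- model$U2
  V <- .acol_V(R_VS_ts, hp$k_V, seed = hp$seed, p = hp$acol_p, eps = eps)
  StS <- crossprod(S); DtD <- crossprod(D)
  obj <- function(V, U1, U2) .check_objective(
    .fro2(R_VS_ts - V %*% U1 %*% t(S)) + .fro2(R_VD_ts - V %*% U2 %*% t(D)) +
      hp$gamma1 * .trq(V, L_V))
  J <- obj(V, U1, U2)
  trace <- J
  for (it in seq_len(hp$max_iter)) {
    if (!hp$reuse_u) {
      VtV <- crossprod(V)
      U1 <- .mult_update(U1, crossprod(V, R_VS_ts %*% S), VtV %*% U1 %*% StS, eps)
      U2 <- .mult_update(U2, crossprod(V, R_VD_ts %*% D), VtV %*% U2 %*% DtD, eps)
    }
    core <- U1 %*% StS %*% t(U1) + U2 %*% DtD %*% t(U2)
    V <- .mult_update(V, R_VS_ts %*% S %*% t(U1) + R_VD_ts %*% D %*% t(U2) +
                        hp$gamma1 * (pv$W %*% V),
                      V %*% core + hp$gamma1 * pv$Deg * V, eps)
    Jnew <- obj(V, U1, U2)
    trace <- c(trace, Jnew)
    if (abs(Jnew - J) / max(J, eps) < hp$tol) break
    J <- Jnew
  }
  structure(list(y_score = as.numeric(V %*% U1 %*% t(model$G_Y)),
                 V_ts = V, U1_ts = U1, U2_ts = U2, objective_trace = trace,
                 threshold = model$threshold),
            class = "snmtf_prediction")
}

#' Grid search over hyperparameters by gene-aware cross-validated AUC
#'
#' Evaluates every combination of the supplied hyperparameter values by
#' [cross_validate()] and returns the combination with the highest mean
#' AUC (ties broken toward the first combination in grid order).
#'
#' @param bundle a [snmtf_bundle()].
#' @param grid named list of hyperparameter values to cross, e.g.
#'   `list(k_V = c(5, 10), gamma1 = c(0.1, 1))`; unlisted parameters keep
#'   the defaults in `base_hp`.
#' @param algorithm `"two_source"` or `"three_source"`.
#' @param k,repeats cross-validation folds and repeats per combination.
#' @param seed seed for fold shuffling and initialization.
#' @param base_hp defaults for parameters not in `grid`.
#' @return list with `best` (a [snmtf_hyperparams()]), `best_auc`, and
#'   `results` (one row per combination with its mean AUC).
#' @export
grid_search <- function(bundle, grid, algorithm = c("two_source", "three_source"),
                        k = 5L, repeats = 1L, seed = 1L,
                        base_hp = snmtf_hyperparams(seed = seed)) {
  algorithm <- match.arg(algorithm)
  if (!length(grid)) stop("validation error: empty grid")
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  aucs <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    hp <- unclass(base_hp)
    for (nm in names(combos)) hp[[nm]] <- combos[[nm]][i]
    hp <- do.call(snmtf_hyperparams, hp)
    cv <- cross_validate(bundle, hp, k = k, repeats = repeats, seed = seed,
                         algorithm = algorithm)
    aucs[i] <- cv$summary["auc", "mean"]
  }
  best_i <- which.max(aucs)
  hp <- unclass(base_hp)
  for (nm in names(combos)) hp[[nm]] <- combos[[nm]][best_i]
  best <- do.call(snmtf_hyperparams, hp)
  list(best = best, best_auc = aucs[best_i],
       results = cbind(combos, mean_auc = aucs))
}
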