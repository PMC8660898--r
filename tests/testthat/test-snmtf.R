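test_that("random-Acol initialization averages data columns deterministically", {
  R <- matrix(1, 8, 5)
  f <- init_factors(R, 3, 2, seed = 1)
  expect_equal(unname(f$V), matrix(1, 8, 3), tolerance = 1e-9)

  # determinism under a fixed seed
  R2 <- matrix(stats::runif(40), 8, 5)
  fa <- init_factors(R2, 3, 2, seed = 7)
  fb <- init_factors(R2, 3, 2, seed = 7)
  expect_identical(fa, fb)

  # p = 1: every V column is exactly one column of R (replay the draws)
  f1 <- init_factors(R2, 4, 2, seed = 11, p = 1, eps = 0)
  set.seed(11)
  idxV <- replicate(4, sample.int(5, 1))
  expect_equal(f1$V, R2[, idxV], ignore_attr = TRUE)

  expect_error(init_factors(R2, 9, 2, seed = 1), "rank")
  expect_error(init_factors(R2, 2, 6, seed = 1), "rank")
})

test_that("objective functions match brute-force elementwise summation", {
  set.seed(21)
  m <- 12; n <- 5; kv <- 3; ks <- 2; nd <- 4; kd <- 2
  R <- matrix(stats::runif(m * n), m, n)
  Y <- matrix(stats::rbinom(m, 1, 0.5), m, 1)
  V <- matrix(stats::runif(m * kv), m, kv)
  U <- matrix(stats::runif(kv * ks), kv, ks)
  S <- matrix(stats::runif(n * ks), n, ks)
  G <- matrix(stats::runif(ks), 1, ks)
  gV <- random_graph(m); gS <- random_graph(n)
  expect_equal(objective_two_source(R, Y, V, U, S, G, gV, gS, 0.7, 1.3),
               brute_objective_two(R, Y, V, U, S, G, gV$W, gS$W, 0.7, 1.3),
               tolerance = 1e-10)

  # exact factorization with zero regularization -> 0
  pl <- planted_two_source(m = 20, n = 6, k_V = 3, k_S = 2)
  expect_equal(objective_two_source(pl$R, pl$Y, pl$V, pl$U, pl$S, pl$G,
                                    zero_laplacian(20), zero_laplacian(6), 0, 0),
               0, tolerance = 1e-20)
  # all-zero factors -> ||R||^2 + ||Y||^2
  z <- matrix(0, m, kv)
  expect_equal(objective_two_source(R, Y, z, matrix(0, kv, ks), matrix(0, n, ks),
                                    matrix(0, 1, ks), gV, gS, 0, 0),
               sum(R^2) + sum(Y^2))

  # three-source reduces to two-source when the disease block vanishes
  R_VD0 <- matrix(0, m, nd)
  D <- matrix(stats::runif(nd * kd), nd, kd)
  gD <- random_graph(nd)
  expect_equal(objective_three_source(R, R_VD0, Y, V, U, matrix(0, kv, kd),
                                      S, D, G, gV, gS, gD, 0.7, 1.3, 0),
               objective_two_source(R, Y, V, U, S, G, gV, gS, 0.7, 1.3))
  # and matches brute force with a live disease block
  U2 <- matrix(stats::runif(kv * kd), kv, kd)
  R_VD <- matrix(stats::rbinom(m * nd, 1, 0.3), m, nd)
  expect_equal(objective_three_source(R, R_VD, Y, V, U, U2, S, D, G,
                                      gV, gS, gD, 0.7, 1.3, 0.5),
               brute_objective_two(R, Y, V, U, S, G, gV$W, gS$W, 0.7, 1.3) +
                 sum((R_VD - V %*% U2 %*% t(D))^2) + 0.5 * brute_quad_form(D, gD$W),
               tolerance = 1e-10)

  # homogeneity: doubling data and factors' row scale quadruples the loss
  expect_equal(objective_two_source(2 * R, 2 * Y, 2 * V, U, S, G,
                                    zero_laplacian(m), zero_laplacian(n), 0, 0),
               4 * objective_two_source(R, Y, V, U, S, G,
                                        zero_laplacian(m), zero_laplacian(n), 0, 0),
               tolerance = 1e-9)
})

test_that("training recovers a planted exact factorization", {
  pl <- planted_two_source()
  hp <- snmtf_hyperparams(k_V = 4, k_S = 3, gamma1 = 0, gamma2 = 0,
                          max_iter = 2000, tol = 1e-12, seed = 5)
  model <- fit_two_source(pl$R, pl$Y, zero_laplacian(nrow(pl$R)),
                          zero_laplacian(ncol(pl$R)), hp)
  tr <- model$objective_trace
  expect_lt(tr[length(tr)], 1e-3 * tr[1])
  expect_true(is_monotone_trace(tr))
  expect_true(all(model$V >= 0) && all(model$U >= 0) && all(model$S >= 0) &&
                all(model$G_Y >= 0))
})

test_that("max_iter = 0 returns the initialization with a length-1 trace", {
  pl <- planted_two_source(m = 15, n = 5, k_V = 2, k_S = 2)
  hp <- snmtf_hyperparams(k_V = 2, k_S = 2, max_iter = 0, seed = 3)
  model <- fit_two_source(pl$R, pl$Y, zero_laplacian(15), zero_laplacian(5), hp)
  expect_length(model$objective_trace, 1L)
  f0 <- init_factors(pl$R, 2, 2, seed = 3, p = hp$acol_p, eps = hp$eps)
  expect_equal(model$V, f0$V)
  expect_equal(model$U, f0$U)
})

test_that("objective traces are monotone and factors stay non-negative on random instances", {
  set.seed(31)
  for (rep in 1:8) {
    m <- sample(10:40, 1); n <- sample(4:9, 1)
    R <- matrix(stats::runif(m * n), m, n)
    Y <- stats::rbinom(m, 1, 0.5)
    gV <- random_graph(m, density = 0.2); gS <- random_graph(n)
    hp <- snmtf_hyperparams(k_V = sample(2:5, 1), k_S = 2,
                            gamma1 = sample(c(0, 0.1, 1, 10), 1),
                            gamma2 = sample(c(0, 0.1, 1), 1),
                            max_iter = 40, seed = rep)
    model <- fit_two_source(R, Y, gV, gS, hp)
    expect_true(is_monotone_trace(model$objective_trace))
    expect_true(all(model$V >= 0) && all(model$U >= 0) && all(model$S >= 0) &&
                all(model$G_Y >= 0))
    pred <- predict_two_source(model, R, gV, hp)
    expect_true(is_monotone_trace(pred$objective_trace))
    expect_true(all(pred$y_score >= 0))
  }
})

test_that("self-prediction is consistent with the training fit", {
  ds <- generate_dataset(synthetic_config(n_genes = 12, variants_per_gene = c(3, 6),
                                          seed = 4))
  b <- as_bundle(ds)
  omap <- fit_orientation(b$table, b$flip_scores)
  R <- normalize_scores(b$table, omap)
  gV <- build_variant_network(b$table$variants, b$ppi, b$gene_map)
  gS <- build_score_network(R)
  hp <- snmtf_hyperparams(k_V = 6, k_S = 3, max_iter = 300, seed = 2)
  model <- fit_two_source(R, b$labels, gV, gS, hp)
  auc_train <- auc(b$labels, as.numeric(model$V %*% model$U %*% t(model$G_Y)))
  pred <- predict_two_source(model, R, gV, hp)
  expect_gte(auc(b$labels, pred$y_score), auc_train - 0.05)
})

test_that("a zero test row with gamma1 = 0 predicts zero", {
  pl <- planted_two_source(m = 30, n = 6, k_V = 3, k_S = 2)
  hp <- snmtf_hyperparams(k_V = 3, k_S = 2, gamma1 = 0, gamma2 = 0,
                          max_iter = 300, seed = 9)
  model <- fit_two_source(pl$R, pl$Y, zero_laplacian(30), zero_laplacian(6), hp)
  R_ts <- rbind(pl$R[1:3, ], 0)
  pred <- predict_two_source(model, R_ts, zero_laplacian(4), hp)
  expect_lt(pred$y_score[4], 1e-6)
})

test_that("prediction validates score column order", {
  set.seed(13)
  R <- matrix(stats::runif(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  hp <- snmtf_hyperparams(k_V = 2, k_S = 2, max_iter = 10, seed = 1)
  model <- fit_two_source(R, stats::rbinom(10, 1, 0.5),
                          zero_laplacian(10), zero_laplacian(3), hp)
  R_bad <- R[, c("b", "a", "c")]
  expect_error(predict_two_source(model, R_bad, zero_laplacian(10), hp),
               "score columns")
})

test_that("three-source fit matches two-source when the disease source is uninformative", {
  set.seed(17)
  m <- 25; n <- 6; nd <- 5
  R <- matrix(stats::runif(m * n), m, n)
  Y <- stats::rbinom(m, 1, 0.5)
  gV <- random_graph(m, 0.2); gS <- random_graph(n)
  hp <- snmtf_hyperparams(k_V = 4, k_S = 2, k_D = 2, gamma3 = 0,
                          max_iter = 60, seed = 23)
  m2 <- fit_two_source(R, Y, gV, gS, hp)
  m3 <- fit_three_source(R, matrix(0, m, nd), Y, gV, gS,
                         weighted_graph(paste0("d", 1:nd), matrix(0, nd, nd)), hp)
  # U2's multiplicative numerator is exactly zero, so from iteration 1 the
  # disease block vanishes and V follows the two-source trajectory
  expect_equal(m3$V, m2$V, tolerance = 1e-8)
  expect_equal(m3$U1, m2$U, tolerance = 1e-8)
  expect_true(all(m3$U2 == 0))
})

test_that("three-source traces are monotone and predictions behave", {
  ds <- generate_dataset(synthetic_config(n_genes = 12, variants_per_gene = c(3, 6),
                                          seed = 6))
  b <- as_bundle(ds)
  omap <- fit_orientation(b$table, b$flip_scores)
  R <- normalize_scores(b$table, omap)
  gV <- build_variant_network(b$table$variants, b$ppi, b$gene_map)
  gS <- build_score_network(R)
  R_VD <- build_relation_vd(b$table$variants, b$gene_disease)
  gD <- build_disease_network(R_VD)
  hp <- snmtf_hyperparams(k_V = 6, k_S = 3, k_D = 3, max_iter = 200, seed = 8)
  model <- fit_three_source(R, R_VD, b$labels, gV, gS, gD, hp)
  expect_true(is_monotone_trace(model$objective_trace))
  expect_true(all(model$V >= 0) && all(model$D >= 0) && all(model$U2 >= 0))

  pred <- predict_three_source(model, R, R_VD, gV, hp)
  expect_true(is_monotone_trace(pred$objective_trace))
  auc_train <- auc(b$labels, as.numeric(model$V %*% model$U1 %*% t(model$G_Y)))
  expect_gte(auc(b$labels, pred$y_score), auc_train - 0.05)

  # a variant with a zero disease row is driven by the score term only
  R_vd_zero <- R_VD; R_vd_zero[, ] <- 0
  p0 <- predict_three_source(model, R[1:4, ], R_VD[1:4, , drop = FALSE] * 0,
                             build_variant_network(b$table$variants[1:4, ]), hp)
  expect_length(p0$y_score, 4L)

  # empty test set
  pe <- predict_three_source(model, R[0, , drop = FALSE],
                             R_VD[0, , drop = FALSE],
                             weighted_graph(character(), matrix(0, 0, 0)), hp)
  expect_length(pe$y_score, 0L)

  expect_error(predict_three_source(model, R, R_VD[, -1], gV, hp), "disease")
})

test_that("increasing the variant-network penalty smooths V along graph edges", {
  # two-block graph; the Laplacian penalty directly targets the weighted
  # edge disagreement, so it must shrink as gamma1 grows
  set.seed(41)
  m <- 40
  block <- rep(1:2, each = m / 2)
  W <- outer(block, block, "==") * 0.8
  diag(W) <- 0
  gV <- weighted_graph(paste0("v", 1:m), W)
  R <- matrix(stats::runif(m * 6), m, 6)
  Y <- stats::rbinom(m, 1, 0.5)
  gS <- random_graph(6)
  disagreement <- vapply(c(0, 0.1, 1, 10), function(g1) {
    hp <- snmtf_hyperparams(k_V = 4, k_S = 2, gamma1 = g1, gamma2 = 0.1,
                            max_iter = 300, seed = 13)
    V <- fit_two_source(R, Y, gV, gS, hp)$V
    tot <- 0
    for (i in 1:(m - 1)) for (j in (i + 1):m)
      tot <- tot + W[i, j] * sum((V[i, ] - V[j, ])^2)
    tot
  }, 0)
  expect_true(all(diff(disagreement) < 0))
})

test_that("removing label supervision degrades held-out ranking", {
  aucs <- t(sapply(1:5, function(s) {
    ds <- generate_dataset(synthetic_config(n_genes = 16, variants_per_gene = c(4, 8),
                                            seed = s))
    b <- as_bundle(ds)
    folds <- gene_aware_folds(b$table$variants, k = 4, seed = s)
    tr <- folds$variant_fold != 1L
    omap <- fit_orientation(score_table(b$table$variants[tr, ], b$table$score_names,
                                        b$table$values[tr, ]), b$flip_scores)
    R_tr <- normalize_scores(score_table(b$table$variants[tr, ], b$table$score_names,
                                         b$table$values[tr, ]), omap)
    R_ts <- normalize_scores(score_table(b$table$variants[!tr, ], b$table$score_names,
                                         b$table$values[!tr, ]), omap)
    gV_tr <- build_variant_network(b$table$variants[tr, ], b$ppi, b$gene_map)
    gV_ts <- build_variant_network(b$table$variants[!tr, ], b$ppi, b$gene_map)
    gS <- build_score_network(R_tr)
    hp <- snmtf_hyperparams(k_V = 8, k_S = 3, max_iter = 200, seed = s)
    sup <- fit_two_source(R_tr, b$labels[tr], gV_tr, gS, hp)
    uns <- fit_two_source(R_tr, rep(0, sum(tr)), gV_tr, gS, hp)
    c(sup = auc(b$labels[!tr], predict_two_source(sup, R_ts, gV_ts, hp)$y_score),
      uns = auc(b$labels[!tr], predict_two_source(uns, R_ts, gV_ts, hp)$y_score))
  }))
  expect_gt(mean(aucs[, "sup"]), mean(aucs[, "uns"]))
})

test_that("grid search returns the single point of a singleton grid, deterministically", {
  ds <- generate_dataset(synthetic_config(n_genes = 8, variants_per_gene = c(3, 5),
                                          seed = 14))
  b <- as_bundle(ds)
  base <- snmtf_hyperparams(k_S = 2, max_iter = 60)
  gs1 <- grid_search(b, list(k_V = 4L), k = 3, repeats = 1, seed = 2, base_hp = base)
  expect_equal(gs1$best$k_V, 4L)
  gs2 <- grid_search(b, list(k_V = 4L), k = 3, repeats = 1, seed = 2, base_hp = base)
  expect_equal(gs1$best_auc, gs2$best_auc)
  expect_error(grid_search(b, list()), "empty grid")
})
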