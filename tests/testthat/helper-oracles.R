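# Independent brute-force oracles and tiny in-code fixtures. The oracles are
# deliberately naive (double loops, set arithmetic) so they share no code
# path with the implementation they check.

# pairwise Jaccard of the variant sets of each disease column
brute_jaccard <- function(R_VD) {
  nD <- ncol(R_VD)
  W <- matrix(0, nD, nD)
  for (a in seq_len(nD)) for (b in seq_len(nD)) {
    if (a == b) next
    va <- which(R_VD[, a] == 1); vb <- which(R_VD[, b] == 1)
    u <- length(union(va, vb))
    W[a, b] <- if (u == 0) 0 else length(intersect(va, vb)) / u
  }
  W
}

# elementwise Manhattan distance between score columns
brute_manhattan <- function(R) {
  n <- ncol(R)
  d <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n))
    d[a, b] <- sum(abs(R[, a] - R[, b]))
  d
}

# AUC by exhaustive pair counting (ties count 1/2)
brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# the printed metric formulas, written out independently
brute_metrics <- function(TP, FP, TN, FN) {
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  c(accuracy = (TP + TN) / (TP + TN + FN + FP),
    precision = if (TP + FP == 0) 0 else TP / (TP + FP),
    sensitivity = if (TP + FN == 0) 0 else TP / (TP + FN),
    specificity = if (FP + TN == 0) 0 else TN / (FP + TN),
    f1 = if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN),
    mcc = if (mcc_den == 0) 0 else (TP * TN - FP * FN) / mcc_den)
}

# tr(X' L X) computed through the edge-sum identity
# 0.5 * sum_jk W[j,k] ||X[j,] - X[k,]||^2
brute_quad_form <- function(X, W) {
  tot <- 0
  for (j in seq_len(nrow(W))) for (k in seq_len(ncol(W)))
    tot <- tot + W[j, k] * sum((X[j, ] - X[k, ])^2)
  tot / 2
}

# two-source objective by elementwise summation
brute_objective_two <- function(R, Y, V, U, S, G, W_V, W_S, g1, g2) {
  hatR <- V %*% U %*% t(S)
  hatY <- V %*% U %*% t(G)
  sum((R - hatR)^2) + sum((Y - hatY)^2) +
    g1 * brute_quad_form(V, W_V) + g2 * brute_quad_form(S, W_S)
}

# a random simple undirected weighted graph
random_graph <- function(n, density = 0.5, ids = paste0("n", seq_len(n))) {
  W <- matrix(0, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    if (stats::runif(1) < density) W[a, b] <- W[b, a] <- stats::runif(1)
  }
  weighted_graph(ids, W)
}

# a small complete score table built in code
tiny_table <- function(m = 6, n = 4, seed = 1,
                       genes = rep(c("gA", "gB", "gC"), length.out = m)) {
  set.seed(seed)
  score_table(data.frame(variant_id = sprintf("v%02d", seq_len(m)),
                         gene_id = genes),
              paste0("s", seq_len(n)),
              matrix(stats::runif(m * n), m, n))
}

# write a score-table TSV and return its path
write_score_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small planted exact factorization (block structure, exactly representable)
planted_two_source <- function(m = 60, n = 9, k_V = 4, k_S = 3, seed = 42) {
  set.seed(seed)
  V <- 0.05 + outer(rep_len(seq_len(k_V), m), seq_len(k_V), "==") * 0.9
  S <- 0.05 + outer(rep_len(seq_len(k_S), n), seq_len(k_S), "==") * 0.9
  U <- matrix(stats::runif(k_V * k_S, 0.2, 1), k_V, k_S)
  G <- matrix(stats::runif(k_S), 1, k_S)
  list(V = V, U = U, S = S, G = G,
       R = V %*% U %*% t(S), Y = V %*% U %*% t(G))
}

zero_laplacian <- function(n) matrix(0, n, n)

sort_ppi <- function(ppi) {
  out <- ppi[order(ppi$protein_a, ppi$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# relative objective decrease check: non-increasing within slack
is_monotone_trace <- function(trace, slack = 1e-9) {
  if (length(trace) < 2) return(TRUE)
  all(diff(trace) <= slack * pmax(abs(trace[-length(trace)]), 1e-300))
}
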