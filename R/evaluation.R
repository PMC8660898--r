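# Classification metrics, threshold selection, gene-aware cross-validation
# and the gene-purity stratification used to diagnose type 2 circularity.

#' Confusion counts at a threshold
#'
#' A variant is called deleterious iff its score is >= `threshold`.
#'
#' @param labels 0/1 vector (1 = deleterious).
#' @param scores numeric vector of continuous predictions.
#' @param threshold decision threshold.
#' @return list(TP, FP, TN, FN) of class `confusion_counts`.
#' @export
confusion_counts <- function(labels, scores, threshold) {
  if (length(labels) != length(scores))
    stop("validation error: labels and scores lengths differ")
  if (!is.finite(threshold)) stop("validation error: threshold must be finite")
  call_pos <- scores >= threshold
  structure(list(TP = sum(labels == 1 & call_pos),
                 FP = sum(labels == 0 & call_pos),
                 TN = sum(labels == 0 & !call_pos),
                 FN = sum(labels == 1 & !call_pos)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy, precision, sensitivity (TPR), specificity (TNR),
#' F1 = 2TP / (2TP + FP + FN) and MCC. Degenerate denominators follow the
#' common conventions: precision/sensitivity/specificity are reported as 0
#' with a warning when their denominator is 0, and MCC is 0 when any factor
#' under its square root is 0. AUC is threshold-free and computed
#' separately by [auc()].
#'
#' @param cc a [confusion_counts()] object.
#' @return Named numeric vector with accuracy, precision, sensitivity,
#'   specificity, f1, mcc.
#' @export
classification_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  TP <- cc$TP; FP <- cc$FP; TN <- cc$TN; FN <- cc$FN
  total <- TP + FP + TN + FN
  if (total == 0L) stop("empty-dataset error: no evaluated variants")
  ratio0 <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reporting 0", what))
      0
    } else num / den
  }
  mcc_den <- prod(sqrt(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  c(accuracy = (TP + TN) / total,
    precision = ratio0(TP, TP + FP, "precision"),
    sensitivity = ratio0(TP, TP + FN, "sensitivity"),
    specificity = ratio0(TN, FP + TN, "specificity"),
    f1 = if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN),
    mcc = if (mcc_den == 0) 0 else (TP * TN - FP * FN) / mcc_den)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Probability that a random deleterious variant scores above a random
#' neutral one; ties contribute 1/2 (midrank convention).
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric predictions.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop("validation error: labels and scores lengths differ")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop("validation error: AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Choose a decision threshold maximizing Youden's J
#'
#' Candidate cuts are the observed score values; the cut maximizing
#' J = sensitivity + specificity - 1 is returned, ties broken toward the
#' higher threshold. With a single distinct score J = 0 everywhere and that
#' score is returned with a warning.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric predictions.
#' @return The selected threshold.
#' @export
choose_threshold <- function(labels, scores) {
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop("validation error: threshold selection needs both classes present")
  cuts <- sort(unique(scores), decreasing = TRUE)
  if (length(cuts) == 1L) {
    warning("all scores identical; Youden's J is 0 at every cut")
    return(cuts)
  }
  j <- vapply(cuts, function(t) {
    sum(labels == 1 & scores >= t) / n_pos +
      sum(labels == 0 & scores < t) / n_neg - 1
  }, 0)
  # ties toward the higher threshold: cuts are in decreasing order
  cuts[which.max(j)]
}

#' Gene-aware fold assignment
#'
#' Genes are shuffled under `seed` and split into `k` near-equal parts; each
#' variant inherits its gene's fold, so no gene ever spans folds. This
#' blocks the train/test information leakage that arises when variants of
#' one gene land on both sides of a split.
#'
#' @param variants data.frame with `variant_id`, `gene_id`.
#' @param k number of folds (>= 2).
#' @param seed shuffle seed.
#' @return list with `variant_fold` (integer per variant, input order) and
#'   `gene_fold` (named integer per gene).
#' @export
gene_aware_folds <- function(variants, k = 10L, seed = 1L) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  genes <- unique(variants$gene_id)
  if (k < 2L) stop("validation error: k must be >= 2")
  if (length(genes) < k)
    stop("validation error: fewer genes than folds")
  set.seed(seed)
  shuffled <- sample(genes)
  # round-robin along the shuffled gene order gives near-equal gene counts
  gene_fold <- stats::setNames(rep_len(seq_len(k), length(genes)), shuffled)
  list(variant_fold = unname(gene_fold[variants$gene_id]),
       gene_fold = gene_fold)
}

#' Partition genes (and their variants) by label purity
#'
#' A gene is "mix" iff it harbours at least one deleterious and at least one
#' neutral variant, otherwise "pure". Comparing performance between pure and
#' mix strata diagnoses type 2 circularity (a predictor that labels variants
#' by their gene looks artificially strong on pure genes). Optionally also
#' flags genes as pathogenic (>= 1 disease association).
#'
#' @param variants data.frame with `variant_id`, `gene_id`.
#' @param labels aligned 0/1 vector.
#' @param gene_disease optional (gene_id, disease_id) table for the
#'   pathogenic/nonpathogenic flag.
#' @return list with `gene_class` (data.frame gene_id, class, and
#'   `pathogenic` if requested) and `variant_class` (per-variant character
#'   vector, input order).
#' @export
partition_by_gene_purity <- function(variants, labels, gene_disease = NULL) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (length(labels) != nrow(variants))
    stop("validation error: labels length does not match variants")
  by_gene <- split(labels, variants$gene_id)
  cls <- vapply(by_gene, function(y) {
    if (any(y == 1) && any(y == 0)) "mix" else "pure"
  }, "")
  gene_class <- data.frame(gene_id = names(cls), class = unname(cls),
                           stringsAsFactors = FALSE)
  if (!is.null(gene_disease))
    gene_class$pathogenic <- gene_class$gene_id %in% gene_disease$gene_id
  list(gene_class = gene_class,
       variant_class = unname(cls[variants$gene_id]))
}

#' Gene-aware repeated cross-validation of the full pipeline
#'
#' For every repeat and fold: normalization bounds, the score network and
#' the model are fit on the training folds only; the test-side
#' variant-variant network is rebuilt from the held-out variants; the
#' decision threshold is chosen on the training-phase reconstruction
#' (never on test data); metrics are computed on the held-out fold.
#'
#' @param bundle a [snmtf_bundle()].
#' @param hp a [snmtf_hyperparams()].
#' @param k folds (default 10).
#' @param repeats repeats of the whole k-fold procedure (default 10).
#' @param seed base seed; repeat r uses seed + r - 1 for fold shuffling.
#' @param algorithm `"two_source"` or `"three_source"` (the latter requires
#'   gene-disease data in the bundle).
#' @param ss_weight score-score edge weighting, see [build_score_network()].
#' @return list with `summary` (data.frame mean/variance per metric over all
#'   fold evaluations) and `per_fold` (one row per repeat x fold).
#' @export
cross_validate <- function(bundle, hp = snmtf_hyperparams(), k = 10L,
                           repeats = 10L, seed = 1L,
                           algorithm = c("two_source", "three_source"),
                           ss_weight = "similarity") {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(bundle, "snmtf_bundle"))
  if (algorithm == "three_source" && is.null(bundle$gene_disease))
    stop("validation error: three_source requires gene-disease associations in the bundle")
  rows <- list()
  disease_order <- if (!is.null(bundle$gene_disease))
    sort(unique(bundle$gene_disease$disease_id))
  for (r in seq_len(repeats)) {
    folds <- gene_aware_folds(bundle$table$variants, k = k, seed = seed + r - 1L)
    for (f in seq_len(k)) {
      tr <- folds$variant_fold != f
      res <- .fit_eval_split(bundle, which(tr), which(!tr), hp,
                             algorithm, ss_weight, disease_order,
                             fit_seed = seed + 997L * r + f)
      rows[[length(rows) + 1L]] <- cbind(repeat_ = r, fold = f, res)
    }
  }
  per_fold <- do.call(rbind, rows)
  mets <- c("accuracy", "precision", "sensitivity", "specificity", "f1",
            "mcc", "auc")
  summary <- data.frame(
    mean = vapply(mets, function(m) mean(per_fold[[m]], na.rm = TRUE), 0),
    variance = vapply(mets, function(m) stats::var(per_fold[[m]], na.rm = TRUE), 0))
  rownames(summary) <- mets
  list(summary = summary, per_fold = per_fold)
}

# Fit on train indices, evaluate on test indices; shared by cross_validate
# and the train/test split helper.
.fit_eval_split <- function(bundle, tr_idx, ts_idx, hp, algorithm, ss_weight,
                            disease_order, fit_seed) {
  tab_tr <- score_table(bundle$table$variants[tr_idx, , drop = FALSE],
                        bundle$table$score_names,
                        bundle$table$values[tr_idx, , drop = FALSE])
  tab_ts <- score_table(bundle$table$variants[ts_idx, , drop = FALSE],
                        bundle$table$score_names,
                        bundle$table$values[ts_idx, , drop = FALSE])
  y_tr <- bundle$labels[tr_idx]; y_ts <- bundle$labels[ts_idx]
  omap <- fit_orientation(tab_tr, bundle$flip_scores)
  R_tr <- normalize_scores(tab_tr, omap)
  R_ts <- normalize_scores(tab_ts, omap)
  g_vv_tr <- build_variant_network(tab_tr$variants, bundle$ppi, bundle$gene_map)
  g_vv_ts <- build_variant_network(tab_ts$variants, bundle$ppi, bundle$gene_map)
  g_ss <- build_score_network(R_tr, weight = ss_weight)
  hp_fit <- hp; hp_fit$seed <- as.integer(fit_seed %% .Machine$integer.max)
  if (algorithm == "two_source") {
    model <- fit_two_source(R_tr, y_tr, g_vv_tr, g_ss, hp_fit)
    y_hat_tr <- as.numeric(model$V %*% model$U %*% t(model$G_Y))
    pred <- predict_two_source(model, R_ts, g_vv_ts, hp_fit)
  } else {
    R_vd_tr <- build_relation_vd(tab_tr$variants, bundle$gene_disease, disease_order)
    R_vd_ts <- build_relation_vd(tab_ts$variants, bundle$gene_disease, disease_order)
    g_dd <- build_disease_network(R_vd_tr)
    model <- fit_three_source(R_tr, R_vd_tr, y_tr, g_vv_tr, g_ss, g_dd, hp_fit)
    y_hat_tr <- as.numeric(model$V %*% model$U1 %*% t(model$G_Y))
    pred <- predict_three_source(model, R_ts, R_vd_ts, g_vv_ts, hp_fit)
  }
  thr <- choose_threshold(y_tr, y_hat_tr)
  cc <- confusion_counts(y_ts, pred$y_score, thr)
  mets <- suppressWarnings(classification_metrics(cc))
  auc_ts <- if (length(unique(y_ts)) == 2L) auc(y_ts, pred$y_score) else NA_real_
  data.frame(n_train = length(tr_idx), n_test = length(ts_idx),
             threshold = thr, t(mets), auc = auc_ts)
}

#' Single gene-aware train/test split evaluation
#'
#' Convenience wrapper: holds out a fraction of genes, fits on the rest and
#' evaluates on the held-out variants with the same leakage-free protocol as
#' [cross_validate()].
#'
#' @param bundle a [snmtf_bundle()].
#' @param hp a [snmtf_hyperparams()].
#' @param test_fraction fraction of genes held out.
#' @param seed split/initialization seed.
#' @param algorithm,ss_weight as in [cross_validate()].
#' @return One-row data.frame of metrics plus `y_score`/`y_test` attributes.
#' @export
holdout_evaluate <- function(bundle, hp = snmtf_hyperparams(),
                             test_fraction = 0.3, seed = 1L,
                             algorithm = c("two_source", "three_source"),
                             ss_weight = "similarity") {
  algorithm <- match.arg(algorithm)
  k <- max(2L, round(1 / test_fraction))
  folds <- gene_aware_folds(bundle$table$variants, k = k, seed = seed)
  ts <- folds$variant_fold == 1L
  disease_order <- if (!is.null(bundle$gene_disease))
    sort(unique(bundle$gene_disease$disease_id))
  .fit_eval_split(bundle, which(!ts), which(ts), hp, algorithm, ss_weight,
                  disease_order, fit_seed = seed)
}
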