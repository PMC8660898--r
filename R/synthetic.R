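# Synthetic datasets with planted co-cluster structure. Every stage of the
# pipeline (ingest dialects, orientation flips, networks, both solvers,
# evaluation) can be exercised without any external downloads.

#' Configuration for the synthetic generator
#'
#' Defaults describe a mid-sized benchmark: 40 genes carrying 5-15 variants
#' each (~400 variants), the nine canonical scores, 30 diseases, a planted
#' rank-(4, 3) co-cluster background, a deleterious score shift (signal) of
#' 0.6 with truncated-Gaussian noise sd 0.1, a modular PPI graph of density
#' 0.3, and disease associations informative for 80% of disease-leaning
#' genes.
#'
#' @param n_genes number of genes.
#' @param variants_per_gene inclusive (lo, hi) range; per-gene counts drawn
#'   uniformly.
#' @param n_scores number of score columns; the first nine take the
#'   canonical names (so SIFT/LRT orientation logic is exercised).
#' @param n_diseases number of diseases.
#' @param k_V_true,k_S_true planted variant/score co-cluster ranks.
#' @param signal upward shift, in normalized score units \[0, 1\], of
#'   deleterious variants' scores.
#' @param ppi_density within-module gene-gene PPI edge probability
#'   (between-module edges occur at 5% of this rate, with lower confidence).
#' @param disease_informative_fraction fraction of genes receiving
#'   propensity-informative disease associations.
#' @param label_balance fraction of deleterious variants (exact up to
#'   rounding).
#' @param noise_sd per-cell Gaussian noise sd, truncated by clipping to
#'   \[0, 1\].
#' @param variant_noise_sd sd of a per-variant noise component shared by all
#'   of that variant's scores. It emulates the correlated part of the
#'   constituent tools' errors (a variant that fools one predictor tends to
#'   fool the others), which is what keeps real meta-predictors below
#'   AUC 1; without it the nine columns act as independent replicates and
#'   even weak signals become perfectly separable.
#' @param missing_row_fraction fraction of rows given one missing raw cell
#'   (exercises [filter_missing()]).
#' @param disease_noise_rate uninformative disease pairs added, as a
#'   fraction of informative pairs.
#' @param seed RNG seed; generation is fully deterministic given the config.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 40L, variants_per_gene = c(5L, 15L),
                             n_scores = 9L, n_diseases = 30L,
                             k_V_true = 4L, k_S_true = 3L,
                             signal = 0.6, ppi_density = 0.3,
                             disease_informative_fraction = 0.8,
                             label_balance = 0.5, noise_sd = 0.1,
                             variant_noise_sd = 0.15,
                             missing_row_fraction = 0,
                             disease_noise_rate = 0.1, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              variants_per_gene = as.integer(variants_per_gene),
              n_scores = as.integer(n_scores),
              n_diseases = as.integer(n_diseases),
              k_V_true = as.integer(k_V_true), k_S_true = as.integer(k_S_true),
              signal = signal, ppi_density = ppi_density,
              disease_informative_fraction = disease_informative_fraction,
              label_balance = label_balance, noise_sd = noise_sd,
              variant_noise_sd = variant_noise_sd,
              missing_row_fraction = missing_row_fraction,
              disease_noise_rate = disease_noise_rate, seed = as.integer(seed))
  with(cfg, {
    if (n_genes < 1L || n_scores < 1L || n_diseases < 1L)
      stop("validation error: counts must be positive")
    if (length(variants_per_gene) != 2L || variants_per_gene[1L] < 1L ||
        variants_per_gene[2L] < variants_per_gene[1L])
      stop("validation error: variants_per_gene must be an increasing positive pair")
    if (signal < 0 || signal > 1 || disease_informative_fraction < 0 ||
        disease_informative_fraction > 1 || label_balance < 0 ||
        label_balance > 1 || missing_row_fraction < 0 || missing_row_fraction > 1)
      stop("validation error: fractions must lie in [0, 1]")
    if (k_S_true > n_scores)
      stop("validation error: k_S_true exceeds n_scores")
    if (k_V_true > n_genes * variants_per_gene[1L])
      stop("validation error: k_V_true exceeds the minimum total variants")
    if (noise_sd < 0 || variant_noise_sd < 0 || ppi_density < 0 || ppi_density > 1)
      stop("validation error: noise sds >= 0 and ppi_density in [0, 1] required")
  })
  structure(cfg, class = "synthetic_config")
}

# raw scales emulating the constituent scores; flip-oriented scores keep the
# unit interval so 1-score is meaningful
.score_scales <- function(score_names) {
  canonical <- list(SIFT = c(0, 1), Polyphen2 = c(0, 1), LRT = c(0, 1),
                    MutationAssessor = c(-5.5, 6), PROVEAN = c(-14, 14),
                    "GERP++" = c(-12, 6), phyloP = c(-14, 6),
                    phastCons = c(0, 1), SiPhy = c(0, 37))
  lapply(stats::setNames(score_names, score_names),
         function(s) canonical[[s]] %||% c(0, 10))
}

.synth_score_names <- function(n) {
  base <- snmtf_score_names()
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("score%02d", seq.int(length(base) + 1L, n)))
}

#' Generate a synthetic dataset with planted structure
#'
#' The generator plants (i) a rank-(k_V_true, k_S_true) non-negative
#' co-cluster background R = V* U* S*' rescaled into \[0.2, 0.4\]; (ii) a
#' per-gene deleteriousness propensity (half the genes lean deleterious)
#' from which exactly `round(m * label_balance)` variants are drawn as
#' deleterious, whose score rows are then shifted upward by `signal` before
#' shared per-variant noise, per-cell truncated-Gaussian noise and clipping;
#' (iii) a modular PPI graph whose
#' gene modules coincide with the planted variant clusters; (iv) disease
#' associations linking disease-leaning genes to one disease block and the
#' remaining genes to the complementary block, for an informative fraction
#' of genes, plus uniform noise pairs; (v) raw score columns on realistic
#' scales with SIFT/LRT emitted pre-flip (low = damaging).
#'
#' @param cfg a [synthetic_config()].
#' @return Object of class `snmtf_synthetic` with elements `table` (raw
#'   [score_table()]), `labels`, `ppi`, `gene_map`, `gene_disease`, `truth`
#'   (planted factors, clusters, propensities, and the noiseless/normalized
#'   matrix), and `config`.
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes
  genes <- sprintf("g%03d", seq_len(G))
  n_per <- sample(seq.int(cfg$variants_per_gene[1L], cfg$variants_per_gene[2L]),
                  G, replace = TRUE)
  m <- sum(n_per)
  if (cfg$k_V_true > m)
    stop("validation error: k_V_true exceeds the number of variants")
  gene_of <- rep(genes, n_per)
  variants <- data.frame(variant_id = sprintf("v%05d", seq_len(m)),
                         gene_id = gene_of, stringsAsFactors = FALSE)
  score_names <- .synth_score_names(cfg$n_scores)
  n <- cfg$n_scores

  # planted co-cluster background
  gene_module <- stats::setNames(sample(rep_len(seq_len(cfg$k_V_true), G)), genes)
  z <- gene_module[gene_of]                      # variant cluster
  cscore <- rep_len(seq_len(cfg$k_S_true), n)    # score cluster
  V_star <- 0.05 + 0.9 * outer(z, seq_len(cfg$k_V_true), "==") +
    matrix(stats::runif(m * cfg$k_V_true, 0, 0.05), m)
  S_star <- 0.05 + 0.9 * outer(cscore, seq_len(cfg$k_S_true), "==") +
    matrix(stats::runif(n * cfg$k_S_true, 0, 0.05), n)
  U_star <- matrix(stats::runif(cfg$k_V_true * cfg$k_S_true, 0.3, 1),
                   cfg$k_V_true)
  base <- V_star %*% U_star %*% t(S_star)
  rng <- range(base)
  base <- 0.2 + 0.20 * (base - rng[1L]) / max(rng[2L] - rng[1L], 1e-12)

  # per-gene deleteriousness propensity -> exactly balanced labels
  lean <- stats::setNames(rep(FALSE, G), genes)
  lean[sample(genes, floor(G / 2))] <- TRUE
  w <- ifelse(lean[gene_of], 0.8, 0.2)
  n_del <- round(m * cfg$label_balance)
  y <- integer(m)
  if (n_del > 0L) y[sample.int(m, n_del, prob = w)] <- 1L

  R_true <- base + cfg$signal * y +
    stats::rnorm(m, 0, cfg$variant_noise_sd) +   # shared tool-correlated error
    matrix(stats::rnorm(m * n, 0, cfg$noise_sd), m)
  R_true <- pmin(pmax(R_true, 0), 1)
  dimnames(R_true) <- list(variants$variant_id, score_names)

  # raw scores on realistic scales, SIFT/LRT pre-flip
  scales <- .score_scales(score_names)
  flip <- score_names %in% snmtf_flip_scores()
  raw <- R_true
  raw[, flip] <- 1 - raw[, flip]
  for (j in seq_len(n)) {
    sc <- scales[[j]]
    raw[, j] <- sc[1L] + (sc[2L] - sc[1L]) * raw[, j]
  }
  n_miss <- round(cfg$missing_row_fraction * m)
  if (n_miss > 0L) {
    rows <- sample.int(m, n_miss)
    raw[cbind(rows, sample.int(n, n_miss, replace = TRUE))] <- NA_real_
  }

  # modular PPI over genes (proteins are one-to-one with genes)
  proteins <- stats::setNames(paste0("P_", genes), genes)
  if (G >= 2L) {
    pair <- utils::combn(genes, 2L)
    same_mod <- gene_module[pair[1L, ]] == gene_module[pair[2L, ]]
    p_edge <- ifelse(same_mod, cfg$ppi_density, cfg$ppi_density * 0.05)
    has_edge <- stats::runif(ncol(pair)) < p_edge
    # strictly above the 0.15 retention threshold so ingest keeps every edge
    conf <- ifelse(same_mod, stats::runif(ncol(pair), 0.16, 1),
                   stats::runif(ncol(pair), 0.16, 0.5))
    ppi <- data.frame(protein_a = proteins[pair[1L, has_edge]],
                      protein_b = proteins[pair[2L, has_edge]],
                      confidence = round(conf[has_edge], 3L),
                      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    ppi <- data.frame(protein_a = character(), protein_b = character(),
                      confidence = numeric())
  }
  swap <- ppi$protein_a > ppi$protein_b
  tmp <- ppi$protein_a[swap]
  ppi$protein_a[swap] <- ppi$protein_b[swap]; ppi$protein_b[swap] <- tmp
  class(ppi) <- c("ppi_edges", "data.frame")
  gene_map <- data.frame(gene_id = genes, protein_id = unname(proteins),
                         stringsAsFactors = FALSE)

  # disease associations: disease-leaning genes hit the first disease block,
  # the rest the complementary block, for an informative fraction of genes
  diseases <- sprintf("d%03d", seq_len(cfg$n_diseases))
  d_hi <- diseases[seq_len(max(1L, floor(cfg$n_diseases / 2)))]
  d_lo <- setdiff(diseases, d_hi)
  if (!length(d_lo)) d_lo <- d_hi
  gd <- list()
  informative <- stats::runif(G) < cfg$disease_informative_fraction
  for (i in seq_len(G)) {
    if (!informative[i]) next
    pool <- if (lean[genes[i]]) d_hi else d_lo
    picked <- sample(pool, min(length(pool), sample.int(2L, 1L)))
    gd[[length(gd) + 1L]] <- data.frame(gene_id = genes[i], disease_id = picked,
                                        stringsAsFactors = FALSE)
  }
  gene_disease <- if (length(gd)) do.call(rbind, gd)
                  else data.frame(gene_id = character(), disease_id = character())
  n_noise <- ceiling(cfg$disease_noise_rate * nrow(gene_disease))
  if (n_noise > 0L) {
    noise <- data.frame(gene_id = sample(genes, n_noise, replace = TRUE),
                        disease_id = sample(diseases, n_noise, replace = TRUE),
                        stringsAsFactors = FALSE)
    gene_disease <- unique(rbind(gene_disease, noise))
  }
  rownames(gene_disease) <- NULL

  structure(list(table = score_table(variants, score_names, raw),
                 labels = y, ppi = ppi, gene_map = gene_map,
                 gene_disease = gene_disease,
                 truth = list(V_star = V_star, U_star = U_star, S_star = S_star,
                              variant_cluster = unname(z),
                              gene_module = gene_module,
                              disease_leaning = lean, R_normalized = R_true),
                 config = cfg),
            class = "snmtf_synthetic")
}

#' @export
print.snmtf_synthetic <- function(x, ...) {
  cat(sprintf("snmtf_synthetic: %d variants on %d genes, %d scores, %d diseases, %d PPI edges\n",
              nrow(x$table$values), x$config$n_genes, x$config$n_scores,
              x$config$n_diseases, nrow(x$ppi)))
  invisible(x)
}

#' Convert a synthetic dataset to an analysis bundle
#'
#' Applies the missing-value filter and packs the tables into the container
#' the evaluation functions consume.
#'
#' @param ds a [generate_dataset()] result.
#' @return A [snmtf_bundle()].
#' @export
as_bundle <- function(ds) {
  stopifnot(inherits(ds, "snmtf_synthetic"))
  flt <- suppressMessages(filter_missing(ds$table, ds$labels))
  snmtf_bundle(flt$table, flt$labels, ppi = ds$ppi, gene_map = ds$gene_map,
               gene_disease = ds$gene_disease,
               flip_scores = intersect(ds$table$score_names, snmtf_flip_scores()))
}

.fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))

#' Write a synthetic dataset in the standard input dialects
#'
#' Emits `scores.tsv`, `labels.tsv`, `ppi.tsv`, `gene_map.tsv` and
#' `gene_disease.tsv` under `dir`, in exactly the formats the ingest
#' functions read, so that write-then-read round-trips the dataset.
#'
#' @param ds a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the file paths.
#' @export
write_bundle <- function(ds, dir) {
  stopifnot(inherits(ds, "snmtf_synthetic"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  sc <- data.frame(ds$table$variants,
                   apply(ds$table$values, 2L, .fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(sc) <- c("variant_id", "gene_id", ds$table$score_names)
  utils::write.table(sc, p("scores.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(variant_id = ds$table$variants$variant_id,
                                label = ds$labels),
                     p("labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ppi_out <- ds$ppi
  ppi_out$confidence <- .fmt_num(ppi_out$confidence)
  names(ppi_out) <- c("protein1", "protein2", "combined_score")
  utils::write.table(ppi_out, p("ppi.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$gene_map, p("gene_map.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$gene_disease, p("gene_disease.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(vapply(c("scores.tsv", "labels.tsv", "ppi.tsv", "gene_map.tsv",
                     "gene_disease.tsv"), p, ""))
}
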