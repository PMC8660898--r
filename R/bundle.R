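# The dataset bundle (everything one training or evaluation run needs) and
# model serialization as MatrixMarket factors plus a JSON manifest.

#' Assemble a dataset bundle
#'
#' A bundle holds the complete (no missing cells) raw score table, aligned
#' labels, the PPI edge list, an optional gene-to-protein map and optional
#' gene-disease associations — everything [cross_validate()] and the
#' training commands need.
#'
#' @param table a complete [score_table()].
#' @param labels aligned 0/1 vector.
#' @param ppi [read_ppi()]-style data.frame (may be empty).
#' @param gene_map optional data.frame gene_id, protein_id (NULL = identity).
#' @param gene_disease optional data.frame gene_id, disease_id.
#' @param flip_scores score names flipped before normalization.
#' @return Object of class `snmtf_bundle`.
#' @export
snmtf_bundle <- function(table, labels, ppi = NULL, gene_map = NULL,
                         gene_disease = NULL,
                         flip_scores = snmtf_flip_scores()) {
  stopifnot(inherits(table, "score_table"))
  if (anyNA(table$values))
    stop("validation error: bundle requires a complete score table; run filter_missing first")
  if (length(labels) != nrow(table$values))
    stop("validation error: labels length does not match score table")
  if (!all(labels %in% c(0, 1)))
    stop("validation error: labels must be 0/1")
  structure(list(table = table, labels = as.integer(labels), ppi = ppi,
                 gene_map = gene_map, gene_disease = gene_disease,
                 flip_scores = flip_scores),
            class = "snmtf_bundle")
}

#' @export
print.snmtf_bundle <- function(x, ...) {
  cat(sprintf("snmtf_bundle: %d variants, %d genes, %d scores, %d PPI edges, %s\n",
              nrow(x$table$values), length(unique(x$table$variants$gene_id)),
              length(x$table$score_names),
              if (is.null(x$ppi)) 0L else nrow(x$ppi),
              if (is.null(x$gene_disease)) "no disease data"
              else sprintf("%d gene-disease pairs", nrow(x$gene_disease))))
  invisible(x)
}

#' Read a bundle from the standard file set
#'
#' Expects `scores.tsv`, `labels.tsv`, `ppi.tsv` and optionally
#' `gene_map.tsv`, `gene_disease.tsv` under `dir` (the dialects written by
#' [write_bundle()]). Variants with missing score cells are dropped.
#'
#' @param dir directory holding the files.
#' @param score_names score columns to use (default [snmtf_score_names()]).
#' @param min_confidence PPI confidence threshold.
#' @param flip_scores scores flipped before normalization.
#' @return A [snmtf_bundle()].
#' @export
read_bundle <- function(dir, score_names = snmtf_score_names(),
                        min_confidence = 0.15,
                        flip_scores = snmtf_flip_scores()) {
  p <- function(f) file.path(dir, f)
  tab <- read_score_table(p("scores.tsv"), score_names)
  labels <- read_labels(p("labels.tsv"), tab$variants$variant_id)
  flt <- filter_missing(tab, labels)
  ppi <- if (file.exists(p("ppi.tsv"))) read_ppi(p("ppi.tsv"), min_confidence)
  gene_map <- if (file.exists(p("gene_map.tsv"))) read_gene_map(p("gene_map.tsv"))
  gd <- if (file.exists(p("gene_disease.tsv"))) read_gene_disease(p("gene_disease.tsv"))
  snmtf_bundle(flt$table, flt$labels, ppi = ppi, gene_map = gene_map,
               gene_disease = gd, flip_scores = flip_scores)
}

.write_mm <- function(X, path) {
  Matrix::writeMM(methods::as(Matrix::Matrix(as.matrix(X), sparse = TRUE),
                              "generalMatrix"), path)
}

.read_mm <- function(path) as.matrix(Matrix::readMM(path))

#' Serialize a fitted model to a directory
#'
#' Factors are written as MatrixMarket files, everything else (hyperparams,
#' score/disease order, objective trace, threshold, algorithm) into
#' `manifest.json`.
#'
#' @param model a `two_source_model` or `three_source_model`.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  two <- inherits(model, "two_source_model")
  if (!two && !inherits(model, "three_source_model"))
    stop("validation error: not a fitted model")
  factors <- if (two) c("V", "U", "S", "G_Y")
             else c("V", "U1", "U2", "S", "D", "G_Y")
  for (f in factors) .write_mm(model[[f]], file.path(dir, paste0(f, ".mtx")))
  manifest <- list(algorithm = if (two) "two_source" else "three_source",
                   hyperparams = unclass(model$hyperparams),
                   score_names = model$score_names,
                   disease_names = model$disease_names,
                   objective_trace = model$objective_trace,
                   threshold = model$threshold,
                   orientation = if (!is.null(model$orientation))
                     unclass(model$orientation))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a model saved by [save_model()]
#'
#' @param dir model directory.
#' @return The reconstructed model object.
#' @export
load_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  two <- manifest$algorithm == "two_source"
  factors <- if (two) c("V", "U", "S", "G_Y")
             else c("V", "U1", "U2", "S", "D", "G_Y")
  model <- lapply(stats::setNames(factors, factors),
                  function(f) .read_mm(file.path(dir, paste0(f, ".mtx"))))
  hp <- do.call(snmtf_hyperparams, manifest$hyperparams)
  model$hyperparams <- hp
  model$score_names <- manifest$score_names
  model$disease_names <- manifest$disease_names
  model$objective_trace <- manifest$objective_trace
  model$threshold <- manifest$threshold
  if (!is.null(manifest$orientation)) {
    om <- manifest$orientation
    om$flip <- stats::setNames(as.logical(om$flip), om$score_names)
    om$a_min <- stats::setNames(as.numeric(om$a_min), om$score_names)
    om$a_max <- stats::setNames(as.numeric(om$a_max), om$score_names)
    model$orientation <- structure(om, class = "orientation_map")
  }
  class(model) <- if (two) "two_source_model" else "three_source_model"
  model
}
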