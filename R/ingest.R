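# Reading, validating, filtering and normalizing the input tables.

#' The nine constituent deleteriousness / conservation scores
#'
#' Default column set for the variant-by-score relation matrix: five
#' functional-impact predictors (SIFT, Polyphen2, LRT, MutationAssessor,
#' PROVEAN) and four conservation scores (GERP++, phyloP, phastCons, SiPhy).
#'
#' @return Character vector of length 9, in canonical column order.
#' @export
snmtf_score_names <- function() {
  c("SIFT", "Polyphen2", "LRT", "MutationAssessor", "PROVEAN",
    "GERP++", "phyloP", "phastCons", "SiPhy")
}

#' Scores whose raw scale runs opposite to damage
#'
#' For SIFT and LRT a *low* raw value means most damaging, so they are
#' replaced by 1 - score before min-max normalization.
#'
#' @return Character vector of score names flipped by default.
#' @export
snmtf_flip_scores <- function() c("SIFT", "LRT")

#' Construct a raw score table
#'
#' @param variants data.frame with columns `variant_id` (unique) and
#'   `gene_id` (non-empty; exactly one gene per variant).
#' @param score_names ordered character vector of score column identifiers.
#' @param values numeric matrix, one row per variant, one column per score;
#'   `NA` marks missing cells.
#' @return An object of class `score_table`.
#' @export
score_table <- function(variants, score_names, values) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (!all(c("variant_id", "gene_id") %in% names(variants)))
    stop("variants must have columns 'variant_id' and 'gene_id'")
  if (anyDuplicated(variants$variant_id))
    stop("validation error: duplicate variant_id in score table")
  if (any(is.na(variants$gene_id)) || any(!nzchar(variants$gene_id)))
    stop("validation error: empty gene_id")
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != nrow(variants) || ncol(values) != length(score_names))
    stop("validation error: score value grid does not match variants x scores")
  dimnames(values) <- list(variants$variant_id, score_names)
  structure(list(variants = variants[, c("variant_id", "gene_id")],
                 score_names = as.character(score_names),
                 values = values),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("score_table: %d variants x %d scores (%d genes, %d missing cells)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$variants$gene_id)), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.score_table <- function(x) dim(x$values)

.parse_numeric <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", ".", "NA", "na", "NaN")] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Read a variant score table from TSV
#'
#' Expects a header row with `variant_id`, `gene_id` and one column per
#' requested score. Missing cells may be written as `NA`, `.` or left empty;
#' any unparseable numeric cell is treated as missing.
#'
#' @param path path to a tab-separated file.
#' @param score_names score columns to extract, in the order the relation
#'   matrix should use (default [snmtf_score_names()]).
#' @return A [score_table()] with rows in file order.
#' @export
read_score_table <- function(path, score_names = snmtf_score_names()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("variant_id", "gene_id", score_names)
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop(sprintf("format error: missing column(s): %s",
                 paste(absent, collapse = ", ")))
  vals <- vapply(score_names, function(s) .parse_numeric(df[[s]]),
                 numeric(nrow(df)))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L,
                                     dimnames = list(NULL, score_names))
  score_table(df[, c("variant_id", "gene_id")], score_names, vals)
}

#' Drop variants with any missing score
#'
#' Rows containing one or more missing score cells are removed, mirroring
#' the discard-incomplete-variants preprocessing rule; the label vector, if
#' supplied, is subset to the surviving rows.
#'
#' @param table a [score_table()].
#' @param labels optional 0/1 label vector aligned with `table` rows.
#' @return list with elements `table`, `labels` (NULL if not given) and
#'   `n_removed`.
#' @export
filter_missing <- function(table, labels = NULL) {
  stopifnot(inherits(table, "score_table"))
  if (!is.null(labels) && length(labels) != nrow(table$values))
    stop("validation error: labels length does not match table rows")
  keep <- !apply(is.na(table$values), 1L, any)
  n_removed <- sum(!keep)
  if (!any(keep))
    stop("empty-dataset error: all rows removed by missing-value filter")
  if (n_removed > 0L)
    message(sprintf("filter_missing: removed %d of %d variants with missing scores",
                    n_removed, length(keep)))
  out <- score_table(table$variants[keep, , drop = FALSE],
                     table$score_names,
                     table$values[keep, , drop = FALSE])
  list(table = out,
       labels = if (is.null(labels)) NULL else labels[keep],
       n_removed = n_removed)
}

#' Fit score orientation and normalization bounds on training data
#'
#' Flip-flagged scores (low raw value = most damaging) are replaced by
#' 1 - score; per-column minimum and maximum are then recorded for the
#' min-max transform. Bounds must come from training data and be reused at
#' test time.
#'
#' @param table complete (no missing cells) [score_table()].
#' @param flip_scores score names to flip; default SIFT and LRT.
#' @return An `orientation_map` holding flip flags and (A_min, A_max) bounds.
#' @export
fit_orientation <- function(table, flip_scores = snmtf_flip_scores()) {
  stopifnot(inherits(table, "score_table"))
  if (anyNA(table$values))
    stop("validation error: fit_orientation requires a complete table; run filter_missing first")
  flip <- table$score_names %in% flip_scores
  vals <- table$values
  vals[, flip] <- 1 - vals[, flip]
  structure(list(score_names = table$score_names,
                 flip = stats::setNames(flip, table$score_names),
                 a_min = apply(vals, 2L, min),
                 a_max = apply(vals, 2L, max)),
            class = "orientation_map")
}

#' Min-max normalize scores into [0, 1]
#'
#' Applies the fitted orientation (flips, then A' = (A - A_min)/(A_max -
#' A_min)) and clips to \[0, 1\] so that test values outside the training
#' range stay admissible. Constant columns (A_min == A_max) map to 0.5.
#'
#' @param table complete [score_table()].
#' @param omap an `orientation_map` from [fit_orientation()].
#' @return m x n numeric matrix (the variant-score relation matrix R_VS),
#'   dimnames variant x score.
#' @export
normalize_scores <- function(table, omap) {
  stopifnot(inherits(table, "score_table"), inherits(omap, "orientation_map"))
  if (!identical(table$score_names, omap$score_names))
    stop("validation error: score columns do not match the orientation map")
  if (anyNA(table$values))
    stop("validation error: normalize_scores requires a complete table")
  vals <- table$values
  vals[, omap$flip] <- 1 - vals[, omap$flip]
  rng <- omap$a_max - omap$a_min
  out <- sweep(vals, 2L, omap$a_min, "-")
  out <- sweep(out, 2L, ifelse(rng > 0, rng, 1), "/")
  out[, rng == 0] <- 0.5
  pmin(pmax(out, 0), 1)
}

#' Read a protein-protein interaction edge list
#'
#' Accepts two formats: `protein1 protein2 combined_score` (STRING export,
#' whitespace or tab separated, optional header) with scores on either the
#' 0-1000 STRING scale or already in (0, 1]. If any score exceeds 1 the
#' whole column is divided by 1000. Self-edges are dropped, duplicate pairs
#' collapsed (max confidence kept), and only edges with confidence strictly
#' above `min_confidence` are retained.
#'
#' @param path edge list file.
#' @param min_confidence retention threshold on the unit scale (default 0.15).
#' @return data.frame with columns `protein_a`, `protein_b`, `confidence`,
#'   canonical pair order (protein_a < protein_b), class `ppi_edges`.
#' @export
read_ppi <- function(path, min_confidence = 0.15) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(structure(data.frame(protein_a = character(), protein_b = character(),
                                confidence = numeric()),
                     class = c("ppi_edges", "data.frame")))
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(toks) != 3L)
  if (length(bad))
    stop(sprintf("format error: line %d does not have 3 fields", bad[1L]))
  m <- do.call(rbind, toks)
  first_row_score <- suppressWarnings(as.numeric(m[1L, 3L]))
  if (is.na(first_row_score)) m <- m[-1L, , drop = FALSE]   # header row
  if (!nrow(m))
    return(structure(data.frame(protein_a = character(), protein_b = character(),
                                confidence = numeric()),
                     class = c("ppi_edges", "data.frame")))
  conf <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(conf))
    stop(sprintf("format error: line %d has a non-numeric score",
                 which(is.na(conf))[1L] + as.integer(is.na(first_row_score))))
  if (any(conf > 1)) conf <- conf / 1000
  a <- m[, 1L]; b <- m[, 2L]
  keep <- a != b
  a <- a[keep]; b <- b[keep]; conf <- conf[keep]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\r")
  conf <- vapply(split(conf, key), max, 0)
  pairs <- do.call(rbind, strsplit(names(conf), "\r", fixed = TRUE))
  keep <- conf > min_confidence
  out <- data.frame(protein_a = pairs[keep, 1L], protein_b = pairs[keep, 2L],
                    confidence = unname(conf[keep]),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out[order(out$protein_a, out$protein_b), , drop = FALSE],
            class = c("ppi_edges", "data.frame"))
}

#' Read gene-disease associations
#'
#' TSV with header `gene_id<TAB>disease_id`; duplicate pairs are collapsed.
#'
#' @param path association file.
#' @return data.frame with unique (gene_id, disease_id) pairs.
#' @export
read_gene_disease <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("gene_id", "disease_id") %in% names(df)))
    stop("format error: gene-disease file needs columns gene_id and disease_id")
  unique(df[, c("gene_id", "disease_id")])
}

#' Read a gene-to-protein mapping
#'
#' TSV with header `gene_id<TAB>protein_id`. When no file is provided the
#' pipeline assumes the identity map (gene ids are protein ids).
#'
#' @param path mapping file.
#' @return data.frame with columns `gene_id`, `protein_id`.
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("gene_id", "protein_id") %in% names(df)))
    stop("format error: gene map needs columns gene_id and protein_id")
  unique(df[, c("gene_id", "protein_id")])
}

#' Read variant labels aligned to a variant order
#'
#' TSV with header `variant_id<TAB>label`, label 1 = deleterious,
#' 0 = neutral. Every variant in `variant_order` must be labelled.
#'
#' @param path label file.
#' @param variant_order character vector giving the row order of the score
#'   table the labels accompany.
#' @return integer 0/1 vector aligned with `variant_order`.
#' @export
read_labels <- function(path, variant_order) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("variant_id", "label") %in% names(df)))
    stop("format error: label file needs columns variant_id and label")
  if (anyDuplicated(df$variant_id))
    stop("validation error: duplicate variant_id in label file")
  lab <- suppressWarnings(as.numeric(df$label))
  if (anyNA(lab) || !all(lab %in% c(0, 1)))
    stop("validation error: labels must be 0 (neutral) or 1 (deleterious)")
  idx <- match(variant_order, df$variant_id)
  if (anyNA(idx))
    stop(sprintf("validation error: no label for variant '%s'",
                 variant_order[which(is.na(idx))[1L]]))
  as.integer(lab[idx])
}

#' Remove variants overlapping another dataset
#'
#' Optional utility for deduplicating user-supplied train/test sets; it is
#' never applied implicitly.
#'
#' @param table a [score_table()].
#' @param other_ids variant ids to exclude.
#' @param labels optional aligned label vector.
#' @return list with `table`, `labels`, `n_removed` as in [filter_missing()].
#' @export
drop_overlapping_variants <- function(table, other_ids, labels = NULL) {
  stopifnot(inherits(table, "score_table"))
  keep <- !(table$variants$variant_id %in% other_ids)
  if (!any(keep))
    stop("empty-dataset error: all variants overlap the other dataset")
  list(table = score_table(table$variants[keep, , drop = FALSE],
                           table$score_names,
                           table$values[keep, , drop = FALSE]),
       labels = if (is.null(labels)) NULL else labels[keep],
       n_removed = sum(!keep))
}
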