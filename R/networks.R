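# Intra-type networks (V-V, S-S, D-D), the variant-disease relation matrix,
# and graph Laplacians.

#' Construct a weighted graph
#'
#' @param node_ids ordered node identifiers.
#' @param W symmetric non-negative weight matrix with zero diagonal.
#' @param meta optional list of metadata (e.g. raw distances).
#' @return Object of class `weighted_graph`.
#' @export
weighted_graph <- function(node_ids, W, meta = list()) {
  W <- as.matrix(W)
  n <- length(node_ids)
  if (!all(dim(W) == n)) stop("validation error: W must be square over node_ids")
  if (max(abs(W - t(W))) > 1e-12) stop("validation error: W must be symmetric")
  if (min(W) < 0) stop("validation error: W must be non-negative")
  diag(W) <- 0
  dimnames(W) <- list(node_ids, node_ids)
  structure(list(node_ids = as.character(node_ids), W = W, meta = meta),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  n <- length(x$node_ids)
  ne <- sum(x$W[upper.tri(x$W)] > 0)
  cat(sprintf("weighted_graph: %d nodes, %d edges\n", n, ne))
  invisible(x)
}

#' Build the variant-variant network from gene membership and PPI
#'
#' Two rules create edges between variants:
#' \itemize{
#' \item same-gene: a gene harbouring n >= 2 variants connects every pair of
#'   them with weight 1/(n - 1), so that a variant's within-gene weighted
#'   degree is exactly 1 regardless of how many variants the gene carries;
#' \item cross-gene: if the proteins of two different genes share a PPI edge
#'   with confidence c, every cross pair of their variants is connected with
#'   weight c.
#' }
#' Variants on genes with neither rule firing are isolated nodes.
#'
#' @param variants data.frame with columns `variant_id`, `gene_id`.
#' @param ppi edge list from [read_ppi()] (or a compatible data.frame).
#' @param gene_map optional data.frame `gene_id`, `protein_id`; identity map
#'   assumed when NULL.
#' @return A [weighted_graph()] over the variants, in input row order.
#' @export
build_variant_network <- function(variants, ppi = NULL, gene_map = NULL) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  m <- nrow(variants)
  W <- matrix(0, m, m)
  gene <- variants$gene_id
  # same-gene rule
  for (idx in split(seq_len(m), gene)) {
    n <- length(idx)
    if (n >= 2L) W[idx, idx] <- 1 / (n - 1)
  }
  # cross-gene rule via PPI
  if (!is.null(ppi) && nrow(ppi)) {
    genes <- unique(gene)
    if (is.null(gene_map)) {
      prot_of <- stats::setNames(genes, genes)
    } else {
      prot_of <- stats::setNames(gene_map$protein_id, gene_map$gene_id)[genes]
      names(prot_of) <- genes
    }
    genes_of_prot <- split(genes[!is.na(prot_of)], prot_of[!is.na(prot_of)])
    var_of_gene <- split(seq_len(m), gene)
    for (e in seq_len(nrow(ppi))) {
      ga <- genes_of_prot[[ppi$protein_a[e]]]
      gb <- genes_of_prot[[ppi$protein_b[e]]]
      if (is.null(ga) || is.null(gb)) next
      conf <- ppi$confidence[e]
      for (g1 in ga) for (g2 in gb) {
        if (g1 == g2) next
        i <- var_of_gene[[g1]]; j <- var_of_gene[[g2]]
        W[i, j] <- pmax(W[i, j], conf)
        W[j, i] <- pmax(W[j, i], conf)
      }
    }
  }
  diag(W) <- 0
  weighted_graph(variants$variant_id, W)
}

#' Build the score-score network
#'
#' Nodes are the score columns of the relation matrix; the dissimilarity
#' between two scores is the Manhattan distance between their columns over
#' all m variants. The stored edge weight defaults to the similarity
#' 1 - d/m (each per-variant absolute difference is at most 1), which is the
#' orientation the Laplacian smoothness penalty requires; the raw distance
#' matrix is kept in `meta$distance` and can be used as the edge weight via
#' `weight = "distance"`.
#'
#' @param R variant-by-score relation matrix, entries in \[0, 1\].
#' @param weight edge weighting, `"similarity"` (default) or `"distance"`.
#' @return A [weighted_graph()] over score columns.
#' @export
build_score_network <- function(R, weight = c("similarity", "distance")) {
  weight <- match.arg(weight)
  R <- as.matrix(R)
  m <- nrow(R)
  if (m == 0L) stop("empty-dataset error: relation matrix has no rows")
  d <- as.matrix(stats::dist(t(R), method = "manhattan"))
  W <- if (weight == "similarity") 1 - d / m else d
  diag(W) <- 0
  weighted_graph(colnames(R) %||% paste0("s", seq_len(ncol(R))), W,
                 meta = list(distance = d, weight = weight))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the disease-disease network by variant-set Jaccard
#'
#' The association between two diseases is the Jaccard index of the sets of
#' variants linked to each through the variant-disease relation matrix:
#' |V1 and V2| / |V1 or V2|. Pairs whose union is empty get weight 0.
#'
#' @param R_VD binary variant-by-disease relation matrix from
#'   [build_relation_vd()].
#' @return A [weighted_graph()] over diseases, in R_VD column order.
#' @export
build_disease_network <- function(R_VD) {
  R_VD <- as.matrix(R_VD)
  if (!all(R_VD %in% c(0, 1)))
    stop("validation error: R_VD must be binary")
  inter <- crossprod(R_VD)                  # |V1 and V2|
  sz <- diag(inter)
  uni <- outer(sz, sz, "+") - inter
  W <- ifelse(uni > 0, inter / uni, 0)
  diag(W) <- 0
  weighted_graph(colnames(R_VD) %||% paste0("d", seq_len(ncol(R_VD))), W)
}

#' Build the variant-disease relation matrix
#'
#' R_VD(i, d) = 1 iff the gene harbouring variant i is associated with
#' disease d. Variants on genes with no associations get all-zero rows.
#'
#' @param variants data.frame with `variant_id`, `gene_id`.
#' @param gene_disease data.frame of (gene_id, disease_id) pairs.
#' @param disease_order column order; defaults to sorted unique disease ids
#'   and must cover every disease in `gene_disease`.
#' @return Binary m x n_D matrix, dimnames variant x disease.
#' @export
build_relation_vd <- function(variants, gene_disease, disease_order = NULL) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  gene_disease <- unique(as.data.frame(gene_disease, stringsAsFactors = FALSE))
  if (is.null(disease_order)) {
    disease_order <- sort(unique(gene_disease$disease_id))
  } else if (!all(gene_disease$disease_id %in% disease_order)) {
    stop("validation error: disease_order does not cover all diseases")
  }
  m <- nrow(variants)
  R <- matrix(0, m, length(disease_order),
              dimnames = list(variants$variant_id, disease_order))
  gi <- match(gene_disease$gene_id, variants$gene_id)  # any variant of the gene
  hit <- split(match(gene_disease$disease_id, disease_order),
               gene_disease$gene_id)
  for (i in seq_len(m)) {
    d <- hit[[variants$gene_id[i]]]
    if (!is.null(d)) R[i, d] <- 1
  }
  R
}

#' Unnormalized graph Laplacian
#'
#' L = Deg - W where Deg is the diagonal matrix of weighted degrees. Row
#' sums are exactly zero and L is positive semi-definite.
#'
#' @param G a [weighted_graph()].
#' @return Symmetric numeric matrix with the graph's node order.
#' @export
laplacian <- function(G) {
  stopifnot(inherits(G, "weighted_graph"))
  diag(rowSums(G$W)) - G$W
}

# Split a Laplacian back into its non-negative parts Deg and W, as needed by
# the multiplicative updates (L = Deg - W).
.split_laplacian <- function(L) {
  Deg <- diag(L)
  W <- -L
  diag(W) <- 0
  list(Deg = Deg, W = W)
}

#' Export a weighted graph as MatrixMarket plus a node-order sidecar
#'
#' Writes `<prefix>.mtx` (sparse symmetric weights) and `<prefix>.nodes.tsv`
#' (node order). [read_graph_mm()] reverses the operation.
#'
#' @param G a [weighted_graph()].
#' @param prefix output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_graph_mm <- function(G, prefix) {
  stopifnot(inherits(G, "weighted_graph"))
  mtx <- paste0(prefix, ".mtx")
  nodes <- paste0(prefix, ".nodes.tsv")
  Matrix::writeMM(methods::as(Matrix::Matrix(G$W, sparse = TRUE), "generalMatrix"), mtx)
  utils::write.table(data.frame(node_id = G$node_ids), nodes,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(mtx, nodes))
}

#' @rdname write_graph_mm
#' @param prefix path prefix used by [write_graph_mm()].
#' @export
read_graph_mm <- function(prefix) {
  W <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  nodes <- utils::read.delim(paste0(prefix, ".nodes.tsv"),
                             colClasses = "character")$node_id
  weighted_graph(nodes, W)
}
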