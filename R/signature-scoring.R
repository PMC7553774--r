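## Gene-signature scoring of clustered single-cell expression: per-cluster
## mean/SEM profiles, log2 ratios to a per-cell baseline, n-SEM reliability
## ordering, and the summed-log2 score whose sign pattern tests whether a
## labeled population matches a directional signature (random positive and
## negative variation cancels in the sum; consistent trends accumulate).

#' @importFrom SummarizedExperiment assay colData
NULL

.getExprs <- function(se, assay_index = 1L) {
  m <- SummarizedExperiment::assay(se, assay_index)
  if (any(m < 0)) stop("expression matrix must be non-negative")
  if (anyDuplicated(rownames(m))) stop("gene identifiers must be unique")
  m
}

.getClusters <- function(se, cluster_col = "cluster") {
  cd <- SummarizedExperiment::colData(se)
  if (!cluster_col %in% colnames(cd))
    stop("colData lacks a '", cluster_col, "' column")
  cl <- as.character(cd[[cluster_col]])
  if (anyNA(cl)) stop("every cell must carry a cluster label")
  cl
}

#' Per-cluster mean and SEM expression profiles
#'
#' @param se a \code{SummarizedExperiment} (genes x cells) with a cluster
#'   label column in \code{colData}.
#' @param cluster_col name of the cluster label column.
#' @param assay_index which assay holds the normalized expression.
#' @return list with gene-by-cluster matrices \code{mean} and \code{sem}
#'   (SEM = sample SD / sqrt(n)), and \code{n_cells} per cluster.
#'   Singleton clusters get SEM = NA with a warning.
#' @examples
#' se <- generateExpression(n_cells_per_cluster = 20, n_genes = 30, seed = 1)
#' prof <- clusterProfiles(se)
#' head(prof$mean)
#' @export
clusterProfiles <- function(se, cluster_col = "cluster", assay_index = 1L) {
  m <- .getExprs(se, assay_index)
  cl <- .getClusters(se, cluster_col)
  clusters <- sort(unique(cl))
  if (length(clusters) < 2) stop("need at least 2 clusters")
  mu <- vapply(clusters, function(k) rowMeans(m[, cl == k, drop = FALSE]),
               numeric(nrow(m)))
  n <- vapply(clusters, function(k) sum(cl == k), integer(1))
  sem <- vapply(clusters, function(k) {
    sub <- m[, cl == k, drop = FALSE]
    if (ncol(sub) < 2) return(rep(NA_real_, nrow(m)))
    apply(sub, 1, stats::sd) / sqrt(ncol(sub))
  }, numeric(nrow(m)))
  if (nrow(m) == 1L) {
    mu <- matrix(mu, 1, dimnames = list(rownames(m), clusters))
    sem <- matrix(sem, 1, dimnames = list(rownames(m), clusters))
  }
  if (any(n < 2))
    warning("cluster(s) of size 1: ", paste(clusters[n < 2], collapse = ", "),
            " have undefined SEM")
  rownames(mu) <- rownames(sem) <- rownames(m)
  list(mean = mu, sem = sem, n_cells = n)
}

.defaultPseudocount <- function(mu) {
  pos <- mu[mu > 0]
  if (!length(pos)) stop("all cluster means are zero")
  0.1 * min(pos)
}

#' Per-gene log2 ratios of cluster means to a baseline
#'
#' The baseline is the per-cell average over the comparison set -- either
#' every cell in the experiment (\code{baseline_cells = NULL}, the
#' "whole set" comparison) or a subset of cells (e.g. only the melanocyte
#' clusters) -- so that positive values signify upregulation relative to
#' that average.
#'
#' @param se the \code{SummarizedExperiment} the profiles came from.
#' @param profiles output of \code{\link{clusterProfiles}}.
#' @param baseline_cells logical/integer index of the baseline cells, or
#'   NULL for all cells.
#' @param pseudocount added to numerator and denominator before the log;
#'   default 0.1 x the smallest positive cluster mean.
#' @param assay_index assay with the expression values.
#' @return gene-by-cluster matrix of \code{log2((mean + eps)/(baseline +
#'   eps))}, with the baseline means and pseudocount as attributes.
#' @export
normalizeLog2 <- function(se, profiles, baseline_cells = NULL,
                          pseudocount = NULL, assay_index = 1L) {
  m <- .getExprs(se, assay_index)
  base <- if (is.null(baseline_cells)) rowMeans(m)
          else rowMeans(m[, baseline_cells, drop = FALSE])
  if (is.null(pseudocount)) pseudocount <- .defaultPseudocount(profiles$mean)
  lg <- log2((profiles$mean + pseudocount) / (base + pseudocount))
  attr(lg, "baseline_mean") <- base
  attr(lg, "pseudocount") <- pseudocount
  lg
}

#' n-SEM reliability ordering of genes
#'
#' Each gene's n-SEM is its normalized SEM (SEM over baseline mean, plus
#' pseudocount) in its least-noisy cluster; sorting ascending puts the most
#' reliable measurements first, so heatmaps run from most to least reliable
#' top to bottom.
#'
#' @param profiles output of \code{\link{clusterProfiles}}.
#' @param baseline_mean per-gene baseline means (e.g. the
#'   \code{baseline_mean} attribute of \code{\link{normalizeLog2}}).
#' @param pseudocount stabilizer for near-zero baselines; default as in
#'   \code{\link{normalizeLog2}}.
#' @return data.frame (one row per gene, sorted ascending by n-SEM) with
#'   columns \code{gene}, \code{n_sem}.
#' @export
nSemOrder <- function(profiles, baseline_mean, pseudocount = NULL) {
  if (is.null(pseudocount)) pseudocount <- .defaultPseudocount(profiles$mean)
  nsem <- apply(profiles$sem / (baseline_mean + pseudocount), 1,
                function(x) min(x, na.rm = TRUE))
  out <- data.frame(gene = rownames(profiles$mean), n_sem = unname(nsem))
  out[order(out$n_sem, out$gene), , drop = FALSE]
}

#' Summed log2 signature score per cluster
#'
#' Sums the per-gene log2 ratios over the signature's genes in each
#' cluster; genes absent from the matrix are dropped (and counted).
#'
#' @param log2_matrix gene-by-cluster matrix from
#'   \code{\link{normalizeLog2}}.
#' @param signature character vector of gene identifiers (or a signature
#'   list with a \code{genes} element, as returned by
#'   \code{\link{readSignatures}}).
#' @return named numeric vector of per-cluster scores, with attributes
#'   \code{n_genes_used} and \code{n_genes_dropped}.
#' @export
summedScore <- function(log2_matrix, signature) {
  genes <- if (is.list(signature)) signature$genes else signature
  stopifnot(is.character(genes), length(genes) > 0)
  hit <- intersect(genes, rownames(log2_matrix))
  if (!length(hit))
    stop("no signature gene is present in the expression matrix")
  sc <- colSums(log2_matrix[hit, , drop = FALSE])
  attr(sc, "n_genes_used") <- length(hit)
  attr(sc, "n_genes_dropped") <- length(unique(genes)) - length(hit)
  sc
}

#' Shared gene count between two signatures
#'
#' @param sigA,sigB character vectors of gene identifiers (or signature
#'   lists with \code{genes} elements).
#' @param ignore_case match case-insensitively (useful across human/mouse
#'   symbol conventions).
#' @return integer size of the intersection.
#' @examples
#' signatureOverlap(c("Mcm2", "Pcna"), c("PCNA", "TOP2A"))  # 1
#' @export
signatureOverlap <- function(sigA, sigB, ignore_case = TRUE) {
  a <- if (is.list(sigA)) sigA$genes else sigA
  b <- if (is.list(sigB)) sigB$genes else sigB
  if (ignore_case) { a <- toupper(a); b <- toupper(b) }
  length(intersect(unique(a), unique(b)))
}

#' Score a set of signatures against every cluster
#'
#' Convenience wrapper chaining \code{\link{clusterProfiles}},
#' \code{\link{normalizeLog2}} and \code{\link{summedScore}} for each
#' signature, under a whole-set or subset baseline.
#'
#' @param se a \code{SummarizedExperiment} with cluster labels.
#' @param signatures list of signatures (character vectors or signature
#'   lists).
#' @param baseline \code{"whole_set"} (all cells) or \code{"subset"}.
#' @param subset_cells cell index defining the subset baseline.
#' @param cluster_col,assay_index,pseudocount as elsewhere.
#' @return data.frame: signature, cluster, score, n_genes_used.
#' @export
scoreSignatures <- function(se, signatures, baseline = c("whole_set", "subset"),
                            subset_cells = NULL, cluster_col = "cluster",
                            assay_index = 1L, pseudocount = NULL) {
  baseline <- match.arg(baseline)
  if (baseline == "subset" && is.null(subset_cells))
    stop("subset baseline requires subset_cells")
  prof <- clusterProfiles(se, cluster_col, assay_index)
  lg <- normalizeLog2(se, prof,
                      baseline_cells = if (baseline == "subset") subset_cells,
                      pseudocount = pseudocount, assay_index = assay_index)
  if (is.null(names(signatures)))
    names(signatures) <- paste0("signature_", seq_along(signatures))
  rows <- lapply(names(signatures), function(nm) {
    sc <- summedScore(lg, signatures[[nm]])
    data.frame(signature = nm, cluster = names(sc), score = unname(sc),
               n_genes_used = attr(sc, "n_genes_used"))
  })
  do.call(rbind, rows)
}
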