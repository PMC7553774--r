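## Ground-truthed synthetic inputs for every analysis stage: nest fields
## from a planar Poisson process with log-normal sizes and optional
## short-range size inhibition; negative-binomial expression matrices with
## planted directional signatures; exact samples from the closed-form
## clone-size law.

#' Generate synthetic nest fields
#'
#' Nest centers follow a homogeneous planar Poisson process; equivalent
#' radii are log-normal. With \code{inhibition_amplitude > 0}, each nest's
#' radius is shrunk by its neighbors through an exponential kernel,
#' \eqn{r_i \to r_i (1 - a \sum_j e^{-d_{ij}/range})} (floored at a small
#' positive fraction), mimicking short-range mutual growth inhibition;
#' amplitude 0 is the independence null in which size and position are
#' unrelated.
#'
#' @param n_fields number of imaging fields.
#' @param intensity nests per mm^2 (default 70, about 25 nests in a typical
#'   field).
#' @param field_extent_um square field edge in um (default 600).
#' @param meanlog,sdlog log-normal parameters of the radius in um (defaults
#'   give a median radius ~19 um with a spread straddling the 20 um split).
#' @param inhibition_amplitude in \[0, 1); 0 disables inhibition.
#' @param inhibition_range_um kernel range (um), default 45.
#' @param seed optional integer seed.
#' @return nest table: field_id, x_um, y_um, area_um2.
#' @examples
#' head(generateNestFields(n_fields = 2, seed = 1))
#' @export
generateNestFields <- function(n_fields = 7, intensity = 70,
                               field_extent_um = 600, meanlog = log(19),
                               sdlog = 0.45, inhibition_amplitude = 0,
                               inhibition_range_um = 45, seed = NULL) {
  stopifnot(n_fields >= 1, intensity > 0, field_extent_um > 0,
            sdlog > 0, inhibition_amplitude >= 0, inhibition_amplitude < 1,
            inhibition_range_um >= 0)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  area_mm2 <- (field_extent_um / 1000)^2
  for (f in seq_len(n_fields)) {
    n <- rpois(1, intensity * area_mm2)
    if (n < 2) n <- 2
    x <- runif(n, 0, field_extent_um)
    y <- runif(n, 0, field_extent_um)
    r <- rlnorm(n, meanlog, sdlog)
    if (inhibition_amplitude > 0 && n > 1) {
      D <- as.matrix(stats::dist(cbind(x, y)))
      diag(D) <- Inf
      load <- rowSums(exp(-D / inhibition_range_um))
      shrink <- pmax(0.05, 1 - inhibition_amplitude * load)
      r <- r * shrink
    }
    out[[f]] <- data.frame(field_id = sprintf("field_%02d", f),
                           x_um = x, y_um = y, area_um2 = pi * r^2)
  }
  do.call(rbind, out)
}

#' Generate a synthetic clustered expression matrix
#'
#' Negative-binomial counts with per-cell library-size normalization and
#' planted directional signatures: the listed genes are scaled by
#' \code{2^log2_fold} in their cluster's mean before sampling.
#'
#' @param n_cells_per_cluster cells per cluster (scalar or per-cluster
#'   vector).
#' @param n_genes number of genes.
#' @param n_clusters number of clusters (>= 2).
#' @param base_mean negative-binomial baseline mean.
#' @param dispersion NB dispersion (size = 1/dispersion); 0.5 is a typical
#'   overdispersed single-cell count model.
#' @param planted list of plantings, each
#'   \code{list(genes =, cluster =, log2_fold =)}; gene entries may be
#'   names or indices.
#' @param normalize if TRUE (default) divide each cell by its library size
#'   and rescale to the median library.
#' @param seed optional integer seed.
#' @return \code{SummarizedExperiment} (genes x cells) with assay
#'   \code{"normcounts"} (or \code{"counts"} if \code{normalize = FALSE})
#'   and a \code{cluster} column in \code{colData}; the planting design is
#'   stored in \code{metadata()$planted}.
#' @examples
#' se <- generateExpression(planted = list(list(genes = 1:20,
#'   cluster = "cluster_2", log2_fold = 2)), seed = 1)
#' @export
generateExpression <- function(n_cells_per_cluster = 50, n_genes = 300,
                               n_clusters = 4, base_mean = 5,
                               dispersion = 0.5, planted = list(),
                               normalize = TRUE, seed = NULL) {
  stopifnot(n_clusters >= 2, n_genes >= 1, all(n_cells_per_cluster >= 1))
  if (!is.null(seed)) set.seed(seed)
  ncc <- rep(n_cells_per_cluster, length.out = n_clusters)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  clusters <- sprintf("cluster_%d", seq_len(n_clusters))
  ## per-gene baseline means with mild gene-to-gene variation
  gmean <- base_mean * exp(stats::rnorm(n_genes, 0, 0.3))
  mu <- matrix(gmean, n_genes, n_clusters,
               dimnames = list(genes, clusters))
  for (pl in planted) {
    gi <- if (is.character(pl$genes)) match(pl$genes, genes) else pl$genes
    if (any(is.na(gi)) || any(gi > n_genes))
      stop("planted genes exceed n_genes / unknown gene names")
    if (!pl$cluster %in% clusters) stop("unknown planted cluster")
    mu[gi, pl$cluster] <- mu[gi, pl$cluster] * 2^pl$log2_fold
  }
  cl <- rep(clusters, ncc)
  counts <- matrix(0, n_genes, length(cl), dimnames = list(genes, NULL))
  for (k in seq_len(n_clusters)) {
    cols <- which(cl == clusters[k])
    counts[, cols] <- rnbinom(n_genes * length(cols),
                              size = 1 / dispersion, mu = mu[, k])
  }
  colnames(counts) <- sprintf("cell_%05d", seq_along(cl))
  assay <- counts
  assay_name <- "counts"
  if (normalize) {
    lib <- colSums(counts)
    lib[lib == 0] <- 1
    assay <- sweep(counts, 2, lib, "/") * stats::median(lib)
    assay_name <- "normcounts"
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = stats::setNames(list(assay), assay_name),
    colData = S4Vectors::DataFrame(cluster = cl,
                                   row.names = colnames(counts)))
  S4Vectors::metadata(se)$planted <- planted
  se
}

#' Exact samples from the closed-form clone-size law
#'
#' Inverse-CDF sampling from \code{\link{cloneSizePmf}} -- an independent
#' sampler against which the cycle-by-cycle simulator can be validated.
#'
#' @param s per-cycle arrest probability, > 0.5 (at exactly 0.5 the law is
#'   critical and heavy-tailed beyond practical support).
#' @param n number of clones to sample.
#' @param variant model variant.
#' @param seed optional integer seed.
#' @param max_support largest size enumerated (the CDF must reach
#'   1 - 1e-8 within it).
#' @return integer vector of clone sizes.
#' @examples
#' mean(generateCloneFixture(0.6, 2000, "founder_divides", seed = 1)) # ~6
#' @export
generateCloneFixture <- function(s, n,
                                 variant = c("founder_may_arrest",
                                             "founder_divides"),
                                 seed = NULL, max_support = 1e6) {
  variant <- match.arg(variant)
  stopifnot(n >= 1)
  if (s <= 0.5)
    stop("s must exceed 0.5 for a practically sampleable distribution")
  if (!is.null(seed)) set.seed(seed)
  sizes <- seq_len(1000L)
  p <- cloneSizePmf(sizes, s, variant)
  while (sum(p) < 1 - 1e-8) {
    if (max(sizes) >= max_support)
      stop("support exceeds max_support before the CDF closes; raise it or s")
    sizes <- seq_len(min(max_support, 10L * max(sizes)))
    p <- cloneSizePmf(sizes, s, variant)
  }
  sample(sizes, n, replace = TRUE, prob = p)
}
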