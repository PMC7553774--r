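## A small SummarizedExperiment built by hand for arithmetic checks.
tiny_se <- function() {
  m <- rbind(
    const  = rep(4, 6),
    up_inA = c(8, 8, 8, 2, 2, 2),
    noisy  = c(1, 5, 3, 2, 4, 3))
  colnames(m) <- paste0("c", 1:6)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(normcounts = m),
    colData = S4Vectors::DataFrame(cluster = rep(c("A", "B"), each = 3),
                                   row.names = colnames(m)))
}

test_that("cluster profiles give exact means and SEMs", {
  prof <- clusterProfiles(tiny_se())
  expect_equal(unname(prof$mean["const", ]), c(4, 4))
  expect_equal(unname(prof$sem["const", ]), c(0, 0))
  expect_equal(unname(prof$mean["up_inA", ]), c(8, 2))
  ## 2-cell cluster {2, 4}: mean 3, SEM = sd/sqrt(2) = sqrt(2)/sqrt(2) = 1
  m2 <- matrix(c(2, 4, 7, 7), 1, dimnames = list("g", NULL))
  se2 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(x = m2),
    colData = S4Vectors::DataFrame(cluster = c("p", "p", "q", "q")))
  p2 <- clusterProfiles(se2)
  expect_equal(unname(p2$mean["g", "p"]), 3)
  expect_equal(unname(p2$sem["g", "p"]), 1)
  ## singleton cluster flagged
  se1 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(x = matrix(1:4, 2)),
    colData = S4Vectors::DataFrame(cluster = c("a", "b")))
  expect_warning(clusterProfiles(se1), "size 1")
})

test_that("profiles match a brute-force group-by on random data", {
  set.seed(41)
  m <- matrix(rpois(100 * 20, 5), nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:100)))
  cl <- sample(c("x", "y", "z"), 100, replace = TRUE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(n = m), colData = S4Vectors::DataFrame(cluster = cl))
  prof <- clusterProfiles(se)
  for (k in c("x", "y", "z")) {
    sub <- m[, cl == k, drop = FALSE]
    expect_equal(unname(prof$mean[, k]), unname(rowMeans(sub)))
    expect_equal(unname(prof$sem[, k]),
                 unname(apply(sub, 1, sd) / sqrt(ncol(sub))))
  }
})

test_that("log2 normalization is zero for flat genes, +2 for 4x enrichment", {
  se <- tiny_se()
  prof <- clusterProfiles(se)
  lg <- normalizeLog2(se, prof, pseudocount = 0)
  expect_equal(unname(lg["const", ]), c(0, 0))
  ## up_inA: cluster A mean 8, baseline (all cells) 5
  expect_equal(unname(lg["up_inA", "A"]), log2(8 / 5))
  ## exact 4x case
  m <- matrix(c(8, 8, 2, 2, 2, 2, 2, 2), 1, dimnames = list("g", NULL))
  se4 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(x = m),
    colData = S4Vectors::DataFrame(cluster = rep(c("hi", "lo"), c(2, 6))))
  lg4 <- normalizeLog2(se4, clusterProfiles(se4), pseudocount = 0,
                       baseline_cells = 3:8)   # baseline mean 2
  expect_equal(unname(lg4["g", "hi"]), 2)
  ## subset baseline equal to all cells coincides with the whole-set one
  lg_sub <- normalizeLog2(se, prof, baseline_cells = seq_len(6),
                          pseudocount = 0)
  expect_equal(lg, lg_sub)
})

test_that("n-SEM ranks genes by their least-noisy cluster", {
  se <- tiny_se()
  prof <- clusterProfiles(se)
  lg <- normalizeLog2(se, prof)
  ord <- nSemOrder(prof, attr(lg, "baseline_mean"))
  expect_equal(ord$gene[1], "const")          # SEM 0 ranks first
  expect_equal(ord$n_sem[1], 0)
  ## agreement with an explicit min over clusters on random profiles
  set.seed(42)
  m <- matrix(rpois(300, 6) + 1, nrow = 15,
              dimnames = list(paste0("g", 1:15), NULL))
  cl <- rep(c("a", "b"), each = 10)
  se_r <- SummarizedExperiment::SummarizedExperiment(
    assays = list(x = m), colData = S4Vectors::DataFrame(cluster = cl))
  pr <- clusterProfiles(se_r)
  base <- rowMeans(m)
  eps <- 0.1 * min(pr$mean[pr$mean > 0])
  byhand <- apply(pr$sem / (base + eps), 1, min)
  ord_r <- nSemOrder(pr, base)
  expect_equal(ord_r$gene, names(sort(byhand)))
})

test_that("summed scores add log ratios over present signature genes", {
  lg <- matrix(0, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
  expect_equal(as.vector(summedScore(lg, c("g1", "g2"))), c(0, 0))
  lg["g1", "A"] <- 1; lg["g2", "A"] <- 2
  sc <- summedScore(lg, c("g1", "g2", "absent"))
  expect_equal(unname(sc["A"]), 3)
  expect_equal(attr(sc, "n_genes_used"), 2)
  expect_equal(attr(sc, "n_genes_dropped"), 1)
  expect_error(summedScore(lg, c("nope1", "nope2")), "no signature gene")
})

test_that("scores are invariant to gene and cell order", {
  se <- generateExpression(n_cells_per_cluster = 30, n_genes = 100,
    planted = list(list(genes = 1:10, cluster = "cluster_1",
                        log2_fold = 1.5)), seed = 43)
  sig <- sprintf("gene_%04d", 1:10)
  score1 <- summedScore(normalizeLog2(se, clusterProfiles(se)), sig)
  perm_g <- sample(nrow(se)); perm_c <- sample(ncol(se))
  se_p <- se[perm_g, perm_c]
  score2 <- summedScore(normalizeLog2(se_p, clusterProfiles(se_p)), sig)
  expect_equal(as.vector(score1), as.vector(score2[names(score1)]))
  expect_equal(summedScore(normalizeLog2(se, clusterProfiles(se)),
                           sample(sig)), score1)
})

test_that("planted signatures stand out against the random-gene-set null", {
  se <- generateExpression(n_cells_per_cluster = 50, n_genes = 300,
    planted = list(list(genes = 1:25, cluster = "cluster_2",
                        log2_fold = 2)), seed = 44)
  lg <- normalizeLog2(se, clusterProfiles(se))
  planted_genes <- sprintf("gene_%04d", 1:25)
  obs <- summedScore(lg, planted_genes)["cluster_2"]
  set.seed(45)
  null <- replicate(300, {
    summedScore(lg, sample(setdiff(rownames(lg), planted_genes),
                           25))["cluster_2"]
  })
  expect_gt(obs, quantile(null, 0.99))
  ## a uniformly expressed gene set scores inside the null band
  flat <- summedScore(lg, sample(setdiff(rownames(lg), planted_genes), 25))
  expect_lt(abs(flat["cluster_2"] - mean(null)), 3 * sd(null))
})

test_that("overlap counts shared genes with optional case folding", {
  expect_equal(signatureOverlap(c("a", "b"), c("c", "d")), 0)
  expect_equal(signatureOverlap(letters[1:7], letters[1:7]), 7)
  expect_equal(signatureOverlap(c("Mcm2", "Pcna"), c("PCNA", "TOP2A")), 1)
  expect_equal(signatureOverlap(c("Mcm2", "Pcna"), c("PCNA", "TOP2A"),
                                ignore_case = FALSE), 0)
  expect_equal(signatureOverlap(list(genes = c("x", "y")),
                                list(genes = c("y", "z"))), 1)
})

test_that("scoreSignatures assembles a tidy per-cluster table", {
  se <- generateExpression(n_cells_per_cluster = 30, n_genes = 120,
    planted = list(list(genes = 1:15, cluster = "cluster_3",
                        log2_fold = 2)), seed = 46)
  tab <- scoreSignatures(se, list(planted = sprintf("gene_%04d", 1:15),
                                  random = sprintf("gene_%04d", 50:64)))
  expect_equal(nrow(tab), 8)   # 2 signatures x 4 clusters
  best <- tab[tab$signature == "planted", ]
  expect_equal(best$cluster[which.max(best$score)], "cluster_3")
})
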