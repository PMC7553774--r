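test_that("degenerate arrest probabilities give the forced outcomes", {
  r1 <- simulateClone(StageModelParams(s = 1, variant = "founder_may_arrest"),
                      seed = 1)
  expect_equal(r1$size, 1)
  expect_equal(r1$stop_cycle, 1L)
  r2 <- simulateClone(StageModelParams(s = 1, variant = "founder_divides"),
                      seed = 1)
  expect_equal(r2$size, 2)
  expect_equal(r2$stop_cycle, 1L)
  expect_error(StageModelParams(s = 1.2), "probability")
  expect_error(StageModelParams(s = 0.5, stages = 0), "stages")
})

test_that("closed-form clone-size pmf matches hand enumeration", {
  ## founder may arrest: P(1) = s; P(2) = (1-s)*s^2 (divide, both arrest)
  expect_equal(cloneSizePmf(1, 0.5), 0.5)
  expect_equal(cloneSizePmf(2, 0.5), 0.125)
  ## n = 3: two 3-leaf binary trees, 2 * s^3 (1-s)^2
  expect_equal(cloneSizePmf(3, 0.56), 2 * 0.56^3 * 0.44^2, tolerance = 1e-12)
  ## forced first division: convolution of two subtrees
  expect_equal(cloneSizePmf(1, 0.7, "founder_divides"), 0)
  expect_equal(cloneSizePmf(2, 0.7, "founder_divides"), 0.49)
  expect_error(cloneSizePmf(5, 0.4), "improper")
})

test_that("pmf is a proper distribution and has the closed-form mean", {
  for (s in c(0.51, 0.56, 0.7)) {
    n <- seq_len(1e6)
    p <- cloneSizePmf(n, s)
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
  ## subtree mean s/(2s-1); with the forced division, twice that
  n <- seq_len(2e5)
  expect_equal(sum(n * cloneSizePmf(n, 0.6)), 0.6 / 0.2, tolerance = 1e-6)
  expect_equal(sum(n * cloneSizePmf(n, 0.6, "founder_divides")), 2 * 0.6 / 0.2,
               tolerance = 1e-6)
})

test_that("extinction recursion reproduces hand-computed generations", {
  expect_equal(extinctionByGeneration(0.56, 1,
                                      variant = "founder_may_arrest")[1], 0.56)
  expect_equal(extinctionByGeneration(0.56, 1)[1], 0.56^2)
  q <- extinctionByGeneration(0.6, 20, variant = "founder_may_arrest")
  expect_equal(which(q >= 0.95)[1], 8L)
  expect_true(all(diff(q) >= 0))
  ## non-decreasing in s at fixed horizon
  e <- vapply(seq(0.5, 0.9, 0.05),
              function(s) extinctionByGeneration(s, 30)[30], numeric(1))
  expect_true(all(diff(e) >= 0))
})

test_that("Monte Carlo size distribution matches the analytic pmf", {
  ## chi-square against the closed form, sizes pooled to expected >= 5
  for (s in c(0.53, 0.56, 0.7)) {
    res <- simulateClones(StageModelParams(s = s,
                                           variant = "founder_may_arrest"),
                          50000, seed = round(1000 * s), horizon = 500)
    n_max <- 200
    p <- cloneSizePmf(seq_len(n_max), s)
    p <- c(p, 1 - sum(p))
    obs <- tabulate(pmin(res$size, n_max + 1), nbins = n_max + 1)
    keep <- which(50000 * p >= 5)
    pool_obs <- c(obs[keep], sum(obs[-keep]))
    pool_p <- c(p[keep], 1 - sum(p[keep]))
    valid <- pool_p > 0
    chi <- suppressWarnings(
      stats::chisq.test(pool_obs[valid], p = pool_p[valid] / sum(pool_p[valid])))
    expect_gt(chi$p.value, 0.001)
  }
})

test_that("Monte Carlo arrest fractions track the extinction recursion", {
  for (v in c("founder_divides", "founder_may_arrest")) {
    n <- 50000
    res <- simulateClones(StageModelParams(s = 0.56, variant = v), n,
                          seed = 5)
    q <- extinctionByGeneration(0.56, 30, variant = v)
    for (g in c(3, 10, 30)) {
      frac <- mean(!is.na(res$stop_cycle) & res$stop_cycle <= g)
      se <- sqrt(q[g] * (1 - q[g]) / n)
      expect_lt(abs(frac - q[g]), 3 * se + 1e-9)
    }
  }
})

test_that("arrest quantile cycles agree with the analytic oracle", {
  expect_equal(
    as.integer(arrestQuantileCycles(
      StageModelParams(s = 1, variant = "founder_may_arrest"), 0.99,
      n_sims = 1000, seed = 1)), 1L)
  got <- arrestQuantileCycles(
    StageModelParams(s = 0.6, variant = "founder_may_arrest"), 0.95,
    n_sims = 20000, seed = 2)
  expect_equal(as.integer(got), 8L)
  ## subcritical s with quantile near 1 is unattainable
  expect_warning(
    out <- arrestQuantileCycles(StageModelParams(s = 0.45), 0.999,
                                n_sims = 1000, seed = 3, max_cycles = 60),
    "unattainable")
  expect_true(is.na(out))
})

test_that("bisection threshold search matches the recursion root", {
  root99 <- uniroot(function(s) extinctionByGeneration(s, 30)[30] - 0.99,
                    c(0.5, 0.9), tol = 1e-6)$root
  est <- minArrestProb(stages = 1, target_fraction = 0.99, n_sims = 5000,
                       seed = 4)
  expect_lt(abs(est - root99), 0.02)
  expect_equal(minArrestProb(stages = 1, target_fraction = 0.9,
                             horizon = Inf), 0.5)
})

test_that("arrest fraction rises and sizes shrink as s grows", {
  stats_at <- function(s) {
    res <- simulateClones(StageModelParams(s = s), 10000, seed = 50 + s * 100)
    c(frac = mean(!res$censored), mean = mean(res$size),
      med = median(res$size))
  }
  grid <- t(vapply(c(0.55, 0.65, 0.8, 0.95), stats_at, numeric(3)))
  expect_true(all(diff(grid[, "frac"]) >= 0))
  expect_true(all(diff(grid[, "mean"]) < 0))
  expect_true(all(diff(grid[, "med"]) <= 0))
})

test_that("tail of the near-critical law has exponent 3/2", {
  expect_equal(tailExponent(function(n) cloneSizePmf(n, 0.5), c(100, 1000)),
               1.5, tolerance = 0.02)
  ## Catalan ratio asymptotics: p(n+1)/p(n) -> 4 s (1-s) (n/(n+1))^{3/2}
  n <- c(1e3, 1e4, 1e5)
  ratio <- cloneSizePmf(n + 1, 0.5) / cloneSizePmf(n, 0.5)
  expect_equal(ratio, (n / (n + 1))^1.5, tolerance = 1e-4)
  ## simulated histogram recovers it too
  res <- simulateClones(StageModelParams(s = 0.51,
                                         variant = "founder_may_arrest"),
                        1e5, seed = 6, horizon = 400)
  d <- SizeDistribution(res$size)
  expect_equal(tailExponent(d, c(4, 100)), 1.5, tolerance = 0.1)
})

test_that("truncation removes small clones and nothing else", {
  d <- SizeDistribution(rep(c(1, 5, 50), c(10, 5, 1)))
  expect_equal(truncateDistribution(d, 0), d)
  t5 <- truncateDistribution(d, 5)
  expect_equal(t5@sizes, c(5L, 50L))
  expect_equal(t5@counts, c(5L, 1L))
  expect_equal(length(t5), 6L)
  expect_warning(empty <- truncateDistribution(d, 100), "empty")
  expect_equal(length(empty), 0L)
  ## scale-free: fitted exponent unchanged under truncation thresholds
  pmf <- function(n) cloneSizePmf(n, 0.5)
  base <- tailExponent(pmf, c(100, 1000))
  for (thr in c(1, 10, 100))
    expect_equal(tailExponent(pmf, c(max(thr, 10) * 2, 2000)), base,
                 tolerance = 0.05)
})

test_that("identical seeds give identical clone streams", {
  a <- simulateClones(StageModelParams(s = 0.55, stages = 2), 2000, seed = 9)
  b <- simulateClones(StageModelParams(s = 0.55, stages = 2), 2000, seed = 9)
  expect_identical(a, b)
  expect_false(identical(
    a, simulateClones(StageModelParams(s = 0.55, stages = 2), 2000,
                      seed = 10)))
})

test_that("median sweep flags arrest and observability regions", {
  sw <- medianSizeSweep(stages_list = c(1, 3), prob_grid = c(0.56, 0.66),
                        threshold_grid = c(0, 10), n_sims = 5000, seed = 11)
  expect_true(all(sw$median >= sw$threshold, na.rm = TRUE))
  expect_true(all(sw$arrest_fraction >= 0 & sw$arrest_fraction <= 1))
  k3 <- sw[sw$stages == 3 & sw$s == 0.66 & sw$threshold == 0, ]
  expect_equal(k3$arrest_fraction, 0.99, tolerance = 0.015)
  expect_false(k3$flag_arrest)
  ## a single stage at a target median of 1 is trivially enough
  expect_equal(as.integer(minStagesForMedian(1, prob_grid = c(0.6, 0.8),
                                             threshold_grid = 0,
                                             n_sims = 2000, seed = 12)), 1L)
})
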