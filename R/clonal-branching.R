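## Cell-autonomous arrest models: Galton-Watson branching with per-cycle
## stage transitions. The proliferating population is a multitype branching
## process with mean-matrix eigenvalue 2(1-s): extinction of proliferation is
## certain iff s >= 1/2, whatever the stage count.

.stageEnsemble <- function(variant, s, k, n, horizon, cap = 1e7) {
  ## Vectorised over clones: N[i, j] = proliferating cells of clone i in
  ## stage j. Exact because cells within a clone are exchangeable.
  N <- matrix(0, n, k)
  N[, 1] <- 1
  arrested <- numeric(n)
  stop_cycle <- rep(NA_integer_, n)
  alive <- rep(TRUE, n)
  supercritical <- FALSE
  for (g in seq_len(horizon)) {
    idx <- which(alive)
    if (!length(idx)) break
    Na <- N[idx, , drop = FALSE]
    if (variant == "founder_divides") {
      ## divide first, then each daughter tests a stage advance
      adv_prev <- numeric(length(idx))
      for (j in seq_len(k)) {
        off <- 2 * Na[, j]
        adv <- rbinom(length(idx), off, s)
        Na[, j] <- off - adv + adv_prev
        adv_prev <- adv
      }
      arrested[idx] <- arrested[idx] + adv_prev
    } else {
      ## test first (arrest forbids division), survivors divide
      adv_prev <- numeric(length(idx))
      for (j in seq_len(k)) {
        adv <- rbinom(length(idx), Na[, j], s)
        Na[, j] <- 2 * (Na[, j] - adv + adv_prev)
        adv_prev <- adv
      }
      arrested[idx] <- arrested[idx] + adv_prev
    }
    N[idx, ] <- Na
    tot <- rowSums(Na)
    done <- idx[tot == 0]
    stop_cycle[done] <- g
    alive[done] <- FALSE
    if (any(tot + arrested[idx] > cap)) {
      supercritical <- TRUE
      over <- idx[tot + arrested[idx] > cap]
      alive[over] <- FALSE
    }
  }
  if (supercritical)
    warning("clone exceeded ", format(cap, scientific = TRUE),
            " cells; run looks supercritical (s < 0.5?) and was capped")
  dividing <- rowSums(N)
  data.frame(size = arrested + dividing, stop_cycle = stop_cycle,
             censored = is.na(stop_cycle), dividing = dividing)
}

#' Simulate one clone under the stage model
#'
#' Runs a single clone from one founder cell until all proliferation has
#' ceased or the cycle horizon is reached.
#'
#' @param params a \linkS4class{StageModelParams}.
#' @param seed optional integer seed.
#' @param trajectory if TRUE, attach the per-cycle (dividing, arrested)
#'   trajectory as an attribute.
#' @return A one-row data.frame with columns \code{size} (final cell count),
#'   \code{stop_cycle} (cycle at which the last proliferating cell arrested;
#'   NA if censored at the horizon) and \code{censored}.
#' @examples
#' simulateClone(StageModelParams(s = 0.56), seed = 1)
#' @export
simulateClone <- function(params, seed = NULL, trajectory = FALSE) {
  stopifnot(is(params, "StageModelParams"))
  validObject(params)
  if (!is.null(seed)) set.seed(seed)
  k <- params@stages
  N <- numeric(k); N[1] <- 1
  arrested <- 0
  traj <- if (trajectory) matrix(0, 0, 2,
    dimnames = list(NULL, c("dividing", "arrested")))
  stop_cycle <- NA_integer_
  for (g in seq_len(params@horizon)) {
    if (params@variant == "founder_divides") {
      adv_prev <- 0
      for (j in seq_len(k)) {
        off <- 2 * N[j]
        adv <- rbinom(1, off, params@s)
        N[j] <- off - adv + adv_prev
        adv_prev <- adv
      }
      arrested <- arrested + adv_prev
    } else {
      adv_prev <- 0
      for (j in seq_len(k)) {
        adv <- rbinom(1, N[j], params@s)
        N[j] <- 2 * (N[j] - adv + adv_prev)
        adv_prev <- adv
      }
      arrested <- arrested + adv_prev
    }
    if (trajectory) traj <- rbind(traj, c(sum(N), arrested))
    if (sum(N) == 0) { stop_cycle <- g; break }
  }
  out <- data.frame(size = arrested + sum(N), stop_cycle = stop_cycle,
                    censored = is.na(stop_cycle))
  if (trajectory) attr(out, "trajectory") <- traj
  out
}

#' Simulate an ensemble of clones
#'
#' @param params a \linkS4class{StageModelParams}.
#' @param n_clones number of independent clones.
#' @param seed optional integer seed.
#' @param horizon optional override of \code{params@horizon} (e.g. to lift
#'   the cap when measuring stopping times).
#' @return data.frame with one row per clone: \code{size},
#'   \code{stop_cycle} (NA when censored), \code{censored}, \code{dividing}
#'   (cells still proliferating at the end).
#' @examples
#' res <- simulateClones(StageModelParams(s = 0.56), 2000, seed = 1)
#' mean(!res$censored)   # fraction fully arrested within 30 cycles
#' @export
simulateClones <- function(params, n_clones, seed = NULL, horizon = NULL) {
  stopifnot(is(params, "StageModelParams"), n_clones >= 1)
  validObject(params)
  if (!is.null(seed)) set.seed(seed)
  h <- if (is.null(horizon)) params@horizon else as.integer(horizon)
  .stageEnsemble(params@variant, params@s, params@stages, n_clones, h)
}

.logCatalan <- function(m) {
  ## log Catalan(m) = log C(2m, m) - log(m + 1), via log-gamma
  lgamma(2 * m + 1) - 2 * lgamma(m + 1) - log(m + 1)
}

#' Exact clone-size distribution of the single-stage model
#'
#' Total-progeny law of the one-hit arrest model. With arrest probability
#' \eqn{s} per daughter per cycle, the final clone is a random binary tree
#' whose leaves are arrested cells, giving
#' \deqn{P(N = n) = C_{n-1}\, s^n (1-s)^{n-1}}
#' for the \code{founder_may_arrest} variant (with \eqn{C_m} the Catalan
#' numbers), and the convolution of two such trees,
#' \eqn{P(N = n) = C_{n-1} s^n (1-s)^{n-2}} for \eqn{n \ge 2}, when the
#' founder's first division is guaranteed (\code{founder_divides}). For
#' \eqn{s} near 1/2 the law has an \eqn{n^{-3/2}} power-law body -- the
#' reason truncating simulated distributions does not change their shape.
#'
#' @param n vector of clone sizes (>= 1).
#' @param s per-cycle arrest probability; must be >= 0.5 (otherwise the
#'   distribution is improper: some clones never stop growing).
#' @param variant model variant.
#' @param log if TRUE return log-probabilities.
#' @return numeric vector of (log-)probabilities.
#' @examples
#' cloneSizePmf(1:3, s = 0.5)
#' sum(cloneSizePmf(1:2000, s = 0.56))  # ~1
#' @export
cloneSizePmf <- function(n, s,
                         variant = c("founder_may_arrest", "founder_divides"),
                         log = FALSE) {
  variant <- match.arg(variant)
  stopifnot(all(n >= 1), length(s) == 1)
  if (s < 0.5)
    stop("s < 0.5: subcritical arrest, some clones never stop growing ",
         "and the size distribution is improper")
  n <- as.numeric(n)
  if (variant == "founder_may_arrest") {
    lp <- .logCatalan(n - 1) + n * base::log(s) +
      ifelse(n == 1, 0, (n - 1) * base::log1p(-s))
  } else {
    lp <- ifelse(n < 2, -Inf,
      .logCatalan(n - 1) + n * base::log(s) +
        ifelse(n == 2, 0, (n - 2) * base::log1p(-s)))
  }
  if (s == 1) lp[!(n == if (variant == "founder_may_arrest") 1 else 2)] <- -Inf
  if (log) lp else exp(lp)
}

#' Probability that all proliferation has ceased by a given generation
#'
#' Analytic companion of \code{\link{simulateClones}}: iterates the
#' offspring generating-function recursion for the probability that every
#' cell of a clone has arrested within \code{generations} cycles. For one
#' stage and \code{founder_may_arrest} this is the classical
#' \eqn{q_g = s + (1-s) q_{g-1}^2}; the multi-stage and founder-divides
#' forms iterate the per-stage system
#' \eqn{e_g(j) = [s\,u + (1-s) e_{g-1}(j)]^2} with \eqn{u = 1} at the last
#' stage and \eqn{u = e_{g-1}(j+1)} below it.
#'
#' @param s per-cycle stage-transition probability.
#' @param generations number of generations to iterate.
#' @param stages stage count.
#' @param variant model variant.
#' @return numeric vector of length \code{generations}: extinction
#'   probability by each generation (non-decreasing).
#' @examples
#' extinctionByGeneration(0.56, 5)[1]                 # s^2 = 0.3136
#' which(extinctionByGeneration(0.6, 20,
#'   variant = "founder_may_arrest") >= 0.95)[1]      # 8
#' @export
extinctionByGeneration <- function(s, generations, stages = 1L,
                                   variant = c("founder_divides",
                                               "founder_may_arrest")) {
  variant <- match.arg(variant)
  stopifnot(s >= 0, s <= 1, generations >= 1, stages >= 1)
  k <- as.integer(stages)
  out <- numeric(generations)
  if (variant == "founder_divides") {
    e <- numeric(k)
    for (g in seq_len(generations)) {
      up <- c(e[-1], 1)            # advance target: next stage, or arrest
      e <- (s * up + (1 - s) * e)^2
      out[g] <- e[1]
    }
  } else {
    a <- numeric(k)
    for (g in seq_len(generations)) {
      up <- c(a[-1]^2, 1)          # advancing non-final cells still divide
      a <- s * up + (1 - s) * a^2
      out[g] <- a[1]
    }
  }
  out
}

#' Cycles needed for a given fraction of clones to arrest
#'
#' Smallest cycle count by which at least \code{quantile} of simulated
#' clones have fully arrested, with the horizon lifted to \code{max_cycles}.
#'
#' @param params a \linkS4class{StageModelParams} (its \code{horizon} is
#'   ignored here).
#' @param quantile target arrest fraction in (0, 1).
#' @param n_sims ensemble size (>= 1000).
#' @param seed optional integer seed.
#' @param max_cycles hard cap; clones still proliferating then are censored.
#' @return integer cycle count, with attribute \code{censored_fraction}.
#'   NA with a warning if the quantile is unattainable (e.g. s < 0.5).
#' @examples
#' arrestQuantileCycles(StageModelParams(s = 0.6), 0.95, 5000, seed = 1)
#' @export
arrestQuantileCycles <- function(params, quantile, n_sims = 20000L,
                                 seed = NULL, max_cycles = 500L) {
  stopifnot(is(params, "StageModelParams"), quantile > 0, quantile < 1,
            n_sims >= 1000)
  if (!is.null(seed)) set.seed(seed)
  res <- .stageEnsemble(params@variant, params@s, params@stages, n_sims,
                        max_cycles)
  cens <- mean(res$censored)
  if (1 - cens < quantile) {
    warning("quantile ", quantile, " unattainable: only ",
            signif(1 - cens, 4), " of clones arrested within ", max_cycles,
            " cycles")
    out <- NA_integer_
  } else {
    ## censored clones count as "not yet arrested" at every cycle
    cyc <- sort(res$stop_cycle[!res$censored])
    out <- cyc[which(seq_along(cyc) / n_sims >= quantile)[1]]
  }
  attr(out, "censored_fraction") <- cens
  out
}

#' Minimal arrest probability for a target arrest fraction at the horizon
#'
#' Bisection over the per-stage transition probability \code{s}; each
#' evaluation is a fresh Monte Carlo ensemble. Returns the smallest \code{s}
#' whose arrest fraction at the horizon reaches \code{target_fraction},
#' to within \code{tol}.
#'
#' @param stages stage count.
#' @param target_fraction required fraction of clones fully arrested by the
#'   horizon, in (0, 1).
#' @param horizon cycle horizon (default 30). \code{Inf} asks for eventual
#'   arrest, which for any stage count requires \code{s >= 0.5} (the
#'   proliferating population's mean growth factor is \code{2(1-s)}).
#' @param n_sims clones per bisection evaluation (>= 20000 recommended).
#' @param seed optional integer seed; evaluation i uses \code{seed + i}.
#' @param variant model variant.
#' @param tol bisection half-width on s (default 0.005).
#' @return estimated threshold s*, with attribute \code{achieved_fraction}.
#' @examples
#' \donttest{minArrestProb(stages = 1, target_fraction = 0.99, seed = 1)}
#' @export
minArrestProb <- function(stages = 1L, target_fraction = 0.99, horizon = 30L,
                          n_sims = 20000L, seed = NULL,
                          variant = c("founder_divides", "founder_may_arrest"),
                          tol = 0.005) {
  variant <- match.arg(variant)
  stopifnot(target_fraction > 0, target_fraction < 1)
  if (is.infinite(horizon)) return(0.5)
  frac <- function(s, i) {
    if (!is.null(seed)) set.seed(seed + i)
    res <- .stageEnsemble(variant, s, as.integer(stages), n_sims,
                          as.integer(horizon))
    mean(!res$censored)
  }
  lo <- 0.30; hi <- 1.0
  if (frac(hi, 0L) < target_fraction)
    stop("target arrest fraction unattainable even at s = 1")
  i <- 1L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (frac(mid, i) >= target_fraction) hi <- mid else lo <- mid
    i <- i + 1L
  }
  out <- (lo + hi) / 2
  attr(out, "achieved_fraction") <- frac(out, i)
  out
}

#' Mean clone size at the horizon
#'
#' Ensemble mean of clone sizes at the cycle horizon; clones still
#' proliferating contribute their current size.
#'
#' @param params a \linkS4class{StageModelParams}.
#' @param n_sims ensemble size (>= 10000 recommended).
#' @param seed optional integer seed.
#' @return mean cells per clone, with attribute \code{arrest_fraction}.
#' @examples
#' \donttest{meanSizeAtHorizon(StageModelParams(s = 0.53), 20000, seed = 1)}
#' @export
meanSizeAtHorizon <- function(params, n_sims = 20000L, seed = NULL) {
  stopifnot(is(params, "StageModelParams"))
  if (!is.null(seed)) set.seed(seed)
  res <- .stageEnsemble(params@variant, params@s, params@stages, n_sims,
                        params@horizon)
  out <- mean(res$size)
  attr(out, "arrest_fraction") <- mean(!res$censored)
  out
}

#' Power-law exponent of a clone-size distribution tail
#'
#' Least-squares slope of log probability against log size over
#' \code{fit_range}, returned as a positive exponent. Near criticality the
#' single-stage law decays as \eqn{n^{-3/2}}, which is why its truncated
#' versions all look alike.
#'
#' @param x either a \linkS4class{SizeDistribution} (empirical) or a
#'   function mapping integer sizes to probabilities (e.g. a closure over
#'   \code{\link{cloneSizePmf}}).
#' @param fit_range length-2 numeric range of sizes to fit over; at least 10
#'   distinct sizes with positive probability must fall inside.
#' @return positive exponent estimate.
#' @examples
#' tailExponent(function(n) cloneSizePmf(n, s = 0.5), c(100, 1000))  # ~1.5
#' @export
tailExponent <- function(x, fit_range) {
  stopifnot(length(fit_range) == 2, fit_range[1] < fit_range[2])
  if (is(x, "SizeDistribution")) {
    keep <- x@sizes >= fit_range[1] & x@sizes <= fit_range[2] & x@counts > 0
    sizes <- x@sizes[keep]
    p <- x@counts[keep] / x@n_clones
  } else if (is.function(x)) {
    sizes <- seq(ceiling(fit_range[1]), floor(fit_range[2]))
    p <- x(sizes)
    keep <- p > 0
    sizes <- sizes[keep]; p <- p[keep]
  } else stop("x must be a SizeDistribution or a pmf function")
  if (length(sizes) < 10)
    stop("need at least 10 sizes with positive probability in fit_range")
  fit <- stats::lm(log(p) ~ log(sizes))
  -unname(coef(fit)[2])
}

#' Truncate a size distribution at an observability threshold
#'
#' Removes all clones smaller than \code{threshold}; the shape above the
#' threshold is untouched.
#'
#' @param dist a \linkS4class{SizeDistribution}.
#' @param threshold minimum observable clone size (>= 0).
#' @return a new \linkS4class{SizeDistribution}.
#' @examples
#' d <- SizeDistribution(c(1, 1, 5, 5, 50))
#' truncateDistribution(d, 5)
#' @export
truncateDistribution <- function(dist, threshold) {
  stopifnot(is(dist, "SizeDistribution"), threshold >= 0)
  keep <- dist@sizes >= threshold
  if (!any(keep))
    warning("threshold ", threshold, " exceeds the largest clone size; ",
            "the truncated distribution is empty")
  new("SizeDistribution", sizes = dist@sizes[keep], counts = dist@counts[keep],
      n_clones = as.integer(sum(dist@counts[keep])),
      truncation_threshold = as.numeric(threshold))
}

#' Median clone size over a (stages, probability, truncation) grid
#'
#' For each combination, simulates an ensemble at the horizon, applies the
#' truncation threshold, and records the truncated median and the arrest
#' fraction. Cells are flagged where fewer than 95% of clones arrest
#' (\code{flag_arrest}) and where the median is less than twice the
#' threshold (\code{flag_observability}) -- i.e. where the threshold would
#' be inconsistent with the observation that median nevi are well above the
#' smallest observable ones.
#'
#' @param stages_list integer vector of stage counts.
#' @param prob_grid numeric vector of per-stage transition probabilities.
#' @param threshold_grid numeric vector of truncation thresholds.
#' @param horizon cycle horizon.
#' @param n_sims clones per (stages, probability) cell.
#' @param seed optional integer seed; cell i uses \code{seed + i}.
#' @param variant model variant.
#' @return data.frame with columns stages, s, threshold, median,
#'   arrest_fraction, n_retained, flag_arrest, flag_observability.
#' @export
medianSizeSweep <- function(stages_list, prob_grid, threshold_grid,
                            horizon = 30L, n_sims = 20000L, seed = NULL,
                            variant = c("founder_divides",
                                        "founder_may_arrest")) {
  variant <- match.arg(variant)
  stopifnot(length(stages_list) > 0, length(prob_grid) > 0,
            length(threshold_grid) > 0)
  rows <- list(); i <- 0L
  for (k in stages_list) for (s in prob_grid) {
    i <- i + 1L
    if (!is.null(seed)) set.seed(seed + i)
    res <- .stageEnsemble(variant, s, as.integer(k), n_sims,
                          as.integer(horizon))
    af <- mean(!res$censored)
    for (thr in threshold_grid) {
      sz <- res$size[res$size >= thr]
      med <- if (length(sz)) stats::median(sz) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        stages = k, s = s, threshold = thr, median = med,
        arrest_fraction = af, n_retained = length(sz),
        flag_arrest = af < 0.95,
        flag_observability = !is.na(med) && med < 2 * thr)
    }
  }
  do.call(rbind, rows)
}

#' Minimum stage count for a target truncated median clone size
#'
#' Smallest number of sequential stages for which some (probability,
#' threshold) combination simultaneously (i) arrests at least
#' \code{arrest_target} of clones by the horizon, (ii) keeps the truncated
#' median at least twice the threshold, and (iii) reaches a truncated median
#' of \code{target_median} cells.
#'
#' @param target_median required median clone size (>= 1).
#' @param arrest_target required arrest fraction (0.95 or 0.99).
#' @param horizon cycle horizon.
#' @param prob_grid probabilities swept per stage count (default
#'   \code{seq(0.5, 0.98, 0.02)}).
#' @param threshold_grid truncation thresholds swept (default a doubling
#'   grid from 0 to 1600 cells).
#' @param max_stages largest stage count tried (default 8).
#' @param n_sims clones per sweep cell.
#' @param seed optional integer seed.
#' @param variant model variant.
#' @return integer stage count (NA with a warning if unreachable), with the
#'   qualifying sweep row as attribute \code{best_cell}.
#' @export
minStagesForMedian <- function(target_median, arrest_target = 0.95,
                               horizon = 30L,
                               prob_grid = seq(0.5, 0.98, by = 0.02),
                               threshold_grid = c(0, 12, 25, 50, 100, 200,
                                                  400, 800, 1600),
                               max_stages = 8L, n_sims = 20000L, seed = NULL,
                               variant = c("founder_divides",
                                           "founder_may_arrest")) {
  variant <- match.arg(variant)
  stopifnot(target_median >= 1)
  for (k in seq_len(max_stages)) {
    sw <- medianSizeSweep(k, prob_grid, threshold_grid, horizon = horizon,
                          n_sims = n_sims,
                          seed = if (is.null(seed)) NULL else seed + 1000L * k,
                          variant = variant)
    ok <- sw$arrest_fraction >= arrest_target & !is.na(sw$median) &
      sw$median >= 2 * sw$threshold & sw$median >= target_median
    if (any(ok)) {
      out <- as.integer(k)
      attr(out, "best_cell") <- sw[which(ok)[which.max(sw$median[ok])], ]
      return(out)
    }
  }
  warning("target median ", target_median, " not reachable within ",
          max_stages, " stages")
  NA_integer_
}
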