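## Collective (renewal-control) arrest: the probability that offspring keep
## dividing falls with the number of already-arrested cells. An integral
## negative feedback -- the arrested pool never shrinks, so it integrates the
## division history and clamps the final size.

#' Renewal probability under arrested-cell feedback
#'
#' @param params a \linkS4class{FeedbackParams}.
#' @param arrested arrested-cell count(s), >= 0.
#' @return \eqn{p = p_{max} K^h / (K^h + A^h)}.
#' @examples
#' renewalProbability(FeedbackParams(), 50)   # 0.5
#' renewalProbability(FeedbackParams(), 150)  # 0.25
#' @export
renewalProbability <- function(params, arrested) {
  stopifnot(is(params, "FeedbackParams"), all(arrested >= 0))
  K <- params@half_max; h <- params@hill_coeff
  params@p_max * K^h / (K^h + arrested^h)
}

.feedbackEnsemble <- function(params, n_runs, cap = 1e6) {
  dividing <- rep(as.numeric(params@initial_dividing), n_runs)
  arrested <- numeric(n_runs)
  stop_cycle <- rep(NA_integer_, n_runs)
  for (g in seq_len(params@horizon_cycles)) {
    idx <- which(dividing > 0)
    if (!length(idx)) break
    p <- renewalProbability(params, arrested[idx])  # start-of-cycle A
    off <- 2 * dividing[idx]
    keep <- rbinom(length(idx), off, p)
    arrested[idx] <- arrested[idx] + off - keep
    dividing[idx] <- keep
    done <- idx[keep == 0]
    stop_cycle[done] <- g
    if (any(dividing[idx] + arrested[idx] > cap)) {
      warning("clone exceeded ", format(cap, scientific = TRUE),
              " cells; capped")
      dividing[idx[dividing[idx] + arrested[idx] > cap]] <- 0
    }
  }
  data.frame(final_arrested = arrested, stop_cycle = stop_cycle,
             censored = is.na(stop_cycle) & dividing > 0)
}

#' Simulate one renewal-controlled clone
#'
#' Per cycle, every dividing cell produces two offspring; each offspring
#' independently remains dividing with probability
#' \code{\link{renewalProbability}} evaluated at the start-of-cycle arrested
#' count, otherwise it permanently arrests. The run ends when no dividing
#' cells remain.
#'
#' @param params a \linkS4class{FeedbackParams}.
#' @param seed optional integer seed.
#' @return list with \code{final_arrested}, \code{stop_cycle} and a
#'   \code{trajectory} data.frame (cycle, dividing, arrested).
#' @examples
#' simulateFeedbackClone(FeedbackParams(), seed = 1)$final_arrested
#' @export
simulateFeedbackClone <- function(params, seed = NULL) {
  stopifnot(is(params, "FeedbackParams"))
  validObject(params)
  if (!is.null(seed)) set.seed(seed)
  dividing <- as.numeric(params@initial_dividing)
  arrested <- 0
  traj <- list()
  stop_cycle <- NA_integer_
  for (g in seq_len(params@horizon_cycles)) {
    p <- renewalProbability(params, arrested)
    off <- 2 * dividing
    keep <- rbinom(1, off, p)
    arrested <- arrested + off - keep
    dividing <- keep
    traj[[g]] <- data.frame(cycle = g, dividing = dividing,
                            arrested = arrested)
    if (dividing == 0) { stop_cycle <- g; break }
  }
  list(final_arrested = arrested, stop_cycle = stop_cycle,
       trajectory = do.call(rbind, traj))
}

#' Simulate an ensemble of renewal-controlled clones
#'
#' @param params a \linkS4class{FeedbackParams}.
#' @param n_runs number of independent clones.
#' @param seed optional integer seed.
#' @return data.frame with \code{final_arrested}, \code{stop_cycle},
#'   \code{censored} per clone.
#' @examples
#' res <- simulateFeedbackEnsemble(FeedbackParams(), 500, seed = 1)
#' summary(res$final_arrested)   # narrow, ~log-normal sizes
#' @export
simulateFeedbackEnsemble <- function(params, n_runs, seed = NULL) {
  stopifnot(is(params, "FeedbackParams"), n_runs >= 1)
  validObject(params)
  if (!is.null(seed)) set.seed(seed)
  .feedbackEnsemble(params, n_runs)
}

#' Mean-field ODE form of the renewal-control model
#'
#' Deterministic limit of the stochastic model:
#' \deqn{dP/dt = (2 p(A) - 1)\, r P, \qquad dA/dt = 2 (1 - p(A))\, r P}
#' with \eqn{r = \ln 2 / \code{cycle_time}}. Integration stops when the
#' dividing population P falls below 0.5 cells.
#'
#' @param params a \linkS4class{FeedbackParams}.
#' @param t_max integration horizon in time units.
#' @param tol absolute/relative integrator tolerance.
#' @return list with \code{A_final}, \code{t_stop} and the full
#'   \code{trajectory} (deSolve output: time, P, A).
#' @examples
#' solveFeedbackODE(FeedbackParams())$A_final
#' @export
solveFeedbackODE <- function(params, t_max = 200 * params@cycle_time,
                             tol = 1e-10) {
  stopifnot(is(params, "FeedbackParams"))
  r <- log(2) / params@cycle_time
  deriv <- function(t, y, parms) {
    p <- renewalProbability(params, y["A"])
    list(c(P = unname((2 * p - 1) * r * y["P"]),
           A = unname(2 * (1 - p) * r * y["P"])))
  }
  root <- function(t, y, parms) y["P"] - 0.5
  y0 <- c(P = as.numeric(params@initial_dividing), A = 0)
  times <- seq(0, t_max, length.out = 2001)
  sol <- deSolve::lsodar(y0, times, deriv, parms = NULL, rtol = tol,
                         atol = tol, rootfunc = root)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed (stiffness?); try a larger tol")
  last <- sol[nrow(sol), ]
  list(A_final = unname(last["A"]), t_stop = unname(last["time"]),
       trajectory = sol)
}

#' Deterministic mean-field map of the synchronous scheme
#'
#' Iterates the exact expectation dynamics of the per-offspring scheme:
#' per cycle \eqn{A \leftarrow A + 2(1 - p(A)) P} and
#' \eqn{P \leftarrow 2 p(A) P}. This cycle map -- not the continuous-time
#' ODE, whose per-cycle growth factor is \eqn{2^{2p-1}} rather than
#' \eqn{2p} -- is the large-\code{half_max} limit of the stochastic
#' ensemble and serves as its oracle.
#'
#' @param params a \linkS4class{FeedbackParams}.
#' @param max_cycles iteration cap.
#' @return list with \code{A_final} (final size once P < 0.5),
#'   \code{stop_cycle} and the per-cycle \code{trajectory}.
#' @examples
#' meanFieldTrajectory(FeedbackParams())$A_final
#' @export
meanFieldTrajectory <- function(params, max_cycles = 10000L) {
  stopifnot(is(params, "FeedbackParams"))
  P <- as.numeric(params@initial_dividing); A <- 0
  rows <- list()
  stop_cycle <- NA_integer_
  for (g in seq_len(max_cycles)) {
    p <- renewalProbability(params, A)
    off <- 2 * P
    A <- A + off * (1 - p)
    P <- off * p
    rows[[g]] <- data.frame(cycle = g, dividing = P, arrested = A)
    if (P < 0.5) { stop_cycle <- g; break }
  }
  list(A_final = A + P, stop_cycle = stop_cycle,
       trajectory = do.call(rbind, rows))
}

#' Robustness of the final size to parameter perturbations
#'
#' Re-runs the model under perturbed initial cell numbers and cycle times
#' and summarises the final arrested count. Because the feedback is
#' integral, the final size should barely move; rows are flagged when the
#' mean shifts by more than twice the baseline ensemble SD.
#'
#' @param params baseline \linkS4class{FeedbackParams}.
#' @param initial_dividing vector of initial dividing-cell counts to try.
#' @param cycle_time vector of cycle times to try (ODE form; a pure time
#'   rescaling, so A_final is exactly invariant).
#' @param n_runs stochastic runs per condition.
#' @param seed optional integer seed.
#' @return data.frame: condition, value, mean_final, sd_final, ode_final,
#'   flagged.
#' @export
robustnessReport <- function(params, initial_dividing = c(1L, 2L, 4L),
                             cycle_time = c(0.5, 1, 2), n_runs = 2000L,
                             seed = NULL) {
  stopifnot(is(params, "FeedbackParams"))
  if (!is.null(seed)) set.seed(seed)
  base <- .feedbackEnsemble(params, n_runs)
  base_mean <- mean(base$final_arrested)
  base_sd <- sd(base$final_arrested)
  rows <- list()
  for (n0 in initial_dividing) {
    p2 <- params; p2@initial_dividing <- as.integer(n0)
    res <- .feedbackEnsemble(p2, n_runs)
    ode <- solveFeedbackODE(p2)$A_final
    m <- mean(res$final_arrested)
    rows[[length(rows) + 1L]] <- data.frame(
      condition = "initial_dividing", value = n0, mean_final = m,
      sd_final = sd(res$final_arrested), ode_final = ode,
      flagged = abs(m - base_mean) > 2 * base_sd)
  }
  for (ct in cycle_time) {
    p2 <- params; p2@cycle_time <- as.numeric(ct)
    ode <- solveFeedbackODE(p2)$A_final
    rows[[length(rows) + 1L]] <- data.frame(
      condition = "cycle_time", value = ct, mean_final = NA_real_,
      sd_final = NA_real_, ode_final = ode,
      flagged = FALSE)
  }
  do.call(rbind, rows)
}

#' Log-normal goodness of fit for a clone-size ensemble
#'
#' Fits a log-normal by moments of the log sizes and tests normality of the
#' logs (Lilliefors/Kolmogorov-Smirnov with estimated parameters, which is
#' well defined at ensemble sizes beyond the Shapiro-Wilk limit).
#'
#' @param sizes positive clone sizes.
#' @param alpha rejection level (default 0.01).
#' @return list: \code{mu}, \code{sigma}, \code{p_value},
#'   \code{rejected} at \code{alpha}.
#' @export
logNormalFit <- function(sizes, alpha = 0.01) {
  stopifnot(all(sizes > 0))
  lx <- log(sizes)
  p <- nortest::lillie.test(lx)$p.value
  list(mu = mean(lx), sigma = sd(lx), p_value = p, rejected = p < alpha)
}
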