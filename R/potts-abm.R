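## Spatial agent-based model: a minimal Cellular Potts model (CPM) in which
## arrested cells secrete a diffusing, decaying signal that raises the
## arrest probability of dividing cells at their next division.

#' Parameters of the Cellular Potts arrest model
#'
#' A single 25 px^2 cell is seeded at the center of a square lattice. Cells
#' carry a target area inflated at one of three growth rates (redrawn at
#' each division); when the target reaches the cell's division area (drawn
#' uniformly in \code{division_area_range}) the cell splits along a randomly
#' oriented plane through its centroid. Each daughter then arrests with
#' probability \code{baseline_arrest} plus a Hill function of the secreted
#' signal concentration at its centroid. Arrested cells secrete the signal
#' at \code{secretion_rate} per pixel; the field diffuses and decays with a
#' steady-state decay length \code{sqrt(diffusion_coeff/decay_rate)} (15 px
#' at the defaults). One cell cycle corresponds to roughly 382 Monte Carlo
#' steps (MCS) at the default growth rates.
#'
#' @slot lattice_size integer edge length (default 300).
#' @slot init_area founder size in pixels (default 25).
#' @slot division_area_range numeric length-2; division target areas drawn
#'   uniformly in this range (default \[72, 80\] px^2).
#' @slot growth_rates three target-area increments (px^2 per MCS).
#' @slot contact_energies symmetric 3x3 matrix over
#'   \{medium, dividing, arrested\}.
#' @slot volume_lambda volume-constraint stiffness.
#' @slot temperature Metropolis acceptance scale.
#' @slot baseline_arrest minimum arrest probability per division (0.01).
#' @slot hill_amplitude,hill_half_max_conc,hill_coeff arrest-augmentation
#'   Hill parameters.
#' @slot diffusion_coeff,decay_rate,secretion_rate signal-field parameters.
#' @slot field_substeps explicit-Euler sub-steps per MCS.
#' @slot max_mcs MCS cap for a run.
#' @export
setClass("PottsParams",
  representation(lattice_size = "integer", init_area = "integer",
                 division_area_range = "numeric", growth_rates = "numeric",
                 contact_energies = "matrix", volume_lambda = "numeric",
                 temperature = "numeric", baseline_arrest = "numeric",
                 hill_amplitude = "numeric", hill_half_max_conc = "numeric",
                 hill_coeff = "numeric", diffusion_coeff = "numeric",
                 decay_rate = "numeric", secretion_rate = "numeric",
                 field_substeps = "integer", max_mcs = "integer"))

setValidity("PottsParams", function(object) {
  msg <- character()
  if (object@lattice_size < 20) msg <- c(msg, "lattice_size too small")
  r <- object@division_area_range
  if (length(r) != 2 || r[1] >= r[2] || r[1] <= object@init_area)
    msg <- c(msg, "division_area_range must be an increasing range above init_area")
  if (!isTRUE(all.equal(object@contact_energies,
                        t(object@contact_energies))))
    msg <- c(msg, "contact_energies must be symmetric")
  if (object@baseline_arrest < 0 || object@baseline_arrest > 1)
    msg <- c(msg, "baseline_arrest must be in [0, 1]")
  if (object@diffusion_coeff <= 0 || object@decay_rate <= 0)
    msg <- c(msg, "diffusion_coeff and decay_rate must be positive")
  if (1 / object@field_substeps *
      (4 * object@diffusion_coeff + object@decay_rate) > 1)
    msg <- c(msg, "field_substeps too few for a stable diffusion step")
  if (length(msg)) msg else TRUE
})

#' Construct Cellular Potts model parameters
#'
#' Defaults reproduce the model's stated observables: a signal decay length
#' of 15 px, a mean inter-division interval of about 382 MCS, and full
#' arrest of the clone within roughly ten generations.
#'
#' @param lattice_size lattice edge (default 300).
#' @param init_area founder pixel count.
#' @param division_area_range range of division target areas.
#' @param growth_rates three growth rates; defaults give ~382 MCS/cycle for
#'   a ~38 px^2 newborn growing to ~76 px^2.
#' @param contact_energies 3x3 symmetric matrix (medium, dividing,
#'   arrested); default J(cell, medium) = 16, J(cell, cell) = 8.
#' @param volume_lambda,temperature CPM energy/acceptance scales.
#' @param baseline_arrest minimum per-division arrest probability.
#' @param hill_amplitude,hill_half_max_conc,hill_coeff Hill augmentation of
#'   the arrest probability by the local signal.
#' @param diffusion_coeff,decay_rate defaults D = 1, k = 1/225 px^-2 so that
#'   sqrt(D/k) = 15 px.
#' @param secretion_rate signal production per arrested pixel per MCS.
#' @param field_substeps diffusion sub-steps per MCS (stability requires
#'   (4D + k)/field_substeps <= 1).
#' @param max_mcs run cap.
#' @return A \linkS4class{PottsParams} object.
#' @examples
#' PottsParams(lattice_size = 100)
#' @export
PottsParams <- function(lattice_size = 300L, init_area = 25L,
                        division_area_range = c(72, 80),
                        growth_rates = c(0.08, 0.10, 0.12),
                        contact_energies = NULL, volume_lambda = 2,
                        temperature = 10, baseline_arrest = 0.01,
                        hill_amplitude = 0.95, hill_half_max_conc = 5,
                        hill_coeff = 2, diffusion_coeff = 1,
                        decay_rate = 1 / 225, secretion_rate = 1,
                        field_substeps = 6L, max_mcs = 20000L) {
  if (is.null(contact_energies)) {
    contact_energies <- matrix(c(0, 16, 16,
                                 16, 8, 8,
                                 16, 8, 8), 3, 3, byrow = TRUE)
  }
  dimnames(contact_energies) <-
    list(c("medium", "dividing", "arrested"),
         c("medium", "dividing", "arrested"))
  new("PottsParams", lattice_size = as.integer(lattice_size),
      init_area = as.integer(init_area),
      division_area_range = as.numeric(division_area_range),
      growth_rates = as.numeric(growth_rates),
      contact_energies = contact_energies,
      volume_lambda = as.numeric(volume_lambda),
      temperature = as.numeric(temperature),
      baseline_arrest = as.numeric(baseline_arrest),
      hill_amplitude = as.numeric(hill_amplitude),
      hill_half_max_conc = as.numeric(hill_half_max_conc),
      hill_coeff = as.numeric(hill_coeff),
      diffusion_coeff = as.numeric(diffusion_coeff),
      decay_rate = as.numeric(decay_rate),
      secretion_rate = as.numeric(secretion_rate),
      field_substeps = as.integer(field_substeps),
      max_mcs = as.integer(max_mcs))
}

setMethod("show", "PottsParams", function(object) {
  cat(sprintf(
    "PottsParams: %dx%d lattice, decay length %.1f px, T = %g, lambda = %g\n",
    object@lattice_size, object@lattice_size,
    sqrt(object@diffusion_coeff / object@decay_rate),
    object@temperature, object@volume_lambda))
})

.pottsParList <- function(params) {
  list(contact_energies = params@contact_energies,
       volume_lambda = params@volume_lambda,
       temperature = params@temperature,
       baseline_arrest = params@baseline_arrest,
       hill_amplitude = params@hill_amplitude,
       hill_half_max_conc = params@hill_half_max_conc,
       hill_coeff = params@hill_coeff,
       diffusion_coeff = params@diffusion_coeff,
       decay_rate = params@decay_rate,
       secretion_rate = params@secretion_rate,
       field_substeps = params@field_substeps,
       growth_rates = params@growth_rates,
       division_area_range = params@division_area_range)
}

#' Initialize a Potts simulation state
#'
#' Seeds one dividing cell of \code{init_area} pixels (a square block) at
#' the lattice center, with an empty signal field.
#'
#' @param params a \linkS4class{PottsParams}.
#' @param seed optional integer seed (drawn growth rate / division area).
#' @return A state list (lattice, field, per-cell vectors, mcs counter)
#'   consumed by \code{\link{pottsStep}} / \code{\link{runSpatialSimulation}}.
#' @export
pottsInit <- function(params, seed = NULL) {
  stopifnot(is(params, "PottsParams"))
  validObject(params)
  if (!is.null(seed)) set.seed(seed)
  n <- params@lattice_size
  lat <- matrix(0L, n, n)
  side <- max(1L, as.integer(round(sqrt(params@init_area))))
  c0 <- as.integer(n / 2 - side / 2)
  lat[c0 + seq_len(side), c0 + seq_len(side)] <- 1L
  list(lattice = lat,
       field = matrix(0, n, n),
       phase = 1L,
       target_area = as.numeric(side^2),
       growth_rate = sample(params@growth_rates, 1),
       division_area = stats::runif(1, params@division_area_range[1],
                                    params@division_area_range[2]),
       birth_mcs = 0L,
       mcs = 0L)
}

#' Advance a Potts state by a number of Monte Carlo steps
#'
#' One MCS = lattice-size^2 random pixel-copy attempts (Metropolis
#' acceptance \code{min(1, exp(-dH/T))}), followed by target-area growth,
#' divisions with per-daughter arrest decisions, and sub-stepped
#' diffusion-decay of the secreted signal. Stops early once no dividing
#' cells remain.
#'
#' @param state a state list from \code{\link{pottsInit}} (or a previous
#'   \code{pottsStep}).
#' @param params the \linkS4class{PottsParams} used throughout the run.
#' @param n_mcs number of MCS to attempt.
#' @return Updated state; \code{$series} holds per-MCS dividing/arrested
#'   counts and \code{$events} the division log (parent, child,
#'   inter-division interval, daughters arrested).
#' @export
pottsStep <- function(state, params, n_mcs) {
  stopifnot(is(params, "PottsParams"), n_mcs >= 1)
  cpp_run_potts(state, .pottsParList(params), as.integer(n_mcs))
}

#' Run one spatial simulation to arrest (or the MCS cap)
#'
#' @param params a \linkS4class{PottsParams}.
#' @param seed optional integer seed.
#' @param chunk MCS per internal chunk (progress granularity only).
#' @return list: \code{final_cells} (total cells), \code{final_arrested},
#'   \code{censored} (TRUE if the cap was hit with dividing cells left),
#'   \code{stop_mcs}, \code{series}, \code{events}, and the final
#'   \code{state}.
#' @examples
#' \donttest{
#' run <- runSpatialSimulation(PottsParams(lattice_size = 100), seed = 1)
#' run$final_cells
#' }
#' @export
runSpatialSimulation <- function(params, seed = NULL, chunk = 2000L) {
  stopifnot(is(params, "PottsParams"))
  if (!is.null(seed)) set.seed(seed)
  state <- pottsInit(params)
  series <- list(); events <- list()
  done <- 0L
  repeat {
    todo <- min(chunk, params@max_mcs - done)
    if (todo <= 0L) break
    state <- pottsStep(state, params, todo)
    series[[length(series) + 1L]] <- state$series
    events[[length(events) + 1L]] <- state$events
    done <- state$mcs
    ndiv <- sum(state$phase == 1L & state$area > 0L)
    if (ndiv == 0L) break
  }
  series <- do.call(rbind, series)
  events <- do.call(rbind, events)
  alive <- state$area > 0L
  ndiv <- sum(state$phase == 1L & alive)
  list(final_cells = sum(alive),
       final_arrested = sum(state$phase == 2L & alive),
       censored = ndiv > 0L,
       stop_mcs = state$mcs,
       series = series, events = events, state = state)
}

#' Incremental energy change of a proposed pixel copy
#'
#' Pure function of the local neighborhood: contact-energy change over the
#' 8-neighborhood plus the volume-constraint change
#' \eqn{\lambda \Delta \sum (a - a_{target})^2}.
#'
#' @param state a Potts state list.
#' @param params a \linkS4class{PottsParams}.
#' @param i,j 1-based pixel coordinates.
#' @param new_id proposed cell id (0 = medium).
#' @return energy change (numeric scalar).
#' @export
hamiltonianDelta <- function(state, params, i, j, new_id) {
  area <- tabulate(state$lattice[state$lattice > 0],
                   nbins = length(state$phase))
  cpp_delta_h(state$lattice, as.integer(state$phase),
              as.numeric(state$target_area), as.integer(area),
              as.integer(i), as.integer(j), as.integer(new_id),
              params@contact_energies, params@volume_lambda)
}

#' Total CPM Hamiltonian of a state (oracle for the incremental form)
#'
#' @param state a Potts state list.
#' @param params a \linkS4class{PottsParams}.
#' @return total energy.
#' @export
fullHamiltonian <- function(state, params) {
  cpp_full_hamiltonian(state$lattice, as.integer(state$phase),
                       as.numeric(state$target_area),
                       params@contact_energies, params@volume_lambda)
}

#' Arrest probability at a given signal concentration
#'
#' @param params a \linkS4class{PottsParams}.
#' @param concentration signal level(s) at the daughter's centroid.
#' @return \code{min(1, baseline + amplitude * c^h / (c^h + K^h))}.
#' @examples
#' arrestProbability(PottsParams(), 0)     # the 1% floor
#' @export
arrestProbability <- function(params, concentration) {
  stopifnot(is(params, "PottsParams"), all(concentration >= 0))
  h <- params@hill_coeff
  ch <- concentration^h
  pmin(1, params@baseline_arrest +
         params@hill_amplitude * ch / (ch + params@hill_half_max_conc^h))
}

#' Integrate the signal field with fixed sources
#'
#' Explicit zero-flux diffusion-decay solver,
#' \eqn{\partial c/\partial t = D \nabla^2 c - k c + source}; used both
#' inside the simulation and standalone (e.g. to verify the steady-state
#' decay length \code{sqrt(D/k)} against the screened-Poisson Bessel
#' profile).
#'
#' @param field numeric matrix of concentrations.
#' @param source numeric matrix of production rates (same shape).
#' @param params a \linkS4class{PottsParams} (supplies D and k).
#' @param time total integration time; sub-stepped for stability.
#' @return updated field matrix.
#' @export
updateSignalField <- function(field, source, params, time = 1) {
  stopifnot(is(params, "PottsParams"), all(dim(field) == dim(source)))
  dt_max <- 0.9 / (4 * params@diffusion_coeff + params@decay_rate)
  nsteps <- max(1L, ceiling(time / dt_max))
  cpp_diffuse(field, source, params@diffusion_coeff, params@decay_rate,
              time / nsteps, as.integer(nsteps))
}

#' Estimate the signal decay length from a steady-state field
#'
#' At steady state around a compact source the 2D screened-diffusion
#' profile is \eqn{c(r) \propto K_0(r/L)}, whose far field goes as
#' \eqn{e^{-r/L}/\sqrt{r}}; regressing \eqn{\log(c\sqrt{r})} on \eqn{r}
#' therefore recovers \eqn{-1/L} without the geometric bias a plain
#' log-slope would carry.
#'
#' @param field concentration matrix.
#' @param center length-2 source position (row, col), 1-based.
#' @param r_range radial fit range in pixels.
#' @return estimated decay length in pixels.
#' @export
estimateDecayLength <- function(field, center, r_range = c(10, 60)) {
  r <- seq(ceiling(r_range[1]), floor(r_range[2]))
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  prof <- vapply(r, function(rr) {
    ii <- round(center[1] + rr * cos(th))
    jj <- round(center[2] + rr * sin(th))
    ok <- ii >= 1 & ii <= nrow(field) & jj >= 1 & jj <= ncol(field)
    mean(field[cbind(ii[ok], jj[ok])])
  }, numeric(1))
  keep <- prof > 0
  fit <- stats::lm(log(prof[keep] * sqrt(r[keep])) ~ r[keep])
  -1 / unname(coef(fit)[2])
}
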