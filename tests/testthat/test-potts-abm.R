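## Helper: a tiny hand-built state with three cells on a small lattice.
tiny_state <- function(n = 20) {
  lat <- matrix(0L, n, n)
  lat[3:7, 3:7] <- 1L            # dividing, 25 px
  lat[10:13, 10:14] <- 2L        # dividing, 20 px
  lat[15:18, 3:6] <- 3L          # arrested, 16 px
  list(lattice = lat, field = matrix(0, n, n),
       phase = c(1L, 1L, 2L),
       target_area = c(25, 22, 16),
       growth_rate = c(0.1, 0.1, 0),
       division_area = c(76, 76, 0),
       birth_mcs = c(0L, 0L, 0L),
       mcs = 0L)
}

test_that("incremental energy change matches the full Hamiltonian", {
  pp <- small_potts()
  st <- tiny_state()
  H0 <- fullHamiltonian(st, pp)
  set.seed(21)
  checked <- 0
  while (checked < 40) {
    i <- sample(2:19, 1); j <- sample(2:19, 1)
    di <- sample(c(-1, 0, 1), 1); dj <- sample(c(-1, 0, 1), 1)
    if (di == 0 && dj == 0) next
    new_id <- st$lattice[i + di, j + dj]
    old_id <- st$lattice[i, j]
    if (new_id == old_id) next
    dH <- hamiltonianDelta(st, pp, i, j, new_id)
    st2 <- st
    st2$lattice[i, j] <- new_id
    expect_equal(dH, fullHamiltonian(st2, pp) - H0, tolerance = 1e-9)
    checked <- checked + 1
  }
  ## a copy that changes nothing costs nothing
  expect_equal(hamiltonianDelta(st, pp, 5, 5, st$lattice[5, 5]), 0)
})

test_that("an isolated resting cell keeps its area near target", {
  pp <- small_potts(temperature = 5)
  st <- tiny_state(30)
  st$lattice[,] <- 0L
  st$lattice[13:17, 13:17] <- 1L
  st$phase <- 1L; st$target_area <- 25
  st$growth_rate <- 0; st$division_area <- 1e9  # never divides
  st$birth_mcs <- 0L
  areas <- numeric(20)
  for (k in 1:20) {
    st <- pottsStep(st, pp, 25)
    areas[k] <- sum(st$lattice == 1L)
  }
  ## stationary: the cell neither vanishes nor drifts; it equilibrates a
  ## few pixels below target (interface tension vs the volume constraint)
  expect_true(all(areas >= 12 & areas <= 32))
  expect_lt(sd(areas), 3)
  expect_lt(abs(mean(areas) - 25), 8)
})

test_that("signal field has decay length 15 px and the K0 radial profile", {
  pp <- PottsParams(lattice_size = 150)
  n <- 150
  src <- matrix(0, n, n); src[75, 75] <- 1
  f <- updateSignalField(matrix(0, n, n), src, pp, time = 1500)
  L <- estimateDecayLength(f, c(75, 75), c(10, 60))
  expect_equal(L, 15, tolerance = 0.10)
  ## screened-Poisson Green's function: c(r) proportional to K0(r/15)
  r <- 5:45
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  prof <- vapply(r, function(rr) {
    mean(f[cbind(round(75 + rr * cos(th)), round(75 + rr * sin(th)))])
  }, numeric(1))
  ratio <- prof / besselK(r / 15, 0)
  expect_lt(max(ratio) / min(ratio) - 1, 0.05)
  ## with no sources the field decays away
  g <- updateSignalField(f, matrix(0, n, n), pp, time = 2000)
  expect_lt(max(g), 1e-3 * max(f))
})

test_that("field solver conserves mass up to sources and decay", {
  pp <- PottsParams(lattice_size = 60)
  n <- 60
  src <- matrix(0, n, n); src[28:32, 28:32] <- 0.3
  Tt <- 50
  f <- updateSignalField(matrix(0, n, n), src, pp, time = Tt)
  ## zero-flux walls: dM/dt = S - k M  =>  M(T) = S/k (1 - exp(-kT))
  S <- sum(src); k <- pp@decay_rate
  expect_equal(sum(f), S / k * (1 - exp(-k * Tt)), tolerance = 0.01)
})

test_that("cells divide near 382 MCS apart, splitting evenly at random angles", {
  ## pure growth: arrest switched off so divisions accumulate
  pp <- PottsParams(lattice_size = 150, baseline_arrest = 0,
                    hill_amplitude = 0, max_mcs = 3600)
  run <- runSpatialSimulation(pp, seed = 31)
  ev <- run$events[-1, ]                    # founder's first cycle is longer
  expect_gt(nrow(ev), 60)
  expect_equal(mean(ev$interval), 382, tolerance = 0.15)
  ## division conserves pixels and splits roughly in half
  imbalance <- abs(ev$area_kept - ev$area_split) /
    (ev$area_kept + ev$area_split)
  expect_lt(mean(imbalance), 0.10)
  ## orientation uniform on [0, pi)
  bins <- cut(run$events$angle, breaks = seq(0, pi, length.out = 13))
  chi <- suppressWarnings(stats::chisq.test(table(bins)))
  expect_gt(chi$p.value, 0.001)
  ## lattice bookkeeping: every non-medium pixel belongs to a live cell
  expect_equal(sum(run$state$lattice > 0), sum(run$state$area))
})

test_that("arrest decision has the floor, midpoint and saturation", {
  pp <- PottsParams()
  expect_equal(arrestProbability(pp, 0), 0.01)
  expect_equal(arrestProbability(pp, pp@hill_half_max_conc),
               0.01 + pp@hill_amplitude / 2)
  expect_equal(arrestProbability(pp, 1e9),
               min(1, 0.01 + pp@hill_amplitude))
  ## stability guard on the field integrator
  expect_error(PottsParams(field_substeps = 1L, diffusion_coeff = 2),
               "substeps")
})

test_that("a full spatial run arrests with consistent bookkeeping", {
  pp <- PottsParams(lattice_size = 250, max_mcs = 15000)
  run <- runSpatialSimulation(pp, seed = 1)
  expect_false(run$censored)
  expect_equal(run$final_cells, run$final_arrested)
  expect_gt(run$final_cells, 50)
  s <- run$series
  expect_true(all(diff(s$arrested) >= 0))
  expect_equal(s$dividing[nrow(s)], 0)
  ## arrested cells only ever appear at divisions
  expect_equal(max(s$arrested), sum(run$events$n_arrested))
})

test_that("seed-identical runs are bit-identical", {
  pp <- small_potts(max_mcs = 400)
  a <- runSpatialSimulation(pp, seed = 7)
  b <- runSpatialSimulation(pp, seed = 7)
  expect_identical(a$state$lattice, b$state$lattice)
  expect_identical(a$series, b$series)
  expect_identical(a$state$field, b$state$field)
  c <- runSpatialSimulation(pp, seed = 8)
  expect_false(identical(a$state$lattice, c$state$lattice))
})
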