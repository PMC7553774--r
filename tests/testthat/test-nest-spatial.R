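test_that("equivalent radius inverts the disk area", {
  expect_equal(equivalentRadius(pi), 1)
  expect_equal(equivalentRadius(4 * pi), 2)
  expect_equal(equivalentRadius(1385), sqrt(1385 / pi))
  expect_equal(round(equivalentRadius(1385), 1), 21.0)
  expect_error(equivalentRadius(-3), "positive")
})

test_that("nests split at the 20 um radius with ties going large", {
  df <- data.frame(field_id = "f", x_um = c(0, 50, 100),
                   y_um = 0, area_um2 = pi * c(19.9, 20.1, 20)^2)
  cls <- classifyNests(df)
  expect_equal(as.vector(cls), c("small", "large", "large"))
  expect_equal(attr(cls, "n_ties"), 1L)
  all_small <- data.frame(field_id = "f", x_um = 1:3, y_um = 0,
                          area_um2 = pi * 5^2)
  expect_true(all(classifyNests(all_small) == "small"))
})

test_that("mean neighbor size uses the annulus beyond the target perimeter", {
  tn <- toy_nests()
  A <- tn[tn$field_id == "A", ]
  ## target radius 10, annulus 45: nothing within 55 um
  expect_true(is.na(meanNeighborSize(1, A, annulus_width = 45)))
  ## widen to 100: only the radius-25 nest at distance 100 qualifies
  expect_equal(meanNeighborSize(1, A, annulus_width = 100), 25)
  ## edge rule credits the neighbor its own radius
  expect_equal(meanNeighborSize(1, A, annulus_width = 85, rule = "edge"), 25)
  expect_true(is.na(meanNeighborSize(1, A, annulus_width = 85)))
  ## brute-force agreement on random fields
  nf <- fixture_nest_fields(seed = 47)
  f1 <- nf[nf$field_id == "field_01", ]
  r <- equivalentRadius(f1$area_um2)
  byhand <- vapply(seq_len(nrow(f1)), function(t) {
    d <- sqrt((f1$x_um - f1$x_um[t])^2 + (f1$y_um - f1$y_um[t])^2)
    nb <- which(d <= r[t] + 45 & seq_along(d) != t)
    if (length(nb)) mean(r[nb]) else NA_real_
  }, numeric(1))
  got <- vapply(seq_len(nrow(f1)), meanNeighborSize, numeric(1),
                field = f1, annulus_width = 45)
  expect_equal(got, byhand)
})

test_that("histograms pool qualifying fields and respect the field filter", {
  nf <- fixture_nest_fields(seed = 48)
  h <- neighborSizeHistograms(nf, min_nests = 10)
  expect_equal(sum(h$small), length(h$values$small))
  expect_equal(sum(h$large), length(h$values$large))
  ## identical radii put all mass in one bin of whichever class is occupied
  uni <- data.frame(field_id = "u", x_um = seq(0, 330, 30), y_um = 0,
                    area_um2 = pi * 12^2)
  hu <- neighborSizeHistograms(uni, min_nests = 10)
  expect_equal(sum(hu$small > 0), 1)
  expect_equal(hu$breaks[which(hu$small > 0)], 10)  # 12 um falls in [10, 15)
  expect_equal(sum(hu$large), 0)
  ## a joint permutation of rows changes nothing
  h2 <- neighborSizeHistograms(nf[sample(nrow(nf)), ], min_nests = 10)
  expect_equal(h$small, h2$small)
  expect_equal(h$large, h2$large)
  expect_error(neighborSizeHistograms(uni, min_nests = 50), "at least")
})

test_that("permutation envelope is seeded, ordered and sane", {
  nf <- fixture_nest_fields(seed = 49)
  e1 <- permutationEnvelope(nf, n_perm = 150, seed = 50)
  e2 <- permutationEnvelope(nf, n_perm = 150, seed = 50)
  expect_identical(e1$lo, e2$lo)
  expect_identical(e1$flags, e2$flags)
  expect_true(all(e1$lo$small <= e1$hi$small))
  expect_true(all(e1$lo$large <= e1$hi$large))
  ## the observed data is one more exchangeable draw: most bins inside
  expect_lt(mean(c(e1$flags$small, e1$flags$large)), 0.5)
  expect_error(permutationEnvelope(nf, n_perm = 50), "n_perm")
  ## constant areas within fields: the permuted statistic is degenerate
  uni <- data.frame(field_id = "u", x_um = seq(0, 330, 30), y_um = 0,
                    area_um2 = pi * 12^2)
  eu <- permutationEnvelope(uni, n_perm = 120, seed = 51)
  expect_equal(eu$lo$small, eu$hi$small)
  expect_equal(eu$lo$small, as.numeric(eu$observed$small))
  expect_false(any(eu$flags_strict$small))
})

test_that("inhibited fields shift large-target neighbors and flag asymmetry", {
  nf <- generateNestFields(n_fields = 7, inhibition_amplitude = 0.5,
                           inhibition_range_um = 45, seed = 52)
  env <- permutationEnvelope(nf, n_perm = 200, seed = 53)
  expect_lt(env$size_proximity$correlation, 0)
  expect_lt(env$size_proximity$p_value, 0.05)
})

test_that("median spacing is the nearest-neighbor center distance", {
  two <- data.frame(field_id = "f", x_um = c(0, 100), y_um = 0,
                    area_um2 = pi)
  expect_equal(medianNestSpacing(two), 100)
  grid <- expand.grid(x_um = seq(0, 200, 50), y_um = seq(0, 200, 50))
  grid$field_id <- "g"; grid$area_um2 <- pi
  expect_equal(medianNestSpacing(grid), 50)
  nf <- fixture_nest_fields(seed = 54)
  byhand <- median(unlist(lapply(split(nf, nf$field_id), function(s) {
    D <- as.matrix(dist(cbind(s$x_um, s$y_um))); diag(D) <- Inf
    apply(D, 1, min)
  })))
  expect_equal(medianNestSpacing(nf), byhand)
})

test_that("morphometric conversions reproduce the worked arithmetic", {
  expect_equal(cellsPerNevusVolumetric(1, 1e4, 1), 1)
  expect_equal(cellsPerNevusVolumetric(2, 1e4, 3), 6)
  expect_equal(cellsPerNevusVolumetric(), 14.4 * 38792 / 1e4 * 12)
  expect_equal(round(cellsPerNevusVolumetric(), 1), 670.3)
  expect_equal(diskAreaMm2(1000 / sqrt(pi)), 1)
  expect_equal(diskAreaMm2(0), 0)
  expect_equal(round(diskAreaMm2(76.8), 3), 0.019)
})
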