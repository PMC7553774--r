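## small deterministic fixtures shared across test files

fixture_nest_fields <- function(seed = 11, ...) {
  generateNestFields(n_fields = 3, intensity = 70, field_extent_um = 600,
                     seed = seed, ...)
}

## two-field toy table with hand-placed nests
toy_nests <- function() {
  data.frame(
    field_id = rep(c("A", "B"), c(4, 3)),
    x_um  = c(0, 100, 200, 210,   0,  50, 500),
    y_um  = c(0,   0,   0,  10,   0,   0,   0),
    area_um2 = c(pi * 10^2, pi * 25^2, pi * 15^2, pi * 30^2,
                 pi * 5^2, pi * 22^2, pi * 18^2))
}

small_potts <- function(...) {
  args <- list(...)
  defaults <- list(lattice_size = 60, max_mcs = 500)
  do.call(PottsParams, modifyList(defaults, args))
}
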