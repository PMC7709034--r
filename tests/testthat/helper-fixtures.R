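# Shared fixtures, built once per test run. The full-size synthetic
# reference and panel are memoized because several files reuse them.

.fx <- new.env(parent = emptyenv())

fx_ref <- function() {
  if (is.null(.fx$ref)) .fx$ref <- synthetic_reference(seed = 7L)
  .fx$ref
}

fx_panel <- function() {
  if (is.null(.fx$panel)) .fx$panel <- simulate_panel(110, 163, 11, seed = 2L)
  .fx$panel
}

# small circle for coordinate arithmetic tests; no planted tracts
toy_ref <- function(L = 200L, seed = 3L) {
  synthetic_reference(L = L, seed = seed, plant_tracts = FALSE)
}

# flat-depth single-source scenario used across caller tests
fx_scenario <- function(haplotype = character(0), depth = 1000,
                        error = error_model(0, 0), seed = 1L, ...) {
  sim_scenario(fx_ref(), fx_panel(), haplotypes = list(haplotype),
               depth = depth_model(depth), error = error, seed = seed, ...)
}
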