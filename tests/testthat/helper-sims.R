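# Simulations shared across test files, memoized for the session.
# All seeds fixed up front; small presets keep the suite fast while the
# acceptance checks use the fragment counts their criteria prescribe.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, maker) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, maker(), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

tiny_config <- function(...) {
  archstats::demography_config(num_fragments = 15, fragment_length = 1e5, ...)
}

# small general-purpose simulation and table (both pulses, rate 1)
tiny_sim <- function() {
  cached("tiny_sim", function() {
    archstats::simulate_fragments(tiny_config(), seed = 101)
  })
}

tiny_table <- function() {
  cached("tiny_table", function() archstats::sim_to_site_table(tiny_sim()))
}

# no admixture at all (null calibration)
null_table <- function() {
  cached("null_table", function() {
    archstats::simulate_site_table(
      archstats::demography_config(num_fragments = 120,
                                   fragment_length = 2e5,
                                   nea_pulse = 0, den_pulse = 0),
      seed = 101)
  })
}

# acceptance-scale scenarios (criteria 1-3, 5)
accept_nea_only <- function() {
  cached("accept_nea_only", function() {
    archstats::simulate_fragments(
      archstats::demography_config(num_fragments = 220, den_pulse = 0),
      seed = 101)
  })
}

accept_sweep_table <- function(rate) {
  name <- paste0("accept_sweep_", rate)
  cached(name, function() {
    archstats::simulate_site_table(
      archstats::demography_config(num_fragments = 220,
                                   migration_rate = rate),
      seed = 101 + rate)
  })
}
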