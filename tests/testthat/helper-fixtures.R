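# Shared fixture builders: everything is generated in code at test time.

# Daily full-replacement protocol with a constant volume (no weekend gaps).
daily_protocol <- function(days = 28, volume = 100) {
  monophasic_protocol(days = days, weekday_volume = volume,
                      weekend_volume = volume, weekend_days = numeric(0))
}

# Noise-free release profile whose cumulative release equals `law(t)` at
# every event time, built through the exact inversion + reconstruction path.
profile_from_law <- function(law, protocol = daily_protocol(),
                             loading = 24400) {
  s <- invert_to_concentrations(law, protocol)
  reconstruct_monophasic(s, protocol, loading = loading)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), rel_tol)
}
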