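# Lazily computed shared objects (helpers are sourced once per test run, so
# the cache environment persists across test files).
.test_cache <- new.env(parent = emptyenv())

cached_sim_grid <- function() {
  if (is.null(.test_cache$grid)) {
    .test_cache$grid <- simulate_grid(default_layout(), n = 56)
  }
  .test_cache$grid
}
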