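# The quasi-steady reference simulation on the default synthetic coral at
# Re ~ 10 is expensive (minutes), so it is computed once per test session and
# cached for every test that needs the steady field.
.run_cache <- new.env(parent = emptyenv())

coral_reference_run <- function() {
  if (is.null(.run_cache$run)) {
    geom <- generate_coral(coral_params())
    cfg <- flow_config(u_inlet = 8.33e-4, width = 0.012,
                       spacing = geom$spacing, tau = 0.9,
                       max_steps = 6000L, check_every = 100L, tol = 2e-4,
                       ramp_steps = 400L)
    .run_cache$run <- list(geometry = geom, config = cfg,
                           field = run_to_quasi_steady(geom, cfg))
  }
  .run_cache$run
}
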