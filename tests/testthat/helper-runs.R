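# Lazily computed, session-cached simulation runs shared across test files.
# Every accessor is deterministic (no randomness anywhere in the engine).

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

fasting_state_normal <- function() {
  cached("fasting_normal", equilibrate(preset_scenario("normal")))
}

run_normal <- function() {
  cached("run_normal",
         run_scenario(preset_scenario("normal"),
                      fasting_state = fasting_state_normal()))
}

run_open_shunt <- function() {
  cached("run_open_shunt",
         run_scenario(scenario(pss_resistance = 0.005,
                               presinusoidal_resistance = 0.005)))
}

# 2-axis sweep used for the interaction sign pattern and monotonicity.
sweep_sens_pgl <- function() {
  cached("sweep_sens_pgl",
         run_sweep(scenario(),
                   list(path = "glp1_glucose_sensitivity", grid = c(2, 10, 50)),
                   list(path = "p_gl", grid = c(0, 0.08, 0.16))))
}

fasting_aux <- function(scn, state) {
  ctx <- splanchsim:::build_context(scn)
  splanchsim:::rhs_full(0, state, ctx)$aux
}
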