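# Scenario description: gavage protocol plus the four headline knobs
# (GLP-1 glucose sensitivity, paracellular permeability, portosystemic
# shunt resistance, presinusoidal resistance) and free parameter overrides.

#' Duodenal glucose gavage protocol
#'
#' @param dose_g Glucose dose in grams (default 50, the standard OGTT load).
#' @param start_time Gavage start, minutes of simulated time (default 100).
#' @param duration Delivery duration, minutes (default 20; the dose enters
#'   the intestinal lumen at a constant rate).
#' @return List of class `splanchsim_gavage`.
#' @export
gavage_protocol <- function(dose_g = 50, start_time = 100, duration = 20) {
  stopifnot(dose_g >= 0, duration > 0, start_time >= 0)
  structure(list(dose_g = dose_g, start_time = start_time,
                 duration = duration,
                 dose_mmol = dose_g / 0.18016),
            class = "splanchsim_gavage")
}

#' Simulation scenario
#'
#' @param glp1_glucose_sensitivity Glucose sensitivity of enteroendocrine
#'   GLP-1 secretion (dimensionless, swept 0.1-100; 50 = healthy high
#'   secretor).
#' @param p_gl Paracellular intestinal glucose permeability, um/s (0-0.16).
#' @param pss_resistance Portosystemic shunt resistance, mmHg s/ml
#'   (40 = shunt effectively closed; 0.005 = wide open, the NASH limit).
#' @param presinusoidal_resistance Portal-vein-to-sinusoid resistance,
#'   mmHg s/ml (0.005 normal; raised to ~0.02-0.025 in NAFLD/NASH).
#' @param gavage A [gavage_protocol()].
#' @param overrides Named list of parameter overrides; names are
#'   dot-separated paths into [default_parameters()] (e.g.
#'   `"secretion.loss.insulin_hepatic"`).
#' @return List of class `splanchsim_scenario`.
#' @export
scenario <- function(glp1_glucose_sensitivity = 50,
                     p_gl = 0.15,
                     pss_resistance = 40,
                     presinusoidal_resistance = 0.005,
                     gavage = gavage_protocol(),
                     overrides = list()) {
  stopifnot(glp1_glucose_sensitivity >= 0, p_gl >= 0,
            pss_resistance > 0, presinusoidal_resistance > 0)
  structure(list(glp1_glucose_sensitivity = glp1_glucose_sensitivity,
                 p_gl = p_gl,
                 pss_resistance = pss_resistance,
                 presinusoidal_resistance = presinusoidal_resistance,
                 gavage = gavage,
                 overrides = overrides),
            class = "splanchsim_scenario")
}

#' Named scenario presets
#'
#' `"normal"`: healthy high GLP-1 secretor, shunt closed. `"low_glp1"`:
#' GLP-1-deficient secretion (sensitivity 0.1, bottom of the sweep range).
#' `"nash_shunt"`: NASH hemodynamics - wide-open portosystemic shunt
#' (0.005 mmHg s/ml) with presinusoidal resistance raised 4x to 0.02.
#'
#' @param name One of `"normal"`, `"low_glp1"`, `"nash_shunt"`.
#' @return A [scenario()].
#' @export
preset_scenario <- function(name = c("normal", "low_glp1", "nash_shunt")) {
  name <- match.arg(name)
  switch(name,
    normal = scenario(),
    low_glp1 = scenario(glp1_glucose_sensitivity = 0.1),
    nash_shunt = scenario(pss_resistance = 0.005,
                          presinusoidal_resistance = 0.020)
  )
}

#' List the scenario presets and their parameter deltas
#'
#' @return data.frame, one row per preset.
#' @export
list_presets <- function() {
  base <- preset_scenario("normal")
  do.call(rbind, lapply(c("normal", "low_glp1", "nash_shunt"), function(nm) {
    s <- preset_scenario(nm)
    data.frame(preset = nm,
               glp1_glucose_sensitivity = s$glp1_glucose_sensitivity,
               p_gl = s$p_gl,
               pss_resistance = s$pss_resistance,
               presinusoidal_resistance = s$presinusoidal_resistance,
               delta = paste(
                 c(if (s$glp1_glucose_sensitivity != base$glp1_glucose_sensitivity)
                     sprintf("glp1_glucose_sensitivity=%g", s$glp1_glucose_sensitivity),
                   if (s$pss_resistance != base$pss_resistance)
                     sprintf("pss_resistance=%g", s$pss_resistance),
                   if (s$presinusoidal_resistance != base$presinusoidal_resistance)
                     sprintf("presinusoidal_resistance=%g", s$presinusoidal_resistance),
                   "-")[1],
                 collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

# Set a dot-separated path inside a nested list.
set_param_path <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  ref <- params
  node <- list()
  # verify path exists
  for (k in keys) {
    if (is.null(ref[[k]])) {
      stop("unknown parameter path: ", path, call. = FALSE)
    }
    ref <- ref[[k]]
  }
  expr <- paste0("params", paste0("[['", keys, "']]", collapse = ""))
  eval(parse(text = paste0(expr, " <- value")))
  params
}

#' Apply a scenario to a parameter set
#'
#' Maps the four scenario knobs onto their parameter slots
#' (shunt/portal-vein resistances, paracellular permeability, GLP-1
#' secretion sensitivity) and then applies any free overrides.
#'
#' @param scn A [scenario()].
#' @param params Base parameters (default [default_parameters()]).
#' @return Modified parameter list.
#' @export
apply_scenario <- function(scn, params = default_parameters()) {
  params$circulation$r_shunt <- scn$pss_resistance
  params$circulation$r_portal_v <- scn$presinusoidal_resistance
  params$absorption$p_gl <- scn$p_gl
  params$secretion$glp1_glc_sensitivity <- scn$glp1_glucose_sensitivity
  for (path in names(scn$overrides)) {
    params <- set_param_path(params, path, scn$overrides[[path]])
  }
  params
}
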