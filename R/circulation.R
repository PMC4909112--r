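# Resistance-compliance circulation network: compartments (compliant nodes)
# joined by resistive vessel segments, with the two ventricles modelled as
# pressure sources in series with their outflow resistances.

#' Transmural pressure of a compliant blood compartment
#'
#' The pressure-volume law is linear: `P = (V - V0) / C`, where `V0` is the
#' unstressed volume (the volume at which the wall is unstretched) and `C`
#' the absolute compliance in ml/mmHg.
#'
#' @param volume Current blood volume of the compartment (ml). May be a
#'   vector, matched element-wise against `spec` fields.
#' @param spec A list (or row of the compartment table) with numeric fields
#'   `compliance` (ml/mmHg) and `unstressed_volume` (ml).
#' @return Pressure in mmHg.
#' @examples
#' compartment_pressure(700, list(compliance = 0.7, unstressed_volume = 626.5))
#' @export
compartment_pressure <- function(volume, spec) {
  if (any(volume < 0)) {
    stop("invalid state: negative compartment volume", call. = FALSE)
  }
  (volume - spec$unstressed_volume) / spec$compliance
}

#' Flow through a resistive vessel segment
#'
#' Ohm's-law analogue: `Q = (P_source - P_sink) / R`. Positive flow runs
#' from source to sink; the function is antisymmetric in its pressure
#' arguments.
#'
#' @param p_source,p_sink Node pressures (mmHg).
#' @param resistance Segment resistance (mmHg s/ml), strictly positive.
#' @return Flow in ml/s (sign = source to sink).
#' @export
segment_flow <- function(p_source, p_sink, resistance) {
  if (any(resistance <= 0)) {
    stop("configuration error: segment resistance must be > 0", call. = FALSE)
  }
  (p_source - p_sink) / resistance
}

#' GLP-1-dependent superior mesenteric artery resistance
#'
#' The SMA is the only vessel whose resistance responds directly to the
#' incretin signal: `R(GLP) = R0 * Km / (Km + GLP)`, a hyperbolic fall from
#' `R0` at zero GLP-1 towards zero at saturating GLP-1.
#'
#' @param glp1_sm GLP-1 concentration sensed in the superior mesenteric
#'   capillary bed (nM), non-negative.
#' @param ctrl List with `r_sma_0` (resistance at zero GLP-1, mmHg s/ml)
#'   and `km_glp1` (half-effect concentration, nM).
#' @return SMA resistance (mmHg s/ml).
#' @export
sma_resistance <- function(glp1_sm, ctrl) {
  if (any(glp1_sm < 0)) {
    stop("invalid state: negative GLP-1 concentration", call. = FALSE)
  }
  ctrl$r_sma_0 * ctrl$km_glp1 / (ctrl$km_glp1 + glp1_sm)
}

#' Compartment volume derivatives from segment flows
#'
#' Sums signed segment flows into each compartment. Because the circuit is
#' closed, the derivatives sum to zero exactly.
#'
#' @param flows Named numeric vector of segment flows (ml/s, sign =
#'   source to sink), named by segment.
#' @param segments Segment table as returned by [vessel_segments()] (or any
#'   data.frame with `name`, `source_node`, `sink_node`).
#' @param compartments Character vector of compartment names.
#' @return Named numeric vector, dV/dt per compartment in ml/s.
#' @export
volume_derivatives <- function(flows, segments, compartments) {
  bad <- setdiff(c(segments$source_node, segments$sink_node), compartments)
  if (length(bad) > 0) {
    stop("configuration error: dangling segment endpoint(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  dv <- stats::setNames(numeric(length(compartments)), compartments)
  f <- flows[segments$name]
  for (i in seq_len(nrow(segments))) {
    dv[segments$source_node[i]] <- dv[segments$source_node[i]] - f[i]
    dv[segments$sink_node[i]] <- dv[segments$sink_node[i]] + f[i]
  }
  dv
}

#' Check node balance of a flow state
#'
#' @param flows Named segment flows (ml/s).
#' @param segments Segment table.
#' @param compartments Compartment names.
#' @param tolerance Maximum allowed |net flow| per node (ml/s).
#' @return TRUE iff every compartment's net flow magnitude is below
#'   `tolerance`.
#' @export
steady_state_check <- function(flows, segments, compartments, tolerance = 0.01) {
  dv <- volume_derivatives(flows, segments, compartments)
  all(abs(dv) < tolerance)
}

#' Vessel segment table of the default circulation network
#'
#' Closed circuit: lungs -> aorta (left-heart pump) -> {somatic, renal,
#' splenic+coeliac, SMA, hepatic artery} -> venous return -> lungs
#' (right-heart pump). The portal side runs SM capillaries -> portal vein ->
#' hepatic sinusoids -> hepatic vein, with the splenic/coeliac bed draining
#' directly into the sinusoids and a portosystemic shunt edge from the
#' portal (SM capillary) node to the systemic veins.
#'
#' @param params Parameter list from [default_parameters()].
#' @return data.frame with columns `name`, `source_node`, `sink_node`,
#'   `resistance` (mmHg s/ml), `pump_pressure` (mmHg; 0 for passive
#'   segments) and `glp1_sensitive`.
#' @export
vessel_segments <- function(params = default_parameters()) {
  cir <- params$circulation
  seg <- function(name, from, to, r, pump = 0, glp1 = FALSE) {
    data.frame(name = name, source_node = from, sink_node = to,
               resistance = r, pump_pressure = pump, glp1_sensitive = glp1,
               stringsAsFactors = FALSE)
  }
  rbind(
    seg("aortic",     "lung",     "sys_art",  cir$r_aortic,   pump = cir$left_pump_pressure),
    seg("pulmonary",  "sys_vein", "lung",     cir$r_pulmonary, pump = cir$right_pump_pressure),
    seg("sma",        "sys_art",  "sm_cap",   cir$r_sma_0, glp1 = TRUE),
    seg("hepatic_a",  "sys_art",  "hep",      cir$r_hepatic_a),
    seg("splenic_a",  "sys_art",  "splanch",  cir$r_splenic_a),
    seg("renal_a",    "sys_art",  "renal",    cir$r_renal_a),
    seg("muscle",     "sys_art",  "somatic",  cir$r_muscle),
    seg("splenic_v",  "splanch",  "hep",      cir$r_splenic_v),
    seg("portal_v",   "sm_cap",   "hep",      cir$r_portal_v),
    seg("hepatic_v",  "hep",      "sys_vein", cir$r_hepatic_v),
    seg("renal_v",    "renal",    "sys_vein", cir$r_renal_v),
    seg("somatic_v",  "somatic",  "sys_vein", cir$r_somatic_v),
    seg("shunt",      "sm_cap",   "sys_vein", cir$r_shunt)
  )
}

#' Compartment table of the default circulation network
#'
#' @param params Parameter list from [default_parameters()].
#' @return data.frame with `name`, `compliance` (absolute, ml/mmHg),
#'   `initial_volume` (ml), `unstressed_volume` (ml).
#' @export
compartment_table <- function(params = default_parameters()) {
  cmp <- params$compartments
  data.frame(
    name = cmp$name,
    compliance = cmp$distensibility * cmp$initial_volume,
    initial_volume = cmp$initial_volume,
    unstressed_volume = cmp$unstressed_volume,
    stringsAsFactors = FALSE
  )
}

#' Pressures and flows of the network at a given volume state
#'
#' @param volumes Named compartment volumes (ml).
#' @param segments Segment table (with the SMA resistance already set for
#'   the prevailing GLP-1 level, see [sma_resistance()]).
#' @param compartments Compartment table from [compartment_table()].
#' @return List with `node_pressures` (mmHg) and `segment_flows` (ml/s),
#'   both named.
#' @export
pressure_state <- function(volumes, segments, compartments) {
  p <- compartment_pressure(volumes[compartments$name],
                            list(compliance = compartments$compliance,
                                 unstressed_volume = compartments$unstressed_volume))
  names(p) <- compartments$name
  q <- segment_flow(p[segments$source_node] + segments$pump_pressure,
                    p[segments$sink_node], segments$resistance)
  names(q) <- segments$name
  list(node_pressures = p, segment_flows = q)
}
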