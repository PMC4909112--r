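# Source, sink and exchange rates for the four transported species:
# glucose (mmol, reported in mM), insulin (pmol, pM), glucagon (nmol, nM)
# and GLP-1 (nmol, nM). Concentrations divide compartment amounts by the
# species distribution volume, taken as 3x the compartment blood volume
# (blood is one third of the rapidly equilibrating extracellular space).

mm <- function(s, km) {
  s <- pmax(s, 0)
  s / (s + km)
}

#' Advective species flux through a segment (donor/upwind convention)
#'
#' @param flow Signed blood flow (volume/time); positive = source to sink.
#' @param conc_source,conc_sink Species concentration in the segment's
#'   source and sink compartments (amount/volume, same volume unit as
#'   `flow`).
#' @return Signed species flux (amount/time, positive = source to sink).
#'   The carried concentration is always the upstream one, so reversing
#'   the flow switches the donor compartment.
#' @export
advective_flux <- function(flow, conc_source, conc_sink) {
  ifelse(flow >= 0, flow * conc_source, flow * conc_sink)
}

#' Intestinal glucose absorption rate
#'
#' Parallel active and passive mucosal pathways: a saturable SGLT1 pump
#' driven by luminal glucose, plus paracellular diffusion proportional to
#' the lumen-to-capillary concentration gradient. The passive term reverses
#' sign when splanchnic capillary glucose exceeds the lumen.
#'
#' @param lumen_glc Intestinal lumen glucose (mM).
#' @param smcap_glc Superior mesenteric capillary glucose (mM).
#' @param p Absorption parameter list: `sglt1_vmax` (mmol/min), `sglt1_km`
#'   (mM), `p_gl` (um/s) and `exchange_scale` (mmol/min per um/s per mM,
#'   the implicit mucosal exchange area).
#' @return Net absorption rate, mmol/min (signed).
#' @export
intestinal_absorption_rate <- function(lumen_glc, smcap_glc, p) {
  active <- p$sglt1_vmax * mm(lumen_glc, p$sglt1_km)
  passive <- p$p_gl * p$exchange_scale * (pmax(lumen_glc, 0) - pmax(smcap_glc, 0))
  active + passive
}

#' Net hepatic glucose metabolic rate
#'
#' Signed rate: positive = net uptake (insulin/GLP-1-driven GLUT2 +
#' glucokinase flux), negative = net output (glucagon-driven
#' gluconeogenesis/glycogenolysis, treated as substrate-unlimited over the
#' simulated hours). The glucagon output term is subtracted after the
#' insulin-dependent uptake factor.
#'
#' @param glc_hep Hepatic sinusoidal glucose (mM).
#' @param ins_hep Hepatic insulin (pM).
#' @param glp1_hep Hepatic GLP-1 (nM).
#' @param gln_hep Hepatic glucagon (nM).
#' @param k Hepatic kinetic list: `vmax_glut2`, `km_glut2`, `km_insulin`,
#'   `hep_insulin_sensitivity`, `vmax_glp1_boost`, `km_glp1`,
#'   `glucagon_coef` (mmol/min scale), `km_glucagon`.
#' @return Net uptake rate, mmol/min.
#' @export
hepatic_metabolic_rate <- function(glc_hep, ins_hep, glp1_hep, gln_hep, k) {
  uptake <- k$vmax_glut2 * mm(glc_hep, k$km_glut2) *
    mm(ins_hep, k$km_insulin) * k$hep_insulin_sensitivity *
    (1 + k$vmax_glp1_boost * mm(glp1_hep, k$km_glp1))
  output <- k$glucagon_coef * mm(gln_hep, k$km_glucagon)
  uptake - output
}

#' Insulin-dependent peripheral glucose metabolic rate (GLUT4 pathway)
#'
#' Muscle and adipose uptake, multiplicative in a glucose factor
#' (Km 2.5 mM), an insulin factor, and a GLP-1 synergy factor `1 +
#' GLP/(GLP+Km)`.
#'
#' @param glc_sys Systemic glucose (mM).
#' @param ins_sys Systemic insulin (pM).
#' @param glp1_sys Systemic GLP-1 (nM).
#' @param k Peripheral kinetic list: `insulin_dep_coef` (mmol/min),
#'   `km_glut4` (mM), `km_insulin` (pM), `glp1_synergy_km` (nM),
#'   `insulin_indep_coef` (mmol/min), `km_glut1` (mM).
#' @return Rate, mmol/min; zero when insulin is zero.
#' @export
peripheral_insulin_dependent_rate <- function(glc_sys, ins_sys, glp1_sys, k) {
  k$insulin_dep_coef * mm(glc_sys, k$km_glut4) * mm(ins_sys, k$km_insulin) *
    (1 + mm(glp1_sys, k$glp1_synergy_km))
}

#' Insulin-independent glucose metabolic rate (GLUT1 pathway)
#'
#' Brain/skin/bone uptake: saturable in glucose only (Km 1.3 mM).
#'
#' @inheritParams peripheral_insulin_dependent_rate
#' @return Rate, mmol/min.
#' @export
insulin_independent_rate <- function(glc_sys, k) {
  k$insulin_indep_coef * mm(glc_sys, k$km_glut1)
}

#' Renal glucose excretion rate
#'
#' Filtered load (filtration fraction x renal plasma glucose flow) minus
#' the saturable SGLT2 reabsorption ceiling, floored at zero: below the
#' tubular maximum there is no glycosuria.
#'
#' @param renal_art_glc Renal arterial glucose (mM).
#' @param renal_flow Renal blood flow (ml/min).
#' @param p Renal parameter list: `filtration_fraction`, `tm_sglt2`
#'   (mmol/min), `km_sglt2` (mM).
#' @return Urinary glucose loss, mmol/min (>= 0).
#' @export
renal_glucose_excretion <- function(renal_art_glc, renal_flow, p) {
  filtered <- p$filtration_fraction * renal_flow / 1000 * pmax(renal_art_glc, 0)
  pmax(0, filtered - p$tm_sglt2 * mm(renal_art_glc, p$km_sglt2))
}

#' Pancreatic beta-cell insulin secretion rate
#'
#' Driven by systemic arterial glucose (GLUT2/glucokinase-limited,
#' half-maximal at 17 mM with Hill exponent `beta_cell_exponent`, 1 or 2;
#' the cooperative default 2 reflects the sigmoidal glucose dependence of
#' glucose-stimulated insulin release) and potentiated by systemic GLP-1.
#' A small GLP-1 floor `glp1_floor` keeps a basal secretion alive in
#' GLP-1-null scenarios. Secretion is released into the superior
#' mesenteric capillary compartment.
#'
#' @param glc_sysA Systemic arterial glucose (mM).
#' @param glp1_sysA Systemic arterial GLP-1 (nM).
#' @param p Secretion parameter list (see [default_parameters()]).
#' @return Secretion rate, pmol/min.
#' @export
insulin_secretion_rate <- function(glc_sysA, glp1_sysA, p) {
  glp <- pmax(glp1_sysA, 0) + p$glp1_floor
  n <- p$beta_cell_exponent
  g <- pmax(glc_sysA, 0)^n
  p$insulin_glc_sensitivity * g / (g + p$beta_cell_km^n) *
    glp / (glp + p$insulin_glp1_km)
}

#' Pancreatic alpha-cell glucagon secretion rate
#'
#' Suppressed by systemic arterial glucose as `1 - G^n/(G^n + Km^n)`
#' (n = 1 or 2); maximal at zero glucose, vanishing at saturating glucose.
#' Released into the superior mesenteric capillary compartment.
#'
#' @param glc_sysA Systemic arterial glucose (mM).
#' @param p Secretion parameter list.
#' @return Secretion rate, nmol/min.
#' @export
glucagon_secretion_rate <- function(glc_sysA, p) {
  g <- pmax(glc_sysA, 0)^p$glucagon_exponent
  p$glucagon_sensitivity * (1 - g / (g + p$glucagon_km^p$glucagon_exponent))
}

#' Enteroendocrine L-cell GLP-1 secretion rate
#'
#' Driven by the splanchnic (superior mesenteric capillary) glucose
#' concentration, not the systemic one: `sens * coef * G/(G + Km_GLUT2)`.
#' `glp1_glc_sensitivity` is the headline sweep knob (0.1-100);
#' `glp1_secretion_coef` converts it to nmol/min.
#'
#' @param glc_smcap SM capillary glucose (mM).
#' @param p Secretion parameter list.
#' @return Secretion rate, nmol/min.
#' @export
glp1_secretion_rate <- function(glc_smcap, p) {
  p$glp1_glc_sensitivity * p$glp1_secretion_coef * mm(glc_smcap, p$glp1_km_glut2)
}

#' First-order species degradation
#'
#' `loss = amount * rate`; in isolation this is exponential decay with
#' half-time `ln(2)/rate`.
#'
#' @param amount Species amount (any unit).
#' @param loss_rate Rate constant (1/min), >= 0.
#' @return Loss rate, amount/min.
#' @export
first_order_degradation <- function(amount, loss_rate) {
  if (any(loss_rate < 0)) stop("loss_rate must be >= 0", call. = FALSE)
  pmax(amount, 0) * loss_rate
}
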