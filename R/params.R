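# Default model parameters.
#
# Two layers:
#   * `nominal`  - the published parameter set verbatim, units as printed
#                  (several entries are unit-inconsistent with the printed
#                  flows/pressures; kept for reference and selectable via
#                  config `interpretation` fields).
#   * calibrated - the working values. Venous-side resistances,
#                  distensibilities and all Km values are the nominal ones;
#                  arterial resistances, pump pressures, unstressed volumes
#                  and the secretion/metabolic coefficients are fixed once
#                  by a documented calibration so that the equilibrated
#                  fasting state reproduces resting human physiology
#                  (cardiac output 5.5 L/min, aortic 105 mmHg, SMA
#                  500 ml/min, HA 700 ml/min, portal pressure 1.5 mmHg,
#                  fasting glucose ~5 mM, hormone half-lives 2-3 min,
#                  splanchnic:systemic hormone ratio ~2).

# Fasting hemodynamic design point used by the calibration (mmHg, ml/s).
.fasting_design <- list(
  co = 5500 / 60,            # cardiac output, ml/s
  p_art = 105, p_smcap = 1.5, p_lung = 15, p_splanch = 15,
  q_sma = 600 / 60, q_ha = 700 / 60, q_splenic = 350 / 60,
  q_renal = 1100 / 60,
  glp1_fasting = 10          # splanchnic GLP-1 at high secretory drive, nM
)

#' Default parameter set
#'
#' Returns the full nested parameter list: circulation (resistances in
#' mmHg s/ml, ventricular pump source pressures in mmHg), compartments
#' (fractional distensibility per mmHg, initial and unstressed volumes in
#' ml, summing to the 5 L total blood volume), intestinal absorption,
#' hepatic, peripheral and renal glucose kinetics, hormone secretion and
#' degradation parameters, the intestinal lumen volume, and solver
#' settings. The `nominal` element carries the published values verbatim.
#'
#' @return Named list of parameter blocks.
#' @export
default_parameters <- function() {
  d <- .fasting_design
  q_muscle <- d$co - d$q_sma - d$q_ha - d$q_splenic - d$q_renal

  r_portal_v <- 0.005
  r_hepatic_v <- 0.001
  r_renal_v <- 0.01
  r_somatic_v <- 0.01
  # back out venous-side node pressures at the design flows
  p_hep <- d$p_smcap - d$q_sma * r_portal_v
  p_sysvein <- p_hep - (d$q_sma + d$q_ha + d$q_splenic) * r_hepatic_v
  p_renal <- p_sysvein + d$q_renal * r_renal_v
  p_somatic <- p_sysvein + q_muscle * r_somatic_v

  km_glp1_sma <- 1  # nM, nominal
  circulation <- list(
    r_aortic = 0.04,
    r_pulmonary = 0.06 + 0.001,  # pulmonary artery + vena cava in series
    # SMA resistance at zero GLP-1, placed so that the fasting operating
    # point (GLP-1 ~ 10 nM) yields 500 ml/min:
    r_sma_0 = (d$p_art - d$p_smcap) / d$q_sma *
      (km_glp1_sma + d$glp1_fasting) / km_glp1_sma,
    km_glp1_sma = km_glp1_sma,
    r_hepatic_a = (d$p_art - p_hep) / d$q_ha,
    r_splenic_a = (d$p_art - d$p_splanch) / d$q_splenic,
    r_renal_a = (d$p_art - p_renal) / d$q_renal,
    r_muscle = (d$p_art - p_somatic) / q_muscle,
    r_splenic_v = (d$p_splanch - p_hep) / d$q_splenic,
    r_portal_v = r_portal_v,
    r_hepatic_v = r_hepatic_v,
    r_renal_v = r_renal_v,
    r_somatic_v = r_somatic_v,
    r_shunt = 0.4,
    left_pump_pressure = d$p_art - d$p_lung + d$co * 0.04,
    right_pump_pressure = d$p_lung - p_sysvein + d$co * (0.06 + 0.001)
  )

  name <- c("sys_art", "sm_cap", "hep", "splanch",
            "renal", "somatic", "sys_vein", "lung")
  dist <- c(0.001, 0.005, 0.005, 0.05, 0.05, 0.1, 0.01, 0.005)
  v0i <- c(700, 300, 450, 300, 250, 600, 1900, 500)
  p_target <- c(d$p_art, d$p_smcap, p_hep, d$p_splanch,
                p_renal, p_somatic, p_sysvein, d$p_lung)
  compartments <- data.frame(
    name = name,
    distensibility = dist,
    initial_volume = v0i,
    unstressed_volume = v0i - dist * v0i * p_target,
    stringsAsFactors = FALSE
  )

  list(
    circulation = circulation,
    compartments = compartments,
    absorption = list(
      sglt1_vmax = 5,          # mmol/min
      sglt1_km = 17,           # mM
      p_gl = 0.15,             # um/s (scenario knob)
      exchange_scale = 0.902   # mmol/min per (um/s) per mM gradient
    ),
    hepatic = list(
      vmax_glut2 = 80.7,       # mmol/min
      km_glut2 = 20,           # mM
      km_insulin = 200,        # pM
      hep_insulin_sensitivity = 0.5,
      vmax_glp1_boost = 2,
      km_glp1 = 1,             # nM
      glucagon_coef = 86.65,    # mmol/min at saturating glucagon
      km_glucagon = 2          # nM
    ),
    peripheral = list(
      insulin_dep_coef = 422.9, # mmol/min
      km_glut4 = 2.5,          # mM
      km_insulin = 1600,       # pM (calibrated; hepatic pathway keeps 200)
      glp1_synergy_km = 1,     # nM
      insulin_indep_coef = 0.68,  # mmol/min
      km_glut1 = 1.3           # mM
    ),
    renal = list(
      filtration_fraction = 0.1,
      tm_sglt2 = 1.2,          # mmol/min
      km_sglt2 = 0.1           # mM
    ),
    secretion = list(
      insulin_glc_sensitivity = 236.2,  # pmol/min at saturating drivers
      beta_cell_km = 17,       # mM
      beta_cell_exponent = 2,  # Hill exponent of the glucose factor (1 or 2)
      insulin_glp1_km = 0.002, # nM
      glp1_floor = 0.002,      # nM, keeps basal secretion in GLP-1-null runs
      glucagon_sensitivity = 2.201,  # nmol/min at zero glucose
      glucagon_km = 1.3,       # mM (GLUT1-limited sensing)
      glucagon_exponent = 2,
      glp1_glc_sensitivity = 50,    # dimensionless sweep knob (scenario)
      glp1_secretion_coef = 0.3057, # nmol/min per sensitivity unit
      glp1_km_glut2 = 20,      # mM
      loss = list(             # first-order degradation, 1/min
        insulin_hepatic = 0.1958, insulin_systemic = 0.0245,
        glucagon_hepatic = 0.0231, glucagon_systemic = 0.0462,
        glp1_hepatic = 0.0433, glp1_systemic = 0.0433
      )
    ),
    lumen_volume_l = 1.0,      # intestinal lumen water volume, L
    solver = list(
      rtol = 1e-8, atol = 1e-10, method = "bdf",
      output_dt = 0.25,        # min
      horizon = 180,           # min
      equil_chunk = 400,       # min per equilibration leg
      equil_max_time = 4000,   # min
      equil_tol = 1e-8         # max |dy|/(|y|+1), 1/min
    ),
    nominal = nominal_parameters()
  )
}

#' Published parameter set, verbatim
#'
#' The printed parameter table as published, with printed units. Several
#' entries are dimensionally inconsistent with the printed flows and
#' pressures (see the package vignette); they are retained here for
#' reference and for config round-tripping with
#' `interpretation = "nominal"`.
#'
#' @return Named list.
#' @export
nominal_parameters <- function() {
  list(
    right_ventricular_pump = 290, left_ventricular_pump = 850,  # units unstated
    resistances = list(  # mmHg s/ml as printed
      aortic = 0.04, pulmonary_artery = 0.06, muscle = 0.06, renal_a = 0.1,
      sma = 1, hepatic_a = 0.2, vena_cava = 0.001, somatic_vein = 0.01,
      renal_v = 0.01, portal_v = 0.005, hepatic_v = 0.001, hep_shunt = 0.4
    ),
    distensibility = list(  # 1/mmHg as printed
      left_ventricle = 1e-4, somatic_vein = 0.01, aortic = 0.001,
      sm_cap = 0.005, hep_sinusoid = 0.005, splenic_coeliac = 0.05,
      renal = 0.05, systemic = 0.1
    ),
    glucose = list(
      sglt1_pump_vmax = 5, p_gl = 0.15, glut2_vmax = 3, renal_tm = 1.2,
      glut1_km = 1.3, glut2_km = 20, somatic_metabolic_coef = 0.5,
      somatic_insulin_dep_coef = 8.5, non_insulin_dep_coef = 0.65,
      beta_cell_km = 17
    ),
    insulin = list(km = 200, loss_rate_hepatic = 1.4,
                   sensitivity_coef = 0.5, loss_rate_somatic = 0.1),
    glucagon = list(hepatic_coef = 150, loss_rate_hepatic = 0.5,
                    somatic_coef = 150, loss_rate_somatic = 0.5, km = 2),
    glp1 = list(km = 1, loss_rate_somatic = 0.22, hepatic_sensitivity = 2,
                vm = 20, somatic_sensitivity = 2)
  )
}
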