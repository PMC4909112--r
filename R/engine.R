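# Simulation engine: state assembly, fasting equilibration, gavage runs
# and parameter sweeps.
#
# State vector layout (all named; n = 8 compartments):
#   V_<comp>     blood volume, ml
#   G_<comp>     glucose amount, mmol      (conc mM   = mmol / (3 V/1000 L))
#   I_<comp>     insulin amount, pmol      (conc pM)
#   N_<comp>     glucagon amount, nmol     (conc nM)
#   P_<comp>     GLP-1 amount, nmol        (conc nM)
#   lumen_glc    intestinal lumen glucose, mmol
# Clock in minutes; vessel resistances in mmHg s/ml, so hemodynamic flows
# are computed in ml/s and converted by the factor 60 where they enter
# volume or species derivatives.

COMPARTMENTS <- c("sys_art", "sm_cap", "hep", "splanch",
                  "renal", "somatic", "sys_vein", "lung")
SYSTEMIC_COMPARTMENTS <- c("sys_art", "renal", "somatic", "sys_vein", "lung")

# Precompute everything the RHS needs for a scenario + parameter set.
build_context <- function(scn, params = default_parameters()) {
  params <- apply_scenario(scn, params)
  seg <- vessel_segments(params)
  cmp <- compartment_table(params)
  stopifnot(identical(cmp$name, COMPARTMENTS))
  n <- nrow(cmp)
  m <- nrow(seg)
  inc <- matrix(0, n, m, dimnames = list(cmp$name, seg$name))
  for (j in seq_len(m)) {
    inc[seg$source_node[j], j] <- -1
    inc[seg$sink_node[j], j] <- 1
  }
  state_names <- c(paste0("V_", cmp$name), paste0("G_", cmp$name),
                   paste0("I_", cmp$name), paste0("N_", cmp$name),
                   paste0("P_", cmp$name), "lumen_glc")
  list(
    params = params, scenario = scn, segments = seg, compartments = cmp,
    incidence = inc,
    i_src = match(seg$source_node, cmp$name),
    i_snk = match(seg$sink_node, cmp$name),
    i_sma = match("sma", seg$name),
    sys_idx = match(SYSTEMIC_COMPARTMENTS, cmp$name),
    hep_idx = match("hep", cmp$name),
    smcap_idx = match("sm_cap", cmp$name),
    sysart_idx = match("sys_art", cmp$name),
    renal_idx = match("renal", cmp$name),
    somatic_idx = match("somatic", cmp$name),
    renal_a_idx = match("renal_a", seg$name),
    state_names = state_names,
    n = n, m = m
  )
}

# Gavage source term into the lumen, mmol/min.
gavage_rate <- function(t, gavage) {
  in_window <- t >= gavage$start_time & t < gavage$start_time + gavage$duration
  ifelse(in_window, gavage$dose_mmol / gavage$duration, 0)
}

# Core derivative computation. Returns list(dy, aux) where aux carries the
# instantaneous flows, concentrations and rates used for output tables.
rhs_full <- function(t, y, ctx) {
  p <- ctx$params
  n <- ctx$n
  y <- unname(y)
  V <- y[1:n]
  G <- y[n + (1:n)]
  I <- y[2 * n + (1:n)]
  N <- y[3 * n + (1:n)]
  P <- y[4 * n + (1:n)]
  lumen <- y[5 * n + 1]

  if (any(!is.finite(y))) {
    bad <- ctx$state_names[which(!is.finite(y))[1]]
    stop("integration abort: non-finite state entry ", bad, call. = FALSE)
  }

  # --- hemodynamics ---------------------------------------------------
  vol_l <- 3 * V / 1000                       # species distribution vol, L
  conc_G <- G / vol_l                         # mM
  conc_I <- I / vol_l                         # pM
  conc_N <- N / vol_l                         # nM
  conc_P <- P / vol_l                         # nM

  pres <- (V - ctx$compartments$unstressed_volume) / ctx$compartments$compliance
  res <- ctx$segments$resistance
  res[ctx$i_sma] <- sma_resistance(
    max(conc_P[ctx$smcap_idx], 0),
    list(r_sma_0 = p$circulation$r_sma_0, km_glp1 = p$circulation$km_glp1_sma))
  q <- (pres[ctx$i_src] + ctx$segments$pump_pressure - pres[ctx$i_snk]) / res
  dV <- 60 * drop(ctx$incidence %*% q)        # ml/min

  # --- advection (donor/upwind), L/min x amount/L = amount/min --------
  q_lmin <- q * 60 / 1000
  adv <- function(conc) {
    donor <- ifelse(q_lmin >= 0, conc[ctx$i_src], conc[ctx$i_snk])
    drop(ctx$incidence %*% (q_lmin * donor))
  }
  dG <- adv(conc_G)
  dI <- adv(conc_I)
  dN <- adv(conc_N)
  dP <- adv(conc_P)

  # --- glucose sources and sinks --------------------------------------
  lumen_conc <- lumen / p$lumen_volume_l      # mM
  absorb <- intestinal_absorption_rate(lumen_conc, conc_G[ctx$smcap_idx],
                                       p$absorption)
  hep_rate <- hepatic_metabolic_rate(conc_G[ctx$hep_idx], conc_I[ctx$hep_idx],
                                     conc_P[ctx$hep_idx], conc_N[ctx$hep_idx],
                                     p$hepatic)
  ins_dep <- peripheral_insulin_dependent_rate(
    conc_G[ctx$somatic_idx], conc_I[ctx$somatic_idx],
    conc_P[ctx$somatic_idx], p$peripheral)
  ins_indep <- insulin_independent_rate(conc_G[ctx$somatic_idx], p$peripheral)
  renal_flow_mlmin <- 60 * q[ctx$renal_a_idx]
  renal_exc <- renal_glucose_excretion(conc_G[ctx$renal_idx],
                                       renal_flow_mlmin, p$renal)

  dG[ctx$smcap_idx] <- dG[ctx$smcap_idx] + absorb
  dG[ctx$hep_idx] <- dG[ctx$hep_idx] - hep_rate
  dG[ctx$somatic_idx] <- dG[ctx$somatic_idx] - ins_dep - ins_indep
  dG[ctx$renal_idx] <- dG[ctx$renal_idx] - renal_exc
  d_lumen <- gavage_rate(t, ctx$scenario$gavage) - absorb

  # --- hormone secretion (all into the SM capillary compartment) ------
  sec <- p$secretion
  sec_ins <- insulin_secretion_rate(conc_G[ctx$sysart_idx],
                                    conc_P[ctx$sysart_idx], sec)
  sec_gln <- glucagon_secretion_rate(conc_G[ctx$sysart_idx], sec)
  sec_glp <- glp1_secretion_rate(conc_G[ctx$smcap_idx], sec)
  dI[ctx$smcap_idx] <- dI[ctx$smcap_idx] + sec_ins
  dN[ctx$smcap_idx] <- dN[ctx$smcap_idx] + sec_gln
  dP[ctx$smcap_idx] <- dP[ctx$smcap_idx] + sec_glp

  # --- degradation: hepatic territory + systemic territories ----------
  loss <- sec$loss
  dI[ctx$hep_idx] <- dI[ctx$hep_idx] -
    first_order_degradation(I[ctx$hep_idx], loss$insulin_hepatic)
  dN[ctx$hep_idx] <- dN[ctx$hep_idx] -
    first_order_degradation(N[ctx$hep_idx], loss$glucagon_hepatic)
  dP[ctx$hep_idx] <- dP[ctx$hep_idx] -
    first_order_degradation(P[ctx$hep_idx], loss$glp1_hepatic)
  si <- ctx$sys_idx
  dI[si] <- dI[si] - first_order_degradation(I[si], loss$insulin_systemic)
  dN[si] <- dN[si] - first_order_degradation(N[si], loss$glucagon_systemic)
  dP[si] <- dP[si] - first_order_degradation(P[si], loss$glp1_systemic)

  dy <- c(dV, dG, dI, dN, dP, d_lumen)
  names(dy) <- ctx$state_names
  names(pres) <- ctx$compartments$name
  q <- stats::setNames(q, ctx$segments$name)
  list(dy = dy,
       aux = list(pressures = pres, flows_mlmin = 60 * q,
                  conc_G = conc_G, conc_I = conc_I, conc_N = conc_N,
                  conc_P = conc_P, lumen_conc = lumen_conc,
                  q_lmin = q_lmin,
                  rates = c(absorption = unname(absorb),
                            nhgu = unname(hep_rate),
                            ins_dep = unname(ins_dep),
                            ins_indep = unname(ins_indep),
                            renal_excretion = unname(renal_exc),
                            sec_insulin = unname(sec_ins),
                            sec_glucagon = unname(sec_gln),
                            sec_glp1 = unname(sec_glp))))
}

#' Assemble the full state derivative vector
#'
#' Composes the right-hand side of the coupled circulation + species system
#' from the module-level operations: compartment pressures and segment
#' flows, upwind advection, intestinal absorption, hepatic/peripheral/renal
#' glucose handling, hormone secretion and first-order degradation, plus
#' the gavage source into the intestinal lumen. Deterministic in
#' `(t, state)`.
#'
#' @param t Time, minutes.
#' @param state Named state vector (layout: volumes, then glucose, insulin,
#'   glucagon, GLP-1 per compartment, then lumen glucose).
#' @param scn A [scenario()].
#' @param params Parameter list.
#' @return Named derivative vector (per minute).
#' @export
assemble_derivatives <- function(t, state, scn, params = default_parameters()) {
  ctx <- build_context(scn, params)
  rhs_full(t, state, ctx)$dy
}

# deSolve-facing wrapper.
rhs_desolve <- function(t, y, ctx) {
  list(rhs_full(t, y, ctx)$dy)
}

initial_state <- function(ctx) {
  cmp <- ctx$compartments
  vol_l <- 3 * cmp$initial_volume / 1000
  splanchnic <- cmp$name %in% c("sm_cap", "splanch", "hep")
  g0 <- 5 * vol_l
  i0 <- ifelse(splanchnic, 60, 30) * vol_l
  n0 <- ifelse(splanchnic, 0.5, 0.25) * vol_l
  sens <- ctx$params$secretion$glp1_glc_sensitivity
  p0 <- ifelse(splanchnic, 10, 5) * vol_l * sens / 50
  y <- c(cmp$initial_volume, g0, i0, n0, p0, 0)
  names(y) <- ctx$state_names
  y
}

#' Equilibrate to the fasting steady state
#'
#' Integrates the system with no gavage until the maximum relative state
#' derivative `|dy|/(|y|+1)` falls below `params$solver$equil_tol`
#' (default 1e-8 per minute), starting either from the nominal initial
#' volumes and rough fasting concentrations or from a supplied state.
#'
#' @param scn A [scenario()].
#' @param params Parameter list.
#' @param state Optional starting state (defaults to the built-in guess).
#' @return Named fasting state vector, with the convergence measure in
#'   attribute `"residual"`.
#' @export
equilibrate <- function(scn, params = default_parameters(), state = NULL) {
  ctx <- build_context(scn, params)
  scn_fast <- scn
  scn_fast$gavage <- gavage_protocol(dose_g = 0)
  ctx$scenario <- scn_fast
  y <- if (is.null(state)) initial_state(ctx) else state
  sol <- ctx$params$solver
  t_done <- 0
  repeat {
    out <- deSolve::ode(y, c(0, sol$equil_chunk), rhs_desolve, ctx,
                        method = sol$method, rtol = sol$rtol, atol = sol$atol,
                        maxsteps = 100000)
    y <- out[nrow(out), -1]
    t_done <- t_done + sol$equil_chunk
    dy <- rhs_full(0, y, ctx)$dy
    resid <- max(abs(dy) / (abs(y) + 1))
    if (resid < sol$equil_tol) break
    if (t_done >= sol$equil_max_time) {
      worst <- names(sort(abs(dy) / (abs(y) + 1), decreasing = TRUE))[1:3]
      stop("equilibrate did not converge (residual ", signif(resid, 3),
           "); worst states: ", paste(worst, collapse = ", "), call. = FALSE)
    }
  }
  attr(y, "residual") <- resid
  y
}

# Assemble the wide output table from integrator output rows.
build_result <- function(times, states, ctx) {
  nt <- length(times)
  rows <- vector("list", nt)
  for (i in seq_len(nt)) {
    a <- rhs_full(times[i], states[i, ], ctx)$aux
    seg <- ctx$segments
    glc_seg_flow <- function(sname) {
      j <- match(sname, seg$name)
      advective_flux(a$q_lmin[j], a$conc_G[ctx$i_src[j]], a$conc_G[ctx$i_snk[j]])
    }
    spec_shunt <- function(conc) {
      j <- match("shunt", seg$name)
      advective_flux(a$q_lmin[j], conc[ctx$i_src[j]], conc[ctx$i_snk[j]])
    }
    grad <- a$lumen_conc - a$conc_G[ctx$smcap_idx]
    rows[[i]] <- c(
      stats::setNames(a$pressures, paste0("pressure_", COMPARTMENTS)),
      stats::setNames(a$flows_mlmin, paste0("flow_", seg$name)),
      stats::setNames(a$conc_G, paste0("glc_", COMPARTMENTS)),
      stats::setNames(a$conc_I, paste0("ins_", COMPARTMENTS)),
      stats::setNames(a$conc_N, paste0("gln_", COMPARTMENTS)),
      stats::setNames(a$conc_P, paste0("glp1_", COMPARTMENTS)),
      stats::setNames(states[i, 1:ctx$n], paste0("volume_", COMPARTMENTS)),
      lumen_glc = unname(a$lumen_conc),
      rate_absorption = unname(a$rates["absorption"]),
      rate_nhgu = unname(a$rates["nhgu"]),
      rate_ins_dep = unname(a$rates["ins_dep"]),
      rate_ins_indep = unname(a$rates["ins_indep"]),
      rate_renal_excretion = unname(a$rates["renal_excretion"]),
      sec_insulin = unname(a$rates["sec_insulin"]),
      sec_glucagon = unname(a$rates["sec_glucagon"]),
      sec_glp1 = unname(a$rates["sec_glp1"]),
      glcflow_portal_v = glc_seg_flow("portal_v"),
      glcflow_hepatic_a = glc_seg_flow("hepatic_a"),
      glcflow_hepatic_v = glc_seg_flow("hepatic_v"),
      glcflow_shunt = spec_shunt(a$conc_G),
      insflow_shunt = spec_shunt(a$conc_I),
      glnflow_shunt = spec_shunt(a$conc_N),
      glp1flow_shunt = spec_shunt(a$conc_P),
      perm_unidirectional = if (grad > 0.1) {
        unname(a$rates["absorption"]) / grad
      } else NA_real_
    )
  }
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(time = times, tab)
  colnames(states) <- ctx$state_names
  structure(list(time = times, series = tab,
                 scenario = ctx$scenario, params = ctx$params,
                 state_names = ctx$state_names,
                 states = states,
                 final_state = states[nt, ],
                 fasting_state = states[1, ]),
            class = "splanchsim_result")
}

#' @export
print.splanchsim_result <- function(x, ...) {
  cat("<splanchsim_result>: ", length(x$time), " time points, ",
      ncol(x$series) - 1, " quantities, t = ",
      min(x$time), "-", max(x$time), " min\n", sep = "")
  invisible(x)
}

#' Run a gavage scenario
#'
#' Equilibrates to the fasting steady state, then simulates the scenario
#' clock from t = 0 through `params$solver$horizon` minutes (default 180,
#' gavage at 100-120 min) with a stiff adaptive integrator, restarting the
#' integration at the gavage on/off discontinuities. The returned wide
#' table carries node pressures (mmHg), segment blood flows (ml/min),
#' species concentrations per compartment (mM / pM / nM / nM),
#' compartment volumes, metabolic and secretion rates (mmol/min,
#' pmol/min, nmol/min), species flows through the portal vein, hepatic
#' artery/vein and shunt, and the unidirectional intestinal glucose
#' permeability (absorption rate per mM lumen-capillary gradient).
#'
#' @param scn A [scenario()].
#' @param params Parameter list.
#' @param fasting_state Optional pre-computed fasting state (skips
#'   re-equilibration, e.g. in sweeps over absorption-phase parameters).
#' @return A `splanchsim_result`.
#' @export
run_scenario <- function(scn, params = default_parameters(),
                         fasting_state = NULL) {
  ctx <- build_context(scn, params)
  y0 <- if (is.null(fasting_state)) equilibrate(scn, params) else fasting_state
  sol <- ctx$params$solver
  g <- scn$gavage
  breaks <- sort(unique(c(0, g$start_time,
                          min(g$start_time + g$duration, sol$horizon),
                          sol$horizon)))
  breaks <- breaks[breaks >= 0 & breaks <= sol$horizon]
  times_all <- NULL
  states_all <- NULL
  y <- y0
  for (k in seq_len(length(breaks) - 1)) {
    tt <- seq(breaks[k], breaks[k + 1], by = sol$output_dt)
    if (tt[length(tt)] < breaks[k + 1]) tt <- c(tt, breaks[k + 1])
    out <- deSolve::ode(y, tt, rhs_desolve, ctx,
                        method = sol$method, rtol = sol$rtol, atol = sol$atol,
                        maxsteps = 100000)
    if (attr(out, "istate")[1] < 0) {
      stop("solver failure in segment starting t = ", breaks[k], call. = FALSE)
    }
    y <- out[nrow(out), -1]
    keep <- if (k == 1) seq_len(nrow(out)) else -1
    times_all <- c(times_all, out[keep, 1])
    states_all <- rbind(states_all, out[keep, -1, drop = FALSE])
  }
  build_result(times_all, states_all, ctx)
}

#' Run a one- or two-axis parameter sweep
#'
#' One independent simulation per grid point, all on the common output time
#' grid. Axis paths are either scenario knob names
#' (`"glp1_glucose_sensitivity"`, `"p_gl"`, `"pss_resistance"`,
#' `"presinusoidal_resistance"`) or dot-separated parameter paths.
#'
#' @param base Base [scenario()].
#' @param axis1 List `list(path = <string>, grid = <numeric>)`.
#' @param axis2 Optional second axis, same form.
#' @param params Parameter list.
#' @return List of class `splanchsim_sweep`: `grid` (data.frame of axis
#'   values per run) and `results` (list of `splanchsim_result` or, for
#'   failed points, the error condition).
#' @export
run_sweep <- function(base, axis1, axis2 = NULL,
                      params = default_parameters()) {
  stopifnot(length(axis1$grid) >= 1)
  if (!is.null(axis2)) stopifnot(length(axis2$grid) >= 1)
  g1 <- axis1$grid
  g2 <- if (is.null(axis2)) NA_real_ else axis2$grid
  grid <- expand.grid(axis1 = g1, axis2 = g2, KEEP.OUT.ATTRS = FALSE)
  set_knob <- function(scn, path, value) {
    if (path %in% c("glp1_glucose_sensitivity", "p_gl",
                    "pss_resistance", "presinusoidal_resistance")) {
      scn[[path]] <- value
    } else {
      scn$overrides[[path]] <- value
    }
    scn
  }
  results <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    scn <- set_knob(base, axis1$path, grid$axis1[i])
    if (!is.null(axis2)) scn <- set_knob(scn, axis2$path, grid$axis2[i])
    results[[i]] <- tryCatch(run_scenario(scn, params),
                             error = function(e) e)
  }
  names(results) <- apply(grid, 1, function(r) {
    if (is.null(axis2)) sprintf("%s=%g", axis1$path, r[["axis1"]])
    else sprintf("%s=%g;%s=%g", axis1$path, r[["axis1"]],
                 axis2$path, r[["axis2"]])
  })
  colnames(grid) <- c(axis1$path, if (!is.null(axis2)) axis2$path else "unused")
  structure(list(grid = grid, results = results,
                 axis1 = axis1, axis2 = axis2),
            class = "splanchsim_sweep")
}
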