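scn_normal <- preset_scenario("normal")

test_that("derivatives vanish at the fasting equilibrium and sum to zero", {
  y <- fasting_state_normal()
  dy <- assemble_derivatives(0, y, scn_normal)
  expect_lt(max(abs(dy) / (abs(y) + 1)), 1e-7)
  n <- 8
  expect_equal(sum(dy[1:n]), 0, tolerance = 1e-9)  # closed circuit
  # during the gavage window the lumen gains dose/duration
  dy_gav <- assemble_derivatives(105, y, scn_normal)
  g <- scn_normal$gavage
  expect_equal(dy_gav[["lumen_glc"]] - dy[["lumen_glc"]],
               g$dose_mmol / g$duration)
  expect_equal(sum(dy_gav[1:n]), 0, tolerance = 1e-9)
  y_bad <- y
  y_bad[3] <- NaN
  expect_error(assemble_derivatives(0, y_bad, scn_normal), "non-finite")
})

test_that("equilibration reproduces resting physiology from any start", {
  y <- fasting_state_normal()
  expect_lt(attr(y, "residual"), 1e-8)
  aux <- fasting_aux(scn_normal, y)
  co <- aux$flows_mlmin[["aortic"]] / 1000
  expect_equal(co, 5.5, tolerance = 0.1)            # L/min
  expect_equal(aux$pressures[["sys_art"]], 105, tolerance = 0.1)
  expect_equal(aux$conc_G[[1]], 5, tolerance = 0.1)  # sys_art glucose, mM
  # two-start uniqueness: perturbed initial volumes reach the same state
  ctx <- splanchsim:::build_context(scn_normal)
  y0 <- splanchsim:::initial_state(ctx)
  nudge <- y0
  nudge[1:8] <- nudge[1:8] + c(40, -20, 10, -10, 15, -15, -30, 10)
  y2 <- equilibrate(scn_normal, state = nudge)
  expect_equal(unname(y2), unname(y), tolerance = 1e-6)
})

test_that("zero-dose gavage leaves every series flat at fasting", {
  scn0 <- scenario(gavage = gavage_protocol(dose_g = 0))
  p <- default_parameters()
  p$solver$horizon <- 40
  res <- run_scenario(scn0, p)
  for (q in c("glc_sys_art", "ins_sys_art", "flow_sma", "pressure_sys_art")) {
    v <- res$series[[q]]
    expect_lt(max(abs(v - v[1])) / (abs(v[1]) + 1), 1e-6)
  }
})

test_that("simulation conserves blood volume and keeps species non-negative", {
  res <- run_normal()
  vol <- rowSums(res$series[paste0("volume_", splanchsim:::COMPARTMENTS)])
  expect_lt(max(abs(vol - vol[1])) / vol[1], 1e-6)
  conc_cols <- grep("^(glc|ins|gln|glp1)_", names(res$series), value = TRUE)
  expect_true(all(as.matrix(res$series[conc_cols]) >= 0))
  expect_true(all(diff(res$time) > 0))
})

test_that("glucose accounting identity holds along the trajectory", {
  # d/dt(total glucose incl. lumen) - gavage source =
  #   -(hepatic net uptake + peripheral + renal) + 0 advection
  res <- run_normal()
  ctx <- splanchsim:::build_context(res$scenario, res$params)
  for (t_probe in c(0, 105, 112, 130, 170)) {
    i <- which.min(abs(res$time - t_probe))
    full <- splanchsim:::rhs_full(res$time[i], res$states[i, ], ctx)
    n <- 8
    lhs <- sum(full$dy[n + (1:n)]) + full$dy[[5 * n + 1]] -
      splanchsim:::gavage_rate(res$time[i], res$scenario$gavage)
    rhs <- -(full$aux$rates[["nhgu"]] + full$aux$rates[["ins_dep"]] +
             full$aux$rates[["ins_indep"]] + full$aux$rates[["renal_excretion"]])
    expect_equal(lhs, rhs, tolerance = 1e-5 * max(1, abs(rhs)))
  }
})

test_that("disabling both absorption pathways reproduces the fasting run", {
  p <- default_parameters()
  p$solver$horizon <- 130  # through the gavage window
  scn_na <- scenario(p_gl = 0, overrides = list(absorption.sglt1_vmax = 0))
  res <- run_scenario(scn_na, p)
  g <- res$series$glc_sm_cap
  expect_lt(max(abs(g - g[1])), 1e-6)
  expect_gt(max(res$series$lumen_glc), 100)  # dose accumulates unabsorbed
})

test_that("splanchnic hormone levels stay above systemic without a shunt", {
  res <- run_normal()
  s <- res$series
  for (h in c("ins", "gln", "glp1")) {
    expect_true(all(s[[paste0(h, "_sm_cap")]] >=
                    s[[paste0(h, "_sys_art")]] * (1 - 1e-6)))
  }
})

test_that("closed shunt carries almost no flow; HA buffers PV emergently", {
  res <- run_normal()
  s <- res$series
  expect_lt(max(abs(s$flow_shunt)), 100)  # ml/min at R = 40
  post <- s$time >= 100 & s$time <= 140
  # portal flow rises while hepatic arterial flow falls, with no coupling
  # programmed between them
  expect_gt(max(s$flow_portal_v[post]), 1.2 * s$flow_portal_v[1])
  expect_lt(min(s$flow_hepatic_a[post]), s$flow_hepatic_a[1])
})

test_that("a one-point sweep reproduces run_scenario and failures are kept", {
  p <- default_parameters()
  p$solver$horizon <- 30
  scn <- scenario(gavage = gavage_protocol(dose_g = 10, start_time = 5,
                                           duration = 5))
  sw <- run_sweep(scn, list(path = "p_gl", grid = 0.15), params = p)
  direct <- run_scenario(scn, p)
  expect_equal(sw$results[[1]]$series, direct$series, tolerance = 1e-10)
  sw_bad <- run_sweep(scn, list(path = "no.such.param", grid = c(1, 2)),
                      params = p)
  expect_true(all(vapply(sw_bad$results, inherits, logical(1), "error")))
})

test_that("reruns are bitwise identical (no randomness in the engine)", {
  p <- default_parameters()
  p$solver$horizon <- 40
  scn <- scenario(gavage = gavage_protocol(dose_g = 25, start_time = 10,
                                           duration = 10))
  r1 <- run_scenario(scn, p)
  r2 <- run_scenario(scn, p)
  expect_identical(r1$series, r2$series)
})
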