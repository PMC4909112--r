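test_that("phase extraction samples the glycaemic extremes", {
  res <- run_normal()
  ph <- extract_phase_values(res, "flow_sma")
  expect_gte(ph$feeding_time, res$scenario$gavage$start_time)
  expect_lt(ph$fasting_time, res$scenario$gavage$start_time)
  expect_gt(ph$feeding_value, ph$fasting_value)
  # the feeding sample coincides with the systemic glucose maximum
  i <- which(res$time == ph$feeding_time)
  post <- res$series$time >= 100
  expect_equal(res$series$glc_sys_art[i], max(res$series$glc_sys_art[post]))
  expect_error(extract_phase_values(res, "nope"), "unknown quantity")
})

test_that("phase extraction degenerates gracefully on constant input", {
  res <- run_normal()
  flat <- res
  flat$series$glc_sys_art <- 5
  flat$series$flow_sma <- 600
  ph <- extract_phase_values(flat, "flow_sma")
  expect_equal(ph$feeding_value, ph$fasting_value)
})

test_that("hyperbolic fitter recovers its own model class exactly", {
  x <- c(0.5, 1, 2, 4, 8, 16)
  y <- 10 * x / (x + 2)
  fit <- fit_hyperbola(x, y, baseline = 0)
  expect_true(fit$converged)
  expect_equal(fit$vmax, 10, tolerance = 1e-8)
  expect_equal(fit$k_half, 2, tolerance = 1e-8)
  expect_lt(fit$residual_norm, 1e-10)
  # with an estimated baseline
  y2 <- 3 + 7 * x / (x + 1.5)
  fit2 <- fit_hyperbola(x, y2)
  expect_equal(fit2$baseline, 3, tolerance = 1e-6)
  expect_equal(fit2$vmax, 7, tolerance = 1e-6)
  expect_equal(fit2$k_half, 1.5, tolerance = 1e-6)
})

test_that("hyperbolic fitter tolerates 1% noise within 5% parameter error", {
  x <- c(0.5, 1, 2, 4, 8, 16, 32)
  mu <- 10 * x / (x + 2)
  set.seed(42)
  for (rep in 1:40) {
    y <- mu * (1 + rnorm(length(x), sd = 0.01))
    fit <- fit_hyperbola(x, y, baseline = 0)
    expect_true(fit$converged)
    expect_lt(abs(fit$vmax - 10) / 10, 0.05)
    expect_lt(abs(fit$k_half - 2) / 2, 0.05)
  }
})

test_that("surface fitter is exact on polynomial data and nests orders", {
  g <- expand.grid(x = seq(0, 1, 0.25), y = seq(0, 1, 0.25))
  z <- 3 * g$x * g$y
  fit <- fit_quadratic_surface(g$x, g$y, z)
  expect_equal(unname(fit$coefficients["c"]), 3, tolerance = 1e-10)
  expect_lt(max(abs(fit$coefficients[c("a", "b", "d", "e", "f")])), 1e-10)
  expect_lt(fit$residual_norm, 1e-10)
  # cubic response: order 3 fits exactly, order 2 cannot; residual nests
  z3 <- 2 * g$x^3 - g$y^2 + g$x * g$y + 0.5
  f2 <- fit_quadratic_surface(g$x, g$y, z3, order = 2)
  f3 <- fit_quadratic_surface(g$x, g$y, z3, order = 3)
  expect_lte(f3$residual_norm, f2$residual_norm)
  expect_lt(f3$residual_norm, 1e-10)
  expect_equal(f3$interaction_c, 1, tolerance = 1e-8)
  # rank deficiency is reported, not silently absorbed
  expect_error(fit_quadratic_surface(c(0, 1, 2), c(0, 0, 0), c(1, 2, 3)),
               "rank-deficient")
})

test_that("surface normalization only rescales the predictors", {
  g <- expand.grid(x = seq(2, 50, length.out = 5), y = seq(0, 0.16, length.out = 5))
  z <- 1.5 * g$x * g$y + 0.2 * g$x
  fit_raw <- fit_quadratic_surface(g$x, g$y, z, normalize = FALSE)
  fit_nrm <- fit_quadratic_surface(g$x, g$y, z, normalize = TRUE)
  expect_equal(unname(fit_raw$coefficients["c"]), 1.5, tolerance = 1e-8)
  # normalized c rescales by the axis ranges; sign is preserved
  expect_equal(fit_nrm$interaction_c, 1.5 * 48 * 0.16, tolerance = 1e-8)
  expect_gt(fit_nrm$interaction_c * fit_raw$interaction_c, 0)
})

test_that("normalized ratio series is 1 for test = control and unit-invariant", {
  res <- run_normal()
  r <- normalized_ratio_series(res, res, "ins_sys_art", "glc_sys_art")
  expect_equal(r$ratio, rep(1, length(res$time)))
  scaled <- res
  scaled$series$ins_sys_art <- res$series$ins_sys_art * 1000  # pM -> fM
  r2 <- normalized_ratio_series(scaled, res, "ins_sys_art", "glc_sys_art")
  r3 <- normalized_ratio_series(res, scaled, "ins_sys_art", "glc_sys_art")
  expect_equal(r2$ratio, rep(1000, length(res$time)))
  expect_equal(r2$ratio * r3$ratio, rep(1, length(res$time)))
  short <- res
  short$time <- res$time[-1]
  short$series <- res$series[-1, ]
  expect_error(normalized_ratio_series(short, res, "ins_sys_art", "glc_sys_art"),
               "alignment")
  neg <- res
  neg$series$glc_sys_art[5] <- 0
  expect_warning(r4 <- normalized_ratio_series(res, neg, "ins_sys_art",
                                               "glc_sys_art"), "masked")
  expect_true(is.na(r4$ratio[5]))
})

test_that("peak metrics match the analytic triangle and refuse monotone decay", {
  tt <- seq(0, 60, by = 0.25)
  tri <- pmax(0, 10 - abs(tt - 20))  # peak 10 at t = 20, zero plateau
  pm <- peak_metrics(tt, tri, after = 5, plateau_window = 10)
  expect_equal(pm$peak_value, 10)
  expect_equal(pm$peak_time, 20)
  expect_equal(pm$plateau, 0)
  expect_equal(pm$half_time, 5)   # falls to 5 at t = 25
  mono <- seq(5, 10, length.out = length(tt))  # never decays from its peak
  pm2 <- peak_metrics(tt, mono)
  expect_true(is.na(pm2$half_time))
})

test_that("sweep summaries are long-format with both phases", {
  sw <- sweep_sens_pgl()
  summ <- sweep_summary(sw, c("flow_sma", "rate_nhgu"))
  expect_equal(nrow(summ), 9 * 2 * 2)
  expect_setequal(unique(summ$phase), c("feeding", "fasting"))
  # fasting values are independent of P_gl (empty lumen)
  fast_sma <- summ[summ$phase == "fasting" & summ$quantity == "flow_sma", ]
  spread <- tapply(fast_sma$value, fast_sma$glp1_glucose_sensitivity,
                   function(v) diff(range(v)))
  expect_lt(max(spread), 1e-4)
})
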