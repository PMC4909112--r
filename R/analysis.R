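# Sensitivity analysis: phase extraction at glycaemic extremes, hyperbolic
# dose-response fits, quadratic/cubic response surfaces with interaction
# coefficient c, normalized ratio series and peak metrics.

#' Extract feeding- and fasting-phase values of a quantity
#'
#' The feeding value is sampled at the time of maximal systemic arterial
#' glucose from the gavage onward; the fasting value at the time of
#' minimal systemic arterial glucose within the pre-gavage fasting window
#' (insulin persistence can push glucose transiently below the fasting
#' level after absorption ends, and that hypoglycemic undershoot is part
#' of the feeding response, not the fasting state). Ties break toward the
#' earliest time; a zero-dose run uses the whole window for both phases.
#'
#' @param result A `splanchsim_result`.
#' @param quantity Column name in `result$series`.
#' @return List with `feeding_time`, `fasting_time`, `feeding_value`,
#'   `fasting_value`.
#' @export
extract_phase_values <- function(result, quantity) {
  tab <- result$series
  if (!quantity %in% names(tab)) {
    stop("unknown quantity: ", quantity, call. = FALSE)
  }
  g <- tab$glc_sys_art
  gav <- result$scenario$gavage
  split_at <- if (gav$dose_g > 0) gav$start_time else Inf
  feed_win <- tab$time >= split_at
  fast_win <- tab$time < split_at
  if (!any(feed_win)) feed_win <- rep(TRUE, length(g))
  if (!any(fast_win)) fast_win <- rep(TRUE, length(g))
  i_feed <- which(feed_win)[which.max(g[feed_win])]
  i_fast <- which(fast_win)[which.min(g[fast_win])]
  list(feeding_time = tab$time[i_feed], fasting_time = tab$time[i_fast],
       feeding_value = tab[[quantity]][i_feed],
       fasting_value = tab[[quantity]][i_fast])
}

#' Fit a hyperbolic (Michaelis-Menten-like) dose-response curve
#'
#' Least-squares fit of `y = baseline + vmax * x / (x + k_half)` by the
#' Levenberg-Marquardt algorithm. With `baseline = NULL` the offset is
#' estimated; pass a number to fix it (0 for a through-origin hyperbola).
#'
#' @param x Predictor values (>= 0, at least 3 distinct).
#' @param y Response values.
#' @param baseline Fixed additive offset, or NULL to estimate it.
#' @return List of class `splanchsim_hyperbolic_fit`: `vmax`, `k_half`,
#'   `baseline`, `residual_norm`, `converged`, `fitted`.
#' @export
fit_hyperbola <- function(x, y, baseline = NULL) {
  stopifnot(length(x) == length(y), length(unique(x)) >= 3, all(x >= 0))
  est_base <- is.null(baseline)
  k0 <- max(stats::median(x), 1e-6)
  b0 <- if (est_base) min(y) else baseline
  v0 <- max(max(y) - b0, 1e-6)
  fit <- tryCatch({
    if (est_base) {
      minpack.lm::nlsLM(y ~ b + v * x / (x + k),
                        start = list(b = b0, v = v0, k = k0),
                        lower = c(-Inf, -Inf, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(y ~ b0 + v * x / (x + k),
                        start = list(v = v0, k = k0),
                        lower = c(-Inf, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    }
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(vmax = NA_real_, k_half = NA_real_,
                          baseline = if (est_base) NA_real_ else baseline,
                          residual_norm = NA_real_, converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "splanchsim_hyperbolic_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(
    vmax = unname(cf["v"]), k_half = unname(cf["k"]),
    baseline = if (est_base) unname(cf["b"]) else baseline,
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    converged = TRUE, fitted = stats::fitted(fit)),
    class = "splanchsim_hyperbolic_fit")
}

#' Fit a second- or third-order response surface
#'
#' Linear least squares of `z = a x^2 + b y^2 + c x y + d x + e y + f`
#' (order 2), or the full cubic basis (order 3, which nests order 2).
#' Predictors are rescaled to [0, 1] before fitting (the interaction
#' coefficient is otherwise unit-dependent); the reported coefficients are
#' on the normalized scale and the sign of `interaction_c` classifies the
#' x*y interaction: synergy (c > 0), antagonism (c < 0), independence
#' (c ~ 0).
#'
#' @param x,y Predictor vectors.
#' @param z Response vector.
#' @param order 2 or 3.
#' @param normalize Rescale predictors to [0, 1] (default TRUE).
#' @return List of class `splanchsim_surface_fit`: `coefficients` (named
#'   a-f plus any cubic terms), `interaction_c`, `order`, `residual_norm`.
#' @export
fit_quadratic_surface <- function(x, y, z, order = 2, normalize = TRUE) {
  stopifnot(order %in% c(2, 3), length(x) == length(y), length(y) == length(z))
  if (normalize) {
    rx <- range(x); ry <- range(y)
    if (diff(rx) > 0) x <- (x - rx[1]) / diff(rx)
    if (diff(ry) > 0) y <- (y - ry[1]) / diff(ry)
  }
  basis <- data.frame(x2 = x^2, y2 = y^2, xy = x * y, x = x, y = y)
  if (order == 3) {
    basis <- cbind(basis, data.frame(x3 = x^3, y3 = y^3,
                                     x2y = x^2 * y, xy2 = x * y^2))
  }
  n_coef <- ncol(basis) + 1
  if (nrow(unique(data.frame(x, y))) < n_coef) {
    stop("rank-deficient design: need at least ", n_coef,
         " distinct (x, y) points", call. = FALSE)
  }
  fit <- stats::lm(z ~ ., data = cbind(z = z, basis))
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design: unidentifiable basis terms ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cf <- stats::coef(fit)
  named <- c(a = unname(cf["x2"]), b = unname(cf["y2"]), c = unname(cf["xy"]),
             d = unname(cf["x"]), e = unname(cf["y"]),
             f = unname(cf["(Intercept)"]))
  if (order == 3) {
    named <- c(named, g_x3 = unname(cf["x3"]), h_y3 = unname(cf["y3"]),
               i_x2y = unname(cf["x2y"]), j_xy2 = unname(cf["xy2"]))
  }
  structure(list(coefficients = named, interaction_c = unname(cf["xy"]),
                 order = order,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 fitted = stats::fitted(fit)),
            class = "splanchsim_surface_fit")
}

#' Shunt-normalized ratio time series
#'
#' Computes `(num_test/den_test) / (num_control/den_control)` pointwise on
#' the shared output grid - e.g. the systemic insulin:glucose ratio of a
#' shunted run relative to the shunt-closed control. Identically 1 when
#' test equals control; invariant to common unit rescaling of both runs.
#'
#' @param test,control `splanchsim_result` objects on the same time grid.
#' @param numerator,denominator Column names in the series tables.
#' @return data.frame with `time` and `ratio` (denominator-nonpositive
#'   points are NA, with a warning).
#' @export
normalized_ratio_series <- function(test, control, numerator, denominator) {
  if (!isTRUE(all.equal(test$time, control$time))) {
    stop("alignment error: test and control time grids differ", call. = FALSE)
  }
  nt <- test$series[[numerator]]; dt <- test$series[[denominator]]
  nc <- control$series[[numerator]]; dc <- control$series[[denominator]]
  if (is.null(nt) || is.null(nc)) stop("unknown numerator: ", numerator, call. = FALSE)
  if (is.null(dt) || is.null(dc)) stop("unknown denominator: ", denominator, call. = FALSE)
  bad <- dt <= 0 | dc <= 0
  if (any(bad)) {
    warning(sum(bad), " points masked: nonpositive denominator")
  }
  ratio <- (nt / dt) / (nc / dc)
  ratio[bad] <- NA_real_
  data.frame(time = test$time, ratio = ratio)
}

#' Peak metrics of a time series
#'
#' Peak value and time (global extremum at or after `after`), rise time
#' from `after` to the peak, and the decay half-time: the first time the
#' post-peak excess over the late plateau (mean of the final
#' `plateau_window` minutes) falls to half. For a series that never decays
#' below half-excess the half-time is NA, not fabricated.
#'
#' @param time Time vector (min).
#' @param value Series values.
#' @param after Only consider peaks at or after this time (e.g. gavage
#'   start; default 0).
#' @param plateau_window Width of the terminal window defining the plateau
#'   (min, default 10).
#' @return List: `peak_value`, `peak_time`, `rise_time`, `half_time`,
#'   `plateau`.
#' @export
peak_metrics <- function(time, value, after = 0, plateau_window = 10) {
  stopifnot(length(time) == length(value), length(time) > 0)
  sel <- time >= after
  t2 <- time[sel]; v2 <- value[sel]
  ip <- which.max(v2)
  peak <- v2[ip]; tpeak <- t2[ip]
  plateau <- mean(v2[t2 >= max(t2) - plateau_window])
  post <- t2 > tpeak
  excess <- v2[post] - plateau
  half <- NA_real_
  if (peak > plateau && any(excess <= (peak - plateau) / 2)) {
    th <- t2[post][which(excess <= (peak - plateau) / 2)[1]]
    half <- th - tpeak
  }
  list(peak_value = peak, peak_time = tpeak, rise_time = tpeak - min(t2),
       half_time = half, plateau = plateau)
}

#' Long-format sweep summary for a set of quantities
#'
#' For every successful run in a sweep, extracts feeding- and fasting-phase
#' values of each quantity (see [extract_phase_values()]).
#'
#' @param sweep A `splanchsim_sweep`.
#' @param quantities Character vector of series column names.
#' @return data.frame: axis columns, `phase`, `quantity`, `value`.
#' @export
sweep_summary <- function(sweep, quantities) {
  out <- list()
  for (i in seq_along(sweep$results)) {
    res <- sweep$results[[i]]
    if (inherits(res, "error")) next
    for (q in quantities) {
      ph <- extract_phase_values(res, q)
      blk <- cbind(
        sweep$grid[rep(i, 2), , drop = FALSE],
        data.frame(phase = c("feeding", "fasting"), quantity = q,
                   value = c(ph$feeding_value, ph$fasting_value)))
      rownames(blk) <- NULL
      out[[length(out) + 1]] <- blk
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
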