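#' Kinetic time series container
#'
#' A labelled storage or dissolution time series: moisture (wet-basis %,
#' days), absorbance at 420 nm (seconds), or brew pH (days). Units are
#' explicit per series; mixing units across series of one fit is an error.
#'
#' @param times Strictly increasing, non-negative times.
#' @param values Responses: pH in (0, 14); absorbance >= 0.
#' @param response One of `"moisture"`, `"abs420"`, `"ph"`.
#' @param unit Time unit, `"days"` or `"seconds"`. Moisture and pH series run
#'   in days; dissolution in seconds.
#' @param erh Environmental relative humidity label, percent (optional).
#' @param replicate Replicate id (optional).
#' @return Object of class `kinetic_series`.
#' @export
kinetic_series <- function(times, values,
                           response = c("moisture", "abs420", "ph"),
                           unit = c("days", "seconds"),
                           erh = NA, replicate = NA) {
  response <- match.arg(response)
  unit <- match.arg(unit)
  if (length(times) != length(values))
    stop("'times' and 'values' must have equal length", call. = FALSE)
  if (any(times < 0)) stop("'times' must be non-negative", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (response == "ph" && (any(values <= 0) || any(values >= 14)))
    stop("pH values must lie in (0, 14)", call. = FALSE)
  if (response == "abs420" && any(values < 0))
    stop("absorbance must be >= 0", call. = FALSE)
  structure(list(times = times, values = values, response = response,
                 unit = unit, erh = erh, replicate = replicate),
            class = "kinetic_series")
}

#' @export
print.kinetic_series <- function(x, ...) {
  cat(sprintf("kinetic series (%s, %s): %d points, ERH = %s\n",
              x$response, x$unit, length(x$times), format(x$erh)))
  invisible(x)
}

#' First-order asymptotic kinetics
#'
#' The empirical first-order law shared by moisture uptake during storage and
#' powder dissolution:
#'
#' \deqn{Y(t) = Y_\infty - (Y_\infty - Y_0)\, e^{-k t}}
#'
#' `Y0` is the response at t = 0, `Yinf` the equilibrium response, and `k` the
#' apparent rate (day^-1 for storage, s^-1 for dissolution). `Yinf` may be
#' below `Y0` — a powder drying toward a low-humidity environment follows the
#' same law downward.
#'
#' @param Y0 Response at time zero.
#' @param Yinf Equilibrium response; must differ from `Y0`.
#' @param k Apparent rate constant, > 0 (inverse time units of `t`).
#' @return Object of class `afo_params`.
#' @examples
#' p <- afo_params(Y0 = 3.3, Yinf = 14.7, k = 0.15)
#' asymptotic_first_order(p, 20)
#' @export
afo_params <- function(Y0, Yinf, k) {
  if (!is.numeric(k) || k <= 0) stop("'k' must be > 0", call. = FALSE)
  if (Y0 == Yinf) stop("'Y0' must differ from 'Yinf' (unidentifiable)",
                       call. = FALSE)
  structure(list(Y0 = Y0, Yinf = Yinf, k = k), class = "afo_params")
}

#' @export
print.afo_params <- function(x, ...) {
  cat(sprintf("first-order asymptotic: Y0 = %.4g, Yinf = %.4g, k = %.4g\n",
              x$Y0, x$Yinf, x$k))
  invisible(x)
}

#' @rdname afo_params
#' @param p An `afo_params` object.
#' @param t Times >= 0.
#' @return `asymptotic_first_order()` returns the response at each `t`.
#' @export
asymptotic_first_order <- function(p, t) {
  stopifnot(inherits(p, "afo_params"))
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  p$Yinf - (p$Yinf - p$Y0) * exp(-p$k * t)
}

#' Exponential pH decay
#'
#' Pseudo-first-order decay of brew pH during storage:
#' \deqn{pH(t) = pH_0\, e^{-k t}} with `k` in day^-1. Over realistic storage
#' spans k is tiny (order 1e-4 day^-1), so tabulated rates are often printed
#' scaled by 1e4; the package always stores and computes with the raw day^-1
#' value and leaves display scaling to the caller.
#'
#' @param pH0 Initial pH, > 0.
#' @param k Decay rate, day^-1, >= 0.
#' @return Object of class `exp_decay_params`.
#' @export
exp_decay_params <- function(pH0, k) {
  if (!is.numeric(pH0) || pH0 <= 0) stop("'pH0' must be > 0", call. = FALSE)
  if (!is.numeric(k) || k < 0) stop("'k' must be >= 0", call. = FALSE)
  structure(list(pH0 = pH0, k = k), class = "exp_decay_params")
}

#' @export
print.exp_decay_params <- function(x, ...) {
  cat(sprintf("pH decay: pH0 = %.4g, k = %.4g per day (k x 1e4 = %.4g)\n",
              x$pH0, x$k, x$k * 1e4))
  invisible(x)
}

#' @rdname exp_decay_params
#' @param p An `exp_decay_params` object.
#' @param t Times in days, >= 0.
#' @return `exp_decay()` returns pH at each `t`.
#' @export
exp_decay <- function(p, t) {
  stopifnot(inherits(p, "exp_decay_params"))
  if (any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  p$pH0 * exp(-p$k * t)
}

#' Fit the first-order asymptotic model
#'
#' Least-squares fit of (`Y0`, `Yinf`, `k`) to a kinetic series. Starting
#' values: `Y0` = first observation, `Yinf` = last observation, `k` =
#' ln(2) / (time of half-range crossing), robust for rising and falling
#' series; `k` is bounded in (1e-8, 1e3).
#'
#' @param s A [kinetic_series()] (or any list with `times` and `values`),
#'   with at least 4 distinct time points.
#' @return List with `params` ([afo_params()]) and `diagnostics`.
#' @export
fit_asymptotic_first_order <- function(s) {
  t <- s$times; y <- s$values
  if (length(unique(t)) < 4L)
    stop("at least 4 distinct time points are required", call. = FALSE)
  if (stats::sd(y) < 1e-12 * (abs(mean(y)) + 1))
    stop("unidentifiable: response series is flat", call. = FALSE)
  k0 <- half_range_rate(t, y)
  starts <- list(
    list(Y0 = y[1], Yinf = y[length(y)], k = k0),
    list(Y0 = y[1], Yinf = y[length(y)], k = k0 * 10),
    list(Y0 = y[1], Yinf = y[length(y)], k = k0 / 10)
  )
  fit <- nls_with_restarts(
    values ~ Yinf - (Yinf - Y0) * exp(-k * times),
    data = data.frame(times = t, values = y), starts = starts,
    lower = c(Y0 = -Inf, Yinf = -Inf, k = 1e-8),
    upper = c(Y0 = Inf, Yinf = Inf, k = 1e3)
  )
  est <- stats::coef(fit)
  list(
    params = afo_params(est[["Y0"]], est[["Yinf"]], est[["k"]]),
    diagnostics = fit_diagnostics(stats::resid(fit), TRUE, fit_se(fit))
  )
}

# ln(2) over the time at which the series first crosses the midpoint of its
# range, linearly interpolated; falls back to 1/median(t) for degenerate paths.
#' @keywords internal
#' @noRd
half_range_rate <- function(t, y) {
  mid <- (y[1] + y[length(y)]) / 2
  crossed <- which(sign(y - mid) != sign(y[1] - mid))
  t_half <- if (length(crossed) > 0 && crossed[1] > 1) {
    i <- crossed[1]
    t[i - 1] + (mid - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
  } else stats::median(t)
  if (!is.finite(t_half) || t_half <= 0) t_half <- stats::median(t[t > 0])
  log(2) / t_half
}

#' Fit the pseudo-first-order pH decay
#'
#' Least squares on the original pH scale (not log-linearized, so the noise
#' model stays additive in pH units). A log-linear regression provides the
#' starting values.
#'
#' @param s A [kinetic_series()] with at least 3 points, all values > 0.
#' @return List with `params` ([exp_decay_params()]) and `diagnostics`.
#' @export
fit_exp_decay <- function(s) {
  t <- s$times; y <- s$values
  if (length(t) < 3L) stop("at least 3 points are required", call. = FALSE)
  if (any(y <= 0)) stop("pH values must be positive", call. = FALSE)
  lf <- stats::lm(log(y) ~ t)
  k0 <- max(-stats::coef(lf)[[2]], 1e-10)
  starts <- list(
    list(pH0 = y[1], k = k0),
    list(pH0 = exp(stats::coef(lf)[[1]]), k = k0),
    list(pH0 = y[1], k = k0 * 10)
  )
  fit <- nls_with_restarts(
    values ~ pH0 * exp(-k * times),
    data = data.frame(times = t, values = y), starts = starts,
    lower = c(pH0 = 1e-8, k = 0),
    upper = c(pH0 = Inf, k = 1e3)
  )
  est <- stats::coef(fit)
  list(
    params = exp_decay_params(est[["pH0"]], est[["k"]]),
    diagnostics = fit_diagnostics(stats::resid(fit), TRUE, fit_se(fit))
  )
}

#' Time for an asymptotic first-order response to reach a level
#'
#' Closed-form inversion of the first-order law:
#' `t = -ln((Yinf - level) / (Yinf - Y0)) / k`. The level must lie strictly
#' between `Y0` and `Yinf`; any other level is never reached.
#'
#' @param p An [afo_params()] object.
#' @param level Target response.
#' @return Time (same units as the fitted rate).
#' @examples
#' time_to_level_asymptotic(afo_params(3.3, 14.7, 0.15), 6.22)
#' @export
time_to_level_asymptotic <- function(p, level) {
  stopifnot(inherits(p, "afo_params"))
  if (level == p$Y0) return(0)
  lo <- min(p$Y0, p$Yinf); hi <- max(p$Y0, p$Yinf)
  if (level <= lo || level >= hi)
    stop("level never reached: outside the open interval (Y0, Yinf)",
         call. = FALSE)
  -log((p$Yinf - level) / (p$Yinf - p$Y0)) / p$k
}

#' Time for pH to decay to a level
#'
#' Closed form `t = ln(pH0 / level) / k`. A level at or above `pH0` returns 0
#' with a warning (already there); `k = 0` never reaches any lower level.
#'
#' @param p An [exp_decay_params()] object.
#' @param level Target pH, > 0.
#' @return Time in days.
#' @export
time_to_level_decay <- function(p, level) {
  stopifnot(inherits(p, "exp_decay_params"))
  if (level <= 0) stop("'level' must be > 0", call. = FALSE)
  if (level >= p$pH0) {
    warning("level at or above pH0; returning 0 by convention")
    return(0)
  }
  if (p$k == 0)
    stop("level never reached: decay rate is zero", call. = FALSE)
  log(p$pH0 / level) / p$k
}

#' Read a tidy kinetics CSV
#'
#' Schema: `time,value,unit,response,erh,replicate`. Returns one
#' [kinetic_series()] per (response, erh, replicate) combination. Mixed time
#' units within one series are an error.
#'
#' @param path File path.
#' @return Named list of `kinetic_series` objects
#'   (`"<response>_erh<erh>_rep<replicate>"`).
#' @export
read_kinetics_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time", "value", "unit", "response", "erh", "replicate")
  if (!all(need %in% names(d)))
    stop("kinetics CSV needs columns ", paste(need, collapse = ","),
         call. = FALSE)
  keys <- interaction(d$response, d$erh, d$replicate, drop = TRUE)
  out <- lapply(split(d, keys), function(g) {
    if (length(unique(g$unit)) != 1L)
      stop("mixed time units within one series", call. = FALSE)
    g <- g[order(g$time), ]
    kinetic_series(g$time, g$value, response = g$response[1],
                   unit = g$unit[1], erh = g$erh[1], replicate = g$replicate[1])
  })
  names(out) <- vapply(out, function(s)
    sprintf("%s_erh%s_rep%s", s$response, s$erh, s$replicate), character(1))
  out
}
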