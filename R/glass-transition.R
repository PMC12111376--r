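#' Gordon–Taylor glass-transition parameters
#'
#' The Gordon–Taylor mixing rule predicts the glass-transition temperature of
#' a solids–water blend:
#'
#' \deqn{T_g = \frac{k\,T_{gi} + \varepsilon W T_{gw}}{k + \varepsilon W}}
#'
#' with `k` the solids mass fraction, `W` the water mass fraction
#' (k + W = 1), `Tgi` the anhydrous-solids T_g, `Tgw` the T_g of water
#' (fixed at -135 degC by convention), and `epsilon` the single interaction
#' parameter. Water strongly plasticizes amorphous food solids, so T_g drops
#' steeply with W.
#'
#' @param Tgi Anhydrous-solids glass-transition temperature, degC.
#' @param epsilon Gordon–Taylor parameter, > 0.
#' @param Tgw Glass-transition temperature of water, degC (default -135).
#' @return Object of class `gordon_taylor_params`.
#' @examples
#' gt <- gordon_taylor_params(Tgi = 47.8, epsilon = 7.2)
#' gordon_taylor_tg(gt, W = 0.0566)
#' @export
gordon_taylor_params <- function(Tgi, epsilon, Tgw = -135) {
  if (!is.numeric(Tgi) || Tgi <= Tgw)
    stop("'Tgi' must exceed 'Tgw'", call. = FALSE)
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("'epsilon' must be > 0", call. = FALSE)
  structure(list(Tgi = Tgi, epsilon = epsilon, Tgw = Tgw),
            class = "gordon_taylor_params")
}

#' @export
print.gordon_taylor_params <- function(x, ...) {
  cat(sprintf("Gordon-Taylor: Tgi = %.4g degC, epsilon = %.4g, Tgw = %g degC\n",
              x$Tgi, x$epsilon, x$Tgw))
  invisible(x)
}

#' Evaluate the Gordon–Taylor equation
#'
#' @param gt A [gordon_taylor_params()] object.
#' @param W Water mass fraction(s), g water / g total, in \[0, 1\]. The solids
#'   fraction is `1 - W`.
#' @return Glass-transition temperature(s), degC.
#' @export
gordon_taylor_tg <- function(gt, W) {
  stopifnot(inherits(gt, "gordon_taylor_params"))
  if (any(W < 0) || any(W > 1))
    stop("'W' must lie in [0, 1]", call. = FALSE)
  k <- 1 - W
  den <- k + gt$epsilon * W
  if (any(den == 0)) stop("degenerate composition: k + epsilon*W = 0",
                          call. = FALSE)
  (k * gt$Tgi + gt$epsilon * W * gt$Tgw) / den
}

#' Fit the Gordon–Taylor model to T_g data
#'
#' Least-squares estimation of (`Tgi`, `epsilon`) with `Tgw` held fixed, as is
#' standard when calorimetric T_g values are available only for the blend.
#'
#' @param data Data frame with columns `water_fraction` (in \[0, 0.5\]) and
#'   `tg_c` (degC). At least 3 points.
#' @param Tgw Fixed water T_g, degC.
#' @return List with `params` ([gordon_taylor_params()]) and `diagnostics`.
#' @export
fit_gordon_taylor <- function(data, Tgw = -135) {
  stopifnot(is.data.frame(data))
  if (!all(c("water_fraction", "tg_c") %in% names(data)))
    stop("T_g data needs columns 'water_fraction' and 'tg_c'", call. = FALSE)
  if (nrow(data) < 3L)
    stop("at least 3 (W, Tg) points are required", call. = FALSE)
  if (any(data$water_fraction < 0) || any(data$water_fraction > 0.5))
    stop("'water_fraction' must lie in [0, 0.5]", call. = FALSE)
  starts <- list(
    list(Tgi = max(data$tg_c), epsilon = 5),
    list(Tgi = max(data$tg_c) + 20, epsilon = 1),
    list(Tgi = 50, epsilon = 10)
  )
  fit <- nls_with_restarts(
    tg_c ~ ((1 - water_fraction) * Tgi + epsilon * water_fraction * Tgw) /
      ((1 - water_fraction) + epsilon * water_fraction),
    data = cbind(data, Tgw = Tgw), starts = starts,
    lower = c(Tgi = Tgw + 1e-6, epsilon = 1e-8),
    upper = c(Tgi = 500, epsilon = 1e3)
  )
  est <- stats::coef(fit)
  list(
    params = gordon_taylor_params(est[["Tgi"]], est[["epsilon"]], Tgw),
    diagnostics = fit_diagnostics(stats::resid(fit), TRUE, fit_se(fit))
  )
}

#' Modified state diagram
#'
#' Pairs a fitted sorption isotherm with a fitted Gordon–Taylor curve at a
#' storage temperature. Chaining the two gives T_g as a function of water
#' activity: the isotherm supplies the equilibrium moisture at a_w, which is
#' converted to a total-mass water fraction `W = M/(1 + M)` and fed to the
#' Gordon–Taylor equation.
#'
#' @param gab A [gab_params()] object.
#' @param gt A [gordon_taylor_params()] object.
#' @param T_storage Storage temperature, degC.
#' @return Object of class `state_diagram`.
#' @examples
#' sd <- state_diagram(gab_params(0.06, 1.10, 0.99),
#'                     gordon_taylor_params(47.8, 7.2), T_storage = 20)
#' tg_at_aw(sd, 0.32)
#' critical_aw(sd)
#' @export
state_diagram <- function(gab, gt, T_storage) {
  stopifnot(inherits(gab, "gab_params"), inherits(gt, "gordon_taylor_params"),
            is.numeric(T_storage), is.finite(T_storage))
  structure(list(gab = gab, gt = gt, T_storage = T_storage),
            class = "state_diagram")
}

#' @export
print.state_diagram <- function(x, ...) {
  cat(sprintf("State diagram at T_storage = %g degC\n", x$T_storage))
  print(x$gab); print(x$gt)
  invisible(x)
}

#' Glass-transition temperature at a water activity
#'
#' @param sd A [state_diagram()].
#' @param a_w Water activity in \[0, 0.95\].
#' @return T_g in degC at each `a_w`.
#' @export
tg_at_aw <- function(sd, a_w) {
  stopifnot(inherits(sd, "state_diagram"))
  M <- gab_moisture(sd$gab, a_w)
  gordon_taylor_tg(sd$gt, M / (1 + M))
}

#' Critical water activity at the storage temperature
#'
#' The water activity at which the chained T_g(a_w) curve crosses the storage
#' temperature: below it the powder is glassy at `T_storage`, above it
#' rubbery. Solved by bracketed root-finding on \[0, 0.95\].
#'
#' @param sd A [state_diagram()].
#' @return Critical water activity (|error| <= 1e-6).
#' @export
critical_aw <- function(sd) {
  stopifnot(inherits(sd, "state_diagram"))
  hi <- tg_at_aw(sd, 0); lo <- tg_at_aw(sd, 0.95)
  if (sd$T_storage >= hi) {
    if (sd$T_storage == hi) return(0)
    stop("always rubbery: storage temperature exceeds the anhydrous T_g",
         call. = FALSE)
  }
  if (sd$T_storage <= lo)
    stop("always glassy: storage temperature below T_g over the whole range",
         call. = FALSE)
  stats::uniroot(function(a) tg_at_aw(sd, a) - sd$T_storage, c(0, 0.95),
                 tol = 1e-9)$root
}

#' Critical moisture at the storage temperature
#'
#' Dry-basis moisture on the isotherm at the [critical_aw()] of the diagram.
#'
#' @param sd A [state_diagram()].
#' @return Critical moisture, g/g dry basis.
#' @export
critical_moisture <- function(sd) {
  gab_moisture(sd$gab, critical_aw(sd))
}

#' Classify the physical state of the powder
#'
#' A powder held at temperature T with glass transition Tg is glassy when
#' `T - Tg < 0`, rubbery when `T - Tg > transition_band`, and in transition in
#' the closed band `[0, transition_band]` — a temperature excess of up to
#' 5 degC is not enough for a complete glass-to-rubber transition.
#'
#' @param T Storage temperature, degC.
#' @param Tg Glass-transition temperature, degC.
#' @param transition_band Width of the transition band, degC (default 5).
#' @return List with `label` (`"glassy"`, `"transition"`, or `"rubbery"`) and
#'   `deltaT` (`T - Tg`, degC).
#' @examples
#' classify_state(20, -41) # rubbery, deltaT = 61
#' classify_state(20, 25)  # glassy, deltaT = -5
#' @export
classify_state <- function(T, Tg, transition_band = 5) {
  stopifnot(is.finite(T), is.finite(Tg), transition_band >= 0)
  deltaT <- T - Tg
  label <- if (deltaT < 0) "glassy"
           else if (deltaT <= transition_band) "transition"
           else "rubbery"
  list(label = label, deltaT = deltaT)
}

#' Read a glass-transition CSV
#'
#' Accepts either `water_fraction,tg_c` or `aw,tg_c` (auto-detected from the
#' header). In the `aw` form a fitted isotherm must be supplied to convert
#' water activity to a water fraction through the sorption curve.
#'
#' @param path File path.
#' @param gab Optional [gab_params()]; required for the `aw,tg_c` schema.
#' @return Data frame with columns `water_fraction`, `tg_c`.
#' @export
read_tg_csv <- function(path, gab = NULL) {
  d <- utils::read.csv(path)
  if (all(c("water_fraction", "tg_c") %in% names(d)))
    return(d[, c("water_fraction", "tg_c")])
  if (all(c("aw", "tg_c") %in% names(d))) {
    if (is.null(gab))
      stop("'aw' schema requires a fitted isotherm ('gab') to derive W",
           call. = FALSE)
    M <- gab_moisture(gab, d$aw)
    return(data.frame(water_fraction = M / (1 + M), tg_c = d$tg_c))
  }
  stop("T_g CSV must have columns 'water_fraction,tg_c' or 'aw,tg_c'",
       call. = FALSE)
}

#' Export a state diagram as JSON
#'
#' Samples the T_g curve and the isotherm on an a_w grid and writes both,
#' together with the parameterization and the critical point, as JSON.
#'
#' @param sd A [state_diagram()].
#' @param path Output file.
#' @param aw_grid Water-activity grid to sample (default 0 to 0.9 by 0.01).
#' @return The path, invisibly.
#' @export
export_state_diagram <- function(sd, path, aw_grid = seq(0, 0.9, by = 0.01)) {
  caw <- tryCatch(critical_aw(sd), error = function(e) NA_real_)
  out <- list(
    T_storage = sd$T_storage,
    gab = unclass(sd$gab),
    gordon_taylor = unclass(sd$gt),
    critical_aw = caw,
    critical_moisture_db = if (is.na(caw)) NA else gab_moisture(sd$gab, caw),
    curves = list(
      aw = aw_grid,
      tg_c = tg_at_aw(sd, aw_grid),
      moisture_db = gab_moisture(sd$gab, aw_grid)
    )
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
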