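#' GAB sorption-isotherm parameters
#'
#' The Guggenheim–Anderson–de Boer (GAB) model relates equilibrium dry-basis
#' moisture M to water activity a_w through three parameters: the monolayer
#' moisture `m0` (g water / g dry solids), the energy constant `C`, and the
#' correction factor `b`:
#'
#' \deqn{M(a_w) = \frac{m_0\, b\, C\, a_w}{(1 - b a_w)(1 - b a_w + C b a_w)}}
#'
#' `b < 1` keeps the curve finite on the working range a_w in \[0, 0.95\].
#'
#' @param m0 Monolayer moisture, g/g dry basis, > 0.
#' @param C Energy constant, > 0.
#' @param b Correction factor, in (0, 1).
#' @return Object of class `gab_params`.
#' @examples
#' p <- gab_params(m0 = 0.06, C = 1.10, b = 0.99)
#' gab_moisture(p, 0.5)
#' @export
gab_params <- function(m0, C, b) {
  if (!is.numeric(m0) || m0 <= 0) stop("'m0' must be > 0", call. = FALSE)
  if (!is.numeric(C) || C <= 0) stop("'C' must be > 0", call. = FALSE)
  if (!is.numeric(b) || b <= 0 || b >= 1)
    stop("'b' must lie in (0, 1)", call. = FALSE)
  structure(list(m0 = m0, C = C, b = b), class = "gab_params")
}

#' @export
print.gab_params <- function(x, ...) {
  cat(sprintf("GAB isotherm: m0 = %.4g g/g db, C = %.4g, b = %.4g\n",
              x$m0, x$C, x$b))
  invisible(x)
}

#' Evaluate the GAB isotherm
#'
#' @param p A [gab_params()] object.
#' @param a_w Water activity values in \[0, 1/b).
#' @return Dry-basis moisture (g/g) at each `a_w`.
#' @export
gab_moisture <- function(p, a_w) {
  stopifnot(inherits(p, "gab_params"))
  if (any(a_w < 0) || any(a_w >= 1 / p$b))
    stop("'a_w' must lie in [0, 1/b): the GAB curve has a pole at 1/b",
         call. = FALSE)
  num <- p$m0 * p$b * p$C * a_w
  den <- (1 - p$b * a_w) * (1 - p$b * a_w + p$C * p$b * a_w)
  num / den
}

#' Fit the GAB model to isotherm data
#'
#' Least-squares fit of the three GAB parameters to (a_w, moisture) pairs.
#' Moisture must be dry basis (g/g). Starting values are `m0` = moisture at
#' the grid midpoint, `C` = 1, `b` = 0.9, with bounded deterministic restarts;
#' bounds are m0 in (0, 1], C in (0, 1e4], b in (0, 0.9999] because the model
#' is ill-conditioned as b approaches 1.
#'
#' @param data Data frame with columns `aw` (strictly increasing, in
#'   \[0, 0.95\]) and `moisture_db` (>= 0). At least 4 points.
#' @return List with elements `params` ([gab_params()]) and `diagnostics`.
#' @examples
#' p <- gab_params(0.06, 1.10, 0.99)
#' aw <- seq(0.1, 0.9, by = 0.1)
#' fit <- fit_gab(data.frame(aw = aw, moisture_db = gab_moisture(p, aw)))
#' fit$params
#' @export
fit_gab <- function(data) {
  data <- validate_isotherm(data)
  if (nrow(data) < 4L)
    stop("at least 4 isotherm points are required (3 free parameters)",
         call. = FALSE)
  if (all(data$moisture_db <= 0))
    stop("degenerate isotherm: all moisture values are zero (m0 -> 0 boundary)",
         call. = FALSE)
  mid <- data$moisture_db[ceiling(nrow(data) / 2)]
  starts <- list(
    list(m0 = max(mid, 1e-4), C = 1, b = 0.9),
    list(m0 = max(mid, 1e-4), C = 10, b = 0.8),
    list(m0 = max(mid / 2, 1e-4), C = 0.5, b = 0.99),
    list(m0 = max(data$moisture_db) / 2 + 1e-4, C = 100, b = 0.5)
  )
  fit <- nls_with_restarts(
    moisture_db ~ m0 * b * C * aw / ((1 - b * aw) * (1 - b * aw + C * b * aw)),
    data = data, starts = starts,
    lower = c(m0 = 1e-12, C = 1e-12, b = 1e-12),
    upper = c(m0 = 1, C = 1e4, b = 0.9999)
  )
  est <- stats::coef(fit)
  list(
    params = gab_params(est[["m0"]], est[["C"]], est[["b"]]),
    diagnostics = fit_diagnostics(stats::resid(fit), TRUE, fit_se(fit))
  )
}

#' Water activity at the monolayer
#'
#' Solves `gab_moisture(p, a_w) = m0` on (0, 0.95\] by bracketed root-finding.
#' This is the water activity at which the powder holds exactly its monolayer
#' moisture — the classical stability threshold.
#'
#' @param p A [gab_params()] object.
#' @return The monolayer water activity `a_w0` (|error| <= 1e-6).
#' @export
monolayer_activity <- function(p) {
  stopifnot(inherits(p, "gab_params"))
  f <- function(a) gab_moisture(p, a) - p$m0
  if (f(0.95) < 0)
    stop("isotherm never reaches the monolayer moisture on (0, 0.95]",
         call. = FALSE)
  stats::uniroot(f, c(1e-6, 0.95), tol = 1e-9)$root
}

#' Invert the GAB isotherm
#'
#' Water activity at which the isotherm attains a given dry-basis moisture,
#' solved on \[0, 0.95\] by bracketed root-finding. Used to place kinetic
#' moisture states onto the state diagram.
#'
#' @param p A [gab_params()] object.
#' @param M Dry-basis moisture, 0 <= M <= `gab_moisture(p, 0.95)`.
#' @return Water activity with `gab_moisture(p, invert_gab(p, M)) = M`
#'   to within 1e-6.
#' @export
invert_gab <- function(p, M) {
  stopifnot(inherits(p, "gab_params"))
  if (M < 0 || M > gab_moisture(p, 0.95))
    stop("'M' outside the attainable moisture range on [0, 0.95]",
         call. = FALSE)
  if (M == 0) return(0)
  stats::uniroot(function(a) gab_moisture(p, a) - M, c(0, 0.95),
                 tol = 1e-9)$root
}

#' Detect gravimetric equilibrium in a sorption step
#'
#' Dynamic vapor sorption instruments hold each water-activity step until the
#' sample mass is stable. A step is declared equilibrated at the earliest time
#' t such that the maximum relative mass variation over the window
#' \[t, t + window\] stays below `rel_threshold` (default 0.01% over 8.5 h).
#' Window endpoints are inclusive and the mass at the right edge is linearly
#' interpolated between samples.
#'
#' @param masses Data frame with columns `time_h` (strictly increasing) and
#'   `mass_g` (> 0); must span at least `window` hours.
#' @param rel_threshold Relative variation threshold (fraction; 1e-4 = 0.01%).
#' @param window Window length in hours.
#' @return List with `reached` (flag) and `t_eq` (hours, or NA if never).
#' @export
detect_equilibrium <- function(masses, rel_threshold = 1e-4, window = 8.5) {
  stopifnot(is.data.frame(masses), all(c("time_h", "mass_g") %in% names(masses)))
  t <- masses$time_h; m <- masses$mass_g
  if (any(diff(t) <= 0)) stop("'time_h' must be strictly increasing", call. = FALSE)
  if (any(m <= 0)) stop("'mass_g' must be positive", call. = FALSE)
  if (max(t) - min(t) < window)
    stop("series shorter than the equilibrium window", call. = FALSE)
  interp <- stats::approxfun(t, m)
  for (i in seq_along(t)) {
    t0 <- t[i]; t1 <- t0 + window
    if (t1 > max(t)) break
    idx <- t >= t0 & t <= t1
    win <- c(m[idx], interp(t1))
    if ((max(win) - min(win)) / win[1] < rel_threshold)
      return(list(reached = TRUE, t_eq = t0))
  }
  list(reached = FALSE, t_eq = NA_real_)
}

#' Read an isotherm CSV
#'
#' Expected schema: header `aw,moisture_db`, decimal point, UTF-8.
#'
#' @param path File path.
#' @return Validated data frame with columns `aw`, `moisture_db`.
#' @export
read_isotherm_csv <- function(path) {
  validate_isotherm(utils::read.csv(path))
}

#' @keywords internal
#' @noRd
validate_isotherm <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("aw", "moisture_db") %in% names(data)))
    stop("isotherm data needs columns 'aw' and 'moisture_db'", call. = FALSE)
  if (any(data$aw < 0) || any(data$aw > 0.95))
    stop("'aw' must lie in [0, 0.95]", call. = FALSE)
  if (any(diff(data$aw) <= 0))
    stop("'aw' must be strictly increasing", call. = FALSE)
  if (any(data$moisture_db < 0))
    stop("'moisture_db' must be >= 0", call. = FALSE)
  data
}
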