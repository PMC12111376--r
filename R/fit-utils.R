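#' Fit diagnostics attached to every nonlinear fit
#'
#' @param residuals Numeric residuals (observed - fitted), response units.
#' @param converged Logical convergence flag from the optimizer.
#' @param se Named numeric standard errors (from the residual covariance),
#'   or NULL when unavailable.
#' @return Object of class `fit_diagnostics` with fields `rmse`, `n_obs`,
#'   `converged`, `residuals`, `se`.
#' @keywords internal
#' @noRd
fit_diagnostics <- function(residuals, converged, se = NULL) {
  structure(
    list(
      rmse = sqrt(mean(residuals^2)),
      n_obs = length(residuals),
      converged = isTRUE(converged),
      residuals = as.numeric(residuals),
      se = se
    ),
    class = "fit_diagnostics"
  )
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat(sprintf("fit: n = %d, RMSE = %.4g, converged = %s\n",
              x$n_obs, x$rmse, x$converged))
  invisible(x)
}

# Run nlsLM with bounded deterministic restarts. `starts` is a list of named
# start vectors tried in order; the first convergent fit wins.
#' @keywords internal
#' @noRd
nls_with_restarts <- function(formula, data, starts, lower, upper) {
  last_err <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        formula, data = data, start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) e
    )
    if (!inherits(fit, "error")) return(fit)
    last_err <- fit
  }
  stop("nonlinear fit failed to converge after restarts: ",
       conditionMessage(last_err), call. = FALSE)
}

# Standard errors from the fit; NULL if the covariance is singular.
#' @keywords internal
#' @noRd
fit_se <- function(fit) {
  tryCatch({
    s <- summary(fit)
    se <- s$coefficients[, "Std. Error"]
    names(se) <- rownames(s$coefficients)
    se
  }, error = function(e) NULL)
}

#' Serialize a fit as a JSON record
#'
#' Every fit in the package can be exported as a JSON record holding the
#' parameter names, estimates, standard errors, RMSE and number of
#' observations — the layout of the parameter tables customary in storage
#' studies.
#'
#' @param params Named list or vector of parameter estimates.
#' @param diagnostics The `fit_diagnostics` object of the fit.
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
fit_record_json <- function(params, diagnostics, path = NULL) {
  rec <- list(
    parameters = as.list(unlist(params)),
    standard_errors = if (is.null(diagnostics$se)) NULL
                      else as.list(diagnostics$se),
    rmse = diagnostics$rmse,
    n_obs = diagnostics$n_obs,
    converged = diagnostics$converged
  )
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
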