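#' Moisture values on an explicit basis
#'
#' Moisture content of a powder can be quoted on a wet (total-mass) basis as a
#' percentage, or on a dry basis as grams of water per gram of dry solids.
#' Storage studies routinely mix the two, so `moisture_value()` carries the
#' basis alongside the number and [convert_basis()] moves between them.
#'
#' @param value Numeric moisture quantity.
#' @param basis Either `"wet_percent"` (percent of total mass) or
#'   `"dry_ratio"` (g water / g dry solids).
#' @return An object of class `moisture_value`.
#' @examples
#' m <- moisture_value(5.66, "wet_percent")
#' convert_basis(m, "dry_ratio")
#' @export
moisture_value <- function(value, basis = c("wet_percent", "dry_ratio")) {
  basis <- match.arg(basis)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("'value' must be a single finite number", call. = FALSE)
  if (basis == "wet_percent" && (value < 0 || value >= 100))
    stop("wet-basis moisture must lie in [0, 100)", call. = FALSE)
  if (basis == "dry_ratio" && value < 0)
    stop("dry-basis moisture must be >= 0", call. = FALSE)
  structure(list(value = value, basis = basis), class = "moisture_value")
}

#' @export
print.moisture_value <- function(x, ...) {
  unit <- if (x$basis == "wet_percent") "% (wet basis)" else "g/g dry basis"
  cat(format(x$value), unit, "\n")
  invisible(x)
}

#' Convert moisture between wet and dry basis
#'
#' Wet-basis percent M_wb maps to dry-basis ratio
#' `M_db = (M_wb/100) / (1 - M_wb/100)` and back. Conversion is exact and
#' involutive; same-basis conversion is the identity.
#'
#' @param m A [moisture_value()].
#' @param target Target basis, `"wet_percent"` or `"dry_ratio"`.
#' @return A `moisture_value` on the target basis.
#' @export
convert_basis <- function(m, target = c("wet_percent", "dry_ratio")) {
  target <- match.arg(target)
  if (!inherits(m, "moisture_value"))
    stop("'m' must be a moisture_value", call. = FALSE)
  if (m$basis == target) return(m)
  if (m$basis == "wet_percent") {
    f <- m$value / 100
    moisture_value(f / (1 - f), "dry_ratio")
  } else {
    moisture_value(m$value / (1 + m$value) * 100, "wet_percent")
  }
}

#' Gravimetric wet-basis moisture from drying weights
#'
#' Moisture percent of a sample dried to constant weight:
#' `M = (w_i - w_f) / w_i * 100`, with `w_i` the initial and `w_f` the final
#' (dry) weight.
#'
#' @param w_i Initial sample weight (g), > 0.
#' @param w_f Final weight after drying (g), 0 < w_f <= w_i.
#' @return Wet-basis moisture percent.
#' @examples
#' moisture_wb_from_weights(1.0000, 0.9642) # 3.58 %
#' @export
moisture_wb_from_weights <- function(w_i, w_f) {
  if (!is.numeric(w_i) || any(w_i <= 0))
    stop("'w_i' must be positive", call. = FALSE)
  if (!is.numeric(w_f) || any(w_f <= 0))
    stop("'w_f' must be positive", call. = FALSE)
  if (any(w_f > w_i))
    stop("'w_f' exceeds 'w_i': final weight cannot exceed initial weight",
         call. = FALSE)
  (w_i - w_f) / w_i * 100
}

# shared helpers ------------------------------------------------------------

#' @keywords internal
#' @noRd
wb_to_db <- function(wet_percent) (wet_percent / 100) / (1 - wet_percent / 100)

#' @keywords internal
#' @noRd
db_to_wb <- function(dry_ratio) dry_ratio / (1 + dry_ratio) * 100
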