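#' Declare a critical method parameter (factor)
#'
#' A factor is a controllable method parameter studied in a designed
#' experiment.  Continuous factors carry a coding convention (a physical
#' centre and a physical step per coded unit) so that coded design levels
#' translate to instrument settings and back; three-level screening factors
#' instead carry the three physical levels at which they were exercised.
#'
#' @param name Factor name, e.g. `"pH"` or `"Buffer_conc"`.
#' @param center Physical value at coded 0 (continuous factors).
#' @param step Physical change per coded unit; must be positive.
#' @param units Unit string used when writing tables (may be `""`).
#' @param rounding Decimal places used when reporting physical settings.
#'   Instruments cannot be set to arbitrary precision, so decoded levels
#'   are rounded to this many places.
#' @param levels For three-level screening factors, the physical values of
#'   levels 1, 2 and 3 (low, middle, high).
#' @param domain Physical `c(low, high)` range over which the factor may be
#'   varied; values outside it are flagged with a warning when coded.
#'   Defaults to the axial range for continuous factors with a known step.
#' @return An object of class `"aqbd_factor"`.
#' @examples
#' f <- factor_spec("Buffer_conc", center = 25, step = 3, units = "mM",
#'                  rounding = 0, domain = c(20, 30))
#' code_values(28, f)    # +1
#' decode_values(0, f)   # the centre, 25 mM
#' @export
factor_spec <- function(name, center = NULL, step = NULL, units = "",
                        rounding = 2, levels = NULL, domain = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.null(levels)) {
    if (length(levels) != 3L)
      stop("a three-level screening factor needs exactly 3 physical levels")
    kind <- "categorical3"
  } else {
    if (is.null(center) || is.null(step))
      stop("continuous factors need 'center' and 'step'")
    if (!is.finite(step) || step <= 0) stop("'step' must be > 0")
    kind <- "continuous"
  }
  out <- list(name = name, kind = kind, center = center, step = step,
              units = units, rounding = rounding, levels = levels,
              domain = domain)
  class(out) <- "aqbd_factor"
  out
}

#' @export
print.aqbd_factor <- function(x, ...) {
  if (x$kind == "continuous") {
    cat(sprintf("Factor %s [%s]: center %s, step %s, rounding %d dp",
                x$name, x$units, format(x$center), format(x$step),
                x$rounding))
    if (!is.null(x$domain))
      cat(sprintf(", domain [%s, %s]", format(x$domain[1]),
                  format(x$domain[2])))
    cat("\n")
  } else {
    cat(sprintf("Factor %s [%s]: 3 levels (%s)\n", x$name, x$units,
                paste(format(x$levels), collapse = ", ")))
  }
  invisible(x)
}

#' Convert physical settings to coded levels
#'
#' `coded = (physical - center) / step`.  Values outside the declared
#' domain raise a warning (not an error): extrapolated settings may still
#' be meaningful but predictions there are not supported by the design.
#'
#' @param x Numeric vector of physical values.
#' @param factor An [factor_spec()] of kind continuous.
#' @return Numeric vector of coded levels.
#' @export
code_values <- function(x, factor) {
  stopifnot(inherits(factor, "aqbd_factor"))
  if (factor$kind != "continuous")
    stop("coding applies to continuous factors only")
  if (!is.null(factor$domain)) {
    out_of <- x < factor$domain[1] - 1e-12 | x > factor$domain[2] + 1e-12
    if (any(out_of, na.rm = TRUE))
      warning(sprintf("%s: %d value(s) outside declared domain [%s, %s]",
                      factor$name, sum(out_of, na.rm = TRUE),
                      format(factor$domain[1]), format(factor$domain[2])))
  }
  (x - factor$center) / factor$step
}

#' Convert coded levels to (rounded) physical settings
#'
#' Inverse of [code_values()], followed by rounding to the factor's
#' reporting precision.
#'
#' @param z Numeric vector of coded levels.
#' @param factor An [factor_spec()] of kind continuous.
#' @param round Round to the factor's `rounding` decimal places
#'   (default `TRUE`).
#' @return Numeric vector of physical values.
#' @export
decode_values <- function(z, factor, round = TRUE) {
  stopifnot(inherits(factor, "aqbd_factor"))
  if (factor$kind != "continuous")
    stop("decoding applies to continuous factors only")
  x <- factor$center + z * factor$step
  if (round) x <- round(x, factor$rounding)
  x
}

factor_names <- function(factors) vapply(factors, `[[`, "", "name")

## coded bounds of the declared physical domain (used as grid/box limits)
coded_domain <- function(factor) {
  if (is.null(factor$domain)) stop(factor$name, ": no declared domain")
  sort((factor$domain - factor$center) / factor$step)
}
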