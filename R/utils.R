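# Small numeric helpers shared across modules.

#' Trapezoidal integral
#'
#' @param x Ordered abscissae.
#' @param y Ordinates.
#' @return Scalar integral of the piecewise-linear interpolant.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-n] + y[-1L]) / 2)
}

#' Cumulative trapezoidal integral (same length as input, starts at 0)
#' @keywords internal
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(diff(x) * (y[-n] + y[-1L]) / 2))
}

#' Convert minutes to hours
#'
#' All kinetic modules work in minutes post-injection; the PK-PD module works
#' in hours post-dose. Every cross-module time conversion goes through these
#' two functions so the unit bridge is explicit and greppable.
#'
#' @param t_min Time in minutes.
#' @return Time in hours.
#' @export
minutes_to_hours <- function(t_min) t_min / 60

#' Convert hours to minutes
#' @param t_h Time in hours.
#' @return Time in minutes.
#' @export
hours_to_minutes <- function(t_h) t_h * 60

# Polynomial rolling hash (mod 2^31 - 1) of a deparsed object; used to stamp
# pipeline outputs so tables from different configurations cannot be mixed.
fnv1a_hash <- function(obj) {
  bytes <- utf8ToInt(paste(deparse(obj), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
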