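# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Integer (or fixed-digit) rounding where exact halves move away from zero,
#' the convention used for the percent-change statements in dose-response
#' reporting (12.5 -> 13, -12.5 -> -13). A small relative guard absorbs
#' binary representation error so that values that are exact halves in
#' decimal arithmetic round as written.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits to keep (default 0).
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_away(c(12.5, -12.5, 14.55, 2.4))
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  scaled <- x * m
  # guard: 1e-9 relative tolerance against FP representation of decimal input
  guard <- 1e-9 * pmax(1, abs(scaled))
  sign(scaled) * floor(abs(scaled) + 0.5 + guard) / m
}

# Stationary AR(1) noise: sd is the stationary standard deviation,
# phi in [0, 1) the lag-1 coefficient. phi = 0 gives iid normal noise.
ar1_noise <- function(n, sd, phi) {
  stopifnot(n >= 1, sd >= 0, phi >= 0, phi < 1)
  if (sd == 0) return(numeric(n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - phi^2))
    for (i in 2:n) x[i] <- phi * x[i - 1] + innov[i - 1]
  }
  x
}

# Numeric-safe membership test for the dose labels (doses are labels drawn
# from a small fixed set, compared with a tolerance well below label spacing).
dose_match <- function(dose, levels, tol = 1e-8) {
  vapply(dose, function(d) any(abs(d - levels) < tol), logical(1))
}
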