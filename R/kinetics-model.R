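# Five-parameter generalized (Richards-type) logistic model and its
# closed-form calculus. The curve runs from the lower asymptote y0 to the
# upper asymptote yf (yf < y0 gives a falling sigmoid), with rate k (per
# hour), inflection-locating time ti (hours) and asymmetry nu (> 0; nu = 1
# recovers the symmetric logistic).

#' Five-parameter generalized logistic curve
#'
#' Evaluates `y(t) = y0 + (yf - y0) / (1 + exp(-k (t - ti)))^(1/nu)`, the
#' sigmoidal model used for fermentation temperature and pH kinetics.
#'
#' @param t Time (hours); vector.
#' @param y0,yf Lower and upper asymptotes in native units (a falling curve
#'   has `yf < y0`).
#' @param k Rate constant (per hour), `> 0`.
#' @param ti Inflection-locating time parameter (hours).
#' @param nu Asymmetry parameter (dimensionless, `> 0`).
#' @return Numeric vector of curve values.
#' @examples
#' richards(0:10, y0 = 0, yf = 1, k = 1, ti = 5, nu = 1)
#' @export
richards <- function(t, y0, yf, k, ti, nu) {
  stopifnot(k > 0, nu > 0)
  y0 + (yf - y0) / (1 + exp(-k * (t - ti)))^(1 / nu)
}

#' Analytic first derivative of the generalized logistic
#'
#' @inheritParams richards
#' @return dy/dt (native units per hour) at each `t`.
#' @export
richards_deriv <- function(t, y0, yf, k, ti, nu) {
  stopifnot(k > 0, nu > 0)
  u <- exp(-k * (t - ti))
  (yf - y0) * (k / nu) * u * (1 + u)^(-1 / nu - 1)
}

# Inflection point in closed form: d2y/dt2 = 0 at u = nu, i.e. at
# t = ti - log(nu)/k; the curve value there is y0 + span * (1+nu)^(-1/nu).
richards_inflection_time <- function(k, ti, nu) ti - log(nu) / k

richards_inflection_value <- function(y0, yf, nu) {
  y0 + (yf - y0) * (1 + nu)^(-1 / nu)
}

# Peak |dy/dt| in closed form (attained at the inflection):
# |yf - y0| * k * (1+nu)^(-(1+nu)/nu); equals k*span/4 for nu = 1.
richards_max_rate <- function(y0, yf, k, nu) {
  abs(yf - y0) * k * (1 + nu)^(-(1 + nu) / nu)
}

# Time at which the curve first reaches y0 + frac * (yf - y0):
# solve (1+u)^(-1/nu) = frac  =>  u = frac^(-nu) - 1.
richards_time_at_fraction <- function(k, ti, nu, frac) {
  stopifnot(frac > 0, frac < 1)
  u <- frac^(-nu) - 1
  ti - log(u) / k
}
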