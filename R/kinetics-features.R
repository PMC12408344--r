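# The thirteen abiotic kinetic features derived from a fitted
# five-parameter curve. "Kinetic energy" of the curve is taken proportional
# to the squared rate of change, so its maximum coincides with the maximum
# rate. Phase boundaries come from the tangent drawn at the inflection
# point: the exponential phase runs from the curve start to the tangent's
# intersection with the lower asymptote, the linear phase between the two
# asymptote intersections, and the decay phase from the upper intersection
# until the curve reaches a configurable fraction (default 0.95) of its
# span.

abiotic_feature_names <- c(
  "max_growth_rate", "time_to_max_ke", "value_at_max_ke",
  "exp_phase_duration", "linear_phase_duration", "decay_phase_duration",
  "delta_exp", "delta_linear", "delta_decay",
  "rate_exp", "rate_linear",
  "time_to_inflection", "inflection_value"
)

# Numeric maximization of dy/dt: coarse grid scan then optimize() polish.
# The search window always covers the analytic inflection so the global
# maximum is found even when it lies outside the observed time range.
max_rate_numeric <- function(y0, yf, k, ti, nu, t_range) {
  t_inf <- richards_inflection_time(k, ti, nu)
  lo <- min(t_range[1], t_inf - 2 / k)
  hi <- max(t_range[2], t_inf + 2 / k)
  sgn <- if (yf >= y0) 1 else -1
  f <- function(t) sgn * richards_deriv(t, y0, yf, k, ti, nu)
  grid <- seq(lo, hi, length.out = 2001)
  i <- which.max(f(grid))
  bl <- grid[max(1, i - 1)]
  bu <- grid[min(length(grid), i + 1)]
  opt <- optimize(f, lower = bl, upper = bu, maximum = TRUE,
                  tol = .Machine$double.eps^0.5)
  list(time = opt$maximum, rate = sgn * opt$objective)
}

#' Derive the thirteen abiotic kinetic features from a fit
#'
#' From a converged [fit_five_param()] object, computes: maximum growth
#' rate and the time and curve value at maximum kinetic energy; the
#' exponential, linear and decay phase durations from the
#' inflection-tangent construction; the value change (delta) within each
#' phase; the rates of change in the exponential and linear phases; and
#' the inflection time and value (closed form for this model).
#'
#' @param fit A converged `five_param_fit`.
#' @param decay_frac Fraction of the span marking the end of the decay
#'   phase (default 0.95).
#' @return One-row tibble with the 13 feature columns.
#' @examples
#' t <- seq(0, 168, length.out = 20)
#' fit <- fit_five_param(t, richards(t, 25, 45, 0.1, 60, 1))
#' extract_abiotic_features(fit)
#' @export
extract_abiotic_features <- function(fit, decay_frac = 0.95) {
  stopifnot(inherits(fit, "five_param_fit"))
  if (!fit$converged) {
    stop("cannot extract features from a non-converged fit", call. = FALSE)
  }
  p <- as.list(fit$par)
  span <- abs(p$yf - p$y0)
  if (span < 1e-8) {
    stop("fitted span is degenerate; series is non-kinetic", call. = FALSE)
  }
  t_range <- range(fit$times)
  t_start <- t_range[1]

  mx <- max_rate_numeric(p$y0, p$yf, p$k, p$ti, p$nu, t_range)
  t_inf <- richards_inflection_time(p$k, p$ti, p$nu)
  y_inf <- richards_inflection_value(p$y0, p$yf, p$nu)

  # tangent at the inflection: y = y_inf + m (t - t_inf)
  m <- richards_deriv(t_inf, p$y0, p$yf, p$k, p$ti, p$nu)
  t_lower <- t_inf + (p$y0 - y_inf) / m
  t_upper <- t_inf + (p$yf - y_inf) / m
  t_decay_end <- richards_time_at_fraction(p$k, p$ti, p$nu, decay_frac)

  # contiguous, non-overlapping boundaries clamped to the curve start
  b <- cummax(c(t_start, t_lower, t_upper, t_decay_end))
  yb <- richards(b, p$y0, p$yf, p$k, p$ti, p$nu)
  dur <- diff(b)
  delta <- diff(yb)
  rate <- ifelse(dur > 0, delta / dur, 0)

  tibble::tibble(
    max_growth_rate = mx$rate,
    time_to_max_ke = mx$time,
    value_at_max_ke = richards(mx$time, p$y0, p$yf, p$k, p$ti, p$nu),
    exp_phase_duration = dur[1],
    linear_phase_duration = dur[2],
    decay_phase_duration = dur[3],
    delta_exp = delta[1],
    delta_linear = delta[2],
    delta_decay = delta[3],
    rate_exp = rate[1],
    rate_linear = rate[2],
    time_to_inflection = t_inf,
    inflection_value = y_inf
  )
}

#' Abiotic features for a table of fitted series
#'
#' Applies [extract_abiotic_features()] to every converged row of a
#' [fit_kinetics()] result.
#'
#' @param fits Tibble returned by [fit_kinetics()].
#' @inheritParams extract_abiotic_features
#' @return Tibble with the series identifier columns and the 13 feature
#'   columns; non-converged series are dropped with a warning.
#' @export
abiotic_features <- function(fits, decay_frac = 0.95) {
  stopifnot("fit" %in% names(fits))
  bad <- !fits$converged
  if (any(bad)) {
    warning(sprintf("dropping %d non-converged series", sum(bad)),
            call. = FALSE)
    fits <- fits[!bad, , drop = FALSE]
  }
  keys <- setdiff(names(fits),
                  c("y0", "yf", "k", "ti", "nu", "rmse", "r_squared",
                    "converged", "n_starts_used", "fit"))
  feats <- purrr::map(fits$fit, extract_abiotic_features,
                      decay_frac = decay_frac)
  dplyr::bind_cols(fits[keys], dplyr::bind_rows(feats))
}
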