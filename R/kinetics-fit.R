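# Least-squares fitting of the five-parameter generalized logistic to a
# single kinetic series, via Levenberg-Marquardt with deterministic
# multi-start initialization.

#' Fit the five-parameter generalized logistic to one series
#'
#' Fits `richards()` to a time series by bounded Levenberg-Marquardt
#' least squares ([minpack.lm::nlsLM()]) from a deterministic grid of
#' starting values: `y0`/`yf` from the data extremes (oriented by the
#' empirical trend), `ti` at the steepest empirical slope, `k` from that
#' slope, and asymmetry starts `nu` in {0.3, 1, 3} plus seeded jittered
#' restarts. The best-residual solution is returned; a failed optimization
#' is reported through `converged = FALSE` rather than an error.
#'
#' @param times Strictly increasing time points (hours).
#' @param values Measurements in native units (degrees C or pH).
#' @param min_points Minimum number of points required to fit (default 15,
#'   the design minimum for these fermentation series).
#' @param span_min Minimum data span (native units) below which the series
#'   is declared non-kinetic and rejected (default 0.5).
#' @param n_starts Total number of starts, including the three `nu`-grid
#'   starts; extras jitter the grid (default 7).
#' @param seed Integer seed controlling jittered restarts.
#' @return An object of class `five_param_fit`: the parameter estimates
#'   `y0`, `yf`, `k`, `ti`, `nu`, plus `rmse`, `r_squared`, `converged`,
#'   `n_starts_used` and the data.
#' @examples
#' t <- seq(0, 168, length.out = 20)
#' y <- richards(t, 25, 45, 0.1, 60, 1)
#' fit_five_param(t, y)
#' @seealso [fit_kinetics()] for the data-frame interface,
#'   [abiotic_features()] for the derived features.
#' @export
fit_five_param <- function(times, values, min_points = 15, span_min = 0.5,
                           n_starts = 7, seed = 1L) {
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length", call. = FALSE)
  }
  if (anyNA(times) || anyNA(values)) {
    stop("missing values are not allowed in a kinetic series", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (length(times) < min_points) {
    stop(sprintf("fitting requires at least %d points, got %d",
                 min_points, length(times)), call. = FALSE)
  }
  span <- diff(range(values))
  if (span <= span_min) {
    stop(sprintf(
      "data span %.3g is below the minimum span %.3g: series is non-kinetic",
      span, span_min), call. = FALSE)
  }

  rising <- values[length(values)] >= values[1]
  y0_start <- if (rising) min(values) else max(values)
  yf_start <- if (rising) max(values) else min(values)
  slopes <- diff(values) / diff(times)
  i_steep <- which.max(abs(slopes))
  ti_start <- (times[i_steep] + times[i_steep + 1]) / 2
  # for the symmetric logistic max slope = k * span / 4
  k_start <- max(4 * abs(slopes[i_steep]) / span, 1e-4)

  starts <- lapply(c(0.3, 1, 3), function(nu) {
    c(y0 = y0_start, yf = yf_start, k = k_start, ti = ti_start, nu = nu)
  })
  n_extra <- max(0L, n_starts - 3L)
  if (n_extra > 0) {
    jit <- with_seed(seed, replicate(n_extra, {
      c(y0 = y0_start + rnorm(1, 0, 0.05 * span),
        yf = yf_start + rnorm(1, 0, 0.05 * span),
        k = k_start * exp(rnorm(1, 0, 0.5)),
        ti = ti_start + rnorm(1, 0, 0.1 * diff(range(times))),
        nu = exp(rnorm(1, 0, 1)))
    }, simplify = FALSE))
    starts <- c(starts, jit)
  }

  lower <- c(y0 = -Inf, yf = -Inf, k = 1e-6, ti = -Inf, nu = 1e-3)
  upper <- c(y0 = Inf, yf = Inf, k = Inf, ti = Inf, nu = 1e3)
  df <- data.frame(t = times, y = values)
  best <- NULL
  best_rss <- Inf
  used <- 0L
  for (st in starts) {
    used <- used + 1L
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ y0 + (yf - y0) / (1 + exp(-k * (t - ti)))^(1 / nu),
        data = df, start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.finite(rss) && rss < best_rss) {
        best_rss <- rss
        best <- fit
      }
    }
  }

  if (is.null(best)) {
    out <- structure(list(
      par = c(y0 = NA_real_, yf = NA_real_, k = NA_real_, ti = NA_real_,
              nu = NA_real_),
      rmse = NA_real_, r_squared = NA_real_, converged = FALSE,
      n_starts_used = used, times = times, values = values
    ), class = "five_param_fit")
    return(out)
  }

  par <- stats::coef(best)
  rmse <- sqrt(best_rss / length(values))
  ss_tot <- sum((values - mean(values))^2)
  structure(list(
    par = par,
    rmse = rmse,
    r_squared = 1 - best_rss / ss_tot,
    converged = TRUE,
    n_starts_used = used,
    times = times,
    values = values
  ), class = "five_param_fit")
}

#' @export
print.five_param_fit <- function(x, ...) {
  cat("Five-parameter generalized logistic fit\n")
  if (x$converged) {
    cat(sprintf("  y0 = %.4g  yf = %.4g  k = %.4g /h  ti = %.4g h  nu = %.4g\n",
                x$par["y0"], x$par["yf"], x$par["k"], x$par["ti"], x$par["nu"]))
    cat(sprintf("  rmse = %.4g  R^2 = %.4f  (%d points, %d starts)\n",
                x$rmse, x$r_squared, length(x$times), x$n_starts_used))
  } else {
    cat("  did not converge (", x$n_starts_used, " starts)\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.five_param_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @export
glance.five_param_fit <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, r_squared = x$r_squared,
                 converged = x$converged, n_starts_used = x$n_starts_used,
                 nobs = length(x$times))
}

#' @export
autoplot.five_param_fit <- function(object, n = 200, ...) {
  pts <- tibble::tibble(time = object$times, value = object$values)
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time (h)", y = "value")
  if (object$converged) {
    grid <- seq(min(object$times), max(object$times), length.out = n)
    cur <- tibble::tibble(
      time = grid,
      value = richards(grid, object$par["y0"], object$par["yf"],
                       object$par["k"], object$par["ti"], object$par["nu"])
    )
    p <- p + ggplot2::geom_line(data = cur, colour = "steelblue")
  }
  p
}

#' Fit kinetic series stored in a long-format data frame
#'
#' Data-frame-first wrapper around [fit_five_param()]: every combination of
#' the non-`time`/`value` columns (for example `variable`, `compartment`,
#' `replicate`) is fitted as one series.
#'
#' @param data Long-format data frame with numeric `time` and `value`
#'   columns; all other columns identify the series.
#' @inheritParams fit_five_param
#' @param on_error `"keep"` (default) records a non-converged row when a
#'   series fails a precondition (too few points, sub-span data);
#'   `"stop"` raises the error.
#' @return A tibble with one row per series: identifier columns, the five
#'   parameter estimates, `rmse`, `r_squared`, `converged`,
#'   `n_starts_used`, and a `fit` list-column of `five_param_fit` objects.
#' @export
fit_kinetics <- function(data, min_points = 15, span_min = 0.5, n_starts = 7,
                         seed = 1L, on_error = c("keep", "stop")) {
  on_error <- match.arg(on_error)
  stopifnot(all(c("time", "value") %in% names(data)))
  keys <- setdiff(names(data), c("time", "value"))
  nested <- tidyr::nest(dplyr::group_by(data, dplyr::across(dplyr::all_of(keys))))
  nested <- dplyr::ungroup(nested)
  fits <- purrr::map(nested$data, function(d) {
    d <- dplyr::arrange(d, .data$time)
    tryCatch(
      fit_five_param(d$time, d$value, min_points = min_points,
                     span_min = span_min, n_starts = n_starts, seed = seed),
      error = function(e) {
        if (on_error == "stop") stop(e)
        warning(conditionMessage(e), call. = FALSE)
        structure(list(
          par = c(y0 = NA_real_, yf = NA_real_, k = NA_real_, ti = NA_real_,
                  nu = NA_real_),
          rmse = NA_real_, r_squared = NA_real_, converged = FALSE,
          n_starts_used = 0L, times = d$time, values = d$value
        ), class = "five_param_fit")
      }
    )
  })
  pars <- purrr::map(fits, \(f) tibble::as_tibble(as.list(f$par)))
  out <- dplyr::bind_cols(
    nested[keys],
    dplyr::bind_rows(pars),
    tibble::tibble(
      rmse = purrr::map_dbl(fits, "rmse"),
      r_squared = purrr::map_dbl(fits, "r_squared"),
      converged = purrr::map_lgl(fits, "converged"),
      n_starts_used = purrr::map_int(fits, \(f) as.integer(f$n_starts_used)),
      fit = fits
    )
  )
  tibble::as_tibble(out)
}

#' Reflect a series about its maximum
#'
#' Replaces `value` with `max(value) - value` within each series, recording
#' the offset so that a second call restores the original values (the
#' transformation used to model falling cotyledon pH with a rising
#' sigmoid).
#'
#' @param data Data frame with a numeric `value` column; all columns other
#'   than `time` and `value` (and the bookkeeping columns added here)
#'   identify the series.
#' @return The data with `value` reflected, an `orientation` column
#'   (`"inverted"` or `"as-is"`) and an `offset` column holding the
#'   reflection offset.
#' @examples
#' d <- data.frame(time = c(0, 24, 48), value = c(6.5, 5.5, 4.8))
#' invert_series(d)$value # 1.7 1.0 0.0
#' @export
invert_series <- function(data) {
  stopifnot("value" %in% names(data))
  keys <- setdiff(names(data), c("time", "value", "orientation", "offset"))
  grouped <- dplyr::group_by(data, dplyr::across(dplyr::all_of(keys)))
  if ("orientation" %in% names(data) &&
      all(data$orientation == "inverted")) {
    out <- dplyr::mutate(grouped,
      value = .data$offset - .data$value,
      orientation = "as-is"
    )
  } else {
    out <- dplyr::mutate(grouped,
      offset = max(.data$value),
      value = .data$offset - .data$value,
      orientation = "inverted"
    )
  }
  tibble::as_tibble(dplyr::ungroup(out))
}

#' Bean-colour summary metrics from RGB channels
#'
#' Computes the plain channel average `(R + G + B) / 3` (greyscale) and the
#' perceptual luminance `0.299 R + 0.587 G + 0.114 B` used to track cocoa
#' bean browning during fermentation.
#'
#' @param data Data frame with numeric columns `R`, `G`, `B` in `[0, 255]`.
#' @return The input with `greyscale` and `luminance` columns appended.
#' @examples
#' colour_metrics(data.frame(R = 255, G = 0, B = 0))
#' @export
colour_metrics <- function(data) {
  stopifnot(all(c("R", "G", "B") %in% names(data)))
  ch <- as.matrix(data[, c("R", "G", "B")])
  if (anyNA(ch) || any(ch < 0) || any(ch > 255)) {
    stop("RGB channel values must lie in [0, 255]", call. = FALSE)
  }
  dplyr::mutate(tibble::as_tibble(data),
    greyscale = (.data$R + .data$G + .data$B) / 3,
    luminance = 0.299 * .data$R + 0.587 * .data$G + 0.114 * .data$B
  )
}
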