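# Seven growth-curve summary features for taxon relative-abundance
# trajectories, plus the PERMANOVA-coefficient marker filter.

growth_feature_names <- c(
  "first_local_max", "initial_density", "auc", "max_density",
  "time_to_max_density", "midpoint", "inflection_point"
)

# Centered moving average with the window shrunk at the edges; w = 1 is the
# identity.
moving_average <- function(y, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1) return(y)
  h <- (window - 1) / 2
  n <- length(y)
  vapply(seq_len(n), function(i) {
    mean(y[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# Earliest index that is a local maximum/minimum; endpoints are compared
# one-sided, so boundary peaks count. Ties resolve to the earliest time.
first_local_extreme <- function(y, maximum = TRUE) {
  n <- length(y)
  cmp <- if (maximum) `>=` else `<=`
  for (i in seq_len(n)) {
    left_ok <- i == 1 || cmp(y[i], y[i - 1])
    right_ok <- i == n || cmp(y[i], y[i + 1])
    if (left_ok && right_ok) return(i)
  }
  1L
}

growth_features_one <- function(times, values, window = 3) {
  if (length(times) < 3) {
    stop("growth features require at least 3 points", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`time` must be strictly increasing within a trajectory",
         call. = FALSE)
  }
  y <- moving_average(values, window)
  n <- length(y)

  i_max <- which.max(y)[1]
  max_density <- y[i_max]
  first_local_max <- y[first_local_extreme(y, maximum = TRUE)]
  initial_density <- y[first_local_extreme(y, maximum = FALSE)]
  auc <- sum(diff(times) * (head(y, -1) + y[-1]) / 2)

  # earliest time the piecewise-linear interpolant reaches half the
  # observed maximum
  half <- max_density / 2
  midpoint <- times[n]
  if (y[1] >= half) {
    midpoint <- times[1]
  } else {
    for (i in seq_len(n - 1)) {
      if (y[i] < half && y[i + 1] >= half) {
        midpoint <- times[i] +
          (half - y[i]) / (y[i + 1] - y[i]) * (times[i + 1] - times[i])
        break
      }
    }
  }

  slopes <- diff(y) / diff(times)
  inflection_point <- times[which.max(slopes)[1]]

  tibble::tibble(
    first_local_max = first_local_max,
    initial_density = initial_density,
    auc = auc,
    max_density = max_density,
    time_to_max_density = times[i_max],
    midpoint = midpoint,
    inflection_point = inflection_point
  )
}

#' Growth-curve features of abundance trajectories
#'
#' Computes, per trajectory: (1) the first local maximum of density,
#' (2) the initial density (earliest local minimum), (3) the trapezoidal
#' area under the curve, (4) the maximum density, (5) the time to maximum
#' density, (6) the midpoint (first time the linearly interpolated curve
#' reaches half the maximum density) and (7) the inflection point (time at
#' which the forward-difference derivative is largest). An optional
#' centered moving average (default window 3 points, shrunk at the edges)
#' is applied first; `window = 1` disables smoothing. Endpoint extrema
#' count (one-sided comparison) and ties resolve to the earliest time.
#'
#' @param data Data frame with numeric `time` and `abundance` columns; all
#'   other columns (for example `taxon`, `replicate`) identify the
#'   trajectory.
#' @param window Odd moving-average window in points (default 3).
#' @return Tibble with one row per trajectory: identifier columns plus the
#'   7 feature columns.
#' @examples
#' d <- data.frame(time = c(0, 24, 48), abundance = c(0, 0.5, 1))
#' growth_features(d, window = 1)
#' @export
growth_features <- function(data, window = 3) {
  stopifnot(all(c("time", "abundance") %in% names(data)))
  if (any(data$abundance < 0 | data$abundance > 1)) {
    stop("`abundance` must lie in [0, 1]", call. = FALSE)
  }
  keys <- setdiff(names(data), c("time", "abundance"))
  nested <- dplyr::ungroup(tidyr::nest(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(keys)))))
  feats <- purrr::map(nested$data, function(d) {
    d <- dplyr::arrange(d, .data$time)
    growth_features_one(d$time, d$abundance, window = window)
  })
  dplyr::bind_cols(nested[keys], dplyr::bind_rows(feats))
}

#' Select marker taxa from PERMANOVA coefficients
#'
#' Applies the per-kingdom coefficient thresholds used to pick the taxa
#' that drive community turnover: bacteria with coefficients at or above
#' 10 and fungi at or above 5 are retained by default (the comparison is
#' inclusive).
#'
#' @param coefficients Data frame with columns `taxon`, `kingdom`
#'   (`"bacteria"` or `"fungi"`) and numeric `coefficient`.
#' @param thresholds Named numeric vector of per-kingdom thresholds.
#' @return Tibble of the selected rows, with a `threshold` column.
#' @examples
#' select_markers(data.frame(
#'   taxon = c("A", "B"), kingdom = "bacteria", coefficient = c(12, 9.9)
#' ))
#' @export
select_markers <- function(coefficients,
                           thresholds = c(bacteria = 10, fungi = 5)) {
  stopifnot(all(c("taxon", "kingdom", "coefficient") %in% names(coefficients)))
  if (nrow(coefficients) == 0) {
    return(tibble::tibble(taxon = character(), kingdom = character(),
                          coefficient = numeric(), threshold = numeric()))
  }
  if (anyNA(coefficients$coefficient) ||
      any(!is.finite(coefficients$coefficient))) {
    stop("coefficients must be finite", call. = FALSE)
  }
  unknown <- setdiff(unique(coefficients$kingdom), names(thresholds))
  if (length(unknown) > 0) {
    stop("unknown kingdom(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- dplyr::mutate(tibble::as_tibble(coefficients),
                       threshold = unname(thresholds[.data$kingdom]))
  dplyr::filter(out, .data$coefficient >= .data$threshold)
}
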