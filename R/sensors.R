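#' Construct a sensor time series
#'
#' A regular-cadence relative-humidity / temperature logger series, the unit
#' of input for dew/fog event statistics. Timestamps must be strictly
#' increasing and equally spaced (default cadence 30 min, the loggers'
#' recording interval). Gaps are represented by rows whose `rh`/`temp` are
#' `NA` on the regular grid, never by missing rows.
#'
#' @param timestamp `POSIXct` vector, strictly increasing, equally spaced.
#' @param rh relative humidity in percent, within \[0, 100\] (or `NA` for a
#'   marked gap).
#' @param temp temperature in degrees Celsius (or `NA`).
#' @param label site or probe identifier.
#' @return A `data.frame` of class `sensor_series` with columns
#'   `timestamp`, `rh`, `temp` and attributes `label` and `cadence_min`.
#' @export
sensor_series <- function(timestamp, rh, temp, label = "site") {
  if (!inherits(timestamp, "POSIXct")) {
    timestamp <- as.POSIXct(timestamp, tz = "UTC")
  }
  n <- length(timestamp)
  stopifnot(length(rh) == n, length(temp) == n, n >= 2)
  dt <- as.numeric(diff(timestamp), units = "mins")
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6) {
    stop("irregular cadence: resample the series to a regular grid first ",
         "(mark gaps as NA rows)")
  }
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) {
    stop("rh must lie within [0, 100]")
  }
  out <- data.frame(timestamp = timestamp, rh = rh, temp = temp)
  attr(out, "label") <- label
  attr(out, "cadence_min") <- dt[1]
  class(out) <- c("sensor_series", "data.frame")
  out
}

.as_sensor_series <- function(x) {
  if (inherits(x, "sensor_series")) return(x)
  stopifnot(is.data.frame(x), all(c("timestamp", "rh", "temp") %in% names(x)))
  sensor_series(x$timestamp, x$rh, x$temp,
                label = if (!is.null(attr(x, "label"))) attr(x, "label") else "site")
}

#' Detect dew or fog events in an RH series
#'
#' An event is a maximal run of consecutive samples with `rh` strictly above
#' the threshold (dew: RH > 95\%; fog: RH > 99\%). Boundary samples at
#' exactly the threshold do not trigger. Event duration is run length times
#' the cadence, so a single above-threshold sample counts the full cadence
#' interval. Gaps (`NA`) terminate runs and never count as above threshold.
#'
#' A calendar day is counted once per event type regardless of how many
#' events fall on it; an event spanning midnight contributes to both days.
#'
#' @param series a [sensor_series()] (or coercible data.frame).
#' @param threshold RH threshold in percent, in (0, 100). Use 95 for dew and
#'   99 for fog.
#' @return A list with `events` (data.frame: `start`, `end`, `duration_h`)
#'   and `summary` (list: `threshold`, `n_events`, `n_days`,
#'   `mean_duration_h`, `max_duration_h`; durations are over events, not
#'   days, and are 0 when no event is found).
#' @export
detect_events <- function(series, threshold = 95) {
  series <- .as_sensor_series(series)
  stopifnot(threshold > 0, threshold < 100)
  cad_min <- attr(series, "cadence_min")
  above <- !is.na(series$rh) & series$rh > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  events <- data.frame(start = series$timestamp[starts[keep]],
                       end = series$timestamp[ends[keep]] + cad_min * 60,
                       duration_h = r$lengths[keep] * cad_min / 60)
  days <- character(0)
  for (i in seq_len(nrow(events))) {
    idx <- seq(starts[keep][i], ends[keep][i])
    days <- c(days, unique(format(series$timestamp[idx], "%Y-%m-%d")))
  }
  summary <- list(threshold = threshold,
                  n_events = nrow(events),
                  n_days = length(unique(days)),
                  mean_duration_h = if (nrow(events)) mean(events$duration_h) else 0,
                  max_duration_h = if (nrow(events)) max(events$duration_h) else 0)
  list(events = events, summary = summary)
}

#' Paired difference between two sensor sites
#'
#' Aligns two series on shared timestamps and summarises the differences
#' `b - a` in temperature and relative humidity, overall and by time of day
#' (48 half-hour bins at the default cadence). Used to quantify, e.g., how
#' much cooler and more humid one site is than another.
#'
#' @param a,b [sensor_series()] objects with the same cadence and an
#'   overlapping span.
#' @return A list: `n_pairs`, `mean_dT` and `mean_dRH` (means of `b - a`
#'   over aligned pairs, `NA` values dropped pairwise), and `by_tod`, a
#'   data.frame with one row per time-of-day bin (`tod_h`, `dT`, `dRH`).
#' @export
site_difference <- function(a, b) {
  a <- .as_sensor_series(a)
  b <- .as_sensor_series(b)
  if (attr(a, "cadence_min") != attr(b, "cadence_min")) {
    stop("series have different cadences")
  }
  ia <- match(as.numeric(b$timestamp), as.numeric(a$timestamp))
  keep <- !is.na(ia)
  if (!any(keep)) stop("series have no overlapping timestamps")
  dT <- b$temp[keep] - a$temp[ia[keep]]
  dRH <- b$rh[keep] - a$rh[ia[keep]]
  ts <- b$timestamp[keep]
  tod <- (as.numeric(ts) %% 86400) / 3600
  by_tod <- aggregate(cbind(dT, dRH) ~ tod, FUN = mean, na.action = stats::na.omit,
                      data = data.frame(tod = tod, dT = dT, dRH = dRH))
  names(by_tod)[1] <- "tod_h"
  list(n_pairs = sum(keep),
       mean_dT = mean(dT, na.rm = TRUE),
       mean_dRH = mean(dRH, na.rm = TRUE),
       by_tod = by_tod)
}

#' Mean daily (diel) profile of a sensor series
#'
#' Bins observations by time of day (one bin per cadence step; 48 bins at
#' 30-min cadence) and returns the mean and SD per bin, the quantity plotted
#' as a "daily average over a year".
#'
#' @param series a [sensor_series()].
#' @return data.frame: `tod_h` (hours since midnight), `rh_mean`, `rh_sd`,
#'   `temp_mean`, `temp_sd`, `n`.
#' @export
daily_profile <- function(series) {
  series <- .as_sensor_series(series)
  tod <- (as.numeric(series$timestamp) %% 86400) / 3600
  f <- factor(tod, levels = sort(unique(tod)))
  agg <- function(v, fun) as.numeric(tapply(v, f, fun, na.rm = TRUE))
  sd0 <- function(x, na.rm) if (sum(!is.na(x)) < 2) 0 else stats::sd(x, na.rm = na.rm)
  data.frame(tod_h = as.numeric(levels(f)),
             rh_mean = agg(series$rh, mean),
             rh_sd = agg(series$rh, sd0),
             temp_mean = agg(series$temp, mean),
             temp_sd = agg(series$temp, sd0),
             n = as.integer(table(f)))
}

#' Local-polynomial kernel regression
#'
#' Gaussian-kernel local polynomial smoother. At each query point the
#' response is fit by weighted least squares to a degree-`degree` polynomial
#' in the centred, bandwidth-scaled predictor; the fitted value is the local
#' intercept. `degree = 0` is the local (kernel-weighted) average used for
#' abundance-versus-distance curves; higher degrees reproduce polynomials of
#' matching degree exactly on noiseless input. A rank-deficient local system
#' falls back to the highest degree that is identifiable at that query
#' point, recorded in `degree_used`.
#'
#' @param x,y numeric vectors of equal length (length at least `degree + 1`).
#' @param bandwidth Gaussian kernel SD, in units of `x`; must be positive.
#' @param degree polynomial degree (default 0).
#' @param grid query points; defaults to the sorted unique `x`.
#' @return data.frame: `x` (grid), `y` (fit), `degree_used`.
#' @export
kernel_smooth <- function(x, y, bandwidth, degree = 0, grid = NULL) {
  stopifnot(length(x) == length(y), bandwidth > 0, degree >= 0)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < degree + 1) stop("need at least degree + 1 points")
  if (is.null(grid)) grid <- sort(unique(x))
  fit <- numeric(length(grid))
  used <- integer(length(grid))
  for (j in seq_along(grid)) {
    z <- (x - grid[j]) / bandwidth
    w <- stats::dnorm(z)
    if (sum(w > 0) == 0) w <- rep(1e-300, length(z))
    for (q in seq(degree, 0)) {
      X <- outer(z, 0:q, "^")
      f <- tryCatch({
        b <- stats::lm.wfit(X, y, w)
        if (b$rank < q + 1 || is.na(b$coefficients[1])) stop("singular")
        b$coefficients[1]
      }, error = function(e) NULL)
      if (!is.null(f)) {
        fit[j] <- f
        used[j] <- q
        break
      }
    }
  }
  data.frame(x = grid, y = fit, degree_used = used)
}
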