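#' Trailing moving mean (2-period trendline)
#'
#' Spreadsheet-style trailing moving mean: each sample is replaced by the
#' mean of itself and the preceding `window - 1` available samples; the
#' first sample is returned unchanged. `window = 1` is the identity.
#'
#' @param x numeric vector.
#' @param window window length (>= 1), default 2.
#' @return Numeric vector of the same length.
#' @export
movingMean <- function(x, window = 2) {
  n <- length(x)
  if (n == 0L) stop("empty series")
  if (window < 1) stop("window must be >= 1")
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - window + 1L):i])
  }, numeric(1L))
}

.halfTimeResult <- function(halfTime, initial, final) {
  structure(list(half_time_s = halfTime, initial_value = initial,
                 final_value = final, crossing_interp = "linear",
                 defined = is.finite(halfTime)),
            class = "HalfTimeResult")
}

#' @export
print.HalfTimeResult <- function(x, ...) {
  if (x$defined)
    cat(sprintf("half-time: %.4g s (from %.4g to %.4g, linear crossing)\n",
                x$half_time_s, x$initial_value, x$final_value))
  else cat("half-time: undefined (no crossing)\n")
  invisible(x)
}

## earliest linearly interpolated crossing of level M within times[seq]
.firstCrossing <- function(times, values, M) {
  for (i in seq_len(length(values) - 1L)) {
    v0 <- values[i]; v1 <- values[i + 1L]
    if (v0 == M) return(times[i])
    if ((v0 - M) * (v1 - M) < 0) {
      return(times[i] + (M - v0) / (v1 - v0) * (times[i + 1L] - times[i]))
    }
  }
  if (values[length(values)] == M) return(times[length(values)])
  NA_real_
}

#' Half-time of a monotone-trending transient
#'
#' The midpoint level M = (v(t_first) + v(t_last))/2 between the first and
#' last sampled values, and the earliest time at which the series crosses M,
#' linearly interpolated between the bracketing samples. No asymptote is
#' fitted: the record's own endpoints define the transition. Undefined
#' (`NA`) if the series never crosses M.
#'
#' @param times sampling times (s), strictly increasing.
#' @param values series values at `times` (>= 3 non-missing points; `NA`
#'   samples are skipped).
#' @return A `HalfTimeResult` list: `half_time_s`, `initial_value`,
#'   `final_value`, `crossing_interp`, `defined`.
#' @export
halfTime <- function(times, values) {
  stopifnot(length(times) == length(values))
  keep <- !is.na(values)
  times <- times[keep]; values <- values[keep]
  if (length(values) < 3L) stop("need >= 3 points")
  v1 <- values[1L]; vn <- values[length(values)]
  if (v1 == vn) return(.halfTimeResult(NA_real_, v1, vn))
  M <- (v1 + vn) / 2
  ## the first sample sits on neither side of M strictly; scan from it
  tc <- .firstCrossing(times, values, M)
  .halfTimeResult(tc, v1, vn)
}

#' Half-time to reach the series' extreme
#'
#' Identifies the global extreme v* (maximum or minimum, whichever has the
#' larger excursion from the first sample; ties go to the maximum) and
#' returns the earliest linearly interpolated crossing of the level
#' (v(t_first) + v*)/2 on the way to that extreme.
#'
#' @inheritParams halfTime
#' @return A `HalfTimeResult`; undefined for a flat series.
#' @export
timeToExtremeHalf <- function(times, values) {
  stopifnot(length(times) == length(values))
  keep <- !is.na(values)
  times <- times[keep]; values <- values[keep]
  if (length(values) < 3L) stop("need >= 3 points")
  v1 <- values[1L]
  iMax <- which.max(values); iMin <- which.min(values)
  excMax <- values[iMax] - v1; excMin <- v1 - values[iMin]
  if (excMax == 0 && excMin == 0)
    return(.halfTimeResult(NA_real_, v1, v1))
  iExt <- if (excMax >= excMin) iMax else iMin
  vExt <- values[iExt]
  M <- (v1 + vExt) / 2
  tc <- .firstCrossing(times[1:iExt], values[1:iExt], M)
  .halfTimeResult(tc, v1, vExt)
}

#' First relative extremum of the trend
#'
#' Detects, on the `window`-period trailing moving-mean trend, the earliest
#' interior point strictly greater (maximum) or strictly smaller (minimum)
#' than both neighbours. Plateaus qualify through their first point when the
#' flat run is strictly above/below both flanking values. A monotone trend
#' yields kind `"none"`.
#'
#' @param times sampling times (s).
#' @param values series values (>= 3 points).
#' @param window moving-mean window applied before detection (default 2;
#'   use 1 to detect on the raw series).
#' @return A list of class `ExtremumResult`: `kind` (`"max"`, `"min"` or
#'   `"none"`), `index`, `time_s`, `trend_value`.
#' @export
firstExtremum <- function(times, values, window = 2) {
  stopifnot(length(times) == length(values))
  keep <- !is.na(values)
  times <- times[keep]; values <- values[keep]
  if (length(values) < 3L) stop("need >= 3 points")
  trend <- movingMean(values, window)
  r <- rle(trend)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  if (length(r$values) >= 3L) {
    for (j in 2:(length(r$values) - 1L)) {
      v <- r$values[j]; vl <- r$values[j - 1L]; vr <- r$values[j + 1L]
      kind <- if (v > vl && v > vr) "max"
              else if (v < vl && v < vr) "min" else NA
      if (!is.na(kind)) {
        i <- starts[j]
        return(structure(list(kind = kind, index = i, time_s = times[i],
                              trend_value = trend[i]),
                         class = "ExtremumResult"))
      }
    }
  }
  structure(list(kind = "none", index = NA_integer_, time_s = NA_real_,
                 trend_value = NA_real_),
            class = "ExtremumResult")
}

#' @export
print.ExtremumResult <- function(x, ...) {
  if (x$kind == "none") cat("first extremum: none (monotone trend)\n")
  else cat(sprintf("first extremum: %s at t = %.4g s (trend value %.4g)\n",
                   x$kind, x$time_s, x$trend_value))
  invisible(x)
}
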