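#' Construct a biomarker time series
#'
#' One patient's irregular time series of one biomarker.  Timestamps are
#' numeric days (fractional after oversampling) and must be strictly
#' increasing; duplicate timestamps are rejected, so same-day readings must
#' be pre-aggregated by the caller.
#'
#' @param biomarker Biomarker identifier (should match a panel spec name).
#' @param time Numeric timestamps in days, strictly increasing.
#' @param value Numeric measurements, same length as \code{time}, finite.
#' @return An object of class \code{"biomarker_series"}.
#' @examples
#' biomarker_series("sBP", c(0, 30, 90, 200, 400), c(118, 124, 131, 135, 142))
#' @export
biomarker_series <- function(biomarker, time, value) {
  time <- as.numeric(time)
  value <- as.numeric(value)
  if (length(time) != length(value)) {
    stop("time and value must have the same length", call. = FALSE)
  }
  if (length(time) < 1L) {
    stop("a biomarker series needs at least one reading", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(!is.finite(value))) {
    stop("timestamps and values must be finite", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("timestamps must be strictly increasing (aggregate same-day readings first)",
         call. = FALSE)
  }
  structure(list(biomarker = as.character(biomarker), time = time,
                 value = value),
            class = "biomarker_series")
}

#' @export
print.biomarker_series <- function(x, ...) {
  cat(sprintf("<biomarker_series> %s: %d samples over %.0f days\n",
              x$biomarker, length(x$value), diff(range(x$time))))
  invisible(x)
}

#' @export
length.biomarker_series <- function(x) length(x$value)

#' Eligibility check for inclination analysis
#'
#' A series is eligible when it holds at least \code{min_readings} original
#' readings (default five, the minimum found to give reliable estimates of
#' the final-state probabilities).
#'
#' @param series A \code{\link{biomarker_series}}.
#' @param min_readings Minimum number of readings required.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
check_eligibility <- function(series, min_readings = 5L) {
  stopifnot(inherits(series, "biomarker_series"))
  length(series$value) >= min_readings
}

#' Midpoint oversampling of an irregular series
#'
#' Densifies a series from N readings to 2N - 1 samples by halving each
#' interval between subsequent readings: every inserted sample sits at the
#' temporal midpoint of its two neighbours and takes their mean value.
#' Applied exactly once, a five-reading series becomes nine samples.
#'
#' @param series A \code{\link{biomarker_series}} with at least two readings.
#' @return A \code{\link{biomarker_series}} of length \code{2 * N - 1}.
#' @examples
#' s <- biomarker_series("sBP", c(0, 10), c(100, 110))
#' oversample(s)$time   # 0 5 10
#' oversample(s)$value  # 100 105 110
#' @export
oversample <- function(series) {
  stopifnot(inherits(series, "biomarker_series"))
  n <- length(series$value)
  if (n < 2L) {
    stop("oversampling needs at least two readings", call. = FALSE)
  }
  t2 <- v2 <- numeric(2L * n - 1L)
  t2[seq(1L, 2L * n - 1L, by = 2L)] <- series$time
  v2[seq(1L, 2L * n - 1L, by = 2L)] <- series$value
  mid <- seq(2L, 2L * n - 2L, by = 2L)
  t2[mid] <- (series$time[-n] + series$time[-1L]) / 2
  v2[mid] <- (series$value[-n] + series$value[-1L]) / 2
  biomarker_series(series$biomarker, t2, v2)
}
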