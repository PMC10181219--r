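#' Configuration of an inclination-analysis variant
#'
#' Eight preset variants (\code{version} 0 to 7) differ in the window length
#' \code{m}, the per-pair trend measure (\code{delta_scheme}) and the
#' clinical weighting rule (\code{weight_scheme}):
#'
#' \tabular{llll}{
#'   version \tab m \tab delta \tab weight \cr
#'   0 \tab 3 \tab difference     \tab constant_one   \cr
#'   1 \tab 3 \tab integral_ratio \tab constant_one   \cr
#'   2 \tab 3 \tab difference     \tab binary_norm_thr\cr
#'   3 \tab 3 \tab slope          \tab binary_norm_thr\cr
#'   4 \tab 3 \tab slope          \tab linear_min_max \cr
#'   5 \tab 3 \tab sign           \tab linear_min_max \cr
#'   6 \tab 4 \tab sign           \tab linear_min_max \cr
#'   7 \tab 3 \tab sign           \tab linear_low_high
#' }
#'
#' The remaining fields parameterize the absorbing Markov model and the
#' decision rule: \code{r_minus} is the probability of a collapse local state
#' at the next step when neither critical level is reached, \code{m_minus}
#' and \code{m_plus} are the critical counts of collapse/survival states that
#' force the next state deterministically (both default to \code{m}, making
#' only the all-collapse and all-survival sequences absorbing),
#' \code{power_iterations} is the matrix power used to approximate the
#' limiting matrix, and \code{delta_band} is the half-width of the
#' no-clear-inclination band around index 1.
#'
#' @param version Integer 0..7 selecting a preset, or \code{NULL} to set the
#'   scheme fields directly.
#' @param m Window length in samples (>= 2; >= 1 for the Markov model alone).
#' @param delta_scheme One of \code{"difference"}, \code{"integral_ratio"},
#'   \code{"slope"}, \code{"sign"}.
#' @param weight_scheme One of \code{"constant_one"}, \code{"binary_norm_thr"},
#'   \code{"linear_min_max"}, \code{"linear_low_high"}.
#' @param delta_band Decision band half-width (>= 0), default 0.1.
#' @param r_minus Transition probability towards collapse below the critical
#'   levels, default 0.5.
#' @param m_minus,m_plus Critical levels; default \code{m}.
#' @param power_iterations Power used for the limiting matrix, default 10000.
#' @return An object of class \code{"inclination_config"}.
#' @examples
#' inclination_config(7)
#' inclination_config(version = NULL, m = 2, delta_scheme = "difference",
#'                    weight_scheme = "constant_one")
#' @export
inclination_config <- function(version = 7L, m = NULL, delta_scheme = NULL,
                               weight_scheme = NULL, delta_band = 0.1,
                               r_minus = 0.5, m_minus = NULL, m_plus = NULL,
                               power_iterations = 10000L) {
  presets <- list(
    list(m = 3L, delta = "difference",     weight = "constant_one"),
    list(m = 3L, delta = "integral_ratio", weight = "constant_one"),
    list(m = 3L, delta = "difference",     weight = "binary_norm_thr"),
    list(m = 3L, delta = "slope",          weight = "binary_norm_thr"),
    list(m = 3L, delta = "slope",          weight = "linear_min_max"),
    list(m = 3L, delta = "sign",           weight = "linear_min_max"),
    list(m = 4L, delta = "sign",           weight = "linear_min_max"),
    list(m = 3L, delta = "sign",           weight = "linear_low_high")
  )
  if (!is.null(version)) {
    version <- as.integer(version)
    if (length(version) != 1L || is.na(version) || version < 0L || version > 7L) {
      stop("version must be a single integer in 0..7", call. = FALSE)
    }
    p <- presets[[version + 1L]]
    if (is.null(m)) m <- p$m
    if (is.null(delta_scheme)) delta_scheme <- p$delta
    if (is.null(weight_scheme)) weight_scheme <- p$weight
  }
  delta_scheme <- match.arg(delta_scheme,
                            c("difference", "integral_ratio", "slope", "sign"))
  weight_scheme <- match.arg(weight_scheme,
                             c("constant_one", "binary_norm_thr",
                               "linear_min_max", "linear_low_high"))
  m <- as.integer(m)
  if (is.null(m_minus)) m_minus <- m
  if (is.null(m_plus)) m_plus <- m
  m_minus <- as.integer(m_minus); m_plus <- as.integer(m_plus)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  if (r_minus < 0 || r_minus > 1) stop("r_minus must be in [0, 1]", call. = FALSE)
  if (delta_band < 0) stop("delta_band must be >= 0", call. = FALSE)
  if (m_minus < 1L || m_minus > m || m_plus < 1L || m_plus > m) {
    stop("critical levels must lie in 1..m", call. = FALSE)
  }
  structure(
    list(version = if (is.null(version)) NA_integer_ else version,
         m = m, delta_scheme = delta_scheme, weight_scheme = weight_scheme,
         delta_band = delta_band, r_minus = r_minus,
         m_minus = m_minus, m_plus = m_plus,
         power_iterations = as.integer(power_iterations)),
    class = "inclination_config"
  )
}

#' @export
print.inclination_config <- function(x, ...) {
  cat(sprintf(
    "<inclination_config> version %s: m = %d, delta = %s, weight = %s\n",
    ifelse(is.na(x$version), "custom", x$version), x$m, x$delta_scheme,
    x$weight_scheme))
  cat(sprintf("  delta_band %.3g | r_minus %.3g | critical levels %d/%d | power %d\n",
              x$delta_band, x$r_minus, x$m_minus, x$m_plus,
              x$power_iterations))
  invisible(x)
}

# total trapezoid area under a series; denominator of the integral-ratio scheme
total_area <- function(series) {
  n <- length(series$value)
  sum(diff(series$time) * (series$value[-n] + series$value[-1L]) / 2)
}

#' Per-pair trend measure
#'
#' The signed contribution of the consecutive sample pair (i, i + 1) under a
#' delta scheme: the raw difference, the time slope, the sign of the change,
#' or the signed fraction of the series' total trapezoid area lying under the
#' pair segment (integral-ratio).
#'
#' @param series A \code{\link{biomarker_series}} (typically oversampled).
#' @param i Pair index, 1..length(series) - 1.
#' @param scheme Delta scheme name (see \code{\link{inclination_config}}).
#' @return A single signed value.
#' @examples
#' s <- biomarker_series("sBP", c(0, 5), c(100, 110))
#' pair_delta(s, 1, "slope") # 2 per day
#' @export
pair_delta <- function(series, i,
                       scheme = c("difference", "integral_ratio", "slope",
                                  "sign")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(series, "biomarker_series"))
  i <- as.integer(i)
  if (i < 1L || i >= length(series$value)) {
    stop("pair index out of range", call. = FALSE)
  }
  x1 <- series$value[i]; x2 <- series$value[i + 1L]
  dt <- series$time[i + 1L] - series$time[i]
  switch(scheme,
    difference = x2 - x1,
    sign = sign(x2 - x1),
    slope = {
      if (dt <= 0) stop("degenerate time spacing for slope", call. = FALSE)
      (x2 - x1) / dt
    },
    integral_ratio = {
      tot <- total_area(series)
      if (tot <= 0) stop("degenerate total area for integral ratio", call. = FALSE)
      sign(x2 - x1) * (dt * (x1 + x2) / 2) / tot
    })
}

#' Clinical weighting factor for one sample pair
#'
#' Maps the later sample of a pair to a weight in [1, 2] that amplifies
#' clinically alarming moves: an increase at a bad value, or a decrease at a
#' good value, is weighted towards 2; the opposite combinations towards 1.
#' "Bad" and "good" are read off the spec's thresholds; for
#' \code{increase_good} biomarkers (HDL) the value axis is mirrored so the
#' same rules apply.
#'
#' Schemes: \code{constant_one} always 1; \code{binary_norm_thr} 1 or 2 by
#' the side of the normality threshold; \code{linear_min_max} and
#' \code{linear_low_high} interpolate linearly between 1 and 2 over
#' [min, max] and [low, high] respectively (clamped).
#'
#' @param value The later sample value of the pair.
#' @param delta_sign Sign of the pair's raw change: -1, 0, or +1.
#' @param spec A \code{\link{biomarker_spec}}.
#' @param scheme Weight scheme name.
#' @return A weight in [1, 2]; 1 whenever \code{delta_sign} is 0.
#' @examples
#' sbp <- default_panel()$sBP
#' pair_weight(110, +1, sbp, "binary_norm_thr") # 1: rise below normality
#' pair_weight(115, +1, sbp, "linear_low_high") # 1.5: midway between 70, 160
#' @export
pair_weight <- function(value, delta_sign, spec,
                        scheme = c("constant_one", "binary_norm_thr",
                                   "linear_min_max", "linear_low_high")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(spec, "biomarker_spec"))
  if (scheme == "constant_one" || delta_sign == 0) return(1)
  mirror <- spec$direction == "increase_good"
  ds <- if (mirror) -delta_sign else delta_sign
  if (scheme == "binary_norm_thr") {
    bad <- if (mirror) value < spec$normality_thr else value > spec$normality_thr
    return(if ((ds > 0 && bad) || (ds < 0 && !bad)) 2 else 1)
  }
  bounds <- if (scheme == "linear_min_max") {
    c(spec$min_val, spec$max_val)
  } else {
    c(spec$low_thr, spec$high_thr)
  }
  pos <- relative_position(value, bounds[1L], bounds[2L])
  if (mirror) pos <- 1 - pos
  if (ds > 0) 1 + pos else 2 - pos
}

# signed, weighted pair contributions over a whole series, mirrored for
# increase_good biomarkers so a clinical worsening is always positive
pair_contributions <- function(series, spec, config) {
  n <- length(series$value)
  v <- series$value
  d <- vapply(seq_len(n - 1L), function(i) {
    pair_delta(series, i, config$delta_scheme)
  }, numeric(1))
  s <- sign(diff(v))
  w <- vapply(seq_len(n - 1L), function(i) {
    pair_weight(v[i + 1L], s[i], spec, config$weight_scheme)
  }, numeric(1))
  mirror <- spec$direction == "increase_good"
  (if (mirror) -d else d) * w
}

#' Weighted trend score of one sliding window
#'
#' The window score is the sum of signed weighted pair contributions over the
#' m - 1 consecutive pairs inside the window ending at sample \code{k}.  A
#' negative score signals local improvement (survival), a non-negative score
#' local worsening (collapse).  For \code{increase_good} biomarkers the delta
#' contributions are sign-flipped so this reading holds panel-wide.
#'
#' @param series A \code{\link{biomarker_series}} (typically oversampled).
#' @param k Window end index; the window spans samples k - m + 1 .. k.
#' @param spec A \code{\link{biomarker_spec}}.
#' @param config An \code{\link{inclination_config}}.
#' @return The score Xs for the window.
#' @export
window_score <- function(series, k, spec, config) {
  m <- config$m
  k <- as.integer(k)
  if (k < m || k > length(series$value)) {
    stop("window [k - m + 1, k] must lie inside the series", call. = FALSE)
  }
  contrib <- pair_contributions(series, spec, config)
  sum(contrib[(k - m + 1L):(k - 1L)])
}

#' Local-state series of a biomarker trajectory
#'
#' Slides a window of m samples along the (oversampled) series and converts
#' each window score to a binary local state: survival when the score is
#' negative, collapse otherwise (a zero score, e.g. a flat window, counts as
#' collapse).  Nine samples yield 7 states at m = 3 and 6 at m = 4.
#'
#' @inheritParams window_score
#' @return An integer vector of 0 (survival) / 1 (collapse) of length
#'   \code{length(series) - m + 1}, with attribute \code{"window_end"} giving
#'   the sample index each state refers to.
#' @export
local_states <- function(series, spec, config) {
  m <- config$m
  n <- length(series$value)
  if (m < 2L) stop("local states need m >= 2", call. = FALSE)
  if (n < m) stop("series shorter than the window length", call. = FALSE)
  contrib <- pair_contributions(series, spec, config)
  cs <- c(0, cumsum(contrib))
  ks <- m:n
  xs <- cs[ks] - cs[ks - m + 1L]
  st <- as.integer(xs >= 0)
  attr(st, "window_end") <- ks
  attr(st, "scores") <- xs
  st
}
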