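# Synthetic EMR-like trajectory generator.  Emulates the structure of a
# primary-care extract: >= 5 readings per biomarker at irregular intervals,
# linear clinical drift plus measurement noise, values kept inside each
# biomarker's observable [min, max] range.

# irregular sampling times in integer days: gamma-distributed gaps with the
# requested mean and jitter (sd), at least one day apart
draw_times <- function(n_readings, mean_gap_days, gap_jitter) {
  if (gap_jitter <= 0) {
    gaps <- rep(mean_gap_days, n_readings - 1L)
  } else {
    shape <- (mean_gap_days / gap_jitter)^2
    gaps <- stats::rgamma(n_readings - 1L, shape = shape,
                          rate = shape / mean_gap_days)
  }
  cumsum(c(0, pmax(1, round(gaps))))
}

#' Simulate one biomarker series with known ground truth
#'
#' Values follow a linear drift expressed as a signed fraction of the
#' biomarker's (high - low) threshold range per year, plus Gaussian noise of
#' standard deviation \code{noise_sd} times that range, sampled at irregular
#' integer-day intervals and clamped to the observable [min, max] range.
#' The ground-truth final state derives from the noiseless trajectory: a
#' drift in the clinically worsening direction (up for
#' \code{decrease_good} biomarkers, down for \code{increase_good}) is a
#' collapse, the opposite drift a survival, and a flat trajectory is labeled
#' by which side of the normality threshold it sits on.
#'
#' @param spec A \code{\link{biomarker_spec}}.
#' @param n_readings Number of readings (>= 5 for eligibility downstream).
#' @param drift_per_year Signed drift in (high - low) fractions per year.
#' @param noise_sd Noise standard deviation in (high - low) fractions.
#' @param start_quantile Position of the trajectory within [low, high] at the
#'   anchor point, as a fraction; \code{NULL} picks 0.2 for upward drifts,
#'   0.8 for downward, 0.5 for flat, so trajectories start on the side they
#'   move away from.
#' @param anchor Where \code{start_quantile} anchors the trajectory: at the
#'   first reading (\code{"start"}) or at the mean sampling time
#'   (\code{"middle"}), where the noiseless per-series average equals the
#'   anchor value regardless of drift -- useful for building cohorts whose
#'   series averages carry no trajectory signal.
#' @param mean_gap_days,gap_jitter Mean and standard deviation of the
#'   sampling gaps, in days.
#' @param time Optional explicit timestamps (days, strictly increasing);
#'   overrides the gap model and \code{n_readings}.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with \code{series} (a \code{\link{biomarker_series}}) and
#'   \code{truth} ("collapse"/"survival").
#' @examples
#' sbp <- default_panel()$sBP
#' sim <- simulate_series(sbp, drift_per_year = 0.4, noise_sd = 0.05,
#'                        seed = 42)
#' sim$truth
#' @export
simulate_series <- function(spec, n_readings = 5L, drift_per_year = 0,
                            noise_sd = 0, start_quantile = NULL,
                            anchor = c("start", "middle"),
                            mean_gap_days = 120, gap_jitter = 60,
                            time = NULL, seed = NULL) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(spec, "biomarker_spec"), n_readings >= 2,
            noise_sd >= 0, mean_gap_days > 0)
  if (!is.null(seed)) set.seed(seed)
  rng <- spec$high_thr - spec$low_thr
  if (is.null(start_quantile)) {
    start_quantile <- if (drift_per_year > 0) 0.2
                      else if (drift_per_year < 0) 0.8 else 0.5
  }
  if (is.null(time)) {
    time <- draw_times(n_readings, mean_gap_days, gap_jitter)
  } else {
    n_readings <- length(time)
  }
  t_anchor <- if (anchor == "middle") mean(time) else 0
  anchor_value <- spec$low_thr + start_quantile * rng
  clean <- anchor_value + drift_per_year * rng * (time - t_anchor) / 365.25
  noisy <- clean + stats::rnorm(n_readings, 0, noise_sd * rng)
  noisy <- pmin(spec$max_val, pmax(spec$min_val, noisy))
  worsening <- if (spec$direction == "decrease_good") drift_per_year > 0
               else drift_per_year < 0
  improving <- if (spec$direction == "decrease_good") drift_per_year < 0
               else drift_per_year > 0
  truth <- if (worsening) {
    "collapse"
  } else if (improving) {
    "survival"
  } else {
    bad_side <- if (spec$direction == "decrease_good") {
      anchor_value > spec$normality_thr
    } else {
      anchor_value < spec$normality_thr
    }
    if (bad_side) "collapse" else "survival"
  }
  list(series = biomarker_series(spec$name, time, noisy), truth = truth)
}

# drift (fractions/year) that moves a trajectory `movement` quantiles in the
# worsening (target "collapse") or improving direction over `span_days`
target_drift <- function(spec, target, movement, span_days) {
  worsen_sign <- if (spec$direction == "decrease_good") 1 else -1
  sgn <- if (target == "collapse") worsen_sign else -worsen_sign
  sgn * movement / (span_days / 365.25)
}

# start quantile on the side a moving trajectory departs from
departure_quantile <- function(spec, target) {
  worsen_up <- spec$direction == "decrease_good"
  going_up <- (target == "collapse") == worsen_up
  if (going_up) stats::runif(1, 0.08, 0.20) else stats::runif(1, 0.80, 0.92)
}

#' Simulate a labeled cohort with planted group patterns
#'
#' Generates \code{n_cases + n_controls} patients with all nine panel
#' biomarkers.  For biomarkers in the reference pattern, a case's trajectory
#' drifts in the pattern direction with probability 0.5 + effect/2 and a
#' control's with probability 0.5 - effect/2; off-pattern biomarkers drift
#' at random.  Trajectories are anchored at their mean sampling time near
#' the middle of the acceptable range, so per-series average values carry
#' little group signal while drift directions carry all of it.
#'
#' @param n_cases,n_controls Group sizes.
#' @param pattern A \code{\link{reference_pattern}}-style named vector.
#' @param effect Collapse-probability gap between groups, in [0, 1].
#' @param noise_sd Measurement noise in (high - low) fractions.
#' @param panel Biomarker panel.
#' @param seed Integer seed.
#' @return A \code{\link{cohort}}.
#' @export
simulate_cohort <- function(n_cases, n_controls,
                            pattern = reference_pattern(), effect = 0.3,
                            noise_sd = 0.1, panel = default_panel(),
                            seed = 1L) {
  stopifnot(effect >= 0, effect <= 1)
  set.seed(seed)
  make_patient <- function(id, label) {
    p_match <- if (label == "case") 0.5 + effect / 2 else 0.5 - effect / 2
    series <- lapply(names(panel), function(bm) {
      spec <- panel[[bm]]
      target <- if (bm %in% names(pattern)) {
        expected <- pattern[[bm]]
        opposite <- if (expected == "collapse") "survival" else "collapse"
        if (stats::runif(1) < p_match) expected else opposite
      } else {
        sample(c("collapse", "survival"), 1L)
      }
      n_readings <- sample(5:7, 1L)
      time <- draw_times(n_readings, 120, 60)
      movement <- stats::runif(1, 0.5, 0.85)
      drift <- target_drift(spec, target, movement, max(time))
      sim <- simulate_series(spec, drift_per_year = drift,
                             noise_sd = noise_sd,
                             start_quantile = stats::runif(1, 0.40, 0.60),
                             anchor = "middle", time = time)
      sim$series
    })
    names(series) <- names(panel)
    patient_record(id, label, series)
  }
  cases <- lapply(seq_len(n_cases), function(i) {
    make_patient(sprintf("case_%04d", i), "case")
  })
  controls <- lapply(seq_len(n_controls), function(i) {
    make_patient(sprintf("ctrl_%04d", i), "control")
  })
  cohort(c(cases, controls))
}

# quantile of the normality threshold within [low, high]
normality_quantile <- function(spec) {
  (spec$normality_thr - spec$low_thr) / (spec$high_thr - spec$low_thr)
}

#' Simulate a labeled validation set of biomarker series
#'
#' A synthetic stand-in for an expert-labeled evaluation set: for each of
#' \code{n_patients} patients all nine panel biomarkers are generated with a
#' known final state, balanced between collapse and survival within each
#' biomarker.  Two clinically motivated trajectory archetypes alternate,
#' reflecting how experts label a trend (values outside the desired range,
#' or moving towards clinical worsening):
#' \itemize{
#'   \item \emph{trending} -- a steep drift across a large fraction of the
#'     acceptable range, departing from the side it moves away from;
#'   \item \emph{stationary-at-position} -- a mild drift of a series seated
#'     on the matching side of the normality threshold (bad side for
#'     collapse, good side for survival).
#' }
#' In both archetypes the ground truth is the drift direction, so at zero
#' noise the truth is unambiguous and recoverable.
#'
#' @param n_patients Number of patients (>= 2; even counts balance exactly).
#' @param noise_sd Measurement noise in (high - low) fractions.
#' @param panel Biomarker panel.
#' @param seed Integer seed.
#' @return A list of entries \code{list(patient_id, series, spec, truth)},
#'   usable with \code{\link{version_performance}}.
#' @export
labeled_validation_set <- function(n_patients = 40L, noise_sd = 0,
                                   panel = default_panel(), seed = 1L) {
  stopifnot(n_patients >= 2)
  set.seed(seed)
  entries <- list()
  for (i in seq_len(n_patients)) {
    archetype <- if (i %% 2L == 0L) "stationary" else "trending"
    for (b in seq_along(panel)) {
      spec <- panel[[b]]
      truth <- if ((i + b) %% 2L == 0L) "collapse" else "survival"
      n_readings <- sample(5:7, 1L)
      time <- draw_times(n_readings, 120, 60)
      if (archetype == "trending") {
        start_q <- departure_quantile(spec, truth)
        movement <- stats::runif(1, 0.5, 0.85)
      } else {
        # seated on the truth-matching side of the normality threshold,
        # drifting mildly in the truth direction
        offset <- stats::runif(1, 0.15, 0.30)
        bad_up <- spec$direction == "decrease_good"
        towards_bad <- (truth == "collapse") == bad_up
        start_q <- normality_quantile(spec) +
          if (towards_bad) offset else -offset
        movement <- stats::runif(1, 0.05, 0.15)
      }
      drift <- target_drift(spec, truth, movement, max(time))
      sim <- simulate_series(spec, drift_per_year = drift,
                             noise_sd = noise_sd, start_quantile = start_q,
                             anchor = "start", time = time)
      entries[[length(entries) + 1L]] <- list(
        patient_id = sprintf("val_%03d", i), series = sim$series,
        spec = spec, truth = truth)
    }
  }
  entries
}
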