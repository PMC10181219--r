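# --- state-sequence encoding -------------------------------------------------
# A length-m sequence of local states is encoded as a binary integer with
# collapse = 1, survival = 0, the OLDEST state in the most significant
# position.  R indices are the integer + 1, so index 1 is all-survival and
# index 2^m is all-collapse.

sequence_bits <- function(index0, m) {
  floor(index0 / 2^((m - 1L):0L)) %% 2L
}

sequence_label <- function(index0, m) {
  paste(ifelse(sequence_bits(index0, m) == 1L, "-", "+"), collapse = "")
}

all_sequence_labels <- function(m) {
  vapply(0:(2^m - 1L), sequence_label, character(1), m = m)
}

#' Transition model over local-state sequences
#'
#' Builds the 2^m x 2^m row-stochastic transition matrix Z over length-m
#' binary state sequences, and its limiting matrix.  A source sequence s with
#' n- collapse states and n+ survival states moves to the shifted sequence
#' obtained by dropping its oldest state and appending a new one: collapse
#' with probability 1 when n- >= m_minus, survival with probability 1 when
#' n+ >= m_plus, and collapse/survival with probability r_minus / 1 - r_minus
#' otherwise.  With both critical levels equal to m, only the all-collapse
#' and all-survival sequences are absorbing and the limiting matrix carries
#' the absorption probabilities.
#'
#' @param config An \code{\link{inclination_config}}.
#' @return An object of class \code{"transition_model"} with elements
#'   \code{m}, \code{labels}, \code{Z}, and \code{Z_inf}
#'   (\code{Z} raised to \code{config$power_iterations}).
#' @examples
#' tm <- transition_model(inclination_config(version = NULL, m = 2,
#'   delta_scheme = "sign", weight_scheme = "constant_one"))
#' round(tm$Z_inf, 3)
#' @export
transition_model <- function(config = inclination_config(7L)) {
  stopifnot(inherits(config, "inclination_config"))
  m <- config$m
  n <- 2L^m
  Z <- matrix(0, n, n, dimnames = list(all_sequence_labels(m),
                                       all_sequence_labels(m)))
  half <- 2L^(m - 1L)
  for (idx in 0:(n - 1L)) {
    n_minus <- sum(sequence_bits(idx, m))
    n_plus <- m - n_minus
    force_minus <- n_minus >= config$m_minus
    force_plus <- n_plus >= config$m_plus
    if (force_minus && force_plus) {
      stop("critical levels conflict: a sequence satisfies both conditions",
           call. = FALSE)
    }
    p_minus <- if (force_minus) 1 else if (force_plus) 0 else config$r_minus
    shifted <- (idx %% half) * 2L
    Z[idx + 1L, shifted + 2L] <- Z[idx + 1L, shifted + 2L] + p_minus
    Z[idx + 1L, shifted + 1L] <- Z[idx + 1L, shifted + 1L] + (1 - p_minus)
  }
  structure(list(m = m, labels = all_sequence_labels(m), Z = Z,
                 Z_inf = limiting_matrix(Z, config$power_iterations)),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  absorbing <- sum(diag(x$Z) == 1)
  cat(sprintf("<transition_model> m = %d: %d sequences (%d absorbing, %d unstable)\n",
              x$m, 2^x$m, absorbing, 2^x$m - absorbing))
  invisible(x)
}

#' Limiting matrix by repeated squaring
#'
#' Raises a row-stochastic matrix to the l-th power via binary
#' exponentiation, approximating the limiting (absorption-probability)
#' matrix for large l.
#'
#' @param Z A square row-stochastic matrix.
#' @param l Non-negative integer power (default 10000).
#' @return \code{Z^l}, row-stochastic up to floating error.
#' @export
limiting_matrix <- function(Z, l = 10000L) {
  stopifnot(is.matrix(Z), nrow(Z) == ncol(Z), l >= 0)
  out <- diag(nrow(Z))
  dimnames(out) <- dimnames(Z)
  base <- Z
  l <- as.integer(l)
  while (l > 0L) {
    if (l %% 2L == 1L) out <- out %*% base
    base <- base %*% base
    l <- l %/% 2L
  }
  out
}

#' Empirical distribution of state sequences
#'
#' Relative frequencies of the overlapping (shift-1) length-m subsequences of
#' a local-state series over all 2^m possible sequences.
#'
#' @param states Integer 0/1 vector of local states (1 = collapse).
#' @param m Sequence length.
#' @return A probability vector of length 2^m summing to 1, named by
#'   sequence label (oldest state first, \code{-} = collapse).
#' @export
sequence_distribution <- function(states, m) {
  states <- as.integer(states)
  L <- length(states)
  m <- as.integer(m)
  if (L < m) stop("local-state series shorter than the sequence length",
                  call. = FALSE)
  weights <- 2^((m - 1L):0L)
  idx <- vapply(1:(L - m + 1L), function(j) {
    sum(states[j:(j + m - 1L)] * weights)
  }, numeric(1))
  q <- tabulate(idx + 1L, nbins = 2L^m) / (L - m + 1L)
  names(q) <- all_sequence_labels(m)
  q
}

#' Final-state probability under the limiting matrix
#'
#' Propagates a distribution over state sequences through the limiting
#' matrix and returns the probability mass landing on a target sequence.
#' Passing the uniform distribution yields the prior probability used as the
#' baseline of the inclination index.
#'
#' @param Z_inf Limiting matrix (rows = source sequences).
#' @param dist Probability vector over the source sequences (sums to 1).
#' @param target Target sequence index (1-based) or label; defaults to the
#'   all-collapse sequence.
#' @return A single probability.
#' @export
final_state_probability <- function(Z_inf, dist, target = nrow(Z_inf)) {
  if (length(dist) != nrow(Z_inf)) {
    stop("distribution length must match the number of sequences",
         call. = FALSE)
  }
  if (abs(sum(dist) - 1) > 1e-8) {
    stop("dist must sum to 1", call. = FALSE)
  }
  p <- as.numeric(crossprod(Z_inf, dist))
  if (is.character(target)) target <- match(target, colnames(Z_inf))
  p[target]
}

#' Decision rule on the inclination index
#'
#' Predicts collapse when the index exceeds 1 + delta_band and survival when
#' it falls below 1 - delta_band.  Inside the band no clear inclination
#' exists and a tie-break compares the share of collapse states in the first
#' and second half of the local-state series (middle state excluded for odd
#' lengths): a higher share in the second half predicts collapse, otherwise
#' survival.
#'
#' @param index The inclination index I.
#' @param states Integer 0/1 local-state series (1 = collapse).
#' @param delta_band Band half-width (default 0.1).
#' @return A list with \code{decision} ("collapse"/"survival") and
#'   \code{tie_break_used}.
#' @export
decide_final_state <- function(index, states, delta_band = 0.1) {
  if (index > 1 + delta_band) {
    return(list(decision = "collapse", tie_break_used = FALSE))
  }
  if (index < 1 - delta_band) {
    return(list(decision = "survival", tie_break_used = FALSE))
  }
  L <- length(states)
  h <- L %/% 2L
  if (h < 1L) stop("tie-break needs at least two local states", call. = FALSE)
  first <- mean(states[1:h] == 1L)
  second <- mean(states[(L - h + 1L):L] == 1L)
  list(decision = if (second > first) "collapse" else "survival",
       tie_break_used = TRUE)
}

#' Fit an inclination analysis to one biomarker series
#'
#' The full pipeline for a single patient-biomarker trajectory: eligibility
#' check, midpoint oversampling, local-state extraction under the configured
#' scoring variant, empirical sequence distribution, propagation through the
#' absorbing transition model, and the banded decision on the inclination
#' index I = Pc- / P- (the probability of the all-collapse final sequence
#' under the observed vs. the uniform prior distribution; I ranges from 0 to
#' 2 when \code{r_minus} is 0.5).
#'
#' @param series A \code{\link{biomarker_series}} of original readings.
#' @param spec The matching \code{\link{biomarker_spec}}.
#' @param config An \code{\link{inclination_config}} (default variant 7, the
#'   best-performing preset).
#' @param model Optional pre-built \code{\link{transition_model}} for
#'   \code{config}; pass one when analysing many series to avoid rebuilding.
#' @param min_readings Eligibility threshold on original readings.
#' @return An object of class \code{"inclination"} with the oversampled
#'   series, local states, sequence distribution \code{q_c}, probabilities
#'   \code{P_c_minus} and \code{P_minus}, \code{index}, \code{decision}, and
#'   \code{tie_break_used}.
#' @examples
#' sbp <- default_panel()$sBP
#' s <- biomarker_series("sBP", c(0, 90, 200, 290, 400),
#'                       c(128, 135, 141, 150, 158))
#' fit <- inclination(s, sbp)
#' fit
#' coef(fit)
#' @export
inclination <- function(series, spec, config = inclination_config(7L),
                        model = NULL, min_readings = 5L) {
  stopifnot(inherits(series, "biomarker_series"),
            inherits(spec, "biomarker_spec"),
            inherits(config, "inclination_config"))
  if (!check_eligibility(series, min_readings)) {
    stop(sprintf("series has %d readings; at least %d required",
                 length(series$value), min_readings), call. = FALSE)
  }
  if (is.null(model)) model <- transition_model(config)
  stopifnot(model$m == config$m)
  os <- oversample(series)
  states <- local_states(os, spec, config)
  q_c <- sequence_distribution(states, config$m)
  n_seq <- 2L^config$m
  uniform <- rep(1 / n_seq, n_seq)
  p_c_minus <- final_state_probability(model$Z_inf, q_c, n_seq)
  p_minus <- final_state_probability(model$Z_inf, uniform, n_seq)
  index <- p_c_minus / p_minus
  dec <- decide_final_state(index, states, config$delta_band)
  structure(
    list(series = series, oversampled = os, spec = spec, config = config,
         states = states, q_c = q_c, P_c_minus = p_c_minus,
         P_minus = p_minus, index = index, decision = dec$decision,
         tie_break_used = dec$tie_break_used),
    class = "inclination"
  )
}

#' @export
print.inclination <- function(x, ...) {
  cat(sprintf("<inclination> %s (variant %s): %s\n",
              x$spec$name,
              ifelse(is.na(x$config$version), "custom", x$config$version),
              x$decision))
  cat(sprintf("  index I = %.3f (Pc- = %.3f, P- = %.3f)%s\n",
              x$index, x$P_c_minus, x$P_minus,
              if (x$tie_break_used) ", decided by half-series tie-break" else ""))
  invisible(x)
}

#' @export
coef.inclination <- function(object, ...) {
  c(P_c_minus = object$P_c_minus, P_minus = object$P_minus,
    index = object$index)
}

#' @export
summary.inclination <- function(object, ...) {
  structure(object, class = c("summary.inclination", "inclination"))
}

#' @export
print.summary.inclination <- function(x, ...) {
  print.inclination(x)
  cat(sprintf("  readings: %d original -> %d oversampled -> %d local states\n",
              length(x$series$value), length(x$oversampled$value),
              length(x$states)))
  cat("  local states: ",
      paste(ifelse(x$states == 1L, "-", "+"), collapse = ""), "\n", sep = "")
  nz <- x$q_c[x$q_c > 0]
  cat("  observed sequence distribution:\n")
  for (lab in names(nz)) cat(sprintf("    %s  %.3f\n", lab, nz[[lab]]))
  invisible(x)
}
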