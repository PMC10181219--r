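#' Construct a patient record
#'
#' @param patient_id Identifier.
#' @param label \code{"case"} (develops the disease) or \code{"control"}.
#' @param series A named list of \code{\link{biomarker_series}}, one per
#'   panel biomarker.
#' @param onset_date Optional onset \code{Date} (cases only).
#' @return An object of class \code{"patient_record"}.
#' @export
patient_record <- function(patient_id, label = c("control", "case"),
                           series, onset_date = NULL) {
  label <- match.arg(label)
  stopifnot(is.list(series), length(series) > 0,
            all(vapply(series, inherits, logical(1), "biomarker_series")))
  if (is.null(names(series)) || any(names(series) == "")) {
    stop("series must be a named list keyed by biomarker", call. = FALSE)
  }
  structure(list(patient_id = as.character(patient_id), label = label,
                 onset_date = onset_date, series = series),
            class = "patient_record")
}

#' Construct a cohort
#'
#' @param patients A list of \code{\link{patient_record}} objects.
#' @return An object of class \code{"cohort"}.
#' @export
cohort <- function(patients = list()) {
  stopifnot(all(vapply(patients, inherits, logical(1), "patient_record")))
  structure(patients, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  labs <- vapply(unclass(x), `[[`, character(1), "label")
  cat(sprintf("<cohort> %d patients (%d cases, %d controls)\n",
              length(x), sum(labs == "case"), sum(labs == "control")))
  invisible(x)
}

#' Apply inclination analysis across a cohort
#'
#' Runs \code{\link{inclination}} on every (patient, biomarker) series under
#' one configuration, reusing a single transition model.  Ineligible series
#' are skipped with a warning, or abort in strict mode.
#'
#' @param x A \code{\link{cohort}}.
#' @param config An \code{\link{inclination_config}}.
#' @param panel A biomarker panel (defaults to \code{\link{default_panel}}).
#' @param min_readings Eligibility threshold.
#' @param strict Error (rather than warn and skip) on ineligible series.
#' @return A data frame with one row per (patient, biomarker): columns
#'   \code{patient_id}, \code{label}, \code{biomarker}, \code{decision},
#'   \code{index}, \code{P_c_minus}, \code{tie_break_used}.
#' @export
predict_cohort <- function(x, config = inclination_config(7L),
                           panel = default_panel(), min_readings = 5L,
                           strict = FALSE) {
  stopifnot(inherits(x, "cohort"))
  model <- transition_model(config)
  rows <- list()
  skipped <- 0L
  for (p in unclass(x)) {
    for (bm in names(p$series)) {
      if (!bm %in% names(panel)) {
        stop(sprintf("biomarker '%s' not in panel (valid: %s)", bm,
                     paste(names(panel), collapse = ", ")), call. = FALSE)
      }
      s <- p$series[[bm]]
      if (!check_eligibility(s, min_readings)) {
        if (strict) {
          stop(sprintf("patient %s, %s: only %d readings", p$patient_id, bm,
                       length(s$value)), call. = FALSE)
        }
        skipped <- skipped + 1L
        next
      }
      fit <- inclination(s, panel[[bm]], config, model = model,
                         min_readings = min_readings)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p$patient_id, label = p$label, biomarker = bm,
        decision = fit$decision, index = fit$index,
        P_c_minus = fit$P_c_minus, tie_break_used = fit$tie_break_used,
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L) {
    warning(sprintf("skipped %d ineligible series", skipped), call. = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(patient_id = character(), label = character(),
                      biomarker = character(), decision = character(),
                      index = numeric(), P_c_minus = numeric(),
                      tie_break_used = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Per-biomarker collapse rates by group
#'
#' Fraction of patients with a predicted collapse in each group for every
#' biomarker, with a 2x2 chi-square test of the group difference.
#'
#' @param predictions A prediction table from \code{\link{predict_cohort}};
#'   it must carry a \code{label} column, or \code{labels} must map
#'   patient_id to label.
#' @param labels Optional named character vector patient_id -> label.
#' @return A data frame with columns \code{biomarker}, \code{rate_case},
#'   \code{rate_control}, \code{p_value} (NA when the table is degenerate),
#'   in panel row order of appearance.
#' @export
collapse_rate_table <- function(predictions, labels = NULL) {
  pred <- predictions
  if (!is.null(labels)) pred$label <- unname(labels[pred$patient_id])
  if (is.null(pred$label) || any(is.na(pred$label))) {
    stop("every prediction needs a case/control label", call. = FALSE)
  }
  bms <- unique(pred$biomarker)
  out <- lapply(bms, function(bm) {
    sub <- pred[pred$biomarker == bm, ]
    collapsed <- sub$decision == "collapse"
    case <- sub$label == "case"
    if (!any(case) || !any(!case)) {
      stop("both groups must be represented", call. = FALSE)
    }
    tab <- table(factor(sub$label, levels = c("case", "control")),
                 factor(collapsed, levels = c(FALSE, TRUE)))
    p <- tryCatch(
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value),
      error = function(e) NA_real_)
    data.frame(biomarker = bm,
               rate_case = mean(collapsed[case]),
               rate_control = mean(collapsed[!case]),
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Case-group reference pattern
#'
#' The expected direction of each biomarker for patients heading towards the
#' disease, restricted to the biomarkers whose group difference is
#' informative: collapse for BMI, sBP, fasting glucose, HbA1c and HDL;
#' survival for LDL and total cholesterol (lipid-lowering treatment makes
#' those improve in cases).  Used by the similarity score.
#'
#' @return A named character vector biomarker -> "collapse"/"survival".
#' @export
reference_pattern <- function() {
  c(BMI = "collapse", sBP = "collapse", fasting_glucose = "collapse",
    HbA1c = "collapse", HDL = "collapse",
    LDL = "survival", total_cholesterol = "survival")
}

#' Similarity score of one patient against a reference pattern
#'
#' Counts how many of the patient's predicted biomarker states match the
#' case-typical pattern; ranges from 0 (all opposite) to the pattern size
#' (default 7).
#'
#' @param decisions Named character vector biomarker -> decision for one
#'   patient (must cover all pattern biomarkers).
#' @param pattern A reference pattern (default \code{\link{reference_pattern}}).
#' @return An integer score.
#' @export
similarity_score <- function(decisions, pattern = reference_pattern()) {
  missing <- setdiff(names(pattern), names(decisions))
  if (length(missing) > 0) {
    stop("missing decisions for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sum(decisions[names(pattern)] == pattern)
}

#' Similarity scores for a whole prediction table
#'
#' @param predictions A table from \code{\link{predict_cohort}}.
#' @param pattern A reference pattern.
#' @return A data frame with columns \code{patient_id}, \code{label} (if
#'   present), \code{score}.
#' @export
similarity_scores <- function(predictions, pattern = reference_pattern()) {
  ids <- unique(predictions$patient_id)
  scores <- vapply(ids, function(id) {
    sub <- predictions[predictions$patient_id == id, ]
    dec <- stats::setNames(sub$decision, sub$biomarker)
    similarity_score(dec, pattern)
  }, numeric(1))
  out <- data.frame(patient_id = ids, score = as.integer(scores),
                    stringsAsFactors = FALSE)
  if (!is.null(predictions$label)) {
    out$label <- predictions$label[match(ids, predictions$patient_id)]
  }
  out
}

binary_metrics <- function(truth_pos, pred_pos) {
  tp <- sum(truth_pos & pred_pos); tn <- sum(!truth_pos & !pred_pos)
  fp <- sum(!truth_pos & pred_pos); fn <- sum(truth_pos & !pred_pos)
  c(accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Performance of one scoring variant on a labeled series set
#'
#' Runs inclination analysis on a set of series with known final states,
#' computes accuracy, sensitivity, specificity and PPV per biomarker
#' (collapse is the positive class) and averages them, unweighted, across
#' biomarkers.  A biomarker with no labeled collapse truths has undefined
#' sensitivity and is dropped from that average with a warning.
#'
#' @param labeled A list of entries, each a list with elements \code{series}
#'   (\code{\link{biomarker_series}}), \code{spec}
#'   (\code{\link{biomarker_spec}}) and \code{truth}
#'   ("collapse"/"survival"); as produced by
#'   \code{\link{labeled_validation_set}}.
#' @param config An \code{\link{inclination_config}}.
#' @return A list with \code{per_biomarker} (data frame) and \code{overall}
#'   (named vector of the four biomarker-averaged metrics).
#' @export
version_performance <- function(labeled, config = inclination_config(7L)) {
  stopifnot(length(labeled) > 0)
  model <- transition_model(config)
  bm <- vapply(labeled, function(e) e$spec$name, character(1))
  truth <- vapply(labeled, `[[`, character(1), "truth")
  pred <- vapply(labeled, function(e) {
    inclination(e$series, e$spec, config, model = model)$decision
  }, character(1))
  per <- lapply(unique(bm), function(b) {
    sel <- bm == b
    met <- binary_metrics(truth[sel] == "collapse", pred[sel] == "collapse")
    data.frame(biomarker = b, accuracy = met["accuracy"],
               sensitivity = met["sensitivity"],
               specificity = met["specificity"], ppv = met["ppv"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  if (anyNA(per$sensitivity)) {
    warning("biomarkers without labeled positives excluded from the sensitivity average",
            call. = FALSE)
  }
  overall <- c(accuracy = mean(per$accuracy, na.rm = TRUE),
               sensitivity = mean(per$sensitivity, na.rm = TRUE),
               specificity = mean(per$specificity, na.rm = TRUE),
               ppv = mean(per$ppv, na.rm = TRUE))
  list(per_biomarker = per, overall = overall)
}
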