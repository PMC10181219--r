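#' Read a cohort from long-format CSV files
#'
#' \code{measurements_path} must hold columns
#' \code{patient_id,biomarker,date,value} (ISO-8601 dates) and
#' \code{labels_path} columns \code{patient_id,label,onset_date} with label
#' \code{case}/\code{control}.  Rows are sorted by date per series; for
#' cases, readings on or after \code{onset_date - lead_days} are dropped
#' before any analysis, so only measurements up to the lead window before
#' onset inform the prediction.  Patients missing any panel biomarker or
#' with fewer than \code{min_readings} readings for one are excluded with a
#' warning (or abort in strict mode).
#'
#' @param measurements_path,labels_path CSV paths.
#' @param panel Biomarker panel the \code{biomarker} column must match.
#' @param lead_days Exclusion window before onset, in days (default 365).
#' @param min_readings Eligibility threshold per biomarker.
#' @param strict Error instead of excluding ineligible patients.
#' @return A \code{\link{cohort}}; patient series timestamps are days since
#'   the earliest measurement date in the file.
#' @export
read_cohort <- function(measurements_path, labels_path,
                        panel = default_panel(), lead_days = 365,
                        min_readings = 5L, strict = FALSE) {
  meas <- utils::read.csv(measurements_path, stringsAsFactors = FALSE)
  labs <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  needed <- c("patient_id", "biomarker", "date", "value")
  if (!all(needed %in% names(meas))) {
    stop("measurements file needs columns ", paste(needed, collapse = ","),
         call. = FALSE)
  }
  if (!all(c("patient_id", "label") %in% names(labs))) {
    stop("labels file needs columns patient_id,label,onset_date",
         call. = FALSE)
  }
  unknown <- setdiff(unique(meas$biomarker), names(panel))
  if (length(unknown) > 0) {
    stop("unknown biomarker(s): ", paste(unknown, collapse = ", "),
         "; valid names: ", paste(names(panel), collapse = ", "),
         call. = FALSE)
  }
  dates <- as.Date(meas$date)
  bad <- which(is.na(dates) | !is.finite(meas$value))
  if (length(bad) > 0) {
    stop("unparseable date or value at measurement row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  origin <- min(dates)
  meas$day <- as.numeric(dates - origin)
  labs$onset <- if ("onset_date" %in% names(labs)) {
    as.numeric(as.Date(labs$onset_date) - origin)
  } else {
    NA_real_
  }
  patients <- list()
  n_excluded <- 0L
  for (r in seq_len(nrow(labs))) {
    id <- as.character(labs$patient_id[r])
    label <- labs$label[r]
    if (!label %in% c("case", "control")) {
      stop(sprintf("patient %s: label must be case/control", id),
           call. = FALSE)
    }
    rows <- meas[as.character(meas$patient_id) == id, ]
    if (label == "case" && !is.na(labs$onset[r])) {
      rows <- rows[rows$day < labs$onset[r] - lead_days, ]
    }
    eligible <- TRUE
    series <- list()
    for (bm in names(panel)) {
      sub <- rows[rows$biomarker == bm, ]
      sub <- sub[order(sub$day), ]
      if (nrow(sub) < min_readings) {
        eligible <- FALSE
        break
      }
      series[[bm]] <- biomarker_series(bm, sub$day, sub$value)
    }
    if (!eligible) {
      if (strict) {
        stop(sprintf("patient %s ineligible: fewer than %d readings for %s",
                     id, min_readings, bm), call. = FALSE)
      }
      n_excluded <- n_excluded + 1L
      next
    }
    onset_date <- if (label == "case" && !is.na(labs$onset[r])) {
      origin + labs$onset[r]
    } else {
      NULL
    }
    patients[[length(patients) + 1L]] <-
      patient_record(id, label, series, onset_date = onset_date)
  }
  if (n_excluded > 0L) {
    warning(sprintf("excluded %d ineligible patient(s)", n_excluded),
            call. = FALSE)
  }
  attr_cohort <- cohort(patients)
  attr(attr_cohort, "origin") <- origin
  attr_cohort
}

#' Write a cohort to long-format CSV files
#'
#' Inverse of \code{\link{read_cohort}}: emits a measurements CSV
#' (\code{patient_id,biomarker,date,value}) and a labels CSV
#' (\code{patient_id,label,onset_date}), with deterministic row order
#' (patients in cohort order, biomarkers in panel order, dates ascending).
#' Timestamps are converted back to ISO-8601 dates from \code{origin}.
#'
#' @param x A \code{\link{cohort}}.
#' @param measurements_path,labels_path Output CSV paths.
#' @param origin Date corresponding to day 0 (default the cohort's
#'   \code{"origin"} attribute, else 2005-01-01).
#' @return Invisibly, the measurement data frame.
#' @export
write_cohort <- function(x, measurements_path, labels_path,
                         origin = NULL) {
  stopifnot(inherits(x, "cohort"))
  if (is.null(origin)) {
    origin <- attr(x, "origin")
    if (is.null(origin)) origin <- as.Date("2005-01-01")
  }
  rows <- list()
  labs <- list()
  for (p in unclass(x)) {
    for (bm in names(p$series)) {
      s <- p$series[[bm]]
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = p$patient_id, biomarker = bm,
        date = format(origin + s$time), value = s$value,
        stringsAsFactors = FALSE)
    }
    labs[[length(labs) + 1L]] <- data.frame(
      patient_id = p$patient_id, label = p$label,
      onset_date = if (is.null(p$onset_date)) "" else format(p$onset_date),
      stringsAsFactors = FALSE)
  }
  meas <- do.call(rbind, rows)
  utils::write.csv(meas, measurements_path, row.names = FALSE)
  utils::write.csv(do.call(rbind, labs), labels_path, row.names = FALSE)
  invisible(meas)
}
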