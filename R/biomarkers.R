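#' Construct a biomarker specification
#'
#' A biomarker specification holds the clinical cut-off profile used by the
#' threshold-aware scoring schemes: the lowest and highest observable values
#' (\code{min_val}, \code{max_val}), the low and high thresholds bounding the
#' clinically acceptable range, the normality threshold separating desirable
#' from undesirable values, and the improvement direction.
#'
#' For most routine biomarkers (blood pressure, glucose, cholesterol, ...)
#' lower is better (\code{direction = "decrease_good"}); HDL is the one
#' default-panel biomarker for which higher is better
#' (\code{direction = "increase_good"}).
#'
#' @param name Biomarker identifier.
#' @param unit Unit label (informational only; no conversion is performed).
#' @param min_val,low_thr,normality_thr,high_thr,max_val Cut-off values in the
#'   biomarker's unit; they must be strictly increasing in this order.
#' @param direction One of \code{"decrease_good"} or \code{"increase_good"}.
#' @return An object of class \code{"biomarker_spec"}.
#' @examples
#' biomarker_spec("sBP", "mmHg", 50, 70, 120, 160, 266, "decrease_good")
#' @export
biomarker_spec <- function(name, unit, min_val, low_thr, normality_thr,
                           high_thr, max_val,
                           direction = c("decrease_good", "increase_good")) {
  direction <- match.arg(direction)
  cuts <- c(min_val, low_thr, normality_thr, high_thr, max_val)
  if (any(!is.finite(cuts))) {
    stop("biomarker cut-off values must be finite", call. = FALSE)
  }
  if (any(diff(cuts) <= 0)) {
    stop("cut-off values must satisfy min < low < normality < high < max",
         call. = FALSE)
  }
  structure(
    list(name = as.character(name), unit = as.character(unit),
         min_val = min_val, low_thr = low_thr, normality_thr = normality_thr,
         high_thr = high_thr, max_val = max_val, direction = direction),
    class = "biomarker_spec"
  )
}

#' @export
print.biomarker_spec <- function(x, ...) {
  cat(sprintf("<biomarker_spec> %s [%s], %s\n", x$name, x$unit, x$direction))
  cat(sprintf("  min %g | low %g | normality %g | high %g | max %g\n",
              x$min_val, x$low_thr, x$normality_thr, x$high_thr, x$max_val))
  invisible(x)
}

#' Default nine-biomarker clinical panel
#'
#' Returns the clinical cut-off profiles for the nine routinely collected
#' biomarkers used for heart-failure-style risk analysis: BMI, diastolic and
#' systolic blood pressure, fasting glucose, HbA1c, HDL, LDL, total
#' cholesterol, and triglycerides.  The panel ships as a plain CSV resource
#' (\code{extdata/biomarker_panel.csv}) so users can supply an alternative
#' panel for other diseases through \code{path}.
#'
#' @param path Optional path to a panel CSV with columns
#'   \code{name,unit,min,low,normality,high,max,direction}.
#' @return A named list of \code{\link{biomarker_spec}} objects, in stable
#'   panel order, of class \code{"biomarker_panel"}.
#' @examples
#' panel <- default_panel()
#' names(panel)
#' panel$sBP
#' @export
default_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "biomarker_panel.csv", package = "inclinr",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("name", "unit", "min", "low", "normality", "high", "max",
              "direction")
  if (!all(needed %in% names(tab))) {
    stop("panel file must have columns ", paste(needed, collapse = ","),
         call. = FALSE)
  }
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    biomarker_spec(tab$name[i], tab$unit[i], tab$min[i], tab$low[i],
                   tab$normality[i], tab$high[i], tab$max[i],
                   tab$direction[i])
  })
  names(specs) <- tab$name
  structure(specs, class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("<biomarker_panel> %d biomarkers: %s\n",
              length(x), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Relative position of a value between two bounds
#'
#' Shared helper for the linear weighting schemes: the position of
#' \code{value} within \code{[lo, hi]} as a fraction, clamped to [0, 1].
#'
#' @param value Measurement value(s).
#' @param lo,hi Bounds with \code{lo < hi}.
#' @return Fraction(s) in [0, 1].
#' @examples
#' relative_position(115, 70, 160) # 0.5
#' @export
relative_position <- function(value, lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop("relative_position() requires finite bounds with lo < hi",
         call. = FALSE)
  }
  pmin(1, pmax(0, (value - lo) / (hi - lo)))
}
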